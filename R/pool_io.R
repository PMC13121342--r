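#' Convert pooled read counts to allele frequencies
#'
#' The alternate-allele frequency of a cell is `alt / (ref + alt)`; cells
#' with zero total depth are missing. The per-cell depth is retained so that
#' downstream filters can re-mask low-coverage cells.
#'
#' @param counts an [allele_counts()].
#' @return a [freq_matrix()].
#' @export
freq_from_counts <- function(counts) {
  stopifnot(inherits(counts, "allele_counts"))
  depth <- counts$ref + counts$alt
  values <- ifelse(depth > 0, counts$alt / depth, NA_real_)
  freq_matrix(values, depth)
}

#' Filtering configuration for a marker panel
#'
#' @param min_reads minimum per-cell read depth; cells below it are masked
#'   missing before the missing-rate filter.
#' @param max_missing maximum tolerated per-locus missing fraction (after
#'   depth masking); loci exceeding it are dropped.
#' @param maf_min minor-allele-frequency threshold; loci whose MAF (computed
#'   on the average raw frequency over all samples) is <= `maf_min` are
#'   dropped.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(min_reads = 30, max_missing = 0.10, maf_min = 0.05) {
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must lie in [0, 0.5]")
  if (max_missing < 0 || max_missing > 1) stop("max_missing must lie in [0, 1]")
  if (min_reads < 0) stop("min_reads must be nonnegative")
  structure(list(min_reads = min_reads, max_missing = max_missing,
                 maf_min = maf_min), class = "filter_config")
}

#' The standard 20-configuration filtering grid
#'
#' Crosses minimum reads per locus (10, 20, 30, 40) with maximum missing
#' rate (1, 5, 10, 20, 30 percent) at a fixed 5 percent MAF threshold.
#'
#' @param min_reads,max_missing,maf_min grid levels.
#' @return list of [filter_config()] objects, named `r<reads>_m<missing%>`.
#' @export
filter_grid <- function(min_reads = c(10, 20, 30, 40),
                        max_missing = c(0.01, 0.05, 0.10, 0.20, 0.30),
                        maf_min = 0.05) {
  g <- expand.grid(min_reads = min_reads, max_missing = max_missing)
  out <- lapply(seq_len(nrow(g)), function(i)
    filter_config(g$min_reads[i], g$max_missing[i], maf_min))
  names(out) <- sprintf("r%d_m%g", g$min_reads, 100 * g$max_missing)
  out
}

#' Apply depth, missing-rate and MAF filters to a frequency matrix
#'
#' Order of operations: (1) cells with depth below `min_reads` are set
#' missing; (2) loci whose missing fraction then exceeds `max_missing` are
#' dropped; (3) loci whose minor allele frequency -- the minor side of the
#' mean raw frequency over all non-missing samples -- is at or below
#' `maf_min` are dropped. Retained loci keep their original order. Depth
#' masking precedes the missing-rate filter because it changes the missing
#' rate.
#'
#' @param freq a [freq_matrix()].
#' @param cfg a [filter_config()].
#' @return a [freq_matrix()] restricted to passing loci; zero loci is a
#'   legitimate outcome (signalled with a warning, not an error).
#' @export
apply_filter <- function(freq, cfg) {
  stopifnot(inherits(freq, "freq_matrix"), inherits(cfg, "filter_config"))
  values <- freq$values
  depth <- freq$depth
  mask <- depth < cfg$min_reads
  values[mask] <- NA_real_
  depth[mask] <- 0
  miss_frac <- colMeans(is.na(values))
  keep <- miss_frac <= cfg$max_missing
  # drop all-missing loci regardless (MAF undefined)
  keep <- keep & miss_frac < 1
  mean_f <- colMeans(values, na.rm = TRUE)
  maf <- pmin(mean_f, 1 - mean_f)
  keep <- keep & !is.na(maf) & maf > cfg$maf_min
  if (!any(keep)) {
    warning("no locus passed the filter: empty marker panel")
    return(freq_matrix(values[, 0, drop = FALSE], depth[, 0, drop = FALSE]))
  }
  freq_matrix(values[, keep, drop = FALSE], depth[, keep, drop = FALSE])
}

#' Impute missing allele frequencies
#'
#' `method = "mean"` replaces each missing cell with the per-locus mean over
#' observed samples. `method = "rf"` runs iterative random-forest regression
#' on the continuous frequency domain: each locus with missing cells is
#' regressed (via \pkg{randomForest}) on the `k_predictors` complete loci
#' most correlated with it, missing cells are replaced by out-of-sample
#' predictions, and the cycle repeats until the mean absolute change drops
#' below `tol` or `max_iter` passes. Imputed values are clipped to \[0, 1\].
#'
#' @param freq a [freq_matrix()] (typically already filtered).
#' @param method `"rf"` or `"mean"`.
#' @param k_predictors number of complete predictor loci per target locus.
#' @param max_iter,tol iteration controls for `"rf"`.
#' @param ntree forest size per locus.
#' @param seed integer seed for the forests.
#' @return a complete [freq_matrix()]; imputed cells are given depth 1 purely
#'   to satisfy the defined-iff-covered invariant (`imputed` attribute holds
#'   the original mask).
#' @export
impute_freq <- function(freq, method = c("rf", "mean"), k_predictors = 50,
                        max_iter = 10, tol = 1e-4, ntree = 100, seed = 1L) {
  stopifnot(inherits(freq, "freq_matrix"))
  method <- match.arg(method)
  values <- freq$values
  depth <- freq$depth
  miss <- is.na(values)
  if (!any(miss)) return(freq)
  if (any(colMeans(miss) == 1))
    stop("locus missing in all samples; filter it out before imputing")
  locus_means <- colMeans(values, na.rm = TRUE)
  filled <- values
  for (j in which(colSums(miss) > 0)) filled[miss[, j], j] <- locus_means[j]

  if (method == "rf") {
    set.seed(seed)
    complete_loci <- which(colSums(miss) == 0)
    if (length(complete_loci) == 0)
      stop("random-forest imputation needs at least one complete locus")
    targets <- which(colSums(miss) > 0)
    for (it in seq_len(max_iter)) {
      change <- 0
      n_cells <- 0
      for (j in targets) {
        cors <- abs(suppressWarnings(
          stats::cor(filled[, j], filled[, complete_loci, drop = FALSE])))
        cors[is.na(cors)] <- 0
        k <- min(k_predictors, length(complete_loci))
        pred_idx <- complete_loci[order(cors, decreasing = TRUE)[seq_len(k)]]
        obs <- !miss[, j]
        fit <- randomForest::randomForest(
          x = filled[obs, pred_idx, drop = FALSE], y = values[obs, j],
          ntree = ntree)
        new_vals <- stats::predict(fit, filled[!obs, pred_idx, drop = FALSE])
        new_vals <- pmin(pmax(new_vals, 0), 1)
        change <- change + sum(abs(new_vals - filled[!obs, j]))
        n_cells <- n_cells + length(new_vals)
        filled[!obs, j] <- new_vals
      }
      if (change / n_cells < tol) break
    }
  }
  depth_out <- depth
  depth_out[miss] <- 1
  out <- freq_matrix(filled, depth_out)
  attr(out, "imputed") <- miss
  out
}

# ---- readers / writers -----------------------------------------------------

#' Read pooled allele counts from a long-format TSV
#'
#' Expected columns: `sample`, `locus`, `ref_count`, `alt_count`.
#'
#' @param path file path.
#' @return an [allele_counts()].
#' @export
read_counts_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "locus", "ref_count", "alt_count")
  if (!all(need %in% names(d)))
    stop("counts TSV must have columns: ", paste(need, collapse = ", "))
  samples <- unique(d$sample)
  loci <- unique(d$locus)
  ref <- matrix(0L, length(samples), length(loci),
                dimnames = list(samples, loci))
  alt <- ref
  ref[cbind(match(d$sample, samples), match(d$locus, loci))] <- d$ref_count
  alt[cbind(match(d$sample, samples), match(d$locus, loci))] <- d$alt_count
  allele_counts(ref, alt)
}

#' Write pooled allele counts as a long-format TSV
#' @param counts an [allele_counts()].
#' @param path output file path.
#' @export
write_counts_tsv <- function(counts, path) {
  stopifnot(inherits(counts, "allele_counts"))
  d <- data.frame(
    sample = rep(rownames(counts$ref), times = ncol(counts$ref)),
    locus = rep(colnames(counts$ref), each = nrow(counts$ref)),
    ref_count = as.vector(counts$ref),
    alt_count = as.vector(counts$alt))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pooled allele counts from a VCF with per-sample AD fields
#'
#' Only biallelic records are used; multi-allelic records are dropped with a
#' message. AD is parsed as "ref,alt" per sample; a missing AD gives depth 0.
#'
#' @param path VCF file path (plain or gzipped).
#' @return an [allele_counts()] with loci named `CHROM:POS`.
#' @export
read_counts_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt_field <- vcfR::getALT(v)
  biallelic <- !grepl(",", alt_field) & nzchar(alt_field)
  if (!all(biallelic)) {
    message(sum(!biallelic), " multi-allelic or ALT-less records dropped")
    v <- v[biallelic, ]
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad)) stop("VCF has no AD field")
  parse_side <- function(x, i) {
    out <- suppressWarnings(as.integer(vapply(
      strsplit(ifelse(is.na(x), "0,0", x), ","),
      function(p) if (length(p) >= i) p[i] else "0", character(1))))
    out[is.na(out)] <- 0L
    out
  }
  ref <- apply(ad, 2, parse_side, i = 1L)
  alt <- apply(ad, 2, parse_side, i = 2L)
  loci <- paste0(vcfR::getCHROM(v), ":", vcfR::getPOS(v))
  rownames(ref) <- rownames(alt) <- loci
  allele_counts(t(ref), t(alt))
}

#' Write pooled allele counts as a minimal VCF with AD fields
#'
#' Loci are laid out on a single synthetic contig at consecutive positions
#' with placeholder REF/ALT alleles; the only per-sample field is AD.
#'
#' @param counts an [allele_counts()].
#' @param path output file path.
#' @export
write_counts_vcf <- function(counts, path) {
  stopifnot(inherits(counts, "allele_counts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr0>",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(counts$ref)), collapse = "\t")), con)
  for (j in seq_len(ncol(counts$ref))) {
    ad <- paste0(counts$ref[, j], ",", counts$alt[, j])
    writeLines(paste(c("chr0", j, colnames(counts$ref)[j], "A", "T", ".",
                       "PASS", ".", "AD", ad), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a frequency matrix as TSV (samples in rows, loci as columns)
#' @param freq a [freq_matrix()].
#' @param path output file path.
#' @export
write_freq_tsv <- function(freq, path) {
  stopifnot(inherits(freq, "freq_matrix"))
  d <- data.frame(sample = rownames(freq$values), freq$values,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sample-to-population design file (two-column TSV)
#' @param design a [pop_design()].
#' @param path output file path.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-population design file
#' @param path two-column TSV with columns `sample` and `population`.
#' @return a [pop_design()].
#' @export
read_design_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  pop_design(d$sample, d$population)
}

#' Read a plot-level trait table
#' @param path CSV with columns `population`, `block` and one column per trait.
#' @return data.frame.
#' @export
read_trait_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("population", "block") %in% names(d)))
    stop("trait table needs 'population' and 'block' columns")
  d
}

#' Write a plot-level trait table as CSV
#' @param traits data.frame from [simulate_traits()] or [read_trait_csv()].
#' @param path output file path.
#' @export
write_trait_csv <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE)
  invisible(path)
}
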