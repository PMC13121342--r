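#' Allele count matrix from pooled sequencing
#'
#' Container for per-sample, per-locus biallelic read counts of bulked DNA
#' samples. Reference and alternate counts are stored as two integer matrices
#' of identical shape (samples in rows, loci in columns).
#'
#' @param ref,alt nonnegative integer matrices of identical dimension with
#'   sample row names and locus column names.
#' @return an object of class `allele_counts`.
#' @export
allele_counts <- function(ref, alt) {
  ref <- as.matrix(ref)
  alt <- as.matrix(alt)
  if (!identical(dim(ref), dim(alt)))
    stop("ref and alt count matrices must have identical dimensions")
  if (anyNA(ref) || anyNA(alt))
    stop("counts must not contain NA; encode missing cells as depth 0")
  if (any(ref < 0) || any(alt < 0))
    stop("read counts must be nonnegative")
  if (is.null(rownames(ref))) rownames(ref) <- paste0("S", seq_len(nrow(ref)))
  if (is.null(colnames(ref))) colnames(ref) <- paste0("L", seq_len(ncol(ref)))
  dimnames(alt) <- dimnames(ref)
  structure(list(ref = ref, alt = alt), class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("allele_counts: %d samples x %d loci (mean depth %.1f)\n",
              nrow(x$ref), ncol(x$ref), mean(x$ref + x$alt)))
  invisible(x)
}

#' @export
dim.allele_counts <- function(x) dim(x$ref)

#' Allele frequency matrix
#'
#' Per-sample alternate-allele frequencies in \[0, 1\] with an explicit
#' missing mask (NA values) and the read depth behind every cell. A cell has
#' a defined frequency if and only if its depth is positive.
#'
#' @param values numeric matrix in \[0,1\], NA where missing.
#' @param depth nonnegative numeric matrix of identical shape.
#' @return an object of class `freq_matrix`.
#' @export
freq_matrix <- function(values, depth) {
  values <- as.matrix(values)
  depth <- as.matrix(depth)
  if (!identical(dim(values), dim(depth)))
    stop("values and depth must have identical dimensions")
  if (any(depth < 0)) stop("depth must be nonnegative")
  bad <- !is.na(values) & (values < 0 | values > 1)
  if (any(bad)) stop("frequencies must lie in [0, 1]")
  if (any(is.na(values) != (depth == 0)))
    stop("a cell must be missing exactly when its depth is 0")
  dimnames(depth) <- dimnames(values)
  structure(list(values = values, depth = depth), class = "freq_matrix")
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat(sprintf("freq_matrix: %d samples x %d loci, %.2f%% missing\n",
              nrow(x$values), ncol(x$values), 100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.freq_matrix <- function(x) dim(x$values)

#' Sample-to-population design
#'
#' @param sample character vector of bulk sample identifiers.
#' @param population character vector of the population each bulk belongs to.
#' @return a data.frame of class `pop_design` with columns `sample` and
#'   `population`.
#' @export
pop_design <- function(sample, population) {
  if (length(sample) != length(population))
    stop("sample and population must have equal length")
  if (anyDuplicated(sample)) stop("sample identifiers must be unique")
  d <- data.frame(sample = as.character(sample),
                  population = as.character(population),
                  stringsAsFactors = FALSE)
  class(d) <- c("pop_design", "data.frame")
  d
}

#' Replicate counts per population
#' @param design a `pop_design`.
#' @return named integer vector of bulk counts per population.
#' @export
replicates_per_population <- function(design) {
  table(design$population) |> c()
}

check_design_consistency <- function(freq_or_counts, design) {
  samp <- if (inherits(freq_or_counts, "freq_matrix")) rownames(freq_or_counts$values)
          else rownames(freq_or_counts$ref)
  if (!setequal(samp, design$sample))
    stop("sample sets of the data matrix and the design file disagree")
  invisible(TRUE)
}

#' Pairwise distinctness matrix
#'
#' Symmetric logical matrix over populations recording which pairs were
#' declared distinct by a criterion, with optional per-pair evidence kept as
#' the `evidence` attribute (a data.frame with one row per unordered pair).
#'
#' @param populations character vector of population names.
#' @param pairs optional two-column character matrix/data.frame of pairs to
#'   mark distinct.
#' @param evidence optional data.frame of per-pair evidence.
#' @return logical matrix of class `distinctness` with FALSE diagonal.
#' @export
distinctness <- function(populations, pairs = NULL, evidence = NULL) {
  n <- length(populations)
  m <- matrix(FALSE, n, n, dimnames = list(populations, populations))
  if (!is.null(pairs) && NROW(pairs) > 0) {
    pairs <- as.matrix(pairs)
    for (i in seq_len(nrow(pairs))) {
      a <- pairs[i, 1]; b <- pairs[i, 2]
      if (!a %in% populations || !b %in% populations)
        stop("pair refers to unknown population")
      m[a, b] <- TRUE
      m[b, a] <- TRUE
    }
  }
  diag(m) <- FALSE
  structure(m, class = c("distinctness", "matrix"), evidence = evidence)
}

#' Number of distinct pairs in a distinctness matrix
#' @param x a `distinctness` matrix.
#' @return integer count of unordered distinct pairs.
#' @export
n_distinct_pairs <- function(x) sum(x[upper.tri(x)])

#' Completely distinct populations
#'
#' A population is completely distinct when it is distinct from every other
#' population in the comparison set.
#'
#' @param x a `distinctness` matrix.
#' @return character vector of completely distinct population names.
#' @export
completely_distinct <- function(x) {
  n <- nrow(x)
  if (n < 2) return(character(0))
  rownames(x)[rowSums(x) == n - 1L]
}

#' @export
print.distinctness <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("distinctness over %d populations: %d/%d pairs distinct, %d completely distinct\n",
              n, n_distinct_pairs(x), choose(n, 2), length(completely_distinct(x))))
  invisible(x)
}

#' All unordered population pairs
#' @param populations character vector.
#' @return two-column character matrix, one row per unordered pair.
#' @export
population_pairs <- function(populations) {
  if (length(populations) < 2) return(matrix(character(0), 0, 2))
  t(utils::combn(populations, 2))
}
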