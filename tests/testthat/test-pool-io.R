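test_that("frequencies from counts follow alt/(ref+alt) with depth-0 missing", {
  ac <- allele_counts(ref = rbind(c(5, 0, 10)), alt = rbind(c(5, 0, 30)))
  fr <- freq_from_counts(ac)
  expect_equal(unname(fr$values[1, ]), c(0.5, NA, 0.75))
  expect_equal(unname(fr$depth[1, ]), c(10, 0, 40))
  expect_error(allele_counts(rbind(-1), rbind(2)), "nonnegative")
})

test_that("the standard filtering grid has exactly 20 configurations", {
  g <- filter_grid()
  expect_length(g, 20)
  combos <- unique(t(vapply(g, function(x) c(x$min_reads, x$max_missing),
                            numeric(2))))
  expect_equal(nrow(combos), 20)
  expect_true(all(vapply(g, function(x) x$maf_min == 0.05, logical(1))))
})

test_that("MAF and missing-rate thresholds drop the loci they should", {
  # locus 1: mean freq 0.04 (below MAF); locus 2: common; locus 3: 2/33 missing
  n <- 33
  vals <- cbind(rep(0.04, n), rep(0.5, n), rep(0.5, n))
  colnames(vals) <- c("V1", "V2", "V3")
  depth <- matrix(50, n, 3)
  depth[1:2, 3] <- 0
  vals[1:2, 3] <- NA
  fr <- freq_matrix(vals, depth)
  kept_strict <- colnames(apply_filter(fr, filter_config(10, 0.05))$values)
  expect_equal(kept_strict, "V2")
  kept_loose <- colnames(apply_filter(fr, filter_config(10, 0.10))$values)
  expect_equal(kept_loose, c("V2", "V3"))
})

test_that("depth masking happens before the missing-rate filter", {
  # depth 15 cells survive min_reads = 10 but are masked at min_reads = 20,
  # pushing the locus over a 10% missing budget
  n <- 20
  vals <- matrix(0.5, n, 1)
  depth <- matrix(50, n, 1)
  depth[1:5, 1] <- 15
  fr <- freq_matrix(vals, depth)
  expect_equal(ncol(apply_filter(fr, filter_config(10, 0.10))$values), 1)
  expect_warning(out <- apply_filter(fr, filter_config(20, 0.10)),
                 "empty marker panel")
  expect_equal(ncol(out$values), 0)
})

test_that("filtering is monotone in its thresholds and idempotent", {
  cfg <- sim_config(n_pops = 5, n_markers = 300, fst = 0.05,
                    missing_rate = 0.1, seed = 21)
  fr <- freq_from_counts(simulate_bulks(
    simulate_population_frequencies(cfg)$pop_freqs, cfg)$counts)
  grid <- filter_grid()
  kept <- lapply(grid, function(g)
    colnames(suppressWarnings(apply_filter(fr, g))$values))
  strict <- kept[["r40_m1"]]
  loose <- kept[["r10_m30"]]
  expect_true(all(strict %in% loose))
  # tightening max_missing at fixed min_reads never adds a locus
  for (r in c(10, 20, 30, 40)) {
    for (mm in list(c(0.01, 0.05), c(0.05, 0.10), c(0.10, 0.20), c(0.20, 0.30))) {
      a <- kept[[sprintf("r%d_m%g", r, 100 * mm[1])]]
      b <- kept[[sprintf("r%d_m%g", r, 100 * mm[2])]]
      expect_true(all(a %in% b))
    }
  }
  g <- filter_grid()[["r30_m10"]]
  once <- apply_filter(fr, g)
  twice <- apply_filter(once, g)
  expect_identical(once$values, twice$values)
})

test_that("mean imputation fills with the per-locus mean and is a no-op when complete", {
  fr <- toy_freq(matrix(c(0.2, 0.4, 0.6, 0.8), 2, 2))
  expect_identical(impute_freq(fr, "mean"), fr)
  vals <- matrix(c(0.2, 0.4, NA, 0.6, 0.8, 0.7), 3, 2)
  depth <- matrix(c(10, 10, 0, 10, 10, 10), 3, 2)
  fr2 <- freq_matrix(vals, depth)
  out <- impute_freq(fr2, "mean")
  expect_equal(out$values[3, 1], 0.3)
  expect_error(impute_freq(freq_matrix(cbind(c(NA, NA)), cbind(c(0, 0))), "mean"),
               "missing in all samples")
})

test_that("random-forest imputation beats the mean baseline on MCAR holes", {
  cfg <- sim_config(n_pops = 5, n_markers = 150, fst = 0.1,
                    missing_rate = 0, mean_depth = 200, seed = 22)
  fr <- freq_from_counts(simulate_bulks(
    simulate_population_frequencies(cfg)$pop_freqs, cfg)$counts)
  truth <- fr$values
  set.seed(23)
  holes <- matrix(runif(length(truth)) < 0.05, nrow(truth), ncol(truth))
  holes[, colSums(!holes) < 2] <- FALSE   # keep every locus estimable
  vals <- truth; vals[holes] <- NA
  depth <- fr$depth; depth[holes] <- 0
  fr_h <- freq_matrix(vals, depth)
  rmse <- function(x) sqrt(mean((x$values[holes] - truth[holes])^2))
  r_mean <- rmse(impute_freq(fr_h, "mean"))
  r_rf <- rmse(impute_freq(fr_h, "rf", k_predictors = 30, ntree = 50,
                           seed = 24))
  expect_lte(r_rf, r_mean)
  expect_false(anyNA(impute_freq(fr_h, "rf", k_predictors = 30, ntree = 50,
                                 seed = 24)$values))
})

test_that("TSV and VCF round trips preserve the counts", {
  cfg <- sim_config(n_pops = 3, n_markers = 25, fst = 0.1, seed = 25)
  counts <- simulate_bulks(simulate_population_frequencies(cfg)$pop_freqs,
                           cfg)$counts
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(counts, tsv)
  back <- read_counts_tsv(tsv)
  expect_equal(back$ref, counts$ref)
  expect_equal(back$alt, counts$alt)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_counts_vcf(counts, vcf)
  back2 <- read_counts_vcf(vcf)
  expect_equal(unname(back2$ref), unname(counts$ref))
  expect_equal(unname(back2$alt), unname(counts$alt))
})
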