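test_that("pair PCA gives five axes for six bulks in general position", {
  x <- two_pop_freq(seed = 51)
  fr <- toy_freq(x)
  sc <- pair_pca(fr, two_pop_design(), c("A", "B"))
  expect_equal(sc$n_axes, 5)
  # degenerate input: duplicated bulks lose axes but do not crash
  x2 <- x
  x2[2, ] <- x2[1, ]
  x2[5, ] <- x2[4, ]
  sc2 <- pair_pca(toy_freq(x2), two_pop_design(), c("A", "B"))
  expect_lt(sc2$n_axes, 5)
})

test_that("pair PCA equals an independent PCA of the six-bulk submatrix", {
  x <- two_pop_freq(seed = 52)
  sc <- pair_pca(toy_freq(x), two_pop_design(), c("A", "B"))
  pr <- prcomp(x, center = TRUE, scale. = FALSE)
  for (a in seq_len(sc$n_axes))
    expect_equal(abs(unname(sc$scores[, a])), abs(unname(pr$x[, a])),
                 tolerance = 1e-8)
})

test_that("well-separated clouds classify 6/6 at k = 1", {
  x <- two_pop_freq(gap = 0.5, spread = 0.005, seed = 53)
  sc <- pair_pca(toy_freq(x), two_pop_design(), c("A", "B"))
  res <- loo_lda(sc, two_pop_design(), k = 1)
  expect_equal(res$n_correct, 6)
  expect_true(res$distinct)
})

test_that("exchangeable populations classify near chance and are rarely distinct", {
  n_sim <- 200
  correct <- integer(n_sim)
  distinct <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    set.seed(500 + i)
    x <- matrix(runif(6 * 30, 0.3, 0.7), 6, 30,
                dimnames = list(c("A_1", "A_2", "A_3", "B_1", "B_2", "B_3"),
                                paste0("L", 1:30)))
    res <- loo_lda(pair_pca(toy_freq(x), two_pop_design(), c("A", "B")),
                   two_pop_design(), k = 2)
    correct[i] <- res$n_correct
    distinct[i] <- res$distinct
  }
  expect_gt(mean(correct), 2)
  expect_lt(mean(correct), 4)
  expect_lt(mean(distinct), 0.2)
})

test_that("k above the within-class df takes the ridge path without error", {
  x <- two_pop_freq(seed = 54)
  sc <- pair_pca(toy_freq(x), two_pop_design(), c("A", "B"))
  res <- loo_lda(sc, two_pop_design(), k = 5)
  expect_true(res$n_correct >= 0 && res$n_correct <= 6)
})

test_that("swapping population labels leaves the correct count unchanged", {
  x <- two_pop_freq(gap = 0.2, spread = 0.05, seed = 55)
  d1 <- two_pop_design()
  d2 <- pop_design(d1$sample, c("B", "B", "B", "A", "A", "A"))
  fr <- toy_freq(x)
  for (k in 1:5) {
    r1 <- loo_lda(pair_pca(fr, d1, c("A", "B")), d1, k)
    r2 <- loo_lda(pair_pca(fr, d2, c("A", "B")), d2, k)
    expect_equal(r1$n_correct, r2$n_correct)
  }
})

test_that("fold predictions agree with MASS::lda on a nonsingular case", {
  skip_if_not_installed("MASS")
  x <- two_pop_freq(gap = 0.15, spread = 0.05, seed = 56)
  design <- two_pop_design()
  sc <- pair_pca(toy_freq(x), design, c("A", "B"))
  k <- 2
  xs <- sc$scores[, 1:k]
  lab <- design$population
  for (i in 1:6) {
    ours <- poolDUS:::lda_predict(xs[-i, ], lab[-i], xs[i, ])
    fit <- MASS::lda(xs[-i, ], grouping = lab[-i], prior = c(0.5, 0.5))
    theirs <- as.character(predict(fit, xs[i, , drop = FALSE])$class)
    expect_equal(ours, theirs)
  }
})

test_that("the all-pairs sweep covers every pair at every k and handles degenerate data", {
  cfg <- sim_config(n_pops = 11, n_markers = 200, fst = 0.1, seed = 57)
  ds <- simulate_dataset(cfg)
  fr <- impute_freq(freq_from_counts(ds$counts), "mean")
  sw <- sweep_pairs(fr, ds$design)
  expect_equal(nrow(sw$table), 55 * 5)
  expect_true(all(table(sw$table$k) == 55))
  expect_true(all(sw$table$n_correct >= 0 & sw$table$n_correct <= 6))

  # identical populations everywhere: nothing distinct, no crash
  const <- toy_freq(matrix(0.5, 6, 20,
                           dimnames = list(two_pop_design()$sample, NULL)))
  sw0 <- sweep_pairs(const, two_pop_design())
  expect_equal(n_distinct_pairs(sw0$distinctness), 0)
  expect_length(completely_distinct(sw0$distinctness), 0)
})

test_that("the strict per-fold PCA refit variant agrees on easy pairs", {
  x <- two_pop_freq(gap = 0.5, spread = 0.005, seed = 58)
  fr <- toy_freq(x)
  sw_leaky <- sweep_pairs(fr, two_pop_design())
  sw_strict <- sweep_pairs(fr, two_pop_design(), refit_per_fold = TRUE)
  expect_true(all(sw_leaky$table$distinct))
  expect_true(all(sw_strict$table$distinct))
})
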