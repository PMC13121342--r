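test_that("sample distances match their defining formulas", {
  set.seed(71)
  x <- matrix(runif(5 * 20), 5, 20,
              dimnames = list(paste0("S", 1:5), paste0("L", 1:20)))
  d_cor <- sample_distance(x, "correlation")
  d_euc <- sample_distance(x, "euclidean")
  for (i in 1:5) for (j in 1:5) {
    expect_equal(d_cor[i, j], 1 - cor(x[i, ], x[j, ]), tolerance = 1e-12)
    expect_equal(d_euc[i, j], sqrt(sum((x[i, ] - x[j, ])^2)),
                 tolerance = 1e-12)
  }
  # identical and anti-correlated vectors hit the metric extremes
  y <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1))
  d <- sample_distance(y, "correlation")
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2)
  expect_error(sample_distance(rbind(a = c(1, 1, 1), b = 1:3), "correlation"),
               "constant")
})

test_that("UPGMA reproduces the hand-worked three-leaf merge", {
  d <- matrix(c(0, 2, 8,
                2, 0, 8,
                8, 8, 0), 3, 3, dimnames = list(c("A", "B", "C"),
                                                c("A", "B", "C")))
  tr <- upgma(d)
  expect_equal(sort(tr$clades[[1]]), c("A", "B"))
  expect_equal(tr$height, c(1, 4))
  # two leaves: one merge at half the distance
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  expect_equal(upgma(d2)$height, 1.5)
})

test_that("UPGMA is exact on ultrametric input and matches hclust average linkage", {
  set.seed(72)
  x <- matrix(rnorm(7 * 12), 7, 12, dimnames = list(paste0("S", 1:7), NULL))
  d <- as.matrix(dist(x))
  tr <- upgma(d)
  hc <- hclust(as.dist(d), method = "average")
  expect_equal(unname(cophenetic_upgma(tr)[paste0("S", 1:7), paste0("S", 1:7)]),
               unname(as.matrix(cophenetic(hc))[paste0("S", 1:7),
                                                paste0("S", 1:7)]),
               tolerance = 1e-10)
  # feeding the ultrametric cophenetic matrix back reproduces it exactly
  co <- cophenetic_upgma(tr)
  expect_equal(cophenetic_upgma(upgma(co)), co, tolerance = 1e-10)
})

test_that("tie-breaking makes the tree invariant to leaf input order", {
  set.seed(73)
  x <- matrix(runif(6 * 15), 6, 15,
              dimnames = list(c("F_1", "A_1", "C_1", "B_1", "E_1", "D_1"), NULL))
  d <- sample_distance(x)
  perm <- c(4, 1, 6, 2, 5, 3)
  t1 <- upgma(d)
  t2 <- upgma(d[perm, perm])
  expect_equal(t1$clades, t2$clades)
  expect_equal(t1$height, t2$height)
})

test_that("the AU fit honours its closed-form fixed points", {
  scales <- seq(0.5, 1.4, by = 0.1)
  B <- 1000
  # BP = 0.5 at every scale: z = 0, v = c = 0, AU = 1 - pnorm(0) = 0.5
  expect_equal(poolDUS:::fit_au_profile(rep(B / 2, 10), scales, B), 0.5,
               tolerance = 1e-12)
  # present in every resample at every scale: AU at the clamped maximum
  expect_equal(poolDUS:::fit_au_profile(rep(B, 10), scales, B), 1 - 1 / (B + 1))
  # never present: AU at the floor
  expect_equal(poolDUS:::fit_au_profile(rep(0, 10), scales, B), 1 / (B + 1))
})

test_that("clearly separated populations earn AU >= 0.95 on their replicate clades", {
  hits <- 0L
  for (seed in 1:5) {
    x <- two_pop_freq(n_loci = 300, gap = 0.3, spread = 0.01, seed = seed)
    sup <- multiscale_au(toy_freq(x), B = 200, seed = 80 + seed)
    cd <- distinct_by_cluster(sup, two_pop_design())
    if (setequal(cd, c("A", "B"))) hits <- hits + 1L
  }
  expect_gte(hits, 5 * 0.95 - 1)  # allow one failure in five runs
})

test_that("AU and BP order consistently on scale-stable nodes", {
  x <- two_pop_freq(n_loci = 200, gap = 0.25, spread = 0.02, seed = 74)
  sup <- multiscale_au(toy_freq(x), B = 200, seed = 75)
  stable <- apply(sup$bp_table, 1, function(b) diff(range(b)) < 0.05)
  if (sum(stable) >= 2) {
    ord_bp <- order(sup$bp[stable])
    ord_au <- order(sup$au[stable])
    expect_equal(ord_bp, ord_au)
  }
  expect_true(all(sup$au >= 0 & sup$au <= 1))
})

test_that("the exclusive-clade rule needs monophyly and the threshold", {
  x <- two_pop_freq(seed = 76)
  tr <- upgma(sample_distance(x))
  sig <- sapply(tr$clades, paste, collapse = "\r")
  a_clade <- match(paste(c("A_1", "A_2", "A_3"), collapse = "\r"), sig)
  au <- rep(0.5, length(sig))
  mk <- function(au) structure(list(tree = tr, au = au), class = "support_tree")
  expect_length(distinct_by_cluster(mk(au), two_pop_design()), 0)
  au2 <- au; au2[a_clade] <- 0.97
  expect_equal(as.character(distinct_by_cluster(mk(au2), two_pop_design())), "A")
  au3 <- au; au3[a_clade] <- 0.90
  expect_length(distinct_by_cluster(mk(au3), two_pop_design()), 0)
})

test_that("newick export is a valid tree with the right tips and support labels", {
  skip_if_not_installed("ape")
  x <- two_pop_freq(seed = 77)
  sup <- multiscale_au(toy_freq(x), B = 50, seed = 78)
  nwk <- write_newick(sup)
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, rownames(x))
  expect_true(ape::is.ultrametric(tr, tol = 1e-6))
})
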