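test_that("RCB sums of squares and p-value match the aov oracle", {
  for (seed in 1:3) {
    tab <- toy_rcb(n_pops = 3, n_blocks = 2, pop_effects = c(0, 1, 2),
                   seed = seed)
    res <- rcb_anova(tab, "y")
    fit <- stats::aov(y ~ factor(population) + factor(block), data = tab)
    an <- summary(fit)[[1]]
    expect_equal(res$p, an[["Pr(>F)"]][1], tolerance = 1e-12)
    expect_equal(res$f, an[["F value"]][1], tolerance = 1e-12)
    expect_equal(res$mse, an[["Mean Sq"]][3], tolerance = 1e-12)
  }
})

test_that("zero error mean square makes every unequal pair distinct", {
  # perfectly additive table: population + block effects, no noise
  g <- expand.grid(block = 1:3, population = c("A", "B", "C"),
                   stringsAsFactors = FALSE)
  g$y <- c(A = 1, B = 1, C = 5)[g$population] + g$block
  res <- rcb_anova(g, "y")
  expect_equal(res$p, 0)
  expect_equal(res$lsd, 0)
  got <- apply(res$distinct_pairs, 1, paste, collapse = "-")
  expect_setequal(got, c("A-C", "B-C"))
})

test_that("the angular transform is applied to proportion traits", {
  g <- expand.grid(block = 1:4, population = c("A", "B"),
                   stringsAsFactors = FALSE)
  set.seed(31)
  g$p <- runif(nrow(g), 0.1, 0.4)
  res <- rcb_anova(g, "p", proportion = TRUE)
  expect_true(res$transform)
  expect_equal(unname(res$means_analysis_scale),
               unname(tapply(asin(sqrt(g$p)), g$population, mean)),
               tolerance = 1e-12)
  # reported means stay on the original scale
  expect_equal(unname(res$means), unname(tapply(g$p, g$population, mean)))
})

test_that("unbalanced designs are rejected", {
  tab <- toy_rcb(n_pops = 3, n_blocks = 3)[-1, ]
  expect_error(rcb_anova(tab, "y"), "unbalanced")
})

test_that("the growth-habit rule uses a strict 1.5-unit threshold", {
  expect_equal(nrow(habit_rule(c(A = 1.0, B = 1.6, C = 2.0))$distinct_pairs), 0)
  expect_equal(nrow(habit_rule(c(A = 1.0, B = 2.6))$distinct_pairs), 1)
  expect_equal(nrow(habit_rule(c(A = 1.0, B = 2.5))$distinct_pairs), 0)
})

test_that("normality diagnostic flags non-normal residuals and handles edge cases", {
  expect_error(normality_check(c(1, 2)), "at least 3")
  const <- normality_check(rep(1, 10))
  expect_true(is.na(const$p))
  expect_match(const$note, "constant")
  set.seed(32)
  p_exp <- replicate(100, normality_check(rexp(50))$p)
  expect_gt(mean(p_exp < 0.05), 0.6)
  p_norm <- replicate(100, normality_check(rnorm(50))$p)
  expect_gt(mean(p_norm), 0.3)  # roughly uniform p under normality
  expect_lt(mean(p_norm), 0.7)
})

test_that("protected LSD can only shrink the distinct set", {
  for (seed in 1:20) {
    tab <- toy_rcb(n_pops = 6, n_blocks = 5,
                   pop_effects = rnorm(6, 0, 0.8), seed = 100 + seed)
    gated <- rcb_anova(tab, "y", gate_alpha = 0.05)
    ungated <- rcb_anova(tab, "y", gate_alpha = 1)
    g1 <- apply(gated$distinct_pairs, 1, paste, collapse = "-")
    g2 <- apply(ungated$distinct_pairs, 1, paste, collapse = "-")
    expect_true(all(g1 %in% g2))
  }
})

test_that("combining traits ORs the evidence and finds completely distinct populations", {
  pops <- make_pop_labels(11)
  none <- structure(list(trait = "t1", p = 0.5, means = setNames(rep(1, 11), pops),
                         distinct_pairs = matrix(character(0), 0, 2)),
                    class = "trait_result")
  dm0 <- combine_morpho(list(none))
  expect_equal(n_distinct_pairs(dm0), 0)
  expect_length(completely_distinct(dm0), 0)
  expect_equal(choose(nrow(dm0), 2), 55)

  # one trait separates population A from all others
  sep <- structure(list(trait = "t2", p = 0.001, means = setNames(rep(1, 11), pops),
                        distinct_pairs = cbind(rep("A", 10), pops[-1])),
                   class = "trait_result")
  dm1 <- combine_morpho(list(none, sep))
  expect_equal(completely_distinct(dm1), "A")
  expect_equal(n_distinct_pairs(dm1), 10)
  expect_true(isSymmetric(unclass(dm1)))
  expect_false(any(diag(dm1)))
})

test_that("the full morpho analysis returns a per-trait report shaped like a DUS table", {
  cfg <- sim_config(n_pops = 6, seed = 33)
  tr <- simulate_traits(cfg)
  out <- morpho_analysis(tr)
  expect_equal(nrow(out$report), 10)
  expect_true(all(c("trait", "range_min", "range_max", "significance",
                    "n_distinct", "proportion_pct") %in% names(out$report)))
  # growth habit goes through the ordinal rule, not ANOVA
  expect_equal(out$report$significance[out$report$trait == "growth_habit"],
               "rule")
  expect_s3_class(out$distinctness, "distinctness")
})
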