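#' Randomized-complete-block ANOVA for one trait with protected LSD
#'
#' Fits the balanced two-way fixed-effects model (population + block) by the
#' direct sum-of-squares decomposition, then -- only when the overall
#' population effect is significant at `gate_alpha` -- performs all pairwise
#' comparisons with Fisher's least significant difference at `lsd_alpha`:
#' a pair is distinct iff |mean_i - mean_j| > t(1 - alpha/2, df_error) *
#' sqrt(2 MSE / b), with b the number of blocks. Proportion traits are
#' angular-transformed, y = arcsin(sqrt(p)) in radians, before analysis
#' (means are reported on the original scale). A zero error mean square is a
#' legitimate degenerate case: the LSD is then 0 and any pair with unequal
#' means is distinct.
#'
#' @param table data.frame with columns `population`, `block` and the trait.
#' @param trait trait column name.
#' @param proportion logical; apply the angular transform.
#' @param gate_alpha overall-F gate (default 0.05).
#' @param lsd_alpha pairwise LSD level (default 0.01).
#' @return list of class `trait_result`: trait name, overall `f` and `p`,
#'   population `means` (original scale), `lsd`, `distinct_pairs` (2-column
#'   character matrix), `residuals`, `transform` flag.
#' @export
rcb_anova <- function(table, trait, proportion = FALSE,
                      gate_alpha = 0.05, lsd_alpha = 0.01) {
  if (!trait %in% names(table)) stop("unknown trait: ", trait)
  pop <- as.character(table$population)
  block <- as.character(table$block)
  y_raw <- table[[trait]]
  pops <- unique(pop)
  blocks <- unique(block)
  t_n <- length(pops)
  b_n <- length(blocks)
  if (t_n < 2 || b_n < 2) stop("need at least 2 populations and 2 blocks")
  tab <- table(pop, block)
  if (any(tab != 1))
    stop("unbalanced design: every population must appear exactly once per block")
  y <- if (proportion) asin(sqrt(y_raw)) else y_raw

  grand <- mean(y)
  pop_means <- tapply(y, pop, mean)[pops]
  block_means <- tapply(y, block, mean)[blocks]
  ss_pop <- b_n * sum((pop_means - grand)^2)
  ss_block <- t_n * sum((block_means - grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_err <- max(ss_total - ss_pop - ss_block, 0)
  # cancellation guard: an error SS below float precision of the total is 0
  if (ss_err < 1e-12 * ss_total) ss_err <- 0
  df_pop <- t_n - 1
  df_err <- (t_n - 1) * (b_n - 1)
  mse <- ss_err / df_err
  ms_pop <- ss_pop / df_pop
  if (mse == 0) {
    f <- if (ms_pop == 0) NaN else Inf
    p <- if (ms_pop == 0) 1 else 0
  } else {
    f <- ms_pop / mse
    p <- stats::pf(f, df_pop, df_err, lower.tail = FALSE)
  }

  fitted <- pop_means[pop] + block_means[block] - grand
  resid <- y - fitted

  lsd <- stats::qt(1 - lsd_alpha / 2, df_err) * sqrt(2 * mse / b_n)
  pairs <- matrix(character(0), 0, 2)
  if (p < gate_alpha) {
    pr <- population_pairs(pops)
    hit <- abs(pop_means[pr[, 1]] - pop_means[pr[, 2]]) > lsd
    pairs <- pr[hit, , drop = FALSE]
  }

  means_raw <- tapply(y_raw, pop, mean)[pops]
  structure(list(trait = trait, f = f, p = p, means = means_raw,
                 means_analysis_scale = pop_means, lsd = lsd, mse = mse,
                 df_error = df_err, distinct_pairs = pairs,
                 residuals = resid, transform = proportion),
            class = "trait_result")
}

#' Ordinal growth-habit distinctness rule
#'
#' Two populations differ for a trait scored on a discrete 1-9 scale when
#' their mean scores differ by strictly more than `threshold` units.
#'
#' @param means named numeric vector of per-population mean scores.
#' @param threshold difference needed to call a pair distinct (default 1.5).
#' @return list of class `trait_result` (with `p = NA`; the rule has no test).
#' @export
habit_rule <- function(means, threshold = 1.5) {
  if (is.null(names(means))) stop("means must be named by population")
  pr <- population_pairs(names(means))
  hit <- abs(means[pr[, 1]] - means[pr[, 2]]) > threshold
  structure(list(trait = "growth_habit", f = NA_real_, p = NA_real_,
                 means = means, lsd = threshold,
                 distinct_pairs = pr[hit, , drop = FALSE],
                 residuals = NULL, transform = FALSE),
            class = "trait_result")
}

#' Shapiro-Wilk normality diagnostic for ANOVA residuals
#'
#' Reported as a diagnostic only; it never gates the analysis.
#'
#' @param residuals numeric vector, n >= 3.
#' @return list with `statistic`, `p` and a `note` (non-NULL when the test is
#'   undefined, e.g. constant residuals).
#' @export
normality_check <- function(residuals) {
  residuals <- residuals[!is.na(residuals)]
  if (length(residuals) < 3) stop("Shapiro-Wilk needs at least 3 residuals")
  if (stats::sd(residuals) == 0)
    return(list(statistic = NA_real_, p = NA_real_,
                note = "constant residuals: statistic undefined"))
  sw <- stats::shapiro.test(residuals)
  list(statistic = unname(sw$statistic), p = sw$p.value, note = NULL)
}

#' Combine per-trait results into a distinctness matrix
#'
#' A pair is distinct when at least one trait separates it; a population is
#' completely distinct when it is distinct from every other.
#'
#' @param results list of `trait_result` objects (from [rcb_anova()] and/or
#'   [habit_rule()]) sharing one population set.
#' @param populations optional population vector (defaults to the union of
#'   the first result's means' names).
#' @return a [distinctness()] matrix; the per-pair supporting traits are kept
#'   in the `evidence` attribute.
#' @export
combine_morpho <- function(results, populations = NULL) {
  if (length(results) == 0) stop("no trait results to combine")
  if (is.null(populations)) populations <- names(results[[1]]$means)
  ev <- list()
  for (r in results) {
    if (!setequal(names(r$means), populations))
      stop("trait results disagree on the population set")
    if (nrow(r$distinct_pairs) > 0)
      ev[[r$trait]] <- data.frame(pop1 = pmin(r$distinct_pairs[, 1], r$distinct_pairs[, 2]),
                                  pop2 = pmax(r$distinct_pairs[, 1], r$distinct_pairs[, 2]),
                                  trait = r$trait, stringsAsFactors = FALSE)
  }
  ev <- if (length(ev)) do.call(rbind, ev) else
    data.frame(pop1 = character(0), pop2 = character(0), trait = character(0))
  distinctness(populations, pairs = unique(ev[, c("pop1", "pop2")]),
               evidence = ev)
}

#' Full morphophysiological distinctness analysis
#'
#' Runs [rcb_anova()] on every trait column of a plot table (angular
#' transform for proportion traits), applies the ordinal rule to the
#' growth-habit trait, and combines everything with [combine_morpho()].
#'
#' @param traits plot table with columns `population`, `block`, one column
#'   per trait.
#' @param proportion_traits character vector of proportion trait names
#'   (default: columns whose values all lie in \[0,1\]).
#' @param habit_trait name of the ordinal growth-habit column, or NULL.
#' @param habit_threshold ordinal rule threshold.
#' @param gate_alpha,lsd_alpha see [rcb_anova()].
#' @return list with `results` (per-trait), `distinctness`, `report`
#'   (per-trait summary data.frame: range, significance, distinct pairs).
#' @export
morpho_analysis <- function(traits, proportion_traits = NULL,
                            habit_trait = "growth_habit",
                            habit_threshold = 1.5,
                            gate_alpha = 0.05, lsd_alpha = 0.01) {
  trait_cols <- setdiff(names(traits), c("population", "block"))
  if (is.null(proportion_traits)) {
    proportion_traits <- trait_cols[vapply(trait_cols, function(tc) {
      v <- traits[[tc]]
      all(v >= 0 & v <= 1)
    }, logical(1))]
  }
  results <- list()
  for (tc in trait_cols) {
    if (!is.null(habit_trait) && tc == habit_trait) {
      means <- tapply(traits[[tc]], as.character(traits$population), mean)
      results[[tc]] <- habit_rule(means, habit_threshold)
    } else {
      results[[tc]] <- rcb_anova(traits, tc,
                                 proportion = tc %in% proportion_traits,
                                 gate_alpha = gate_alpha,
                                 lsd_alpha = lsd_alpha)
    }
  }
  dm <- combine_morpho(results)
  n_pairs <- choose(nrow(dm), 2)
  report <- do.call(rbind, lapply(results, function(r) data.frame(
    trait = r$trait,
    range_min = min(r$means), range_max = max(r$means),
    p = r$p,
    significance = if (is.na(r$p)) "rule" else if (r$p < 0.01) "**"
                   else if (r$p < 0.05) "*" else "NS",
    n_distinct = nrow(r$distinct_pairs),
    proportion_pct = 100 * nrow(r$distinct_pairs) / n_pairs,
    stringsAsFactors = FALSE)))
  rownames(report) <- NULL
  list(results = results, distinctness = dm, report = report)
}
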