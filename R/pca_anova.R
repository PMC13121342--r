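#' Principal component scores of a bulk frequency matrix
#'
#' Columns (loci) are mean-centered but not variance-scaled (allele
#' frequencies share a scale), then decomposed by SVD. Axes are ordered by
#' nonincreasing variance; axes with numerically zero singular value are
#' dropped, so a constant matrix yields zero axes.
#'
#' @param freq a complete [freq_matrix()] (no missing cells) or a plain
#'   numeric matrix, samples in rows.
#' @param scale. also scale loci to unit variance (default FALSE).
#' @return list of class `pc_scores`: `scores` (samples x axes), `sdev`,
#'   `var_explained`, `n_axes`.
#' @export
pca_scores <- function(freq, scale. = FALSE) {
  x <- if (inherits(freq, "freq_matrix")) freq$values else as.matrix(freq)
  if (anyNA(x)) stop("PCA input must be complete; impute first")
  if (nrow(x) < 3) stop("PCA needs at least 3 samples")
  xc <- scale(x, center = TRUE, scale = scale.)
  sv <- svd(xc)
  tol <- max(sv$d) * 1e-10
  keep <- sv$d > tol
  if (max(sv$d) == 0 || !any(keep)) {
    return(structure(list(
      scores = matrix(0, nrow(x), 0, dimnames = list(rownames(x), NULL)),
      sdev = numeric(0), var_explained = numeric(0), n_axes = 0L),
      class = "pc_scores"))
  }
  d <- sv$d[keep]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(d, length(d))
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_along(d)))
  structure(list(scores = scores, sdev = d / sqrt(nrow(x) - 1),
                 var_explained = d^2 / sum(sv$d^2), n_axes = length(d)),
            class = "pc_scores")
}

# One-way ANOVA + all-pairs LSD on a single score vector.
# Returns overall p, per-pair significance at alpha, group means, MSE.
anova_lsd <- function(y, groups, alpha = 0.01) {
  groups <- as.character(groups)
  g <- unique(groups)
  n_i <- table(groups)[g]
  if (any(n_i < 2)) stop("every population needs at least 2 replicates")
  grand <- mean(y)
  means <- tapply(y, groups, mean)[g]
  ss_among <- sum(n_i * (means - grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_within <- max(ss_total - ss_among, 0)
  if (ss_within < 1e-12 * ss_total) ss_within <- 0
  df_among <- length(g) - 1
  df_err <- length(y) - length(g)
  mse <- ss_within / df_err
  if (mse == 0) {
    p <- if (ss_among == 0) 1 else 0
  } else {
    p <- stats::pf((ss_among / df_among) / mse, df_among, df_err,
                   lower.tail = FALSE)
  }
  pr <- population_pairs(g)
  tcrit <- stats::qt(1 - alpha / 2, df_err)
  lsd_pair <- tcrit * sqrt(mse * (1 / n_i[pr[, 1]] + 1 / n_i[pr[, 2]]))
  sig <- abs(means[pr[, 1]] - means[pr[, 2]]) > lsd_pair
  list(p_overall = p, pairs = pr, significant = unname(sig),
       means = means, mse = mse, df_error = df_err)
}

#' Sequential per-axis ANOVA distinctness scan
#'
#' Walks the PC axes in order. On each axis, a one-way ANOVA of the sample
#' scores by population is followed by all-pairs Fisher LSD comparisons at
#' `alpha` (unprotected by default; set `protected = TRUE` to require the
#' overall F test at `protect_alpha` first). Pairs newly exceeding the LSD
#' are marked distinct with that axis recorded as their first distinguishing
#' axis. The scan stops once `stop_after` consecutive axes flag nothing, or
#' when axes run out.
#'
#' @param scores a [pca_scores()] result.
#' @param design a [pop_design()] covering all score rows.
#' @param alpha pairwise LSD level (default 0.01).
#' @param stop_after number of consecutive uninformative axes that ends the
#'   scan (default 3).
#' @param protected gate each axis's comparisons on its overall F test.
#' @param protect_alpha gate level when `protected`.
#' @param stopping `"new_pairs"` (default): an axis counts as uninformative
#'   when it separates no not-yet-distinct pair; `"any_pair"`: when it
#'   separates no pair at all, including already-distinct ones.
#' @return list of class `sequential_result`: `distinctness`, `first_axis`
#'   (data.frame pair -> axis), `axes_examined`, `overall_p` per axis.
#' @export
sequential_axis_test <- function(scores, design, alpha = 0.01, stop_after = 3,
                                 protected = FALSE, protect_alpha = 0.05,
                                 stopping = c("new_pairs", "any_pair")) {
  stopifnot(inherits(scores, "pc_scores"))
  stopping <- match.arg(stopping)
  idx <- match(design$sample, rownames(scores$scores))
  if (anyNA(idx)) stop("design samples missing from the score matrix")
  groups <- design$population
  pops <- unique(groups)
  pr <- population_pairs(pops)
  key <- paste(pmin(pr[, 1], pr[, 2]), pmax(pr[, 1], pr[, 2]))
  first_axis <- stats::setNames(rep(NA_integer_, nrow(pr)), key)
  overall_p <- numeric(0)
  quiet <- 0L
  a <- 0L
  while (a < scores$n_axes && quiet < stop_after) {
    a <- a + 1L
    res <- anova_lsd(scores$scores[idx, a], groups, alpha)
    overall_p[a] <- res$p_overall
    sig <- res$significant
    if (protected && !(res$p_overall < protect_alpha)) sig[] <- FALSE
    rkey <- paste(pmin(res$pairs[, 1], res$pairs[, 2]),
                  pmax(res$pairs[, 1], res$pairs[, 2]))
    sig_key <- rkey[sig]
    new_key <- sig_key[is.na(first_axis[sig_key])]
    first_axis[new_key] <- a
    informative <- if (stopping == "new_pairs") length(new_key) > 0
                   else length(sig_key) > 0
    quiet <- if (informative) 0L else quiet + 1L
  }
  done <- !is.na(first_axis)
  dm <- distinctness(pops, pairs = pr[done, , drop = FALSE],
                     evidence = data.frame(pop1 = pr[, 1], pop2 = pr[, 2],
                                           first_axis = unname(first_axis)))
  structure(list(distinctness = dm,
                 first_axis = data.frame(pop1 = pr[, 1], pop2 = pr[, 2],
                                         first_axis = unname(first_axis)),
                 axes_examined = a, overall_p = overall_p),
            class = "sequential_result")
}

#' PCA + sequential ANOVA distinctness in one call
#'
#' @param freq complete [freq_matrix()].
#' @param design a [pop_design()].
#' @param ... passed to [sequential_axis_test()].
#' @return a `sequential_result`.
#' @export
pca_anova_distinctness <- function(freq, design, ...) {
  check_design_consistency(freq, design)
  sequential_axis_test(pca_scores(freq), design, ...)
}
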