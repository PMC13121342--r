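#' Per-pair PCA of one population pair's bulks
#'
#' Dimension reduction fitted once on all bulks of the two populations
#' (default six), before the leave-one-out loop; with six observations at
#' most five axes carry variance.
#'
#' @param freq complete [freq_matrix()].
#' @param design a [pop_design()].
#' @param pair character vector of the two population names.
#' @return a [pca_scores()] object restricted to the pair's bulks.
#' @export
pair_pca <- function(freq, design, pair) {
  if (length(pair) != 2) stop("pair must name exactly two populations")
  sel <- design$sample[design$population %in% pair]
  reps <- table(design$population[design$population %in% pair])
  if (length(reps) < 2 || any(reps < 2))
    stop("each population of the pair needs at least 2 bulks")
  x <- freq$values[sel, , drop = FALSE]
  pca_scores(x)
}

# Two-class linear discriminant prediction with pooled covariance, equal
# priors and a diagonal ridge when the pooled covariance is singular
# (within-class df < k). Returns the predicted label for newx.
lda_predict <- function(train_x, train_lab, newx, ridge_eps = 1e-6) {
  labs <- sort(unique(train_lab))
  if (length(labs) != 2) stop("training fold must contain both classes")
  k <- ncol(train_x)
  mus <- lapply(labs, function(l) colMeans(train_x[train_lab == l, , drop = FALSE]))
  df_within <- nrow(train_x) - 2L
  S <- matrix(0, k, k)
  for (i in seq_along(labs)) {
    xc <- sweep(train_x[train_lab == labs[i], , drop = FALSE], 2, mus[[i]])
    S <- S + crossprod(xc)
  }
  S <- S / df_within
  needs_ridge <- df_within < k || ill_conditioned(S)
  if (needs_ridge) {
    tr <- sum(diag(S))
    S <- S + diag(if (tr > 0) ridge_eps * tr / k else ridge_eps, k)
  }
  Sinv <- solve(S)
  d2 <- vapply(mus, function(m) {
    v <- newx - m
    drop(v %*% Sinv %*% v)
  }, numeric(1))
  labs[which.min(d2)]  # equal priors; ties resolve to the first label
}

ill_conditioned <- function(S) {
  rc <- tryCatch(rcond(S), error = function(e) 0)
  !is.finite(rc) || rc < 1e-12
}

#' Leave-one-out LDA classification of one population pair
#'
#' Each bulk is held out in turn; a two-class linear discriminant (pooled
#' within-class covariance, equal priors) is fitted on the remaining bulks
#' using the first `k` PC axes and the held-out bulk is classified. The pair
#' is distinct when every bulk is classified correctly. When the pooled
#' covariance is singular (within-class df below k) a diagonal ridge
#' `eps * trace/k` is added before inversion.
#'
#' @param scores a [pca_scores()] from [pair_pca()] (or a plain score matrix).
#' @param design a [pop_design()] covering the score rows.
#' @param k number of leading PC axes used (1..5); capped at the number of
#'   available axes.
#' @param ridge_eps ridge coefficient for singular covariances.
#' @return list: `pair`, `k`, `n_correct`, `n_total`, `distinct`.
#' @export
loo_lda <- function(scores, design, k, ridge_eps = 1e-6) {
  x <- if (inherits(scores, "pc_scores")) scores$scores else as.matrix(scores)
  if (k < 1) stop("k must be at least 1")
  lab <- design$population[match(rownames(x), design$sample)]
  if (anyNA(lab)) stop("score rows missing from the design")
  n <- nrow(x)
  k_eff <- min(k, ncol(x))
  if (k_eff == 0) {
    # degenerate pair (e.g. all bulks identical): nothing to discriminate on
    pair <- sort(unique(lab))
    return(list(pair = pair, k = k, n_correct = 0L, n_total = n,
                distinct = FALSE))
  }
  x <- x[, seq_len(k_eff), drop = FALSE]
  correct <- 0L
  for (i in seq_len(n)) {
    pred <- lda_predict(x[-i, , drop = FALSE], lab[-i], x[i, ], ridge_eps)
    if (pred == lab[i]) correct <- correct + 1L
  }
  pair <- sort(unique(lab))
  list(pair = pair, k = k, n_correct = correct, n_total = n,
       distinct = correct == n)
}

#' All-pairs leave-one-out discriminant sweep
#'
#' Evaluates every unordered population pair at every `k`, mirroring an
#' increasing number of PC axes from one to five. `refit_per_fold = TRUE`
#' switches to the strict variant where the per-pair PCA is refitted inside
#' every leave-one-out fold (training bulks only, held-out bulk projected).
#'
#' @param freq complete [freq_matrix()].
#' @param design a [pop_design()].
#' @param k_values PC-axis counts to sweep (default 1:5).
#' @param refit_per_fold strict no-leakage PCA refit (default FALSE: PCA is
#'   fitted once on all bulks of the pair).
#' @param ridge_eps see [loo_lda()].
#' @return list of class `lda_sweep`: `table` (pair x k results),
#'   `distinctness_by_k` (list of [distinctness()] per k), `distinctness`
#'   (distinct at any k), `best_k` (smallest k with the most distinct pairs).
#' @export
sweep_pairs <- function(freq, design, k_values = 1:5, refit_per_fold = FALSE,
                        ridge_eps = 1e-6) {
  check_design_consistency(freq, design)
  pops <- unique(design$population)
  pr <- population_pairs(pops)
  rows <- list()
  for (i in seq_len(nrow(pr))) {
    pair <- pr[i, ]
    sel <- design$sample[design$population %in% pair]
    sub_design <- design[design$sample %in% sel, , drop = FALSE]
    if (!refit_per_fold) sc <- pair_pca(freq, design, pair)
    for (k in k_values) {
      if (refit_per_fold) {
        res <- loo_lda_refit(freq$values[sel, , drop = FALSE], sub_design, k,
                             ridge_eps)
      } else {
        res <- loo_lda(sc, sub_design, k, ridge_eps)
      }
      rows[[length(rows) + 1]] <- data.frame(
        pop1 = pair[1], pop2 = pair[2], k = k,
        n_correct = res$n_correct, n_total = res$n_total,
        distinct = res$distinct, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  by_k <- lapply(stats::setNames(k_values, paste0("k", k_values)), function(k) {
    sub <- tab[tab$k == k & tab$distinct, c("pop1", "pop2"), drop = FALSE]
    distinctness(pops, pairs = sub)
  })
  any_k <- tab[tab$distinct, c("pop1", "pop2"), drop = FALSE]
  structure(list(table = tab, distinctness_by_k = by_k,
                 distinctness = distinctness(pops, pairs = unique(any_k))),
            class = "lda_sweep")
}

# Strict leave-one-out variant: PCA refitted on the 5 training bulks, the
# held-out bulk projected onto the training axes before classification.
loo_lda_refit <- function(x, design, k, ridge_eps = 1e-6) {
  lab <- design$population[match(rownames(x), design$sample)]
  n <- nrow(x)
  correct <- 0L
  for (i in seq_len(n)) {
    tr <- x[-i, , drop = FALSE]
    ctr <- colMeans(tr)
    trc <- sweep(tr, 2, ctr)
    sv <- svd(trc)
    keep <- sv$d > max(sv$d) * 1e-10
    if (!any(keep)) next
    V <- sv$v[, keep, drop = FALSE]
    k_eff <- min(k, ncol(V))
    V <- V[, seq_len(k_eff), drop = FALSE]
    tr_s <- trc %*% V
    new_s <- drop((x[i, ] - ctr) %*% V)
    pred <- lda_predict(tr_s, lab[-i], new_s, ridge_eps)
    if (pred == lab[i]) correct <- correct + 1L
  }
  pair <- sort(unique(lab))
  list(pair = pair, k = k, n_correct = correct, n_total = n,
       distinct = correct == n)
}
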