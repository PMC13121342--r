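#' Distance between bulk samples on allele-frequency profiles
#'
#' `"correlation"`: d = 1 - Pearson r between the two samples' frequency
#' vectors (range \[0, 2\]); `"euclidean"`: ordinary L2 distance.
#'
#' @param freq complete [freq_matrix()] or plain matrix (samples in rows).
#' @param metric `"correlation"` (default) or `"euclidean"`.
#' @return square symmetric distance matrix with zero diagonal.
#' @export
sample_distance <- function(freq, metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  x <- if (inherits(freq, "freq_matrix")) freq$values else as.matrix(freq)
  if (anyNA(x)) stop("distance input must be complete; impute first")
  if (metric == "correlation") {
    rv <- rowMeans(x^2) - rowMeans(x)^2
    if (any(rv <= 0))
      stop("constant sample vector: correlation distance undefined")
    d <- 1 - stats::cor(t(x))
  } else {
    d <- as.matrix(stats::dist(x))
  }
  diag(d) <- 0
  d[d < 0] <- 0  # guard against -1e-17 from floating point
  d
}

#' UPGMA dendrogram with deterministic tie-breaking
#'
#' Iteratively merges the closest pair of clusters; the distance from a
#' merged cluster to any other is the size-weighted arithmetic mean of its
#' members' distances, and the merge height is half the merge distance (so
#' cophenetic distances reproduce an ultrametric input exactly). Ties are
#' broken by the lexicographically smallest pair of minimum leaf labels, so
#' the tree is invariant to input row order.
#'
#' @param dist square symmetric distance matrix with labelled rows.
#' @return list of class `upgma_tree`: `labels`, `merge` (hclust-style),
#'   `height` (merge heights, = d/2), `clades` (sorted leaf-label vector per
#'   internal node, in merge order).
#' @export
upgma <- function(dist) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 leaves")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("S", seq_len(n))
  # active clusters: id < 0 = leaf -id, id > 0 = merge row id
  ids <- -seq_len(n)
  sizes <- rep(1L, n)
  minlab <- labels
  leafsets <- as.list(labels)
  D <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  clades <- vector("list", n - 1)
  active <- rep(TRUE, n)
  for (step in seq_len(n - 1)) {
    act <- which(active)
    Dact <- D[act, act, drop = FALSE]
    Dact[lower.tri(Dact, diag = TRUE)] <- Inf
    best_d <- min(Dact)
    cand <- which(Dact == best_d, arr.ind = TRUE)
    if (nrow(cand) > 1) {
      # tie-break: lexicographically smallest pair of minimum leaf labels
      keys <- apply(cand, 1, function(rc)
        paste(sort(c(minlab[act[rc[1]]], minlab[act[rc[2]]])), collapse = "\r"))
      cand <- cand[order(keys)[1], , drop = FALSE]
    }
    i <- act[cand[1, 1]]; j <- act[cand[1, 2]]
    merge[step, ] <- c(ids[i], ids[j])
    height[step] <- best_d / 2
    newset <- sort(c(leafsets[[i]], leafsets[[j]]))
    clades[[step]] <- newset
    # size-weighted average linkage, stored in slot i
    wi <- sizes[i]; wj <- sizes[j]
    for (k in act) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <- (wi * D[i, k] + wj * D[j, k]) / (wi + wj)
    }
    sizes[i] <- wi + wj
    leafsets[[i]] <- newset
    minlab[i] <- min(minlab[i], minlab[j])
    ids[i] <- step
    active[j] <- FALSE
  }
  structure(list(labels = labels, merge = merge, height = height,
                 clades = clades), class = "upgma_tree")
}

#' Cophenetic distance matrix of a UPGMA tree
#' @param tree an [upgma()] tree.
#' @return square matrix: 2 x the height of the first common merge.
#' @export
cophenetic_upgma <- function(tree) {
  n <- length(tree$labels)
  coph <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  members <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    get_m <- function(id) if (id < 0) -id else members[[id]]
    a <- get_m(tree$merge[s, 1])
    b <- get_m(tree$merge[s, 2])
    coph[a, b] <- coph[b, a] <- 2 * tree$height[s]
    members[[s]] <- c(a, b)
  }
  coph
}

clade_signatures <- function(clades) {
  vapply(clades, paste, character(1), collapse = "\r")
}

# Weighted least-squares fit of the multiscale signed-distance/curvature
# decomposition z_r = v sqrt(r) + c / sqrt(r) for one clade's bootstrap
# counts across scales; AU = 1 - pnorm(v - c). Only scales with a
# non-degenerate BP (0 < count < B) inform the fit: an all-0 or all-1
# profile carries no curvature information and pins AU to the matching
# clamp, 1/(B+1) or 1 - 1/(B+1).
fit_au_profile <- function(counts_row, scales, B) {
  lo <- 1 / (B + 1)
  bp <- counts_row / B
  use <- counts_row > 0 & counts_row < B
  if (sum(use) < 2)
    return(if (mean(bp) >= 0.5) 1 - lo else lo)
  bp_cl <- pmin(pmax(bp[use], lo), 1 - lo)
  z <- stats::qnorm(1 - bp_cl)
  w <- B * stats::dnorm(z)^2 / (bp_cl * (1 - bp_cl))
  sq <- sqrt(scales[use])
  fit <- stats::lm.wfit(cbind(v = sq, c = 1 / sq), z, w)
  vc <- fit$coefficients
  min(max(1 - stats::pnorm(vc["v"] - vc["c"]), lo), 1 - lo)
}

#' Multiscale-bootstrap approximately-unbiased clade support
#'
#' Builds the observed UPGMA tree on the full locus set, then for every
#' scale r resamples round(r * M) loci with replacement B times, rebuilds
#' the tree and records the bootstrap probability BP_r of each observed
#' clade (fraction of resampled trees containing an identical leaf set).
#' BP values are clamped to \[1/(B+1), 1 - 1/(B+1)\]; the signed-distance /
#' curvature decomposition z_r = v sqrt(r) + c / sqrt(r), with
#' z_r = qnorm(1 - BP_r) and weights from the binomial variance of BP_r, is
#' fitted by weighted least squares per clade, and AU = 1 - pnorm(v - c).
#' A clade never seen at any scale sits at the clamp floor at every scale
#' and gets an AU near 0 (flagged).
#'
#' @param freq complete [freq_matrix()] or matrix (samples in rows).
#' @param metric passed to [sample_distance()].
#' @param scales resampling ratios; must include values below and above 1.
#' @param B bootstrap replicates per scale (default 1000).
#' @param seed integer seed.
#' @return list of class `support_tree`: the observed `tree`, `au` and
#'   `bp` (per internal node; `bp` is at scale closest to 1), `bp_table`
#'   (node x scale), `never_seen` flags, `scales`, `B`.
#' @export
multiscale_au <- function(freq, metric = "correlation",
                          scales = seq(0.5, 1.4, by = 0.1), B = 1000,
                          seed = 1L) {
  if (length(scales) < 2 || !any(scales < 1) || !any(scales > 1))
    stop("scales must include values below and above 1")
  x <- if (inherits(freq, "freq_matrix")) freq$values else as.matrix(freq)
  M <- ncol(x)
  tree <- upgma(sample_distance(x, metric))
  sig <- clade_signatures(tree$clades)
  n_clades <- length(sig)
  counts <- matrix(0L, n_clades, length(scales),
                   dimnames = list(NULL, sprintf("r%.1f", scales)))
  set.seed(seed)
  for (s in seq_along(scales)) {
    m_r <- max(2L, round(scales[s] * M))
    for (b in seq_len(B)) {
      idx <- sample.int(M, m_r, replace = TRUE)
      db <- tryCatch(sample_distance(x[, idx, drop = FALSE], metric),
                     error = function(e) NULL)
      if (is.null(db)) next  # degenerate resample (constant row)
      tb <- upgma(db)
      hit <- sig %in% clade_signatures(tb$clades)
      counts[hit, s] <- counts[hit, s] + 1L
    }
  }
  bp <- counts / B
  never_seen <- rowSums(counts) == 0
  au <- vapply(seq_len(n_clades), function(i)
    fit_au_profile(counts[i, ], scales, B), numeric(1))
  au[never_seen] <- 0
  s1 <- which.min(abs(scales - 1))
  structure(list(tree = tree, au = au, bp = bp[, s1], bp_table = bp,
                 never_seen = never_seen, scales = scales, B = B),
            class = "support_tree")
}

#' Completely distinct populations by the exclusive-clade rule
#'
#' A population is distinct from every other when some internal node's leaf
#' set equals exactly the set of that population's replicate bulks and the
#' node's approximately-unbiased support is at or above `threshold`.
#'
#' @param support a [multiscale_au()] result.
#' @param design a [pop_design()] whose samples are the tree leaves.
#' @param threshold AU threshold (default 0.95).
#' @return character vector of completely distinct populations; the per-
#'   population AU of the matching clade (NA if not monophyletic) is kept as
#'   the `au` attribute.
#' @export
distinct_by_cluster <- function(support, design, threshold = 0.95) {
  stopifnot(inherits(support, "support_tree"))
  sig <- clade_signatures(support$tree$clades)
  pops <- unique(design$population)
  au_pop <- stats::setNames(rep(NA_real_, length(pops)), pops)
  for (p in pops) {
    want <- paste(sort(design$sample[design$population == p]), collapse = "\r")
    hit <- match(want, sig)
    if (!is.na(hit)) au_pop[p] <- support$au[hit]
  }
  out <- names(au_pop)[!is.na(au_pop) & au_pop >= threshold]
  attr(out, "au") <- au_pop
  out
}

#' Newick export of a UPGMA tree with optional node support labels
#'
#' @param tree an [upgma()] tree or a [multiscale_au()] result (whose AU
#'   values then become internal node labels).
#' @param path optional file path; when NULL the string is returned.
#' @param digits label precision.
#' @return newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL, digits = 3) {
  labels_au <- NULL
  if (inherits(tree, "support_tree")) {
    labels_au <- tree$au
    tree <- tree$tree
  }
  h_of <- function(id) if (id < 0) 0 else tree$height[id]
  build <- function(id) {
    if (id < 0) return(tree$labels[-id])
    a <- tree$merge[id, 1]; b <- tree$merge[id, 2]
    h <- tree$height[id]
    lab <- if (!is.null(labels_au)) format(round(labels_au[id], digits)) else ""
    sprintf("(%s:%g,%s:%g)%s", build(a), h - h_of(a), build(b), h - h_of(b), lab)
  }
  nwk <- paste0(build(length(tree$height)), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
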