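#' Nei's (1972) standard genetic distance between two frequency profiles
#'
#' For biallelic loci with alternate-allele frequencies p and q in the two
#' samples, the normalized identity is I = Jxy / sqrt(Jx Jy) with
#' Jxy = mean over loci of (p q + (1-p)(1-q)), and Jx, Jy the analogous
#' self-identities; D = -ln I. D is 0 for identical profiles and +Inf when
#' the profiles are completely fixed for opposite alleles at every locus
#' (Jxy = 0).
#'
#' @param x,y numeric vectors of alternate-allele frequencies in \[0,1\],
#'   equal length.
#' @return nonnegative distance (possibly `Inf`).
#' @export
nei_distance <- function(x, y) {
  if (length(x) != length(y)) stop("frequency vectors must have equal length")
  if (anyNA(x) || anyNA(y)) stop("frequencies must be complete")
  jxy <- mean(x * y + (1 - x) * (1 - y))
  jx <- mean(x^2 + (1 - x)^2)
  jy <- mean(y^2 + (1 - y)^2)
  if (jxy == 0) return(Inf)
  max(-log(jxy / sqrt(jx * jy)), 0)
}

#' Nei distance matrix between all bulk samples
#'
#' @param freq complete [freq_matrix()] (bulks in rows).
#' @return symmetric `dist`-like matrix with zero diagonal.
#' @export
nei_distance_matrix <- function(freq) {
  x <- if (inherits(freq, "freq_matrix")) freq$values else as.matrix(freq)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- nei_distance(x[i, ], x[j, ])
  }
  d
}

# All ways to assign n1 of n sample indices to group 1 (group sizes fixed),
# as a list of index vectors. Used for exhaustive permutation.
group_assignments <- function(n, n1) {
  utils::combn(n, n1, simplify = FALSE)
}

amova_ss <- function(d2, g1_idx) {
  n <- nrow(d2)
  all_idx <- seq_len(n)
  g2_idx <- setdiff(all_idx, g1_idx)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_w <- sum(d2[g1_idx, g1_idx][upper.tri(diag(length(g1_idx)))]) / length(g1_idx) +
          sum(d2[g2_idx, g2_idx][upper.tri(diag(length(g2_idx)))]) / length(g2_idx)
  c(among = ss_total - ss_w, within = ss_w, total = ss_total)
}

#' Two-group AMOVA with a permutation test
#'
#' Partitions squared distances between the bulks of two populations into
#' among- and within-population components, computes Phi_ST, and tests the
#' among-group component by permuting the sample-to-group assignment. When
#' the number of distinct assignments (choose(n, n1)) does not exceed
#' `nperm`, the permutation distribution is enumerated exhaustively and the
#' p-value is the exact fraction of assignments (the observed one included)
#' whose among-group SS is at least the observed; otherwise `nperm` random
#' assignments are drawn and the add-one rule applies. With 3 + 3 bulks the
#' exhaustive floor is 2/20 = 0.1 (the observed assignment and its
#' complement), so no pair can reach P < 0.05; with 4 + 4 the floor is
#' 2/70 ~ 0.029.
#'
#' @param dist square distance matrix over the pair's bulks (e.g. a Nei
#'   matrix from [nei_distance_matrix()] restricted to six rows).
#' @param labels group label per row of `dist` (exactly 2 groups, each with
#'   >= 2 samples).
#' @param nperm Monte-Carlo budget (default 10000).
#' @param seed seed for the Monte-Carlo fallback.
#' @return list of class `amova_result`: `ss` (among/within/total),
#'   `variance_components`, `phi_st` (clamped to \[0,1\], `clamped` flag),
#'   `p`, `n_assignments`, `exhaustive`.
#' @export
amova_pair <- function(dist, labels, nperm = 10000, seed = 1L) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  labels <- as.character(labels)
  if (length(labels) != n) stop("one label per sample required")
  g <- sort(unique(labels))
  if (length(g) != 2) stop("AMOVA here is two-group only")
  n1 <- sum(labels == g[1])
  n2 <- n - n1
  if (min(n1, n2) < 2) stop("each group needs at least 2 samples")
  if (any(!is.finite(dist)))
    stop("distance matrix contains non-finite entries")
  d2 <- dist^2
  obs <- amova_ss(d2, which(labels == g[1]))

  df_among <- 1
  df_within <- n - 2
  ms_among <- obs["among"] / df_among
  ms_within <- obs["within"] / df_within
  n0 <- (n - (n1^2 + n2^2) / n) / df_among
  sigma_w <- unname(ms_within)
  sigma_a <- unname((ms_among - ms_within) / n0)
  clamped <- FALSE
  if (obs["total"] == 0) {
    phi <- NA_real_
    p <- 1
  } else {
    if (sigma_a < 0) { sigma_a <- 0; clamped <- TRUE }
    phi <- if (sigma_a + sigma_w == 0) NA_real_ else sigma_a / (sigma_a + sigma_w)
  }

  n_assign <- choose(n, n1)
  exhaustive <- n_assign <= nperm
  if (obs["total"] > 0) {
    if (exhaustive) {
      perms <- group_assignments(n, n1)
      ss_perm <- vapply(perms, function(ix) amova_ss(d2, ix)["among"], numeric(1))
      p <- mean(ss_perm >= obs["among"] - 1e-12)
    } else {
      set.seed(seed)
      hits <- 0L
      for (b in seq_len(nperm)) {
        ix <- sample.int(n, n1)
        if (amova_ss(d2, ix)["among"] >= obs["among"] - 1e-12) hits <- hits + 1L
      }
      p <- (1 + hits) / (1 + nperm)
    }
  }
  structure(list(ss = obs,
                 variance_components = c(among = sigma_a, within = sigma_w),
                 phi_st = unname(phi), clamped = clamped, p = unname(p),
                 n_assignments = n_assign, exhaustive = exhaustive),
            class = "amova_result")
}

#' Pairwise AMOVA distinctness over all population pairs
#'
#' Computes the Nei distance matrix between all bulks once, then runs
#' [amova_pair()] on every unordered population pair; a pair is distinct
#' when its permutation p-value is below `alpha`.
#'
#' @param freq complete [freq_matrix()].
#' @param design a [pop_design()].
#' @param alpha significance level (default 0.05).
#' @param nperm,seed see [amova_pair()].
#' @return list of class `amova_sweep`: `table` (pair, phi_st, p, distinct),
#'   `distinctness`, `dist` (the bulk-level Nei matrix).
#' @export
amova_distinctness <- function(freq, design, alpha = 0.05, nperm = 10000,
                               seed = 1L) {
  check_design_consistency(freq, design)
  d <- nei_distance_matrix(freq)
  pops <- unique(design$population)
  pr <- population_pairs(pops)
  rows <- vector("list", nrow(pr))
  for (i in seq_len(nrow(pr))) {
    sel <- design$population %in% pr[i, ]
    samp <- design$sample[sel]
    res <- amova_pair(d[samp, samp], design$population[sel], nperm = nperm,
                      seed = seed + i)
    rows[[i]] <- data.frame(pop1 = pr[i, 1], pop2 = pr[i, 2],
                            phi_st = res$phi_st, p = res$p,
                            distinct = res$p < alpha, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  dm <- distinctness(pops, pairs = tab[tab$distinct, c("pop1", "pop2")],
                     evidence = tab)
  structure(list(table = tab, distinctness = dm, dist = d),
            class = "amova_sweep")
}
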