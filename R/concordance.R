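#' Population-level Euclidean distance for one information layer
#'
#' Marker layer: each population's vector is the mean of its replicate bulk
#' frequency vectors; distances are plain Euclidean. Trait layer: the input
#' is a plot table, per-population means are taken for the selected traits
#' (those with significant overall variation), each trait is standardized to
#' zero mean and unit variance across populations (units differ between
#' traits), then Euclidean distances are computed; set `standardize = FALSE`
#' to skip the scaling.
#'
#' @param layer a complete [freq_matrix()] (marker layer) or a plot-level
#'   trait data.frame with columns `population`, `block` plus trait columns.
#' @param design a [pop_design()] (marker layer only).
#' @param traits for a trait layer: which trait columns to use (e.g. those
#'   with overall p < 0.05). Zero selected traits is an error (empty layer).
#' @param standardize standardize traits before the distance (trait layer).
#' @return square population-level distance matrix.
#' @export
population_layer_distance <- function(layer, design = NULL, traits = NULL,
                                      standardize = TRUE) {
  if (inherits(layer, "freq_matrix")) {
    if (is.null(design)) stop("marker layer needs a design")
    check_design_consistency(layer, design)
    pops <- unique(design$population)
    pv <- t(vapply(pops, function(p)
      colMeans(layer$values[design$sample[design$population == p], ,
                            drop = FALSE]),
      numeric(ncol(layer$values))))
    rownames(pv) <- pops
    return(as.matrix(stats::dist(pv)))
  }
  if (is.null(traits)) stop("trait layer: specify which traits to use")
  if (length(traits) == 0)
    stop("empty layer: no trait with significant population variation")
  pops <- unique(as.character(layer$population))
  pm <- vapply(traits, function(tc)
    tapply(layer[[tc]], as.character(layer$population), mean)[pops],
    numeric(length(pops)))
  pm <- matrix(pm, nrow = length(pops),
               dimnames = list(pops, traits))
  if (standardize) pm <- scale(pm)
  as.matrix(stats::dist(pm))
}

#' Mantel correlation test between two distance matrices
#'
#' r is the Pearson correlation of corresponding off-diagonal entries; the
#' p-value is the add-one tail probability of r under simultaneous
#' row/column permutation of the second matrix.
#'
#' @param d1,d2 square distance matrices with the same labels (>= 4 rows).
#' @param nperm permutations (default 10000).
#' @param seed integer seed.
#' @return list of class `mantel_result`: `r`, `p`, `nperm`.
#' @export
mantel_test <- function(d1, d2, nperm = 10000, seed = 1L) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  n <- nrow(d1)
  if (n < 4) stop("Mantel test needs at least 4 populations")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    if (!setequal(rownames(d1), rownames(d2)))
      stop("distance matrices must share labels")
    d2 <- d2[rownames(d1), rownames(d1)]
  }
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  if (stats::sd(v1) == 0 || stats::sd(d2[lt]) == 0)
    stop("zero variance among off-diagonal distances: r undefined")
  r_obs <- stats::cor(v1, d2[lt])
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(nperm)) {
    pi <- sample.int(n)
    if (stats::cor(v1, d2[pi, pi][lt]) >= r_obs - 1e-12) hits <- hits + 1L
  }
  structure(list(r = r_obs, p = (1 + hits) / (1 + nperm), nperm = nperm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.3f, p = %.4g (%d permutations)\n",
              x$r, x$p, x$nperm))
  invisible(x)
}

#' Concordance report across information layers
#'
#' Runs [mantel_test()] on every pair of population-level distance matrices.
#'
#' @param layers named list of square population-level distance matrices
#'   (e.g. from [population_layer_distance()]).
#' @param nperm,seed see [mantel_test()].
#' @return data.frame: layer1, layer2, r, p, nperm.
#' @export
concordance_report <- function(layers, nperm = 10000, seed = 1L) {
  if (length(layers) < 2) stop("need at least two layers")
  pr <- population_pairs(names(layers))
  rows <- lapply(seq_len(nrow(pr)), function(i) {
    m <- mantel_test(layers[[pr[i, 1]]], layers[[pr[i, 2]]], nperm,
                     seed + i)
    data.frame(layer1 = pr[i, 1], layer2 = pr[i, 2], r = m$r, p = m$p,
               nperm = nperm, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
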