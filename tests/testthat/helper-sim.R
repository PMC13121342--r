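# Small fixtures shared across test files; everything is built in code.

# Complete frequency matrix with all depths positive.
toy_freq <- function(x) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("L", seq_len(ncol(x)))
  freq_matrix(x, matrix(100, nrow(x), ncol(x), dimnames = dimnames(x)))
}

# Two-population, three-bulk frequency matrix with a controllable gap:
# bulks are Gaussian around each population centre, clipped to [0, 1].
two_pop_freq <- function(n_loci = 40, gap = 0.4, spread = 0.01, seed = 1) {
  set.seed(seed)
  centre <- runif(n_loci, 0.3, 0.7)
  shift <- sample(c(-1, 1), n_loci, replace = TRUE) * gap / 2
  rows <- rbind(
    t(replicate(3, centre - shift + rnorm(n_loci, 0, spread))),
    t(replicate(3, centre + shift + rnorm(n_loci, 0, spread))))
  rows <- pmin(pmax(rows, 0), 1)
  rownames(rows) <- c("A_1", "A_2", "A_3", "B_1", "B_2", "B_3")
  colnames(rows) <- paste0("L", seq_len(n_loci))
  rows
}

two_pop_design <- function() {
  pop_design(c("A_1", "A_2", "A_3", "B_1", "B_2", "B_3"),
             rep(c("A", "B"), each = 3))
}

# Balanced RCB plot table with iid noise and optional population effects.
toy_rcb <- function(n_pops = 4, n_blocks = 5, pop_effects = NULL, sd = 1,
                    seed = 1) {
  set.seed(seed)
  pops <- make_pop_labels(n_pops)
  if (is.null(pop_effects)) pop_effects <- rep(0, n_pops)
  g <- expand.grid(block = seq_len(n_blocks), population = pops,
                   stringsAsFactors = FALSE)
  g$y <- 10 + pop_effects[match(g$population, pops)] + rnorm(nrow(g), 0, sd)
  g[, c("population", "block", "y")]
}
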