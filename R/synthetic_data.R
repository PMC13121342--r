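#' Simulation configuration for pooled-genotyping experiments
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate a
#' bulked-DNA distinctness study on an autotetraploid outbred forage crop:
#' 11 populations drawn from one genetic base, genotyped as 3 replicate bulks
#' of 200 plants each, with thousands of biallelic markers read at GBS-like
#' depth, plus a 10-trait field trial laid out as a randomized complete block
#' with 5 blocks and 22 plants per plot.
#'
#' @param n_pops number of populations.
#' @param n_markers number of biallelic loci.
#' @param fst divergence of each population from the shared ancestral base,
#'   a single value in \[0, 1) or one value per population. `fst = 0` makes
#'   populations exact clones of the base (the null model).
#' @param n_plants_per_bulk plants pooled into one bulk DNA sample.
#' @param ploidy allele copies per plant (4 for autotetraploid alfalfa).
#' @param n_bulks replicate bulks per population.
#' @param mean_depth mean read depth per cell; ~64 emulates GBS, ~596 a
#'   targeted amplicon panel.
#' @param depth_dispersion negative-binomial size parameter of the per-cell
#'   depth distribution (smaller = more overdispersed).
#' @param missing_rate probability that a cell is missing (depth forced to 0)
#'   in addition to cells whose sampled depth is 0.
#' @param n_blocks complete blocks in the trait trial.
#' @param plants_per_plot plants measured per plot.
#' @param trait_spec data.frame describing the simulated traits; see
#'   [default_trait_spec()].
#' @param seed integer seed; every generator operation derives its own stream
#'   from it so that identical configurations give identical output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 11, n_markers = 1500, fst = 0.05,
                       n_plants_per_bulk = 200, ploidy = 4, n_bulks = 3,
                       mean_depth = 64, depth_dispersion = 5,
                       missing_rate = 0.05, n_blocks = 5, plants_per_plot = 22,
                       trait_spec = default_trait_spec(), seed = 1L) {
  fst <- rep_len(fst, n_pops)
  if (any(fst < 0) || any(fst >= 1)) stop("fst must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must lie in [0, 1]")
  if (n_bulks < 2) stop("need at least 2 bulks per population")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (depth_dispersion <= 0) stop("depth_dispersion must be positive")
  structure(list(n_pops = as.integer(n_pops), n_markers = as.integer(n_markers),
                 fst = fst, n_plants_per_bulk = as.integer(n_plants_per_bulk),
                 ploidy = as.integer(ploidy), n_bulks = as.integer(n_bulks),
                 mean_depth = mean_depth, depth_dispersion = depth_dispersion,
                 missing_rate = missing_rate, n_blocks = as.integer(n_blocks),
                 plants_per_plot = as.integer(plants_per_plot),
                 trait_spec = trait_spec, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default morphophysiological trait specification
#'
#' Ten traits patterned on an Italian alfalfa DUS trial: spring/autumn plant
#' height, onset of flowering, three flower-colour proportions, stem length,
#' leaflet length and width, and the 1-9 growth-habit score. Four traits
#' (onset of flowering, dark- and variegated-flower proportions, leaflet
#' length) carry real population effects; the rest are pure noise, emulating
#' populations from a common genetic base that differ in little besides
#' flowering and flower colour. For proportion traits `pop_sd` and `plot_sd`
#' act on the logit scale and `plant_sd` is ignored (plant values are
#' Bernoulli draws).
#'
#' @return data.frame with columns `trait`, `mean`, `pop_sd`, `plot_sd`,
#'   `plant_sd`, `proportion`.
#' @export
default_trait_spec <- function() {
  data.frame(
    trait = c("spring_height", "flowering_onset", "dark_flower",
              "variegated_flower", "cream_flower", "stem_length",
              "leaflet_length", "leaflet_width", "growth_habit",
              "autumn_height"),
    mean = c(33, 13, 0.03, 0.20, 0, 89, 31.5, 12.5, 1.5, 28.5),
    pop_sd = c(0, 0.9, 0.8, 1.0, 0, 0, 0.5, 0, 0, 0),
    plot_sd = c(1.5, 0.8, 0.25, 0.25, 0, 2.5, 0.7, 0.5, 0.25, 1.2),
    plant_sd = c(4, 2.5, 0, 0, 0, 6, 2, 1.5, 0.8, 3.5),
    proportion = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                   FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Heterogeneous divergence profile across populations
#'
#' Populations bred from one genetic base by different selection schemes
#' drift away from it to different degrees: a mass-selected population keeps
#' most of the base's allele frequencies while progeny-based selection of a
#' dozen parents (possibly selfed) shifts them much more. This helper spreads
#' per-population divergence evenly over a range, giving the population set a
#' non-trivial distance structure (pairs involving strongly drifted
#' populations sit farther apart), which is what makes independent marker
#' panels agree on the diversity pattern. A single shared `fst` value, by
#' contrast, makes all true pair distances exchangeable.
#'
#' @param n_pops number of populations.
#' @param range lower and upper divergence, defaults 0.02 to 0.10.
#' @return numeric vector of length `n_pops` for [sim_config()]'s `fst`.
#' @export
heterogeneous_fst <- function(n_pops = 11, range = c(0.02, 0.10)) {
  seq(range[1], range[2], length.out = n_pops)
}

#' Population labels in trial style
#'
#' Single-letter codes skipping the easily confused I and L, as customary in
#' variety trials; falls back to P01, P02, ... beyond 24 populations.
#' @param n number of populations.
#' @return character vector of length `n`.
#' @export
make_pop_labels <- function(n) {
  letters_ok <- setdiff(LETTERS, c("I", "L"))
  if (n <= length(letters_ok)) letters_ok[seq_len(n)]
  else sprintf("P%02d", seq_len(n))
}

#' Simulate population allele frequencies under a star divergence model
#'
#' Ancestral frequencies are drawn from Uniform(0.05, 0.95); each population's
#' frequency at each locus is a Balding-Nichols draw,
#' Beta(p0(1-F)/F, (1-p0)(1-F)/F), whose mean is p0 and whose variance is
#' F p0 (1 - p0). With F = 0 the population frequency equals p0 exactly.
#'
#' @param cfg a [sim_config()].
#' @return list with `pop_freqs` (n_pops x n_markers matrix, populations in
#'   rows) and `ancestral` (length n_markers vector).
#' @export
simulate_population_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  M <- cfg$n_markers
  p0 <- stats::runif(M, 0.05, 0.95)
  pops <- make_pop_labels(cfg$n_pops)
  pf <- matrix(NA_real_, cfg$n_pops, M,
               dimnames = list(pops, sprintf("L%05d", seq_len(M))))
  for (i in seq_len(cfg$n_pops)) {
    f <- cfg$fst[i]
    pf[i, ] <- if (f == 0) p0
               else stats::rbeta(M, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
  }
  list(pop_freqs = pf, ancestral = p0)
}

#' Simulate bulked-DNA read counts from population frequencies
#'
#' For every bulk and locus: the pool allele frequency is the binomial
#' sampling of `ploidy * n_plants_per_bulk` allele copies from the population
#' frequency; read depth is negative-binomial around `mean_depth`; alternate
#' reads are binomial at the pool frequency; cells are additionally set
#' missing (depth 0) at `missing_rate`.
#'
#' @param pop_freqs population-by-marker frequency matrix (rows must match
#'   `cfg$n_pops`), e.g. `simulate_population_frequencies(cfg)$pop_freqs`.
#' @param cfg a [sim_config()].
#' @param seed_offset added to `cfg$seed` so that independent re-bulking of
#'   the same population structure (e.g. a second marker panel read at a
#'   different depth) uses a fresh stream.
#' @return list with `counts` (an [allele_counts()]) and `design`
#'   (a [pop_design()], `n_bulks` bulks per population).
#' @export
simulate_bulks <- function(pop_freqs, cfg, seed_offset = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(pop_freqs) != cfg$n_pops)
    stop("pop_freqs rows must match cfg$n_pops")
  set.seed(cfg$seed + seed_offset)
  pops <- rownames(pop_freqs)
  M <- ncol(pop_freqs)
  copies <- cfg$ploidy * cfg$n_plants_per_bulk
  n_samp <- cfg$n_pops * cfg$n_bulks
  ref <- matrix(0L, n_samp, M)
  alt <- matrix(0L, n_samp, M)
  samp_names <- character(n_samp)
  row <- 0L
  for (i in seq_len(cfg$n_pops)) {
    for (b in seq_len(cfg$n_bulks)) {
      row <- row + 1L
      samp_names[row] <- paste0(pops[i], "_", b)
      pool <- stats::rbinom(M, copies, pop_freqs[i, ]) / copies
      depth <- stats::rnbinom(M, size = cfg$depth_dispersion, mu = cfg$mean_depth)
      if (cfg$missing_rate > 0)
        depth[stats::runif(M) < cfg$missing_rate] <- 0L
      a <- stats::rbinom(M, depth, pool)
      alt[row, ] <- a
      ref[row, ] <- depth - a
    }
  }
  dimnames(ref) <- dimnames(alt) <- list(samp_names, colnames(pop_freqs))
  design <- pop_design(samp_names, rep(pops, each = cfg$n_bulks))
  list(counts = allele_counts(ref, alt), design = design)
}

#' Simulate a plot-level trait table from a randomized complete block trial
#'
#' Quantitative traits: plot value = grand mean + population effect + block
#' effect + plot error + mean of `plants_per_plot` plant deviations. Block
#' effects share the plot-error SD. Proportion traits: each plant is a
#' Bernoulli draw at a probability that combines the population, block and
#' plot effects on the logit scale; the plot value is the plant fraction.
#'
#' @param cfg a [sim_config()].
#' @param seed_offset stream offset, see [simulate_bulks()].
#' @return data.frame with columns `population`, `block` and one column per
#'   trait; one row per plot (complete block design).
#' @export
simulate_traits <- function(cfg, seed_offset = 2L) {
  stopifnot(inherits(cfg, "sim_config"))
  ts <- cfg$trait_spec
  if (is.null(ts) || nrow(ts) == 0) stop("trait_spec must be non-empty")
  set.seed(cfg$seed + seed_offset)
  pops <- make_pop_labels(cfg$n_pops)
  grid <- expand.grid(block = seq_len(cfg$n_blocks), population = pops,
                      stringsAsFactors = FALSE)[, c("population", "block")]
  out <- grid
  npl <- cfg$plants_per_plot
  for (j in seq_len(nrow(ts))) {
    pe <- stats::rnorm(cfg$n_pops, 0, ts$pop_sd[j]); names(pe) <- pops
    be <- stats::rnorm(cfg$n_blocks, 0, ts$plot_sd[j])
    if (ts$proportion[j]) {
      base_logit <- stats::qlogis(ts$mean[j])  # -Inf when mean is 0
      p_plot <- stats::plogis(base_logit + pe[grid$population] + be[grid$block] +
                                stats::rnorm(nrow(grid), 0, ts$plot_sd[j]))
      out[[ts$trait[j]]] <- stats::rbinom(nrow(grid), npl, p_plot) / npl
    } else {
      out[[ts$trait[j]]] <- ts$mean[j] + pe[grid$population] + be[grid$block] +
        stats::rnorm(nrow(grid), 0, ts$plot_sd[j]) +
        stats::rnorm(nrow(grid), 0, ts$plant_sd[j] / sqrt(npl))
    }
  }
  out
}

#' Simulate a full distinctness study
#'
#' Convenience wrapper producing population frequencies, one bulked marker
#' panel and the trait trial from a single configuration.
#'
#' @param cfg a [sim_config()].
#' @return list with `pop_freqs`, `ancestral`, `counts`, `design`, `traits`.
#' @export
simulate_dataset <- function(cfg) {
  pf <- simulate_population_frequencies(cfg)
  bl <- simulate_bulks(pf$pop_freqs, cfg)
  tr <- simulate_traits(cfg)
  list(pop_freqs = pf$pop_freqs, ancestral = pf$ancestral,
       counts = bl$counts, design = bl$design, traits = tr)
}
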