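#' Run configuration for the full distinctness pipeline
#'
#' @param criteria which criteria to run; any of `"pca_anova"`,
#'   `"discriminant"`, `"amova"`, `"cluster"`.
#' @param grid list of [filter_config()]s swept by the PCA+ANOVA and
#'   discriminant criteria (default: the full 20-configuration
#'   [filter_grid()]).
#' @param fixed_config the single well-discriminating configuration used for
#'   AMOVA, clustering and Mantel's test (default: min 30 reads, max 10%
#'   missing).
#' @param lsd_alpha pairwise LSD level for the molecular ANOVA criterion.
#' @param amova_alpha AMOVA significance level.
#' @param au_threshold AU support threshold for the cluster criterion.
#' @param morpho_gate_alpha,morpho_lsd_alpha morphophysiological ANOVA gate
#'   and LSD levels.
#' @param nperm permutation budget for AMOVA and Mantel.
#' @param boot_B bootstrap replicates per scale for AU support.
#' @param impute_method `"mean"` or `"rf"` (see [impute_freq()]).
#' @param cluster_metric distance metric for the cluster criterion.
#' @param seed master seed for all stochastic steps.
#' @return list of class `run_config`.
#' @export
run_config <- function(criteria = c("pca_anova", "discriminant", "amova",
                                    "cluster"),
                       grid = filter_grid(),
                       fixed_config = filter_config(min_reads = 30,
                                                    max_missing = 0.10),
                       lsd_alpha = 0.01, amova_alpha = 0.05,
                       au_threshold = 0.95,
                       morpho_gate_alpha = 0.05, morpho_lsd_alpha = 0.01,
                       nperm = 10000, boot_B = 1000,
                       impute_method = "mean",
                       cluster_metric = "correlation", seed = 1L) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  if (length(criteria) == 0) stop("enable at least one criterion")
  structure(list(criteria = criteria, grid = grid,
                 fixed_config = fixed_config, lsd_alpha = lsd_alpha,
                 amova_alpha = amova_alpha, au_threshold = au_threshold,
                 morpho_gate_alpha = morpho_gate_alpha,
                 morpho_lsd_alpha = morpho_lsd_alpha, nperm = nperm,
                 boot_B = boot_B, impute_method = impute_method,
                 cluster_metric = cluster_metric, seed = as.integer(seed)),
            class = "run_config")
}

prepare_panel <- function(counts, fcfg, impute_method, seed) {
  f <- apply_filter(freq_from_counts(counts), fcfg)
  if (ncol(f$values) == 0) return(NULL)
  impute_freq(f, method = impute_method, seed = seed)
}

#' Orchestrate the full distinctness analysis
#'
#' Runs the enabled molecular criteria -- PCA + sequential per-axis ANOVA
#' and leave-one-out discriminant analysis over every filter configuration
#' of the grid; AMOVA and bootstrap clustering at the single fixed
#' configuration -- plus, when a trait table is supplied, the
#' morphophysiological analysis and the Mantel concordance between layers.
#' Deterministic given the configuration: every stochastic step is seeded
#' from `config$seed`.
#'
#' @param counts an [allele_counts()].
#' @param design a [pop_design()].
#' @param traits optional plot-level trait table (see [simulate_traits()]).
#' @param config a [run_config()].
#' @return list of class `dus_run`: `summary` (one row per criterion x
#'   configuration: pairs distinct, proportion, completely distinct
#'   populations, proportion; the cluster criterion reports populations
#'   only), `details` (per-criterion objects), `concordance` (Mantel table
#'   or NULL).
#' @export
run_distinctness <- function(counts, design, traits = NULL,
                             config = run_config()) {
  check_design_consistency(counts, design)
  pops <- unique(design$population)
  n_pop <- length(pops)
  n_pair <- choose(n_pop, 2)
  summary_rows <- list()
  details <- list()
  add_row <- function(criterion, cfg_name, n_pairs, n_complete) {
    summary_rows[[length(summary_rows) + 1]] <<- data.frame(
      criterion = criterion, configuration = cfg_name,
      n_distinct_pairs = n_pairs,
      prop_pairs_pct = if (is.na(n_pairs)) NA_real_ else 100 * n_pairs / n_pair,
      n_completely_distinct = n_complete,
      prop_pops_pct = 100 * n_complete / n_pop,
      stringsAsFactors = FALSE)
  }

  if (!is.null(traits)) {
    mo <- morpho_analysis(traits, gate_alpha = config$morpho_gate_alpha,
                          lsd_alpha = config$morpho_lsd_alpha)
    details$morpho <- mo
    add_row("morpho", "trial", n_distinct_pairs(mo$distinctness),
            length(completely_distinct(mo$distinctness)))
  }

  grid_panels <- NULL
  if (any(c("pca_anova", "discriminant") %in% config$criteria)) {
    grid_panels <- lapply(config$grid, prepare_panel, counts = counts,
                          impute_method = config$impute_method,
                          seed = config$seed)
  }
  if ("pca_anova" %in% config$criteria) {
    details$pca_anova <- list()
    for (nm in names(config$grid)) {
      panel <- grid_panels[[nm]]
      if (is.null(panel)) { add_row("pca_anova", nm, NA, 0); next }
      res <- pca_anova_distinctness(panel, design, alpha = config$lsd_alpha)
      details$pca_anova[[nm]] <- res
      add_row("pca_anova", nm, n_distinct_pairs(res$distinctness),
              length(completely_distinct(res$distinctness)))
    }
  }
  if ("discriminant" %in% config$criteria) {
    details$discriminant <- list()
    for (nm in names(config$grid)) {
      panel <- grid_panels[[nm]]
      if (is.null(panel)) { add_row("discriminant", nm, NA, 0); next }
      res <- sweep_pairs(panel, design)
      details$discriminant[[nm]] <- res
      add_row("discriminant", nm, n_distinct_pairs(res$distinctness),
              length(completely_distinct(res$distinctness)))
    }
  }

  fixed_panel <- NULL
  if (any(c("amova", "cluster") %in% config$criteria) || !is.null(traits)) {
    fixed_panel <- prepare_panel(counts, config$fixed_config,
                                 config$impute_method, config$seed)
    if (is.null(fixed_panel))
      stop("the fixed filter configuration left no markers")
  }
  if ("amova" %in% config$criteria) {
    res <- amova_distinctness(fixed_panel, design,
                              alpha = config$amova_alpha,
                              nperm = config$nperm, seed = config$seed)
    details$amova <- res
    add_row("amova", "fixed", n_distinct_pairs(res$distinctness),
            length(completely_distinct(res$distinctness)))
  }
  if ("cluster" %in% config$criteria) {
    sup <- multiscale_au(fixed_panel, metric = config$cluster_metric,
                         B = config$boot_B, seed = config$seed)
    cd <- distinct_by_cluster(sup, design, config$au_threshold)
    details$cluster <- list(support = sup, distinct = cd)
    # no pairwise counts for the cluster criterion by construction
    add_row("cluster", "fixed", NA_integer_, length(cd))
  }

  concordance <- NULL
  if (!is.null(traits) && !is.null(fixed_panel)) {
    sig_traits <- details$morpho$report$trait[
      !is.na(details$morpho$report$p) & details$morpho$report$p < 0.05]
    layers <- list(marker = population_layer_distance(fixed_panel, design))
    if (length(sig_traits) > 0)
      layers$morpho <- population_layer_distance(traits, traits = sig_traits)
    if (length(layers) >= 2)
      concordance <- concordance_report(layers, nperm = config$nperm,
                                        seed = config$seed)
  }

  structure(list(summary = do.call(rbind, summary_rows), details = details,
                 concordance = concordance),
            class = "dus_run")
}

#' @export
print.dus_run <- function(x, ...) {
  cat("Distinctness pipeline summary\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$concordance)) {
    cat("\nLayer concordance (Mantel)\n")
    print(x$concordance, row.names = FALSE)
  }
  invisible(x)
}

#' Write the pipeline summary as TSV
#' @param run a `dus_run`.
#' @param path output file path.
#' @export
write_summary_tsv <- function(run, path) {
  utils::write.table(run$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
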