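#' Configuration for an end-to-end pipeline run
#'
#' Collects every input and tuning choice of the full analysis so a run is
#' reproducible from its config alone. Either provide file inputs
#' (`traits_csv`, `trees_files`) or set `simulate = TRUE` to generate a
#' synthetic study dataset internally.
#'
#' @param traits_csv Path to the 16-trait CSV (ignored when simulating).
#' @param trees_files Character vector of tree files (ignored when
#'   simulating).
#' @param synonyms Optional named character vector for tip-label
#'   reconciliation.
#' @param simulate Generate the inputs with [simulate_study()].
#' @param sim_config A [study_config()] used when `simulate = TRUE`.
#' @param n_trees Number of trees to analyse (sampled from the files when
#'   reading; generated when simulating).
#' @param k Neighbour count for uniqueness.
#' @param ks Neighbour counts for the robustness check.
#' @param alpha Significance level.
#' @param pgls_correlation `"BM"` or `"lambda"`.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(traits_csv = NULL, trees_files = NULL,
                            synonyms = NULL, simulate = is.null(traits_csv),
                            sim_config = study_config(n_trees = n_trees),
                            n_trees = 100, k = 5, ks = c(1, 3, 5, 10, 100),
                            alpha = 0.05, pgls_correlation = "BM", seed = 1) {
  if (!simulate && (is.null(traits_csv) || is.null(trees_files))) {
    stop("config error: provide traits_csv and trees_files, or simulate = TRUE")
  }
  structure(
    list(traits_csv = traits_csv, trees_files = trees_files,
         synonyms = synonyms, simulate = simulate, sim_config = sim_config,
         n_trees = n_trees, k = k, ks = ks, alpha = alpha,
         pgls_correlation = pgls_correlation, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full niche-space pipeline
#'
#' Sequences every stage: trait ingestion (or simulation), listwise
#' deletion, correlation screen, life-history PCA, mixed-data factor
#' analysis with Kaiser retention, uniqueness/specialisation scoring with
#' neighbour robustness, per-tree phylogenetic signal and evolutionary-mode
#' fits with cross-tree summaries, and tree-replicated PGLS for both
#' scores. All artifacts are flat CSV/JSON files under `out_dir`; a
#' manifest records the config, seed and stage outputs. Reruns with the
#' same config produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing and returns results only.
#' @return Invisibly, a list with every stage result: `table` (raw),
#'   `elements` (11-element table), `lh` (life-history PCA),
#'   `correlations`, `famd`, `space`, `scores`, `robustness`, `evo`
#'   (per-tree), `evo_summary`, `pgls_uniqueness`, `pgls_specialisation`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if (config$simulate) {
    sim <- stage("simulate", simulate_study(config$sim_config, seed = config$seed))
    raw <- sim$table
    trees <- sim$trees
    truth <- sim$truth
  } else {
    raw <- stage("read_traits", read_trait_table(config$traits_csv))
    trees <- stage("read_trees",
                   load_tree_set(config$trees_files, n_sample = config$n_trees,
                                 seed = config$seed))
    truth <- NULL
  }

  complete <- stage("drop_incomplete", suppressMessages(drop_incomplete(raw)))
  corr <- stage("correlation_screen", correlation_screen(complete))
  lh <- stage("life_history", life_history_score(complete))
  fam <- stage("famd", famd_fit(lh$table))
  space <- stage("kaiser", retain_kaiser(fam))
  scores <- stage("metrics", niche_scores(space, k = config$k))
  ks_ok <- config$ks[config$ks < nrow(scores)]
  robust <- stage("robustness", neighbour_robustness(space, ks = ks_ok,
                                                     k_ref = config$k))
  evo <- stage("evo_inference", evo_across_trees(space, trees))
  evo_sum <- summarise_across_trees(evo, alpha = config$alpha)
  pgls_u <- stage("pgls_uniqueness",
                  multi_tree_pgls(lh$table, scores, "uniqueness", trees,
                                  alpha = config$alpha,
                                  correlation = config$pgls_correlation))
  pgls_s <- stage("pgls_specialisation",
                  multi_tree_pgls(lh$table, scores, "specialisation", trees,
                                  alpha = config$alpha,
                                  correlation = config$pgls_correlation))

  manifest <- list(
    seed = config$seed,
    n_species = nrow(complete),
    n_trees = length(trees),
    k = config$k,
    alpha = config$alpha,
    pgls_correlation = config$pgls_correlation,
    n_dimensions = space$n_dimensions,
    pct_variance_retained = sum(space$pct_variance),
    lh_pct_variance_pc1 = lh$pct_variance_pc1,
    artifacts = c("coordinates.csv", "eigenvalues.csv", "contributions.csv",
                  "scores.csv", "robustness.csv", "evo_per_tree.csv",
                  "evo_summary.csv", "pgls_uniqueness.csv",
                  "pgls_specialisation.csv")
  )
  res <- list(table = raw, elements = lh$table, lh = lh, correlations = corr,
              famd = fam, space = space, scores = scores, robustness = robust,
              evo = evo, evo_summary = evo_sum,
              pgls_uniqueness = pgls_u, pgls_specialisation = pgls_s,
              truth = truth, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) readr::write_csv(x, file.path(out_dir, f), progress = FALSE)
    w(space$coordinates, "coordinates.csv")
    w(tibble::tibble(dimension = paste0("Dim", seq_len(space$n_dimensions)),
                     eigenvalue = space$eigenvalues,
                     pct_variance = space$pct_variance,
                     cum_pct_variance = space$cum_pct_variance),
      "eigenvalues.csv")
    w(space$contributions, "contributions.csv")
    w(tibble::as_tibble(scores), "scores.csv")
    w(robust, "robustness.csv")
    w(evo, "evo_per_tree.csv")
    w(evo_sum, "evo_summary.csv")
    w(tibble::as_tibble(pgls_u), "pgls_uniqueness.csv")
    w(tibble::as_tibble(pgls_s), "pgls_specialisation.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(truth)) write_truth(truth, file.path(out_dir, "truth.json"))
  }
  invisible(res)
}
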