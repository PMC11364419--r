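#' Pipeline run configuration
#'
#' Bundles everything a reproducible run needs: the circuit, ensemble
#' sizes, seeds, scoring options and the output directory. Validated on
#' construction so pipeline entry points can fail fast with a clear
#' message.
#'
#' @param out_dir Output directory (created if missing).
#' @param topology Path to a `.topo` file, or `NULL` for the packaged
#'   melanocyte circuit.
#' @param n_models,n_init Ensemble size.
#' @param seed Master seed (first element used for single-ensemble runs).
#' @param seeds Replicate seeds for perturbation runs.
#' @param pig_nodes Pigmentation node set.
#' @param threshold High-pigment cutoff.
#' @param k Cluster count, `NULL` for automatic silhouette selection.
#' @param settings An [engine_settings()] list.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir, topology = NULL, n_models = 2000L,
                       n_init = 20L, seed = 1L, seeds = c(101L, 102L, 103L),
                       pig_nodes = c("MITF", "LEF1"), threshold = 0.22,
                       k = NULL, settings = engine_settings()) {
  if (n_models < 1 || n_init < 1) abort("counts must be at least 1")
  if (length(seeds) < 1) abort("`seeds` must not be empty")
  if (!is.null(topology) && !file.exists(topology)) {
    abort(sprintf("topology file not found: %s", topology))
  }
  structure(list(out_dir = out_dir, topology = topology,
                 n_models = as.integer(n_models), n_init = as.integer(n_init),
                 seed = as.integer(seed), seeds = as.integer(seeds),
                 pig_nodes = pig_nodes, threshold = threshold, k = k,
                 settings = settings),
            class = "run_config")
}

config_network <- function(config) {
  if (is.null(config$topology)) {
    melanocyte_network()
  } else {
    read_topology(config$topology)
  }
}

# Write a manifest of config, package version and output checksums.
write_manifest <- function(config, files, path) {
  manifest <- list(
    package = "melcircuit",
    version = as.character(packageVersion("melcircuit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[setdiff(names(config), "settings")],
    settings = unclass(config$settings),
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# Run a block, removing any files it wrote if it fails part-way.
with_cleanup <- function(out_dir, files, expr) {
  tryCatch(expr, error = function(e) {
    for (f in files) if (file.exists(f)) unlink(f)
    abort(conditionMessage(e))
  })
}

#' Simulate-and-classify pipeline
#'
#' End-to-end control run: ensemble simulation, log2/z normalisation,
#' Ward clustering with silhouette-selected k, pigmentation scoring and
#' high-pigment classification. Writes `parameters.csv`,
#' `steady_states.csv`, `states_annotated.csv`, `cluster_profiles.csv`,
#' `run_log.txt` and `manifest.json` into the configured output
#' directory.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the `ensemble_result`, the
#'   `state_assignment`, the `pigment_classification` and the output
#'   paths.
#' @export
run_state_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir,
                     c("parameters.csv", "steady_states.csv",
                       "states_annotated.csv", "cluster_profiles.csv",
                       "run_log.txt", "manifest.json"))
  names(paths) <- c("parameters", "steady_states", "states_annotated",
                    "cluster_profiles", "run_log", "manifest")
  with_cleanup(config$out_dir, paths, {
    net <- config_network(config)
    ens <- run_ensemble(net, n_models = config$n_models,
                        n_init = config$n_init, seed = config$seed,
                        settings = config$settings)
    norm <- log2_znormalize(ens)
    assign <- cluster_states(norm, k = config$k,
                             pig_nodes = config$pig_nodes,
                             threshold = config$threshold)
    cls <- classify_pigment_states(assign$pigmentation_score,
                                   config$threshold)
    readr::write_csv(ens$params, paths["parameters"])
    readr::write_csv(ens$states, paths["steady_states"])
    readr::write_csv(tidy(assign), paths["states_annotated"])
    readr::write_csv(assign$cluster_profiles, paths["cluster_profiles"])
    log_lines <- c(
      sprintf("seed: %d", config$seed),
      sprintf("models: %d  inits: %d", config$n_models, config$n_init),
      sprintf("steady states: %d", nrow(ens$states)),
      sprintf("non-converged trajectories: %d", ens$n_nonconverged),
      sprintf("models with no state: %d", ens$n_models_empty),
      sprintf("selected k: %d", assign$k),
      if (!is.null(assign$silhouette)) {
        sprintf("mean silhouette (k=%s): %s",
                paste(names(assign$silhouette), collapse = ","),
                paste(sprintf("%.4f", assign$silhouette), collapse = ","))
      },
      sprintf("fraction high-pigment (score > %g): %.4f",
              config$threshold, cls$fraction_high)
    )
    writeLines(log_lines, paths["run_log"])
    write_manifest(config, paths[names(paths) != "manifest"],
                   paths["manifest"])
    invisible(list(ensemble = ens, assignment = assign,
                   classification = cls, paths = paths))
  })
}

#' Re-run state analysis on an existing steady-state table
#'
#' Reads a `steady_states.csv` written by [run_state_pipeline()] (or any
#' table with `model_id`, `state_index`, node columns and `residual`) and
#' repeats normalisation, clustering and classification without
#' re-simulating.
#'
#' @param states_csv Path to a steady-state table.
#' @param config A [run_config()] (ensemble sizes are ignored).
#' @return Invisibly, a list with the `state_assignment`, classification
#'   and output paths (`states_annotated.csv`, `cluster_profiles.csv`,
#'   `manifest.json`).
#' @export
run_classification_pipeline <- function(states_csv, config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(states_csv)) {
    abort(sprintf("steady-state table not found: %s", states_csv))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir,
                     c("states_annotated.csv", "cluster_profiles.csv",
                       "manifest.json"))
  names(paths) <- c("states_annotated", "cluster_profiles", "manifest")
  with_cleanup(config$out_dir, paths, {
    states <- readr::read_csv(states_csv, show_col_types = FALSE)
    norm <- log2_znormalize(states)
    assign <- cluster_states(norm, k = config$k,
                             pig_nodes = config$pig_nodes,
                             threshold = config$threshold)
    cls <- classify_pigment_states(assign$pigmentation_score,
                                   config$threshold)
    readr::write_csv(tidy(assign), paths["states_annotated"])
    readr::write_csv(assign$cluster_profiles, paths["cluster_profiles"])
    write_manifest(config, paths[names(paths) != "manifest"],
                   paths["manifest"])
    invisible(list(assignment = assign, classification = cls,
                   paths = paths))
  })
}

#' Overexpression-experiment pipeline
#'
#' Wraps [run_perturbation_experiment()] and writes
#' `perturbation_summary.csv` (per-replicate fractions plus the pooled
#' delta and t test) and `manifest.json`.
#'
#' @param config A [run_config()] (uses `seeds` as replicate seeds).
#' @param node Node to overexpress.
#' @param fold Overexpression fold.
#' @return Invisibly, a list with the `perturbation_comparison` and
#'   output paths.
#' @export
run_perturbation_pipeline <- function(config, node, fold = 20) {
  stopifnot(inherits(config, "run_config"))
  net <- config_network(config)
  if (!node %in% network_nodes(net)) {
    abort(sprintf("node '%s' is not in the network", node))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir,
                     c("perturbation_summary.csv", "manifest.json"))
  names(paths) <- c("summary", "manifest")
  with_cleanup(config$out_dir, paths, {
    cmp <- run_perturbation_experiment(
      net, node, fold = fold, n_models = config$n_models,
      n_init = config$n_init, seeds = config$seeds,
      pig_nodes = config$pig_nodes, threshold = config$threshold,
      settings = config$settings)
    summary <- dplyr::bind_cols(tidy(cmp),
                                glance(cmp)[, c("node", "fold", "delta",
                                                "t_statistic", "p_value")])
    readr::write_csv(summary, paths["summary"])
    write_manifest(config, paths["summary"], paths["manifest"])
    invisible(list(comparison = cmp, paths = paths))
  })
}

#' Synthetic-expression pipeline
#'
#' Wraps the simulate-score-classify loop of the synthetic single-cell
#' stage: generates a matrix, scores the cluster-by-state heatmap with the
#' true labels as clusters, and reports recovery accuracy. Writes
#' `expression_matrix.csv` (genes x cells), `cell_labels.csv`,
#' `state_scores.csv`, `recovery.json` and `manifest.json`.
#'
#' @param config A [run_config()] (uses `seed`).
#' @param n_states,n_cells,effect,dispersion Generator geometry.
#' @return Invisibly, a list with the `synthetic_expression`, the
#'   `state_score_matrix`, `accuracy` and output paths.
#' @export
run_synthesis_pipeline <- function(config, n_states = 4L, n_cells = 1000L,
                                   effect = 1, dispersion = 0.5) {
  stopifnot(inherits(config, "run_config"))
  if (n_states < 1 || n_cells < n_states) {
    abort("invalid geometry: need n_states >= 1 and n_cells >= n_states")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir,
                     c("expression_matrix.csv", "cell_labels.csv",
                       "state_scores.csv", "recovery.json",
                       "manifest.json"))
  names(paths) <- c("matrix", "labels", "scores", "recovery", "manifest")
  with_cleanup(config$out_dir, paths, {
    mm <- marker_map(states = paste0("S", seq_len(n_states)))
    mat <- simulate_cells(mm, n_cells = n_cells, effect = effect,
                          dispersion = dispersion, seed = config$seed)
    sm <- state_score_heatmap(mat)
    acc <- evaluate_recovery(sm)
    readr::write_csv(tibble::as_tibble(mat$expr, rownames = "gene"),
                     paths["matrix"])
    readr::write_csv(tibble::tibble(cell = colnames(mat$expr),
                                    state = mat$labels), paths["labels"])
    readr::write_csv(tidy(sm), paths["scores"])
    jsonlite::write_json(list(accuracy = acc, effect = effect,
                              dispersion = dispersion,
                              n_states = n_states, n_cells = n_cells),
                         paths["recovery"], auto_unbox = TRUE, digits = NA)
    write_manifest(config, paths[names(paths) != "manifest"],
                   paths["manifest"])
    invisible(list(matrix = mat, scores = sm, accuracy = acc,
                   paths = paths))
  })
}
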