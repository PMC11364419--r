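#' Marker map for synthetic cell states
#'
#' Defines the gene universe of the synthetic single-cell generator: each
#' transcriptional state owns a disjoint set of marker genes, plus a pool
#' of unassigned background genes. This mirrors the structure exploited by
#' gene-set state scoring of real single-cell clusters, where each state
#' is identified by elevated mean expression of its own markers.
#'
#' @param states Character vector of state names.
#' @param genes_per_state Markers per state.
#' @param background_genes Number of unassigned genes.
#' @return A `marker_map`: list with `$markers` (named list of gene name
#'   vectors per state) and `$background` (character vector).
#' @examples
#' mm <- marker_map(states = paste0("S", 1:4))
#' lengths(mm$markers)
#' @export
marker_map <- function(states = paste0("S", 1:4), genes_per_state = 20L,
                       background_genes = 100L) {
  if (length(states) < 1) abort("need at least one state")
  if (anyDuplicated(states)) abort("state names must be unique")
  if (genes_per_state < 1) abort("each state needs at least one marker")
  markers <- lapply(states, function(s) {
    sprintf("%s_M%02d", s, seq_len(genes_per_state))
  })
  names(markers) <- states
  background <- sprintf("BG%03d", seq_len(background_genes))
  structure(list(markers = markers, background = background),
            class = "marker_map")
}

#' @export
print.marker_map <- function(x, ...) {
  cat(sprintf("<marker_map> %d states x %d markers + %d background genes\n",
              length(x$markers), length(x$markers[[1]]),
              length(x$background)))
  invisible(x)
}

#' Simulate a synthetic single-cell expression matrix
#'
#' Generates cells drawn from a small number of discrete transcriptional
#' states: gene `g` in cell `c` has expression
#' `exp(base + effect * [g is a marker of c's state] + N(0, dispersion))`,
#' i.e., log-normal multiplicative noise around a baseline, with the
#' cell's own-state markers elevated by `effect` on the log scale.
#' At `effect = 0` states are statistically indistinguishable (null
#' construction); the generator is fully reproducible under `seed`.
#'
#' @param markers A [marker_map()].
#' @param n_cells Number of cells (at least the number of states).
#' @param effect Log-scale elevation of own-state markers (non-negative).
#' @param dispersion Standard deviation of the log-scale noise.
#' @param seed Integer seed.
#' @param base Baseline log expression.
#' @param proportions Optional state proportions (recycled to the states,
#'   normalised to 1); default uniform.
#' @return A `synthetic_expression`: list with `$expr` (genes x cells
#'   matrix), `$labels` (state per cell), `$markers`, and the generation
#'   parameters.
#' @examples
#' mat <- simulate_cells(marker_map(), n_cells = 100, effect = 1,
#'                       dispersion = 0.5, seed = 7)
#' dim(mat$expr)
#' @export
simulate_cells <- function(markers, n_cells = 1000L, effect = 1,
                           dispersion = 0.5, seed = 1L, base = 2,
                           proportions = NULL) {
  stopifnot(inherits(markers, "marker_map"))
  states <- names(markers$markers)
  if (length(states) == 0) abort("empty marker map")
  if (effect < 0) abort("`effect` must be non-negative")
  if (n_cells < length(states)) {
    abort("need at least as many cells as states")
  }
  if (is.null(proportions)) proportions <- rep(1, length(states))
  proportions <- rep_len(proportions, length(states))
  proportions <- proportions / sum(proportions)
  genes <- c(unlist(markers$markers, use.names = FALSE), markers$background)
  withr::local_seed(seed)
  labels <- sample(states, n_cells, replace = TRUE, prob = proportions)
  mu <- matrix(base, nrow = length(genes), ncol = n_cells,
               dimnames = list(genes, sprintf("cell%04d", seq_len(n_cells))))
  for (s in states) {
    mu[markers$markers[[s]], labels == s] <-
      mu[markers$markers[[s]], labels == s] + effect
  }
  expr <- exp(mu + matrix(rnorm(length(mu), 0, dispersion), nrow = nrow(mu)))
  structure(list(expr = expr, labels = labels, markers = markers,
                 params = list(n_cells = n_cells, effect = effect,
                               dispersion = dispersion, seed = seed,
                               base = base, proportions = proportions)),
            class = "synthetic_expression")
}

#' @export
print.synthetic_expression <- function(x, ...) {
  cat(sprintf(
    "<synthetic_expression> %d genes x %d cells, %d states (effect %g, dispersion %g)\n",
    nrow(x$expr), ncol(x$expr), length(unique(x$labels)),
    x$params$effect, x$params$dispersion))
  invisible(x)
}

#' @describeIn simulate_cells Long tibble (gene, cell, state, expression).
#' @param x A `synthetic_expression`.
#' @param ... Unused.
#' @export
tidy.synthetic_expression <- function(x, ...) {
  out <- tibble::as_tibble(x$expr, rownames = "gene")
  out <- tidyr::pivot_longer(out, -"gene", names_to = "cell",
                             values_to = "expression")
  out$state <- x$labels[match(out$cell, colnames(x$expr))]
  out[, c("gene", "cell", "state", "expression")]
}

#' Gene-set module score per cell
#'
#' Mean expression of a gene set in each cell minus the mean expression of
#' a size-matched random background set drawn (with a fixed seed) from the
#' non-member genes. The background subtraction centres the score so that
#' global additive shifts in expression cancel; this is a simplified
#' stand-in for expression-binned control-gene module scoring.
#'
#' @param mat A `synthetic_expression` (or genes x cells matrix).
#' @param gene_set Character vector of member genes.
#' @param bg_seed Seed of the background draw.
#' @return Named numeric vector: one score per cell.
#' @export
module_score <- function(mat, gene_set, bg_seed = 42L) {
  expr <- if (inherits(mat, "synthetic_expression")) mat$expr else mat
  if (length(gene_set) == 0) abort("`gene_set` must not be empty")
  missing <- setdiff(gene_set, rownames(expr))
  if (length(missing) > 0) {
    abort(paste0("gene(s) not in matrix: ", paste(missing, collapse = ", ")))
  }
  pool <- setdiff(rownames(expr), gene_set)
  if (length(pool) == 0) abort("no non-member genes to draw a background from")
  bg <- withr::with_seed(bg_seed, {
    sample(pool, min(length(gene_set), length(pool)))
  })
  colMeans(expr[gene_set, , drop = FALSE]) -
    colMeans(expr[bg, , drop = FALSE])
}

#' Cluster-by-state score matrix ("z-score of mean" heatmap)
#'
#' For every combination of cell cluster and transcriptional state,
#' computes the mean module score of that state's marker set over the
#' cluster's cells, then z-scores each cluster row across states. When
#' clusters align with the generating states and the marker effect is
#' strong, the matrix is diagonal-dominant: each cluster's top score lies
#' on its own state.
#'
#' @param mat A `synthetic_expression`.
#' @param cluster_labels Cluster label per cell (defaults to the true
#'   generating states).
#' @param markers A [marker_map()] (defaults to the matrix's own).
#' @param bg_seed Background seed passed to [module_score()].
#' @return A `state_score_matrix`: clusters x states numeric matrix with
#'   attribute `means` (the pre-z-scored cluster means). Rows with zero
#'   variance (e.g., a single state) are reported as all-zero by
#'   convention.
#' @export
state_score_heatmap <- function(mat, cluster_labels = NULL, markers = NULL,
                                bg_seed = 42L) {
  stopifnot(inherits(mat, "synthetic_expression"))
  if (is.null(cluster_labels)) cluster_labels <- mat$labels
  if (length(cluster_labels) != ncol(mat$expr)) {
    abort("`cluster_labels` must label every cell")
  }
  if (is.null(markers)) markers <- mat$markers
  states <- names(markers$markers)
  clusters <- sort(unique(cluster_labels))
  small <- clusters[table(factor(cluster_labels, clusters)) < 2]
  if (length(small) > 0) {
    warn(paste0("cluster(s) with fewer than 2 cells: ",
                paste(small, collapse = ", ")))
  }
  scores <- vapply(states, function(s) {
    module_score(mat, markers$markers[[s]], bg_seed = bg_seed)
  }, numeric(ncol(mat$expr)))
  means <- t(vapply(clusters, function(cl) {
    colMeans(scores[cluster_labels == cl, , drop = FALSE])
  }, numeric(length(states))))
  dimnames(means) <- list(clusters, states)
  z <- t(apply(means, 1, function(r) {
    s <- sd(r)
    if (length(r) < 2 || !is.finite(s) || s == 0) {
      rep(0, length(r))
    } else {
      (r - mean(r)) / s
    }
  }))
  dimnames(z) <- dimnames(means)
  structure(z, means = means, class = c("state_score_matrix", "matrix"))
}

#' @export
print.state_score_matrix <- function(x, ...) {
  cat(sprintf("<state_score_matrix> %d clusters x %d states (row z-scores)\n",
              nrow(x), ncol(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

#' @describeIn state_score_heatmap Long tibble (cluster, state, z, mean).
#' @param x A `state_score_matrix`.
#' @param ... Unused.
#' @export
tidy.state_score_matrix <- function(x, ...) {
  means <- attr(x, "means")
  out <- expand.grid(cluster = rownames(x), state = colnames(x),
                     stringsAsFactors = FALSE)
  out$z <- as.vector(unclass(x))
  out$mean_score <- as.vector(means)
  tibble::as_tibble(out)
}

#' Cluster-to-state recovery accuracy
#'
#' Fraction of clusters whose argmax column in the state-score matrix
#' matches the state that generated them -- the end-to-end check that the
#' simulate-score-classify loop recovers the truth.
#'
#' @param score_mat A `state_score_matrix`.
#' @param truth Named character vector mapping each cluster (rowname) to
#'   its generating state; defaults to clusters named after their states.
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_recovery <- function(score_mat, truth = NULL) {
  stopifnot(inherits(score_mat, "state_score_matrix"))
  if (is.null(truth)) {
    truth <- setNames(rownames(score_mat), rownames(score_mat))
  }
  missing <- setdiff(rownames(score_mat), names(truth))
  if (length(missing) > 0) {
    abort(paste0("no generating state given for cluster(s): ",
                 paste(missing, collapse = ", ")))
  }
  predicted <- colnames(score_mat)[apply(unclass(score_mat), 1, which.max)]
  mean(predicted == unname(truth[rownames(score_mat)]))
}
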