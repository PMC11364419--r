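#' Log2 z-normalisation of ensemble steady states
#'
#' All downstream analysis works in z-score coordinates: steady-state
#' expression levels are log2-transformed and each node column is centred
#' and scaled over all steady states (each state counted once, regardless
#' of which model produced it). The per-node means and standard deviations
#' are stored so that a perturbed ensemble can be projected into the
#' *control* coordinate system via the `reference` argument, which is how
#' overexpression experiments are scored.
#'
#' @param ens An `ensemble_result` from [run_ensemble()], or a data frame
#'   of steady states with one column per node.
#' @param reference Optional `normalized_ensemble` whose stored means/sds
#'   are applied instead of recomputing them (control-anchored scoring).
#' @return A `normalized_ensemble`: list with matrix `$z` (states x nodes),
#'   `$node_means`, `$node_sds` (log2 scale), `$nodes`, `$states` (the
#'   bookkeeping columns `model_id`, `state_index`, `residual`) and
#'   `$network`.
#' @export
log2_znormalize <- function(ens, reference = NULL) {
  if (inherits(ens, "ensemble_result")) {
    states <- ens$states
    nodes <- network_nodes(ens$network)
    network <- ens$network
  } else {
    states <- tibble::as_tibble(ens)
    nodes <- setdiff(names(states), c("model_id", "state_index", "residual"))
    network <- NULL
  }
  if (nrow(states) < 2) abort("need at least 2 steady states to normalise")
  xm <- as.matrix(states[, nodes])
  if (any(!is.finite(xm)) || any(xm <= 0)) {
    abort("steady-state levels must be finite and strictly positive")
  }
  lx <- log2(xm)
  if (is.null(reference)) {
    mu <- colMeans(lx)
    sdv <- apply(lx, 2, sd)
    zero <- nodes[sdv == 0]
    if (length(zero) > 0) {
      abort(paste0("zero variance in node(s): ", paste(zero, collapse = ", ")))
    }
  } else {
    stopifnot(inherits(reference, "normalized_ensemble"))
    if (!identical(reference$nodes, nodes)) {
      abort("reference normalisation was computed for different nodes")
    }
    mu <- reference$node_means
    sdv <- reference$node_sds
  }
  z <- sweep(sweep(lx, 2, mu), 2, sdv, "/")
  book <- states[, intersect(c("model_id", "state_index", "residual"),
                             names(states))]
  structure(list(z = z, node_means = mu, node_sds = sdv, nodes = nodes,
                 states = book, network = network),
            class = "normalized_ensemble")
}

#' @export
print.normalized_ensemble <- function(x, ...) {
  cat(sprintf("<normalized_ensemble> %d states x %d nodes (log2 z-scores)\n",
              nrow(x$z), length(x$nodes)))
  invisible(x)
}

#' @describeIn log2_znormalize z-score matrix as a tibble with bookkeeping
#'   columns.
#' @param x A `normalized_ensemble`.
#' @param ... Unused.
#' @export
tidy.normalized_ensemble <- function(x, ...) {
  dplyr::bind_cols(x$states, tibble::as_tibble(x$z))
}

#' Per-state pigmentation score
#'
#' The pigmentation score of a steady state is the mean z-normalised
#' expression of the pigmentation nodes (by default MITF and LEF1). On the
#' melanocyte circuit its distribution over the ensemble is bimodal, with
#' the two modes corresponding to the low- and high-pigment phenotypes.
#'
#' @param norm A `normalized_ensemble`.
#' @param pig_nodes Character vector of pigmentation node names.
#' @return Numeric score vector, one value per steady state.
#' @export
pigmentation_score <- function(norm, pig_nodes = c("MITF", "LEF1")) {
  stopifnot(inherits(norm, "normalized_ensemble"))
  if (length(pig_nodes) == 0) abort("`pig_nodes` must not be empty")
  missing <- setdiff(pig_nodes, norm$nodes)
  if (length(missing) > 0) {
    abort(paste0("pigmentation node(s) not in ensemble: ",
                 paste(missing, collapse = ", ")))
  }
  rowMeans(norm$z[, pig_nodes, drop = FALSE])
}

#' Classify high- vs low-pigment steady states
#'
#' A steady state is called high-pigment when its pigmentation score
#' strictly exceeds the threshold. The default cutoff 0.22 is the value
#' derived from the antimode of the bimodal control-ensemble score
#' distribution (see [rederive_threshold()]).
#'
#' @param scores Numeric pigmentation score vector.
#' @param threshold Score cutoff (strict inequality).
#' @return A `pigment_classification`: list with `threshold`, logical
#'   `is_high`, `fraction_high` and `n_total`.
#' @export
classify_pigment_states <- function(scores, threshold = 0.22) {
  if (length(scores) == 0) abort("`scores` must not be empty")
  if (!is.finite(threshold)) abort("`threshold` must be finite")
  is_high <- scores > threshold
  structure(list(threshold = threshold, is_high = is_high,
                 fraction_high = mean(is_high), n_total = length(scores)),
            class = "pigment_classification")
}

#' @export
print.pigment_classification <- function(x, ...) {
  cat(sprintf(
    "<pigment_classification> %.1f%% of %d states high-pigment (score > %g)\n",
    100 * x$fraction_high, x$n_total, x$threshold))
  invisible(x)
}

#' @describeIn classify_pigment_states One-row summary tibble.
#' @param x A `pigment_classification`.
#' @param ... Unused.
#' @export
glance.pigment_classification <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, fraction_high = x$fraction_high,
                 n_high = sum(x$is_high), n_total = x$n_total)
}

#' Assess bimodality of a score distribution
#'
#' Operationalises "clearly bimodal" with two independent checks: the dip
#' test of unimodality (reject at `alpha`) and a model-selection check that
#' a two-component unequal-variance Gaussian mixture beats one component by
#' BIC (fitted with mclust).
#'
#' @param scores Numeric vector.
#' @param alpha Dip-test significance level.
#' @param n_sim Monte-Carlo simulations for the dip p-value.
#' @return A list: `dip`, `dip_p`, `bic1`, `bic2`, `mixture_preferred`,
#'   `bimodal` (both checks passed).
#' @export
assess_bimodality <- function(scores, alpha = 0.05, n_sim = 1000L) {
  dt <- dip_test(scores, n_sim = n_sim)
  bic <- mclust::mclustBIC(scores, G = 1:2, modelNames = "V",
                           verbose = FALSE)
  bic1 <- bic["1", "V"]
  bic2 <- bic["2", "V"]
  mixture_preferred <- is.finite(bic2) && bic2 > bic1
  list(dip = dt$statistic, dip_p = dt$p_value, bic1 = bic1, bic2 = bic2,
       mixture_preferred = mixture_preferred,
       bimodal = dt$p_value < alpha && mixture_preferred)
}

#' Re-derive the pigmentation threshold from a bimodal score distribution
#'
#' Locates the antimode -- the minimum of a kernel density estimate between
#' the two dominant modes -- of a control-ensemble score distribution.
#' Offered as a data-driven alternative to the fixed 0.22 default; errors
#' on distributions that fail the bimodality assessment.
#'
#' @param scores Numeric score vector.
#' @param n_sim Monte-Carlo simulations for the dip p-value.
#' @return The antimode (scalar score cutoff).
#' @export
rederive_threshold <- function(scores, n_sim = 1000L) {
  bim <- assess_bimodality(scores, n_sim = n_sim)
  if (!bim$bimodal) {
    abort(paste0("score distribution is not clearly bimodal ",
                 sprintf("(dip p = %.3g, BIC1 = %.1f, BIC2 = %.1f); ",
                         bim$dip_p, bim$bic1, bim$bic2),
                 "use the fixed default threshold instead"))
  }
  d <- density(scores)
  # local maxima of the KDE, ranked by height
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_max) < 2) {
    abort("kernel density estimate has fewer than 2 modes; use the fixed default")
  }
  top2 <- sort(is_max[order(y[is_max], decreasing = TRUE)][1:2])
  between <- seq(top2[1], top2[2])
  d$x[between[which.min(y[between])]]
}

#' Cluster z-normalised steady states into phenotypic states
#'
#' Agglomerative clustering (Ward linkage on Euclidean distance in z-score
#' space) of ensemble steady states. When `k` is `NULL` the number of
#' clusters is chosen by maximal mean silhouette width over `k_range`.
#' Clusters are relabelled canonically in descending mean pigmentation
#' score, so cluster 1 is always the most pigmented phenotype.
#'
#' @param norm A `normalized_ensemble`.
#' @param k Number of clusters, or `NULL` for automatic selection.
#' @param k_range Candidate cluster numbers for automatic selection.
#' @param pig_nodes Pigmentation nodes used for scoring and canonical
#'   ordering; defaults to those present among MITF/LEF1, falling back to
#'   ordering by cluster size for circuits without them.
#' @param threshold High-pigment cutoff passed to
#'   [classify_pigment_states()].
#' @return A `state_assignment`: list with `labels`, `k`,
#'   `silhouette` (mean width per candidate k), `cluster_profiles` (tibble
#'   of per-cluster mean z per node, plus size and mean score),
#'   `pigmentation_score`, `is_high_pigment`, `threshold` and the
#'   underlying `normalized_ensemble`.
#' @export
cluster_states <- function(norm, k = NULL, k_range = 2:8,
                           pig_nodes = c("MITF", "LEF1"),
                           threshold = 0.22) {
  stopifnot(inherits(norm, "normalized_ensemble"))
  z <- norm$z
  n <- nrow(z)
  if (!is.null(k) && n < k) {
    abort(sprintf("cannot form %d clusters from %d states", k, n))
  }
  dd <- dist(z)
  hc <- hclust(dd, method = "ward.D2")
  sil <- NULL
  if (is.null(k)) {
    k_range <- k_range[k_range < n]
    sil <- vapply(k_range, function(kk) {
      mean(cluster::silhouette(cutree(hc, kk), dd)[, "sil_width"])
    }, numeric(1))
    names(sil) <- k_range
    k <- k_range[which.max(sil)]
  }
  labels <- cutree(hc, k)

  pig_nodes <- intersect(pig_nodes, norm$nodes)
  scores <- if (length(pig_nodes) > 0) {
    pigmentation_score(norm, pig_nodes)
  } else {
    rep(NA_real_, n)
  }
  # canonical ordering: descending mean pigmentation score, falling back to
  # descending cluster size (ties broken by old label for determinism)
  key <- if (length(pig_nodes) > 0) {
    -vapply(seq_len(k), function(cl) mean(scores[labels == cl]), numeric(1))
  } else {
    -tabulate(labels, k)
  }
  new_order <- order(key, seq_len(k))
  relabel <- integer(k)
  relabel[new_order] <- seq_len(k)
  labels <- relabel[labels]

  profiles <- dplyr::bind_cols(
    tibble::tibble(cluster = seq_len(k),
                   n_states = tabulate(labels, k)),
    tibble::as_tibble(t(vapply(seq_len(k), function(cl) {
      colMeans(z[labels == cl, , drop = FALSE])
    }, numeric(ncol(z)))))
  )
  if (length(pig_nodes) > 0) {
    profiles$mean_pigmentation <- vapply(seq_len(k), function(cl) {
      mean(scores[labels == cl])
    }, numeric(1))
  }
  cls <- if (length(pig_nodes) > 0) {
    classify_pigment_states(scores, threshold)
  } else {
    NULL
  }
  structure(list(labels = labels, k = k, silhouette = sil,
                 cluster_profiles = profiles,
                 pigmentation_score = scores,
                 is_high_pigment = if (!is.null(cls)) cls$is_high else NULL,
                 threshold = threshold, pig_nodes = pig_nodes,
                 norm = norm),
            class = "state_assignment")
}

#' @export
print.state_assignment <- function(x, ...) {
  cat(sprintf("<state_assignment> %d states in %d clusters\n",
              length(x$labels), x$k))
  if (!is.null(x$silhouette)) {
    cat("mean silhouette by k:",
        paste(names(x$silhouette), sprintf("%.3f", x$silhouette),
              sep = "=", collapse = ", "), "\n")
  }
  print(x$cluster_profiles)
  invisible(x)
}

#' @describeIn cluster_states Per-state tibble: bookkeeping, z-scores,
#'   cluster label, pigmentation score, high-pigment call.
#' @param x A `state_assignment`.
#' @param ... Unused.
#' @export
tidy.state_assignment <- function(x, ...) {
  out <- dplyr::bind_cols(x$norm$states, tibble::as_tibble(x$norm$z))
  out$cluster <- x$labels
  out$pigmentation_score <- x$pigmentation_score
  if (!is.null(x$is_high_pigment)) out$is_high_pigment <- x$is_high_pigment
  out
}

#' @describeIn cluster_states One-row summary: chosen k, best silhouette,
#'   fraction of high-pigment states.
#' @export
glance.state_assignment <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    mean_silhouette = if (!is.null(x$silhouette)) max(x$silhouette) else NA_real_,
    n_states = length(x$labels),
    fraction_high = if (!is.null(x$is_high_pigment)) {
      mean(x$is_high_pigment)
    } else NA_real_
  )
}

#' Principal-component projection of a normalised ensemble
#'
#' Standard PCA of the z-score matrix for state inspection: on the
#' melanocyte circuit the pigmentation-node loadings and the MYC/E2F
#' loadings separate into opposing half-planes of the leading components,
#' mirroring the inverse association between the pigmentation and
#' proliferation programs.
#'
#' @param norm A `normalized_ensemble` with at least 3 states.
#' @return A `state_pca`: list with `coordinates` (states x PCs tibble),
#'   `loadings` (nodes x PCs tibble), `var_explained`.
#' @export
pca_projection <- function(norm) {
  stopifnot(inherits(norm, "normalized_ensemble"))
  if (nrow(norm$z) < 3) abort("need at least 3 states for a PCA")
  pc <- prcomp(norm$z, center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    coordinates = dplyr::bind_cols(norm$states,
                                   tibble::as_tibble(pc$x)),
    loadings = dplyr::bind_cols(tibble::tibble(node = norm$nodes),
                                tibble::as_tibble(pc$rotation)),
    var_explained = ve
  ), class = "state_pca")
}

#' @export
print.state_pca <- function(x, ...) {
  cat(sprintf("<state_pca> %d states; var explained: %s\n",
              nrow(x$coordinates),
              paste(sprintf("%.1f%%", 100 * head(x$var_explained, 3)),
                    collapse = ", ")))
  invisible(x)
}
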