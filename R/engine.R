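#' Shifted Hill regulation factor
#'
#' The regulation factor multiplying a target's production rate:
#' \deqn{H_s(x; x_0, n, \lambda) = \lambda + \frac{1-\lambda}{1+(x/x_0)^n}}
#' It equals 1 at \eqn{x = 0}, tends to \eqn{\lambda} as \eqn{x \to \infty},
#' and takes the midpoint value \eqn{(1+\lambda)/2} at \eqn{x = x_0}.
#' \eqn{\lambda > 1} encodes activation, \eqn{0 < \lambda < 1} inhibition,
#' and \eqn{\lambda = 1} switches the edge off.
#'
#' @param x Regulator level(s), non-negative. Vectorised.
#' @param x0 Half-functional threshold, positive.
#' @param n Hill coefficient, at least 1.
#' @param lam Fold-change \eqn{\lambda}, positive.
#' @return Numeric vector of regulation factors.
#' @examples
#' shifted_hill(50, x0 = 50, n = 4, lam = 5) # midpoint: (1 + 5) / 2
#' @export
shifted_hill <- function(x, x0, n, lam) {
  if (any(x0 <= 0)) abort("`x0` must be positive")
  if (any(n < 1)) abort("`n` must be at least 1")
  if (any(lam <= 0)) abort("`lam` must be positive")
  if (any(x < 0)) abort("`x` must be non-negative")
  lam + (1 - lam) / (1 + (x / x0)^n)
}

#' Engine settings: sampling ranges and integration tolerances
#'
#' Collects every tunable of the ensemble simulator in one list so runs are
#' fully described by (network, settings, seed). Defaults follow the
#' published conventions of random-circuit-perturbation simulators:
#' production `g ~ U[1, 100]`, degradation `k ~ U[0.1, 1]`, Hill coefficient
#' `n ~ U{1..6}`, fold-change `lambda ~ U[1, 100]` (activation) or
#' `U[0.01, 1]` (inhibition), and half-functional thresholds
#' `x0 ~ U[0.02 M, 1.98 M]` with `M = median(g)/median(k) = 50.5/0.55`,
#' which keeps thresholds inside the dynamic range of unregulated regulator
#' levels. Initial conditions are log-uniform over
#' `[g_min/k_max, g_max/k_min] = [1, 1000]`, the span of achievable
#' unregulated fixed points.
#'
#' @param g_range,k_range Production/degradation sampling ranges.
#' @param n_range Inclusive integer range of Hill coefficients.
#' @param lam_act_range,lam_inh_range Fold-change ranges by edge sign.
#' @param x0_spread Half-functional spread: `x0 ~ U[(1-s) M, (1+s) M]`
#'   with `s = 0.98`.
#' @param ic_range Base range of the log-uniform initial-condition draw,
#'   the span of unregulated fixed points `[g_min/k_max, g_max/k_min]`.
#' @param ic_mode With `"regulated"` (default) each node's draw range is
#'   widened by its incoming regulation -- the lower bound multiplied by
#'   the strongest inhibitory fold-change per inhibiting edge and the
#'   upper bound by the strongest activating fold-change per activating
#'   edge -- so initial conditions span the node's minimum to maximum
#'   achievable levels; `"unregulated"` uses `ic_range` for every node.
#' @param t_max Integration horizon (time units).
#' @param check_dt Spacing of convergence checkpoints (time units).
#' @param settle_tol Scale-free settling tolerance on
#'   `max_i |dx_i/dt| / (1 + |x_i|)`: once sustained at two consecutive
#'   checkpoints, integration stops and the endpoint is refined to a
#'   fixed point by Newton iteration.
#' @param conv_tol Convergence tolerance on the same residual that the
#'   Newton-polished endpoint must meet to count as a steady state.
#' @param rtol,atol Relative/absolute local error tolerances of the
#'   adaptive Cash-Karp integrator.
#' @param dedup_eps Two converged endpoints are the same steady state when
#'   the Euclidean distance of their log2 vectors is below this (0.05 is
#'   about a 3.5% relative difference per node).
#' @param lam_inh_mode How inhibitory fold-changes are drawn over
#'   `lam_inh_range`: `"reciprocal"` (default) samples the reciprocal of a
#'   uniform draw on `[1/max, 1/min]`, the established convention that
#'   makes strong repression as likely as weak; `"uniform"` samples the
#'   fold-change itself uniformly.
#' @param x0_mode How half-functional thresholds are centred:
#'   `"refined"` (default) centres each edge's threshold range on a
#'   Monte-Carlo estimate of its regulator's median level given the
#'   regulator's own inputs (see [threshold_medians()]); `"simple"` uses
#'   the closed-form unregulated median `median(g)/median(k)` for every
#'   regulator.
#' @param x0_mc,x0_iters Monte-Carlo sample size and fixed-point
#'   iterations of the threshold refinement.
#' @return A named list of class `engine_settings`.
#' @export
engine_settings <- function(g_range = c(1, 100), k_range = c(0.1, 1),
                            n_range = c(1L, 6L),
                            lam_act_range = c(1, 100),
                            lam_inh_range = c(0.01, 1),
                            x0_spread = 0.98,
                            ic_range = c(1, 1000),
                            t_max = 1000, check_dt = 5,
                            settle_tol = 1e-5, conv_tol = 1e-8,
                            rtol = 1e-6, atol = 1e-9,
                            dedup_eps = 0.05,
                            lam_inh_mode = c("reciprocal", "uniform"),
                            x0_mode = c("refined", "simple"),
                            x0_mc = 5000L, x0_iters = 3L,
                            ic_mode = c("regulated", "unregulated")) {
  lam_inh_mode <- match.arg(lam_inh_mode)
  x0_mode <- match.arg(x0_mode)
  ic_mode <- match.arg(ic_mode)
  for (r in list(g_range, k_range, n_range, lam_act_range, lam_inh_range,
                 ic_range)) {
    if (length(r) != 2 || r[1] >= r[2]) abort("ranges must be ordered (min < max)")
  }
  structure(list(
    g_range = g_range, k_range = k_range, n_range = as.integer(n_range),
    lam_act_range = lam_act_range, lam_inh_range = lam_inh_range,
    x0_spread = x0_spread, ic_range = ic_range,
    t_max = t_max, check_dt = check_dt, settle_tol = settle_tol,
    conv_tol = conv_tol, rtol = rtol, atol = atol, dedup_eps = dedup_eps,
    lam_inh_mode = lam_inh_mode, x0_mode = x0_mode,
    x0_mc = as.integer(x0_mc), x0_iters = as.integer(x0_iters),
    ic_mode = ic_mode
  ), class = "engine_settings")
}

# Median unregulated level used by the half-functional threshold rule.
half_functional_median <- function(settings) {
  stats::median(settings$g_range) / stats::median(settings$k_range)
}

#' Monte-Carlo medians for the half-functional threshold rule
#'
#' Estimates the median expression level of each node under random kinetic
#' parameters, accounting for the node's own regulation: starting from the
#' unregulated median `median(g)/median(k)`, each iteration redraws random
#' parameters and regulator levels (spread around the current medians) and
#' updates each node's median level. Edge thresholds are then sampled
#' around the *regulator's* estimated median, which keeps every edge
#' functional in roughly half the ensemble even for strongly suppressed or
#' amplified regulators.
#'
#' The estimate uses its own fixed internal seed: thresholds are part of
#' the study conditions, identical across ensembles and independent of the
#' run seed.
#'
#' @param net A [reg_network()].
#' @param settings An [engine_settings()] list.
#' @return Named numeric vector: estimated median level per node.
#' @export
threshold_medians <- function(net, settings = engine_settings()) {
  nodes <- network_nodes(net)
  edges <- net$edges
  n_mc <- settings$x0_mc
  withr::with_seed(777L, {
    med <- setNames(rep(half_functional_median(settings), length(nodes)),
                    nodes)
    for (it in seq_len(settings$x0_iters)) {
      newmed <- med
      for (nd in nodes) {
        g <- runif(n_mc, settings$g_range[1], settings$g_range[2])
        k <- runif(n_mc, settings$k_range[1], settings$k_range[2])
        lvl <- g / k
        for (e in which(edges$target == nd)) {
          src <- edges$source[e]
          lam <- if (edges$sign[e] == "activation") {
            runif(n_mc, settings$lam_act_range[1], settings$lam_act_range[2])
          } else if (settings$lam_inh_mode == "reciprocal") {
            1 / runif(n_mc, 1 / settings$lam_inh_range[2],
                      1 / settings$lam_inh_range[1])
          } else {
            runif(n_mc, settings$lam_inh_range[1], settings$lam_inh_range[2])
          }
          n_h <- sample(seq(settings$n_range[1], settings$n_range[2]),
                        n_mc, replace = TRUE)
          x0 <- runif(n_mc, (1 - settings$x0_spread) * med[src],
                      (1 + settings$x0_spread) * med[src])
          xs <- runif(n_mc, (1 - settings$x0_spread) * med[src],
                      (1 + settings$x0_spread) * med[src])
          lvl <- lvl * (lam + (1 - lam) / (1 + (xs / x0)^n_h))
        }
        newmed[nd] <- stats::median(lvl)
      }
      med <- newmed
    }
    med
  })
}

# Deterministic per-model seed derived from the master seed; injective in
# model_id (multiples of 1013 are distinct modulo the prime 2^31 - 1).
model_seed <- function(seed, model_id) {
  p <- 2147483647
  as.integer((((seed %% p) * 69069) %% p + (model_id %% p) * 1013) %% p)
}

edge_label <- function(edges) paste(edges$source, edges$target, sep = "_")

#' Sample one kinetic parameter set for a circuit
#'
#' Draws one model of the ensemble: per node a basal production rate `g`
#' and degradation rate `k`, per edge a Hill coefficient `n`, fold-change
#' `lambda` (above 1 for activation, below 1 for inhibition) and
#' half-functional threshold `x0`. The draw is a pure function of
#' `(seed, model_id)`, so ensembles are reproducible and independent of
#' execution order, and perturbation runs can re-materialise the identical
#' parameter set.
#'
#' @param net A [reg_network()].
#' @param model_id Integer model index within the ensemble.
#' @param seed Master seed of the ensemble.
#' @param settings An [engine_settings()] list.
#' @param medians Optional per-node median levels from
#'   [threshold_medians()]; computed on the fly when `NULL` and
#'   `settings$x0_mode == "refined"`. [run_ensemble()] computes them once
#'   and reuses them across models.
#' @return A `model_params` list with `model_id`, numeric vectors `g`, `k`
#'   (named by node) and `n`, `lam`, `x0` (named `source_target` per edge).
#' @export
sample_model_parameters <- function(net, model_id = 1L, seed = 1L,
                                    settings = engine_settings(),
                                    medians = NULL) {
  nodes <- network_nodes(net)
  edges <- net$edges
  n_nodes <- length(nodes)
  n_edges <- nrow(edges)
  if (settings$x0_mode == "refined" && n_edges > 0) {
    if (is.null(medians)) medians <- threshold_medians(net, settings)
    x0_centre <- unname(medians[edges$source])
  } else {
    x0_centre <- rep(half_functional_median(settings), n_edges)
  }
  withr::local_seed(model_seed(seed, model_id))
  g <- runif(n_nodes, settings$g_range[1], settings$g_range[2])
  k <- runif(n_nodes, settings$k_range[1], settings$k_range[2])
  names(g) <- names(k) <- nodes
  if (n_edges > 0) {
    nn <- sample(seq(settings$n_range[1], settings$n_range[2]), n_edges,
                 replace = TRUE)
    act <- edges$sign == "activation"
    lam <- numeric(n_edges)
    lam[act] <- runif(sum(act), settings$lam_act_range[1],
                      settings$lam_act_range[2])
    if (settings$lam_inh_mode == "reciprocal") {
      lam[!act] <- 1 / runif(sum(!act), 1 / settings$lam_inh_range[2],
                             1 / settings$lam_inh_range[1])
    } else {
      lam[!act] <- runif(sum(!act), settings$lam_inh_range[1],
                         settings$lam_inh_range[2])
    }
    x0 <- runif(n_edges, (1 - settings$x0_spread) * x0_centre,
                (1 + settings$x0_spread) * x0_centre)
    nn <- as.numeric(nn)
    names(nn) <- names(lam) <- names(x0) <- edge_label(edges)
  } else {
    nn <- integer(0); lam <- numeric(0); x0 <- numeric(0)
  }
  structure(list(model_id = as.integer(model_id), g = g, k = k,
                 n = nn, lam = lam, x0 = x0),
            class = "model_params")
}

# Per-node log-uniform initial-condition bounds: the base range widened
# by each node's incoming regulation when ic_mode = "regulated".
node_ic_bounds <- function(net, settings) {
  nodes <- network_nodes(net)
  lo <- setNames(rep(settings$ic_range[1], length(nodes)), nodes)
  hi <- setNames(rep(settings$ic_range[2], length(nodes)), nodes)
  if (settings$ic_mode == "regulated" && nrow(net$edges) > 0) {
    for (i in seq_len(nrow(net$edges))) {
      tgt <- net$edges$target[i]
      if (net$edges$sign[i] == "activation") {
        hi[tgt] <- hi[tgt] * settings$lam_act_range[2]
      } else {
        lo[tgt] <- lo[tgt] * settings$lam_inh_range[1]
      }
    }
  }
  list(lo = lo, hi = hi)
}

# 0-based edge endpoint indices for the C++ core
edge_indices <- function(net) {
  nodes <- network_nodes(net)
  list(src = match(net$edges$source, nodes) - 1L,
       tgt = match(net$edges$target, nodes) - 1L)
}

#' Right-hand side of the circuit ODE system
#'
#' Rate of change of each node:
#' \deqn{dx_i/dt = g_i \prod_{j \to i} H_s(x_j; x_{0,ji}, n_{ji},
#'   \lambda_{ji}) - k_i x_i}
#' where the product runs over the incoming edges of node \eqn{i} and
#' equals 1 for unregulated nodes.
#'
#' @param x Numeric state vector in node order (non-negative).
#' @param params A `model_params` from [sample_model_parameters()].
#' @param net The [reg_network()] the parameters were sampled for.
#' @return Numeric rate vector in node order.
#' @export
dxdt <- function(x, params, net) {
  n_nodes <- nrow(net$nodes)
  if (length(x) != n_nodes) {
    abort(sprintf("state vector has length %d, network has %d nodes",
                  length(x), n_nodes))
  }
  if (any(x < 0)) abort("`x` must be non-negative")
  idx <- edge_indices(net)
  as.numeric(cpp_dxdt(as.numeric(x), as.numeric(params$g),
                      as.numeric(params$k), idx$src, idx$tgt,
                      as.numeric(params$n), as.numeric(params$lam),
                      as.numeric(params$x0)))
}

# Greedy deduplication of converged endpoints on the log2 scale.
# Returns representative rows (first occurrence) of the endpoint matrix.
dedupe_endpoints <- function(x, residual, eps) {
  keep <- integer(0)
  lx <- log2(pmax(x, .Machine$double.xmin))
  for (s in seq_len(nrow(x))) {
    dup <- FALSE
    for (r in keep) {
      if (sqrt(sum((lx[s, ] - lx[r, ])^2)) < eps) { dup <- TRUE; break }
    }
    if (!dup) keep <- c(keep, s)
  }
  keep
}

#' Find the stable steady states of one kinetic model
#'
#' Integrates the circuit ODEs from `n_init` random initial conditions
#' (log-uniform per node over the configured range) until the scale-free
#' residual stays below tolerance, then deduplicates the converged
#' endpoints on the log2 scale into distinct steady states.
#' Non-converged trajectories (within the time horizon) are dropped and
#' counted; a model where no trajectory converges is flagged as possibly
#' oscillatory and yields zero states with a warning.
#'
#' @param params A `model_params` from [sample_model_parameters()].
#' @param net The [reg_network()].
#' @param n_init Number of random initial conditions.
#' @param seed Seed for the initial-condition draw (defaults to the
#'   parameter set's own deterministic seed so runs are reproducible).
#' @param settings An [engine_settings()] list.
#' @return A tibble with one row per distinct steady state: `model_id`,
#'   `state_index`, one column per node, `residual`, and attribute
#'   `n_nonconverged`.
#' @export
find_steady_states <- function(params, net, n_init = 20L, seed = NULL,
                               settings = engine_settings()) {
  stopifnot(n_init >= 1)
  nodes <- network_nodes(net)
  n_nodes <- length(nodes)
  if (is.null(seed)) seed <- model_seed(params$model_id, 7919L)
  withr::local_seed(seed)
  b <- node_ic_bounds(net, settings)
  u <- matrix(runif(n_init * n_nodes), nrow = n_init)
  inits <- exp(sweep(sweep(u, 2, log(b$hi / b$lo), "*"), 2, log(b$lo), "+"))
  idx <- edge_indices(net)
  res <- cpp_find_endpoints(inits, as.numeric(params$g), as.numeric(params$k),
                            idx$src, idx$tgt, as.numeric(params$n),
                            as.numeric(params$lam), as.numeric(params$x0),
                            settings$t_max, settings$check_dt,
                            settings$settle_tol, settings$conv_tol,
                            settings$rtol, settings$atol)
  ok <- res$converged & !res$negative
  n_bad <- sum(!ok)
  if (!any(ok)) {
    warn(sprintf("model %d: no trajectory converged (possible oscillation)",
                 params$model_id))
    out <- tibble::as_tibble(matrix(numeric(0), ncol = n_nodes,
                                    dimnames = list(NULL, nodes)))
    out <- dplyr::bind_cols(tibble::tibble(model_id = integer(0),
                                           state_index = integer(0)),
                            out, tibble::tibble(residual = numeric(0)))
    attr(out, "n_nonconverged") <- n_bad
    attr(out, "n_unstable") <- 0L
    return(out)
  }
  x <- res$x[ok, , drop = FALSE]
  resid <- res$residual[ok]
  keep <- dedupe_endpoints(x, resid, settings$dedup_eps)
  x <- x[keep, , drop = FALSE]
  resid <- resid[keep]
  # drop saddles/unstable fixed points that slow trajectories parked near
  stable <- vapply(seq_len(nrow(x)), function(i) {
    J <- rate_jacobian(x[i, ], params, net)
    max(Re(eigen(J, only.values = TRUE)$values)) < 1e-6
  }, logical(1))
  n_unstable <- sum(!stable)
  x <- x[stable, , drop = FALSE]
  resid <- resid[stable]
  colnames(x) <- nodes
  out <- dplyr::bind_cols(
    tibble::tibble(model_id = params$model_id,
                   state_index = seq_len(nrow(x))),
    tibble::as_tibble(x),
    tibble::tibble(residual = resid)
  )
  attr(out, "n_nonconverged") <- n_bad
  attr(out, "n_unstable") <- n_unstable
  out
}

#' Jacobian of the circuit rate function
#'
#' Numerical (central-difference) Jacobian of [dxdt()] at a state; used to
#' check linear stability of fixed points (all eigenvalue real parts
#' negative).
#'
#' @inheritParams dxdt
#' @return An n-by-n numeric matrix.
#' @export
rate_jacobian <- function(x, params, net) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-6 * (1 + abs(x[j]))
    xp <- x; xm <- x
    xp[j] <- x[j] + h
    xm[j] <- max(x[j] - h, 0)
    J[, j] <- (dxdt(xp, params, net) - dxdt(xm, params, net)) / (xp[j] - xm[j])
  }
  J
}

params_as_row <- function(params) {
  v <- c(setNames(params$g, paste0("g_", names(params$g))),
         setNames(params$k, paste0("k_", names(params$k))),
         setNames(params$n, paste0("n_", names(params$n))),
         setNames(params$lam, paste0("lam_", names(params$lam))),
         setNames(params$x0, paste0("x0_", names(params$x0))))
  c(model_id = params$model_id, v)
}

#' Simulate an ensemble of kinetic models for a circuit
#'
#' The core random-circuit-perturbation loop: for each of `n_models`
#' independently sampled kinetic parameter sets, find all distinct stable
#' steady states from `n_init` random initial conditions, and collect them
#' with full bookkeeping. A parameter set reaching more than one steady
#' state is multistable, i.e., admits several coexisting phenotypes.
#' With a fixed seed the whole ensemble is bit-reproducible.
#'
#' @param net A [reg_network()].
#' @param n_models Number of kinetic parameter sets.
#' @param n_init Random initial conditions per model.
#' @param seed Master seed; per-model substreams are derived from it.
#' @param settings An [engine_settings()] list.
#' @param perturb Optional in-silico perturbation applied after sampling:
#'   a list `list(node =, fold =)` multiplying that node's basal
#'   production rate (see [apply_perturbation()]).
#' @return An `ensemble_result`: list with `$network`, `$params` (tibble,
#'   one labelled column per kinetic parameter), `$states` (tibble, one row
#'   per steady state), `$seed`, `$settings`, `$perturb`, and convergence
#'   bookkeeping `$n_nonconverged`, `$n_models_empty`.
#' @examples
#' \donttest{
#' ens <- run_ensemble(melanocyte_network(), n_models = 50, n_init = 10,
#'                     seed = 1)
#' glance(ens)
#' }
#' @export
run_ensemble <- function(net, n_models = 2000L, n_init = 20L, seed = 1L,
                         settings = engine_settings(), perturb = NULL) {
  stopifnot(n_models >= 1, n_init >= 1)
  if (!is.null(perturb) && !perturb$node %in% network_nodes(net)) {
    abort(sprintf("perturbation node '%s' is not in the network",
                  perturb$node))
  }
  medians <- if (settings$x0_mode == "refined" && nrow(net$edges) > 0) {
    threshold_medians(net, settings)
  } else {
    NULL
  }
  param_rows <- vector("list", n_models)
  state_tbls <- vector("list", n_models)
  n_nonconv <- 0L
  n_empty <- 0L
  for (m in seq_len(n_models)) {
    p <- sample_model_parameters(net, model_id = m, seed = seed,
                                 settings = settings, medians = medians)
    if (!is.null(perturb)) p <- apply_perturbation(p, perturb$node,
                                                   perturb$fold)
    param_rows[[m]] <- params_as_row(p)
    st <- withCallingHandlers(
      find_steady_states(p, net, n_init = n_init,
                         seed = model_seed(seed, m + n_models),
                         settings = settings),
      warning = function(w) invokeRestart("muffleWarning")
    )
    n_nonconv <- n_nonconv + attr(st, "n_nonconverged")
    if (nrow(st) == 0) n_empty <- n_empty + 1L
    state_tbls[[m]] <- st
  }
  params <- tibble::as_tibble(do.call(rbind, param_rows))
  params$model_id <- as.integer(params$model_id)
  states <- dplyr::bind_rows(state_tbls)
  structure(list(network = net, params = params, states = states,
                 seed = as.integer(seed), settings = settings,
                 perturb = perturb, n_nonconverged = n_nonconv,
                 n_models_empty = n_empty),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(
    "<ensemble_result> %d models x %d-node circuit: %d steady states (seed %d)\n",
    nrow(x$params), nrow(x$network$nodes), nrow(x$states), x$seed))
  if (!is.null(x$perturb)) {
    cat(sprintf("perturbation: %s x%g\n", x$perturb$node, x$perturb$fold))
  }
  cat(sprintf("non-converged trajectories: %d; models with no state: %d\n",
              x$n_nonconverged, x$n_models_empty))
  invisible(x)
}

#' @describeIn run_ensemble Steady-state table (one row per state).
#' @param x An `ensemble_result`.
#' @param ... Unused.
#' @export
tidy.ensemble_result <- function(x, ...) x$states

#' @describeIn run_ensemble One-row ensemble summary: model counts, state
#'   counts, fraction of multistable models, convergence bookkeeping.
#' @export
glance.ensemble_result <- function(x, ...) {
  per_model <- dplyr::count(x$states, .data$model_id)
  tibble::tibble(
    n_models = nrow(x$params),
    n_states = nrow(x$states),
    n_multistable = sum(per_model$n > 1),
    frac_multistable = sum(per_model$n > 1) / nrow(x$params),
    n_nonconverged = x$n_nonconverged,
    n_models_empty = x$n_models_empty,
    seed = x$seed
  )
}
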