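# Small circuits used across test files -------------------------------------

toggle_network <- function() {
  reg_network(tibble::tibble(source = c("A", "B"), target = c("B", "A"),
                             sign = "inhibition"))
}

single_node_network <- function(name = "A") {
  reg_network(tibble::tibble(source = character(), target = character(),
                             sign = character()),
              nodes = tibble::tibble(name = name, role = "unassigned"))
}

# random small network: n nodes, random signed edges, no duplicate pairs
random_network <- function(n_nodes = 4, n_edges = 5) {
  nodes <- LETTERS[seq_len(n_nodes)]
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pick <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  reg_network(tibble::tibble(
    source = pairs$source[pick], target = pairs$target[pick],
    sign = sample(c("activation", "inhibition"), length(pick),
                  replace = TRUE)
  ), nodes = tibble::tibble(name = nodes, role = "unassigned"))
}

# Brute-force steady-state oracle for 2-node circuits ------------------------
# Circuits where each node has at most one incoming edge (from the other
# node): the fixed-point condition reduces to a 1-D root-finding problem
# x2 = f2(f1(x2)), solved by sign-change scan + bisection on a dense log
# grid, followed by a Jacobian stability check. Independent of the ODE
# integration path.
oracle_two_node_states <- function(params, net, grid_n = 6000) {
  nodes <- network_nodes(net)
  stopifnot(length(nodes) == 2)
  edges <- net$edges
  stopifnot(all(edges$source != edges$target))
  # production of node given the other node's level
  prod_fun <- function(target, x_other) {
    e <- which(edges$target == target)
    f <- 1
    for (i in e) {
      f <- f * shifted_hill(x_other, params$x0[i], params$n[i], params$lam[i])
    }
    unname(params$g[target]) * f
  }
  x1_of_x2 <- function(x2) prod_fun(nodes[1], x2) / unname(params$k[nodes[1]])
  F2 <- function(x2) {
    prod_fun(nodes[2], x1_of_x2(x2)) / unname(params$k[nodes[2]]) - x2
  }
  grid <- exp(seq(log(1e-5), log(1e6), length.out = grid_n))
  vals <- vapply(grid, F2, numeric(1))
  roots <- c()
  for (i in seq_len(grid_n - 1)) {
    if (sign(vals[i]) != sign(vals[i + 1])) {
      lo <- grid[i]; hi <- grid[i + 1]
      for (b in 1:80) {
        mid <- (lo + hi) / 2
        if (sign(F2(mid)) == sign(F2(lo))) lo <- mid else hi <- mid
      }
      roots <- c(roots, (lo + hi) / 2)
    }
  }
  if (length(roots) == 0) return(matrix(numeric(0), ncol = 2))
  states <- cbind(vapply(roots, x1_of_x2, numeric(1)), roots)
  stable <- vapply(seq_len(nrow(states)), function(i) {
    J <- rate_jacobian(states[i, ], params, net)
    max(Re(eigen(J, only.values = TRUE)$values)) < 0
  }, logical(1))
  states[stable, , drop = FALSE]
}

# Cached melanocyte control ensembles shared by the acceptance tests --------
.test_cache <- new.env(parent = emptyenv())

melanocyte_control <- function(seed, n_models = 2000L, n_init = 20L) {
  key <- sprintf("ctrl_%d_%d_%d", seed, n_models, n_init)
  if (is.null(.test_cache[[key]])) {
    ens <- run_ensemble(melanocyte_network(), n_models = n_models,
                        n_init = n_init, seed = seed)
    norm <- log2_znormalize(ens)
    .test_cache[[key]] <- list(ens = ens, norm = norm,
                               score = pigmentation_score(norm))
  }
  .test_cache[[key]]
}
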