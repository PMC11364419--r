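test_that("shifted Hill function satisfies its closed-form identities", {
  # lam = 1 collapses the edge; x = 0 gives full basal production
  expect_equal(shifted_hill(c(0, 1, 50, 1e4), x0 = 30, n = 3, lam = 1),
               rep(1, 4))
  expect_equal(shifted_hill(0, x0 = 10, n = 2, lam = 0.02), 1)
  # half-saturation midpoint
  expect_equal(shifted_hill(50, x0 = 50, n = 4, lam = 5), 3)
  expect_equal(shifted_hill(7, x0 = 7, n = 1, lam = 0.2), 0.6)
  expect_error(shifted_hill(1, x0 = -1, n = 2, lam = 2), "x0")
})

test_that("shifted Hill is monotone with direction set by lambda", {
  set.seed(11)
  x <- seq(0, 500, length.out = 200)
  for (i in 1:25) {
    x0 <- runif(1, 2, 180)
    n <- sample(1:6, 1)
    up <- shifted_hill(x, x0, n, lam = runif(1, 1, 100))
    dn <- shifted_hill(x, x0, n, lam = runif(1, 0.01, 1))
    expect_true(all(diff(up) >= 0))
    expect_true(all(diff(dn) <= 0))
  }
})

test_that("parameter sampling is deterministic and respects its ranges", {
  net <- melanocyte_network()
  p1 <- sample_model_parameters(net, model_id = 7, seed = 3)
  p2 <- sample_model_parameters(net, model_id = 7, seed = 3)
  expect_identical(p1, p2)
  expect_false(identical(
    p1, sample_model_parameters(net, model_id = 8, seed = 3)))

  tog <- toggle_network()
  med <- threshold_medians(tog)
  draws <- lapply(1:1000, function(m) {
    sample_model_parameters(tog, m, seed = 1, medians = med)
  })
  g <- unlist(lapply(draws, `[[`, "g"))
  lam <- unlist(lapply(draws, `[[`, "lam"))
  nh <- unlist(lapply(draws, `[[`, "n"))
  expect_true(all(g >= 1 & g <= 100))
  expect_true(all(unlist(lapply(draws, `[[`, "k")) >= 0.1))
  expect_true(all(lam > 0.0099 & lam <= 1)) # inhibition-only circuit
  expect_true(all(nh %in% 1:6))
  # CLT bound on the mean of U[1,100]: 50.5 +/- well under 5 at n >= 2000
  expect_gt(mean(g), 45)
  expect_lt(mean(g), 56)
})

test_that("activating and inhibiting fold-changes fall in their ranges", {
  net <- melanocyte_network()
  med <- threshold_medians(net)
  act <- net$edges$sign == "activation"
  for (m in 1:200) {
    p <- sample_model_parameters(net, m, seed = 5, medians = med)
    expect_true(all(p$lam[act] >= 1 & p$lam[act] <= 100))
    expect_true(all(p$lam[!act] >= 0.01 & p$lam[!act] <= 1))
    expect_true(all(p$x0 > 0))
  }
})

test_that("dxdt matches its closed forms", {
  net1 <- single_node_network()
  p <- sample_model_parameters(net1, 1, 1)
  p$g[] <- 50; p$k[] <- 0.5
  expect_equal(dxdt(100, p, net1), 0)
  expect_equal(dxdt(0, p, net1), 50)

  tog <- toggle_network()
  pt <- sample_model_parameters(tog, 1, 1)
  # at the origin every Hill factor is 1, so rates equal g
  expect_equal(dxdt(c(0, 0), pt, tog), unname(pt$g))
  # manual evaluation at a generic point
  x <- c(30, 70)
  manual <- c(
    pt$g[["A"]] * shifted_hill(70, pt$x0[["B_A"]], pt$n[["B_A"]],
                               pt$lam[["B_A"]]) - pt$k[["A"]] * 30,
    pt$g[["B"]] * shifted_hill(30, pt$x0[["A_B"]], pt$n[["A_B"]],
                               pt$lam[["A_B"]]) - pt$k[["B"]] * 70
  )
  expect_equal(dxdt(x, pt, tog), unname(manual))
  expect_error(dxdt(c(1, 2, 3), pt, tog), "nodes")
})

test_that("an unregulated node converges to g/k from every start", {
  net1 <- single_node_network()
  p <- sample_model_parameters(net1, 1, 1)
  p$g[] <- 50; p$k[] <- 0.5
  st <- find_steady_states(p, net1, n_init = 8, seed = 2)
  expect_equal(nrow(st), 1)
  expect_lt(abs(st$A - 100) / 100, 1e-6)
  set.seed(9)
  for (i in 1:10) {
    p$g[] <- runif(1, 1, 100); p$k[] <- runif(1, 0.1, 1)
    st <- find_steady_states(p, net1, n_init = 4, seed = i)
    expect_equal(nrow(st), 1)
    expect_lt(abs(st$A - p$g / p$k) / (p$g / p$k), 1e-6)
  }
})

test_that("a strong symmetric toggle switch yields exactly two states", {
  tog <- toggle_network()
  p <- sample_model_parameters(tog, 1, 1)
  # symmetric strong mutual inhibition thresholded at the unregulated level
  p$g[] <- 50; p$k[] <- 0.5
  p$lam[] <- 0.01; p$n[] <- 4; p$x0[] <- 50
  st <- find_steady_states(p, tog, n_init = 40, seed = 4)
  expect_equal(nrow(st), 2)
  # each state has one node high, one low, mirrored
  hi <- pmax(st$A, st$B); lo <- pmin(st$A, st$B)
  expect_true(all(hi > 50 & lo < 50))
  oracle <- oracle_two_node_states(p, tog)
  expect_equal(nrow(oracle), 2)
})

test_that("engine agrees with the brute-force two-node oracle", {
  tog <- toggle_network()
  act2 <- reg_network(tibble::tibble(source = c("A", "B"),
                                     target = c("B", "A"),
                                     sign = "activation"))
  mixed <- reg_network(tibble::tibble(source = c("A", "B"),
                                      target = c("B", "A"),
                                      sign = c("activation", "inhibition")))
  nets <- list(tog, act2, mixed)
  n_checked <- 0
  for (i in 1:51) {
    net <- nets[[(i %% 3) + 1]]
    p <- sample_model_parameters(net, i, seed = 99)
    st <- suppressWarnings(find_steady_states(p, net, n_init = 30,
                                              seed = 1000 + i))
    oracle <- oracle_two_node_states(p, net)
    expect_equal(nrow(st), nrow(oracle),
                 info = sprintf("state count, parameter set %d", i))
    if (nrow(oracle) > 0 && nrow(st) == nrow(oracle)) {
      got <- as.matrix(st[, network_nodes(net)])
      ord <- order(got[, 1]); oord <- order(oracle[, 1])
      expect_equal(log2(got[ord, , drop = FALSE]),
                   log2(oracle[oord, , drop = FALSE]),
                   tolerance = 1e-4, ignore_attr = TRUE,
                   info = sprintf("state location, parameter set %d", i))
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 50)
})

test_that("a lambda = 1 edge is equivalent to deleting the edge", {
  mixed <- reg_network(tibble::tibble(source = c("A", "B"),
                                      target = c("B", "A"),
                                      sign = c("activation", "inhibition")))
  only_ab <- reg_network(tibble::tibble(source = "A", target = "B",
                                        sign = "activation"),
                         nodes = tibble::tibble(name = c("A", "B")))
  set.seed(21)
  for (i in 1:10) {
    p <- sample_model_parameters(mixed, i, seed = 7)
    p$lam[["B_A"]] <- 1 # switch the B -| A edge off
    p_del <- list(model_id = p$model_id, g = p$g, k = p$k,
                  n = p$n["A_B"], lam = p$lam["A_B"], x0 = p$x0["A_B"])
    class(p_del) <- "model_params"
    st1 <- find_steady_states(p, mixed, n_init = 20, seed = 100 + i)
    st2 <- find_steady_states(p_del, only_ab, n_init = 20, seed = 100 + i)
    expect_equal(nrow(st1), nrow(st2))
    m1 <- as.matrix(st1[order(st1$A), c("A", "B")])
    m2 <- as.matrix(st2[order(st2$A), c("A", "B")])
    expect_lt(max(abs(log2(m1) - log2(m2))), 0.05)
  }
})

test_that("ensembles are bit-reproducible and bookkeeping is consistent", {
  net <- melanocyte_network()
  e1 <- run_ensemble(net, n_models = 40, n_init = 10, seed = 123)
  e2 <- run_ensemble(net, n_models = 40, n_init = 10, seed = 123)
  expect_identical(e1$states, e2$states)
  expect_identical(e1$params, e2$params)
  expect_false(identical(
    e1$states, run_ensemble(net, n_models = 40, n_init = 10,
                            seed = 124)$states))
  # rows = sum of per-model states; residual contract on every row
  expect_equal(nrow(e1$states), sum(table(e1$states$model_id)))
  expect_true(all(e1$states$residual <= engine_settings()$conv_tol))
  nodes <- network_nodes(net)
  expect_true(all(as.matrix(e1$states[, nodes]) > 0))
  expect_true(all(is.finite(as.matrix(e1$states[, nodes]))))
})

test_that("melanocyte ensembles are multistable for some parameter sets", {
  ctrl <- melanocyte_control(101)
  per_model <- table(ctrl$ens$states$model_id)
  expect_gt(sum(per_model > 1), 0)
  expect_gt(glance(ctrl$ens)$frac_multistable, 0)
})

test_that("steady states agree with an independent stiff ODE solver", {
  skip_if_not_installed("deSolve")
  net <- melanocyte_network()
  p <- sample_model_parameters(net, 17, seed = 5)
  st <- suppressWarnings(find_steady_states(p, net, n_init = 15, seed = 55))
  expect_gt(nrow(st), 0)
  nodes <- network_nodes(net)
  f <- function(t, y, parms) list(dxdt(pmax(y, 0), p, net))
  set.seed(3)
  for (i in 1:5) {
    y0 <- exp(runif(7, log(1), log(1000)))
    out <- deSolve::lsoda(y0, times = c(0, 3000), func = f,
                          rtol = 1e-10, atol = 1e-10)
    end <- pmax(out[2, -1], .Machine$double.xmin)
    d <- apply(as.matrix(st[, nodes]), 1, function(s) {
      sqrt(sum((log2(s) - log2(end))^2))
    })
    expect_lt(min(d), 0.05)
  }
})
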