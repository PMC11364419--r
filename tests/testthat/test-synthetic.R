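test_that("marker maps are disjoint and sized as requested", {
  mm <- marker_map(states = paste0("S", 1:4), genes_per_state = 20,
                   background_genes = 100)
  expect_length(mm$markers, 4)
  expect_true(all(lengths(mm$markers) == 20))
  all_markers <- unlist(mm$markers)
  expect_equal(anyDuplicated(all_markers), 0)
  expect_length(intersect(all_markers, mm$background), 0)
  expect_length(mm$background, 100)
  expect_error(marker_map(states = character(0)), "at least one")
  expect_error(marker_map(genes_per_state = 0), "marker")
})

test_that("the cell generator is seed-reproducible with labelled structure", {
  mm <- marker_map()
  m1 <- simulate_cells(mm, n_cells = 200, effect = 1, dispersion = 0.5,
                       seed = 7)
  m2 <- simulate_cells(mm, n_cells = 200, effect = 1, dispersion = 0.5,
                       seed = 7)
  expect_identical(m1$expr, m2$expr)
  expect_identical(m1$labels, m2$labels)
  expect_equal(dim(m1$expr), c(4 * 20 + 100, 200))
  expect_true(all(m1$expr > 0))
  # own-state markers are elevated for every state
  for (s in names(mm$markers)) {
    own <- mean(log(m1$expr[mm$markers[[s]], m1$labels == s]))
    other <- mean(log(m1$expr[mm$markers[[s]], m1$labels != s]))
    expect_gt(own, other)
  }
})

test_that("effect 0 produces no state separation", {
  mm <- marker_map()
  m0 <- simulate_cells(mm, n_cells = 400, effect = 0, dispersion = 0.5,
                       seed = 3)
  for (s in names(mm$markers)) {
    own <- mean(log(m0$expr[mm$markers[[s]], m0$labels == s]))
    other <- mean(log(m0$expr[mm$markers[[s]], m0$labels != s]))
    # standard error of a mean of thousands of log-normal draws
    expect_lt(abs(own - other), 0.1)
  }
})

test_that("label proportions follow the request within binomial error", {
  mm <- marker_map(states = c("S1", "S2"))
  m <- simulate_cells(mm, n_cells = 2000, effect = 1, seed = 5,
                      proportions = c(0.8, 0.2))
  p_hat <- mean(m$labels == "S1")
  expect_lt(abs(p_hat - 0.8), 3 * sqrt(0.8 * 0.2 / 2000) + 0.01)
})

test_that("module scores centre on background and cancel global shifts", {
  mm <- marker_map()
  mat <- simulate_cells(mm, n_cells = 300, effect = 1, dispersion = 0.5,
                        seed = 11)
  s1 <- mm$markers$S1
  sc <- module_score(mat, s1)
  # own-state cells score higher on their own marker set
  expect_gt(mean(sc[mat$labels == "S1"]), mean(sc[mat$labels != "S1"]))
  # additive shift of the whole matrix cancels exactly
  shifted <- mat
  shifted$expr <- mat$expr + 5
  expect_equal(module_score(shifted, s1), sc + 0)
  # with no state structure, any random gene set scores near zero
  null_mat <- simulate_cells(mm, n_cells = 300, effect = 0,
                             dispersion = 0.5, seed = 12)
  set.seed(2)
  random_set <- sample(rownames(null_mat$expr), 20)
  expect_lt(abs(mean(module_score(null_mat, random_set))), 0.3)
  expect_error(module_score(mat, c("S1_M01", "NOPE")), "NOPE")
  expect_error(module_score(mat, character(0)), "empty")
})

test_that("state-score heatmap is diagonal-dominant at strong effect", {
  mm <- marker_map()
  mat <- simulate_cells(mm, n_cells = 1000, effect = 1, dispersion = 0.5,
                        seed = 9)
  sm <- state_score_heatmap(mat)
  expect_equal(dim(sm), c(4, 4))
  # each row z-scores to mean 0
  expect_true(all(abs(rowMeans(unclass(sm))) < 1e-12))
  # the maximal entry of each cluster row is its own state
  expect_equal(colnames(sm)[apply(unclass(sm), 1, which.max)],
               rownames(sm))
  expect_equal(evaluate_recovery(sm), 1)
})

test_that("degenerate and permuted heatmaps behave by convention", {
  mm1 <- marker_map(states = "S1")
  one <- simulate_cells(mm1, n_cells = 50, effect = 1, seed = 1)
  sm1 <- state_score_heatmap(one)
  expect_equal(unname(unclass(sm1)[1, 1]), 0) # single state: z is 0
  # permuting marker-map states permutes the heatmap columns identically
  mm <- marker_map()
  mat <- simulate_cells(mm, n_cells = 400, effect = 1, seed = 13)
  sm <- state_score_heatmap(mat)
  mm_perm <- mm
  mm_perm$markers <- mm$markers[c(3, 1, 4, 2)]
  sm_perm <- state_score_heatmap(mat, markers = mm_perm)
  strip <- function(m) matrix(as.numeric(m), nrow(m), dimnames = dimnames(m))
  expect_equal(strip(sm_perm), strip(sm)[, c(3, 1, 4, 2)])
  # tiny clusters warn but are retained
  labs <- mat$labels
  labs[1] <- "tiny"
  expect_warning(state_score_heatmap(mat, cluster_labels = labs), "tiny")
})

test_that("recovery is perfect at strong effect and chance-level at zero", {
  mm <- marker_map()
  # the documented operating point: 4 states x 250 cells, effect 1
  mat <- simulate_cells(mm, n_cells = 1000, effect = 1, dispersion = 0.5,
                        seed = 20)
  expect_equal(evaluate_recovery(state_score_heatmap(mat)), 1)
  acc0 <- vapply(1:20, function(sd) {
    m <- simulate_cells(mm, n_cells = 200, effect = 0, dispersion = 0.5,
                        seed = sd)
    evaluate_recovery(state_score_heatmap(m))
  }, numeric(1))
  # chance level 1/4; binomial error over 20 seeds x 4 clusters
  se <- sqrt(0.25 * 0.75 / (20 * 4))
  expect_lt(abs(mean(acc0) - 0.25), 4 * se)
})

test_that("recovery accuracy does not decrease with effect size", {
  mm <- marker_map()
  acc <- vapply(c(0, 0.25, 0.5, 1), function(eff) {
    mean(vapply(1:5, function(sd) {
      m <- simulate_cells(mm, n_cells = 300, effect = eff,
                          dispersion = 0.5, seed = 100 + sd)
      evaluate_recovery(state_score_heatmap(m))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(acc) >= -0.15)) # non-decreasing within MC error
  expect_equal(acc[4], 1)
})
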