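fake_norm <- function(z, nodes = colnames(z)) {
  structure(list(z = z, node_means = rep(0, ncol(z)),
                 node_sds = rep(1, ncol(z)), nodes = nodes,
                 states = tibble::tibble(model_id = seq_len(nrow(z)),
                                         state_index = 1L,
                                         residual = 0),
                 network = NULL),
            class = "normalized_ensemble")
}

test_that("log2 z-normalisation satisfies its identities", {
  ctrl <- melanocyte_control(101, n_models = 200, n_init = 10)
  z <- ctrl$norm$z
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-9))
  # reusing stored statistics reproduces z exactly
  again <- log2_znormalize(ctrl$ens, reference = ctrl$norm)
  expect_equal(again$z, z)
  # identical states produce identical rows
  st <- ctrl$ens$states[c(1, 1, 2:10), ]
  nz <- log2_znormalize(st)
  expect_equal(nz$z[1, ], nz$z[2, ])
  # zero variance errors name the node
  bad <- tibble::tibble(model_id = 1:3, state_index = 1L,
                        A = c(2, 2, 2), B = c(1, 2, 3), residual = 0)
  expect_error(log2_znormalize(bad), "zero variance.*A")
  expect_error(log2_znormalize(ctrl$ens$states[1, ]), "at least 2")
})

test_that("pigmentation score is the mean z of the pigmentation nodes", {
  z <- matrix(c(1, 0.5, -2, 0, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, c("MITF", "LEF1", "MYC")))
  norm <- fake_norm(z)
  expect_equal(pigmentation_score(norm), c(0.75, 0))
  expect_equal(pigmentation_score(norm, "MYC"), c(-2, 0))
  expect_error(pigmentation_score(norm, character(0)), "empty")
  expect_error(pigmentation_score(norm, "TYR"), "TYR")
})

test_that("high-pigment classification uses a strict threshold", {
  cls <- classify_pigment_states(c(0.30, 0.22, -1), threshold = 0.22)
  expect_equal(cls$is_high, c(TRUE, FALSE, FALSE))
  expect_equal(cls$fraction_high, 1 / 3)
  expect_equal(classify_pigment_states(rep(-1, 5))$fraction_high, 0)
  expect_error(classify_pigment_states(numeric(0)), "empty")
  # monotone in the threshold
  set.seed(1)
  sc <- rnorm(500)
  fr <- vapply(seq(-2, 2, 0.25), function(th) {
    classify_pigment_states(sc, th)$fraction_high
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("dip statistic matches closed forms and is affine invariant", {
  # equally spaced distinct points: dip is exactly 1/(2n)
  expect_equal(dip_statistic(1:10), 0.05)
  expect_equal(dip_statistic(seq(0, 1, length.out = 50)), 0.01)
  # two-point mixture with masses p and 1-p: dip = min(p, 1-p)/2
  expect_equal(dip_statistic(rep(c(0, 1), c(5, 5))), 0.25)
  expect_equal(dip_statistic(rep(c(0, 1), c(3, 7))), 0.15)
  expect_equal(dip_statistic(rep(c(-4, 2), c(20, 80))), 0.10)
  # degenerate inputs
  expect_equal(dip_statistic(rep(3, 10)), 0)
  expect_equal(dip_statistic(2), 0)
  # affine invariance
  set.seed(4)
  x <- c(rnorm(150, -1), rnorm(150, 3, 0.5))
  expect_equal(dip_statistic(5 - 2 * x), dip_statistic(x))
})

test_that("dip test separates bimodal from unimodal samples", {
  set.seed(7)
  sep <- c(rnorm(300, -2, 0.4), rnorm(300, 2, 0.4))
  expect_lt(dip_test(sep, n_sim = 300)$p_value, 0.01)
  uni <- rnorm(600)
  expect_gt(dip_test(uni, n_sim = 300)$p_value, 0.05)
})

test_that("bimodality assessment combines dip and mixture BIC", {
  set.seed(12)
  bim <- assess_bimodality(c(rnorm(400, -1, 0.3), rnorm(400, 1, 0.3)),
                           n_sim = 300)
  expect_true(bim$bimodal)
  expect_gt(bim$bic2, bim$bic1)
  uni <- assess_bimodality(rnorm(800), n_sim = 300)
  expect_false(uni$bimodal)
})

test_that("rederived threshold finds the antimode and shifts with the data", {
  set.seed(5)
  x <- c(rnorm(5000, -1, 0.3), rnorm(5000, 1, 0.3))
  thr <- rederive_threshold(x, n_sim = 300)
  expect_gt(thr, -0.2)
  expect_lt(thr, 0.2)
  # translation equivariance
  thr_shift <- rederive_threshold(x + 0.8, n_sim = 300)
  expect_equal(thr_shift, thr + 0.8, tolerance = 0.05)
  # unimodal input refuses with advice
  expect_error(rederive_threshold(rnorm(2000), n_sim = 300),
               "not clearly bimodal")
})

test_that("clustering is canonical, deterministic and permutation invariant", {
  set.seed(31)
  centres <- rbind(c(2, 2, -2), c(-2, -2, 2))
  z <- centres[rep(1:2, each = 60), ] + matrix(rnorm(360, 0, 0.4), ncol = 3)
  colnames(z) <- c("MITF", "LEF1", "MYC")
  norm <- fake_norm(z)
  a1 <- cluster_states(norm, k = 2)
  # cluster 1 is the high-pigmentation cluster by construction
  expect_equal(a1$labels, rep(c(1L, 2L), each = 60))
  expect_gt(a1$cluster_profiles$mean_pigmentation[1],
            a1$cluster_profiles$mean_pigmentation[2])
  # identical input, identical labels
  expect_identical(cluster_states(norm, k = 2)$labels, a1$labels)
  # permuting rows permutes labels consistently
  perm <- sample(nrow(z))
  a2 <- cluster_states(fake_norm(z[perm, ]), k = 2)
  expect_identical(a2$labels, a1$labels[perm])
  expect_error(cluster_states(norm, k = 500), "cannot form")
})

test_that("a single Gaussian cloud has low silhouette at every k", {
  set.seed(8)
  z <- matrix(rnorm(7000), ncol = 7)
  colnames(z) <- paste0("N", 1:7)
  asg <- cluster_states(fake_norm(z), pig_nodes = character(0))
  expect_true(all(asg$silhouette < 0.25))
})

test_that("PCA projection has standard properties", {
  ctrl <- melanocyte_control(101, n_models = 200, n_init = 10)
  pca <- pca_projection(ctrl$norm)
  expect_true(all(diff(pca$var_explained) <= 1e-12))
  expect_equal(sum(pca$var_explained), 1)
  # sign symmetry: projecting -z mirrors the coordinates
  neg <- ctrl$norm
  neg$z <- -neg$z
  pca2 <- pca_projection(neg)
  p1 <- as.matrix(pca$coordinates[, grep("^PC", names(pca$coordinates))])
  p2 <- as.matrix(pca2$coordinates[, grep("^PC", names(pca2$coordinates))])
  # columns may flip sign as a whole; compare absolute coordinates
  expect_equal(abs(p1), abs(p2), tolerance = 1e-8)
})

test_that("pigmentation and proliferation loadings oppose on the lead axis", {
  ctrl <- melanocyte_control(101)
  pca <- pca_projection(ctrl$norm)
  load <- pca$loadings
  pc1 <- load$PC1
  names(pc1) <- load$node
  # MITF/LEF1 point opposite to MYC/E2F on the dominant component
  expect_lt(sign(pc1[["MITF"]]) * sign(pc1[["MYC"]]), 0)
  expect_lt(sign(pc1[["LEF1"]]) * sign(pc1[["E2F"]]), 0)
  expect_gt(sign(pc1[["MITF"]]) * sign(pc1[["LEF1"]]), 0)
})
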