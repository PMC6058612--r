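test_that("correlation_distance matches hand-computed Pearson values", {
  expect_equal(correlation_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(correlation_distance(c(1, 2, 3), -c(1, 2, 3)), 2)
  expect_equal(correlation_distance(c(1, 2, 3), c(1, 2, 4)),
               1 - 0.981980506061966, tolerance = 1e-12)
  # zero variance is non-informative: distance 1
  expect_equal(correlation_distance(c(5, 5, 5), c(1, 2, 3)), 1)
  expect_error(correlation_distance(1:3, 1:4), "length mismatch")
  expect_error(correlation_distance(1, 2), "length")
})

test_that("Szekely distance-correlation variant detects linear dependence", {
  set.seed(1)
  u <- stats::runif(12)
  expect_equal(correlation_distance(u, 3 * u + 1, method = "szekely"), 0,
               tolerance = 1e-9)
  # anti-correlation is still perfect dependence for dCor, unlike Pearson
  expect_equal(correlation_distance(u, -u, method = "szekely"), 0,
               tolerance = 1e-9)
})

test_that("denoise_weak is the identity at sigma 0 and on constants", {
  m <- matrix(stats::runif(64), 8, 8)
  expect_equal(denoise_weak(m, sigma_px = 0), m)
  expect_equal(denoise_weak(matrix(3, 9, 9), sigma_px = 2), matrix(3, 9, 9))
})

test_that("renormalized masked smoothing conserves the mass of an impulse", {
  m <- matrix(0, 15, 15)
  m[8, 8] <- 1
  sm <- denoise_weak(m, sigma_px = 1)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  # an off-mask stripe is excluded and stays missing
  mask <- matrix(TRUE, 15, 15); mask[, 1:2] <- FALSE
  sm2 <- denoise_weak(m, sigma_px = 1, mask = mask)
  expect_true(all(is.na(sm2[, 1:2])))
  # border renormalization makes conservation approximate near the mask edge
  expect_equal(sum(sm2, na.rm = TRUE), 1, tolerance = 1e-3)
})

test_that("2-means recovers perfectly separable populations exactly", {
  mi <- micro_instance(6, 4, noise = 0)
  fit <- bisecting_kmeans(mi$X, k = 2, seed = 1)
  expect_equal(ari(fit$labels, mi$truth), 1)
  expect_equal(fit$k_actual, 2L)
})

test_that("split objective equals the exhaustive 2-partition minimum", {
  for (case in 1:6) {
    mi <- micro_instance(sample(2:5, 1), sample(2:5, 1), noise = 0.05,
                         seed = case)
    fit <- bisecting_kmeans(mi$X, k = 2, seed = case, n_restarts = 8)
    brute <- o_best_bipartition(mi$X)
    expect_equal(fit$tree$objective_after[1], brute, tolerance = 1e-9)
  }
})

test_that("bisecting k-means is deterministic and permutation invariant", {
  mi <- micro_instance(7, 5, noise = 0.05, seed = 3)
  f1 <- bisecting_kmeans(mi$X, k = 2, seed = 9)
  f2 <- bisecting_kmeans(mi$X, k = 2, seed = 9)
  expect_identical(f1$labels, f2$labels)
  perm <- sample(nrow(mi$X))
  f3 <- bisecting_kmeans(mi$X[perm, ], k = 2, seed = 9)
  expect_equal(ari(f3$labels, f1$labels[perm]), 1)
})

test_that("total within-segment distance never increases across bisections", {
  set.seed(11)
  X <- rbind(micro_instance(8, 8, noise = 0.3, seed = 1)$X,
             micro_instance(8, 8, noise = 0.3, seed = 2)$X * 3 + 1)
  fit <- bisecting_kmeans(X, k = 5, seed = 4)
  expect_true(all(fit$tree$objective_after <=
                    fit$tree$scatter_before + 1e-9))
})

test_that("degenerate segmentation inputs are handled", {
  mi <- micro_instance(3, 3, noise = 0)
  expect_error(bisecting_kmeans(mi$X, k = 10), "exceeds")
  # identical points cannot be split into k segments
  X <- matrix(rep(c(1, 2, 3, 4), each = 5), 5, 4)
  expect_warning(fit <- suppressMessages(bisecting_kmeans(X, k = 3, seed = 1)),
                 "no segment splittable")
  expect_lt(fit$k_actual, 3L)
})

test_that("phantom segmentation recovers the histological compartments", {
  sc <- lung_scenario()
  sim <- simulate_msi(sc, seed = 31)
  seg <- segment_msi(sim$dataset, k = 6, seed = 31)
  pred <- as.vector(seg$labels)
  keep <- pred >= 0
  expect_gte(ari(pred[keep], as.vector(sim$truth$labels)[keep]), 0.8)
  expect_equal(seg$k_actual, 6L)
  expect_equal(nrow(seg$tree), 5L)
})

test_that("segments are named by marker enrichment, with ring-shape as an
           epithelium tie-break only", {
  # synthetic 3-segment map: a disk (0), a ring around it (1), field (2)
  labels <- matrix(2L, 24, 24)
  d <- sqrt((row(labels) - 12.5)^2 + (col(labels) - 12.5)^2)
  labels[d <= 5] <- 0L
  labels[d > 5 & d <= 8] <- 1L
  seg <- structure(list(labels = labels, k = 3L, k_actual = 3L,
                        tree = NULL, seed = 1L), class = "segmentation_map")
  mk <- function(vals) {
    g <- matrix(vals[3], 24, 24); g[labels == 0] <- vals[1]
    g[labels == 1] <- vals[2]
    structure(list(grid = g, analyte = NULL, normalized = TRUE,
                   pixel_size = 1), class = "ion_image")
  }
  roles <- function(imgs, rr) {
    for (i in seq_along(imgs)) imgs[[i]]$analyte <-
        analyte(names(imgs)[i], 500, role = rr[i])
    imgs
  }
  # markers as designed: alveolar marker in the field, bronchiolar in the
  # ring, vessel marker nowhere special
  imgs <- roles(list(heme = mk(c(1, 1, 1)), alv = mk(c(5, 10, 100)),
                     bro = mk(c(30, 120, 10))),
                c("marker_vessel", "marker_alveolar", "marker_bronchiolar"))
  rois <- segments_to_rois(seg, imgs)
  map <- setNames(rois$mapping$compartment, rois$mapping$label)
  expect_equal(unname(map["2"]), "alveolar")
  expect_equal(unname(map["1"]), "epithelium")

  # adversarial swap: alveolar marker now highest in the ring; naming must
  # follow the marker, not the shape
  imgs2 <- roles(list(heme = mk(c(1, 1, 1)), alv = mk(c(5, 100, 10)),
                      bro = mk(c(30, 10, 120))),
                 c("marker_vessel", "marker_alveolar", "marker_bronchiolar"))
  rois2 <- segments_to_rois(seg, imgs2)
  map2 <- setNames(rois2$mapping$compartment, rois2$mapping$label)
  expect_equal(unname(map2["1"]), "alveolar")

  # fewer than 3 segments cannot support targeting
  seg2 <- seg; seg2$k_actual <- 2L
  expect_error(segments_to_rois(seg2, imgs), ">= 3 segments")
})
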