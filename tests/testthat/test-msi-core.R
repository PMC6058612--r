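test_that("msi_dataset enforces its invariants", {
  expect_error(tiny_dataset(matrix(-1, 1, 1)), "negative")
  expect_error(msi_dataset(cbind(x = c(1L, 1L), y = c(1L, 1L)),
                           mz = 500, intensities = matrix(1, 2, 1),
                           mode = "continuous"),
               "duplicate")
  expect_error(msi_dataset(matrix(integer(), 0, 2), mz = 500,
                           intensities = matrix(0, 0, 1)),
               "empty")
  expect_error(tiny_dataset(matrix(1, 1, 1), mz = 100,
                            mz_range = c(300, 1000)),
               "mz_range")
})

test_that("tic_normalize rescales to the target and conserves proportions", {
  d <- tiny_dataset(rbind(c(10, 30), c(5, 5)))
  n1 <- tic_normalize(d, target = 1)
  expect_equal(n1$intensities[1, ], c(0.25, 0.75))
  expect_equal(rowSums(n1$intensities), c(1, 1))
  # default target preserves the global scale (mean raw TIC)
  nm <- tic_normalize(d)
  expect_equal(unique(round(rowSums(nm$intensities), 12)), 25)
  # idempotence
  n2 <- tic_normalize(n1, target = 1)
  expect_identical(n1$intensities, n2$intensities)
})

test_that("tic_normalize conserves within-pixel peak ratios on random data", {
  set.seed(42)
  for (rep in 1:20) {
    X <- matrix(stats::runif(8 * 5, 0.1, 100), 8, 5)
    d <- tiny_dataset(X)
    n <- tic_normalize(d, target = stats::runif(1, 0.5, 50))
    for (i in 1:8) {
      expect_lt(max(abs(n$intensities[i, ] / n$intensities[i, 1] -
                          X[i, ] / X[i, 1])) / max(X[i, ] / X[i, 1]),
                1e-12)
    }
  }
})

test_that("tic_normalize drops zero-TIC pixels and rejects all-zero data", {
  X <- rbind(c(1, 2), c(0, 0), c(3, 1))
  d <- tiny_dataset(X)
  expect_message(n <- tic_normalize(d), "dropped 1 zero-TIC")
  expect_equal(n_pixels(n), 2L)
  expect_equal(n$metadata$dropped_zero_tic, 1L)
  expect_error(suppressMessages(tic_normalize(tiny_dataset(matrix(0, 2, 2)))),
               "zero total ion count")
})

test_that("extract_ion_image reduces the closed m/z window", {
  d <- tiny_dataset(rbind(c(5, 7)), mz = c(416.10, 416.30))
  img <- extract_ion_image(d, analyte("salmeterol", 416.1, tol = 0.1))
  expect_equal(img$grid[1, 1], 5)
  # empty window at an acquired pixel gives 0, not missing
  img0 <- extract_ion_image(d, analyte("x", 500, tol = 0.1))
  expect_equal(img0$grid[1, 1], 0)
  # window outside the mass range errors, naming the window
  expect_error(extract_ion_image(d, analyte("y", 1200, tol = 0.1)),
               "\\[1199.9, 1200.1\\]")
})

test_that("extract_ion_image is additive over disjoint windows", {
  set.seed(7)
  mzs <- sort(stats::runif(12, 350, 900))
  d <- tiny_dataset(matrix(stats::runif(6 * 12, 0, 50), 6, 12), mz = mzs)
  w1 <- analyte("a", 500, tol = 150)   # [350, 650]
  w2 <- analyte("b", 775, tol = 125)   # [650.0001...) approx disjoint
  w2$mz_center <- 800; w2$tol <- 149.9 # [650.1, 949.9]
  whole <- analyte("c", 650, tol = 300)
  g1 <- extract_ion_image(d, w1)$grid
  g2 <- extract_ion_image(d, w2)$grid
  g <- extract_ion_image(d, whole)$grid
  expect_equal(g1 + g2, g, tolerance = 1e-12)
})

test_that("ion images mark unacquired grid cells as missing, not zero", {
  d <- msi_dataset(cbind(x = c(1L, 3L), y = c(1L, 2L)), mz = 500,
                   intensities = matrix(c(2, 4), 2, 1), mode = "continuous",
                   mz_range = c(300, 1000))
  img <- extract_ion_image(d, analyte("a", 500, tol = 1))
  expect_equal(dim(img$grid), c(2L, 3L))
  expect_equal(sum(is.na(img$grid)), 4L)
  expect_equal(img$grid[1, 1], 2)
  expect_equal(img$grid[2, 3], 4)
})

test_that("tissue mask recovers a clean phantom exactly and rejects empties", {
  g <- matrix(0, 8, 8)
  g[3:6, 3:6] <- 10
  d <- msi_dataset(cbind(x = as.vector(col(g)), y = as.vector(row(g))),
                   mz = 500, intensities = matrix(as.vector(g)),
                   mode = "continuous", mz_range = c(300, 1000))
  msk <- compute_tissue_mask(tic_image(d), threshold_quantile = 0.5)
  expect_identical(msk$grid, g > 0)
  zero <- msi_dataset(cbind(x = 1:4, y = rep(1L, 4)), mz = 500,
                      intensities = matrix(0, 4, 1), mode = "continuous",
                      mz_range = c(300, 1000))
  expect_error(compute_tissue_mask(tic_image(zero)), "empty")
})

test_that("tissue mask overlaps ground truth on the default phantom", {
  sim <- simulate_msi(lung_scenario(), seed = 21)
  msk <- compute_tissue_mask(tic_image(sim$dataset))
  expect_gte(jaccard_index(msk, truth_tissue_mask(sim$truth)), 0.95)
})
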