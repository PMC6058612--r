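test_that("exposure and targeting-factor arithmetic", {
  expect_equal(normalized_exposure(10, 2), 5)
  expect_equal(normalized_exposure(0, 5), 0)
  expect_error(normalized_exposure(10, 0), "positive")
  expect_equal(targeting_factor(45, 1), 45)
  expect_equal(targeting_factor(3, 3), 1)
  expect_error(targeting_factor(1, 0), "positive")
})

test_that("noiseless phantom with truth ROIs recovers the design factors
           exactly", {
  sc <- lung_scenario(noise = "none")
  sim <- simulate_msi(sc, seed = 3)
  an <- drug_analytes()
  rep <- lung_targeting(sim$dataset, sim$truth$labels, an$inhaled, an$iv,
                        sc$plasma, masks = truth_tissue_mask(sim$truth))
  tf <- coef(rep)
  expect_lt(rel_err(tf[["alveolar"]], 5), 1e-12)
  expect_lt(rel_err(tf[["sub_epithelium"]], 31), 1e-12)
  expect_lt(rel_err(tf[["epithelium"]], 45), 1e-12)
  expect_equal(rep$aggregate$n, rep(1L, 3))
})

test_that("identical channels and plasma give unit factors everywhere", {
  sc <- small_scenario()
  sim <- simulate_msi(sc, seed = 6)
  an <- drug_analytes()
  plasma <- list(inhaled = 3.3, iv = 3.3)
  rep <- lung_targeting(sim$dataset, sim$truth$labels, an$iv, an$iv, plasma,
                        masks = truth_tissue_mask(sim$truth))
  expect_equal(unname(coef(rep)), rep(1, 4), tolerance = 1e-12)
})

test_that("targeting factors are invariant to common intensity rescaling and
           scale inversely with one route's plasma", {
  sc <- small_scenario()
  sim <- simulate_msi(sc, seed = 7)
  an <- drug_analytes()
  base <- lung_targeting(sim$dataset, sim$truth$labels, an$inhaled, an$iv,
                         sc$plasma, masks = truth_tissue_mask(sim$truth))
  scaled <- sim$dataset
  scaled$intensities <- scaled$intensities * 37.5
  rep2 <- lung_targeting(scaled, sim$truth$labels, an$inhaled, an$iv,
                         sc$plasma, masks = truth_tissue_mask(sim$truth))
  expect_equal(coef(rep2), coef(base), tolerance = 1e-12)
  p2 <- sc$plasma; p2$inhaled <- p2$inhaled * 4
  rep3 <- lung_targeting(sim$dataset, sim$truth$labels, an$inhaled, an$iv,
                         p2, masks = truth_tissue_mask(sim$truth))
  expect_equal(coef(rep3), coef(base) / 4, tolerance = 1e-12)
})

test_that("plasma validation catches missing routes, bad values and unit
           mismatches", {
  sc <- small_scenario()
  sim <- simulate_msi(sc, seed = 8)
  an <- drug_analytes()
  gt <- sim$truth$labels
  msk <- truth_tissue_mask(sim$truth)
  expect_error(lung_targeting(sim$dataset, gt, an$inhaled, an$iv,
                              list(inhaled = 1), masks = msk),
               "missing plasma concentration for route iv")
  expect_error(lung_targeting(sim$dataset, gt, an$inhaled, an$iv,
                              list(inhaled = -1, iv = 2), masks = msk),
               "must be positive")
  expect_error(lung_targeting(sim$dataset, gt, an$inhaled, an$iv,
                              list(inhaled = 1, iv = 2,
                                   unit_inhaled = "nM", unit_iv = "ng/mL"),
                              masks = msk),
               "units differ")
})

test_that("per-replicate aggregation reports mean and sd over sections", {
  sc <- small_scenario()
  an <- drug_analytes()
  sims <- lapply(1:3, function(r) simulate_msi(sc, seed = 90 + r))
  rep <- lung_targeting(lapply(sims, `[[`, "dataset"),
                        lapply(sims, function(s) s$truth$labels),
                        an$inhaled, an$iv, sc$plasma,
                        masks = lapply(sims, function(s)
                          truth_tissue_mask(s$truth)))
  expect_equal(rep$n_replicates, 3L)
  expect_false(anyNA(rep$aggregate$sd))
  per <- rep$per_replicate
  for (comp in c("alveolar", "sub_epithelium", "epithelium")) {
    tfs <- per$targeting_factor[per$compartment == comp]
    expect_equal(mean(tfs),
                 rep$aggregate$targeting_factor[
                   rep$aggregate$compartment == comp])
  }
})

test_that("kinetic profiles track the generating concentration curve", {
  sc <- small_scenario(grid = c(40L, 40L), noise = "none",
                       n_airways = 1L, n_vessels = 1L)
  times <- c(5, 15, 30, 60, 120)
  ser <- simulate_kinetic_series(sc, times, seed = 2)
  an <- drug_analytes()
  prof <- kinetic_profile(ser$datasets, times, an$inhaled,
                          masks = ser$masks, reference = ser$concentration)
  expect_gte(prof$pearson_r, 0.99)
  # biphasic decay: strictly decreasing after the (initial) peak
  expect_true(all(diff(prof$profile$msi_mean) < 0))
  # constant sections give a flat profile
  flat <- kinetic_profile(rep(ser$datasets[1], 3), c(1, 2, 3), an$inhaled,
                          masks = rep(ser$masks[1], 3))
  expect_equal(diff(range(flat$profile$msi_mean)), 0, tolerance = 1e-12)
  expect_error(kinetic_profile(ser$datasets[1], 5, an$inhaled), ">= 2")
  expect_error(kinetic_profile(ser$datasets, times[-1], an$inhaled),
               "mismatched time vector")
})
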