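test_that("geometry generation is deterministic and degenerate-safe", {
  sc <- small_scenario()
  g1 <- generate_geometry(sc, seed = 5)
  g2 <- generate_geometry(sc, seed = 5)
  expect_identical(g1$labels, g2$labels)
  g3 <- generate_geometry(sc, seed = 6)
  expect_false(identical(g1$labels, g3$labels))

  empty <- lung_scenario(grid_size = c(40L, 40L), n_airways = 0L,
                         n_vessels = 0L, alveolar_porosity = 0)
  ge <- generate_geometry(empty, seed = 1)
  expect_setequal(unique(as.vector(ge$labels)), c("alveolar", "background"))

  # structures that cannot fit are a hard error
  big <- lung_scenario(grid_size = c(40L, 40L), n_airways = 5L,
                       lumen_radius = c(12, 14))
  expect_error(generate_geometry(big, seed = 1), "cannot place")
})

test_that("ring pixel counts match the analytic annulus areas", {
  sc <- lung_scenario(grid_size = c(80L, 80L), n_airways = 1L,
                      lumen_radius = c(5, 5), epithelium_thickness = 2,
                      subepithelium_thickness = 3, n_vessels = 0L,
                      alveolar_porosity = 0)
  g <- generate_geometry(sc, seed = 2)
  counts <- as.vector(g$counts)
  names(counts) <- names(g$counts)
  expect_equal(unname(counts["lumen"]), pi * 5^2, tolerance = 0.1)
  expect_equal(unname(counts["epithelium"]), pi * (7^2 - 5^2),
               tolerance = 0.1)
  expect_equal(unname(counts["sub_epithelium"]), pi * (10^2 - 7^2),
               tolerance = 0.1)
})

test_that("the intensity table derives inhaled means from the targeting
           factors", {
  sc <- lung_scenario()
  tab <- scenario_intensity_table(sc)
  pr <- sc$plasma$inhaled / sc$plasma$iv
  for (comp in c("alveolar", "sub_epithelium", "epithelium"))
    expect_equal(tab["salmeterol", comp],
                 sc$ground_truth_tf[[comp]] * pr * sc$iv_means[[comp]])
  # so the implied targeting factors are exactly the requested ones
  imp <- (tab["salmeterol", ] / sc$plasma$inhaled) /
    (tab["d3_salmeterol", ] / sc$plasma$iv)
  expect_equal(imp[c("alveolar", "sub_epithelium", "epithelium")],
               sc$ground_truth_tf[c("alveolar", "sub_epithelium",
                                    "epithelium")],
               tolerance = 1e-12)
})

test_that("zero-noise simulation reproduces the noiseless truth exactly", {
  sc <- small_scenario(noise = "none")
  sim <- simulate_msi(sc, seed = 9)
  an <- default_analytes()
  img <- extract_ion_image(sim$dataset, an$salmeterol)
  expect_equal(img$grid, sim$truth$images$salmeterol, tolerance = 1e-15)
  img2 <- extract_ion_image(sim$dataset, an$heme_b)
  expect_equal(img2$grid, sim$truth$images$heme_b, tolerance = 1e-15)
})

test_that("TIC normalization removes multiplicative drift exactly", {
  drift_only <- list(tic_sigma = 0.4, pixel_sigma = c(default = 0),
                     airway_sigma = 0, poisson = FALSE, counts_scale = 1)
  sc_d <- small_scenario(noise = drift_only)
  sc_0 <- small_scenario(noise = "none")
  geom <- generate_geometry(sc_d, seed = 5)
  noisy <- simulate_msi(sc_d, geom, seed = 5)$dataset
  clean <- simulate_msi(sc_0, geom, seed = 5)$dataset
  expect_false(isTRUE(all.equal(noisy$intensities, clean$intensities)))
  nn <- suppressMessages(tic_normalize(noisy, target = 1))
  nc <- suppressMessages(tic_normalize(clean, target = 1))
  expect_equal(nn$intensities, nc$intensities, tolerance = 1e-9)
})

test_that("noise multipliers are mean-one: ROI means converge to the design
           means with pixel count and counting statistics", {
  an <- default_analytes()
  err_at <- function(cs, grid) {
    sc <- small_scenario(grid = grid, n_airways = 1L, n_vessels = 1L,
                         noise = list(tic_sigma = 0, pixel_sigma =
                                        c(default = 0.3), airway_sigma = 0,
                                      poisson = TRUE, counts_scale = cs))
    sim <- simulate_msi(sc, seed = 12)
    img <- extract_ion_image(sim$dataset, an$pc_32_0)
    m <- roi_mean_intensity(img, roi_pixels(sim$truth$labels,
                                            "alveolar"))$mean
    rel_err(m, scenario_intensity_table(sc)["pc_32_0", "alveolar"])
  }
  expect_lt(err_at(1, c(60L, 60L)), 0.05)
  expect_lt(err_at(1, c(120L, 120L)), err_at(1, c(40L, 40L)) + 0.02)
})

test_that("each marker correlates most with its own compartment", {
  sim <- simulate_msi(lung_scenario(), seed = 41)
  dn <- suppressMessages(tic_normalize(sim$dataset))
  an <- default_analytes()
  marker_home <- c(heme_b = "vessel", pc_32_0 = "alveolar",
                   pc_36_4 = "epithelium")
  msk <- truth_tissue_mask(sim$truth)
  for (m in names(marker_home)) {
    img <- extract_ion_image(dn, an[[m]])
    cors <- vapply(c("alveolar", "epithelium", "sub_epithelium", "vessel"),
                   function(comp) {
      ind <- structure(list(grid = (sim$truth$labels == comp) * 1,
                            analyte = analyte(comp, 500),
                            normalized = TRUE, pixel_size = 1),
                       class = "ion_image")
      pearson_image_correlation(img, ind, msk)
    }, numeric(1))
    best <- names(which.max(cors))
    expected <- marker_home[[m]]
    # the two bronchiolar ring layers are interchangeable homes
    if (m == "pc_36_4")
      expect_true(best %in% c("epithelium", "sub_epithelium"))
    else expect_equal(best, expected)
  }
})

test_that("scenarios serialize to YAML and round-trip", {
  sc <- lung_scenario()
  f <- withr::local_tempfile(fileext = ".yaml")
  scenario_to_yaml(sc, f)
  sc2 <- scenario_from_yaml(f)
  expect_equal(sc2, sc, tolerance = 1e-12)
  # and the round-tripped scenario generates identical data
  expect_identical(generate_geometry(sc2, 3)$labels,
                   generate_geometry(sc, 3)$labels)
})

test_that("the default scenario encodes the study-structure ground truth", {
  sc <- lung_scenario()
  expect_equal(unname(sc$ground_truth_tf[c("alveolar", "sub_epithelium",
                                           "epithelium")]),
               c(5, 31, 45))
  # one realization: the inhaled pattern is patchier than the IV pattern
  sim <- simulate_msi(sc, seed = 1)
  msk <- compute_tissue_mask(tic_image(sim$dataset))
  dn <- suppressMessages(tic_normalize(sim$dataset))
  an <- default_analytes()
  r_in <- pixel_rsd(extract_ion_image(dn, an$salmeterol), msk)
  r_iv <- pixel_rsd(extract_ion_image(dn, an$d3_salmeterol), msk)
  expect_gt(r_in$rsd_percent, r_iv$rsd_percent)
})
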