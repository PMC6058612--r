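# Programmatic fixtures: everything is generated at test time.

# a scenario small enough for fast unit tests (radii scaled to the grid)
small_scenario <- function(grid = c(60L, 60L), noise = NULL, ...) {
  args <- list(grid_size = grid, n_airways = 2L, lumen_radius = c(3, 5),
               epithelium_thickness = 2, subepithelium_thickness = 2,
               n_vessels = 2L, vessel_radius = c(2, 3),
               alveolar_porosity = 0.03)
  args <- utils::modifyList(args, list(...))
  if (!is.null(noise)) args$noise <- noise
  do.call(lung_scenario, args)
}

# hand-built continuous-mode dataset: n pixels in a row, explicit spectra
tiny_dataset <- function(intensities, mz = NULL, mz_range = c(300, 1000)) {
  intensities <- as.matrix(intensities)
  if (is.null(mz))
    mz <- seq(400, by = 50, length.out = ncol(intensities))
  msi_dataset(cbind(x = seq_len(nrow(intensities)),
                    y = rep(1L, nrow(intensities))),
              mz = mz, intensities = intensities,
              mode = "continuous", mz_range = mz_range)
}

# two well-separated spectral populations on a tiny grid; returns features
# and the true assignment
micro_instance <- function(n1, n2, p = 4, noise = 0.01, seed = 1) {
  set.seed(seed)
  base1 <- c(10, 1, 1, 10, rep(1, max(0, p - 4)))[1:p]
  base2 <- c(1, 10, 10, 1, rep(1, max(0, p - 4)))[1:p]
  X <- rbind(
    t(replicate(n1, base1 + rnorm(p, 0, noise))),
    t(replicate(n2, base2 + rnorm(p, 0, noise))))
  list(X = X, truth = rep(c(0L, 1L), c(n1, n2)))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

drug_analytes <- function() {
  an <- default_analytes()
  list(inhaled = an$salmeterol, iv = an$d3_salmeterol,
       markers = an[c("heme_b", "pc_32_0", "pc_36_4")])
}

# full single-section pipeline: segmentation-derived ROIs, returns report
run_section_pipeline <- function(dataset, seed, plasma, k = 6) {
  an <- drug_analytes()
  seg <- segment_msi(dataset, k = k, seed = seed)
  dn <- suppressMessages(tic_normalize(dataset))
  mimgs <- lapply(an$markers, function(a) extract_ion_image(dn, a))
  rois <- segments_to_rois(seg, mimgs, tic = tic_image(dataset))
  lung_targeting(dataset, rois, an$inhaled, an$iv, plasma)
}
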