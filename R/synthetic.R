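# Synthetic rat-lung MSI sections with known ground truth. The virtual
# section is a 2-D ellipse of alveolar parenchyma carrying circular airways
# (lumen + epithelium ring + sub-epithelium ring), blood vessels, and
# off-tissue micro-holes, imaged as a full rectangular field of view in which
# off-tissue pixels carry matrix-cluster ions. Each analyte channel gets a
# per-compartment mean intensity; the inhaled-drug means are DERIVED from the
# requested ground-truth targeting factors and plasma concentrations, never
# set independently, so parameter-recovery tests are well posed.

COMPARTMENTS <- c("alveolar", "epithelium", "sub_epithelium", "vessel",
                  "lumen", "background")

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  expr
}

#' Define a synthetic lung scenario
#'
#' The default values are the documented study conditions of the package's
#' validation phantom: a 200 x 200 pixel pseudo-section at 10 um (2 x 2 mm),
#' ground-truth targeting factors of 5 / 31 / 45 (alveolar / sub-epithelium /
#' epithelium) mirroring the structure of the dual-isotope rat study this
#' pipeline is built for, a patchy inhaled-drug texture versus a smooth IV
#' texture, and endogenous markers (Heme b in vessels, PC(32:0) in alveoli,
#' PC(36:4) in bronchiolar rings). Plasma concentrations are invented,
#' plausible values — the IV bolus gives ten-fold higher plasma than
#' nebulization — and are scenario design, not measured data.
#'
#' Noise model, in order: a per-airway log-normal deposition multiplier on
#' the inhaled drug (patchiness), a per-pixel per-channel log-normal
#' biological effect, Poisson counting noise on scaled counts, then a
#' multiplicative per-pixel TIC drift applied to all peaks. All log-normal
#' multipliers are mean-one, so region means are unbiased and TIC
#' normalization removes exactly the drift term.
#'
#' @param grid_size integer 2-vector, pixels (rows, cols).
#' @param pixel_size um per pixel.
#' @param tissue_axes ellipse semi-axes as fractions of the grid dimensions.
#' @param n_airways,lumen_radius,epithelium_thickness,subepithelium_thickness
#'   airway geometry (radii/thicknesses in pixels; `lumen_radius` a range).
#' @param n_vessels,vessel_radius vessel geometry.
#' @param alveolar_porosity fraction of alveolar pixels punched out as
#'   off-tissue micro-holes.
#' @param ground_truth_tf named targeting factors for the three quantified
#'   compartments.
#' @param plasma invented plasma concentrations per route plus unit string.
#' @param iv_means IV-drug mean intensity per compartment; the inhaled means
#'   follow from `ground_truth_tf` and `plasma`.
#' @param inhaled_vessel,inhaled_lumen inhaled-drug means in compartments
#'   not covered by a targeting factor.
#' @param marker_means list of per-compartment means for `heme_b`,
#'   `pc_32_0`, `pc_36_4`, matrix-cluster ions and the baseline ion.
#' @param noise list: `tic_sigma`, `pixel_sigma` (named per channel,
#'   `default` fallback), `airway_sigma`, `poisson`, `counts_scale`. The
#'   string `"none"` disables everything.
#' @param d3_shift deuterium mass shift passed to [default_analytes()].
#' @return A `lung_scenario` list.
#' @export
lung_scenario <- function(grid_size = c(200L, 200L),
                          pixel_size = 10,
                          tissue_axes = c(0.475, 0.41),
                          n_airways = 6L,
                          lumen_radius = c(6, 12),
                          epithelium_thickness = 3,
                          subepithelium_thickness = 4,
                          n_vessels = 5L,
                          vessel_radius = c(2, 4),
                          alveolar_porosity = 0.05,
                          ground_truth_tf = c(alveolar = 5,
                                              sub_epithelium = 31,
                                              epithelium = 45),
                          plasma = list(inhaled = 1.2, iv = 12,
                                        unit = "nmol_per_L"),
                          iv_means = c(alveolar = 10, epithelium = 3,
                                       sub_epithelium = 4, vessel = 12,
                                       lumen = 0, background = 0),
                          inhaled_vessel = 1.5,
                          inhaled_lumen = 0,
                          marker_means = NULL,
                          noise = list(tic_sigma = 0.25,
                                       pixel_sigma = c(salmeterol = 0.9,
                                                       d3_salmeterol = 0.3,
                                                       default = 0.2),
                                       airway_sigma = 0.5,
                                       poisson = TRUE,
                                       counts_scale = 2),
                          d3_shift = 3 * 1.00628) {
  if (identical(noise, "none"))
    noise <- list(tic_sigma = 0, pixel_sigma = c(default = 0),
                  airway_sigma = 0, poisson = FALSE, counts_scale = 1)
  if (is.null(marker_means))
    marker_means <- list(
      heme_b   = c(alveolar = 10, epithelium = 5, sub_epithelium = 15,
                   vessel = 200, lumen = 0, background = 0),
      pc_32_0  = c(alveolar = 200, epithelium = 10, sub_epithelium = 70,
                   vessel = 60, lumen = 0, background = 0),
      pc_36_4  = c(alveolar = 20, epithelium = 180, sub_epithelium = 120,
                   vessel = 20, lumen = 1, background = 0),
      matrix_337 = c(alveolar = 15, epithelium = 15, sub_epithelium = 15,
                     vessel = 15, lumen = 3, background = 25),
      matrix_550 = c(alveolar = 15, epithelium = 15, sub_epithelium = 15,
                     vessel = 15, lumen = 3, background = 25),
      baseline_320 = c(alveolar = 2, epithelium = 2, sub_epithelium = 2,
                       vessel = 2, lumen = 2, background = 2))
  stopifnot(all(grid_size >= 20), alveolar_porosity >= 0,
            alveolar_porosity < 1, all(ground_truth_tf > 0),
            plasma$inhaled > 0, plasma$iv > 0, all(iv_means >= 0))
  structure(list(grid_size = as.integer(grid_size), pixel_size = pixel_size,
                 tissue_axes = tissue_axes, n_airways = as.integer(n_airways),
                 lumen_radius = lumen_radius,
                 epithelium_thickness = epithelium_thickness,
                 subepithelium_thickness = subepithelium_thickness,
                 n_vessels = as.integer(n_vessels),
                 vessel_radius = vessel_radius,
                 alveolar_porosity = alveolar_porosity,
                 ground_truth_tf = ground_truth_tf, plasma = plasma,
                 iv_means = iv_means, inhaled_vessel = inhaled_vessel,
                 inhaled_lumen = inhaled_lumen, marker_means = marker_means,
                 noise = noise, d3_shift = d3_shift),
            class = "lung_scenario")
}

#' @export
print.lung_scenario <- function(x, ...) {
  cat("<lung_scenario> ", x$grid_size[1], " x ", x$grid_size[2],
      " px at ", x$pixel_size, " um; ", x$n_airways, " airways, ",
      x$n_vessels, " vessels\n", sep = "")
  cat("  ground-truth targeting factors: ",
      paste(names(x$ground_truth_tf), x$ground_truth_tf, sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-channel, per-compartment mean-intensity table of a scenario
#'
#' The inhaled-drug row is derived from the ground-truth targeting factors:
#' `inhaled_mean[c] = TF[c] * (plasma_inhaled / plasma_iv) * iv_mean[c]` for
#' the quantified compartments, so the scenario's truth is internally
#' consistent by construction.
#'
#' @param scenario a `lung_scenario`.
#' @return numeric matrix, channels x compartments.
#' @export
scenario_intensity_table <- function(scenario) {
  pr <- scenario$plasma$inhaled / scenario$plasma$iv
  inh <- c(alveolar = unname(scenario$ground_truth_tf["alveolar"] * pr *
                               scenario$iv_means["alveolar"]),
           epithelium = unname(scenario$ground_truth_tf["epithelium"] * pr *
                                 scenario$iv_means["epithelium"]),
           sub_epithelium = unname(scenario$ground_truth_tf["sub_epithelium"] *
                                     pr * scenario$iv_means["sub_epithelium"]),
           vessel = scenario$inhaled_vessel, lumen = scenario$inhaled_lumen,
           background = 0)
  rows <- c(list(salmeterol = inh[COMPARTMENTS],
                 d3_salmeterol = scenario$iv_means[COMPARTMENTS]),
            lapply(scenario$marker_means, function(v) v[COMPARTMENTS]))
  tab <- do.call(rbind, rows)
  colnames(tab) <- COMPARTMENTS
  tab
}

scenario_channel_mz <- function(scenario) {
  an <- default_analytes(scenario$d3_shift)
  c(salmeterol = an$salmeterol$mz_center,
    d3_salmeterol = an$d3_salmeterol$mz_center,
    heme_b = an$heme_b$mz_center, pc_32_0 = an$pc_32_0$mz_center,
    pc_36_4 = an$pc_36_4$mz_center,
    matrix_337 = 337.10, matrix_550 = 550.20, baseline_320 = 320.20)
}

place_circles <- function(n, radii, axes, center, occupied, gap = 2,
                          max_tries = 500L) {
  placed <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0))
  all_prev <- rbind(occupied, placed)
  for (i in seq_len(n)) {
    r <- radii[i]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      x <- stats::runif(1, center[1] - axes[1], center[1] + axes[1])
      y <- stats::runif(1, center[2] - axes[2], center[2] + axes[2])
      inside <- ((x - center[1]) / (axes[1] - r - 1))^2 +
        ((y - center[2]) / (axes[2] - r - 1))^2 <= 1
      if (!inside) next
      all_prev <- rbind(occupied, placed)
      if (nrow(all_prev) == 0 ||
          all(sqrt((all_prev$x - x)^2 + (all_prev$y - y)^2) >
              all_prev$r + r + gap)) {
        placed <- rbind(placed, data.frame(x = x, y = y, r = r))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("cannot place structure ", i, " of ", n,
                  " without overlap after ", max_tries, " tries")
  }
  placed
}

#' Generate the ground-truth geometry of a synthetic lung section
#'
#' Places non-overlapping circular airways (lumen + epithelium ring +
#' sub-epithelium ring) and vessels inside an elliptical tissue boundary,
#' punches out alveolar micro-holes, and labels every grid cell with its
#' compartment. Deterministic per seed.
#'
#' @param scenario a `lung_scenario`.
#' @param seed integer seed.
#' @return list: `labels` (character matrix of compartment names),
#'   `airway_id` (integer matrix, 0 outside airways), `airways`/`vessels`
#'   data frames, per-compartment pixel `counts`, and the `seed`.
#' @export
generate_geometry <- function(scenario, seed = 1L) {
  with_seed(seed, {
    nr <- scenario$grid_size[1]; nc <- scenario$grid_size[2]
    cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
    ax <- scenario$tissue_axes[1] * nc; ay <- scenario$tissue_axes[2] * nr
    X <- matrix(rep(seq_len(nc), each = nr), nr)
    Y <- matrix(rep(seq_len(nr), nc), nr)
    labels <- matrix("background", nr, nc)
    inside <- ((X - cx) / ax)^2 + ((Y - cy) / ay)^2 <= 1
    labels[inside] <- "alveolar"

    ring <- scenario$epithelium_thickness + scenario$subepithelium_thickness
    airway_id <- matrix(0L, nr, nc)
    airways <- data.frame()
    if (scenario$n_airways > 0) {
      lum_r <- stats::runif(scenario$n_airways, scenario$lumen_radius[1],
                            scenario$lumen_radius[2])
      airways <- place_circles(scenario$n_airways, lum_r + ring,
                               c(ax, ay), c(cx, cy),
                               occupied = data.frame(x = numeric(0),
                                                     y = numeric(0),
                                                     r = numeric(0)))
      airways$lumen_r <- airways$r - ring
      for (i in seq_len(nrow(airways))) {
        d <- sqrt((X - airways$x[i])^2 + (Y - airways$y[i])^2)
        lr <- airways$lumen_r[i]
        sel <- d <= airways$r[i] & inside
        airway_id[sel] <- i
        labels[d <= lr & inside] <- "lumen"
        labels[d > lr & d <= lr + scenario$epithelium_thickness & inside] <-
          "epithelium"
        labels[d > lr + scenario$epithelium_thickness & d <= airways$r[i] &
                 inside] <- "sub_epithelium"
      }
    }
    vessels <- data.frame()
    if (scenario$n_vessels > 0) {
      ves_r <- stats::runif(scenario$n_vessels, scenario$vessel_radius[1],
                            scenario$vessel_radius[2])
      vessels <- place_circles(scenario$n_vessels, ves_r, c(ax, ay),
                               c(cx, cy), occupied = airways[,
                                 c("x", "y", "r"), drop = FALSE])
      for (i in seq_len(nrow(vessels))) {
        d <- sqrt((X - vessels$x[i])^2 + (Y - vessels$y[i])^2)
        labels[d <= vessels$r[i] & inside] <- "vessel"
      }
    }
    if (scenario$alveolar_porosity > 0) {
      # micro-holes are small blobs (airspaces), not isolated pixels
      alv_n <- sum(labels == "alveolar")
      target <- round(alv_n * scenario$alveolar_porosity)
      punched <- 0L
      tries <- 0L
      while (punched < target && tries < 50L * target) {
        tries <- tries + 1L
        hx <- stats::runif(1, cx - ax, cx + ax)
        hy <- stats::runif(1, cy - ay, cy + ay)
        hr <- stats::runif(1, 1, 2.2)
        sel <- (X - hx)^2 + (Y - hy)^2 <= hr^2 & labels == "alveolar"
        if (any(sel)) {
          labels[sel] <- "background"
          punched <- punched + sum(sel)
        }
      }
    }
    counts <- table(factor(labels, levels = COMPARTMENTS))
    list(labels = labels, airway_id = airway_id, airways = airways,
         vessels = vessels, counts = counts, seed = seed)
  })
}

#' Simulate an MSI acquisition of a synthetic section
#'
#' Builds a continuous-mode dataset over the full rectangular field of view:
#' every pixel gets a spectrum with one peak per analyte channel at intensity
#' `compartment mean x mean-one log-normal pixel effect` (the inhaled drug
#' additionally times a mean-one per-airway deposition multiplier), then
#' Poisson counting noise on scaled counts, then all peaks are multiplied by
#' a per-pixel TIC drift factor. Off-tissue pixels carry matrix-cluster ions
#' only.
#'
#' @param scenario a `lung_scenario`.
#' @param geometry output of [generate_geometry()]; generated from `seed`
#'   when `NULL`.
#' @param seed integer seed for the noise draws (and geometry if needed).
#' @return list: `dataset` (an `msi_dataset`), `truth` (ground-truth labels,
#'   noiseless per-channel images, targeting factors, plasma, scenario).
#' @export
simulate_msi <- function(scenario, geometry = NULL, seed = 1L) {
  if (is.null(geometry)) geometry <- generate_geometry(scenario, seed)
  tab <- scenario_intensity_table(scenario)
  mzs <- scenario_channel_mz(scenario)
  stopifnot(identical(rownames(tab), names(mzs)))
  ord <- order(mzs)
  labels <- geometry$labels
  nr <- nrow(labels); nc <- ncol(labels)
  labv <- as.vector(labels)
  n <- length(labv)
  p <- length(mzs)
  M <- t(tab)[match(labv, COMPARTMENTS), , drop = FALSE]  # n x p means
  noiseless <- M

  nz <- scenario$noise
  sigma_for <- function(ch) {
    s <- nz$pixel_sigma[ch]
    if (is.na(s)) s <- nz$pixel_sigma["default"]
    if (is.na(s)) s <- 0
    unname(s)
  }
  out <- with_seed(seed + 1L, {
    A <- M
    if (nz$airway_sigma > 0 && nrow(geometry$airways) > 0) {
      s <- nz$airway_sigma
      mult <- exp(stats::rnorm(nrow(geometry$airways), 0, s) - s^2 / 2)
      aid <- as.vector(geometry$airway_id)
      w <- aid > 0
      A[w, "salmeterol"] <- A[w, "salmeterol"] * mult[aid[w]]
    }
    for (j in seq_len(p)) {
      s <- sigma_for(colnames(A)[j])
      if (s > 0)
        A[, j] <- A[, j] * exp(stats::rnorm(n, 0, s) - s^2 / 2)
    }
    if (isTRUE(nz$poisson)) {
      cs <- nz$counts_scale
      A[] <- stats::rpois(length(A), lambda = A * cs) / cs
    }
    if (nz$tic_sigma > 0) {
      s <- nz$tic_sigma
      A <- A * exp(stats::rnorm(n, 0, s) - s^2 / 2)
    }
    A
  })

  coords <- cbind(x = as.vector(matrix(rep(seq_len(nc), each = nr), nr)),
                  y = as.vector(matrix(rep(seq_len(nr), nc), nr)))
  ds <- msi_dataset(coords, mz = unname(mzs[ord]),
                    intensities = out[, ord, drop = FALSE],
                    mode = "continuous", pixel_size = scenario$pixel_size,
                    polarity = "positive", mz_range = c(300, 1000),
                    metadata = list(synthetic = TRUE, seed = seed))
  truth_images <- lapply(seq_len(p), function(j)
    matrix(noiseless[, j], nr, nc))
  names(truth_images) <- colnames(noiseless)
  list(dataset = ds,
       truth = list(labels = labels, images = truth_images,
                    tf = scenario$ground_truth_tf,
                    section_tf = NA_real_, plasma = scenario$plasma,
                    airway_id = geometry$airway_id, scenario = scenario,
                    seed = seed))
}

#' Ground-truth tissue mask of a simulated section
#'
#' Tissue means the four cellular compartments (alveolar, epithelium,
#' sub-epithelium, vessel); lumens, micro-holes and off-tissue background
#' are excluded.
#'
#' @param truth the `truth` element returned by [simulate_msi()] (or a label
#'   matrix).
#' @return a `tissue_mask` with `provenance = "ground_truth"`.
#' @export
truth_tissue_mask <- function(truth) {
  labels <- if (is.matrix(truth)) truth else truth$labels
  new_tissue_mask(matrix(labels %in% c("alveolar", "epithelium",
                                       "sub_epithelium", "vessel"),
                         nrow(labels)),
                  "ground_truth")
}

#' Write a scenario to YAML (and read it back)
#'
#' @param scenario a `lung_scenario`.
#' @param path YAML file path.
#' @return `path` invisibly; `scenario_from_yaml()` returns the
#'   reconstructed `lung_scenario`.
#' @export
scenario_to_yaml <- function(scenario, path) {
  x <- unclass(scenario)
  x$ground_truth_tf <- as.list(x$ground_truth_tf)
  x$iv_means <- as.list(x$iv_means)
  x$marker_means <- lapply(x$marker_means, as.list)
  x$noise$pixel_sigma <- as.list(x$noise$pixel_sigma)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname scenario_to_yaml
#' @param path YAML file path.
#' @export
scenario_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  x$ground_truth_tf <- unlist(x$ground_truth_tf)
  x$iv_means <- unlist(x$iv_means)
  x$marker_means <- lapply(x$marker_means, unlist)
  x$noise$pixel_sigma <- unlist(x$noise$pixel_sigma)
  do.call(lung_scenario, x[setdiff(names(x), character(0))])
}

#' Simulate a kinetic time series of sections
#'
#' Scales the inhaled-drug channel by a biphasic disposition curve
#' `a1 * exp(-k1 t) + a2 * exp(-k2 t)` and simulates one section per time
#' point, for exercising [kinetic_profile()].
#'
#' @param scenario a `lung_scenario` (use a small grid).
#' @param times minutes post dose.
#' @param seed integer seed.
#' @param a1,k1,a2,k2 biphasic curve parameters (amplitudes, 1/min rates).
#' @return list: `datasets`, `times`, `concentration` (the generating
#'   curve), `masks` (ground-truth tissue masks).
#' @export
simulate_kinetic_series <- function(scenario, times, seed = 1L,
                                    a1 = 0.7, k1 = 0.15, a2 = 0.3,
                                    k2 = 0.01) {
  conc <- a1 * exp(-k1 * times) + a2 * exp(-k2 * times)
  geom <- generate_geometry(scenario, seed)
  sims <- lapply(seq_along(times), function(i) {
    sc <- scenario
    f <- conc[i] / conc[1]
    sc$ground_truth_tf <- scenario$ground_truth_tf * f
    sc$inhaled_vessel <- scenario$inhaled_vessel * f
    simulate_msi(sc, geom, seed = seed + i)
  })
  list(datasets = lapply(sims, `[[`, "dataset"), times = times,
       concentration = conc,
       masks = lapply(sims, function(s) truth_tissue_mask(s$truth)))
}
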