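# The headline statistic: plasma-normalized regional exposure and the
# inhaled-to-IV lung targeting factor per histological compartment, from a
# dual-isotope design in which the inhaled drug and its deuterated
# isotopologue (IV) are imaged in the same section and distinguished by mass
# shift. The targeting factor expresses, for a defined location, the fold
# gain in local drug exposure attributable to inhaled delivery at matched
# systemic (plasma) exposure.

QUANTIFIED_COMPARTMENTS <- c("alveolar", "sub_epithelium", "epithelium")

#' Plasma-normalized exposure
#'
#' @param mean_intensity mean MSI intensity of a region (arbitrary units,
#'   >= 0).
#' @param plasma_concentration plasma concentration of the same analyte
#'   (> 0, any amount/volume unit kept consistent within an analysis).
#' @return exposure in intensity/(amount/volume) units.
#' @export
normalized_exposure <- function(mean_intensity, plasma_concentration) {
  if (plasma_concentration <= 0) stop("plasma concentration must be positive")
  mean_intensity / plasma_concentration
}

#' Lung targeting factor
#'
#' @param exposure_inhaled,exposure_iv plasma-normalized exposures of the
#'   inhaled and IV species in the same region; `exposure_iv` > 0.
#' @return dimensionless fold gain of inhaled over IV delivery.
#' @export
targeting_factor <- function(exposure_inhaled, exposure_iv) {
  if (exposure_iv <= 0) stop("IV exposure must be positive")
  exposure_inhaled / exposure_iv
}

check_plasma <- function(plasma) {
  stopifnot(is.list(plasma))
  for (r in c("inhaled", "iv")) {
    if (is.null(plasma[[r]])) stop("missing plasma concentration for route ",
                                   r)
    if (plasma[[r]] <= 0) stop("plasma concentration for route ", r,
                               " must be positive")
  }
  if (!is.null(plasma$unit_inhaled) && !is.null(plasma$unit_iv) &&
      !identical(plasma$unit_inhaled, plasma$unit_iv))
    stop("plasma units differ between routes: ", plasma$unit_inhaled,
         " vs ", plasma$unit_iv)
  plasma
}

#' Compute the dual-isotope lung targeting report
#'
#' The central analysis. For each replicate section: TIC-normalize, extract
#' the inhaled-drug and IV-drug ion images, average each over the three
#' quantified compartments (alveolar, sub-epithelium, epithelium), normalize
#' each route's means by its plasma concentration, and ratio them into
#' per-compartment targeting factors. A section-level factor is computed the
#' same way over the whole tissue mask, with no consideration of regions.
#' Replicates are aggregated by averaging per-replicate factors (preserving
#' biological-replicate variance) or by pooling pixels.
#'
#' @param sections an `msi_dataset` or list of them (dual-dosed replicate
#'   sections).
#' @param rois an `roi_set` (or ground-truth compartment-name grid), or a
#'   list of them matching `sections`.
#' @param inhaled,iv `analyte` definitions of the two drug channels.
#' @param plasma list with elements `inhaled` and `iv` (concentrations > 0)
#'   and optional `unit_inhaled`/`unit_iv` strings which must match.
#' @param masks optional `tissue_mask` (or list) for the section-level
#'   factor; default: [compute_tissue_mask()] on the raw TIC image.
#' @param aggregate `"per_replicate"` (default: factor per section, then
#'   mean +/- sd) or `"pooled"` (pool pixels across sections).
#' @param response_factor multiplicative ionization response correction
#'   applied to the IV channel (default 1: no isotope-effect correction).
#' @param tic_target TIC normalization target (see [tic_normalize()]).
#' @return A `targeting_report` with per-replicate and aggregate tables;
#'   see [coef.targeting_report()], [summary.targeting_report()].
#' @export
lung_targeting <- function(sections, rois, inhaled, iv, plasma,
                           masks = NULL,
                           aggregate = c("per_replicate", "pooled"),
                           response_factor = 1,
                           tic_target = "mean") {
  aggregate <- match.arg(aggregate)
  if (inherits(sections, "msi_dataset")) sections <- list(sections)
  if (!is.list(rois) || inherits(rois, "roi_set")) rois <- list(rois)
  if (length(rois) == 1L && length(sections) > 1L)
    rois <- rep(rois, length(sections))
  stopifnot(length(rois) == length(sections))
  if (!is.null(masks) && inherits(masks, "tissue_mask")) masks <- list(masks)
  if (!is.null(masks) && length(masks) == 1L)
    masks <- rep(masks, length(sections))
  plasma <- check_plasma(plasma)
  n_rep <- length(sections)

  per <- list()
  section_rows <- list()
  for (s in seq_len(n_rep)) {
    raw <- sections[[s]]
    tic_raw <- tic_image(raw)
    dn <- suppressMessages(tic_normalize(raw, target = tic_target))
    img_in <- extract_ion_image(dn, inhaled)
    img_iv <- extract_ion_image(dn, iv)
    img_iv$grid <- img_iv$grid * response_factor
    for (comp in QUANTIFIED_COMPARTMENTS) {
      roi <- roi_pixels(rois[[s]], comp)
      if (!any(roi)) stop("compartment '", comp, "' is empty in replicate ",
                          s)
      mi <- roi_mean_intensity(img_in, roi)
      mv <- roi_mean_intensity(img_iv, roi)
      ei <- normalized_exposure(mi$mean, plasma$inhaled)
      ev <- normalized_exposure(mv$mean, plasma$iv)
      per[[length(per) + 1L]] <- data.frame(
        replicate = s, compartment = comp,
        mean_inhaled = mi$mean, mean_iv = mv$mean,
        exposure_inhaled = ei, exposure_iv = ev,
        targeting_factor = targeting_factor(ei, ev),
        n_pixels = mi$n)
    }
    msk <- if (is.null(masks))
      compute_tissue_mask(tic_raw, method = "tic_threshold")
    else masks[[s]]
    mgrid <- if (inherits(msk, "tissue_mask")) msk$grid else msk
    mi <- roi_mean_intensity(img_in, mgrid)
    mv <- roi_mean_intensity(img_iv, mgrid)
    ei <- normalized_exposure(mi$mean, plasma$inhaled)
    ev <- normalized_exposure(mv$mean, plasma$iv)
    section_rows[[s]] <- data.frame(
      replicate = s, targeting_factor = targeting_factor(ei, ev),
      n_pixels = mi$n)
  }
  per <- do.call(rbind, per)
  section <- do.call(rbind, section_rows)

  agg <- if (aggregate == "per_replicate") {
    do.call(rbind, lapply(QUANTIFIED_COMPARTMENTS, function(comp) {
      tf <- per$targeting_factor[per$compartment == comp]
      data.frame(compartment = comp, targeting_factor = mean(tf),
                 sd = if (n_rep > 1) stats::sd(tf) else NA_real_, n = n_rep)
    }))
  } else {
    do.call(rbind, lapply(QUANTIFIED_COMPARTMENTS, function(comp) {
      rows <- per[per$compartment == comp, ]
      w <- rows$n_pixels
      ei <- normalized_exposure(sum(rows$mean_inhaled * w) / sum(w),
                                plasma$inhaled)
      ev <- normalized_exposure(sum(rows$mean_iv * w) / sum(w), plasma$iv)
      data.frame(compartment = comp,
                 targeting_factor = targeting_factor(ei, ev),
                 sd = NA_real_, n = n_rep)
    }))
  }

  structure(list(per_replicate = per, aggregate = agg,
                 section_level = section,
                 section_level_factor = mean(section$targeting_factor),
                 plasma = plasma, n_replicates = n_rep,
                 analytes = c(inhaled = inhaled$name, iv = iv$name),
                 aggregate_mode = aggregate),
            class = "targeting_report")
}

#' @export
print.targeting_report <- function(x, ...) {
  cat("Dual-isotope lung targeting report (", x$analytes[["inhaled"]],
      " inhaled / ", x$analytes[["iv"]], " IV; n = ", x$n_replicates,
      " replicate sections)\n", sep = "")
  a <- x$aggregate
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-15s targeting factor %6.2f%s\n", a$compartment[i],
                a$targeting_factor[i],
                if (is.na(a$sd[i])) "" else sprintf(" (sd %.2f)", a$sd[i])))
  cat(sprintf("  %-15s targeting factor %6.2f\n", "whole section",
              x$section_level_factor))
  invisible(x)
}

#' Aggregate targeting factors of a report
#'
#' @param object a `targeting_report`.
#' @param ... unused.
#' @return named numeric: the three compartment factors and the
#'   section-level factor.
#' @export
coef.targeting_report <- function(object, ...) {
  c(setNames(object$aggregate$targeting_factor,
             object$aggregate$compartment),
    section = object$section_level_factor)
}

#' @export
summary.targeting_report <- function(object, ...) {
  print(object)
  cat("\nPer-replicate detail:\n")
  print(object$per_replicate, row.names = FALSE, digits = 4)
  cat("\nPlasma concentrations: inhaled ", object$plasma$inhaled, ", IV ",
      object$plasma$iv,
      if (!is.null(object$plasma$unit_inhaled))
        paste0(" ", object$plasma$unit_inhaled), "\n", sep = "")
  invisible(object)
}

#' @export
as.data.frame.targeting_report <- function(x, ...) x$per_replicate

#' @export
plot.targeting_report <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 3), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(old))
  per <- x$per_replicate
  comp <- QUANTIFIED_COMPARTMENTS
  mi <- vapply(comp, function(cc) mean(per$mean_inhaled[per$compartment == cc]),
               numeric(1))
  mv <- vapply(comp, function(cc) mean(per$mean_iv[per$compartment == cc]),
               numeric(1))
  ei <- vapply(comp, function(cc)
    mean(per$exposure_inhaled[per$compartment == cc]), numeric(1))
  ev <- vapply(comp, function(cc)
    mean(per$exposure_iv[per$compartment == cc]), numeric(1))
  graphics::barplot(rbind(mi, mv), beside = TRUE, names.arg = comp,
                    las = 2, main = "mean intensity",
                    legend.text = c("inhaled", "IV"))
  graphics::barplot(rbind(ei, ev), beside = TRUE, names.arg = comp,
                    las = 2, main = "plasma-normalized")
  graphics::barplot(setNames(x$aggregate$targeting_factor, comp), las = 2,
                    main = "targeting factor")
  invisible(x)
}

#' Whole-section kinetic profile
#'
#' Mean TIC-normalized intensity of one analyte across a time series of
#' sections, optionally overlaid on (rescaled to) a companion concentration
#' series, with the Pearson correlation between the two reported.
#'
#' @param datasets list of `msi_dataset`s, one per time point.
#' @param times numeric time vector (minutes post dose), same length.
#' @param analyte the `analyte` to profile.
#' @param masks optional list of `tissue_mask`s per dataset.
#' @param reference optional numeric concentration series, same length.
#' @return A `kinetic_profile`: data frame `profile` (time, msi_mean, and if
#'   given, reference and reference_scaled) plus `pearson_r`.
#' @export
kinetic_profile <- function(datasets, times, analyte, masks = NULL,
                            reference = NULL) {
  if (length(datasets) < 2) stop("need >= 2 time points")
  if (length(times) != length(datasets))
    stop("mismatched time vector: ", length(times), " times for ",
         length(datasets), " datasets")
  if (!is.null(reference) && length(reference) != length(times))
    stop("mismatched reference series length")
  msi_mean <- vapply(seq_along(datasets), function(i) {
    dn <- suppressMessages(tic_normalize(datasets[[i]]))
    img <- extract_ion_image(dn, analyte)
    m <- if (is.null(masks)) !is.na(img$grid) else
      (if (inherits(masks[[i]], "tissue_mask")) masks[[i]]$grid
       else masks[[i]])
    mean(img$grid[m & !is.na(img$grid)])
  }, numeric(1))
  prof <- data.frame(time = times, msi_mean = msi_mean)
  r <- NA_real_
  if (!is.null(reference)) {
    prof$reference <- reference
    sc <- sum(msi_mean * reference) / sum(reference^2)
    prof$reference_scaled <- reference * sc
    if (stats::sd(msi_mean) > 0 && stats::sd(reference) > 0)
      r <- stats::cor(msi_mean, reference)
  }
  structure(list(profile = prof[order(prof$time), ], pearson_r = r,
                 analyte = analyte$name),
            class = "kinetic_profile")
}

#' @export
print.kinetic_profile <- function(x, ...) {
  cat("<kinetic_profile> ", x$analyte, ", ", nrow(x$profile),
      " time points", sep = "")
  if (!is.na(x$pearson_r))
    cat("; Pearson r vs reference = ", format(round(x$pearson_r, 4)),
        sep = "")
  cat("\n")
  print(x$profile, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.kinetic_profile <- function(x, ...) {
  p <- x$profile
  graphics::plot(p$time, p$msi_mean, type = "b", pch = 16,
                 xlab = "time post dose (min)",
                 ylab = "mean section intensity",
                 main = paste0(x$analyte, " kinetic profile"), ...)
  if (!is.null(p$reference_scaled))
    graphics::lines(p$time, p$reference_scaled, lty = 2, col = "grey40")
  invisible(x)
}
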