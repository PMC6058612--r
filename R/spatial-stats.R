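# Image statistics for drug-distribution heterogeneity and marker
# colocalization: pixel-to-pixel relative standard deviation, Pearson spatial
# correlation between ion images, per-ROI mean intensity, and the two-sided
# two-sample t-test used for group comparisons.

mask_values <- function(image, mask) {
  g <- if (inherits(image, "ion_image")) image$grid else image
  m <- if (inherits(mask, "tissue_mask")) mask$grid else mask
  if (is.null(m)) m <- !is.na(g)
  stopifnot(identical(dim(g), dim(m)))
  v <- g[m & !is.na(m)]
  v[!is.na(v)]
}

#' Pixel-to-pixel heterogeneity (RSD %)
#'
#' Relative standard deviation of the masked pixel intensities: sample
#' standard deviation (n - 1 denominator) divided by the mean, times 100.
#' High values mean a patchy distribution, low values a homogeneous one.
#'
#' @param image an `ion_image` (normally TIC-normalized).
#' @param mask a `tissue_mask` or logical matrix restricting to on-tissue
#'   pixels; default: all acquired pixels.
#' @param route optional route label carried into the result (e.g.
#'   `"inhaled"`).
#' @return A `heterogeneity_result`: `rsd_percent`, `n_pixels`, `analyte`,
#'   `route`.
#' @export
pixel_rsd <- function(image, mask = NULL, route = NA_character_) {
  v <- mask_values(image, mask)
  if (length(v) < 2) stop("need >= 2 masked pixels, got ", length(v))
  m <- mean(v)
  if (m <= 0) stop("mean intensity is not positive; RSD undefined")
  structure(list(rsd_percent = 100 * stats::sd(v) / m,
                 n_pixels = length(v),
                 analyte = if (inherits(image, "ion_image"))
                   image$analyte$name else NA_character_,
                 route = route),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat("<heterogeneity> ", if (!is.na(x$route)) paste0(x$route, " "), x$analyte,
      ": RSD ", format(round(x$rsd_percent, 1)), "% over ", x$n_pixels,
      " pixels\n", sep = "")
  invisible(x)
}

#' Pearson spatial correlation between two ion images
#'
#' Pearson r over the pixel pairs of the shared mask, reported in percent as
#' correlation tables in this field customarily are.
#'
#' @param image_a,image_b `ion_image`s on the same grid.
#' @param mask `tissue_mask`/logical matrix; default: pixels acquired in
#'   both.
#' @return correlation in percent, in `[-100, 100]`.
#' @export
pearson_image_correlation <- function(image_a, image_b, mask = NULL) {
  ga <- if (inherits(image_a, "ion_image")) image_a$grid else image_a
  gb <- if (inherits(image_b, "ion_image")) image_b$grid else image_b
  stopifnot(identical(dim(ga), dim(gb)))
  m <- if (is.null(mask)) !is.na(ga) & !is.na(gb)
       else (if (inherits(mask, "tissue_mask")) mask$grid else mask) &
         !is.na(ga) & !is.na(gb)
  a <- ga[m]; b <- gb[m]
  if (length(a) < 3) stop("need >= 3 masked pixels")
  if (stats::sd(a) == 0) stop("first image is constant on the mask")
  if (stats::sd(b) == 0) stop("second image is constant on the mask")
  100 * stats::cor(a, b)
}

#' Pairwise correlation table of ion images
#'
#' @param images named list of `ion_image`s on one grid.
#' @param mask shared mask (see [pearson_image_correlation()]).
#' @param digits rounding for display (default 0, whole percent as in
#'   published marker-correlation tables); full precision retained when
#'   `digits = NULL`.
#' @return symmetric matrix of correlations in percent, 100 on the diagonal.
#' @export
correlation_table <- function(images, mask = NULL, digits = 0) {
  n <- length(images)
  stopifnot(n >= 2, !is.null(names(images)))
  M <- diag(100, n)
  dimnames(M) <- list(names(images), names(images))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- pearson_image_correlation(images[[i]], images[[j]], mask)
    M[i, j] <- M[j, i] <- r
  }
  if (!is.null(digits)) M <- round(M, digits)
  M
}

#' Mean intensity over a region of interest
#'
#' @param image an `ion_image` (TIC-normalized for quantitative use).
#' @param roi logical matrix of ROI membership (e.g. from [roi_pixels()]).
#' @return list with `mean` and `n` (pixels contributing; missing cells are
#'   excluded).
#' @export
roi_mean_intensity <- function(image, roi) {
  g <- if (inherits(image, "ion_image")) image$grid else image
  stopifnot(identical(dim(g), dim(roi)))
  v <- g[roi & !is.na(g)]
  if (!length(v)) stop("empty ROI")
  list(mean = mean(v), n = length(v))
}

#' Two-sided two-sample t-test
#'
#' Classical Student's t with pooled variance by default (`welch = TRUE`
#' selects the unequal-variance variant), two-sided.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param welch use the Welch correction (default `FALSE`).
#' @return the two-sided p-value.
#' @export
two_sided_t_test <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 values")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0 &&
      mean(group_a) == mean(group_b))
    return(1)
  stats::t.test(group_a, group_b, var.equal = !welch,
                alternative = "two.sided")$p.value
}
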