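# Ion images: 2-D maps of summed intensity within an m/z window, laid out on
# the bounding box of the dataset's pixel grid. Rows are y (downward), columns
# are x (rightward); this conversion from 1-based imzML pixel indices to
# 0-offset row/col lives here and nowhere else. Grid cells never acquired are
# NA ("missing"), which is distinct from an acquired pixel whose window is
# empty (0).

grid_geometry <- function(coords) {
  xmin <- min(coords[, 1]); ymin <- min(coords[, 2])
  list(xmin = xmin, ymin = ymin,
       ncol = max(coords[, 1]) - xmin + 1L,
       nrow = max(coords[, 2]) - ymin + 1L)
}

coords_to_idx <- function(coords, geom) {
  cbind(row = coords[, 2] - geom$ymin + 1L,
        col = coords[, 1] - geom$xmin + 1L)
}

grid_from_values <- function(values, coords, geom = grid_geometry(coords)) {
  g <- matrix(NA_real_, geom$nrow, geom$ncol)
  g[coords_to_idx(coords, geom)] <- values
  g
}

new_ion_image <- function(grid, analyte = NULL, normalized = FALSE,
                          pixel_size = 1) {
  structure(list(grid = grid, analyte = analyte,
                 normalized = isTRUE(normalized),
                 pixel_size = as.numeric(pixel_size)),
            class = "ion_image")
}

#' @export
print.ion_image <- function(x, ...) {
  nm <- if (is.null(x$analyte)) "unnamed" else x$analyte$name
  cat("<ion_image> ", nm, ": ", nrow(x$grid), " x ", ncol(x$grid),
      " grid, ", sum(!is.na(x$grid)), " acquired pixels",
      if (x$normalized) ", TIC-normalized" else "", "\n", sep = "")
  invisible(x)
}

#' @export
plot.ion_image <- function(x, main = NULL, ...) {
  if (is.null(main))
    main <- if (is.null(x$analyte)) "ion image" else x$analyte$name
  g <- x$grid
  graphics::image(t(g[nrow(g):1, , drop = FALSE]), main = main, axes = FALSE,
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Extract an ion image for one analyte
#'
#' For each acquired pixel, reduces (default: sums) the intensities of all
#' spectral points whose m/z lies in the analyte's closed extraction window.
#' Pixels with no point in the window get 0; grid cells never acquired stay
#' missing (`NA`).
#'
#' @param x an `msi_dataset`.
#' @param analyte an `analyte` whose window must intersect the dataset's mass
#'   range.
#' @param reducer function reducing in-window intensities to one number
#'   (default `sum`).
#' @return An `ion_image`.
#' @export
extract_ion_image <- function(x, analyte, reducer = sum) {
  stopifnot(inherits(x, "msi_dataset"), inherits(analyte, "analyte"))
  w <- analyte_window(analyte)
  if (w[2] < x$mz_range[1] || w[1] > x$mz_range[2])
    stop(sprintf("extraction window [%g, %g] lies outside the mass range [%g, %g]",
                 w[1], w[2], x$mz_range[1], x$mz_range[2]))
  n <- n_pixels(x)
  vals <- numeric(n)
  if (x$mode == "continuous") {
    sel <- x$mz >= w[1] & x$mz <= w[2]
    if (any(sel)) {
      sub <- x$intensities[, sel, drop = FALSE]
      vals <- if (identical(reducer, sum)) rowSums(sub)
              else apply(sub, 1, reducer)
    }
  } else {
    for (i in seq_len(n)) {
      sel <- x$mz[[i]] >= w[1] & x$mz[[i]] <= w[2]
      vals[i] <- if (any(sel)) reducer(x$intensities[[i]][sel]) else 0
    }
  }
  new_ion_image(grid_from_values(vals, x$coords), analyte,
                normalized = is_tic_normalized(x), pixel_size = x$pixel_size)
}

#' Total-ion-count image of a dataset
#'
#' @param x an `msi_dataset`.
#' @return An `ion_image` whose values are per-pixel summed intensity.
#' @export
tic_image <- function(x) {
  new_ion_image(grid_from_values(pixel_tic(x), x$coords),
                analyte = analyte("TIC", mz_center = mean(x$mz_range),
                                  tol = diff(x$mz_range) / 2),
                normalized = is_tic_normalized(x), pixel_size = x$pixel_size)
}

new_tissue_mask <- function(grid, provenance = c("threshold", "manual",
                                                 "ground_truth")) {
  provenance <- match.arg(provenance)
  stopifnot(is.logical(grid))
  structure(list(grid = grid, provenance = provenance),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat("<tissue_mask> ", sum(x$grid, na.rm = TRUE), " on-tissue pixels of ",
      length(x$grid), " (", x$provenance, ")\n", sep = "")
  invisible(x)
}

#' Compute an on-tissue mask from ion images
#'
#' Restricting statistics to on-tissue pixels must be explicit; this builds
#' the boolean mask. `tic_threshold` marks acquired pixels whose raw TIC
#' exceeds the stated quantile of the TIC distribution; `marker_union` marks
#' pixels where any supplied marker image exceeds its own quantile threshold.
#'
#' @param images a single `ion_image` (for `tic_threshold`, normally the
#'   [tic_image()]) or a list of marker `ion_image`s (for `marker_union`).
#' @param method `"tic_threshold"` or `"marker_union"`.
#' @param threshold_quantile quantile of each image's acquired-pixel value
#'   distribution used as the cut (default 0.45).
#' @return A `tissue_mask` with `provenance = "threshold"`. Missing (never
#'   acquired) cells are off-mask.
#' @export
compute_tissue_mask <- function(images,
                                method = c("tic_threshold", "marker_union"),
                                threshold_quantile = 0.45) {
  method <- match.arg(method)
  if (inherits(images, "ion_image")) images <- list(images)
  if (length(images) < 1L) stop("at least one ion image required")
  masks <- lapply(images, function(im) {
    v <- im$grid
    thr <- stats::quantile(v[!is.na(v)], threshold_quantile, names = FALSE)
    !is.na(v) & v > thr
  })
  grid <- Reduce(`|`, masks)
  if (!any(grid)) stop("tissue mask is empty at quantile ", threshold_quantile)
  new_tissue_mask(grid, "threshold")
}

#' Write an ion image or mask grid to CSV
#' @param x an `ion_image`, `tissue_mask`, or numeric matrix.
#' @param path output CSV path; cells as a dense matrix, NA for missing.
#' @return `path`, invisibly.
#' @export
write_image_csv <- function(x, path) {
  g <- if (is.matrix(x)) x else x$grid
  utils::write.table(g, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an ion image or mask as 32-bit TIFF
#'
#' Values are rescaled to `[0, 1]` float samples for display; missing cells
#' are written as 0. Quantitative values belong in the companion CSV
#' ([write_image_csv()]), the TIFF is for viewing.
#'
#' @param x an `ion_image`, `tissue_mask`, or numeric matrix.
#' @param path output `.tiff` path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(x, path) {
  g <- if (is.matrix(x)) x else x$grid
  storage.mode(g) <- "double"
  g[is.na(g)] <- 0
  rng <- range(g)
  gn <- if (diff(rng) > 0) (g - rng[1]) / diff(rng) else g * 0
  tiff::writeTIFF(gn, path, bits.per.sample = 32L)
  invisible(path)
}

#' Jaccard overlap between two boolean grids
#' @param a,b logical matrices (or `tissue_mask`s) of equal shape.
#' @return intersection-over-union in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  if (inherits(a, "tissue_mask")) a <- a$grid
  if (inherits(b, "tissue_mask")) b <- b$grid
  stopifnot(identical(dim(a), dim(b)))
  a <- a & !is.na(a); b <- b & !is.na(b)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
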