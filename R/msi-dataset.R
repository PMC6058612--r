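#' Construct an MSI dataset
#'
#' The raw unit of analysis: a set of pixels on an integer grid, each carrying
#' a mass spectrum (m/z values in Da, intensities in arbitrary counts).
#' In `"continuous"` mode all pixels share one m/z axis and intensities form a
#' pixel-by-channel matrix; in `"processed"` mode each pixel has its own m/z
#' axis and both `mz` and `intensities` are lists.
#'
#' @param coords integer matrix with columns `x`, `y` (1-based imzML pixel
#'   indices, x rightward, y downward), one row per pixel.
#' @param mz numeric vector (continuous mode) or list of numeric vectors
#'   (processed mode), in Da.
#' @param intensities numeric matrix `n_pixels x length(mz)` (continuous) or
#'   list of numeric vectors matching `mz` (processed); all values >= 0.
#' @param mode `"continuous"` or `"processed"`.
#' @param pixel_size pixel edge length in micrometres (> 0).
#' @param polarity `"positive"` or `"negative"`.
#' @param mz_range numeric length-2, the acquisition mass range in Da.
#' @param metadata free-form named list.
#' @return An object of class `msi_dataset`.
#' @export
msi_dataset <- function(coords, mz, intensities,
                        mode = c("continuous", "processed"),
                        pixel_size = 10,
                        polarity = c("positive", "negative"),
                        mz_range = NULL,
                        metadata = list()) {
  mode <- match.arg(mode)
  polarity <- match.arg(polarity)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("coords must have two columns (x, y)")
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("x", "y")
  if (nrow(coords) == 0L) stop("empty dataset: no pixels")
  if (mode == "continuous") {
    mz <- as.numeric(mz)
    intensities <- as.matrix(intensities)
    if (nrow(intensities) != nrow(coords))
      stop("intensities must have one row per pixel")
    if (ncol(intensities) != length(mz))
      stop("intensities must have one column per m/z value")
  } else {
    if (!is.list(mz) || !is.list(intensities))
      stop("processed mode requires list-valued mz and intensities")
    if (length(mz) != nrow(coords) || length(intensities) != nrow(coords))
      stop("mz and intensities lists must have one element per pixel")
    bad <- which(lengths(mz) != lengths(intensities))
    if (length(bad))
      stop("pixel ", bad[1], ": mz and intensity lengths differ")
  }
  if (is.null(mz_range)) {
    allmz <- if (mode == "continuous") mz else unlist(mz, use.names = FALSE)
    mz_range <- if (length(allmz)) range(allmz) else c(0, Inf)
  }
  obj <- structure(
    list(coords = coords, mz = mz, intensities = intensities, mode = mode,
         pixel_size = as.numeric(pixel_size), polarity = polarity,
         mz_range = as.numeric(mz_range), metadata = metadata),
    class = "msi_dataset")
  validate_msi_dataset(obj)
  obj
}

#' Validate an MSI dataset against its invariants
#'
#' Checks coordinate uniqueness, non-negative intensities, and that all m/z
#' values lie inside the declared mass range.
#'
#' @param x an `msi_dataset`.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_msi_dataset <- function(x) {
  stopifnot(inherits(x, "msi_dataset"))
  if (anyDuplicated(paste(x$coords[, 1], x$coords[, 2])))
    stop("duplicate pixel coordinates")
  if (x$pixel_size <= 0) stop("pixel_size must be positive")
  if (x$mode == "continuous") {
    if (any(x$intensities < 0)) stop("negative intensities")
    if (length(x$mz) && (min(x$mz) < x$mz_range[1] || max(x$mz) > x$mz_range[2]))
      stop("m/z values outside declared mz_range")
    if (is.unsorted(x$mz)) stop("continuous-mode m/z axis must be sorted")
  } else {
    for (i in seq_along(x$intensities)) {
      if (any(x$intensities[[i]] < 0))
        stop("negative intensities at pixel ", i)
      m <- x$mz[[i]]
      if (length(m) && (min(m) < x$mz_range[1] || max(m) > x$mz_range[2]))
        stop("m/z values outside declared mz_range at pixel ", i)
    }
  }
  invisible(x)
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat("<msi_dataset> ", nrow(x$coords), " pixels, ", x$mode, " mode, ",
      x$polarity, " polarity\n", sep = "")
  cat("  m/z range: ", format(x$mz_range[1]), "-", format(x$mz_range[2]),
      " Da; pixel size ", x$pixel_size, " um\n", sep = "")
  if (isTRUE(x$metadata$tic_normalized))
    cat("  TIC-normalized (target ", format(x$metadata$tic_target), ")\n",
        sep = "")
  invisible(x)
}

#' Number of pixels in an MSI dataset
#' @param x an `msi_dataset`.
#' @return integer pixel count.
#' @export
n_pixels <- function(x) nrow(x$coords)

#' Per-pixel total ion count
#'
#' @param x an `msi_dataset`.
#' @return numeric vector of per-pixel summed intensity, in pixel order.
#' @export
pixel_tic <- function(x) {
  if (x$mode == "continuous") rowSums(x$intensities)
  else vapply(x$intensities, sum, numeric(1))
}

#' TIC-normalize an MSI dataset
#'
#' Rescales each pixel's spectrum so its total ion count equals a common
#' target, removing per-pixel acquisition drift while conserving the relative
#' peak proportions within each pixel. Pixels with zero total intensity carry
#' no spectral information and are dropped (with a message reporting how
#' many); the dropped count is recorded in `metadata$dropped_zero_tic`.
#'
#' @param x an `msi_dataset`.
#' @param target the common per-pixel TIC after normalization: `"mean"` (the
#'   default; the mean raw TIC across retained pixels, preserving global
#'   intensity scale) or a single positive number such as `1`.
#' @return A TIC-normalized `msi_dataset`.
#' @export
tic_normalize <- function(x, target = "mean") {
  stopifnot(inherits(x, "msi_dataset"))
  tic <- pixel_tic(x)
  keep <- tic > 0
  if (!any(keep)) stop("all pixels have zero total ion count")
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message("tic_normalize: dropped ", n_drop, " zero-TIC pixel(s)")
  tic_kept <- tic[keep]
  tgt <- if (identical(target, "mean")) mean(tic_kept) else as.numeric(target)
  if (!is.finite(tgt) || tgt <= 0) stop("target must be positive")
  scale <- tgt / tic_kept
  out <- x
  out$coords <- x$coords[keep, , drop = FALSE]
  if (x$mode == "continuous") {
    out$intensities <- x$intensities[keep, , drop = FALSE] * scale
  } else {
    out$mz <- x$mz[keep]
    ints <- x$intensities[keep]
    out$intensities <- Map(function(v, s) v * s, ints, scale)
  }
  out$metadata$tic_normalized <- TRUE
  out$metadata$tic_target <- tgt
  out$metadata$dropped_zero_tic <- n_drop
  out
}

#' Is a dataset TIC-normalized?
#' @param x an `msi_dataset`.
#' @return logical flag read from the dataset metadata.
#' @export
is_tic_normalized <- function(x) isTRUE(x$metadata$tic_normalized)
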