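# Unsupervised spatial segmentation of MSI data: pixel spectra are binned,
# TIC-normalized, weakly denoised, then clustered top-down by bisecting
# k-means under correlation distance (1 - Pearson between pixel feature
# vectors), the parameterization used by commercial MSI segmentation tools.

#' Correlation distance between two feature vectors
#'
#' `1 - Pearson(u, v)`, in `[0, 2]`. A vector with zero variance is
#' uninformative and gets the maximal non-informative distance 1 to
#' everything. `method = "szekely"` instead returns `1 - dCor(u, v)` with
#' Szekely's distance correlation (a dependence measure in `[0, 1]`),
#' offered because the colloquial parameter name is ambiguous; the
#' segmentation always uses the Pearson form.
#'
#' @param u,v numeric vectors of equal length >= 2.
#' @param method `"pearson"` (default) or `"szekely"`.
#' @return a distance: `[0, 2]` for Pearson, `[0, 1]` for Szekely.
#' @export
correlation_distance <- function(u, v, method = c("pearson", "szekely")) {
  method <- match.arg(method)
  if (length(u) != length(v)) stop("length mismatch: ", length(u), " vs ",
                                   length(v))
  if (length(u) < 2L) stop("vectors must have length >= 2")
  if (method == "pearson") {
    if (stats::sd(u) == 0 || stats::sd(v) == 0) return(1)
    1 - stats::cor(u, v)
  } else {
    1 - dcor_szekely(u, v)
  }
}

# Szekely's distance correlation for univariate samples (double-centered
# pairwise-distance covariance), small-n direct computation.
dcor_szekely <- function(u, v) {
  n <- length(u)
  A <- abs(outer(u, u, "-")); B <- abs(outer(v, v, "-"))
  A <- A - rowMeans(A)[row(A)] - colMeans(A)[col(A)] + mean(A)
  B <- B - rowMeans(B)[row(B)] - colMeans(B)[col(B)] + mean(B)
  dcov2 <- sum(A * B) / n^2
  du <- sum(A * A) / n^2; dv <- sum(B * B) / n^2
  if (du <= 0 || dv <= 0) return(0)
  sqrt(dcov2 / sqrt(du * dv))
}

#' Bin spectra onto a regular m/z grid
#'
#' Sums each pixel's intensities into fixed-width m/z bins over the dataset's
#' mass range; bins empty in every pixel are dropped. This is the feature
#' space the segmentation operates in.
#'
#' @param x an `msi_dataset`.
#' @param bin_width bin width in Da (default 0.5).
#' @return list with `features` (pixel x bin matrix) and `bin_mz` (bin
#'   centers, Da).
#' @export
bin_spectra <- function(x, bin_width = 0.5) {
  stopifnot(inherits(x, "msi_dataset"), bin_width > 0)
  lo <- x$mz_range[1]
  nb <- max(1L, ceiling((x$mz_range[2] - lo) / bin_width))
  bin_of <- function(mz) pmin(nb, pmax(1L, floor((mz - lo) / bin_width) + 1L))
  n <- n_pixels(x)
  if (x$mode == "continuous") {
    idx <- bin_of(x$mz)
    agg <- t(rowsum(t(x$intensities), group = idx))
    used <- sort(unique(idx))
  } else {
    feats <- matrix(0, n, nb)
    for (i in seq_len(n)) {
      b <- bin_of(x$mz[[i]])
      for (j in seq_along(b)) feats[i, b[j]] <- feats[i, b[j]] +
          x$intensities[[i]][j]
    }
    used <- which(colSums(feats) > 0)
    agg <- feats[, used, drop = FALSE]
  }
  list(features = agg, bin_mz = lo + (used - 0.5) * bin_width)
}

#' Weak spatial denoising of a feature stack
#'
#' Smooths each feature channel with a Gaussian kernel of standard deviation
#' `sigma_px` pixels, as a masked, renormalized convolution: off-mask cells
#' contribute nothing and the kernel weights are renormalized over the mask,
#' so edges are not darkened. `sigma_px = 0` is the identity.
#'
#' @param stack 3-D numeric array `nrow x ncol x n_channels` (use `NA` for
#'   missing cells) or a single matrix.
#' @param sigma_px Gaussian sigma in pixels (>= 0); the kernel is truncated
#'   at 4 sigma.
#' @param mask logical matrix; defaults to the non-`NA` cells of the first
#'   channel.
#' @return the smoothed stack, same shape, off-mask cells `NA`.
#' @export
denoise_weak <- function(stack, sigma_px = 1, mask = NULL) {
  stopifnot(sigma_px >= 0)
  was_matrix <- is.matrix(stack)
  if (was_matrix) stack <- array(stack, c(dim(stack), 1L))
  if (is.null(mask)) mask <- !is.na(stack[, , 1])
  if (sigma_px == 0) {
    out <- stack
    out[array(!mask, dim(stack))] <- NA_real_
    return(if (was_matrix) out[, , 1] else out)
  }
  sm <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-d^2 / (2 * sigma_px^2))
    k[d > 4 * sigma_px] <- 0
    k
  }
  Sr <- sm(nrow(mask)); Sc <- sm(ncol(mask))
  m <- mask * 1
  W <- Sr %*% m %*% Sc
  out <- stack
  for (ch in seq_len(dim(stack)[3])) {
    a <- stack[, , ch]
    a[!mask | is.na(a)] <- 0
    sm_a <- (Sr %*% (a * m) %*% Sc) / W
    sm_a[!mask] <- NA_real_
    out[, , ch] <- sm_a
  }
  if (was_matrix) out[, , 1] else out
}

# standardize rows to centered unit norm (zero rows for constant vectors)
row_standardize <- function(X) {
  Xc <- X - rowMeans(X)
  nrm <- sqrt(rowSums(Xc^2))
  nrm[nrm == 0] <- Inf
  Xc / nrm
}

#' Bisecting k-means under correlation distance
#'
#' Greedy top-down clustering: all points start in one segment; at each of
#' `k - 1` steps the segment with the largest within-segment sum of
#' correlation distances to its mean-vector centroid is split by 2-means
#' under correlation distance (ties broken by larger pixel count, then lower
#' label id). The first 2-means restart uses a deterministic farthest-point
#' initialization; further restarts use seeded random point pairs, and the
#' best split objective is kept. Deterministic given `seed`.
#'
#' @param features numeric matrix, one row per point (pixel), one column per
#'   spectral feature.
#' @param k number of segments requested (>= 2, <= number of points).
#' @param seed integer RNG seed for the restart initializations.
#' @param n_restarts 2-means initializations per split (default 5).
#' @param max_iter 2-means iteration cap (default 100).
#' @return list with `labels` (integer in `0..k_actual-1` per row), `k`
#'   requested, `k_actual` achieved, and `tree` (one row per split: step,
#'   label split, new label, sizes, scatter before, objective after). If no
#'   segment can be split further, stops early with a warning and
#'   `k_actual < k`.
#' @export
bisecting_kmeans <- function(features, k, seed = 1L, n_restarts = 5L,
                             max_iter = 100L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("k = ", k, " exceeds the number of points (", n, ")")
  Z <- row_standardize(features)
  if (any(rowSums(Z^2) == 0))
    message("bisecting_kmeans: ", sum(rowSums(Z^2) == 0),
            " zero-variance point(s) have distance 1 to every centroid")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  labels <- rep.int(0L, n)
  scatter <- c(`0` = .cluster_scatter(features, Z))
  tree <- list()
  next_label <- 1L

  farthest_init <- function(idx) {
    Xs <- features[idx, , drop = FALSE]
    zc <- colMeans(Xs); zc <- zc - mean(zc)
    nz <- sqrt(sum(zc^2)); if (nz > 0) zc <- zc / nz else zc <- zc * 0
    d_cent <- 1 - as.vector(Z[idx, , drop = FALSE] %*% zc)
    i1 <- which.max(d_cent)
    z1 <- Z[idx[i1], ]
    d1 <- 1 - as.vector(Z[idx, , drop = FALSE] %*% z1)
    i2 <- which.max(d1)
    if (i2 == i1) i2 <- if (i1 == 1L) 2L else 1L
    c(i1, i2)
  }

  while (next_label < k) {
    cur <- sort(unique(labels))
    sizes <- vapply(cur, function(l) sum(labels == l), integer(1))
    ord <- order(-scatter[as.character(cur)], -sizes, cur)
    candidates <- cur[ord]
    split_done <- FALSE
    for (lab in candidates) {
      idx <- which(labels == lab)
      if (length(idx) < 2L) next
      # a segment of identical points has no 2-partition structure
      if (nrow(unique(features[idx, , drop = FALSE])) < 2L) next
      inits <- matrix(0L, n_restarts, 2)
      inits[1, ] <- farthest_init(idx)
      if (n_restarts > 1)
        for (r in 2:n_restarts)
          inits[r, ] <- sample.int(length(idx), 2L)
      res <- .kmeans2_cor(features[idx, , drop = FALSE],
                          Z[idx, , drop = FALSE], inits, max_iter)
      if (!isTRUE(res$valid)) next
      sc_before <- unname(scatter[as.character(lab)])
      a <- as.integer(res$assign)
      i0 <- idx[a == 0L]; i1 <- idx[a == 1L]
      labels[i1] <- next_label
      scatter[as.character(lab)] <-
        .cluster_scatter(features[i0, , drop = FALSE], Z[i0, , drop = FALSE])
      scatter[as.character(next_label)] <-
        .cluster_scatter(features[i1, , drop = FALSE], Z[i1, , drop = FALSE])
      tree[[length(tree) + 1L]] <- data.frame(
        step = length(tree) + 1L, split_label = lab, new_label = next_label,
        size_0 = length(i0), size_1 = length(i1),
        scatter_before = sc_before,
        objective_after = res$objective)
      split_done <- TRUE
      next_label <- next_label + 1L
      break
    }
    if (!split_done) {
      warning("no segment splittable; stopping at k_actual = ", next_label)
      break
    }
  }
  tree <- if (length(tree)) do.call(rbind, tree) else
    data.frame(step = integer(), split_label = integer(),
               new_label = integer(), size_0 = integer(), size_1 = integer(),
               scatter_before = numeric(), objective_after = numeric())
  list(labels = labels, k = k, k_actual = next_label, tree = tree,
       seed = seed)
}

#' Segment an MSI dataset into spatial-spectral clusters
#'
#' End-to-end segmentation: TIC-normalize, bin spectra, weakly denoise the
#' binned channels on the pixel grid, then run [bisecting_kmeans()] on the
#' masked pixels.
#'
#' @param x an `msi_dataset` (raw; normalization happens internally).
#' @param k number of segments (default 6: three quantified tissue
#'   compartments plus lumen, vessel, and off-tissue background).
#' @param mask optional `tissue_mask` or logical matrix restricting which
#'   acquired pixels are clustered; default: all acquired pixels with
#'   nonzero TIC.
#' @param sigma_px denoising strength in pixels (default 1, "weak").
#' @param bin_width spectral bin width in Da (default 0.5).
#' @param seed,n_restarts passed to [bisecting_kmeans()].
#' @param tissue a `tissue_mask` (or `"auto"`, the default, for
#'   [compute_tissue_mask()] on the TIC image; `NULL` to disable): the
#'   denoising is applied separately inside and outside the tissue, so the
#'   smoothing cannot blend on- and off-tissue spectra across the section
#'   boundary into artificial intermediate classes.
#' @return A `segmentation_map`: integer `labels` grid (`-1` off-mask), the
#'   requested and achieved `k`, the bisection `tree`, and the `seed`.
#' @export
segment_msi <- function(x, k = 6L, mask = NULL, sigma_px = 1,
                        bin_width = 0.5, seed = 1L, n_restarts = 5L,
                        tissue = "auto") {
  dn <- suppressMessages(tic_normalize(x))
  bs <- bin_spectra(dn, bin_width)
  geom <- grid_geometry(x$coords)
  idx <- coords_to_idx(dn$coords, geom)
  acquired <- matrix(FALSE, geom$nrow, geom$ncol)
  acquired[idx] <- TRUE
  if (is.null(mask)) {
    mgrid <- acquired
  } else {
    mgrid <- (if (inherits(mask, "tissue_mask")) mask$grid else mask) &
      acquired
  }
  stack <- array(NA_real_, c(geom$nrow, geom$ncol, ncol(bs$features)))
  for (ch in seq_len(ncol(bs$features)))
    stack[, , ch][idx] <- bs$features[, ch]
  if (identical(tissue, "auto"))
    tissue <- tryCatch(compute_tissue_mask(tic_image(x)),
                       error = function(e) NULL)
  if (is.null(tissue)) {
    stack <- denoise_weak(stack, sigma_px, mask = mgrid)
  } else {
    tgrid <- (if (inherits(tissue, "tissue_mask")) tissue$grid else tissue)
    inner <- denoise_weak(stack, sigma_px, mask = mgrid & tgrid)
    outer <- denoise_weak(stack, sigma_px, mask = mgrid & !tgrid)
    sel <- array(rep(tgrid, dim(stack)[3]), dim(stack))
    stack <- ifelse(sel, inner, outer)
  }
  on_mask <- which(mgrid[idx])
  feats <- vapply(seq_len(dim(stack)[3]),
                  function(ch) stack[, , ch][idx[on_mask, , drop = FALSE]],
                  numeric(length(on_mask)))
  fit <- bisecting_kmeans(feats, k = k, seed = seed, n_restarts = n_restarts)
  labels <- matrix(-1L, geom$nrow, geom$ncol)
  labels[idx[on_mask, , drop = FALSE]] <- fit$labels
  structure(list(labels = labels, k = k, k_actual = fit$k_actual,
                 tree = fit$tree, seed = seed, geom = geom),
            class = "segmentation_map")
}

#' @export
print.segmentation_map <- function(x, ...) {
  cat("<segmentation_map> k = ", x$k_actual, " (requested ", x$k, "), ",
      sum(x$labels >= 0), " labelled pixels, seed ", x$seed, "\n", sep = "")
  tab <- table(x$labels[x$labels >= 0])
  cat("  segment sizes: ", paste(names(tab), tab, sep = ":",
                                 collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
plot.segmentation_map <- function(x, ...) {
  g <- x$labels
  g[g < 0] <- NA
  graphics::image(t(g[nrow(g):1, , drop = FALSE]),
                  col = grDevices::hcl.colors(max(g, na.rm = TRUE) + 1L,
                                              "Dark 3"),
                  axes = FALSE, useRaster = TRUE, main = "segmentation", ...)
  invisible(x)
}

# shape metric: (boundary pixel count)^2 / area; thin rings score high,
# filled disks low (~4*pi for a disk in the continuum limit)
segment_ring_score <- function(member_grid) {
  A <- sum(member_grid)
  if (A == 0) return(0)
  pad <- rbind(FALSE, cbind(FALSE, member_grid, FALSE), FALSE)
  nr <- nrow(pad); nc <- ncol(pad)
  core <- pad[2:(nr - 1), 2:(nc - 1)]
  nb_all <- pad[1:(nr - 2), 2:(nc - 1)] & pad[3:nr, 2:(nc - 1)] &
    pad[2:(nr - 1), 1:(nc - 2)] & pad[2:(nr - 1), 3:nc]
  B <- sum(core & !nb_all)
  B^2 / A
}

segments_adjacent <- function(labels, a, b) {
  ga <- labels == a; gb <- labels == b
  nr <- nrow(labels); nc <- ncol(labels)
  any(ga[-1, ] & gb[-nr, ]) || any(ga[-nr, ] & gb[-1, ]) ||
    any(ga[, -1] & gb[, -nc]) || any(ga[, -nc] & gb[, -1])
}

#' Map segments to named histological compartments
#'
#' Assigns compartment names to segments by marker enrichment: the segment
#' with the highest mean alveolar marker (PC(32:0)) becomes `alveolar`;
#' among the rest, the highest-mean bronchiolar marker (PC(36:4)) segment
#' that forms a thin ring-like structure (boundary^2/area above
#' `ring_threshold`) becomes `epithelium`; the segment adjacent to the
#' epithelium with the next-highest bronchiolar marker becomes
#' `sub_epithelium`; the highest vessel-marker (Heme b) segment becomes
#' `vessel`; the lowest-TIC segment becomes `lumen_or_background`; leftovers
#' are `unassigned`. The ring-shape criterion is only an epithelium
#' tie-break — assignment is marker-driven.
#'
#' @param seg a `segmentation_map` with `k_actual >= 3`.
#' @param marker_images named list of TIC-normalized `ion_image`s containing
#'   roles `marker_alveolar`, `marker_bronchiolar`, `marker_vessel`.
#' @param tic optional raw-TIC `ion_image` used for the lumen/background
#'   rule; defaults to the sum of the marker images.
#' @param ring_threshold boundary^2/area cut for "ring-like" (default 30; a
#'   filled disk scores about 12.6).
#' @return An `roi_set`: data frame `mapping` (label, compartment, n_pixels)
#'   plus the labels grid.
#' @export
segments_to_rois <- function(seg, marker_images, tic = NULL,
                             ring_threshold = 30) {
  stopifnot(inherits(seg, "segmentation_map"))
  if (seg$k_actual < 3)
    stop("targeting analysis needs >= 3 segments; got ", seg$k_actual)
  roles <- vapply(marker_images, function(im) im$analyte$role, character(1))
  need <- c("marker_alveolar", "marker_bronchiolar", "marker_vessel")
  if (!all(need %in% roles))
    stop("marker_images must include roles: ",
         paste(setdiff(need, roles), collapse = ", "))
  m_alv <- marker_images[[which(roles == "marker_alveolar")[1]]]$grid
  m_bro <- marker_images[[which(roles == "marker_bronchiolar")[1]]]$grid
  m_ves <- marker_images[[which(roles == "marker_vessel")[1]]]$grid
  g_tic <- if (is.null(tic)) {
    s <- m_alv; s[] <- 0
    for (im in marker_images) s <- s + ifelse(is.na(im$grid), 0, im$grid)
    s
  } else tic$grid

  labs <- sort(unique(seg$labels[seg$labels >= 0]))
  seg_mean <- function(img, lab)
    mean(img[seg$labels == lab], na.rm = TRUE)
  means <- data.frame(
    label = labs,
    alv = vapply(labs, function(l) seg_mean(m_alv, l), numeric(1)),
    bro = vapply(labs, function(l) seg_mean(m_bro, l), numeric(1)),
    ves = vapply(labs, function(l) seg_mean(m_ves, l), numeric(1)),
    tic = vapply(labs, function(l) seg_mean(g_tic, l), numeric(1)),
    n = vapply(labs, function(l) sum(seg$labels == l), numeric(1)),
    ring = vapply(labs, function(l) segment_ring_score(seg$labels == l),
                  numeric(1)))

  assigned <- character(0)
  comp <- setNames(rep("unassigned", length(labs)), labs)
  take <- function(lab, name) {
    comp[as.character(lab)] <<- name
    assigned <<- c(assigned, as.character(lab))
  }
  rem <- function() means[!(as.character(means$label) %in% assigned), ]

  r <- rem(); take(r$label[which.max(r$alv)], "alveolar")
  r <- rem(); r <- r[order(-r$bro), ]
  epi <- r$label[which(r$ring >= ring_threshold)[1]]
  if (is.na(epi)) epi <- r$label[1]
  take(epi, "epithelium")
  r <- rem()
  adj <- vapply(r$label, function(l) segments_adjacent(seg$labels, l, epi),
                logical(1))
  cand <- if (any(adj)) r[adj, ] else r
  take(cand$label[which.max(cand$bro)], "sub_epithelium")
  r <- rem()
  if (nrow(r)) take(r$label[which.max(r$ves)], "vessel")
  r <- rem()
  if (nrow(r)) take(r$label[which.min(r$tic)], "lumen_or_background")

  mapping <- data.frame(label = labs, compartment = unname(comp),
                        n_pixels = means$n)
  structure(list(mapping = mapping, labels = seg$labels,
                 marker_means = means),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set>\n")
  print(x$mapping, row.names = FALSE)
  invisible(x)
}

#' Logical pixel grid of one named compartment
#'
#' @param rois an `roi_set` (or a ground-truth label grid of compartment
#'   names).
#' @param compartment compartment name, e.g. `"alveolar"`.
#' @return logical matrix, `TRUE` on the compartment's pixels.
#' @export
roi_pixels <- function(rois, compartment) {
  if (inherits(rois, "roi_set")) {
    labs <- rois$mapping$label[rois$mapping$compartment == compartment]
    if (!length(labs)) stop("no segment mapped to compartment '",
                            compartment, "'")
    matrix(rois$labels %in% labs, nrow(rois$labels))
  } else {
    rois == compartment
  }
}
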