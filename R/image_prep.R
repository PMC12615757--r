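#' Select three cubic ROIs from a trabecular scan
#'
#' The scan is divided along its third (scan) axis into a top, a center and
#' a bottom slab of `side_mm` thickness; within each slab a cube of side
#' `side_mm` is selected, centered laterally at the slab's grey-value
#' center of mass and clipped so it lies inside the image. The top slab
#' starts at the first slice, the bottom slab ends at the last slice, and
#' the center slab is centered on mid-height.
#'
#' @param image A [grey_image()].
#' @param side_mm Cube side length in mm (default 5.3).
#' @return A list of three cubic [grey_image()] objects named `top`,
#'   `center`, `bottom`.
#' @export
select_rois <- function(image, side_mm = 5.3) {
  stopifnot(inherits(image, "grey_image"))
  d <- dim(image$values)
  side <- round(side_mm / image$spacing_mm)
  if (any(d < side))
    stop(sprintf("image (%s voxels) smaller than the %.3g mm ROI side (%d voxels)",
                 paste(d, collapse = "x"), side_mm, side))
  nz <- d[3]
  zc <- round((nz - side) / 2)
  slabs <- list(top = 1:side,
                center = (zc + 1):(zc + side),
                bottom = (nz - side + 1):nz)
  lapply(slabs, function(zr) {
    slab <- image$values[, , zr, drop = FALSE]
    w <- slab - min(slab)
    if (sum(w) == 0) w <- array(1, dim(slab))  # uniform slab: geometric center
    cx <- sum(slice.index(slab, 1) * w) / sum(w)
    cy <- sum(slice.index(slab, 2) * w) / sum(w)
    x0 <- min(max(round(cx - (side + 1) / 2) + 1, 1), d[1] - side + 1)
    y0 <- min(max(round(cy - (side + 1) / 2) + 1, 1), d[2] - side + 1)
    grey_image(image$values[x0:(x0 + side - 1), y0:(y0 + side - 1), zr],
               image$spacing_mm)
  })
}

#' Coarsen a grey-value image by block averaging
#'
#' Each output voxel is the arithmetic mean of a `factor`^3 block of input
#' voxels; trailing voxels that do not fill a complete block are cropped.
#' The voxel size is multiplied by `factor`. Coarsening precedes
#' segmentation in the preprocessing pipeline, mimicking a lower-resolution
#' (HR-pQCT-like) acquisition.
#'
#' @param image A [grey_image()].
#' @param factor Positive integer downsampling factor (default 4).
#' @return A coarsened [grey_image()].
#' @export
coarsen <- function(image, factor = 4L) {
  stopifnot(inherits(image, "grey_image"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be a positive integer")
  if (factor == 1L) return(image)
  d <- dim(image$values)
  nd <- d %/% factor
  if (any(nd < 1L)) stop("image smaller than one block")
  v <- image$values[1:(nd[1] * factor), 1:(nd[2] * factor), 1:(nd[3] * factor)]
  dim(v) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  out <- colMeans(aperm(v, c(1, 3, 5, 2, 4, 6)), dims = 3)
  grey_image(out, image$spacing_mm * factor)
}

#' Otsu threshold of a grey-value image
#'
#' Threshold maximizing the between-class variance of the grey-value
#' histogram (`n_bins` equal-width bins over the image's min-max range).
#' The returned threshold is the upper edge of the last bin assigned to the
#' lower class, so that segmentation with `values >= threshold` separates
#' the classes.
#'
#' @param image A [grey_image()].
#' @param n_bins Number of histogram bins (default 128).
#' @return Scalar threshold in image units.
#' @seealso [average_otsu_threshold()] for the dataset-level single cut.
#' @export
otsu_threshold <- function(image, n_bins = 128L) {
  stopifnot(inherits(image, "grey_image"))
  v <- as.vector(image$values)
  rng <- range(v)
  if (rng[1] == rng[2]) stop("constant image: no separable classes")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  centers <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)                       # class 0 = bins 1..t
  mu0 <- cumsum(p * centers)
  mu_t <- mu0[n_bins]
  w1 <- 1 - w0
  # between-class variance for split after bin t (t = 1..n_bins-1)
  t <- seq_len(n_bins - 1L)
  num <- (mu_t * w0[t] - mu0[t])^2
  den <- w0[t] * w1[t]
  bcv <- ifelse(den > 0, num / den, -Inf)
  best <- which.max(bcv)
  edges[best + 1L]
}

#' Dataset-level average Otsu threshold
#'
#' The single global cut applied to every scan: the unweighted arithmetic
#' mean of the per-scan Otsu thresholds.
#'
#' @param images List of [grey_image()] objects.
#' @param n_bins Bins for the per-scan histograms.
#' @return Scalar global threshold.
#' @export
average_otsu_threshold <- function(images, n_bins = 128L) {
  mean(vapply(images, otsu_threshold, numeric(1), n_bins = n_bins))
}

#' Segment a grey-value image with a single threshold
#'
#' Foreground (bone) is `values >= threshold`.
#'
#' @param image A [grey_image()].
#' @param threshold Finite scalar threshold.
#' @param source_id,position Optional labels carried into the ROI.
#' @return A [binary_roi()].
#' @export
segment <- function(image, threshold, source_id = NA_character_,
                    position = NA_character_) {
  stopifnot(inherits(image, "grey_image"))
  if (!is.finite(threshold)) stop("`threshold` must be finite")
  binary_roi(image$values >= threshold, image$spacing_mm,
             source_id = source_id, position = position)
}

#' Clean a segmented ROI
#'
#' Keeps only the largest 26-connected bone component and fills
#' 6-connected marrow pockets fully enclosed in bone, removing the
#' isolated islands produced by single-threshold segmentation.
#'
#' @param roi A [binary_roi()].
#' @return A cleaned [binary_roi()].
#' @export
clean_islands <- function(roi) {
  stopifnot(inherits(roi, "binary_roi"))
  if (!any(roi$mask)) stop("empty mask: nothing to clean")
  m <- cpp_largest_component(roi$mask, dim(roi$mask))
  m <- cpp_fill_enclosed_pores(m, dim(m))
  out <- roi
  out$mask <- array(m, dim(roi$mask))
  out
}

#' Preprocess a grey ROI into a clean binary ROI
#'
#' Applies the fixed pipeline order: coarsening, segmentation, cleaning.
#'
#' @param image Cubic [grey_image()] ROI.
#' @param threshold Global segmentation threshold (grey units, applied to
#'   the coarsened image); `NULL` uses the ROI's own Otsu threshold.
#' @param factor Coarsening factor.
#' @inheritParams segment
#' @return A [binary_roi()].
#' @export
prep_roi <- function(image, threshold = NULL, factor = 4L,
                     source_id = NA_character_, position = NA_character_) {
  co <- coarsen(image, factor)
  if (is.null(threshold)) threshold <- otsu_threshold(co)
  clean_islands(segment(co, threshold, source_id = source_id,
                        position = position))
}
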