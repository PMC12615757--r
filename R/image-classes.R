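#' Grey-value 3-D image
#'
#' Lightweight container for a 3-D scalar volume with isotropic voxel size,
#' the raw input of the preprocessing pipeline.
#'
#' @param values 3-D numeric array (arbitrary attenuation units).
#' @param spacing_mm Positive scalar, isotropic voxel size in mm.
#' @return An object of class `grey_image`.
#' @export
grey_image <- function(values, spacing_mm) {
  if (length(dim(values)) != 3L) stop("`values` must be a 3-D array")
  if (length(values) == 0L) stop("`values` must be non-empty")
  if (!all(is.finite(values))) stop("`values` must be finite")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0)
    stop("`spacing_mm` must be a positive scalar")
  structure(list(values = values, spacing_mm = as.numeric(spacing_mm)),
            class = "grey_image")
}

#' Binary region of interest
#'
#' A segmented cubic (or general box) trabecular region: a logical voxel
#' mask where `TRUE` marks bone.
#'
#' @param mask 3-D logical array, `TRUE` = bone.
#' @param spacing_mm Positive scalar voxel size in mm.
#' @param source_id Optional label of the originating scan/donor.
#' @param position Optional ROI position label (`"top"`, `"center"`,
#'   `"bottom"`).
#' @return An object of class `binary_roi`.
#' @export
binary_roi <- function(mask, spacing_mm, source_id = NA_character_,
                       position = NA_character_) {
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3-D array")
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("`mask` must not contain NA")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0)
    stop("`spacing_mm` must be a positive scalar")
  structure(list(mask = mask, spacing_mm = as.numeric(spacing_mm),
                 source_id = as.character(source_id),
                 position = as.character(position)),
            class = "binary_roi")
}

#' @export
print.grey_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<grey_image> %d x %d x %d voxels, %.4g mm/voxel, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$spacing_mm, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.binary_roi <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<binary_roi> %d x %d x %d voxels, %.4g mm/voxel, rho = %.3f\n",
              d[1], d[2], d[3], x$spacing_mm, mean(x$mask)))
  invisible(x)
}

is_cubic <- function(x) {
  d <- dim(if (inherits(x, "binary_roi")) x$mask else x$values)
  length(unique(d)) == 1L
}
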