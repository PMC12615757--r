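#' Bone volume fraction
#'
#' Fraction of voxels belonging to the bone phase (BV/TV).
#'
#' @param roi A [binary_roi()] (or logical array).
#' @return Scalar in \[0, 1\].
#' @export
bone_volume_fraction <- function(roi) {
  m <- if (inherits(roi, "binary_roi")) roi$mask else roi
  if (length(m) == 0L) stop("empty array")
  mean(m)
}

#' Local thickness of a phase (Hildebrand-Ruegsegger)
#'
#' Volume-weighted mean and SD of the local thickness map: for every voxel
#' of the phase, the diameter of the largest sphere that contains the voxel
#' and fits entirely within the phase. Used on the bone phase for Tb.Th and
#' on the marrow phase for Tb.Sp / Tb.Sp.SD.
#'
#' @param mask 3-D logical array selecting the phase of interest.
#' @param spacing_mm Voxel size in mm.
#' @return Named list with `mean` and `sd` (mm) and the thickness `map`
#'   (mm, 0 outside the phase).
#' @export
local_thickness <- function(mask, spacing_mm) {
  if (!any(mask)) stop("empty phase")
  if (all(mask)) stop("phase fills the image: thickness unbounded")
  th <- cpp_thickness_map(mask, dim(mask)) * spacing_mm
  v <- th[mask]
  list(mean = mean(v), sd = stats::sd(v), map = array(th, dim(mask)))
}

#' Trabecular number from the plate model
#'
#' Tb.N = 1 / (Tb.Th + Tb.Sp), in 1/mm.
#'
#' @param tb_th Trabecular thickness (mm).
#' @param tb_sp Trabecular spacing (mm).
#' @return Scalar (1/mm).
#' @export
trabecular_number <- function(tb_th, tb_sp) {
  if (!is.finite(tb_th) || !is.finite(tb_sp) || tb_th <= 0 || tb_sp <= 0)
    stop("thickness and spacing must be positive")
  1 / (tb_th + tb_sp)
}

#' Quasi-uniform directions on the half-sphere
#'
#' Fibonacci-lattice points on the unit sphere, folded to z >= 0, used as
#' MIL test directions.
#'
#' @param n Number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
halfsphere_directions <- function(n = 128L) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - i / n          # upper hemisphere only
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Mean-intercept-length fabric tensor
#'
#' Casts a parallel grid of test lines through the ROI along each of
#' `n_directions` quasi-uniform directions; the mean intercept length in a
#' direction is the total line length in bone divided by the number of
#' bone-void intersections. A second-order tensor H is fit by least squares
#' to \eqn{1/MIL(n)^2 = n \cdot H \cdot n}; the fabric tensor is
#' \eqn{M = H^{-1/2}}, eigenvalues sorted ascending and trace-normalized to
#' 3. The degree of anisotropy is DA = m3/m1.
#'
#' @param roi A [binary_roi()].
#' @param n_directions Number of test directions (>= 9; default 128).
#' @param line_spacing_vox Spacing of the test-line grid in voxels.
#' @param step_vox Sampling step along each line in voxels.
#' @return An object of class `fabric_tensor`: list with `matrix`,
#'   `values` (m1 <= m2 <= m3), `vectors` (columns matching `values`),
#'   `da`, `mil` (per-direction table), and `normalization`.
#' @export
mil_fabric <- function(roi, n_directions = 128L, line_spacing_vox = 1,
                       step_vox = 0.5) {
  stopifnot(inherits(roi, "binary_roi"))
  m <- roi$mask
  if (!any(m) || all(m)) stop("mask must contain both phases")
  if (n_directions < 9L) stop("need at least 9 directions for the tensor fit")
  dirs <- halfsphere_directions(n_directions)
  sc <- cpp_mil_scan(m, dim(m), dirs, step_vox, line_spacing_vox)
  keep <- sc[, 2] > 0
  if (sum(keep) < 6L) stop("fewer than 6 directions with intercepts")
  mil <- sc[keep, 1] / sc[keep, 2] * roi$spacing_mm
  dk <- dirs[keep, , drop = FALSE]
  # least-squares fit of the quadratic form 1/MIL^2 = n' H n
  X <- cbind(dk[, 1]^2, dk[, 2]^2, dk[, 3]^2,
             2 * dk[, 1] * dk[, 2], 2 * dk[, 1] * dk[, 3], 2 * dk[, 2] * dk[, 3])
  h <- stats::lsfit(X, 1 / mil^2, intercept = FALSE)$coefficients
  H <- matrix(c(h[1], h[4], h[5],
                h[4], h[2], h[6],
                h[5], h[6], h[3]), 3, 3)
  eh <- eigen(H, symmetric = TRUE)
  if (any(eh$values <= 0)) stop("MIL quadratic form not positive definite")
  vals <- 1 / sqrt(eh$values)          # M = H^(-1/2)
  ord <- order(vals)
  vals <- vals[ord]
  vecs <- eh$vectors[, ord, drop = FALSE]
  if (det(vecs) < 0) vecs[, 3] <- -vecs[, 3]
  vals_n <- vals * 3 / sum(vals)
  Mn <- vecs %*% diag(vals_n) %*% t(vecs)
  structure(list(matrix = Mn, values = vals_n, vectors = vecs,
                 da = vals_n[3] / vals_n[1],
                 mil = data.frame(dx = dk[, 1], dy = dk[, 2], dz = dk[, 3],
                                  mil_mm = mil),
                 normalization = "trace3"),
            class = "fabric_tensor")
}

#' Build a fabric tensor from eigenvalues and eigenvectors
#'
#' @param values Three positive eigenvalues (any order).
#' @param vectors 3 x 3 orthonormal eigenvector matrix (columns matching
#'   `values`); default identity.
#' @return A `fabric_tensor` (eigenvalues sorted ascending, trace 3).
#' @export
fabric_tensor <- function(values, vectors = diag(3)) {
  if (any(values <= 0)) stop("fabric eigenvalues must be positive")
  if (max(abs(crossprod(vectors) - diag(3))) > 1e-8)
    stop("eigenvectors must be orthonormal")
  ord <- order(values)
  values <- values[ord] * 3 / sum(values)
  vectors <- vectors[, ord, drop = FALSE]
  if (det(vectors) < 0) vectors[, 3] <- -vectors[, 3]
  structure(list(matrix = vectors %*% diag(values) %*% t(vectors),
                 values = values, vectors = vectors,
                 da = values[3] / values[1], mil = NULL,
                 normalization = "trace3"),
            class = "fabric_tensor")
}

#' @export
print.fabric_tensor <- function(x, ...) {
  cat(sprintf("<fabric_tensor> m = (%.3f, %.3f, %.3f), DA = %.3f\n",
              x$values[1], x$values[2], x$values[3], x$da))
  invisible(x)
}

#' Coefficient of variation of octant density
#'
#' The ROI is split into 8 cubic sub-volumes of identical size (odd
#' dimensions are cropped by one voxel); the CV is the population standard
#' deviation of the 8 octant bone volume fractions divided by their mean.
#' It gates the homogeneity (RVE) assumption of homogenization.
#'
#' @param roi A [binary_roi()].
#' @return Scalar CV (unitless, >= 0).
#' @export
coefficient_of_variation <- function(roi) {
  m <- if (inherits(roi, "binary_roi")) roi$mask else roi
  d <- dim(m) %/% 2L
  if (any(d < 1L)) stop("ROI too small to split into octants")
  rhos <- numeric(8)
  i <- 1L
  for (oz in 0:1) for (oy in 0:1) for (ox in 0:1) {
    rhos[i] <- mean(m[ox * d[1] + 1:d[1], oy * d[2] + 1:d[2], oz * d[3] + 1:d[3]])
    i <- i + 1L
  }
  mu <- mean(rhos)
  if (mu == 0) stop("empty octants: CV undefined")
  sqrt(mean((rhos - mu)^2)) / mu
}

#' Full morphometric profile of a binary ROI
#'
#' Computes the standard trabecular metrics and fabric in one call and
#' returns them as a one-row tibble, ready to be bound into a cohort table.
#'
#' @param roi A [binary_roi()].
#' @param n_directions MIL test directions.
#' @return One-row tibble with columns `source_id`, `position`, `rho`,
#'   `tb_n`, `tb_th`, `tb_sp`, `tb_sp_sd`, `da`, `cv`, `m1`, `m2`, `m3`
#'   and eigenvector components `evec_*`.
#' @export
morphometry <- function(roi, n_directions = 128L) {
  stopifnot(inherits(roi, "binary_roi"))
  rho <- bone_volume_fraction(roi)
  th <- local_thickness(roi$mask, roi$spacing_mm)
  sp <- local_thickness(!roi$mask, roi$spacing_mm)
  fab <- mil_fabric(roi, n_directions = n_directions)
  tibble::tibble(
    source_id = roi$source_id, position = roi$position,
    rho = rho,
    tb_th = th$mean, tb_sp = sp$mean, tb_sp_sd = sp$sd,
    tb_n = trabecular_number(th$mean, sp$mean),
    da = fab$da, cv = coefficient_of_variation(roi),
    m1 = fab$values[1], m2 = fab$values[2], m3 = fab$values[3],
    evec1_x = fab$vectors[1, 1], evec1_y = fab$vectors[2, 1], evec1_z = fab$vectors[3, 1],
    evec3_x = fab$vectors[1, 3], evec3_y = fab$vectors[2, 3], evec3_z = fab$vectors[3, 3])
}
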