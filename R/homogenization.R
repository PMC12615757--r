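#' Isotropic tissue material
#'
#' Elastic constants assigned to every bone voxel. The default is the
#' homogenization reference material for trabecular tissue: E = 10 GPa,
#' nu = 0.3.
#'
#' @param youngs_modulus Young's modulus in MPa (default 10000).
#' @param poisson_ratio Poisson's ratio (default 0.3).
#' @return An object of class `tissue_material`.
#' @export
tissue_material <- function(youngs_modulus = 10000, poisson_ratio = 0.3) {
  if (youngs_modulus <= 0) stop("Young's modulus must be positive")
  if (poisson_ratio <= -1 || poisson_ratio >= 0.5)
    stop("Poisson's ratio must lie in (-1, 0.5)")
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio),
            class = "tissue_material")
}

#' Stiffness tensor in Mandel notation
#'
#' A symmetric fourth-order elasticity tensor stored as a 6 x 6 matrix in
#' Mandel (normalized Voigt) notation, component order
#' (11, 22, 33, 23, 13, 12) with the sqrt(2) shear scaling, so the matrix
#' Frobenius norm equals the fourth-order tensor norm. `lambda(S, i, j)`
#' and `mu(S, i, j)` read the tensor components \eqn{S_{iijj}} and
#' \eqn{S_{ijij}}.
#'
#' @param mandel Symmetric 6 x 6 numeric matrix (MPa).
#' @param frame Frame tag, `"image"` or `"fabric"`.
#' @return An object of class `stiffness_tensor`.
#' @export
stiffness_tensor <- function(mandel, frame = c("image", "fabric")) {
  frame <- match.arg(frame)
  if (!is.matrix(mandel) || !all(dim(mandel) == c(6, 6)))
    stop("`mandel` must be a 6 x 6 matrix")
  if (max(abs(mandel - t(mandel))) > 1e-6 * max(1, max(abs(mandel))))
    stop("`mandel` must be symmetric")
  structure(list(mandel = (mandel + t(mandel)) / 2, frame = frame),
            class = "stiffness_tensor")
}

#' @export
print.stiffness_tensor <- function(x, ...) {
  cat(sprintf("<stiffness_tensor> frame = %s, Mandel 6x6 (MPa):\n", x$frame))
  print(round(x$mandel, 1))
  invisible(x)
}

shear_pairs <- cbind(c(2, 1, 1), c(3, 3, 2))  # Mandel rows 4..6 = (23, 13, 12)

#' @rdname stiffness_tensor
#' @param S A `stiffness_tensor`.
#' @param i,j Tensor indices in 1..3.
#' @export
lambda_ij <- function(S, i, j) S$mandel[i, j]

#' @rdname stiffness_tensor
#' @export
mu_ij <- function(S, i, j) {
  if (i == j) stop("mu is defined for i != j")
  a <- which(shear_pairs[, 1] == min(i, j) & shear_pairs[, 2] == max(i, j))
  S$mandel[3 + a, 3 + a] / 2
}

#' Element stiffness matrix of a voxel brick
#'
#' 24 x 24 stiffness matrix of a fully integrated (2x2x2 Gauss) linear
#' hexahedron of side `voxel_mm` with the given isotropic material. It is
#' identical for every bone voxel and precomputed once per solve.
#'
#' @param material A [tissue_material()].
#' @param voxel_mm Voxel side length in mm.
#' @return 24 x 24 numeric matrix (N/mm), dofs node-major (ux, uy, uz),
#'   nodes ordered x-fastest over the unit cube corners.
#' @export
hex8_element_stiffness <- function(material, voxel_mm) {
  stopifnot(inherits(material, "tissue_material"))
  cpp_hex8_ke(material$youngs_modulus, material$poisson_ratio, voxel_mm)
}

#' Apparent stiffness by KUBC voxel homogenization
#'
#' Solves six load cases (three uni-axial, three pure shear) on the voxel
#' mesh of the ROI's bone phase with kinematic uniform boundary conditions:
#' every node on an external face of the cube is prescribed the affine
#' displacement u = E x of the imposed apparent strain E. Interior
#' displacements are obtained with a matrix-free Jacobi-preconditioned
#' conjugate-gradient solver; the apparent stress is the volume average of
#' element stresses over the full cube (voids contribute zero). The six
#' stress columns assemble the apparent 6 x 6 Mandel matrix, symmetrized
#' as (S + t(S))/2.
#'
#' @param roi A [binary_roi()] whose bone phase spans the cube.
#' @param material A [tissue_material()].
#' @param solver_tol Relative residual tolerance of the CG solver.
#' @param max_iterations Iteration cap per load case.
#' @return A [stiffness_tensor()] in the image frame, with attributes
#'   `iterations` and `n_elements`.
#' @export
homogenize <- function(roi, material = tissue_material(),
                       solver_tol = 1e-6, max_iterations = 20000L) {
  stopifnot(inherits(roi, "binary_roi"), inherits(material, "tissue_material"))
  if (!any(roi$mask)) stop("empty structure: no bone voxels")
  m <- array(cpp_largest_component(roi$mask, dim(roi$mask)), dim(roi$mask))
  d <- dim(m)
  spans <- any(m[1, , ]) && any(m[d[1], , ]) && any(m[, 1, ]) &&
    any(m[, d[2], ]) && any(m[, , 1]) && any(m[, , d[3]])
  if (!spans)
    stop("singular system: largest bone component does not span the cube")
  res <- cpp_homogenize(m, d, roi$spacing_mm, material$youngs_modulus,
                        material$poisson_ratio, solver_tol,
                        as.integer(max_iterations))
  if (!all(res$converged))
    stop("CG did not converge within ", max_iterations, " iterations")
  S <- stiffness_tensor((res$mandel + t(res$mandel)) / 2, frame = "image")
  attr(S, "iterations") <- res$iterations
  attr(S, "n_elements") <- res$n_elements
  S
}

# 6x6 Mandel rotation matrix of a 3x3 rotation Q (basis-change rows)
mandel_rotation <- function(Q) {
  R <- matrix(0, 6, 6)
  s2 <- sqrt(2)
  for (a in 1:3) {
    for (b in 1:3) R[a, b] <- Q[a, b]^2
    for (b in 1:3) {
      p <- shear_pairs[b, 1]; q <- shear_pairs[b, 2]
      R[a, 3 + b] <- s2 * Q[a, p] * Q[a, q]
    }
  }
  for (a in 1:3) {
    i <- shear_pairs[a, 1]; j <- shear_pairs[a, 2]
    for (b in 1:3) R[3 + a, b] <- s2 * Q[i, b] * Q[j, b]
    for (b in 1:3) {
      p <- shear_pairs[b, 1]; q <- shear_pairs[b, 2]
      R[3 + a, 3 + b] <- Q[i, p] * Q[j, q] + Q[i, q] * Q[j, p]
    }
  }
  R
}

#' Express a stiffness tensor in the fabric frame
#'
#' Rotates the fourth-order tensor into the basis of the fabric
#' eigenvectors (ordered m1, m2, m3). The Frobenius norm is preserved
#' exactly in Mandel notation.
#'
#' @param S A [stiffness_tensor()] in the image frame.
#' @param fabric A `fabric_tensor`.
#' @return A [stiffness_tensor()] with `frame = "fabric"`.
#' @export
rotate_to_fabric <- function(S, fabric) {
  stopifnot(inherits(S, "stiffness_tensor"), inherits(fabric, "fabric_tensor"))
  V <- fabric$vectors
  if (max(abs(crossprod(V) - diag(3))) > 1e-8)
    stop("fabric eigenvectors are not orthonormal")
  R <- mandel_rotation(t(V))
  stiffness_tensor(R %*% S$mandel %*% t(R), frame = "fabric")
}

#' Orthotropic projection of a stiffness tensor
#'
#' In the fabric frame, keeps the 3 x 3 upper-left (lambda) block and the
#' three shear diagonal entries and zeroes all coupling terms — the 12
#' non-zero components of an orthotropic tensor (9 independent). Reports
#' the relative Frobenius norm of what was discarded.
#'
#' @param S A [stiffness_tensor()] with `frame = "fabric"`.
#' @return List with `S_ortho` (a [stiffness_tensor()]) and
#'   `rel_norm_error` = ||S - S_ortho||_F / ||S||_F.
#' @export
project_orthotropic <- function(S) {
  stopifnot(inherits(S, "stiffness_tensor"))
  if (!identical(S$frame, "fabric"))
    stop("projection requires a tensor in the fabric frame")
  M <- (S$mandel + t(S$mandel)) / 2
  P <- matrix(0, 6, 6)
  P[1:3, 1:3] <- M[1:3, 1:3]
  diag(P)[4:6] <- diag(M)[4:6]
  nS <- sqrt(sum(M^2))
  err <- if (nS > 0) sqrt(sum((M - P)^2)) / nS else 0
  list(S_ortho = stiffness_tensor(P, frame = "fabric"),
       rel_norm_error = err)
}

#' Engineering constants from a stiffness tensor
#'
#' Inverts the Mandel matrix to the compliance and reads the orthotropic
#' engineering constants: directional Young's moduli, Poisson's ratios and
#' shear moduli.
#'
#' @param S A [stiffness_tensor()].
#' @return Named list with `E` (length 3, MPa), `nu` (3 x 3 matrix,
#'   `nu[i, j]` = -eps_j/eps_i under uniaxial stress i), `G` (length 3,
#'   MPa, order G23, G13, G12).
#' @export
engineering_constants <- function(S) {
  stopifnot(inherits(S, "stiffness_tensor"))
  N <- solve(S$mandel)
  E <- 1 / diag(N)[1:3]
  nu <- matrix(NA_real_, 3, 3)
  for (i in 1:3) for (j in 1:3) if (i != j) nu[i, j] <- -N[j, i] / N[i, i]
  G <- 1 / (2 * diag(N)[4:6])
  list(E = E, nu = nu, G = G)
}

#' Closed-form isotropic stiffness tensor
#'
#' Mandel 6 x 6 matrix of an isotropic material, used as the oracle for
#' the solid-cube homogenization and in the Young's modulus curve.
#'
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio.
#' @param frame Frame tag.
#' @return A [stiffness_tensor()].
#' @export
isotropic_stiffness <- function(E, nu, frame = "image") {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  M <- matrix(lam, 3, 3)
  diag(M) <- lam + 2 * mu
  out <- matrix(0, 6, 6)
  out[1:3, 1:3] <- M
  diag(out)[4:6] <- 2 * mu
  stiffness_tensor(out, frame = frame)
}
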