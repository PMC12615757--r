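# Deterministic phantoms and small random structures used across tests.

solid_cube_roi <- function(n = 16, spacing = 0.0592) {
  binary_roi(array(TRUE, c(n, n, n)), spacing)
}

# parallel plates normal to z: `on` bone layers out of every `period`
plate_phantom <- function(n = 41, on = 3, period = 8, spacing = 0.06) {
  m <- array(FALSE, c(n, n, n))
  z <- slice.index(m, 3)
  m[(z - 1) %% period < on] <- TRUE
  binary_roi(m, spacing)
}

# simple-cubic lattice of orthogonal square rods (cubic symmetry)
rod_lattice_roi <- function(n = 18, rod = 3, period = 6, spacing = 0.06) {
  i <- slice.index(array(0, c(n, n, n)), 1) - 1
  j <- slice.index(array(0, c(n, n, n)), 2) - 1
  k <- slice.index(array(0, c(n, n, n)), 3) - 1
  on <- function(a) a %% period < rod
  m <- (on(i) & on(j)) | (on(j) & on(k)) | (on(i) & on(k))
  binary_roi(m, spacing)
}

# small spanning porous structure from the generator
porous_roi <- function(n = 16, rho = 0.5, seed = 5, spacing = 0.06) {
  generate_structure(structure_spec(
    size_voxels = n, spacing_mm = spacing, rho_target = rho,
    corr_lengths_mm = rep(2.2 * spacing, 3), seed = seed))
}

expect_tensor_equal <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b)), tol)
}
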