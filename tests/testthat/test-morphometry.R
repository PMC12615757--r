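test_that("bone volume fraction counts voxels", {
  expect_equal(bone_volume_fraction(solid_cube_roi(4)), 1)
  expect_equal(bone_volume_fraction(binary_roi(array(FALSE, c(4, 4, 4)), 1,
                                               source_id = "x")$mask), 0)
  half <- array(FALSE, c(4, 4, 4)); half[1:2, , ] <- TRUE
  expect_equal(bone_volume_fraction(binary_roi(half, 1)), 0.5)
  set.seed(7)
  m <- array(runif(6^3) < 0.3, c(6, 6, 6))
  expect_equal(bone_volume_fraction(binary_roi(m, 1)), sum(m) / length(m))
})

test_that("local thickness matches analytic phantoms", {
  # full-width slab of 5 layers: thickness = 5 * spacing everywhere
  m <- array(FALSE, c(15, 15, 15))
  m[, , 6:10] <- TRUE
  th <- local_thickness(m, 0.1)
  expect_equal(th$mean, 0.5)
  expect_equal(th$sd, 0)

  # single-voxel phase: one voxel diameter
  s <- array(FALSE, c(7, 7, 7)); s[4, 4, 4] <- TRUE
  expect_equal(local_thickness(s, 0.1)$mean, 0.1)

  # solid cylinder of diameter 9 voxels: thickness within one voxel of 9
  n <- 15
  cy <- array(FALSE, c(n, n, n))
  for (i in 1:n) for (j in 1:n)
    if ((i - 8)^2 + (j - 8)^2 <= 4.5^2) cy[i, j, ] <- TRUE
  tc <- local_thickness(cy, 1)
  expect_lt(abs(max(tc$map) - 9), 1)

  expect_error(local_thickness(array(FALSE, c(3, 3, 3)), 1), "empty")
  expect_error(local_thickness(array(TRUE, c(3, 3, 3)), 1), "fills")
})

test_that("local thickness equals the brute-force inscribed-sphere oracle", {
  set.seed(11)
  for (rep in 1:3) {
    m <- array(runif(12^3) < 0.45, c(12, 12, 12))
    if (!any(m) || all(m)) next
    th <- local_thickness(m, 1)
    expect_equal(th$map, oracle_thickness(m), tolerance = 1e-12)
  }
})

test_that("trabecular number follows the plate model", {
  expect_equal(trabecular_number(0.5, 0.5), 1)
  expect_equal(trabecular_number(0.30, 0.66), 1 / 0.96, tolerance = 1e-12)
  # consistency with reported medians: 1/(0.31 + 0.68) ~ 1.01
  expect_equal(round(trabecular_number(0.31, 0.68), 2), 1.01)
  expect_error(trabecular_number(0, 0.5), "positive")
  expect_error(trabecular_number(0.5, -1), "positive")
})

test_that("MIL fabric identifies plate orientation and satisfies invariants", {
  roi <- plate_phantom(n = 41, on = 3, period = 8)
  fab <- mil_fabric(roi, n_directions = 64)
  # plates normal to z: smallest MIL (smallest eigenvalue) along z
  expect_gt(abs(fab$vectors[3, 1]), 0.99)
  expect_gte(fab$da, 1)
  expect_equal(sum(fab$values), 3, tolerance = 1e-12)
  expect_true(all(diff(fab$values) >= 0))
  # right-handed orthonormal eigenvectors
  expect_equal(crossprod(fab$vectors), diag(3), tolerance = 1e-10)
  expect_equal(det(fab$vectors), 1, tolerance = 1e-10)
})

test_that("MIL intercept counts match a direct line walk on plate phantoms", {
  roi <- plate_phantom(n = 21, on = 2, period = 5)
  for (axis in 1:3) {
    dir <- rbind(c(axis == 1, axis == 2, axis == 3) * 1)
    sc <- fabelast:::cpp_mil_scan(roi$mask, dim(roi$mask), dir,
                                  step = 0.5, line_spacing = 1)
    orc <- oracle_axis_intercepts(roi$mask, axis)
    expect_equal(sc[1, 2], orc$intercepts)
    # two samples per voxel at step 0.5: length equals the voxel count
    expect_equal(sc[1, 1], orc$bone, tolerance = 0.02 * orc$bone)
  }
})

test_that("MIL fabric is rotation-consistent on axis-aligned phantoms", {
  roi <- plate_phantom(n = 31, on = 3, period = 8)
  fab_z <- mil_fabric(roi, n_directions = 64)
  # rotate structure 90 degrees: plates now normal to x
  roi_x <- binary_roi(aperm(roi$mask, c(3, 2, 1)), roi$spacing_mm)
  fab_x <- mil_fabric(roi_x, n_directions = 64)
  expect_gt(abs(fab_x$vectors[1, 1]), 0.99)
  expect_equal(fab_x$values, fab_z$values, tolerance = 0.02)
})

test_that("isotropic random structures have near-unit DA", {
  st <- generate_structure(structure_spec(size_voxels = 48, rho_target = 0.35,
                                          seed = 17))
  fab <- mil_fabric(st)
  expect_gte(fab$da, 1)
  expect_lt(fab$da, 1.1)
})

test_that("octant CV follows the population-SD definition", {
  # octants with rho {0.2 x4, 0.4 x4}: CV = 0.1/0.3
  n <- 10  # octant side 5: 0.2 and 0.4 are exact voxel counts (25, 50 of 125)
  m <- array(FALSE, c(n, n, n))
  h <- n / 2
  oct <- 0
  for (oz in 0:1) for (oy in 0:1) for (ox in 0:1) {
    oct <- oct + 1
    rho <- if (oct <= 4) 0.2 else 0.4
    block <- array(FALSE, c(h, h, h))
    block[seq_len(round(rho * h^3))] <- TRUE
    m[ox * h + 1:h, oy * h + 1:h, oz * h + 1:h] <- block
  }
  expect_equal(coefficient_of_variation(binary_roi(m, 1)), 1 / 3,
               tolerance = 1e-12)

  # homogeneous periodic lattice: CV ~ 0
  expect_lt(coefficient_of_variation(rod_lattice_roi(n = 24, rod = 3, period = 6)),
            0.02)

  # scale invariance on an exact block phantom
  m2 <- m[rep(1:n, each = 2), rep(1:n, each = 2), rep(1:n, each = 2)]
  expect_equal(coefficient_of_variation(binary_roi(m2, 0.5)),
               coefficient_of_variation(binary_roi(m, 1)), tolerance = 1e-12)

  expect_error(coefficient_of_variation(binary_roi(array(FALSE, c(4, 4, 4)), 1)),
               "empty|undefined")
})

test_that("morphometry returns a complete one-row profile", {
  roi <- porous_roi(n = 24, rho = 0.4, seed = 3)
  row <- morphometry(roi, n_directions = 32)
  expect_s3_class(row, "tbl_df")
  expect_equal(nrow(row), 1L)
  expect_true(all(c("rho", "tb_n", "tb_th", "tb_sp", "tb_sp_sd", "da", "cv",
                    "m1", "m2", "m3") %in% names(row)))
  expect_equal(row$rho, mean(roi$mask))
  expect_equal(row$tb_n, 1 / (row$tb_th + row$tb_sp))
  expect_equal(row$m1 + row$m2 + row$m3, 3, tolerance = 1e-10)
  expect_gte(row$da, 1)
})
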