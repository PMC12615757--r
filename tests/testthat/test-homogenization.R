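test_that("hex8 element stiffness has the right nullspace, rank and scaling", {
  mat <- tissue_material(10000, 0.3)
  Ke <- hex8_element_stiffness(mat, 0.0592)
  expect_equal(Ke, t(Ke), tolerance = 1e-12)

  # rigid translations produce zero force
  for (c in 1:3) {
    u <- rep(0, 24); u[seq(c, 24, by = 3)] <- 1
    expect_lt(max(abs(Ke %*% u)), 1e-9 * max(abs(Ke)))
  }
  # positive semidefinite with exactly 6 rigid modes (rank 18)
  ev <- eigen(Ke, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-9 * max(ev))
  expect_equal(sum(ev < 1e-9 * max(ev)), 6L)

  # linear in voxel size and in tissue modulus
  expect_equal(hex8_element_stiffness(mat, 2 * 0.0592), 2 * Ke, tolerance = 1e-12)
  expect_equal(hex8_element_stiffness(tissue_material(20000, 0.3), 0.0592),
               2 * Ke, tolerance = 1e-12)
})

test_that("a solid cube recovers the tissue law exactly under KUBC", {
  S <- homogenize(solid_cube_roi(16))
  expect_equal(S$frame, "image")
  # uniform-strain fields are exact: apparent = tissue stiffness
  expect_tensor_equal(S$mandel, isotropic_stiffness(10000, 0.3)$mandel, 1e-6)
  ec <- engineering_constants(S)
  expect_equal(ec$E, rep(10000, 3), tolerance = 1e-9)
  expect_equal(ec$nu[1, 2], 0.3, tolerance = 1e-9)
  expect_equal(ec$G, rep(10000 / 2.6, 3), tolerance = 1e-9)
})

test_that("homogenize matches a dense direct solve on a porous structure", {
  roi <- porous_roi(n = 12, rho = 0.5, seed = 5)
  S <- homogenize(roi)
  Sd <- oracle_homogenize_dense(roi)
  expect_lt(norm(S$mandel - Sd, "F") / norm(Sd, "F"), 1e-5)
  # apparent stiffness is symmetric positive definite
  expect_equal(S$mandel, t(S$mandel), tolerance = 1e-8)
  expect_gt(min(eigen(S$mandel, symmetric = TRUE)$values), 0)
})

test_that("homogenize rejects empty and non-spanning structures", {
  expect_error(homogenize(binary_roi(array(FALSE, c(8, 8, 8)), 0.06)), "empty")
  blob <- array(FALSE, c(10, 10, 10))
  blob[4:6, 4:6, 4:6] <- TRUE  # interior island, no boundary contact
  expect_error(homogenize(binary_roi(blob, 0.06)), "span")
})

test_that("removing material never increases the apparent stiffness (KUBC bound)", {
  # nested deterministic lattices: thinner rods are a strict subset
  roi_big <- rod_lattice_roi(n = 12, rod = 3, period = 6)
  roi_small <- rod_lattice_roi(n = 12, rod = 2, period = 6)
  expect_true(all(roi_big$mask[roi_small$mask]))
  S_big <- homogenize(roi_big)$mandel
  S_small <- homogenize(roi_small)$mandel
  ev <- eigen((S_big + t(S_big)) / 2 - (S_small + t(S_small)) / 2,
              symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-4 * max(abs(S_big)))
})

test_that("apparent stiffness scales linearly in tissue modulus", {
  roi <- porous_roi(n = 10, rho = 0.55, seed = 4)
  S1 <- homogenize(roi, tissue_material(10000, 0.3))$mandel
  S2 <- homogenize(roi, tissue_material(25000, 0.3))$mandel
  expect_equal(S2, 2.5 * S1, tolerance = 1e-5)
})

test_that("a cubic-symmetry lattice yields a cubic apparent tensor", {
  S <- homogenize(rod_lattice_roi(n = 18, rod = 3, period = 6))$mandel
  lam <- diag(S)[1:3]
  mu <- diag(S)[4:6] / 2
  expect_lt(max(lam) - min(lam), 1e-3 * max(lam))
  expect_lt(max(mu) - min(mu), 1e-3 * max(mu))
})

test_that("rotation to the fabric frame preserves the tensor norm", {
  iso <- isotropic_stiffness(10000, 0.3)
  fab <- fabric_tensor(c(0.8, 1.0, 1.2),
                       qr.Q(qr(matrix(c(1, 2, 3, 0, 1, 4, 5, 6, 0), 3, 3))))
  rot <- rotate_to_fabric(iso, fab)
  expect_equal(rot$frame, "fabric")
  # isotropic tensor invariant under any rotation
  expect_tensor_equal(rot$mandel, iso$mandel, 1e-8)

  # random SPD tensor: Frobenius norm preserved
  set.seed(8)
  A <- matrix(rnorm(36), 6, 6)
  Sr <- stiffness_tensor(crossprod(A) * 1000, frame = "image")
  rot2 <- rotate_to_fabric(Sr, fab)
  expect_equal(norm(rot2$mandel, "F"), norm(Sr$mandel, "F"), tolerance = 1e-10)

  # identity basis leaves the matrix unchanged
  fab_id <- fabric_tensor(c(0.9, 1.0, 1.1), diag(3))
  expect_tensor_equal(rotate_to_fabric(Sr, fab_id)$mandel, Sr$mandel, 1e-10)
})

test_that("orthotropic projection keeps 12 components and is orthogonal", {
  set.seed(9)
  A <- matrix(rnorm(36), 6, 6)
  S <- stiffness_tensor(crossprod(A) * 1000, frame = "fabric")
  pr <- project_orthotropic(S)
  M <- pr$S_ortho$mandel
  # 12 non-zero components in the fourth-order accounting:
  # 3 diagonal lambdas + 6 off-diagonal lambdas + 3 shear moduli
  expect_equal(sum(M[1:3, 1:3] != 0), 9L)
  expect_equal(sum(diag(M)[4:6] != 0), 3L)
  expect_equal(sum(M != 0), 12L)

  # idempotence: projecting an orthotropic tensor changes nothing
  pr2 <- project_orthotropic(pr$S_ortho)
  expect_equal(pr2$rel_norm_error, 0)
  expect_tensor_equal(pr2$S_ortho$mandel, M, 1e-12)

  # orthogonality: the discarded part is Frobenius-orthogonal to the kept part
  expect_lt(abs(sum((S$mandel - M) * M)), 1e-8 * sum(M^2))

  # single small coupling: error equals the hand-computed ratio
  M1 <- isotropic_stiffness(10000, 0.3, frame = "fabric")$mandel
  c <- 150
  M1[1, 4] <- M1[4, 1] <- c
  Sc <- stiffness_tensor(M1, frame = "fabric")
  prc <- project_orthotropic(Sc)
  expect_equal(prc$rel_norm_error, sqrt(2 * c^2) / norm(M1, "F"),
               tolerance = 1e-12)

  # projection requires the fabric frame
  expect_error(project_orthotropic(stiffness_tensor(M1, frame = "image")),
               "fabric")
})
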