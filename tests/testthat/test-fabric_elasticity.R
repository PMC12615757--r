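truth <- zc_reference_params()

test_that("zc_predict obeys the isotropy limit, power law and direct arithmetic", {
  # isotropic fabric at full density: lambda*, lambda0', mu0 on the nose
  S <- zc_predict(truth, 1, c(1, 1, 1))
  expect_equal(diag(S$mandel)[1:3], rep(truth$lambda0 + 2 * truth$mu0, 3))
  expect_equal(S$mandel[1, 2], truth$lambda0p)
  expect_equal(diag(S$mandel)[4:6], rep(2 * truth$mu0, 3))

  # doubling rho multiplies every component by 2^k
  S1 <- zc_predict(truth, 0.2, c(0.9, 1.0, 1.1))$mandel
  S2 <- zc_predict(truth, 0.4, c(0.9, 1.0, 1.1))$mandel
  expect_equal(S2, 2^truth$k * S1, tolerance = 1e-12)

  # hand-computed powers at rho 0.3, m = (0.9, 1.0, 1.1)
  m <- c(0.9, 1.0, 1.1)
  S3 <- zc_predict(truth, 0.3, m)$mandel
  rk <- 0.3^1.7
  expect_equal(S3[1, 1], (3959 + 2 * 3413) * rk * 0.9^1.3)
  expect_equal(S3[2, 3], 3253 * rk * (1.0 * 1.1)^0.65)
  expect_equal(S3[4, 4], 2 * 3413 * rk * (1.0 * 1.1)^0.65)

  expect_error(zc_predict(truth, 0, c(1, 1, 1)), "rho")
  expect_error(zc_predict(truth, 0.3, c(-1, 1, 1)), "positive")
})

test_that("the regression design has the printed 12-row structure", {
  d <- generate_zc_dataset(1, truth = truth, sigma = 0, seed = 1)
  ds <- build_design(d)
  expect_equal(dim(ds$X), c(12L, 5L))
  # indicator pattern: rows 1, 5, 9 are the diagonal lambdas; 10-12 the mus
  expect_equal(ds$X[, "d_lam_star"], as.numeric(seq_len(12) %in% c(1, 5, 9)))
  expect_equal(ds$X[, "d_mu"], as.numeric(seq_len(12) %in% 10:12))
  expect_equal(ds$X[, "d_lam_p"],
               as.numeric(!seq_len(12) %in% c(1, 5, 9, 10:12)))
  expect_equal(ds$X[, "ln_rho"], rep(log(d$rho), 12))
  # fabric column: ln(mi mj) in the printed row order
  m <- c(d$m1, d$m2, d$m3)
  ii <- c(1, 1, 1, 2, 2, 2, 3, 3, 3, 2, 3, 1)
  jj <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 3, 1, 2)
  expect_equal(ds$X[, "ln_fab"], log(m[ii] * m[jj]))

  # isotropic fabric zeroes the fabric column
  d_iso <- d
  d_iso$m1 <- d_iso$m2 <- d_iso$m3 <- 1
  expect_equal(build_design(d_iso)$X[, "ln_fab"], rep(0, 12))

  # two identical ROIs duplicate the row blocks
  ds2 <- build_design(dplyr::bind_rows(d, d))
  expect_equal(ds2$X[1:12, ], ds2$X[13:24, ])
  expect_equal(ds2$roi, rep(1:2, each = 12))
})

test_that("noise-free tensors are recovered exactly (identifiability oracle)", {
  for (seed in c(2, 31)) {
    d <- generate_zc_dataset(15, truth = truth, sigma = 0, seed = seed)
    f <- fit_zc(d)
    expect_equal(f$params$lambda0, truth$lambda0, tolerance = 1e-8)
    expect_equal(f$params$lambda0p, truth$lambda0p, tolerance = 1e-8)
    expect_equal(f$params$mu0, truth$mu0, tolerance = 1e-8)
    expect_equal(f$params$k, truth$k, tolerance = 1e-10)
    expect_equal(f$params$l, truth$l, tolerance = 1e-10)
    expect_equal(f$r2adj, 1, tolerance = 1e-10)
    expect_equal(f$ne, 0, tolerance = 1e-8)
  }
  # arbitrary other truth recovers too
  other <- zc_params(2000, 1500, 1800, k = 2.1, l = 0.9)
  d2 <- generate_zc_dataset(10, truth = other, sigma = 0, seed = 5)
  f2 <- fit_zc(d2)
  expect_equal(f2$params$k, 2.1, tolerance = 1e-10)
  expect_equal(f2$params$lambda0, 2000, tolerance = 1e-6)
})

test_that("the restricted fit reproduces the free fit when constants match", {
  d <- generate_zc_dataset(25, truth = truth, sigma = 0.05, seed = 7)
  free <- fit_zc(d)
  restr <- fit_zc(d, fixed = free$params)
  expect_equal(restr$params$k, free$params$k, tolerance = 1e-10)
  expect_equal(restr$params$l, free$params$l, tolerance = 1e-10)
  expect_equal(restr$type, "restricted")
  expect_equal(nrow(restr$ci95), 2L)
  # noise-free degenerate CI: zero width, no failure
  d0 <- generate_zc_dataset(10, truth = truth, sigma = 0, seed = 8)
  f0 <- fit_zc(d0, fixed = truth)
  expect_equal(f0$ci95$conf.low, f0$ci95$conf.high, tolerance = 1e-8)
})

test_that("Monte-Carlo recovery at moderate noise stays within a few percent", {
  d <- generate_zc_dataset(200, truth = truth, sigma = 0.05, seed = 11)
  f <- fit_zc(d)
  expect_lt(abs(f$params$lambda0 - truth$lambda0) / truth$lambda0, 0.02)
  expect_lt(abs(f$params$lambda0p - truth$lambda0p) / truth$lambda0p, 0.02)
  expect_lt(abs(f$params$mu0 - truth$mu0) / truth$mu0, 0.02)
  expect_lt(abs(f$params$k - truth$k) / truth$k, 0.02)
  expect_lt(abs(f$params$l - truth$l) / truth$l, 0.05)
  # residual scatter reflects the generating noise (NE ~ sigma within 30%)
  expect_lt(abs(f$ne - 0.05) / 0.05, 0.3)
})

test_that("fit quality is invariant to ROI relabeling and common rescaling", {
  d <- generate_zc_dataset(40, truth = truth, sigma = 0.08, seed = 13)
  f <- fit_zc(d)
  # relabel/permute ROIs
  f_perm <- fit_zc(d[rev(seq_len(nrow(d))), ])
  expect_equal(f_perm$r2adj, f$r2adj, tolerance = 1e-12)
  expect_equal(f_perm$ne, f$ne, tolerance = 1e-12)
  # multiply all stiffness columns by a common positive factor and refit
  d2 <- d
  comp <- c("lam11", "lam22", "lam33", "lam23", "lam13", "lam12",
            "mu23", "mu31", "mu12")
  d2[comp] <- d2[comp] * 2.5
  f2 <- fit_zc(d2)
  expect_equal(f2$ne, f$ne, tolerance = 1e-10)
  expect_equal(f2$r2adj, f$r2adj, tolerance = 1e-6)
  expect_equal(f2$params$k, f$params$k, tolerance = 1e-10)
})

test_that("confidence intervals shrink like 1/sqrt(n)", {
  w <- vapply(c(50, 200), function(n) {
    f <- fit_zc(generate_zc_dataset(n, truth = truth, sigma = 0.05, seed = 21),
                fixed = truth)
    diff(range(f$ci95[f$ci95$term == "k", c("conf.low", "conf.high")]))
  }, numeric(1))
  expect_equal(w[1] / w[2], 2, tolerance = 0.35)
})

test_that("degenerate fabric spread breaks identifiability of l", {
  d <- generate_zc_dataset(10, truth = truth, sigma = 0,
                           da_range = c(1, 1), seed = 3)
  expect_error(fit_zc(d), "rank-deficient")
})

test_that("the Young's modulus curve follows the density power law", {
  # tissue-consistent constants: E(1) = 10 GPa at nu = 0.3
  E0 <- 10000; nu0 <- 0.3
  lam <- E0 * nu0 / ((1 + nu0) * (1 - 2 * nu0))
  mu <- E0 / (2 * (1 + nu0))
  p <- zc_params(lam, lam, mu, k = 1.7, l = 0.65)
  cur <- youngs_modulus_curve(p, rho_grid = c(0.1, 0.3, 0.5, 1))
  expect_equal(cur$E_MPa[4], 10000, tolerance = 1e-9)
  # exact power law in rho for isotropic fabric
  expect_equal(cur$E_MPa, 10000 * cur$rho^1.7, tolerance = 1e-9)

  # a 1% difference in k gives ~1% curves over the trabecular range
  p2 <- zc_params(lam, lam, mu, k = 1.7 * 1.01, l = 0.65)
  c1 <- youngs_modulus_curve(p, rho_grid = seq(0.1, 0.5, 0.05))
  c2 <- youngs_modulus_curve(p2, rho_grid = seq(0.1, 0.5, 0.05))
  expect_lt(max(abs(c2$E_MPa / c1$E_MPa - 1)), 0.045)
})

test_that("tidy and glance expose the fit in broom form", {
  d <- generate_zc_dataset(30, truth = truth, sigma = 0.05, seed = 17)
  f <- fit_zc(d)
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("lambda_star", "lambda0p", "mu0", "k", "l"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  g <- glance(f)
  expect_equal(g$n_obs, 30L * 12L)
  expect_true(g$r2adj > 0.9 && g$r2adj <= 1)
})
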