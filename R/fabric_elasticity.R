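#' Zysset-Curnier model parameters
#'
#' The fabric-elasticity law expresses the orthotropic stiffness in the
#' fabric frame through three stiffness constants and two exponents:
#' \deqn{\lambda_{ii} = (\lambda_0 + 2\mu_0)\,\rho^k m_i^{2l},\quad
#'       \lambda_{ij} = \lambda_0'\,\rho^k (m_i m_j)^l,\quad
#'       \mu_{ij} = \mu_0\,\rho^k (m_i m_j)^l.}
#'
#' @param lambda0,lambda0p,mu0 Stiffness constants (MPa), all positive.
#' @param k Exponent on bone volume fraction (> 0).
#' @param l Exponent on the fabric eigenvalues (>= 0).
#' @return An object of class `zc_params` with derived
#'   `lambda_star = lambda0 + 2 mu0`.
#' @export
zc_params <- function(lambda0, lambda0p, mu0, k, l) {
  if (any(c(lambda0, lambda0p, mu0) <= 0)) stop("stiffness constants must be positive")
  if (k <= 0) stop("k must be positive")
  if (l < 0) stop("l must be non-negative")
  structure(list(lambda0 = lambda0, lambda0p = lambda0p, mu0 = mu0,
                 k = k, l = l, lambda_star = lambda0 + 2 * mu0),
            class = "zc_params")
}

#' @export
print.zc_params <- function(x, ...) {
  cat(sprintf(
    "<zc_params> lambda0 = %.4g, lambda0' = %.4g, mu0 = %.4g MPa; k = %.4g, l = %.4g\n",
    x$lambda0, x$lambda0p, x$mu0, x$k, x$l))
  invisible(x)
}

zc_component_names <- c("lam11", "lam22", "lam33", "lam23", "lam13", "lam12",
                        "mu23", "mu31", "mu12")

#' Predict an orthotropic stiffness tensor from the Zysset-Curnier model
#'
#' @param params A [zc_params()].
#' @param rho Bone volume fraction in (0, 1].
#' @param m Three positive fabric eigenvalues (trace-normalized to 3).
#' @return A [stiffness_tensor()] in the fabric frame.
#' @export
zc_predict <- function(params, rho, m) {
  stopifnot(inherits(params, "zc_params"))
  if (rho <= 0 || rho > 1) stop("rho must lie in (0, 1]")
  if (length(m) != 3L || any(m <= 0)) stop("m must be three positive eigenvalues")
  rk <- rho^params$k
  M <- matrix(0, 6, 6)
  for (i in 1:3) for (j in 1:3) {
    M[i, j] <- if (i == j) params$lambda_star * rk * m[i]^(2 * params$l)
               else params$lambda0p * rk * (m[i] * m[j])^params$l
  }
  for (a in 1:3) {
    i <- shear_pairs[a, 1]; j <- shear_pairs[a, 2]
    M[3 + a, 3 + a] <- 2 * params$mu0 * rk * (m[i] * m[j])^params$l
  }
  stiffness_tensor(M, frame = "fabric")
}

#' Extract the 12 orthotropic components of a fabric-frame tensor
#'
#' @param S A [stiffness_tensor()] in the fabric frame (orthotropic or
#'   projected).
#' @return One-row tibble with columns `lam11 ... lam12, mu23, mu31, mu12`
#'   (MPa; off-diagonal lambdas from the symmetrized matrix).
#' @export
stiffness_components <- function(S) {
  stopifnot(inherits(S, "stiffness_tensor"))
  M <- (S$mandel + t(S$mandel)) / 2
  tibble::tibble(lam11 = M[1, 1], lam22 = M[2, 2], lam33 = M[3, 3],
                 lam23 = M[2, 3], lam13 = M[1, 3], lam12 = M[1, 2],
                 mu23 = M[4, 4] / 2, mu31 = M[5, 5] / 2, mu12 = M[6, 6] / 2)
}

components_to_mandel <- function(row) {
  M <- matrix(0, 6, 6)
  M[1:3, 1:3] <- matrix(c(row$lam11, row$lam12, row$lam13,
                          row$lam12, row$lam22, row$lam23,
                          row$lam13, row$lam23, row$lam33), 3, 3)
  diag(M)[4:6] <- 2 * c(row$mu23, row$mu31, row$mu12)
  M
}

#' Build the log-space regression system
#'
#' Each ROI contributes 12 rows: the logs of
#' \eqn{\lambda_{11}, \lambda_{12}, \lambda_{13}, \lambda_{21},
#' \lambda_{22}, \lambda_{23}, \lambda_{31}, \lambda_{32}, \lambda_{33},
#' \mu_{23}, \mu_{31}, \mu_{12}} (both \eqn{\lambda_{ij}} and
#' \eqn{\lambda_{ji}} of the symmetrized tensor enter as separate rows).
#' The design has five columns: indicator columns for the three log
#' intercepts (\eqn{\ln\lambda^*}, \eqn{\ln\lambda_0'}, \eqn{\ln\mu_0}),
#' \eqn{\ln\rho}, and the fabric log term (\eqn{\ln m_i^2} on diagonal
#' rows, \eqn{\ln m_i m_j} elsewhere).
#'
#' @param data Tibble with columns `rho`, `m1`, `m2`, `m3` and the 9
#'   component columns of [stiffness_components()]; one row per ROI.
#' @return List with `y` (response vector), `X` (n x 5 design matrix with
#'   columns `d_lam_star`, `d_lam_p`, `d_mu`, `ln_rho`, `ln_fab`), and
#'   `roi` (ROI index per row). Rows with non-positive components are
#'   dropped with a warning.
#' @export
build_design <- function(data) {
  need <- c("rho", "m1", "m2", "m3", zc_component_names)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(data)
  # per-ROI row template: component, (i, j) in the lambda/mu accounting
  comp <- c("lam11", "lam12", "lam13", "lam12", "lam22", "lam23",
            "lam13", "lam23", "lam33", "mu23", "mu31", "mu12")
  ii <- c(1, 1, 1, 2, 2, 2, 3, 3, 3, 2, 3, 1)
  jj <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 3, 1, 2)
  kind <- c("diag", "off", "off", "off", "diag", "off",
            "off", "off", "diag", "mu", "mu", "mu")
  y <- numeric(0); X <- NULL; roi <- integer(0); kept <- character(0)
  rows <- vector("list", n)
  for (r in seq_len(n)) {
    m <- c(data$m1[r], data$m2[r], data$m3[r])
    vals <- unlist(data[r, comp], use.names = FALSE)
    ok <- vals > 0
    if (!all(ok))
      warning(sprintf("ROI %d: %d non-positive stiffness component(s) dropped",
                      r, sum(!ok)))
    fab <- log(m[ii] * m[jj])
    Xr <- cbind(d_lam_star = as.numeric(kind == "diag"),
                d_lam_p = as.numeric(kind == "off"),
                d_mu = as.numeric(kind == "mu"),
                ln_rho = rep(log(data$rho[r]), 12),
                ln_fab = fab)
    y <- c(y, log(vals[ok]))
    X <- rbind(X, Xr[ok, , drop = FALSE])
    roi <- c(roi, rep.int(r, sum(ok)))
  }
  list(y = y, X = X, roi = roi)
}

zc_norm_error <- function(data, params, aggregate = c("mean", "pooled")) {
  aggregate <- match.arg(aggregate)
  diffs <- obs <- numeric(nrow(data))
  for (r in seq_len(nrow(data))) {
    Mobs <- components_to_mandel(data[r, ])
    Mfit <- zc_predict(params, data$rho[r],
                       c(data$m1[r], data$m2[r], data$m3[r]))$mandel
    diffs[r] <- sum((Mfit - Mobs)^2)
    obs[r] <- sum(Mobs^2)
  }
  if (aggregate == "mean") mean(sqrt(diffs / obs)) else sqrt(sum(diffs) / sum(obs))
}

#' Fit the Zysset-Curnier model by log-space multiple linear regression
#'
#' Ordinary least squares on the 12-rows-per-ROI log system built by
#' [build_design()]. The free fit estimates the three log intercepts and
#' the two exponents; exponentiating the intercepts yields
#' \eqn{\lambda^*}, \eqn{\lambda_0'} and \eqn{\mu_0}, with
#' \eqn{\lambda_0 = \lambda^* - 2\mu_0}. The restricted fit fixes the
#' three stiffness constants (shifting the responses by the known log
#' intercepts) and estimates only the exponents k and l, enabling
#' exponent comparison between groups under a common tissue law.
#'
#' Fit quality: `r2adj` is the squared Pearson correlation between
#' observed and fitted log responses, adjusted for the number of fitted
#' columns; `ne` is the mean over ROIs of the relative Frobenius norm
#' error of the predicted fourth-order tensor.
#'
#' @param data Tibble with columns `rho`, `m1`, `m2`, `m3` and the 9
#'   stiffness component columns (one row per ROI).
#' @param fixed `NULL` for the free five-parameter fit, or a [zc_params()]
#'   (or list with `lambda0`, `lambda0p`, `mu0`) whose stiffness constants
#'   are imposed.
#' @param conf_level Confidence level for parameter intervals.
#' @param ne_aggregate `"mean"` (default) or `"pooled"` norm-error
#'   aggregation.
#' @param cluster_se If `TRUE`, confidence intervals use cluster-robust
#'   (by ROI) standard errors instead of OLS normal theory.
#' @return An object of class `zc_fit`: `params` ([zc_params()]), `ci95`
#'   (tibble of intervals), `r2adj`, `ne`, `n_obs`, `n_roi`, `type`, and
#'   the underlying `lm` fit as `model`.
#' @export
fit_zc <- function(data, fixed = NULL, conf_level = 0.95,
                   ne_aggregate = c("mean", "pooled"), cluster_se = FALSE) {
  if (nrow(data) < 3L) stop("need at least 3 ROIs")
  ds <- build_design(data)
  restricted <- !is.null(fixed)
  if (restricted) {
    lam_star <- fixed$lambda0 + 2 * fixed$mu0
    if (any(c(fixed$lambda0p, fixed$mu0) <= 0) || lam_star <= 0)
      stop("fixed constants must be positive")
    shift <- ds$X[, 1] * log(lam_star) + ds$X[, 2] * log(fixed$lambda0p) +
      ds$X[, 3] * log(fixed$mu0)
    df <- data.frame(y = ds$y - shift, ds$X[, c("ln_rho", "ln_fab")])
    fit <- lm(y ~ 0 + ln_rho + ln_fab, data = df)
  } else {
    df <- data.frame(y = ds$y, ds$X)
    fit <- lm(y ~ 0 + d_lam_star + d_lam_p + d_mu + ln_rho + ln_fab, data = df)
    if (any(is.na(coef(fit)))) stop("rank-deficient design: parameters not identifiable")
  }
  if (any(is.na(coef(fit))))
    stop("rank-deficient design: parameters not identifiable")
  b <- coef(fit)
  vc <- suppressWarnings(  # noise-free data: summary.lm warns on perfect fit
    if (cluster_se) sandwich::vcovCL(fit, cluster = ds$roi) else stats::vcov(fit))
  se <- sqrt(pmax(diag(vc), 0))
  tq <- qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
  lo <- b - tq * se
  hi <- b + tq * se

  if (restricted) {
    params <- structure(list(lambda0 = fixed$lambda0, lambda0p = fixed$lambda0p,
                             mu0 = fixed$mu0, k = b[["ln_rho"]], l = b[["ln_fab"]],
                             lambda_star = lam_star),
                        class = "zc_params")
    ci <- tibble::tibble(
      term = c("k", "l"),
      estimate = c(b[["ln_rho"]], b[["ln_fab"]]),
      conf.low = c(lo[["ln_rho"]], lo[["ln_fab"]]),
      conf.high = c(hi[["ln_rho"]], hi[["ln_fab"]]))
    p <- 2L
  } else {
    lam_star <- exp(b[["d_lam_star"]])
    lam0p <- exp(b[["d_lam_p"]])
    mu0 <- exp(b[["d_mu"]])
    lam0 <- lam_star - 2 * mu0
    if (lam0 <= 0)
      warning("lambda* - 2 mu0 <= 0: lambda0 is not a valid stiffness constant")
    params <- structure(list(lambda0 = lam0, lambda0p = lam0p, mu0 = mu0,
                             k = b[["ln_rho"]], l = b[["ln_fab"]],
                             lambda_star = lam_star),
                        class = "zc_params")
    ci <- tibble::tibble(
      term = c("lambda_star", "lambda0p", "mu0", "k", "l"),
      estimate = c(lam_star, lam0p, mu0, b[["ln_rho"]], b[["ln_fab"]]),
      conf.low = c(exp(lo[["d_lam_star"]]), exp(lo[["d_lam_p"]]), exp(lo[["d_mu"]]),
                   lo[["ln_rho"]], lo[["ln_fab"]]),
      conf.high = c(exp(hi[["d_lam_star"]]), exp(hi[["d_lam_p"]]), exp(hi[["d_mu"]]),
                    hi[["ln_rho"]], hi[["ln_fab"]]))
    p <- 5L
  }
  yhat <- stats::fitted(fit)
  r2 <- if (stats::sd(df$y) == 0 || stats::sd(yhat) == 0) 1 else cor(df$y, yhat)^2
  n <- length(df$y)
  r2adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  ne <- zc_norm_error(data, params, ne_aggregate)
  structure(list(params = params, ci95 = ci, r2adj = r2adj, ne = ne,
                 n_obs = n, n_roi = nrow(data),
                 type = if (restricted) "restricted" else "free",
                 conf_level = conf_level, model = fit,
                 observed = df$y, fitted = yhat, roi = ds$roi),
            class = "zc_fit")
}

#' @export
print.zc_fit <- function(x, ...) {
  cat(sprintf("<zc_fit> %s fit, %d ROIs (%d log-rows)\n", x$type, x$n_roi, x$n_obs))
  print(x$params)
  cat(sprintf("  R2adj = %.4f, NE = %.4f\n", x$r2adj, x$ne))
  invisible(x)
}

#' @export
tidy.zc_fit <- function(x, ...) x$ci95

#' @export
glance.zc_fit <- function(x, ...) {
  tibble::tibble(r2adj = x$r2adj, ne = x$ne, n_obs = x$n_obs,
                 n_roi = x$n_roi, type = x$type)
}

#' Young's modulus versus bone volume fraction
#'
#' Evaluates the model's isotropic-fabric Young's modulus
#' (m = (1, 1, 1)) over a grid of bone volume fractions by inverting the
#' predicted tensor to engineering constants; with isotropic fabric
#' \eqn{E(\rho) = E(1)\,\rho^k} exactly.
#'
#' @param params A [zc_params()].
#' @param rho_grid Vector of bone volume fractions in (0, 1].
#' @return Tibble with columns `rho` and `E_MPa`.
#' @export
youngs_modulus_curve <- function(params, rho_grid = seq(0.1, 0.5, by = 0.01)) {
  stopifnot(inherits(params, "zc_params"))
  E <- vapply(rho_grid, function(r)
    engineering_constants(zc_predict(params, r, c(1, 1, 1)))$E[1], numeric(1))
  tibble::tibble(rho = rho_grid, E_MPa = E)
}
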