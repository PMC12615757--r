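#' Specification of a synthetic trabecular structure
#'
#' Parameters of the Gaussian-random-field structure generator:
#' anisotropic correlation lengths control the fabric (and hence DA), a
#' linear density gradient controls the octant CV, and the threshold is
#' placed at the exact quantile matching the target bone volume fraction.
#'
#' @param size_voxels Integer triple (or scalar) of volume dimensions.
#' @param spacing_mm Voxel size in mm (default 0.0592, an HR-pQCT-like
#'   resolution).
#' @param rho_target Target bone volume fraction in (0.05, 0.95).
#' @param corr_lengths_mm Three correlation lengths in mm (>= 2 voxels).
#' @param gradient_strength Linear density gradient along z, in units of
#'   the field SD (0 = homogeneous).
#' @param seed Integer seed.
#' @return An object of class `structure_spec`.
#' @export
structure_spec <- function(size_voxels = c(90, 90, 90), spacing_mm = 0.0592,
                           rho_target = 0.35,
                           corr_lengths_mm = rep(4 * spacing_mm, 3),
                           gradient_strength = 0, seed = 1L) {
  if (length(size_voxels) == 1L) size_voxels <- rep(size_voxels, 3L)
  size_voxels <- as.integer(size_voxels)
  if (any(size_voxels < 8L)) stop("volume must be at least 8 voxels per side")
  if (rho_target <= 0.05 || rho_target >= 0.95)
    stop("rho_target must lie in (0.05, 0.95)")
  if (any(corr_lengths_mm < 2 * spacing_mm))
    stop("correlation lengths must be at least 2 voxels")
  if (gradient_strength < 0) stop("gradient_strength must be >= 0")
  structure(list(size_voxels = size_voxels, spacing_mm = spacing_mm,
                 rho_target = rho_target, corr_lengths_mm = corr_lengths_mm,
                 gradient_strength = gradient_strength, seed = as.integer(seed)),
            class = "structure_spec")
}

#' Generate a trabecular-like binary structure
#'
#' Thresholded anisotropic Gaussian random field: white noise is smoothed
#' with per-axis correlation lengths (periodic FFT convolution), an
#' optional linear z-gradient is added, and the field is thresholded at
#' the exact quantile yielding the target bone volume fraction. The mask
#' is then cleaned (largest component, enclosed pores filled); if the
#' cleaned structure does not span the cube the generator retries with a
#' shifted seed.
#'
#' @param spec A [structure_spec()].
#' @param max_retries Seed retries if cleaning breaks spanning
#'   connectivity.
#' @return A [binary_roi()] with attribute `rho_raw` (pre-cleaning bone
#'   volume fraction).
#' @export
generate_structure <- function(spec, max_retries = 5L) {
  stopifnot(inherits(spec, "structure_spec"))
  d <- spec$size_voxels
  sig <- spec$corr_lengths_mm / spec$spacing_mm
  for (attempt in 0:max_retries) {
    field <- withr::with_seed(spec$seed + 100003L * attempt, {
      noise <- array(rnorm(prod(d)), dim = d)
      sm <- gauss_smooth_fft3(noise, sig)
      sm <- (sm - mean(sm)) / stats::sd(sm)
      if (spec$gradient_strength > 0) {
        z <- (slice.index(sm, 3) - 1) / (d[3] - 1) - 0.5
        sm <- sm + spec$gradient_strength * z
      }
      sm
    })
    n_fg <- round(length(field) * spec$rho_target)
    ord <- order(field, decreasing = TRUE)
    mask <- array(FALSE, dim = d)
    mask[ord[seq_len(n_fg)]] <- TRUE
    rho_raw <- mean(mask)
    cleaned <- array(cpp_fill_enclosed_pores(
      cpp_largest_component(mask, d), d), dim = d)
    spans <- any(cleaned[1, , ]) && any(cleaned[d[1], , ]) &&
      any(cleaned[, 1, ]) && any(cleaned[, d[2], ]) &&
      any(cleaned[, , 1]) && any(cleaned[, , d[3]])
    if (spans) {
      roi <- binary_roi(cleaned, spec$spacing_mm,
                        source_id = sprintf("synthetic-seed%d", spec$seed))
      attr(roi, "rho_raw") <- rho_raw
      return(roi)
    }
  }
  stop("could not generate a spanning structure in ", max_retries + 1, " attempts")
}

# FFT Gaussian smoothing with per-axis sigma (voxels), periodic boundaries
gauss_smooth_fft3 <- function(x, sigma_vox) {
  d <- dim(x)
  k1 <- lapply(1:3, function(ax) {
    i <- 0:(d[ax] - 1)
    di <- pmin(i, d[ax] - i)
    k <- exp(-0.5 * (di / sigma_vox[ax])^2)
    k / sum(k)
  })
  kern <- outer(outer(k1[[1]], k1[[2]]), k1[[3]])
  dim(kern) <- d
  Re(fft(fft(x) * fft(kern), inverse = TRUE)) / length(x)
}

#' Fabric eigenvalues for a target degree of anisotropy
#'
#' Minimal one-parameter family m = (1 - a, 1, 1 + a) (trace 3) with
#' a solved from DA = m3/m1.
#'
#' @param da Target degree of anisotropy (>= 1).
#' @return Sorted eigenvalue triple with trace 3.
#' @export
fabric_from_da <- function(da) {
  if (da < 1) stop("DA must be >= 1")
  a <- (da - 1) / (da + 1)
  c(1 - a, 1, 1 + a)
}

#' Generate a synthetic Zysset-Curnier stiffness dataset
#'
#' Draws bone volume fractions and degrees of anisotropy uniformly,
#' builds noise-free model tensors from the ground-truth parameters, and
#' perturbs each tensor entry with multiplicative lognormal noise before
#' re-symmetrizing — the standard fixture for parameter-recovery studies
#' of the log-space regression.
#'
#' @param n Number of ROIs.
#' @param truth Ground-truth [zc_params()].
#' @param rho_range,da_range Uniform sampling ranges.
#' @param sigma Lognormal sdlog of the component noise (0 = noise-free).
#' @param seed Integer seed.
#' @return Tibble with one row per ROI: `rho`, `da`, `m1`, `m2`, `m3` and
#'   the 9 stiffness component columns.
#' @export
generate_zc_dataset <- function(n, truth = zc_reference_params(),
                                rho_range = c(0.15, 0.5),
                                da_range = c(1.2, 2.2),
                                sigma = 0.05, seed = 1L) {
  stopifnot(inherits(truth, "zc_params"), sigma >= 0)
  withr::with_seed(as.integer(seed), {
    rho <- runif(n, rho_range[1], rho_range[2])
    da <- runif(n, da_range[1], da_range[2])
    rows <- purrr::map_dfr(seq_len(n), function(i) {
      m <- fabric_from_da(da[i])
      S <- zc_predict(truth, rho[i], m)$mandel
      if (sigma > 0) {
        Nz <- matrix(1, 6, 6)
        Nz[1:3, 1:3] <- matrix(rlnorm(9, 0, sigma), 3, 3)
        diag(Nz)[4:6] <- rlnorm(3, 0, sigma)
        S <- S * Nz
        S <- (S + t(S)) / 2
      }
      dplyr::bind_cols(
        tibble::tibble(roi = i, rho = rho[i], da = da[i],
                       m1 = m[1], m2 = m[2], m3 = m[3]),
        stiffness_components(stiffness_tensor(S, frame = "fabric")))
    })
    rows
  })
}

#' Reference Zysset-Curnier parameters
#'
#' The pooled-fit constants and exponents used as the default ground
#' truth of the synthetic generators: lambda0 = 3959, lambda0' = 3253,
#' mu0 = 3413 MPa, k = 1.7, l = 0.65.
#'
#' @return A [zc_params()].
#' @export
zc_reference_params <- function() {
  zc_params(lambda0 = 3959, lambda0p = 3253, mu0 = 3413, k = 1.7, l = 0.65)
}

#' Specification of a synthetic two-group cohort
#'
#' Emulates the study design: two groups of donors contributing three
#' cubic ROIs each, with morphometric distributions in the ranges of
#' femoral-head trabecular bone and stiffness tensors generated from the
#' Zysset-Curnier model with multiplicative noise. Group effects default
#' to zero (a null cohort).
#'
#' @param n_donors Donors per group (default 28).
#' @param rois_per_donor ROIs per donor (default 3).
#' @param effect_rho,effect_da Additive shifts of the second group's
#'   means (default 0 = null).
#' @param sigma Lognormal component noise of the stiffness tensors.
#' @param truth Ground-truth [zc_params()].
#' @param donor_sd_rho,donor_sd_da Between-donor SDs (default 0:
#'   exchangeable ROIs; positive values induce within-donor correlation).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_donors = 28L, rois_per_donor = 3L,
                        effect_rho = 0, effect_da = 0, sigma = 0.05,
                        truth = zc_reference_params(),
                        donor_sd_rho = 0, donor_sd_da = 0, seed = 1L) {
  if (n_donors < 2L) stop("need at least 2 donors per group")
  if (sigma < 0) stop("sigma must be >= 0")
  if (abs(seed) >= 2^31 / 10)
    stop("seed too large: derived group streams must stay below 2^31")
  structure(list(n_donors = as.integer(n_donors),
                 rois_per_donor = as.integer(rois_per_donor),
                 effect_rho = effect_rho, effect_da = effect_da,
                 sigma = sigma, truth = truth,
                 donor_sd_rho = donor_sd_rho, donor_sd_da = donor_sd_da,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic two-group cohort table
#'
#' Draws per-ROI morphometry (rho, Tb metrics, DA, CV) from distributions
#' centered on femoral-head trabecular values, with the second group's
#' rho/DA means shifted by the requested group effects, and attaches
#' Zysset-Curnier stiffness components with lognormal noise. The tails of
#' the rho and CV distributions deliberately produce occasional ROIs
#' beyond the rho < 0.5 and CV < 0.263 filters so every filter branch is
#' exercised.
#'
#' @param spec A [cohort_spec()].
#' @param groups Group labels.
#' @param stiffness If `FALSE`, skip the stiffness components (a
#'   morphometry-only cohort, e.g. for test-calibration loops).
#' @return Tibble with donor/ROI identifiers, `group`, morphometric
#'   columns, fabric eigenvalues, the 9 stiffness components, and the
#'   orthotropy relative norm error `ortho_ne`.
#' @export
generate_cohort <- function(spec = cohort_spec(), groups = c("Ctrl", "T2D"),
                            stiffness = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  # separate seed streams per group and per block so that the morphometry
  # draws are unchanged when the stiffness block is switched off
  per_group <- function(gidx, glab, eff_rho, eff_da) {
    nd <- spec$n_donors; nr <- spec$rois_per_donor
    n <- nd * nr
    donor <- rep(seq_len(nd), each = nr)
    morpho <- withr::with_seed(10L * spec$seed + gidx, {
      d_rho <- rep(rnorm(nd, 0, spec$donor_sd_rho), each = nr)
      d_da <- rep(rnorm(nd, 0, spec$donor_sd_da), each = nr)
      rho <- pmin(pmax(0.36 + eff_rho + d_rho + rnorm(n, 0, 0.07), 0.08), 0.93)
      da <- pmax(1.68 + eff_da + d_da + rnorm(n, 0, 0.20), 1.02)
      tibble::tibble(
        donor = sprintf("%s-%02d", glab, donor),
        position = rep(c("top", "center", "bottom"), length.out = n),
        group = glab, rho = rho,
        tb_th = pmax(rnorm(n, 0.31, 0.04), 0.12),
        tb_sp = pmax(rnorm(n, 0.68, 0.11), 0.2),
        tb_sp_sd = pmax(rnorm(n, 0.075, 0.015), 0.02),
        da = da, cv = rlnorm(n, log(0.07), 0.65),
        m1 = vapply(da, function(x) fabric_from_da(x)[1], numeric(1)),
        m2 = 1,
        m3 = vapply(da, function(x) fabric_from_da(x)[3], numeric(1)),
        ortho_ne = rlnorm(n, log(0.06), 0.3))
    })
    morpho$tb_n <- 1 / (morpho$tb_th + morpho$tb_sp)
    if (!stiffness) return(morpho)
    rows <- withr::with_seed(10L * spec$seed + 4L + gidx, {
      purrr::map_dfr(seq_len(n), function(i) {
        m <- fabric_from_da(morpho$da[i])
        S <- zc_predict(spec$truth, morpho$rho[i], m)$mandel
        if (spec$sigma > 0) {
          Nz <- matrix(1, 6, 6)
          Nz[1:3, 1:3] <- matrix(rlnorm(9, 0, spec$sigma), 3, 3)
          diag(Nz)[4:6] <- rlnorm(3, 0, spec$sigma)
          S <- (S * Nz + t(S * Nz)) / 2
        }
        stiffness_components(stiffness_tensor(S, frame = "fabric"))
      })
    })
    dplyr::bind_cols(morpho, rows)
  }
  dplyr::bind_rows(per_group(1L, groups[1], 0, 0),
                   per_group(2L, groups[2], spec$effect_rho, spec$effect_da))
}
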