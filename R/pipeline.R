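#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the defaults of
#' the reference protocol: 5.3 mm cubic ROIs, coarsening factor 4, tissue
#' E = 10 GPa and nu = 0.3, rho < 0.5 and CV < 0.263 filters, matching on
#' (rho, DA).
#'
#' @param side_mm ROI side length (mm).
#' @param coarsen_factor Block-averaging factor before segmentation.
#' @param threshold Segmentation threshold policy: `"auto"` (dataset
#'   average Otsu) or a numeric grey value.
#' @param material A [tissue_material()].
#' @param solver_tol Micro-FE CG relative tolerance.
#' @param rho_max,cv_max Filter thresholds.
#' @param match_variables Matching variables.
#' @param n_directions MIL directions.
#' @param seed Seed recorded with every output.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(side_mm = 5.3, coarsen_factor = 4L,
                            threshold = "auto",
                            material = tissue_material(10000, 0.3),
                            solver_tol = 1e-6, rho_max = 0.5,
                            cv_max = 0.263,
                            match_variables = c("rho", "da"),
                            n_directions = 128L, seed = 1L) {
  structure(list(side_mm = side_mm, coarsen_factor = as.integer(coarsen_factor),
                 threshold = threshold, material = material,
                 solver_tol = solver_tol, rho_max = rho_max, cv_max = cv_max,
                 match_variables = match_variables,
                 n_directions = as.integer(n_directions),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# FNV-1a hash of the deparsed config, recorded in output metadata so
# reruns are attributable to an exact configuration
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config[setdiff(names(config), "material")]),
                           collapse = ""))
  bytes <- c(bytes, round(1e6 * c(config$material$youngs_modulus,
                                  config$material$poisson_ratio)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Process one binary ROI through morphometry and mechanics
#'
#' Morphometry (including fabric), KUBC homogenization, rotation into the
#' fabric frame and orthotropic projection, returned as one cohort-table
#' row.
#'
#' @param roi A cleaned [binary_roi()].
#' @param config A [pipeline_config()].
#' @return One-row tibble: morphometry columns, the 9 orthotropic
#'   stiffness components, and `ortho_ne`.
#' @export
process_roi <- function(roi, config = pipeline_config()) {
  morpho <- morphometry(roi, n_directions = config$n_directions)
  S <- homogenize(roi, config$material, solver_tol = config$solver_tol)
  fab <- mil_fabric(roi, n_directions = config$n_directions)
  Sf <- rotate_to_fabric(S, fab)
  pr <- project_orthotropic(Sf)
  dplyr::bind_cols(morpho, stiffness_components(pr$S_ortho),
                   tibble::tibble(ortho_ne = pr$rel_norm_error))
}

#' Three-step Zysset-Curnier regression
#'
#' The group-comparison protocol: (1) free fit with both groups pooled,
#' (2) free fit per group (fit-quality comparison), (3) restricted fit
#' per group with the stiffness constants imposed from step 1 (exponent
#' comparison).
#'
#' @param data Cohort tibble (matched mechanical subset) with a `group`
#'   column and the regression columns of [build_design()].
#' @param groups The two group labels.
#' @return List with `pooled` (zc_fit), `free` (named list of per-group
#'   zc_fit), `restricted` (named list of per-group zc_fit).
#' @export
three_step_fit <- function(data, groups = sort(unique(data$group))) {
  pooled <- fit_zc(data)
  free <- lapply(groups, function(g) fit_zc(data[data$group == g, ]))
  restricted <- lapply(groups, function(g)
    fit_zc(data[data$group == g, ], fixed = pooled$params))
  names(free) <- names(restricted) <- groups
  list(pooled = pooled, free = free, restricted = restricted)
}

#' Run the full cohort analysis
#'
#' Executes the group-comparison stages on a cohort table (either from
#' [generate_cohort()] or assembled from [process_roi()] rows): filtering,
#' morphological comparison, orthotropy-error t-test, (rho, DA) matching,
#' and the three-step fabric-elasticity regression on the matched
#' mechanical subset. Optionally writes flat CSV/JSON artifacts.
#'
#' @param cohort Cohort tibble with `group`, morphometry and stiffness
#'   columns.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return List of class `pipeline_result`: `table` (flagged cohort),
#'   `morpho_comparison`, `ortho_test` (p-value), `matches`, `matched`
#'   (the matched subset), `fits` (three-step result), `log` (row counts,
#'   config hash, seed).
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  groups <- sort(unique(cohort$group))
  if (length(groups) != 2L) stop("cohort must contain exactly two groups")
  tab <- apply_filters(cohort, rho_max = config$rho_max, cv_max = config$cv_max)
  morpho_sub <- subset_morphological(tab)
  mech_sub <- subset_mechanical(tab)

  morpho_vars <- intersect(c("rho", "tb_n", "tb_th", "tb_sp", "tb_sp_sd", "da", "cv"),
                           names(tab))
  morpho_cmp <- compare_groups(morpho_sub, morpho_vars, groups)

  ortho_p <- if ("ortho_ne" %in% names(mech_sub))
    t_test(mech_sub$ortho_ne[mech_sub$group == groups[1]],
           mech_sub$ortho_ne[mech_sub$group == groups[2]]) else NA_real_

  g1 <- mech_sub[mech_sub$group == groups[1], ]
  g2 <- mech_sub[mech_sub$group == groups[2], ]
  matches <- match_groups(g2, g1, variables = config$match_variables)
  matched <- dplyr::bind_rows(g1[matches$ctrl_idx, ], g2[matches$t2d_idx, ])
  fits <- three_step_fit(matched, groups)

  log <- list(config_hash = config_hash(config), seed = config$seed,
              n_total = nrow(cohort), n_morphological = nrow(morpho_sub),
              n_mechanical = nrow(mech_sub), n_matched_per_group = nrow(matches),
              n_fit_rows = fits$pooled$n_roi)
  stopifnot(log$n_fit_rows == 2L * nrow(matches))  # fits consume the matched subset

  res <- structure(list(table = tab, morpho_comparison = morpho_cmp,
                        ortho_test = ortho_p, matches = matches,
                        matched = matched, fits = fits, log = log),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  ROIs: %d total, %d morphological, %d mechanical, %d matched/group\n",
              x$log$n_total, x$log$n_morphological, x$log$n_mechanical,
              x$log$n_matched_per_group))
  cat(sprintf("  orthotropy NE t-test p = %.3g\n", x$ortho_test))
  cat("  pooled fit:\n")
  print(x$fits$pooled)
  invisible(x)
}

fit_report <- function(fit) {
  list(type = fit$type,
       params = fit$params[c("lambda0", "lambda0p", "mu0", "k", "l", "lambda_star")],
       ci95 = fit$ci95, r2adj = fit$r2adj, ne = fit$ne,
       n_obs = fit$n_obs, n_roi = fit$n_roi)
}

#' Write pipeline artifacts
#'
#' Flat, diffable outputs: the flagged cohort table and comparison table
#' as CSV, the fit reports and run log as JSON.
#'
#' @param res A `pipeline_result`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$table, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  write.csv(res$morpho_comparison, file.path(out_dir, "morpho_comparison.csv"),
            row.names = FALSE)
  write.csv(res$matches, file.path(out_dir, "matches.csv"), row.names = FALSE)
  fits <- list(pooled = fit_report(res$fits$pooled),
               free = lapply(res$fits$free, fit_report),
               restricted = lapply(res$fits$restricted, fit_report))
  jsonlite::write_json(list(fits = fits, ortho_test_p = res$ortho_test,
                            log = res$log),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
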