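#' Observed-versus-fitted plot of a Zysset-Curnier fit
#'
#' Scatter of fitted against observed stiffness components (log responses
#' back-transformed to MPa) with the identity line, the standard visual
#' check of the fabric-elasticity regression.
#'
#' @param object A `zc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zc_fit <- function(object, ...) {
  df <- tibble::tibble(observed = exp(object$observed),
                       fitted = exp(object$fitted))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$fitted)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "observed component (MPa)",
                  y = "fitted component (MPa)",
                  title = sprintf("%s fit: R2adj = %.3f, NE = %.3f",
                                  object$type, object$r2adj, object$ne)) +
    ggplot2::theme_minimal()
}

#' Young's modulus curves for a set of fitted parameters
#'
#' @param fits Named list of [zc_params()] (or `zc_fit` objects).
#' @param rho_grid Bone volume fraction grid.
#' @return A ggplot object.
#' @export
plot_modulus_curves <- function(fits, rho_grid = seq(0.1, 0.5, by = 0.01)) {
  df <- purrr::map_dfr(names(fits), function(nm) {
    p <- fits[[nm]]
    if (inherits(p, "zc_fit")) p <- p$params
    dplyr::mutate(youngs_modulus_curve(p, rho_grid), fit = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = .data$E_MPa,
                                   color = .data$fit)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(rho), y = "E (MPa)", color = NULL) +
    ggplot2::theme_minimal()
}

#' Filter-plane plot of a cohort
#'
#' CV against bone volume fraction with the exclusion thresholds, showing
#' which ROIs enter each analysis subset.
#'
#' @param table Cohort tibble with `rho`, `cv`, `group`.
#' @param rho_max,cv_max Filter thresholds to draw.
#' @return A ggplot object.
#' @export
plot_filter_plane <- function(table, rho_max = 0.5, cv_max = 0.263) {
  ggplot2::ggplot(table, ggplot2::aes(x = .data$rho, y = .data$cv,
                                      color = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = rho_max, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = cv_max, linetype = "dashed") +
    ggplot2::labs(x = expression(rho), y = "CV", color = NULL) +
    ggplot2::theme_minimal()
}
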