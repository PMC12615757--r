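#' Apply the trabecular analysis filters to a cohort table
#'
#' Adds logical flag columns: `pass_rho` (rho < 0.5, purely trabecular
#' bone) and `pass_cv` (CV < 0.263, mass-homogeneity limit of the RVE
#' assumption). Both thresholds are strict inequalities. Rows with missing
#' rho or CV are dropped with a warning.
#'
#' @param table Tibble with at least `rho` and `cv` columns.
#' @param rho_max,cv_max Filter thresholds.
#' @return The table with `pass_rho` and `pass_cv` columns.
#' @seealso [subset_morphological()], [subset_mechanical()]
#' @export
apply_filters <- function(table, rho_max = 0.5, cv_max = 0.263) {
  miss <- !is.finite(table$rho) | !is.finite(table$cv)
  if (any(miss)) {
    warning(sum(miss), " row(s) with missing rho/CV excluded")
    table <- table[!miss, , drop = FALSE]
  }
  dplyr::mutate(table, pass_rho = .data$rho < rho_max,
                pass_cv = .data$cv < cv_max)
}

#' Analysis subsets of a filtered cohort
#'
#' The morphological subset keeps ROIs with rho below the trabecular
#' limit; the mechanical subset additionally requires the homogeneity CV
#' criterion.
#'
#' @param table A table from [apply_filters()].
#' @return Filtered tibble.
#' @export
subset_morphological <- function(table) dplyr::filter(table, .data$pass_rho)

#' @rdname subset_morphological
#' @export
subset_mechanical <- function(table) {
  dplyr::filter(table, .data$pass_rho, .data$pass_cv)
}

#' Two-sided Mann-Whitney U test
#'
#' Wrapper around the rank-sum test used for all morphological and
#' component-wise group comparisons: exact distribution for small
#' tie-free samples, mid-rank normal approximation with tie correction
#' otherwise.
#'
#' @param a,b Numeric samples.
#' @return Two-sided p-value.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("need at least 2 values per group")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && length(a) <= 20L && length(b) <= 20L
  suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = !exact)$p.value)
}

#' Two-sided Welch t-test
#'
#' Used to compare the orthotropy relative norm error between groups.
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @return Two-sided p-value.
#' @export
t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("need at least 2 values per group")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) return(1)
    stop("zero variance in both samples")
  }
  t.test(a, b, var.equal = FALSE)$p.value
}

#' Match ROIs across groups on density and anisotropy
#'
#' Each ROI of the second group is matched to the closest ROI of the first
#' group in standardized (rho, DA) space: variables are scaled by their
#' pooled SD, and greedy nearest-neighbor matching without replacement
#' proceeds in ascending order of pair distance. Unmatched ROIs are
#' dropped, yielding a one-to-one pairing.
#'
#' @param t2d_rows,ctrl_rows Tibbles with the matching variables.
#' @param variables Character vector of matching columns (default
#'   `c("rho", "da")`).
#' @return Tibble with `t2d_idx`, `ctrl_idx` (row indices into the input
#'   tables) and `distance`, sorted by ascending distance.
#' @export
match_groups <- function(t2d_rows, ctrl_rows, variables = c("rho", "da")) {
  if (nrow(t2d_rows) == 0L || nrow(ctrl_rows) == 0L) stop("empty group")
  A <- as.matrix(t2d_rows[, variables, drop = FALSE])
  B <- as.matrix(ctrl_rows[, variables, drop = FALSE])
  if (!all(is.finite(A)) || !all(is.finite(B)))
    stop("matching variables must be finite")
  pooled_sd <- apply(rbind(A, B), 2, stats::sd)
  pooled_sd[pooled_sd == 0] <- 1
  A <- sweep(A, 2, pooled_sd, "/")
  B <- sweep(B, 2, pooled_sd, "/")
  D <- outer(seq_len(nrow(A)), seq_len(nrow(B)),
             Vectorize(function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))))
  n <- min(nrow(A), nrow(B))
  pairs <- matrix(0L, n, 2)
  dist <- numeric(n)
  for (s in seq_len(n)) {
    idx <- arrayInd(which.min(D), dim(D))
    pairs[s, ] <- idx
    dist[s] <- D[idx]
    D[idx[1], ] <- Inf
    D[, idx[2]] <- Inf
  }
  tibble::tibble(t2d_idx = pairs[, 1], ctrl_idx = pairs[, 2], distance = dist)
}

#' Median and interquartile range of a cohort variable
#'
#' @param table Cohort tibble.
#' @param variable Column name.
#' @return Tibble with `median`, `q25`, `q75` (linear-interpolation
#'   quantiles, type 7).
#' @export
summarize_variable <- function(table, variable) {
  v <- table[[variable]]
  if (length(v) < 1L) stop("no values")
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(variable = variable, median = q[2], q25 = q[1], q75 = q[3])
}

#' Group comparison table
#'
#' For each variable, the two-group Mann-Whitney p-value and the per-group
#' median with interquartile range, mirroring a standard morphometric
#' comparison table.
#'
#' @param table Cohort tibble with a `group` column.
#' @param variables Character vector of columns to compare.
#' @param groups The two group labels (default the sorted unique values).
#' @return Tibble with one row per variable.
#' @export
compare_groups <- function(table, variables,
                           groups = sort(unique(table$group))) {
  if (length(groups) != 2L) stop("exactly two groups required")
  purrr::map_dfr(variables, function(v) {
    a <- table[[v]][table$group == groups[1]]
    b <- table[[v]][table$group == groups[2]]
    qa <- quantile(a, c(0.25, 0.5, 0.75), names = FALSE)
    qb <- quantile(b, c(0.25, 0.5, 0.75), names = FALSE)
    tibble::tibble(variable = v, p_value = mann_whitney(a, b),
                   median_1 = qa[2], q25_1 = qa[1], q75_1 = qa[3],
                   median_2 = qb[2], q25_2 = qb[1], q75_2 = qb[3])
  })
}
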