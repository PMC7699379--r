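#' Tidy a cross-validated Lasso fit
#'
#' @param x A [fit_lasso_cv()] result.
#' @param ... Unused.
#' @return One row per predictor with a nonzero coefficient at
#'   `lambda_min`: `term`, `estimate`, `type`.
#' @method tidy lasso_fit
#' @export
tidy.lasso_fit <- function(x, ...) {
  out <- select_items(x)
  dplyr::rename(out, estimate = "coefficient")
}

#' @rdname tidy.lasso_fit
#' @return For `glance()`: a one-row tibble with `lambda_min`,
#'   `n_nonzero`, `cv_error_min`, `n_folds`, `nobs`.
#' @method glance lasso_fit
#' @export
glance.lasso_fit <- function(x, ...) {
  tibble::tibble(
    lambda_min = x$lambda_min,
    n_nonzero = sum(x$coefficients != 0),
    cv_error_min = min(x$cv_mean_error),
    n_folds = x$n_folds,
    nobs = length(x$design$y)
  )
}

#' Tidy a multiple correspondence analysis
#'
#' @param x An [fit_mca()] result.
#' @param ... Unused.
#' @return One row per dimension: `dim`, `eigenvalue`,
#'   `explained_fraction`, `cumulative_fraction`.
#' @method tidy mca_fit
#' @export
tidy.mca_fit <- function(x, ...) {
  tibble::tibble(
    dim = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    explained_fraction = x$explained_fraction,
    cumulative_fraction = cumsum(x$explained_fraction)
  )
}

#' @rdname tidy.mca_fit
#' @return For `glance()`: `total_inertia`, `n_dims`, `n_categories`,
#'   `n_items`, `nobs`.
#' @method glance mca_fit
#' @export
glance.mca_fit <- function(x, ...) {
  tibble::tibble(
    total_inertia = x$total_inertia,
    n_dims = length(x$eigenvalues),
    n_categories = nrow(x$col_coords),
    n_items = x$q,
    nobs = nrow(x$row_coords)
  )
}

#' Tidy the dimension regression
#'
#' @param x A [regress_dims()] result.
#' @param ... Unused.
#' @return One row per retained dimension: `dim`, `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `significant`.
#' @method tidy dim_regression
#' @export
tidy.dim_regression <- function(x, ...) {
  dplyr::rename(x$table, estimate = "beta", std.error = "se",
                statistic = "z", p.value = "p_value")
}

#' @rdname tidy.dim_regression
#' @return For `glance()`: final `aic`, retained dimension count,
#'   significant count, random-effect variances and the fitting method.
#' @method glance dim_regression
#' @export
glance.dim_regression <- function(x, ...) {
  tibble::tibble(
    aic = x$aic_trace$aic[nrow(x$aic_trace)],
    n_dims = length(x$included_dims),
    n_significant = length(x$significant_dims),
    var_horse = unname(x$re_variances[grep("horse", names(x$re_variances))][1]),
    var_observer = unname(
      x$re_variances[grep("observer", names(x$re_variances))][1]),
    resid_autocorr = x$resid_autocorr,
    method = x$method
  )
}
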