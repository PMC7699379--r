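#' @export
print.gait_params <- function(x, ...) {
  cat(sprintf(
    "<gait_params> %.2f Hz, %d strides @ %g Hz; asym head %+.1f / pelvis %+.1f mm; noise %.1f mm\n",
    x$stride_frequency, x$n_strides, x$sampling_rate, x$head_asym_mm,
    x$pelvis_asym_mm, x$noise_sd_mm))
  invisible(x)
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf(
    "<trial_design> %d horses, b0 + %d post occasions, %d observers, %d repeat(s); %d item effect(s)\n",
    x$n_horses, x$n_post_occasions, x$n_observers, x$n_repeats,
    sum(x$item_effects != 0)))
  invisible(x)
}

#' @export
print.lasso_fit <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf(
    "<lasso_fit> lambda_min = %.4g (%d-fold CV, seed %s): %d of %d nonzero\n",
    x$lambda_min, x$n_folds, x$seed, nz, length(x$coefficients)))
  top <- utils::head(select_items(x), 5)
  if (nrow(top) > 0) {
    cat(paste0("  ", top$term, " = ", signif(top$coefficient, 3),
               collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
print.mca_fit <- function(x, ...) {
  cat(sprintf(
    "<mca_fit> %d rows x %d categories (%d items); total inertia %.3f\n",
    nrow(x$row_coords), nrow(x$col_coords), x$q, x$total_inertia))
  k <- min(5, length(x$eigenvalues))
  cat("  explained:", paste0(sprintf("%.1f%%",
                                     100 * x$explained_fraction[1:k]),
                             collapse = ", "),
      if (length(x$eigenvalues) > k) "..." else "", "\n")
  invisible(x)
}

#' @export
print.dim_regression <- function(x, ...) {
  cat(sprintf(
    "<dim_regression> %s fit; %d dims retained, %d significant (p < %g)\n",
    x$method, length(x$included_dims), length(x$significant_dims),
    x$p_threshold))
  if (nrow(x$table) > 0) print(x$table)
  invisible(x)
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf(
    "<run_summary> seed %s: %d horses, %d measurements (%d kept), %d assessments\n",
    x$config_seed, nrow(x$per_horse), x$n_measurements,
    x$n_measurements_kept, x$n_assessments))
  cat(sprintf("  max total asymmetry score: mean %.1f mm (sd %.1f)\n",
              mean(x$per_horse$max_score_mm), stats::sd(x$per_horse$max_score_mm)))
  cat(sprintf("  selected items: %d; retained dims: %d; significant dims: %d\n",
              sum(x$selected_items$type == "item"), length(x$retained_dims),
              length(x$dim_regression$significant_dims)))
  invisible(x)
}
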