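#' Study configuration
#'
#' Assembles the configuration of a full synthetic study run: the trial
#' design, the gait generator settings, and the tuning parameters of
#' every analysis stage.  A run is fully reproducible from the
#' configuration (all stage seeds derive from `seed`).
#'
#' @param seed Master seed.
#' @param design A [trial_design()]; `NULL` builds the default design
#'   from `seed`.
#' @param gait Named list overriding [gait_params()] defaults
#'   (`stride_frequency`, `n_strides`, `base_amplitude_mm`,
#'   `noise_sd_mm`, ...).
#' @param cutoff_multiplier Low-pass cutoff multiple of stride frequency.
#' @param min_prominence_frac Peak prominence threshold.
#' @param n_folds Lasso cross-validation folds.
#' @param per_scale Also fit one Lasso per scale (default `TRUE`).
#' @param min_fraction Minimum explained-inertia fraction for retaining
#'   an MCA dimension.
#' @param p_threshold Significance threshold in the dimension
#'   regression.
#' @param row_mode MCA row mode, `"observer"` or `"assessment"`.
#' @param max_occasion Optional named character vector overriding the
#'   automatic per-horse maximum-score occasion (names = horses).
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = 1L, design = NULL, gait = list(),
                         cutoff_multiplier = 6, min_prominence_frac = 0.2,
                         n_folds = 10, per_scale = TRUE,
                         min_fraction = 0.01, p_threshold = 0.01,
                         row_mode = "observer", max_occasion = NULL) {
  if (is.null(design)) design <- trial_design(seed = seed)
  structure(
    list(seed = seed, design = design, gait = gait,
         cutoff_multiplier = cutoff_multiplier,
         min_prominence_frac = min_prominence_frac,
         n_folds = n_folds, per_scale = per_scale,
         min_fraction = min_fraction, p_threshold = p_threshold,
         row_mode = row_mode, max_occasion = max_occasion),
    class = "study_config"
  )
}

# decompose a horse-occasion total asymmetry into signed head and pelvis
# minima differences for the gait generator: pd carries 3/4 of the total
# and hd/2 the remaining 1/4, both on the induced side; the baseline
# carries a small residual asymmetry (|pd| = 3 mm) on the same side
asym_components <- function(true_score_mm, side) {
  base_pd <- 3
  base_hd <- 2
  total <- abs(base_hd) / 2 + abs(base_pd) + true_score_mm
  list(pd = side * 0.75 * total, hd = side * 0.5 * total)
}

#' Run the full synthetic study
#'
#' Executes the complete analysis flow on simulated data: gait
#' generation per horse and occasion, kinematic asymmetry measurement,
#' total asymmetry scoring against baseline, per-horse truncation at
#' the maximum-score occasion, observer score simulation, per-item
#' reliability, Lasso item selection (all scales, plus per scale), and
#' MCA with the mixed-model dimension regression.  Since induction
#' targets the hindlimb with the higher baseline asymmetry, the
#' simulator books the induced side as the side of the horse's baseline
#' asymmetry.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, all stage artifacts
#'   are written (`scores.csv`, `asymmetry.csv`, `reliability.csv`,
#'   `lasso.json`, `mca.json`, `summary.json`, `report.md`).
#' @param write_trajectories Also write per-trial trajectory CSVs under
#'   `out_dir/trajectories/` (off by default; they are bulky).
#' @return A list of class `run_summary`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      write_trajectories = FALSE) {
  stopifnot(inherits(config, "study_config"))
  design <- config$design
  scales <- pain_scales()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  scores <- stage("simulate_scores", simulate_scores(design, scales))
  truth <- score_truth(scores)
  traj_truth <- truth$asymmetry

  # gait simulation + kinematics per horse x occasion (x trot repeat)
  measured <- stage("kinematics", {
    purrr::map_dfr(seq_len(nrow(traj_truth)), function(i) {
      comp <- asym_components(traj_truth$true_score_mm[i],
                              traj_truth$side[i])
      purrr::map_dfr(seq_len(design$n_repeats), function(rep_i) {
        gp <- do.call(gait_params, utils::modifyList(
          list(pelvis_asym_mm = comp$pd, head_asym_mm = comp$hd,
               seed = child_seed(config$seed, i * 10 + rep_i)),
          config$gait))
        traj <- simulate_gait(gp)
        m <- measure_asymmetry(traj, config$cutoff_multiplier,
                               config$min_prominence_frac)
        m$horse <- traj_truth$horse[i]
        m$occasion <- traj_truth$occasion[i]
        m$trot_repeat <- rep_i
        if (write_trajectories && !is.null(out_dir)) {
          tdir <- file.path(out_dir, "trajectories")
          dir.create(tdir, showWarnings = FALSE, recursive = TRUE)
          readr::write_csv(traj, file.path(tdir, sprintf(
            "trajectories_%s_%s_%d.csv", traj_truth$horse[i],
            traj_truth$occasion[i], rep_i)))
        }
        m
      })
    })
  })
  asymmetry <- stage("asymmetry_score", asymmetry_score(measured))

  # per-horse truncation at the maximum-score occasion (manual override
  # via config$max_occasion)
  keep <- kept_occasions(asymmetry)
  if (!is.null(config$max_occasion)) {
    keep <- purrr::map_dfr(names(config$max_occasion), function(h) {
      occ <- occasion_levels(asymmetry$occasion)
      upto <- match(config$max_occasion[[h]], occ)
      tibble::tibble(horse = h, occasion = occ[seq_len(upto)])
    }) |>
      dplyr::bind_rows(dplyr::filter(keep,
                                     !.data$horse %in%
                                       names(config$max_occasion)))
  }
  asym_kept <- dplyr::semi_join(asymmetry, keep, by = c("horse", "occasion"))
  scores_kept <- dplyr::semi_join(scores, keep, by = c("horse", "occasion"))

  reliability <- stage("reliability", reliability_report(scores_kept, scales))

  design_mat <- stage("build_design",
                      build_design(scores_kept, asym_kept,
                                   truncate_at_max = FALSE, scales = scales))
  lasso <- stage("lasso", fit_lasso_cv(design_mat, n_folds = config$n_folds,
                                       seed = child_seed(config$seed, 101)))
  selected <- select_items(lasso)
  lasso_per_scale <- NULL
  if (isTRUE(config$per_scale)) {
    lasso_per_scale <- stage("lasso_per_scale", {
      purrr::map(rlang::set_names(unique(scales$scale)), function(sc) {
        sub <- dplyr::filter(scores_kept, .data$scale == sc)
        d <- build_design(sub, asym_kept, truncate_at_max = FALSE,
                          scales = scales)
        fit <- fit_lasso_cv(d, n_folds = config$n_folds,
                            seed = child_seed(config$seed, 103))
        select_items(fit)
      })
    })
  }

  mca_out <- stage("mca", {
    z <- build_indicator(scores_kept, row_mode = config$row_mode,
                         scales = scales)
    mca <- fit_mca(z)
    dims <- select_dims(mca, config$min_fraction)
    keys <- attr(z, "keys")
    resp <- keys |>
      dplyr::left_join(
        dplyr::summarise(
          dplyr::group_by(asym_kept, .data$horse, .data$occasion),
          score_mm = mean(.data$score_mm), .groups = "drop"),
        by = c("horse", "occasion"))
    obs <- if ("observer" %in% names(keys)) keys$observer else
      rep("consensus", nrow(keys))
    reg <- regress_dims(mca$row_coords, resp$score_mm, keys$horse, obs,
                        dims = dims, p_threshold = config$p_threshold)
    interp <- purrr::map(rlang::set_names(reg$significant_dims,
                                          paste0("dim",
                                                 reg$significant_dims)),
                         function(d) interpret_dim(mca, reg, d))
    list(mca = mca, dims = dims, regression = reg, interpretation = interp)
  })

  per_horse <- asymmetry |>
    dplyr::group_by(.data$horse) |>
    dplyr::slice_max(.data$score_mm, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("horse", max_occasion = "occasion",
                  max_score_mm = "score_mm")

  summary <- structure(
    list(
      config_seed = config$seed,
      per_horse = per_horse,
      n_measurements = nrow(measured),
      n_measurements_kept = nrow(asym_kept),
      n_assessments = nrow(dplyr::distinct(
        scores, .data$horse, .data$occasion, .data$phase)),
      asymmetry = asymmetry,
      asymmetry_kept = asym_kept,
      scores = scores,
      scores_kept = scores_kept,
      reliability = reliability,
      lasso = lasso,
      selected_items = selected,
      selected_per_scale = lasso_per_scale,
      mca = mca_out$mca,
      retained_dims = mca_out$dims,
      dim_regression = mca_out$regression,
      dim_interpretation = mca_out$interpretation,
      diagnostics = list(
        degenerate_items = reliability$item[reliability$degenerate],
        fold_seed = lasso$seed,
        resid_autocorr = mca_out$regression$resid_autocorr,
        regression_method = mca_out$regression$method
      )
    ),
    class = "run_summary"
  )

  if (!is.null(out_dir)) write_artifacts(summary, out_dir)
  summary
}

# serialize the stage artifacts of a run; formatting is fixed so that
# identical runs produce byte-identical files
write_artifacts <- function(summary, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wj <- function(x, file) {
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = 10, pretty = TRUE, na = "null")
  }
  readr::write_csv(summary$scores, file.path(out_dir, "scores.csv"))
  readr::write_csv(summary$asymmetry, file.path(out_dir, "asymmetry.csv"))
  readr::write_csv(summary$reliability, file.path(out_dir, "reliability.csv"))
  wj(list(lambda_path = summary$lasso$lambda_path,
          cv_mean_error = summary$lasso$cv_mean_error,
          cv_se = summary$lasso$cv_se,
          lambda_min = summary$lasso$lambda_min,
          seed = summary$lasso$seed,
          intercept = summary$lasso$intercept,
          selected = summary$selected_items,
          per_scale = summary$selected_per_scale), "lasso.json")
  wj(list(eigenvalues = summary$mca$eigenvalues,
          explained_fraction = summary$mca$explained_fraction,
          retained_dims = summary$retained_dims,
          regression = summary$dim_regression$table,
          re_variances = as.list(summary$dim_regression$re_variances),
          interpretation = summary$dim_interpretation), "mca.json")
  wj(list(seed = summary$config_seed,
          per_horse = summary$per_horse,
          n_measurements = summary$n_measurements,
          n_measurements_kept = summary$n_measurements_kept,
          n_assessments = summary$n_assessments,
          degenerate_items = summary$diagnostics$degenerate_items,
          resid_autocorr = summary$diagnostics$resid_autocorr,
          regression_method = summary$diagnostics$regression_method),
     "summary.json")
  writeLines(report(summary), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' Render a run summary as a markdown report
#'
#' Pure rendering of the saved artifacts: per-item reliability (with
#' degenerate items marked), the selected Lasso items (or an explicit
#' note that none were selected), the dimension-regression table, and
#' the per-horse asymmetry trajectories.  Regenerating the report from
#' the same summary is byte-identical.
#'
#' @param summary A [run_study()] result.
#' @return Character vector of markdown lines.
#' @export
report <- function(summary) {
  stopifnot(inherits(summary, "run_summary"))
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "f")
  lines <- c("# Synthetic induction study report", "")
  lines <- c(lines, sprintf("Seed: %s", summary$config_seed),
             sprintf("Measurements: %d (%d kept after truncation)",
                     summary$n_measurements, summary$n_measurements_kept),
             sprintf("Assessments: %d", summary$n_assessments), "")
  lines <- c(lines, "## Per-horse maximum total asymmetry score", "",
             "| horse | occasion | score (mm) |", "|---|---|---|",
             sprintf("| %s | %s | %s |", summary$per_horse$horse,
                     summary$per_horse$max_occasion,
                     fmt(summary$per_horse$max_score_mm, 1)), "")
  rel <- summary$reliability
  lines <- c(lines, "## Inter-observer reliability (behavioral items)", "",
             "| scale | item | n | W | p | band |", "|---|---|---|---|---|---|",
             sprintf("| %s | %s | %d | %s | %s | %s |", rel$scale, rel$item,
                     rel$n_used,
                     ifelse(rel$degenerate, "degenerate", fmt(rel$w)),
                     ifelse(rel$degenerate, "-", fmt(rel$p_value)),
                     ifelse(rel$degenerate, "-", rel$band)), "")
  sel <- summary$selected_items
  lines <- c(lines, "## Lasso selection (all scales)", "")
  if (nrow(sel) == 0) {
    lines <- c(lines, "no items selected", "")
  } else {
    lines <- c(lines, "| term | coefficient | type |", "|---|---|---|",
               sprintf("| %s | %s | %s |", sel$term, fmt(sel$coefficient),
                       sel$type), "")
  }
  tab <- summary$dim_regression$table
  lines <- c(lines, "## Significant MCA dimensions", "")
  if (nrow(tab) == 0) {
    lines <- c(lines, "no dimensions retained", "")
  } else {
    lines <- c(lines, "| dim | beta | SE | z | p |", "|---|---|---|---|---|",
               sprintf("| %d | %s | %s | %s | %s |", tab$dim, fmt(tab$beta, 2),
                       fmt(tab$se, 2), fmt(tab$z, 2), fmt(tab$p_value, 4)),
               "")
  }
  lines
}
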