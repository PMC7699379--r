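#' Build the item-factor design for Lasso selection
#'
#' Joins each pain assessment (horse x occasion x phase x observer) to
#' its occasion's total asymmetry score and expands every scale item
#' into indicator columns for each observed score level above 0 (level 0
#' is the reference), named `<scale>_<item><level>` (e.g. `hgs_orb1` is
#' score 1 on orbital tightening).  Horse (`h1..hK`) and observer
#' (`o1..oM`) indicators are appended as fixed-effect columns.
#'
#' Pairing rule: with one trot measurement on an occasion, the pre and
#' post assessments share its score; with two measurements
#' (`trot_repeat` 1 and 2), the pre assessment is paired with the first
#' and the post assessment with the second.  Per horse, data are
#' truncated at the occasion of maximum total asymmetry score (later
#' occasions, where asymmetry declines back towards baseline, are
#' excluded).
#'
#' @param scores Long score table.
#' @param asymmetry Tibble `horse`, `occasion`, `score_mm` (optionally
#'   `trot_repeat`), as from [asymmetry_score()].
#' @param truncate_at_max Truncate each horse at its maximum-score
#'   occasion (default `TRUE`).
#' @param scales Scale registry.
#' @return An object of class `asym_design`: list with the numeric
#'   matrix `x`, response `y` (mm), row `keys`, and the column
#'   classification `item_cols` / `effect_cols`.
#' @export
build_design <- function(scores, asymmetry, truncate_at_max = TRUE,
                         scales = pain_scales()) {
  stopifnot(all(c("horse", "occasion", "score_mm") %in% names(asymmetry)))
  viol <- validate_scores(scores, scales)
  if (nrow(viol) > 0) {
    stop("score table has ", nrow(viol), " violation(s)", call. = FALSE)
  }
  asym <- asymmetry
  if (!"trot_repeat" %in% names(asym)) asym$trot_repeat <- 1L
  if (truncate_at_max) {
    keep <- kept_occasions(asym)
    asym <- dplyr::semi_join(asym, keep, by = c("horse", "occasion"))
    scores <- dplyr::semi_join(scores, keep, by = c("horse", "occasion"))
  }
  # pre assessments pair with the first repeat, post with the last
  asym_phase <- asym |>
    dplyr::group_by(.data$horse, .data$occasion) |>
    dplyr::reframe(
      phase = c("pre", "post"),
      score_mm = c(.data$score_mm[which.min(.data$trot_repeat)],
                   .data$score_mm[which.max(.data$trot_repeat)])
    )
  wide <- scores |>
    dplyr::mutate(col = paste0(scale_prefix(.data$scale), "_", .data$item,
                               .data$score)) |>
    dplyr::inner_join(asym_phase, by = c("horse", "occasion", "phase"))
  dropped <- dplyr::anti_join(scores, asym_phase,
                              by = c("horse", "occasion", "phase"))
  if (nrow(dropped) > 0) {
    warning(length(unique(paste(dropped$horse, dropped$occasion,
                                dropped$phase))),
            " assessment(s) without a matching trot measurement dropped",
            call. = FALSE)
  }
  keys <- wide |>
    dplyr::distinct(.data$horse, .data$occasion, .data$phase,
                    .data$observer, .data$score_mm)
  # indicator columns for observed levels > 0, in registry order
  lvl <- wide |>
    dplyr::filter(.data$score > 0) |>
    dplyr::distinct(.data$scale, .data$item, .data$score, .data$col) |>
    dplyr::left_join(
      dplyr::mutate(scales, ord = dplyr::row_number())[, c("scale", "item",
                                                           "ord")],
      by = c("scale", "item")
    ) |>
    dplyr::arrange(.data$ord, .data$score)
  n <- nrow(keys)
  x_items <- matrix(0, n, nrow(lvl), dimnames = list(NULL, lvl$col))
  hit <- wide |>
    dplyr::filter(.data$score > 0) |>
    dplyr::left_join(dplyr::mutate(keys, row = dplyr::row_number()),
                     by = c("horse", "occasion", "phase", "observer",
                            "score_mm"))
  x_items[cbind(hit$row, match(hit$col, lvl$col))] <- 1
  horses <- sort(unique(keys$horse))
  observers <- sort(unique(keys$observer))
  x_horse <- outer(keys$horse, horses, `==`) * 1
  colnames(x_horse) <- horses
  x_obs <- outer(keys$observer, observers, `==`) * 1
  colnames(x_obs) <- observers
  x <- cbind(x_items, x_horse, x_obs)
  structure(
    list(x = x, y = keys$score_mm, keys = keys,
         item_cols = lvl$col, effect_cols = c(horses, observers),
         item_map = lvl[, c("col", "scale", "item", "score")]),
    class = "asym_design"
  )
}

#' Occasions retained by the maximum-score truncation rule
#'
#' For each horse, the baseline and every occasion up to and including
#' the occasion of maximum total asymmetry score (ties broken towards
#' the earlier occasion).
#'
#' @param asymmetry Tibble `horse`, `occasion`, `score_mm`.
#' @return A tibble of kept `horse`, `occasion` pairs.
#' @export
kept_occasions <- function(asymmetry) {
  asymmetry |>
    dplyr::mutate(occ = factor(.data$occasion,
                               occasion_levels(.data$occasion))) |>
    dplyr::group_by(.data$horse, .data$occ, .data$occasion) |>
    dplyr::summarise(score_mm = max(.data$score_mm), .groups = "drop") |>
    dplyr::arrange(.data$horse, .data$occ) |>
    dplyr::group_by(.data$horse) |>
    dplyr::filter(dplyr::row_number() <= which.max(.data$score_mm)) |>
    dplyr::ungroup() |>
    dplyr::select("horse", "occasion")
}

#' Fit the cross-validated Lasso
#'
#' Lasso (`alpha = 1`) regression of the total asymmetry score on the
#' factor-encoded design, fitted over a log-spaced lambda path with
#' 10-fold cross-validation; the reported model is the one at the lambda
#' minimizing mean cross-validated error.  Predictors are standardized
#' internally and coefficients reported on the original scale.  Folds
#' are assigned by a seeded permutation and the seed recorded.
#'
#' @param design An [build_design()] result.
#' @param n_folds Number of cross-validation folds.
#' @param seed Seed for fold assignment.
#' @param penalize_effects Penalize horse/observer indicator columns
#'   like item columns (default, matching a plain Lasso over all
#'   predictors); set `FALSE` to leave them unpenalized.
#' @param thresh Coordinate-descent convergence threshold.
#' @return An object of class `lasso_fit`.
#' @export
fit_lasso_cv <- function(design, n_folds = 10, seed = 1L,
                         penalize_effects = TRUE, thresh = 1e-10) {
  stopifnot(inherits(design, "asym_design"))
  n <- length(design$y)
  if (n < n_folds) stop("fewer rows than folds", call. = FALSE)
  if (stats::var(design$y) == 0) stop("constant response", call. = FALSE)
  foldid <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  pf <- rep(1, ncol(design$x))
  if (!penalize_effects) {
    pf[colnames(design$x) %in% design$effect_cols] <- 0
  }
  cv <- glmnet::cv.glmnet(design$x, design$y, alpha = 1, foldid = foldid,
                          standardize = TRUE, penalty.factor = pf,
                          thresh = thresh)
  beta <- stats::coef(cv, s = "lambda.min")
  coefs <- as.numeric(beta)[-1]
  names(coefs) <- rownames(beta)[-1]
  structure(
    list(cv = cv, lambda_path = cv$lambda, cv_mean_error = cv$cvm,
         cv_se = cv$cvsd, lambda_min = cv$lambda.min,
         coefficients = coefs, intercept = as.numeric(beta)[1],
         seed = seed, n_folds = n_folds, foldid = foldid,
         design = design),
    class = "lasso_fit"
  )
}

#' Rank the selected predictors
#'
#' Nonzero coefficients at `lambda_min`, item columns separated from
#' horse/observer effect columns and sorted by absolute magnitude.
#'
#' @param fit A [fit_lasso_cv()] result.
#' @return A tibble `term`, `coefficient`, `type` (`"item"` or
#'   `"effect"`), sorted by `abs(coefficient)` within type.
#' @export
select_items <- function(fit) {
  stopifnot(inherits(fit, "lasso_fit"))
  nz <- fit$coefficients[fit$coefficients != 0]
  if (length(nz) == 0) {
    return(tibble::tibble(term = character(0), coefficient = numeric(0),
                          type = character(0)))
  }
  tibble::tibble(
    term = names(nz),
    coefficient = unname(nz),
    type = ifelse(names(nz) %in% fit$design$item_cols, "item", "effect")
  ) |>
    dplyr::arrange(.data$type == "effect", dplyr::desc(abs(.data$coefficient)))
}

# KKT optimality residuals of a lasso fit at lambda_min, computed on the
# internally standardized predictor scale glmnet solves on: for active
# coefficients |g_j - lambda * sign(b_j)|, for inactive max(|g_j| - lambda, 0)
# where g_j = (1/n) x_sj' r.  Used by the test suite as the optimality
# contract.
lasso_kkt <- function(fit, lambda = fit$lambda_min) {
  x <- fit$design$x
  y <- fit$design$y
  n <- nrow(x)
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(sweep(x, 2, mu)^2))
  sdv[sdv == 0] <- 1
  beta <- as.numeric(stats::coef(fit$cv, s = lambda, exact = TRUE,
                                 x = x, y = y, thresh = 1e-12,
                                 penalty.factor = rep(1, ncol(x))))
  b0 <- beta[1]
  b <- beta[-1]
  r <- y - as.numeric(x %*% b) - b0
  g <- as.numeric(crossprod(x, r)) / n / sdv  # gradient wrt standardized beta
  active <- b != 0
  viol_active <- if (any(active)) {
    max(abs(g[active] - lambda * sign(b[active])))
  } else 0
  viol_inactive <- if (any(!active)) {
    max(pmax(abs(g[!active]) - lambda, 0))
  } else 0
  max(viol_active, viol_inactive)
}
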