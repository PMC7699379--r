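#' Complete disjunctive (indicator) coding of a score table
#'
#' Expands a long score table into the 0/1 indicator matrix used by
#' multiple correspondence analysis: one column per (scale item,
#' observed score level) category, labelled `<scale>_<item><level>`,
#' with each item's category block summing to 1 in every row.  Rows are
#' one per (assessment, observer) by default — each observer's scoring
#' is its own row, since the follow-up regression models observer as a
#' random effect — or a per-assessment median consensus.
#'
#' @param scores Long score table.
#' @param row_mode `"observer"` (default) or `"assessment"` (median
#'   consensus across observers, rounded half down).
#' @param scales Scale registry.
#' @return A numeric matrix with attributes `keys` (row key tibble),
#'   `q` (number of items) and `constant_items` (items with a single
#'   observed level; kept, but contributing zero inertia).
#' @export
build_indicator <- function(scores, row_mode = c("observer", "assessment"),
                            scales = pain_scales()) {
  row_mode <- match.arg(row_mode)
  viol <- validate_scores(scores, scales)
  if (nrow(viol) > 0) {
    stop("score table has ", nrow(viol), " violation(s)", call. = FALSE)
  }
  df <- tibble::as_tibble(scores)
  if (row_mode == "assessment") {
    df <- df |>
      dplyr::group_by(.data$horse, .data$occasion, .data$phase, .data$scale,
                      .data$item) |>
      dplyr::summarise(score = floor(stats::median(.data$score)),
                       .groups = "drop")
    key_cols <- c("horse", "occasion", "phase")
  } else {
    key_cols <- c("horse", "occasion", "phase", "observer")
  }
  keys <- dplyr::distinct(df[key_cols])
  df <- df |>
    dplyr::left_join(dplyr::mutate(keys, row = dplyr::row_number()),
                     by = key_cols) |>
    dplyr::mutate(col = paste0(scale_prefix(.data$scale), "_", .data$item,
                               .data$score))
  lvl <- df |>
    dplyr::distinct(.data$scale, .data$item, .data$score, .data$col) |>
    dplyr::left_join(
      dplyr::mutate(scales, ord = dplyr::row_number())[, c("scale", "item",
                                                           "ord")],
      by = c("scale", "item")
    ) |>
    dplyr::arrange(.data$ord, .data$score)
  z <- matrix(0, nrow(keys), nrow(lvl), dimnames = list(NULL, lvl$col))
  z[cbind(df$row, match(df$col, lvl$col))] <- 1
  n_levels <- lvl |>
    dplyr::count(.data$scale, .data$item)
  attr(z, "keys") <- keys
  attr(z, "q") <- nrow(n_levels)
  attr(z, "constant_items") <- n_levels[n_levels$n == 1, c("scale", "item")]
  z
}

#' Multiple correspondence analysis of an indicator matrix
#'
#' Correspondence analysis of the complete disjunctive table `Z`:
#' with `P = Z / sum(Z)`, row masses `r` and column masses `c`, the
#' standardized residual matrix
#' `S = D_r^{-1/2} (P - r c') D_c^{-1/2}` is decomposed by SVD; the
#' principal inertias (eigenvalues) are the squared singular values and
#' explained fractions are raw inertia shares (no Benzecri correction).
#' Row and column principal coordinates follow the usual transition
#' formulas.  For reproducibility, each dimension's sign is fixed so
#' that its largest-magnitude category coordinate is positive.
#'
#' @param z Indicator matrix from [build_indicator()] (any 0/1 complete
#'   disjunctive matrix works; `q` is then inferred from row sums).
#' @return An object of class `mca_fit`: `eigenvalues`,
#'   `explained_fraction`, `row_coords`, `col_coords` (principal
#'   coordinates), `col_contrib` (per-dimension category contributions),
#'   `total_inertia`, `row_masses`, `col_masses`, `q`, `keys`.
#' @export
fit_mca <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 2 || ncol(z) < 2) stop("degenerate indicator matrix",
                                       call. = FALSE)
  total <- sum(z)
  if (total <= 0) stop("empty indicator matrix", call. = FALSE)
  p <- z / total
  r <- rowSums(p)
  cm <- colSums(p)
  if (any(r <= 0) || any(cm <= 0)) {
    stop("empty row or column in indicator matrix", call. = FALSE)
  }
  s <- (p - tcrossprod(r, cm)) / sqrt(tcrossprod(r, cm))
  dec <- svd(s)
  keep <- dec$d > max(dec$d[1], 1e-12) * 1e-9
  sv <- dec$d[keep]
  u <- dec$u[, keep, drop = FALSE]
  v <- dec$v[, keep, drop = FALSE]
  row_coords <- sweep(u / sqrt(r), 2, sv, `*`)
  col_coords <- sweep(v / sqrt(cm), 2, sv, `*`)
  # deterministic orientation: largest-|coordinate| category positive
  for (k in seq_along(sv)) {
    j <- which.max(abs(col_coords[, k]))
    if (col_coords[j, k] < 0) {
      col_coords[, k] <- -col_coords[, k]
      row_coords[, k] <- -row_coords[, k]
    }
  }
  eig <- sv^2
  contrib <- sweep(cm * col_coords^2, 2, eig, `/`)
  dimnames(col_coords) <- list(colnames(z), paste0("dim", seq_along(sv)))
  dimnames(contrib) <- dimnames(col_coords)
  colnames(row_coords) <- paste0("dim", seq_along(sv))
  q <- attr(z, "q")
  if (is.null(q)) q <- round(mean(rowSums(z)))
  structure(
    list(eigenvalues = eig, explained_fraction = eig / sum(eig),
         row_coords = row_coords, col_coords = col_coords,
         col_contrib = contrib, total_inertia = sum(eig),
         row_masses = r, col_masses = cm, q = q,
         keys = attr(z, "keys")),
    class = "mca_fit"
  )
}

#' Dimensions retained for the follow-up regression
#'
#' All dimensions explaining at least `min_fraction` of the total
#' inertia (default 1%), in order.
#'
#' @param mca An [fit_mca()] result.
#' @param min_fraction Minimum explained-variance fraction.
#' @return Integer vector of retained dimension indices.
#' @export
select_dims <- function(mca, min_fraction = 0.01) {
  stopifnot(inherits(mca, "mca_fit"))
  which(mca$explained_fraction >= min_fraction)
}

#' Mixed-model regression of asymmetry on MCA dimensions
#'
#' Linear regression of the total asymmetry score on the retained MCA
#' row coordinates, with random intercepts for horse and observer,
#' fitted by maximum likelihood.  The fixed effects are reduced by
#' greedy backward elimination: at each step the dimension whose removal
#' lowers AIC the most is dropped, until no single removal lowers AIC.
#' Retained dimensions get Wald z statistics (`beta / SE`, normal
#' reference) and are flagged significant at `p < p_threshold`.  A lag-1
#' within-horse residual autocorrelation is reported as a temporal
#' diagnostic.  If the mixed model cannot be fitted the function falls
#' back to fixed-intercept least squares with a recorded warning.
#'
#' @param row_coords Matrix of MCA row coordinates (columns `dim1`,
#'   `dim2`, ...), one row per assessment row.
#' @param asymmetry Numeric response (total asymmetry score, mm).
#' @param horse,observer Factors aligned with the rows.
#' @param dims Dimensions (indices) to start from; default all columns.
#' @param p_threshold Significance threshold for retained dimensions.
#' @return An object of class `dim_regression`: coefficient `table`,
#'   `included_dims`, `significant_dims`, `aic_trace`,
#'   `re_variances`, `resid_autocorr`, `method`.
#' @export
regress_dims <- function(row_coords, asymmetry, horse, observer,
                         dims = seq_len(ncol(row_coords)),
                         p_threshold = 0.01) {
  row_coords <- as.matrix(row_coords)
  stopifnot(length(asymmetry) == nrow(row_coords),
            length(horse) == nrow(row_coords),
            length(observer) == nrow(row_coords))
  dn <- colnames(row_coords)
  if (is.null(dn)) dn <- paste0("dim", seq_len(ncol(row_coords)))
  df <- data.frame(.y = asymmetry, row_coords,
                   .horse = factor(horse), .observer = factor(observer),
                   check.names = FALSE)
  names(df)[1 + seq_len(ncol(row_coords))] <- dn
  use <- dn[dims]

  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  method <- "lmm"
  fit_one <- function(terms, reml = FALSE) {
    rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
    if (method == "lmm") {
      f <- stats::as.formula(
        paste("`.y` ~", rhs, "+ (1 | `.horse`) + (1 | `.observer`)"))
      suppressMessages(suppressWarnings(
        lme4::lmer(f, data = df, REML = reml, control = ctrl)))
    } else {
      stats::lm(stats::as.formula(paste("`.y` ~", rhs)), data = df)
    }
  }
  current <- tryCatch(fit_one(use), error = function(e) NULL)
  if (is.null(current)) {
    warning("mixed model failed; falling back to fixed-intercept OLS",
            call. = FALSE)
    method <- "ols"
    current <- fit_one(use)
  }
  trace <- tibble::tibble(step = 0L, dropped = NA_character_,
                          aic = stats::AIC(current))
  repeat {
    if (length(use) == 0) break
    cands <- lapply(use, function(d) fit_one(setdiff(use, d)))
    aics <- vapply(cands, stats::AIC, numeric(1))
    best <- which.min(aics)
    if (aics[best] < stats::AIC(current)) {
      trace <- dplyr::bind_rows(trace, tibble::tibble(
        step = max(trace$step) + 1L, dropped = use[best], aic = aics[best]))
      current <- cands[[best]]
      use <- setdiff(use, use[best])
    } else break
  }

  if (length(use) > 0) {
    cf <- if (method == "lmm") {
      summary(current)$coefficients
    } else {
      summary(current)$coefficients[, 1:2, drop = FALSE]
    }
    cf <- cf[rownames(cf) %in% use, , drop = FALSE]
    tab <- tibble::tibble(
      dim = match(rownames(cf), dn),
      term = rownames(cf),
      beta = unname(cf[, 1]),
      se = unname(cf[, 2]),
      z = unname(cf[, 1] / cf[, 2]),
      p_value = unname(2 * stats::pnorm(-abs(cf[, 1] / cf[, 2])))
    )
    tab$significant <- tab$p_value < p_threshold
  } else {
    tab <- tibble::tibble(dim = integer(0), term = character(0),
                          beta = numeric(0), se = numeric(0), z = numeric(0),
                          p_value = numeric(0), significant = logical(0))
  }

  re_var <- if (method == "lmm") {
    vc <- as.data.frame(lme4::VarCorr(current))
    stats::setNames(vc$vcov, vc$grp)
  } else c(.horse = NA_real_, .observer = NA_real_)

  res <- stats::residuals(current)
  ac <- tibble::tibble(h = factor(horse), r = res) |>
    dplyr::group_by(.data$h) |>
    dplyr::summarise(
      ac1 = if (dplyr::n() > 2 && stats::sd(.data$r) > 0) {
        stats::cor(.data$r[-1], .data$r[-dplyr::n()])
      } else NA_real_,
      .groups = "drop"
    )

  structure(
    list(table = tab, included_dims = match(use, dn),
         significant_dims = tab$dim[tab$significant],
         aic_trace = trace,
         re_variances = re_var,
         resid_autocorr = mean(ac$ac1, na.rm = TRUE),
         p_threshold = p_threshold, method = method,
         model = current),
    class = "dim_regression"
  )
}

#' Signed category associations of a retained dimension
#'
#' For a dimension retained in the final regression, reports each
#' category whose contribution to that dimension exceeds a threshold,
#' with the direction of its association with the asymmetry response:
#' `sign(beta_dim * category coordinate)`.  The report is invariant to
#' the sign indeterminacy of the dimension (flipping coordinates flips
#' beta).
#'
#' @param mca An [fit_mca()] result.
#' @param regression A [regress_dims()] result.
#' @param dim Dimension index.
#' @param contrib_threshold Minimum category contribution (fraction of
#'   the dimension's inertia).
#' @return A tibble `category`, `coord`, `contribution`, `association`
#'   (`"positive"`/`"negative"`), sorted by contribution.
#' @export
interpret_dim <- function(mca, regression, dim, contrib_threshold = 0.02) {
  stopifnot(inherits(mca, "mca_fit"), inherits(regression, "dim_regression"))
  if (!dim %in% regression$included_dims) {
    stop("dimension ", dim, " not in the final model", call. = FALSE)
  }
  beta <- regression$table$beta[regression$table$dim == dim]
  keep <- mca$col_contrib[, dim] >= contrib_threshold
  tibble::tibble(
    category = rownames(mca$col_coords)[keep],
    coord = mca$col_coords[keep, dim],
    contribution = mca$col_contrib[keep, dim],
    association = ifelse(beta * mca$col_coords[keep, dim] > 0,
                         "positive", "negative")
  ) |>
    dplyr::arrange(dplyr::desc(.data$contribution))
}
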