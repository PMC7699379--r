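#' Tie-corrected Kendall's coefficient of concordance
#'
#' Agreement of `m` observers ranking `n` assessments.  Scores are
#' ranked within each observer with mid-ranks for ties;
#' `W = 12 S / (m^2 (n^3 - n) - m sum(T_j))` where `S` is the sum of
#' squared deviations of the assessment rank sums from their mean and
#' `T_j = sum(t^3 - t)` over the tie groups of observer `j`.  The
#' chi-square approximation `m (n - 1) W` on `n - 1` degrees of freedom
#' gives the p-value.  When every observer's scores are completely tied
#' the denominator vanishes and W is undefined; the result is flagged
#' degenerate rather than assigned a conventional value.
#'
#' @param x Numeric matrix of ordinal scores, `n` assessments (rows) by
#'   `m` observers (columns).
#' @return A list: `w`, `chi2`, `df`, `p_value`, `n`, `m`, `degenerate`.
#' @examples
#' kendalls_w(cbind(o1 = c(0, 1, 2), o2 = c(0, 1, 2)))
#' @export
kendalls_w <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  if (n < 2) stop("need at least 2 assessments", call. = FALSE)
  if (m < 2) stop("need at least 2 observers", call. = FALSE)
  if (anyNA(x)) stop("missing scores; drop incomplete assessments first",
                     call. = FALSE)
  ranks <- apply(x, 2, rank)
  rsum <- rowSums(ranks)
  s <- sum((rsum - mean(rsum))^2)
  ties <- vapply(seq_len(m), function(j) {
    t <- table(x[, j])
    sum(t^3 - t)
  }, numeric(1))
  denom <- m^2 * (n^3 - n) - m * sum(ties)
  if (denom <= 0) {
    return(list(w = NA_real_, chi2 = NA_real_, df = n - 1L,
                p_value = NA_real_, n = n, m = m, degenerate = TRUE))
  }
  w <- 12 * s / denom
  chi2 <- m * (n - 1) * w
  list(w = w, chi2 = chi2, df = n - 1L,
       p_value = stats::pchisq(chi2, n - 1, lower.tail = FALSE),
       n = n, m = m, degenerate = FALSE)
}

#' Agreement band for a concordance coefficient
#'
#' Classifies W into the conventional agreement bands: very strong for
#' `W > 0.9`, strong for `0.7 <= W <= 0.9`, moderate for
#' `0.5 <= W < 0.7`, and weak for `W < 0.5`.  Both interval endpoints
#' 0.7 and 0.9 fall in "strong" and 0.5 in "moderate".
#'
#' @param w Numeric vector of coefficients in `[0, 1]`; `NA` passes
#'   through (degenerate items have no band).
#' @return Character vector of bands.
#' @examples
#' agreement_band(c(0.794, 0.920, 0.470))
#' @export
agreement_band <- function(w) {
  if (any(!is.na(w) & (w < 0 | w > 1))) {
    stop("W must lie in [0, 1]", call. = FALSE)
  }
  dplyr::case_when(
    is.na(w) ~ NA_character_,
    w > 0.9 ~ "very_strong",
    w >= 0.7 ~ "strong",
    w >= 0.5 ~ "moderate",
    .default = "weak"
  )
}

#' Per-item inter-observer reliability report
#'
#' Computes tie-corrected Kendall's W for every behavioral scale item in
#' a long score table, pooling assessments across horses, occasions and
#' phases.  Physiological CPS items are excluded (they are objectively
#' measured, not observer judgments).  For each item, observers with no
#' scores at all are dropped, then only assessments scored by all
#' remaining observers are used.
#'
#' @param scores Long score table (`horse`, `occasion`, `phase`,
#'   `observer`, `scale`, `item`, `score`).
#' @param scales Scale registry, as returned by [pain_scales()].
#' @return A tibble with one row per behavioral item: `scale`, `item`,
#'   `n_used`, `m_observers`, `w`, `chi2`, `df`, `p_value`, `band`,
#'   `degenerate`.
#' @export
reliability_report <- function(scores, scales = pain_scales()) {
  viol <- validate_scores(scores, scales)
  if (nrow(viol) > 0) {
    stop("score table has ", nrow(viol),
         " violation(s); run validate_scores()", call. = FALSE)
  }
  behavioral <- scales[scales$behavioral, c("scale", "item")]
  keyed <- dplyr::inner_join(scores, behavioral, by = c("scale", "item"))
  purrr::map_dfr(seq_len(nrow(behavioral)), function(i) {
    sc <- behavioral$scale[i]
    it <- behavioral$item[i]
    wide <- keyed |>
      dplyr::filter(.data$scale == sc, .data$item == it) |>
      tidyr::pivot_wider(id_cols = c("horse", "occasion", "phase"),
                         names_from = "observer", values_from = "score")
    obs_cols <- setdiff(names(wide), c("horse", "occasion", "phase"))
    obs_cols <- obs_cols[colSums(!is.na(wide[obs_cols])) > 0]
    mat <- as.matrix(wide[obs_cols])
    mat <- mat[stats::complete.cases(mat), , drop = FALSE]
    if (nrow(mat) < 2 || ncol(mat) < 2) {
      return(tibble::tibble(scale = sc, item = it, n_used = nrow(mat),
                            m_observers = ncol(mat), w = NA_real_,
                            chi2 = NA_real_, df = NA_integer_,
                            p_value = NA_real_, band = NA_character_,
                            degenerate = TRUE))
    }
    res <- kendalls_w(mat)
    tibble::tibble(scale = sc, item = it, n_used = res$n,
                   m_observers = res$m, w = res$w, chi2 = res$chi2,
                   df = as.integer(res$df), p_value = res$p_value,
                   band = agreement_band(res$w), degenerate = res$degenerate)
  })
}
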