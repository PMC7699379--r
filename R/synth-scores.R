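#' Trial design for synthetic pain assessments
#'
#' Describes a synthetic induction study: horses, occasions (baseline
#' `b0` then post-induction `p1`, `p2`, ...), observers, the true total
#' asymmetry score trajectory of each horse (rising from ~0 to an
#' individual peak then declining, mirroring a transient synovitis), and
#' the latent-variable model coupling scale items to asymmetry.
#'
#' Scores are generated from a thresholded-Gaussian ordinal model: for
#' each horse x occasion x phase x observer x item,
#' `latent = effect(item) * a + horse_effect + observer_noise`, where `a`
#' is the horse-occasion true asymmetry score normalized to `[0, 1]`, and
#' the latent value is cut at the scale's ordinal thresholds into the
#' item's score range.
#'
#' @param n_horses Number of horses (study default 8).
#' @param n_observers Observers per assessment (study default 3; two core
#'   observers plus one rotating).
#' @param n_post_occasions Post-induction occasions (>= 3).
#' @param asymmetry_trajectory Optional tibble `horse`, `occasion`,
#'   `true_score_mm` (total asymmetry score, 0 at baseline).  If `NULL` a
#'   rise-and-fall trajectory is drawn per horse with peak ~ N(61, 24) mm
#'   truncated at 20 mm.
#' @param item_effects Named numeric vector of latent effects, keyed
#'   `"SCALE:item"` (e.g. `c("EPS:pos" = 2)`); unnamed items have zero
#'   effect.  `NULL` means the package default set of posture, location,
#'   focus, orbital and physiological effects.
#' @param observer_noise_sd Observer noise on the latent scale.
#' @param horse_effect_sd Between-horse random shift on the latent scale.
#' @param ordinal_thresholds Named list of strictly increasing cut points
#'   per scale (length equal to the scale's max score).  `NULL` for
#'   defaults.
#' @param n_repeats Straight-line trot repeats per occasion (1 or 2).
#' @param rotate_observers If `TRUE`, two core observers are present for
#'   every assessment and the third slot rotates across horses among a
#'   pool of three (as in a live study where extra raters attend by
#'   availability).  The default `FALSE` keeps one fixed observer panel,
#'   which is what pooled per-item concordance requires.
#' @param seed Integer seed.
#' @return A validated list of class `trial_design`.
#' @export
trial_design <- function(n_horses = 8,
                         n_observers = 3,
                         n_post_occasions = 4,
                         asymmetry_trajectory = NULL,
                         item_effects = NULL,
                         observer_noise_sd = 0.5,
                         horse_effect_sd = 0.5,
                         ordinal_thresholds = NULL,
                         n_repeats = 1,
                         rotate_observers = FALSE,
                         seed = 1L) {
  if (n_post_occasions < 3) stop("need >= 3 post-induction occasions", call. = FALSE)
  if (n_horses < 1 || n_observers < 2) stop("invalid design size", call. = FALSE)
  if (!n_repeats %in% c(1, 2)) stop("n_repeats must be 1 or 2", call. = FALSE)
  if (is.null(item_effects)) {
    item_effects <- c("EPS:pos" = 2, "CPS:pos" = 2, "EPS:loc" = 1.2,
                      "EQUUS_FAP:focus" = 1.5, "HGS:orb" = 1,
                      "CPS:temp" = 1.5, "CPS:heart_rate" = 1)
  }
  if (is.null(ordinal_thresholds)) {
    ordinal_thresholds <- list(
      HGS = c(0.7, 1.6),
      EQUUS_FAP = c(0.7, 1.6),
      EPS = c(0.7, 1.25, 1.8, 2.35),
      CPS = c(0.7, 1.4, 2.1)
    )
  }
  for (sc in names(ordinal_thresholds)) {
    th <- ordinal_thresholds[[sc]]
    if (any(diff(th) <= 0)) {
      stop("ordinal thresholds for ", sc, " must be strictly increasing",
           call. = FALSE)
    }
  }
  d <- list(n_horses = n_horses, n_observers = n_observers,
            n_post_occasions = n_post_occasions,
            asymmetry_trajectory = asymmetry_trajectory,
            item_effects = item_effects,
            observer_noise_sd = observer_noise_sd,
            horse_effect_sd = horse_effect_sd,
            ordinal_thresholds = ordinal_thresholds,
            n_repeats = n_repeats, rotate_observers = rotate_observers,
            seed = seed)
  if (is.null(d$asymmetry_trajectory)) {
    d$asymmetry_trajectory <- default_trajectory(n_horses, n_post_occasions,
                                                 seed)
  }
  traj <- d$asymmetry_trajectory
  stopifnot(all(c("horse", "occasion", "true_score_mm") %in% names(traj)))
  chk <- traj |>
    dplyr::mutate(occasion = factor(.data$occasion,
                                    occasion_levels(.data$occasion))) |>
    dplyr::arrange(.data$horse, .data$occasion) |>
    dplyr::group_by(.data$horse) |>
    dplyr::summarise(
      starts_low = dplyr::first(.data$true_score_mm) <
        max(.data$true_score_mm) / 4 + 1e-9,
      .groups = "drop"
    )
  if (!all(chk$starts_low)) {
    stop("each horse's trajectory must start near 0", call. = FALSE)
  }
  structure(d, class = "trial_design")
}

# per-horse rise-and-fall total asymmetry score trajectories, plus the
# induced side (3:5 left:right split at the study size)
default_trajectory <- function(n_horses, n_post, seed) {
  with_seed(child_seed(seed, 17), {
    peaks <- pmax(20, stats::rnorm(n_horses, mean = 61, sd = 24))
    n_left <- round(n_horses * 3 / 8)
    sides <- sample(rep(c(-1, 1), c(n_left, n_horses - n_left)))
    peak_at <- sample(seq(max(2, ceiling(n_post / 2)), n_post - 1),
                      n_horses, replace = TRUE)
    purrr::map_dfr(seq_len(n_horses), function(h) {
      k <- peak_at[h]
      shape <- c(0, vapply(seq_len(n_post), function(j) {
        if (j <= k) 0.25 + 0.75 * (j - 1) / max(1, k - 1) else
          max(0.15, 1 - 0.35 * (j - k))
      }, numeric(1)))
      shape[2] <- if (k == 1) 1 else shape[2]
      tibble::tibble(
        horse = sprintf("h%d", h),
        occasion = c("b0", sprintf("p%d", seq_len(n_post))),
        true_score_mm = peaks[h] * shape,
        side = sides[h]
      )
    })
  })
}

#' Simulate observer score tables
#'
#' Draws a long-format ordinal score table for every horse x occasion x
#' phase (pre/post) x observer x scale item under the latent-variable
#' model described in [trial_design()].  The ground truth (per-horse
#' asymmetry trajectory, item effects, horse effects) is attached as
#' attribute `"truth"` and retrievable with [score_truth()].
#'
#' @param design A [trial_design()].
#' @param scales Scale registry, as returned by [pain_scales()].
#' @return A tibble with columns `horse`, `occasion`, `phase`,
#'   `observer`, `scale`, `item`, `score`.
#' @export
simulate_scores <- function(design = trial_design(), scales = pain_scales()) {
  stopifnot(inherits(design, "trial_design"))
  for (sc in unique(scales$scale)) {
    th <- design$ordinal_thresholds[[sc]]
    maxs <- unique(scales$max_score[scales$scale == sc])
    if (is.null(th) || length(th) != maxs) {
      stop("ordinal thresholds for ", sc, " must have length ", maxs,
           call. = FALSE)
    }
  }
  traj <- design$asymmetry_trajectory
  amax <- max(traj$true_score_mm)
  traj$norm_asym <- if (amax > 0) traj$true_score_mm / amax else 0

  horses <- sprintf("h%d", seq_len(design$n_horses))
  grid <- tidyr::expand_grid(
    horse = horses,
    occasion = c("b0", sprintf("p%d", seq_len(design$n_post_occasions))),
    phase = c("pre", "post")
  )
  grid <- dplyr::inner_join(grid, traj[, c("horse", "occasion", "norm_asym")],
                            by = c("horse", "occasion"))

  obs_for_horse <- function(h_idx) {
    if (isTRUE(design$rotate_observers) && design$n_observers == 3) {
      c("o1", "o2", sprintf("o%d", 3 + (h_idx - 1) %% 3))
    } else {
      sprintf("o%d", seq_len(design$n_observers))
    }
  }

  eff_key <- paste(scales$scale, scales$item, sep = ":")
  effects <- design$item_effects[match(eff_key, names(design$item_effects))]
  effects[is.na(effects)] <- 0

  out <- with_seed(child_seed(design$seed, 29), {
    horse_effect <- stats::rnorm(design$n_horses,
                                 sd = design$horse_effect_sd)
    names(horse_effect) <- horses
    rows <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
      h <- grid$horse[i]
      obs <- obs_for_horse(match(h, horses))
      tidyr::expand_grid(observer = obs, idx = seq_len(nrow(scales))) |>
        dplyr::mutate(
          horse = h, occasion = grid$occasion[i], phase = grid$phase[i],
          scale = scales$scale[.data$idx], item = scales$item[.data$idx],
          latent = effects[.data$idx] * grid$norm_asym[i] +
            horse_effect[h] +
            stats::rnorm(dplyr::n(), sd = design$observer_noise_sd)
        )
    })
    th_list <- design$ordinal_thresholds
    maxs <- scales$max_score[match(paste(rows$scale, rows$item, sep = ":"),
                                   eff_key)]
    score <- vapply(seq_len(nrow(rows)), function(i) {
      sum(rows$latent[i] > th_list[[rows$scale[i]]])
    }, numeric(1))
    rows$score <- as.integer(pmin(score, maxs))
    rows[, c("horse", "occasion", "phase", "observer", "scale", "item",
             "score")]
  })
  out <- tibble::as_tibble(out)
  attr(out, "truth") <- list(
    asymmetry = traj,
    item_effects = design$item_effects,
    design = design
  )
  out
}

#' Ground truth of a simulated score table
#'
#' @param scores A table produced by [simulate_scores()].
#' @return The attached truth record: asymmetry trajectory, item effects
#'   and the generating design.
#' @export
score_truth <- function(scores) {
  truth <- attr(scores, "truth")
  if (is.null(truth)) stop("no ground-truth record attached", call. = FALSE)
  truth
}
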