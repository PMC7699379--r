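#' Zero-phase Butterworth low-pass filter
#'
#' Filters a marker displacement series with a fourth-order Butterworth
#' filter applied forward and backward (zero phase lag), with the cutoff
#' adjusted to the horse's stride frequency: `cutoff = cutoff_multiplier
#' * stride_frequency`.  The default multiplier of 6 keeps at least three
#' harmonics of the dominant twice-per-stride displacement component.
#'
#' @param x Numeric signal (mm), uniformly sampled.
#' @param sampling_rate Sampling rate (Hz).
#' @param stride_frequency Stride frequency (Hz).
#' @param order Filter order (default 4).
#' @param cutoff_multiplier Cutoff as a multiple of stride frequency.
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_filter <- function(x, sampling_rate, stride_frequency, order = 4,
                           cutoff_multiplier = 6) {
  cutoff <- cutoff_multiplier * stride_frequency
  if (cutoff >= sampling_rate / 2) {
    stop("cutoff frequency at or above Nyquist", call. = FALSE)
  }
  if (length(x) <= 6 * order) {
    stop("signal too short to filter", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (sampling_rate / 2), type = "low")
  # odd-symmetric reflection padding so the forward-backward pass starts
  # from a continuation of the signal instead of zero state (edge
  # transients would otherwise bleed into the outer strides)
  n <- length(x)
  pad <- min(n - 1, ceiling(6 * sampling_rate / cutoff))
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- as.numeric(signal::filtfilt(bf, c(head_pad, x, tail_pad)))
  y[(pad + 1):(pad + n)]
}

#' Estimate stride frequency from the pelvis signal
#'
#' At trot the pelvis oscillates vertically twice per stride, so the
#' dominant spectral peak of the mean-removed tubera sacrale signal lies
#' at twice the stride frequency.  The peak location is refined by
#' parabolic interpolation of the periodogram.
#'
#' @param pelvis Vertical displacement of the tubera sacrale (mm).
#' @param sampling_rate Sampling rate (Hz).
#' @param bounds Physiologic stride-frequency bounds (Hz).
#' @return Stride frequency (Hz).
#' @export
estimate_stride_frequency <- function(pelvis, sampling_rate,
                                      bounds = c(0.5, 2.5)) {
  x <- pelvis - mean(pelvis)
  n <- length(x)
  if (n < 8 || stats::var(x) < 1e-12) {
    stop("degenerate pelvis signal: no oscillation to segment", call. = FALSE)
  }
  spec <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1) * sampling_rate / n
  keep <- freq >= bounds[1] & freq <= 2 * bounds[2]
  if (!any(keep)) stop("no spectral support in stride-frequency bounds",
                       call. = FALSE)
  idx <- which(keep)[which.max(spec[keep])]
  if (spec[idx] < 1e-9 * sum(spec)) {
    stop("no dominant spectral peak in stride-frequency bounds",
         call. = FALSE)
  }
  # the dominant component is the twice-per-stride oscillation for mild
  # asymmetry but can be the once-per-stride component when the minima
  # difference rivals the base amplitude; disambiguate by comparing the
  # power near twice the dominant frequency with the power near half of
  # it — a strong first harmonic above marks the dominant peak as the
  # once-per-stride component
  band_power <- function(f0) {
    j <- which(abs(freq - f0) <= 1.5 * sampling_rate / n & freq > 0)
    if (length(j) == 0) 0 else max(spec[j])
  }
  fd <- freq[idx]
  if (band_power(2 * fd) > band_power(fd / 2) &&
      band_power(2 * fd) > 0.05 * spec[idx]) {
    two_f <- which(abs(freq - 2 * fd) <= 1.5 * sampling_rate / n & freq > 0)
    idx <- two_f[which.max(spec[two_f])]
  }
  # parabolic refinement over log-power of the three bins around the peak
  f2 <- freq[idx]
  if (idx > 1 && idx < n) {
    y <- log(spec[(idx - 1):(idx + 1)] + 1e-300)
    denom <- y[1] - 2 * y[2] + y[3]
    if (is.finite(denom) && denom < 0) {
      delta <- 0.5 * (y[1] - y[3]) / denom
      f2 <- f2 + delta * sampling_rate / n
    }
  }
  f <- f2 / 2
  if (f < bounds[1] || f > bounds[2]) {
    stop("estimated stride frequency outside physiologic bounds",
         call. = FALSE)
  }
  f
}

# local maxima with topographic prominence and a minimum spacing;
# returns sorted sample indices
find_peaks <- function(x, min_dist, min_prominence) {
  n <- length(x)
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(p) {
    left <- x[seq_len(p - 1)]
    right <- x[seq(min(p + 1, n), n)]
    higher_l <- which(left > x[p])
    higher_r <- which(right > x[p])
    base_l <- if (length(higher_l)) min(x[(max(higher_l) + 1):(p - 1)]) else
      min(left)
    base_r <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1)]) else
      min(right)
    x[p] - max(base_l, base_r)
  }, numeric(1))
  cand <- cand[prom >= min_prominence]
  if (length(cand) == 0) return(integer(0))
  # greedy enforcement of minimum spacing, keeping the taller peak
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord) {
    if (all(abs(kept - p) >= min_dist)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Segment strides from the filtered pelvis signal
#'
#' Detects peaks of the filtered tubera sacrale displacement (one peak
#' per half-stride at trot) with prominence at least 20% of the signal's
#' interquartile range and minimum spacing `spacing_frac /
#' stride_frequency` seconds.  A stride spans two consecutive vertical
#' oscillations, i.e. every second peak is a stride boundary; incomplete
#' edge strides are discarded.  The default spacing fraction of 0.35
#' rejects noise-induced spurious peaks while keeping the genuine
#' half-stride peaks, whose spacing contracts below 0.4 of the stride
#' period once a severe asymmetry shifts the peak positions.
#'
#' @param pelvis Filtered pelvis signal (mm).
#' @param sampling_rate Sampling rate (Hz).
#' @param stride_frequency Stride frequency (Hz).
#' @param min_prominence_frac Peak prominence threshold as a fraction of
#'   the signal IQR.
#' @param spacing_frac Minimum peak spacing as a fraction of the stride
#'   period.
#' @return An object of class `stride_segmentation`: peak indices, a
#'   stride table, and a half-stride table (sides unassigned until
#'   [assign_sides()]).
#' @export
segment_strides <- function(pelvis, sampling_rate, stride_frequency,
                            min_prominence_frac = 0.2,
                            spacing_frac = 0.35) {
  min_dist <- round(spacing_frac / stride_frequency * sampling_rate)
  min_prom <- min_prominence_frac * stats::IQR(pelvis)
  peaks <- find_peaks(pelvis, min_dist, min_prom)
  n_strides <- (length(peaks) - 1) %/% 2
  if (n_strides < 1) {
    stop("fewer than one complete stride detected", call. = FALSE)
  }
  strides <- tibble::tibble(
    stride = seq_len(n_strides),
    start = peaks[2 * seq_len(n_strides) - 1],
    mid = peaks[2 * seq_len(n_strides)],
    end = peaks[2 * seq_len(n_strides) + 1]
  )
  halves <- tibble::tibble(
    stride = rep(strides$stride, each = 2),
    half = rep(c(1L, 2L), n_strides),
    start = as.vector(rbind(strides$start, strides$mid)),
    end = as.vector(rbind(strides$mid, strides$end)),
    side = NA_character_
  )
  structure(
    list(peaks = peaks, strides = strides, halves = halves,
         stride_frequency = stride_frequency,
         sampling_rate = sampling_rate),
    class = "stride_segmentation"
  )
}

#' Assign stance sides to half-strides from pelvic roll
#'
#' Labels each half-stride left or right by the sign of the mean pelvic
#' roll over the half-stride window: positive mean roll marks the
#' right-stance half (the convention shared with the simulator).  Yaw is
#' accepted for interface completeness but not used by the default rule.
#' Half-strides whose mean roll magnitude falls below 10% of the roll
#' amplitude are ambiguous; they are filled by alternation from the
#' nearest confident half-stride, with a warning.
#'
#' @param segmentation A [segment_strides()] result.
#' @param roll Pelvic roll series (deg), synchronized with the pelvis
#'   signal.
#' @param yaw Optional pelvic yaw series (deg); ingested, not used.
#' @return The segmentation with `halves$side` filled in.
#' @export
assign_sides <- function(segmentation, roll, yaw = NULL) {
  stopifnot(inherits(segmentation, "stride_segmentation"))
  h <- segmentation$halves
  mroll <- vapply(seq_len(nrow(h)), function(i) {
    mean(roll[h$start[i]:(h$end[i] - 1)])
  }, numeric(1))
  amp <- max(abs(roll))
  confident <- abs(mroll) > 0.1 * amp & amp > 0
  side <- ifelse(mroll > 0, "right", "left")
  if (!any(confident)) {
    warning("pelvic roll ambiguous everywhere; falling back to alternation",
            call. = FALSE)
    side <- rep(c("left", "right"), length.out = nrow(h))
  } else if (!all(confident)) {
    warning(sum(!confident),
            " half-stride(s) with ambiguous roll; filled by alternation",
            call. = FALSE)
    anchor <- which(confident)[1]
    parity <- (seq_len(nrow(h)) - anchor) %% 2
    side <- ifelse(parity == 0, side[anchor],
                   setdiff(c("left", "right"), side[anchor]))
    side[confident] <- ifelse(mroll[confident] > 0, "right", "left")
  }
  segmentation$halves$side <- side
  segmentation
}

#' Per-stride difference between the two displacement minima
#'
#' For each stride, locates the displacement minimum during the
#' right-stance half and during the left-stance half and returns the
#' signed difference `min_right - min_left` (mm): the pelvis (or head)
#' drops lower during the sound stance, so a shallower left minimum —
#' a left-sided asymmetry — gives a negative value.  If two equal minima
#' occur in a half, the earlier sample is taken.  Strides whose minima
#' fall on a window edge (no interior minimum) are excluded and counted.
#'
#' @param x Filtered displacement signal (mm), e.g. sacrale or poll.
#' @param segmentation A side-assigned [segment_strides()] result.
#' @return A list with `per_stride` (tibble `stride`, `min_left`,
#'   `min_right`, `diff_mm`), `mean_mm`, `n_used`, `n_excluded`.
#' @export
compute_min_diff <- function(x, segmentation) {
  stopifnot(inherits(segmentation, "stride_segmentation"))
  h <- segmentation$halves
  if (anyNA(h$side)) stop("sides not assigned; call assign_sides() first",
                          call. = FALSE)
  per <- purrr::map_dfr(unique(h$stride), function(s) {
    hs <- h[h$stride == s, ]
    mins <- vapply(seq_len(nrow(hs)), function(i) {
      win <- hs$start[i]:hs$end[i]
      j <- win[which.min(x[win])]
      # require an interior minimum
      if (j == hs$start[i] || j == hs$end[i]) NA_real_ else x[j]
    }, numeric(1))
    tibble::tibble(
      stride = s,
      min_left = mins[hs$side == "left"][1],
      min_right = mins[hs$side == "right"][1]
    )
  })
  per$diff_mm <- per$min_right - per$min_left
  ok <- stats::complete.cases(per)
  list(
    per_stride = per[ok, ],
    mean_mm = mean(per$diff_mm[ok]),
    n_used = sum(ok),
    n_excluded = sum(!ok)
  )
}

#' Total movement asymmetry
#'
#' Combines the mean head and pelvis minima differences of a measurement
#' into a single magnitude: `|HDmin / 2| + |PDmin|` (mm).  Halving the
#' head term weights the two landmarks comparably, since head vertical
#' asymmetry runs roughly twice the pelvic one for an equivalent
#' hindlimb deficit.
#'
#' @param hd_min_mm Mean head minima difference (signed mm).
#' @param pd_min_mm Mean pelvis minima difference (signed mm).
#' @return Total asymmetry (mm, non-negative).
#' @examples
#' total_asymmetry(-10, 20) # 25
#' @export
total_asymmetry <- function(hd_min_mm, pd_min_mm) {
  stopifnot(is.finite(hd_min_mm), is.finite(pd_min_mm))
  abs(hd_min_mm / 2) + abs(pd_min_mm)
}

#' Measure movement asymmetry of one trot trial
#'
#' Full per-trial kinematic chain: stride-frequency estimation from the
#' sacrale signal, zero-phase low-pass filtering of head and pelvis
#' signals, stride segmentation on the filtered pelvis signal, side
#' assignment from pelvic roll, and the per-stride minima differences.
#' Head minima are located within the pelvis-defined stride windows (the
#' poll signal is noisier and is not segmented independently).
#'
#' @param traj A trajectory tibble with columns `time_s`, `poll_z_mm`,
#'   `sacrale_z_mm`, `roll_deg` (as written by [simulate_gait()]).
#' @param cutoff_multiplier Low-pass cutoff as a multiple of stride
#'   frequency.
#' @param min_prominence_frac Peak prominence threshold (fraction of
#'   IQR).
#' @return A one-row tibble: `hd_min_mm`, `pd_min_mm`,
#'   `total_asymmetry_mm`, `n_strides_used`, `stride_frequency_hz`.
#' @export
measure_asymmetry <- function(traj, cutoff_multiplier = 6,
                              min_prominence_frac = 0.2) {
  need <- c("time_s", "poll_z_mm", "sacrale_z_mm", "roll_deg")
  stopifnot(all(need %in% names(traj)))
  sr <- 1 / stats::median(diff(traj$time_s))
  f <- estimate_stride_frequency(traj$sacrale_z_mm, sr)
  pelvis_f <- lowpass_filter(traj$sacrale_z_mm, sr, f,
                             cutoff_multiplier = cutoff_multiplier)
  poll_f <- lowpass_filter(traj$poll_z_mm, sr, f,
                           cutoff_multiplier = cutoff_multiplier)
  seg <- segment_strides(pelvis_f, sr, f,
                         min_prominence_frac = min_prominence_frac)
  seg <- assign_sides(seg, traj$roll_deg)
  pd <- compute_min_diff(pelvis_f, seg)
  hd <- compute_min_diff(poll_f, seg)
  tibble::tibble(
    hd_min_mm = hd$mean_mm,
    pd_min_mm = pd$mean_mm,
    total_asymmetry_mm = total_asymmetry(hd$mean_mm, pd$mean_mm),
    n_strides_used = pd$n_used,
    stride_frequency_hz = f
  )
}

#' Total asymmetry score relative to baseline
#'
#' The change in total movement asymmetry from the horse's baseline
#' measurement; the pain proxy used by the selection and regression
#' stages.  The baseline occasion scores 0 by construction; occasions
#' where asymmetry fell below baseline get negative scores.
#'
#' @param measurements A tibble with columns `horse`, `occasion`,
#'   `total_asymmetry_mm` (one row per measurement; a `trot_repeat`
#'   column is carried through if present).
#' @param baseline Occasion id of the baseline measurement.
#' @return The input with a `score_mm` column appended.
#' @export
asymmetry_score <- function(measurements, baseline = "b0") {
  stopifnot(all(c("horse", "occasion", "total_asymmetry_mm") %in%
                  names(measurements)))
  base <- measurements |>
    dplyr::filter(.data$occasion == baseline) |>
    dplyr::group_by(.data$horse) |>
    dplyr::summarise(baseline_mm = mean(.data$total_asymmetry_mm),
                     .groups = "drop")
  missing <- setdiff(unique(measurements$horse), base$horse)
  if (length(missing) > 0) {
    stop("missing baseline occasion for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  measurements |>
    dplyr::left_join(base, by = "horse") |>
    dplyr::mutate(score_mm = .data$total_asymmetry_mm - .data$baseline_mm) |>
    dplyr::select(-"baseline_mm")
}
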