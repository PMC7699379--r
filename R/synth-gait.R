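#' Gait simulation parameters
#'
#' Bundles and validates the parameters of the synthetic trot generator.
#' The vertical displacement of pelvis (tubera sacrale) and head (poll)
#' markers is modeled per stride of period `T = 1/stride_frequency` as a
#' dominant half-stride oscillation plus a once-per-stride component:
#'
#' \deqn{z(t) = -A\cos(4\pi f t) + (d/2)\cos(2\pi f t) + \epsilon(t)}
#'
#' where `A` is `base_amplitude_mm` and `d` the injected asymmetry.  The
#' two minima of the noiseless signal are exactly `-A + d/2` (right-stance
#' half) and `-A - d/2` (left-stance half), so the signed minima
#' difference (right minus left) equals `d` in closed form.  Negative `d`
#' therefore encodes a left-sided asymmetry, matching the downstream sign
#' convention.  Pelvic roll is a once-per-stride sinusoid
#' `roll_amplitude_deg * cos(2 pi f t)` phase-locked so that its mean is
#' positive over the right-stance half and negative over the left-stance
#' half; side assignment shares this convention.
#'
#' @param stride_frequency Strides per second (Hz); trot is ~1.1--1.5 Hz.
#' @param n_strides Number of strides to simulate (>= 3).
#' @param sampling_rate Samples per second (Hz); motion capture at 200 Hz.
#' @param head_asym_mm Injected head minima difference (signed mm,
#'   negative = left-sided).
#' @param pelvis_asym_mm Injected pelvis minima difference (signed mm).
#' @param base_amplitude_mm Amplitude of the half-stride vertical
#'   oscillation (mm); sound trot pelvis motion is on the order of tens
#'   of mm.
#' @param noise_sd_mm Additive Gaussian noise on the vertical signals (mm).
#' @param roll_amplitude_deg Amplitude of the pelvic roll sinusoid (deg).
#' @param seed Integer seed; trajectories are reproducible from it.
#' @return A validated list of class `gait_params`.
#' @export
gait_params <- function(stride_frequency = 1.3,
                        n_strides = 20,
                        sampling_rate = 200,
                        head_asym_mm = 0,
                        pelvis_asym_mm = 0,
                        base_amplitude_mm = 40,
                        noise_sd_mm = 2,
                        roll_amplitude_deg = 4,
                        seed = 1L) {
  p <- list(stride_frequency = stride_frequency, n_strides = n_strides,
            sampling_rate = sampling_rate, head_asym_mm = head_asym_mm,
            pelvis_asym_mm = pelvis_asym_mm,
            base_amplitude_mm = base_amplitude_mm, noise_sd_mm = noise_sd_mm,
            roll_amplitude_deg = roll_amplitude_deg, seed = seed)
  if (!is.numeric(stride_frequency) || stride_frequency <= 0) {
    stop("stride_frequency must be > 0", call. = FALSE)
  }
  if (sampling_rate < 20 * stride_frequency) {
    stop("sampling_rate must be at least 20 x stride_frequency", call. = FALSE)
  }
  if (n_strides < 3) stop("n_strides must be >= 3", call. = FALSE)
  if (base_amplitude_mm <= 0) stop("base_amplitude_mm must be > 0", call. = FALSE)
  if (noise_sd_mm < 0) stop("noise_sd_mm must be >= 0", call. = FALSE)
  # the once-per-stride component must stay small enough that the signal
  # keeps two minima per stride: |d/2| < 4A
  if (abs(pelvis_asym_mm) / 2 >= 4 * base_amplitude_mm ||
      abs(head_asym_mm) / 2 >= 4 * base_amplitude_mm) {
    stop("asymmetry too large for base amplitude (needs |d|/2 < 4A)",
         call. = FALSE)
  }
  structure(p, class = "gait_params")
}

#' Simulate a straight-line trot trial
#'
#' Generates synchronized vertical displacement series for the poll and
#' tubera sacrale markers, companion tubera coxae signals, and pelvic
#' roll/yaw rotations, with known injected head and pelvis asymmetries
#' (see [gait_params()] for the signal model and sign convention).
#'
#' @param params A [gait_params()] object.
#' @return A tibble with columns `time_s`, `poll_z_mm`, `sacrale_z_mm`,
#'   `left_tc_z_mm`, `right_tc_z_mm`, `roll_deg`, `yaw_deg`; the
#'   parameters are attached as attribute `"params"`.
#' @examples
#' traj <- simulate_gait(gait_params(pelvis_asym_mm = -20, noise_sd_mm = 0))
#' @export
simulate_gait <- function(params = gait_params()) {
  stopifnot(inherits(params, "gait_params"))
  f <- params$stride_frequency
  sr <- params$sampling_rate
  t <- seq(0, params$n_strides / f, by = 1 / sr)
  w <- 2 * pi * f
  A <- params$base_amplitude_mm
  pelvis <- -A * cos(2 * w * t) + (params$pelvis_asym_mm / 2) * cos(w * t)
  poll <- -A * cos(2 * w * t) + (params$head_asym_mm / 2) * cos(w * t)
  roll <- params$roll_amplitude_deg * cos(w * t)
  yaw <- 0.5 * params$roll_amplitude_deg * sin(w * t)
  # tubera coxae move with the pelvis plus an antiphase roll-driven offset
  tc_off <- 0.2 * A * cos(w * t)
  out <- with_seed(params$seed, {
    n <- length(t)
    noise <- function(sd) if (sd > 0) stats::rnorm(n, sd = sd) else 0
    tibble::tibble(
      time_s = t,
      poll_z_mm = poll + noise(params$noise_sd_mm),
      sacrale_z_mm = pelvis + noise(params$noise_sd_mm),
      left_tc_z_mm = pelvis - tc_off + noise(params$noise_sd_mm),
      right_tc_z_mm = pelvis + tc_off + noise(params$noise_sd_mm),
      roll_deg = roll + noise(params$noise_sd_mm * 0.02),
      yaw_deg = yaw + noise(params$noise_sd_mm * 0.02)
    )
  })
  attr(out, "params") <- params
  out
}
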