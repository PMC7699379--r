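test_that("zero-phase filter preserves the passband and contracts noise", {
  sr <- 200
  f <- 1.3
  t <- seq(0, 10, by = 1 / sr)
  # displacement component at 2f sits well inside the 6f cutoff
  x <- sin(2 * pi * 2 * f * t)
  y <- lowpass_filter(x, sr, f)
  mid <- 500:1500  # avoid edges
  expect_equal(max(abs(y[mid])), 1, tolerance = 0.01)
  set.seed(1)
  noise <- rnorm(length(t))
  expect_lt(var(lowpass_filter(noise, sr, f)), var(noise))
  expect_equal(lowpass_filter(rep(3, 500), sr, f), rep(3, 500),
               tolerance = 1e-8)
  expect_error(lowpass_filter(x, 10, f), "Nyquist")
})

test_that("stride frequency is recovered from pelvis oscillation", {
  for (f in c(1.1, 1.3, 1.5)) {
    tr <- simulate_gait(gait_params(stride_frequency = f, noise_sd_mm = 2,
                                    seed = 3))
    expect_equal(estimate_stride_frequency(tr$sacrale_z_mm, 200), f,
                 tolerance = 0.05 / f)
  }
  # a pure 2.6 Hz oscillation is two pelvis drops per stride at 1.3 Hz
  t <- seq(0, 12, by = 1 / 200)
  expect_equal(estimate_stride_frequency(sin(2 * pi * 2.6 * t), 200), 1.3,
               tolerance = 0.01)
  expect_error(estimate_stride_frequency(rep(0, 1000), 200), "degenerate")
})

test_that("stride segmentation finds near-all complete strides", {
  p <- gait_params(n_strides = 20, pelvis_asym_mm = 10, noise_sd_mm = 0)
  tr <- simulate_gait(p)
  f <- estimate_stride_frequency(tr$sacrale_z_mm, 200)
  seg <- segment_strides(lowpass_filter(tr$sacrale_z_mm, 200, f), 200, f)
  expect_gte(nrow(seg$strides), 18)
  expect_lte(nrow(seg$strides), 20)
  expect_true(all(diff(seg$peaks) > 0))
  expect_error(
    segment_strides(lowpass_filter(tr$sacrale_z_mm[1:80], 200, f), 200, f),
    "stride")
})

test_that("doubling the sampling rate leaves the stride count unchanged", {
  n_strides <- function(sr) {
    tr <- simulate_gait(gait_params(sampling_rate = sr, n_strides = 15,
                                    pelvis_asym_mm = 15, noise_sd_mm = 1,
                                    seed = 8))
    measure_asymmetry(tr)$n_strides_used
  }
  expect_equal(n_strides(200), n_strides(400))
})

test_that("sides come from pelvic roll and flip with it", {
  tr <- simulate_gait(gait_params(pelvis_asym_mm = -20, noise_sd_mm = 0))
  f <- 1.3
  pf <- lowpass_filter(tr$sacrale_z_mm, 200, f)
  seg <- assign_sides(segment_strides(pf, 200, f), tr$roll_deg)
  expect_true(all(seg$halves$side %in% c("left", "right")))
  # sides alternate within every stride
  by_stride <- split(seg$halves$side, seg$halves$stride)
  expect_true(all(vapply(by_stride, function(s) s[1] != s[2], logical(1))))
  flipped <- assign_sides(segment_strides(pf, 200, f), -tr$roll_deg)
  expect_true(all(flipped$halves$side != seg$halves$side))
  expect_warning(assign_sides(segment_strides(pf, 200, f),
                              rep(0, nrow(tr))), "ambiguous")
})

test_that("minima differences recover the injected asymmetry", {
  m <- measure_asymmetry(simulate_gait(gait_params(
    pelvis_asym_mm = -30, head_asym_mm = 0, noise_sd_mm = 0)))
  expect_equal(m$pd_min_mm, -30, tolerance = 0.1)
  m0 <- measure_asymmetry(simulate_gait(gait_params(
    pelvis_asym_mm = 0, noise_sd_mm = 0)))
  expect_lt(abs(m0$pd_min_mm), 1e-3)
})

test_that("flipping the side flips signs but not total asymmetry", {
  m_l <- measure_asymmetry(simulate_gait(gait_params(
    pelvis_asym_mm = -24, head_asym_mm = -12, noise_sd_mm = 0)))
  m_r <- measure_asymmetry(simulate_gait(gait_params(
    pelvis_asym_mm = 24, head_asym_mm = 12, noise_sd_mm = 0)))
  expect_equal(m_l$pd_min_mm, -m_r$pd_min_mm, tolerance = 1e-4)
  expect_equal(m_l$hd_min_mm, -m_r$hd_min_mm, tolerance = 1e-4)
  expect_equal(m_l$total_asymmetry_mm, m_r$total_asymmetry_mm,
               tolerance = 1e-4)
})

test_that("total asymmetry is invariant to time reversal", {
  tr <- simulate_gait(gait_params(pelvis_asym_mm = 18, head_asym_mm = -8,
                                  noise_sd_mm = 1, seed = 5))
  rev_tr <- tr |>
    dplyr::mutate(dplyr::across(-time_s, rev))
  m <- measure_asymmetry(tr)
  m_rev <- measure_asymmetry(rev_tr)
  expect_equal(m$total_asymmetry_mm, m_rev$total_asymmetry_mm,
               tolerance = 0.2)
})

test_that("filtering twice changes recovered asymmetry by < 0.5%", {
  p <- gait_params(pelvis_asym_mm = 30, noise_sd_mm = 0)
  tr <- simulate_gait(p)
  f <- estimate_stride_frequency(tr$sacrale_z_mm, 200)
  once <- lowpass_filter(tr$sacrale_z_mm, 200, f)
  twice <- lowpass_filter(once, 200, f)
  md <- function(x) {
    seg <- assign_sides(segment_strides(x, 200, f), tr$roll_deg)
    compute_min_diff(x, seg)$mean_mm
  }
  expect_equal(md(twice), md(once), tolerance = 0.005 * abs(md(once)))
})

test_that("total_asymmetry follows |hd/2| + |pd|", {
  expect_equal(total_asymmetry(0, 0), 0)
  expect_equal(total_asymmetry(-10, 20), 25)
  expect_equal(total_asymmetry(8, -46), 50)
  expect_error(total_asymmetry(NA, 1))
})

test_that("asymmetry scores are changes from baseline", {
  m <- tibble::tibble(
    horse = c("h1", "h1", "h1"),
    occasion = c("b0", "p1", "p2"),
    total_asymmetry_mm = c(5, 66, 3)
  )
  s <- asymmetry_score(m)
  expect_equal(s$score_mm, c(0, 61, -2))  # below-baseline goes negative
  expect_error(asymmetry_score(dplyr::filter(m, occasion != "b0")),
               "baseline")
})
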