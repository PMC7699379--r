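---
title: "Models and design choices in equiasym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in equiasym}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equiasym)
```

`equiasym` reconstructs, on synthetic data, an analysis chain for mild
induced orthopedic pain in horses: movement asymmetry measured from
marker trajectories at trot, and its relationship to ordinal pain-scale
scores given by observers at rest. This vignette is the package's
account of the underlying models, the tunable parameters, and the
choices made where the design was genuinely open.

## The synthetic gait signal

The vertical displacement of the pelvis (tubera sacrale) and head
(poll) markers at trot is modeled per stride of period $T = 1/f$ as

$$z(t) = -A\cos(4\pi f t) + \tfrac{d}{2}\cos(2\pi f t) + \varepsilon(t),$$

a dominant half-stride oscillation of amplitude $A$ plus a
once-per-stride component carrying the asymmetry $d$, with additive
Gaussian noise. The two stride minima of the noiseless signal are
exactly $-A + d/2$ and $-A - d/2$, so the signed minima difference
(right-stance minimum minus left-stance minimum) equals $d$ in closed
form — the property that makes ground truth exact. This closed form is
itself cross-checked in the tests by dense numerical minimization of
the continuous signal. A biomechanical model (stance/swing shape,
impact transients) was deliberately not used: it would add realism the
downstream statistics never see, at the cost of an exact mapping from
parameters to the quantity under test.

Pelvic roll is a once-per-stride sinusoid
$R\cos(2\pi f t)$ phase-locked so its mean is positive over the
right-stance half and negative over the left-stance half. Side
assignment in the kinematics module uses this one documented
convention, shared with the simulator, because the original procedure
delegates side detection to expected roll/yaw patterns without a
printed formula. Yaw is generated and ingested but unused by the
default rule.

Parameter defaults, with units:

| parameter | default | rationale |
|---|---|---|
| `sampling_rate` | 200 Hz | motion-capture rate of the emulated system |
| `stride_frequency` | 1.3 Hz | mid-range trot stride rate |
| `base_amplitude_mm` | 40 mm | sound-trot pelvic vertical motion is tens of mm peak-to-peak; 40 mm gives an 80 mm range. Not fixed by the emulated study; a free choice, documented here |
| `noise_sd_mm` | 2 mm | marker + soft-tissue jitter after tracking |
| `roll_amplitude_deg` | 4 deg | typical pelvic roll at trot |
| `n_strides` | 20 | a straight-line hard-surface pass |

Sign convention throughout: negative HDmin/PDmin means left-sided
asymmetry; vertical axis is positive up, so minima are signal minima.

## The synthetic score tables

Observer scores come from a thresholded-Gaussian ordinal model. For
horse $h$, occasion $o$, observer $j$ and item $i$:

$$\ell = \beta_i \, a_{ho} + u_h + e_{j}, \qquad
  \text{score} = \#\{\text{thresholds} < \ell\},$$

where $a_{ho}$ is the horse-occasion true total asymmetry score
normalized to $[0,1]$, $u_h \sim N(0, \sigma_h^2)$ a horse shift and
$e \sim N(0, \sigma_o^2)$ observer noise. The latent model gives direct
control of item–asymmetry coupling (for recovery tests) and
inter-observer agreement (for reliability tests). Thresholds are shared
per scale and sized so that a null item at rest scores 0 most of the
time: `c(0.7, 1.6)` for the 0–2 scales, `c(0.7, 1.4, 2.1)` for CPS,
`c(0.7, 1.25, 1.8, 2.35)` for EPS. These were fixed once, before any
testing, and not revisited.

Each horse's true asymmetry trajectory rises from 0 at baseline to an
individual peak at an interior occasion and then declines, emulating a
transient chemically induced synovitis; peaks are drawn from
$N(61, 24)$ mm truncated at 20 mm, matching the reported scale of
maximum score increases, and sides split 3 left : 5 right at the
default study size. The default item-effect set couples posture
(EPS/CPS), stall location, focus, orbital tightening, temperature and
heart rate to asymmetry — the combination the emulated study found most
predictive — so the default `run_study()` exercise has a known right
answer.

What the generator does *not* emulate: rescue analgesia (two horses in
the original study; no rescue mechanism exists here), walk or lunging
conditions, soft surfaces, drift or marker dropout, and observer
rotation by default. On rotation: the study had two fixed observers
plus a third rotating by availability, but a pooled per-item
concordance over three raters is undefined when the third rater's
identity changes across horses, and the original reconciliation is not
described; the simulator therefore defaults to a fixed three-observer
panel (`rotate_observers = TRUE` restores rotation). Passing tests on
this generator show the pipeline's correctness and calibration, not
that real pain behavior follows a single-factor latent model.

## Kinematics: numerical choices

- **Filtering.** Fourth-order Butterworth, applied forward and backward
  (zero phase). The cutoff is `6 × stride frequency` — the lowest
  multiple that keeps three harmonics of the twice-per-stride component
  essentially unattenuated (the squared magnitude response at $2f$ with
  cutoff $6f$ is 0.9997). The multiplier is exposed in the
  configuration. `signal::filtfilt` starts from zero filter state, so
  the input is padded by odd-symmetric reflection before filtering and
  cropped after; without padding the edge transient bleeds into the
  outer strides.
- **Stride frequency** is estimated from the periodogram of the
  mean-removed pelvis signal. The dominant peak is $2f$ for mild
  asymmetry, but once $|d|/2$ rivals $A$ the once-per-stride component
  dominates instead; the estimator disambiguates by comparing the power
  near twice the dominant frequency with the power near half of it.
  The estimate is refined by parabolic interpolation and must land in
  physiologic bounds (0.5–2.5 Hz).
- **Peak detection** requires topographic prominence of at least 20% of
  the signal IQR and a minimum spacing of `0.35 / f` seconds. A 0.4/f
  spacing was considered and rejected: the asymmetry component shifts
  the two per-stride peaks toward each other, and at $d = 100$ mm with
  $A = 40$ mm their spacing falls to 0.399 T, so a 0.4/f rule starts
  culling genuine peaks exactly in the severe-lameness regime the
  pipeline must handle. At 0.35/f the admissible asymmetry extends to
  roughly 145 mm, while noise-induced spurious peaks remain excluded by
  the prominence requirement (the signal is low-passed at $6f$ first).
- **Strides and sides.** A stride spans two vertical oscillations
  (every second peak); incomplete edge strides are discarded. Sides
  come from the sign of mean roll per half-stride; halves whose mean
  roll magnitude is below 10% of the roll amplitude are ambiguous and
  filled by alternation from the nearest confident half, with a
  warning. Head minima are located within the pelvis-defined windows —
  the poll signal is noisier and is not segmented independently.
- **Minima.** The per-half minimum must be interior to its window;
  strides violating this are excluded and counted. Equal minima take
  the earlier sample. HDmin/PDmin per measurement are means over
  strides (a median variant would only matter for a robust average,
  since the factor ½ on HDmin commutes with the mean).

## Reliability

Kendall's W uses mid-ranks within each observer and the tie-corrected
denominator $m^2(n^3-n) - m\sum T_j$. Assessments are pooled across
horses, occasions and phases into a single $n$ per item, giving one W
per item. Two conventions required a decision:

- **Degenerate items.** When every observer's scores are completely
  tied the denominator vanishes; the item is reported as degenerate
  with W undefined rather than assigned $1/m$. A fixed-value convention
  for all-tied tables exists in some software but is unverifiable from
  the emulated study's description, so it is not reproduced.
- **Band endpoints.** The band intervals are ambiguous at 0.7 and 0.9;
  both are assigned to "strong", and 0.5 to "moderate". No packaged
  reference coefficient falls on a boundary, so the choice is
  observationally neutral there.

Chi-square p-values are reported unadjusted for multiplicity, matching
the per-item reporting style being emulated.

## Lasso item selection

Item scores enter as indicator columns for each observed level above 0
(level 0 is the reference), named `<scale>_<item><level>`; horse and
observer indicators are appended and penalized like any other column
(an option removes their penalty). The model is the glmnet Gaussian
lasso (`alpha = 1`), 10-fold cross-validation with a seeded fold
permutation, reporting the fit at the lambda minimizing mean CV error.
The optimality contract is the KKT system of the lasso objective,
checked on the internally standardized scale; the tests also verify the
$\lambda \to 0$ limit against ordinary least squares.

Pairing and truncation rules: with one trot measurement per occasion,
the pre- and post-assessments share its score; with two, the first
pairs with pre and the second with post. Each horse's data stop at the
occasion of its maximum total asymmetry score (earliest occasion on
ties); the truncation can be overridden per horse in the study
configuration, mirroring a manually determined maximum. The response is
the total asymmetry score of the paired measurement.

## MCA and the dimension regression

The indicator matrix is analyzed by plain correspondence analysis:
standardized residuals $D_r^{-1/2}(P - rc^\top)D_c^{-1/2}$, SVD,
eigenvalues as squared singular values, raw (uncorrected) inertia
fractions. A Benzécri-style correction is deliberately not applied, so
the "explains at least 1% of variation" retention rule operates on the
same scale as the package being emulated. Two identities anchor the
implementation: total inertia equals $J/Q - 1$, and the eigenvalues of
the Burt-matrix route equal those of the indicator route; both are
verified in the tests to 1e−8. Dimension signs are fixed by forcing the
largest-magnitude category coordinate positive, and all interpretation
is invariant to per-dimension sign flips.

Rows are one per (assessment, observer) by default — each observer's
scoring is its own observation, consistent with observer appearing as a
random effect downstream; a per-assessment median-consensus mode is
available, and neither mode is claimed to be the emulated study's
(unstated) choice.

The follow-up regression is a linear mixed model with random intercepts
for horse and observer, fitted by maximum likelihood, reduced by greedy
single-drop backward elimination on AIC (no re-entry), with Wald z
statistics and a p < 0.01 significance flag on the retained dimensions,
and a lag-1 within-horse residual autocorrelation as a temporal
diagnostic. Two inference choices deserve a note:

- **One likelihood throughout.** AIC selection and the reported z
  values come from the same ML fit. Refitting the final model by REML
  was tried and rejected: recomputing z from a different fit than the
  one the selection acted on decouples selection from inference and
  measurably worsened the null calibration in simulation.
- **Wald z, no df correction.** The reference is the normal
  distribution, matching the z-value reporting style being emulated.
  At small row counts this is mildly anticonservative (the exact
  reference would be a t with residual df, and ML variance estimates
  are biased low by a factor $(n-p)/n$); the package's calibration
  experiments therefore run at several hundred rows, where the normal
  reference is accurate. If the model cannot be fitted at all, the
  function falls back to fixed-intercept least squares with a recorded
  warning.

## Known limitations

- **Singleton indicator instability.** At `lambda_min`, an indicator
  column active in only one or two rows can absorb a single large
  residual and appear with a large raw coefficient. In planted-effect
  simulations the planted posture item is almost always among the top
  two item columns, but in a minority of replicates such a rare-level
  column of a null item outranks it. This is a property of the
  cross-validated lasso on sparse ordinal dummies (the KKT checks
  confirm the solver is exact), and it is worth remembering when
  reading single top coefficients from this kind of analysis; ranks
  below the first few are more stable.
- The latent-variable score model is single-factor: all of an item's
  coupling to pain runs through one asymmetry scalar. Real behavior has
  item-specific dynamics (e.g. facial expressions appearing only at
  rest between postural adjustments) that this cannot represent.
- The simulator's trajectories are smooth rise-and-fall curves; real
  induced lameness shows measurement-to-measurement variability beyond
  noise, and rescue interventions truncate it non-smoothly.
- Problem sizes in the test suite (e.g. 200 noisy gait replicates,
  1000-replicate calibration at 720 rows, 100-replicate recovery runs)
  were chosen as the smallest sizes at which the Monte-Carlo error is
  comfortably below the tolerances being asserted.

## Session info

```{r}
sessionInfo()
```
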