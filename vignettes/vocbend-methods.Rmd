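---
title: "Methods: synthetic bending sessions, filament tracking and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic bending sessions, filament tracking and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

A strip of a chemo-mechanically active polymer film is hung by its root in the
headspace above a solvent mixture and filmed. Exposure to volatile organic
compounds (VOCs) — here acetone and ethanol, with water as a diluent — makes
the film bend, and the *time course* of bending carries information about the
vapor composition. The analysis chain has four stages: extract the filament's
midline and tip angle from each video frame; characterize the dimensionality
of the observed shapes; summarize each exposure transient with a
triple-exponential fit; and calibrate linear maps between composition and
bending (forward) and between transient parameters and composition (inverse).

Because raw experimental videos are generally not available, the package's
first-class citizen is a synthetic-data generator that emulates the whole
experiment — randomized exposure schedule, hysteretic bending dynamics, and
rendered binary frame sequences with exact ground truth — so that every stage
of the chain is testable end to end.

# The synthetic experiment

## Exposure design

One session exposes one specimen to six headspace environments (pure acetone,
pure ethanol, and their binary/ternary mixtures with water; volumes 60, 30+30
or 20+20+20 mL) five times each: five independent uniform-random permutations
of the six solution ids strung together, 30 trials in all, with a 60 s
recovery interlude between trials. `generate_exposure_design()` reproduces
this structure for any number of blocks and any solution set. Real trial
durations varied (each test ran until deflection visually saturated); the
generator uses a fixed configurable duration, 180 s by default, for
reproducibility.

## Bending dynamics

The generator's tip angle $\vartheta(t)$ obeys a deliberately minimal model
that reproduces the qualitative structure of the real films:

* **Speed, not steady state, encodes composition.** During a trial with
  volume fractions $(f_a, f_e, f_w)$ the drive rate is
  $k = k_0 + k_a f_a + k_e f_e$ with $k_a > k_e$, and the deflection
  $D(t) = \theta_{\mathrm{rest}}(t) - \vartheta(t)$ relaxes toward the full
  amplitude $A \cdot (f_a + f_e + f_w)$ as a weighted sum of three exponential
  modes with rates $\nu_i k$. All vapors eventually produce the same
  deflection; acetone-rich headspaces get there faster. (The amplitude
  scaling by total vapor fraction makes the degenerate empty-flask
  composition produce no response; every real mixture has fractions summing
  to 1, so the scaling is inert for actual designs.)
* **Hysteresis.** A hidden state $h$ relaxes toward $f_w$ during exposure and
  toward 0 during recovery with time constant $\tau_h = 600$ s, and shifts
  the rest angle by $\gamma_h h$. Together with the few percent of deflection
  that survives each interlude, this makes the pre-trial "initial angle"
  drift on a time scale of tens of minutes and gives the initial-angle series
  positive lag-1 autocorrelation — the diagnostic signature
  `hysteresis_diagnostic()` measures.
* **Noise.** i.i.d. Gaussian angle noise (1° SD by default) per recorded
  sample.

Defaults: $\theta_{\mathrm{rest},0} = -90°$ (plumb), $A = 60°$,
$k_0 = 0.005$, $k_a = 0.15$, $k_e = 0.03\ \mathrm{s}^{-1}$,
$\nu = (1, 0.2, 0.05)$, $w = (0.7, 0.2, 0.1)$,
$k_{\mathrm{recover}} = 0.05\ \mathrm{s}^{-1}$, $\tau_h = 600$ s,
$\gamma_h = 15°$, $\sigma_\vartheta = 1°$. The recovery rate deserves a note:
the 60 s interlude was chosen, in the experiment this emulates, to allow
*substantial* recovery. With $k_{\mathrm{recover}} = 0.05$ the interlude
recovers about 95% of the deflection; the residual few percent depends on the
previous trial's composition and is small compared with the slow
$\gamma_h h$ drift. A much slower recovery rate would leave ~30% residuals,
an effectively white composition-dependent perturbation of the initial angles
large enough to mask the slow state entirely — the initial-angle series would
then show no positive autocorrelation, contradicting the drift structure the
generator exists to emulate. The state is propagated analytically through
each interlude (exact one-step updates of the linear relaxations), so the
integration has no step-size error.

## Rendering

Each sample is rendered as a constant-curvature arc of fixed arc length
(100 px by default), clamped at a fixed root at the top of the canvas with a
plumb root tangent, stroked at 5 px thickness (disks stamped along the
midline), black on white. The curvature is chosen so that the *tip angle* —
defined throughout as the direction of the first principal component of the
distal 25% of the midline, which for a circular arc equals the tangent at
87.5% of arc length — equals the simulated angle. Angles are measured
counterclockwise from the +x image axis with y pointing down, in
$(-180°, 180°]$; a plumb filament reads $-90°$. The true midline accompanies
every frame as ground truth.

What the renderer does *not* emulate: grayscale texture, lighting gradients,
shadows, background clutter, camera shake, and out-of-plane twisting. Passing
the round-trip tests therefore certifies the geometry of the tracker — row
scanning, two-cluster splitting, path assembly, tip-angle extraction — not
its robustness to real-world segmentation noise. Binarization of real frames
is exercised only through synthetic grayscale conversions.

## Emulated manual annotation

`emulate_manual_annotation()` mimics the human labeling protocol: one frame
every 5 s, seven clicked points from root to tip. Points are placed exactly
equidistant in arc length on the true midline (the protocol required only
"roughly equidistant") and isotropic Gaussian click noise (2 px SD default)
is added. `compare_to_manual()` rebuilds each annotated frame's midline by
cubic-spline interpolation through the clicks (parameterized by cumulative
chord length), computes the manual tip angle with the *same* PCA tip-angle
operation, and fits a cubic polynomial predicting automatic angles from
manual ones; agreement is the squared Pearson correlation between prediction
and the automatic values.

# The tracker

Frames are binarized (Otsu threshold on luminance by default, fixed threshold
available), then each pixel row is scanned: the default midpoint is the mean
column of the row's foreground pixels. Rows whose foreground is
non-contiguous are split with a two-cluster k-means (initialized
deterministically at the first and last run centroids); the split is accepted
only when both clusters are substantial (at least `max(3, thickness/2)`
pixels) and separated by at least 1.5 thicknesses, where thickness is the
median foreground run length over contiguous rows. Accepted pairs mean the
filament crosses that row twice (it has curled past horizontal). Path
assembly starts at the topmost row and steps downward, choosing the nearest
continuation; on two-midpoint rows the other candidate is stashed, and after
the lowest row the stashed ascending branch is traversed bottom to top. A gap
exceeding 3 thicknesses truncates the path and flags it broken; frames that
fail any stage are flagged as gaps, never interpolated.

Row scanning parameterizes the midline by image row, which fails where the
filament runs nearly horizontally (a horizontal stretch occupies few rows,
and rows under the stroke's belly average unrelated pixels). A refinement
pass fixes this: points on stretches flatter than 45° are re-centered using
column means; the distal end is extended along its local tangent with
orthogonal-slice means (slices 2 px long along the tangent, 1.5 thicknesses
wide, advancing only while each step makes forward progress); both
coordinates are smoothed with a running mean of about one thickness; and 0.3
thicknesses of arc length are trimmed from each end, discarding the stroke's
end caps, which contain no midline information. With the refinement the
tracker holds tip-angle error below 2° and path-length error below 5% over
tip angles from $-170°$ to $-10°$ on clean renders; without it, errors near
the horizontal extremes reach 8°.

Tip angles are computed as the sign-oriented first principal direction of the
distal-quarter points (orientation fixed by the chord from the segment's
proximal end to the tip endpoint — PCA alone is sign-ambiguous), and unwrapped
across frames by nearest-branch continuation (consecutive angles differ by at
most 180°).

# Shape-ensemble PCA

Each tracked path is resampled to $P = 100$ points equally spaced in arc
length (the resampling scheme is this package's choice; some fixed-length
representation is required for a well-defined covariance) and flattened to a
200-vector. All frames of all trials of a session are pooled and
mean-centered PCA is run without per-coordinate standardization, since all
coordinates share pixel units. Procrustes alignment is deliberately *not*
applied: overall orientation is the measurement, not a nuisance. Broken paths
shorter than half the nominal filament length are excluded with a classed
condition rather than silently dropped. On synthetic sessions the shape
ensemble is a one-parameter family of constant-curvature arcs plus noise, so
the leading two components capture essentially all variance; this reproduces
the low-dimensionality finding the generator was built to emulate, but on
real films the spectrum would be fatter.

# Transient fitting

Each trial's tip-angle transient is fit with
$\vartheta(t) = a_0 + a_1 e^{-\lambda_1 t} + a_2 e^{-\lambda_2 t} + a_3 e^{-\lambda_3 t}$
by nonlinear least squares. Numerical choices, in order of importance:

* **Variable projection.** For fixed rates the amplitudes are linear; only
  the three log-rates are searched (positivity by construction), with the
  amplitudes solved by linear least squares inside the objective.
* **Amplitude ridge.** Multi-exponential fitting is notoriously
  ill-conditioned: $\lambda \to 0$ mimics the constant term and near-equal
  rates trade off gigantic opposite-sign amplitudes, all at the same residual
  norm. A tiny ridge on the exponential amplitudes
  ($10^{-9}\, n\, \mathrm{var}(y)$) selects the smallest-amplitude member of
  each near-tie. It is orders of magnitude below the noise floor of any
  realistic series — noiseless recovery tests still recover rates to
  $10^{-4}$ relative — but it keeps the fitted parameters usable as
  regression features, which is what the inverse model needs. Near-degenerate
  rate pairs remain allowed; the parameters are features, not physical
  constants.
* **Multi-start.** One deterministic log-spaced rate triple plus nine seeded
  random triples drawn log-uniformly from $[1/T, 30/T]$ for trial length $T$,
  each refined by Levenberg–Marquardt (`minpack.lm::nls.lm`) with the
  log-rates bounded in $[0.05/T, 2/\Delta t]$; the best residual wins. Rates
  are reported sorted ascending. If every start fails, the constant fit is
  returned flagged unconverged.

Response-speed and bending summaries: `time_to_max_deflection()` returns the
time until the absolute change from the trial's starting angle first reaches
95% of its maximum over the trial (a reproducible operationalization of
"time to clear maximum deflection by visual inspection"); a 1 s moving
median tames noise (exact on monotone transients), and trials whose maximum
deflection stays below 3 estimated noise SDs are flagged undefined.
`delta_tip_angle()` is end-minus-start by default (an extremum variant is
available). The per-trial *initial angle* is estimated as the mean over the
trial's first second rather than the single first sample; under 1° sample
noise the windowed estimate keeps the hysteresis diagnostic's autocorrelation
from being diluted by measurement noise.

# Calibration models

$R^2$ throughout is the **squared Pearson correlation** between prediction
and actual value (so a 0.67 correlation is a 0.45 $R^2$); note this is
sign-blind and, for in-sample OLS fits, coincides with the usual coefficient
of determination. All model fits are in-sample ordinary least squares —
matching the exploratory usage this pipeline emulates — with two separate
single-output regressions per direction rather than one multivariate fit.

* **Forward:** `delta_theta ~ f_acetone + f_ethanol + initial_angle`
  (intercept included; the initial angle can be dropped by a switch to test
  whether it adds predictive power — by nesting it can only help in-sample).
* **Inverse:** per analyte, the transient-fit features. The full set is
  $(a_0, a_1, a_2, a_3, \lambda_1, \lambda_2, \lambda_3)$; the reduced set
  $(a_0, \lambda_1, \lambda_2, \lambda_3)$ keeps the constant term and the
  exponents only. Both are always fitted and the per-analyte difference is
  reported. Features are used raw; OLS $R^2$ is invariant to affine feature
  rescaling, so standardization would change nothing. Collinear designs fail
  loudly, naming the dependent features.

Because $k_a > k_e$, the rate features carry more acetone than ethanol
information, and on low-noise synthetic sessions the inverse acetone $R^2$
exceeds the ethanol one — the acetone-dominance structure the generator
encodes by construction.

A note on the permutation null used in the tests: with $n = 30$ trials and
three features, the in-sample $R^2$ of a single permuted-label fit follows a
Beta(1.5, 13) distribution with mean 0.10 and a roughly 20% chance of
exceeding 0.15, so asserting one permutation below a threshold would be a
coin flip. The tests therefore assert the *mean* $R^2$ over 100 seeded
permutations, the standard form of a permutation-null summary.

# Problem sizes and runtime choices

Full synthetic sessions in the tests and the acceptance script are rendered
at 5 Hz (27,000 frames per 30-trial session at 180 s per trial), a sampling
rate that keeps an end-to-end session around a minute of computation while
leaving hundreds of samples per transient; the dynamics are band-limited far
below 2.5 Hz, so no information relevant to the fitted summaries is lost.
Shape PCA uses all tracked frames. Parameter-recovery checks use 100
simulated transients per noise level.

# Known limitations

* The tracker assumes a single filament hanging roots-up; multi-filament
  scenes and out-of-plane twisting are out of scope (twisting specimens were
  excluded in the emulated experiment too).
* The two-cluster row split handles one curl-back; shapes crossing a row
  more than twice (S-curls) would confuse path assembly.
* The synthetic shape family is one-dimensional by construction, so the PCA
  dimensionality results on synthetic data certify the pipeline, not the
  physics of real films.
* The triple-exponential parameters are regression features; no physical
  meaning (diffusion or swelling constants) should be read into individual
  rates.
* DNN-based tracking is a non-goal; the classical row-scan approach is the
  method under study.
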