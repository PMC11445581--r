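---
title: "Models and methods: in-cell dissociation constants by FCCS and single-cell degradation kinetics"
author: "fccstools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fccstools)
```

# The measurement problem

During mitosis, the ubiquitin ligase APC/C targets Cyclin B1 for
degradation the moment the spindle assembly checkpoint is silenced, and
degradation starts earlier at chromatin, spindle and centrosomes than in
the cytoplasm. Two quantitative readouts anchor that observation:

1. **Dual-colour fluorescence cross-correlation spectroscopy (FCCS)** on
   endogenously tagged Cyclin B1 (green) and APC8 (red) gives the in-cell
   dissociation constant of the pair, compartment by compartment —
   roughly 80 nM at chromatin versus 180 nM in the cytoplasm, with both
   partners near 100 nM total.
2. **Anaphase-aligned single-cell intensity trajectories** give each
   cell's degradation onset frame and maximum degradation speed.

`fccstools` implements both analysis chains and a seeded synthetic-data
generator that emulates the statistical structure each chain assumes, so
that every stage can be validated against recorded ground truth without
the original microscopy data.

# Fluorescence correlation analysis

## Estimator

For photon counts binned at width $\Delta$, the normalised fluctuation
correlation at bin offset $k$ is estimated over all overlapping pairs,

$$\hat G(k\Delta) \;=\;
\frac{\overline{a_{1..n-k}\,b_{k+1..n}}}
     {\overline{a_{1..n-k}}\;\overline{b_{k+1..n}}} \;-\; 1,$$

with the means taken over each *truncated* segment, which removes the
linear-trend bias a single global mean would introduce. Lag 0 is never
reported: at zero lag the estimator is dominated by shot noise rather
than number fluctuations. `correlateDirect()` evaluates this estimator
exactly at arbitrary lags and serves as the reference oracle.

`correlateMultiTau()` is the production correlator: the first $2m$ lags
at native resolution, then $m$ lags per octave with the bin width doubled
by *averaging* (not summing) adjacent bins, so the normalised estimator
is unchanged in expectation. At the shared native lags the two
correlators agree to floating-point precision; the suite asserts $10^{-9}$
relative on random traces. Per-lag uncertainties come from splitting the
trace into `nSegments` equal segments (default 10), correlating each on a
grid built for the segment length, and taking
$\mathrm{sd}/\sqrt{n_\mathrm{seg}}$ (`estimateCurveNoise()`); these are the
default weights for fitting. The defaults $m = 8$ and 10 segments are
conventional correlator settings, exposed as arguments.

## Diffusion model and fitting

Free 3D diffusion through a 3D Gaussian observation volume with lateral
$1/e^2$ radius $w_{xy}$ and structure parameter $\kappa = w_z/w_{xy}$
gives

$$G(\tau) = \frac{1}{N}\Bigl(1+\frac{\tau}{\tau_D}\Bigr)^{-1}
\Bigl(1+\frac{\tau}{\kappa^2\tau_D}\Bigr)^{-1/2},
\qquad D = \frac{w_{xy}^2}{4\tau_D},$$

with $G(0) = 1/N$ the inverse mean molecule number in the effective
volume $V_\mathrm{eff} = \pi^{3/2} w_{xy}^2 w_z$. `fitCorrelation()`
minimises the sd-weighted squared residuals with bounded
Levenberg–Marquardt (via minpack.lm), starting from $N_0 = 1/G$ at the
first lag and $\tau_{D,0}$ at the half-amplitude lag, with up to three
deterministic restarts from perturbed initials. $\kappa$ is fixed from
calibration during sample fits — refitting it would be nearly collinear
with $\tau_D$ — and `calibrateVolume()` recovers $(w_{xy}, \kappa)$ from
a reference dye of known $D$. No triplet-state term is included: the
tagged proteins here are slow, and triplet kinetics live below the fitted
lag range. A two-component variant with shared $\kappa$ is available for
mixed bound/free populations. Curves with non-positive amplitude yield an
explicit no-fit result, never a number.

Physical conversions are kept separate and exactly invertible:
concentration $C = N/(N_A V_\mathrm{eff})$, and the Stokes–Einstein
radius $R_h = k_B T/(6\pi\eta D)$. Temperature and viscosity are always
explicit inputs (`sampleEnvironment()`): the package asserts no "correct"
intracellular viscosity, since the choice dominates $R_h$.

## From amplitudes to a dissociation constant

With equal brightness within each channel and no spectral cross-talk
(the tags here are spectrally well separated), molecule numbers
$N = C N_A V_\mathrm{eff}$ give the zero-lag amplitudes

$$G_g(0) = \frac{1}{N_{g,\mathrm{free}}+N_{gr}},\quad
G_r(0) = \frac{1}{N_{r,\mathrm{free}}+N_{gr}},\quad
G_\times(0) = \frac{N_{gr}}{(N_{g,\mathrm{free}}+N_{gr})(N_{r,\mathrm{free}}+N_{gr})}.$$

`amplitudesToConcentrations()` inverts these; `kdFromConcentrations()`
forms $K_D = [g][r]/[gr]$ (with $+\infty$ reported when no complex is
detected), and `crossCorrelationQuotient()` reports the bound fractions
$G_\times/G_r$ and $G_\times/G_g$ with $q$ defined as the larger of the
two — the limiting autocorrelation normalises the quotient. Noise can
push an inferred free concentration negative; such results are flagged
and $K_D$ withheld, but the concentrations are reported *unclipped* so
that aggregate statistics stay unbiased. The forward direction
(`solveEquilibrium()`, the stable root of the mass-action quadratic, plus
`equilibriumAmplitudes()`) is used by the generator, and the full
algebraic loop is exact to $10^{-9}$ relative in the tests.

# The synthetic generator

`simulatePhotonTraces()` performs Brownian dynamics of point emitters in
a periodic cuboid observed through the 3D Gaussian profile
$W(\mathbf r) = \exp(-2(x^2+y^2)/w_{xy}^2 - 2z^2/w_z^2)$, with
per-channel Poisson counts. Design choices that matter:

* **Exact propagation, point sampling.** Gaussian displacement with
  per-axis sd $\sqrt{2D\,\delta t}$ is the exact free-diffusion
  propagator at any step size, and evaluating $W$ once per bin at the
  propagated position makes the sample autocorrelation an unbiased
  estimate of the model at every lag $\ge$ one bin — integrating the
  rate within bins would impose a triangular smoothing on the curve.
  Finer sub-steps remain available through the `timestep` field for
  users who want within-bin integration.
* **Box size.** Half-widths are `boxMultiplier` $\times (w_{xy}, w_{xy},
  w_z)$, default 4. A closed box with a *fixed* number of molecules is a
  canonical ensemble, and its correlation carries a constant offset:
  $G_\mathrm{closed}(\tau) = G_\mathrm{open}(\tau) - 1/N_\mathrm{box}$
  (suppressed total-number fluctuations). At the default geometry and
  100 nM this offset is about 2% of the zero-lag amplitude — absorbed
  almost entirely by the fit and invisible in the recovered
  concentration ratios — but it becomes relatively large where
  $G$ itself is small, i.e. at lags beyond several $\tau_D$. Analyses
  that compare raw long-lag values against the open-system model should
  either subtract $1/N_\mathrm{box}$ (recorded in the truth object) or
  enlarge the box; the ACF-agreement test uses `boxMultiplier = 6` for
  exactly this reason.
* **One seed, one stream.** All randomness flows from a single
  xoshiro256++ stream (seeded via splitmix64 from the user's integer
  seed), with a polar-method normal and a PTRS Poisson sampler. A
  self-contained generator rather than the C++ standard library's
  distributions keeps output bit-identical across compilers, not just
  across runs.

The default study conditions mirror the measured system: observation
volume $w_{xy} = 0.2\,\mu m$, $\kappa = 5$ ($V_\mathrm{eff} \approx
0.223$ fL, the calibration scale of a typical confocal FCS setup);
both binding partners at 100 nM total; APC8 reporter diffusion
$6.44\,\mu m^2/s$ as measured; the free Cyclin B1–Cdk1 pool set to
$15\,\mu m^2/s$ (a ~100 kDa complex in cytoplasm; the study does not
print this value) and the APC/C-bound complex to $6.0\,\mu m^2/s$,
slightly below free APC/C; per-molecule peak brightness 12 kHz per
channel with zero cross-talk. `bindingPairSpecies()` assembles the three
equilibrium populations from a ground-truth $K_D$.

What the generator deliberately does *not* emulate: triplet/blinking
photophysics, detector afterpulsing, background and cross-talk,
cell-to-cell variability of totals, membrane-bounded geometry, and any
slow drift. Passing recovery tests therefore demonstrates correctness of
the estimator chain under the model's own assumptions, not robustness to
every artefact of live-cell data.

`simulateDegradationTrace()` produces anaphase-aligned trajectories

$$I(t) = \mathrm{baseline}\times b(t)\times d(t) + \varepsilon_t,$$

with a linear bleach term $b(t) = 1 - \beta(t - t_\mathrm{first})$ (the
straight-line correction's own model; exponential bleaching is an
option), $d(t) = 1$ up to the onset frame and a first-order decay after
it, and i.i.d. Gaussian noise. The in-cell decay shape is not firmly
established, so the post-onset shape is a parameter (`decayShape`,
default exponential — the simplest monotone form consistent with the
measured mean curves) rather than an assertion.
`simulateLineProfileImage()` builds 2D Gaussian-peak images for the
centrosome–chromatin–centrosome three-peak geometry.

# Degradation kinetics

Conventions follow the measurement protocol throughout: anaphase is
frame 0, "$N$ frames prior to anaphase" is frame $-N$, and all slopes
are in normalised intensity **per frame** — the onset threshold is
applied unchanged at 30 s and 60 s intervals, so the frame interval is
carried as metadata only.

* `normalizeTrace()` divides the background-subtracted trace by its
  value at the reference frame (−20 by convention; −25 and −10 are used
  for some acquisition settings, so the reference is always explicit).
* `bleachCorrectControl()` divides by a matched control from
  translation-blocked, proteasome-inhibited cells (cycloheximide +
  MG132), cancelling bleaching exactly. `bleachCorrectLinear()` instead
  fits a straight line to frames −30..−25 and divides by its
  extrapolation. Note the statistics of the latter: with only 6 fitted
  frames, noise of sd $\sigma$ leaves a residual slope of sd
  $\approx 0.24\,\sigma$ per frame in the corrected trace; the control
  division does not have this failure mode.
* `detectOnset()` smooths with a trailing 4-value window (trailing, so
  the onset label never uses future frames; the protocol does not state
  the alignment), slides a 5-value window, and reports the first window
  whose least-squares slope falls **strictly** below −0.05 — a window at
  exactly the threshold does not trigger. Its first frame is the onset,
  its slope the initial degradation speed; absence of such a window is a
  valid result (control traces), reported as NA, serialised as null.
* `maxDegradationSpeed()` takes the first difference of the smoothed
  trace, finds its minimum (ties resolve to the earliest frame), and
  fits a line through the 5 smoothed values centred there (window
  clamped at the trace ends, "centred" meaning minimum ±2). Whether that
  5-point fit should use smoothed or raw values is ambiguous in the
  protocol wording; smoothed is the default, `useSmoothed = FALSE` gives
  the raw reading.
* `extractLineProfile()` samples at unit spacing along the
  centrosome-to-centrosome segment, averaging bilinear interpolations at
  10 perpendicular offsets (−4.5..+4.5 px for the default thickness);
  `minmaxScale()` then maps the background-subtracted profile onto
  [0, 1] (constant input is an error, not a silent 0/0).
  `compartmentMeans()` quantifies signal inside versus outside a mask,
  e.g. polar-chromosome chromatids versus surrounding cytoplasm.

# Numerical choices and degenerate inputs

* Fit convergence: minpack.lm tolerances at $10^{-14}$, up to 3
  deterministic restarts (×2, ×½, ×5 perturbations of the initials);
  failures are reported as no-fit, never interpolated.
* Zero-amplitude or all-zero traces raise explicit errors/no-fit
  signals (a constant trace has no defined fluctuation correlation).
* Per-lag sds of 0 (periodic inputs) are floored at $10^{-3}$ of the
  smallest positive sd before weighting.
* kd = 0 equilibria take the limit complex = min(totals); complex = 0
  reports $K_D = +\infty$ with the JSON sentinel `"Inf"`.
* Seeds: every generator takes one integer seed; R-level noise runs
  through one seeded RNG scope that restores the caller's RNG state.

# Validation scale

The test-suite recovery experiments use 20 seeds with 15 s dual-colour
traces (0.2 ms bins) for the dissociation-constant chain and 8 s traces
for diffusion; `scripts/acceptance.R` runs the same chain at 30 s per
seed. At these sizes the median recovered quantities sit well inside the
acceptance bands (a pilot at half scale was already unbiased within a
few percent); single seeds scatter by roughly ±15% in $K_D$, which is
why the median over seeds is the reported estimator — mirroring the
per-cell dot plots with median bars used for the in-cell measurements.

# Known limitations

* Amplitude relations assume equal brightness within a channel and no
  cross-talk; a correction hook exists in the algebra (set effective
  amplitudes upstream) but no spectral unmixing is implemented.
* No anomalous-diffusion or 2D membrane models; no maximum-entropy
  $\tau_D$ distributions.
* Compartments are metadata labels; positioning the measurement volume
  (or drawing the mask) is the caller's task, as it was manual in the
  original protocol.
* The multi-tau octave grid rebins by pairwise averaging; at very long
  lags (beyond ~1/4 of the trace) estimates are noisy and the segment
  -based sd reflects that — fitting weights handle it, but users reading
  raw curves should expect scatter there.
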