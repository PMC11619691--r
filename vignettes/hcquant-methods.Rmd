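---
title: "Methods: hemichannel assay quantification and binding energetics"
author: "hcquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hemichannel assay quantification and binding energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcquant)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the tunable parameters, and the design
choices made where more than one reasonable option existed.

## The experimental readouts being modelled

The package quantifies the activity of connexin-32 hemichannels (HCs)
and its pharmacological block by an anti-connexin antibody. Cx32 is a
protomer of a hexameric connexon; the disease mutant studied here
(p.D178Y, in an extracellular loop) forms leaky HCs. Four live-cell
readouts and one in-silico arm are covered:

1. **GCaMP6s Ca²⁺ imaging.** Cytosolic Ca²⁺ is reported by the
   genetically encoded indicator GCaMP6s. Each ROI yields a
   fluorescence series F(t); background from a cell-free ROI is
   subtracted pointwise. A bolus Ca²⁺ stimulus evokes a transient;
   ionomycin applied later saturates the indicator and provides the
   per-ROI normalisation maximum. The study statistic is the cytosolic
   Ca²⁺ load (CCL), the trapezoidal integral of ΔF/ΔF_max over a fixed
   100 s post-stimulus window.
2. **Dose–response.** Mean CCL per antibody concentration, normalised
   to the antibody-free control, fitted with an inhibitory Hill model.
3. **DAPI uptake.** DAPI permeates open HCs and fluoresces on nuclear
   binding; uptake is quantified as the slope of a straight line
   through the origin after first-frame subtraction.
4. **ATP release.** Luciferin–luciferase luminescence in plate format;
   the statistic is the area under the baseline-subtracted curve.
5. **Binding energetics.** An alchemical transformation (wild-type
   residue to mutant) is run in two states — the antibody-bound complex
   and the free HC — across 32 λ-windows. Free energies are estimated
   per window, summed per leg, and differenced through the
   thermodynamic cycle: ΔΔG = ΔG_complex − ΔG_free, positive when the
   mutation weakens binding. Because the six mutated sites of the
   hexamer do not interact, per-protomer ΔΔG values are additive. The
   affinity fold change is exp(ΔΔG/RT) with
   R = 1.9872×10⁻³ kcal mol⁻¹ K⁻¹.

The package *consumes* trajectories and work samples; running the MD or
replica-exchange machinery is out of scope, as are image segmentation,
docking and electrostatics.

## Trace preprocessing

**Baseline F₀.** The pre-stimulus window `[0, stimulusTime)` defines
F₀ as the sample mean. With the default 1.3 s frame interval and a
10 s baseline this is 8 samples — adequate for a level estimate, far
too short to constrain a decay (see below).

**Photobleaching.** `fitBleach()` fits a·exp(−t/τ)+c by
Levenberg–Marquardt and removes the fitted trend, retaining the offset
(`corrected = F − trend + c`). The amplitude is constrained a ≥ 0:
bleaching is a decay, and on a short noisy window an unconstrained fit
can support a spurious rising exponential whose extrapolation corrupts
the rest of the trace. When a stimulus is set, the fit uses the
pre-stimulus window only, so evoked signal cannot bias the decay; the
cost is that mild bleaching (default synthetic τ = 2000 s, ~16% over a
6 min recording, a realistically tuned imaging experiment) is usually
undetectable from 8 samples and the correction degenerates to a no-op.
This residual trend contributes at the percent level to CCL and
largely cancels in condition ratios. For recordings *without* an
evoked transient (e.g. oscillation-only sessions) a wider `fitWindow`
plus `robust = TRUE` — iterative refitting that discards positive
outliers beyond 2 robust s.d. — recovers the decay in the presence of
sparse Ca²⁺ events. Non-convergence falls back to a linear detrend of
the window, except in the far-extrapolation regime (trace much longer
than the window), where a straight-line extrapolation is statistically
meaningless and the trace is returned uncorrected, flagged.

**Normalisation.** ΔF = F − F₀; ΔF_max is the maximum ΔF in the
ionomycin window. ROIs with non-positive ΔF_max carry no usable
normalisation and are excluded with a recorded reason (classed
condition `hcq_exclusion`, collected by `normalizeEnsemble()`).
Negative values after background subtraction are kept — no clamping —
so all area statistics remain linear.

**Peaks.** `detectPeaks()` reports local maxima above
`baseline + k·(1.4826·MAD)` (k = 3 by default), amplitudes relative to
the baseline, and FWHM by linear interpolation of the half-amplitude
crossings; peaks closer than 3 samples are merged (highest wins,
earliest on ties). The default baseline is the trace median,
appropriate when activity is sparse; traces dominated by a broad
evoked transient should pass the pre-stimulus mean instead, since
their median is itself elevated.

## Assay statistics

* **CCL**: trapezoidal integration over `[0, 100]` s relative to the
  stimulus, endpoints interpolated linearly when off-grid. Per-ROI
  areas are computed first and then averaged (matching per-cell dot
  plots); the aggregation order matters only through weighting and is
  a documented choice.
* **DAPI rate**: closed-form origin-constrained least squares
  ΣtF/Σt², after first-sample subtraction and re-zeroing. The
  acquisition interval of the synthetic DAPI series defaults to 2 s
  (configurable); the imaging protocol leaves it open.
* **ATP**: baseline = mean pre-stimulus; AUC of the
  baseline-subtracted curve over a 600 s post-stimulus horizon.
  Trapezoids interpolate linearly across instrument gaps, which is
  exact whenever the underlying signal is piecewise linear across the
  gap.
* **qPCR**: 2^(−ΔΔCt) with per-condition ΔCt from replicate means. No
  efficiency correction (out of scope).
* **Dose–response**: the control (concentration 0) is the normaliser,
  not a fitted point; fitting is least squares in log₁₀ concentration
  with a free floor (incomplete inhibition at saturating antibody is
  observed for the mutant), h bounded to [0.3, 4]. The optimiser works
  on the residual function directly (`minpack.lm::nls.lm`), because
  exact-fit data can break the construction of a full `nls` model
  object; parameter uncertainty comes from a seeded bootstrap over
  ROIs within each concentration (default 200 resamples, percentile
  CIs). Panels with no usable inhibition are *flagged* (IC₅₀ CI
  `[0, ∞)`), never fatal.

## Free-energy estimation

`barEstimator()` solves the Bennett self-consistent equation

Σ_F f(β(W_F − ΔG) + M) = Σ_R f(β(W_R + ΔG) − M),  f(x) = 1/(1+eˣ),
M = ln(n_F/n_R)

by bracketed root-finding (bracket expanded geometrically from the
two-sided mean estimate; root polished to 10⁻⁹ kcal/mol). BAR is the
primary estimator because it is the minimum-variance two-sided choice
and is checkable against closed forms; one-sided exponential averaging
(`expEstimator()`, log-sum-exp stabilised) is retained as a
cross-check. Uncertainty is a seeded bootstrap (default 200 resamples)
rather than the analytic variance, for uniform treatment across
estimators. Windows are treated as independent: leg ΔG is the sum,
its s.e. the quadrature sum. Replica-exchange bookkeeping is out of
scope — samples are treated as equilibrium draws of their window.

Temperature enters only through RT. The thermostat default is 310 K;
the printed-precision conversion exp(1.32/RT) = 8.52 → nearest power
of ten 10 uses the same temperature, since the source analysis leaves
the conversion temperature unstated.

Per-protomer aggregation reports the component sum. Note one genuine
bookkeeping tension in the source material: the three printed
per-protomer values (1.43, 0.50, −0.37 kcal/mol) sum to 1.56, while
the printed grand total is 1.32 kcal/mol with the remaining three
sites described only as non-significant. The package does not
reconcile these; `aggregateProtomers()` reports whatever six values it
is given, and the affinity conversion can be applied to a
user-supplied total.

## Trajectory statistics

Contacts use heavy atoms only (hydrogen positions are the least
reliable coordinates and the 3 Å criterion does not name a selection),
with *strict* inequality at the cutoff: a pair at exactly 3.000 Å is
not a contact. RMSD uses Kabsch superposition via SVD with a
determinant correction against reflections; at least 3 non-collinear
atoms are required to define the rotation. Multi-model PDB is the only
trajectory format (plus in-memory arrays); engine-specific energy-file
dialects are deliberately not parsed — work samples arrive as tidy CSV
(`window, direction, work_kcal_mol, temperature_k`).

## Statistics module

The gate requires *all* groups to pass Shapiro–Wilk at α; a single
failure routes the whole comparison to the nonparametric branch. A
group with zero variance cannot be tested and is treated as
non-normal. The nonparametric branch is Kruskal–Wallis with the
standard tie correction and Dunn's rank z-tests with Šidák adjustment
1 − (1−p)^m; the parametric branch is one-way ANOVA with
Bonferroni-adjusted pooled t tests (a plain two-sided t test for two
groups). The source's star legend overlaps its own asterisk rule; the
package implements nested thresholds — `*` p < 0.05, `**` p < 0.005,
`***` p < 0.0005 — as a deliberate reconciliation.

## What the synthetic data emulate — and what they do not

`genGcampEnsemble()` builds each trace as

baseline·e^(−t/τ_bleach) + Σ spontaneous events + evoked transient +
ionomycin plateau + iid Gaussian noise

* **Evoked transient**: smooth unimodal
  (1 − e^(−t/rise))·e^(−t/decay), rise 10 s, decay 40 s, scaled to a
  peak amplitude. Any smooth unimodal shape would do; this one has an
  analytic area (`transientArea()`), which anchors the closed-form CCL
  ground truth. Condition effects scale the amplitude: mutant/WT
  ratio 1.58, antibody inhibition 1/(1+(c/IC₅₀)^h) with IC₅₀ 10 nM
  (WT) and 80 nM (mutant), h = 1.
* **Spontaneous oscillations**: homogeneous Poisson timing (default
  1 event/min, in the physiological range and sparse enough that
  coincidence summing of overlapping events stays small), log-normal
  amplitudes (their empirical distributions are non-normal) with the
  arithmetic mean anchored so evoked transients are 9-fold larger in
  amplitude and FWHM.
* **Ionomycin**: saturates the indicator — the plateau *replaces*
  ongoing activity rather than adding to it, so ΔF_max equals the
  plateau exactly and zero-noise recovery is exact to machine
  precision.
* **Noise**: additive i.i.d. Gaussian (sCMOS shot/read noise at
  moderate intensity). No pixel-level simulation, no PSFs, no motion:
  passing tests demonstrate the *analysis chain*, not robustness to
  segmentation or imaging artefacts.
* **ATP**: piecewise-linear rise to fold·baseline 300 s after
  stimulation, linear decay, 30 s sampling, with configurable gap
  indices emulating reagent-addition blackouts. Piecewise linearity
  makes the trapezoid AUC exact, so gap-robustness is testable
  exactly.
* **FEP work**: per window, forward ~ N(ΔG + σ²/2RT, σ²) and
  reverse ~ N(−ΔG + σ²/2RT, σ²) — the unique Gaussian pair satisfying
  the Crooks relation. Defaults: 32 windows, 750 samples/direction
  (1.5 ns per window with energies every 10 ps across 5 replicas),
  σ = 0.25 kcal/mol (≈ 0.4 kT, a well-converged window).
* **Toy trajectories**: two residues whose minimum heavy-atom distance
  is exactly 2.5 Å on scheduled contact frames and 4.5 Å otherwise,
  plus a decoy hydrogen nearer than any heavy atom so that
  heavy-atom-only selection is exercised.

One global seed is hashed into per-stream sub-seeds
(`subSeed(seed, stream)`), so adding a generator never perturbs
another's draws and every pipeline output is byte-reproducible from
`(config, seed)`.

## Problem sizes and numerical choices

The default study (`defaultRunConfig()`) uses 30 ROIs per condition,
7 antibody concentrations (0 plus 10⁻¹⁰–5×10⁻⁶ M), 40 DAPI ROIs,
5 ATP wells, 32 λ-windows × 750 samples/direction per leg, 100
trajectory frames, and 100–200 bootstrap resamples — sizes chosen to
mirror the emulated experiments while keeping a full run in seconds.
`zeroNoiseRunConfig()` switches off every stochastic component; under
it the pipeline reproduces the generator truth to ≤ 10⁻⁶ relative
error (verified in the test suite). Root-finding tolerances are
10⁻⁹ kcal/mol (BAR) and 10⁻¹⁵ relative (Levenberg–Marquardt `ftol`);
trapezoid endpoints are interpolated linearly; ties in peak merging go
to the earliest sample.

## Known limitations

* With a 10 s baseline the per-trace bleach correction can only detect
  strong bleaching; mild trends pass through and contribute ~1% to
  condition ratios.
* FWHM of narrow spontaneous events (≈ 4.7 s) is measured on a 1.3 s
  grid; linear-interpolation width estimates run ~10% high at that
  sampling ratio, so the recovered FWHM fold is biased slightly below
  the generator's 9. The amplitude fold does not share this bias.
* Peak merging can, in adversarial noise configurations, split a
  merged group when the threshold removes its middle member; peak
  counts are monotone in the threshold for well-separated events.
* The Hill floor is bounded to [0, 0.95]; a panel whose true floor
  exceeds this is mis-fit rather than flagged.
* BAR assumes uncorrelated samples; autocorrelated work series would
  need prior subsampling.
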