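---
title: "Methods: block-design fNIRS analysis for a two-arm sleep trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: block-design fNIRS analysis for a two-arm sleep trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`nirsvft` analyses multichannel functional near-infrared spectroscopy
(fNIRS) recordings acquired under a block-design verbal fluency task
(VFT) in a two-arm, pre/post randomized trial of chronic insomnia, and
ships a synthetic-cohort generator so that every stage of the analysis
can be verified against known ground truth. This vignette is the
package's own account of the models and the choices behind them.

## The measurement and the paradigm

Each recording is a 48-channel time series of oxygenated haemoglobin
(HbO2) concentration change, in mmol/L·mm (concentration times optical
pathlength), sampled at 5 Hz from a 15-source / 16-detector
frontotemporal probe cap. Channels are grouped into nine regions of
interest (ROIs): bilateral superior frontal cortex (SFC), dorsolateral
prefrontal cortex (DLPFC), ventrolateral prefrontal cortex (VLPFC),
superior temporal cortex (STC), and the medial prefrontal cortex
(mPFC). The published description of this montage fixes only three
channel anchors (16 and 36 in mPFC, 18 in lDLPFC) and the overall
probe geometry; `default_montage()` is therefore a documented
*plausible default* consistent with those anchors, with equal left and
right channel counts for the eight lateral ROIs (SFC and VLPFC 5 per
side, DLPFC 6, STC 4, mPFC 8). Every downstream computation is
map-agnostic: a device-specific map can be supplied via
`load_montage()` (TSV or YAML) and everything else follows it.

The VFT paradigm is 25 s of pre-task rest, three contiguous 20 s
word-generation blocks (no inter-block rest), and 55 s of post-task
rest: 140 s, 700 samples. `vft_paradigm()` encodes this and all window
arithmetic derives from it; times are `[start, end)` in seconds, sample
`i` covers time `(i-1)/fs`, indexing is 1-based in the API.

## Preprocessing

The chain is fixed and logged in each recording's provenance:
optional intensity conversion, motion-artifact handling, rest-window
detrending, low-pass filtering, baseline panning.

**Modified Beer–Lambert conversion** (`mbll_convert()`), used when the
device exports raw dual-wavelength (785/825 nm) intensities rather
than haemoglobin units. Optical density change is
`dOD = -log10(I / I0)`; `I0` is the *geometric* mean over the first
10 s — the arithmetic mean in optical-density space — so the
conversion is an exact linear re-reference (the arithmetic intensity
mean would make the round trip only approximate). The 2×2 extinction
system (rows scaled by the differential pathlength factors) is solved
per sample. Extinction defaults follow the standard literature shape
around the ~800 nm isosbestic point: deoxygenated haemoglobin absorbs
more strongly below it, less above it. The operation is optional
because most devices, including the one this pipeline emulates, export
HbO2 directly.

**Motion artifacts** (`detect_motion()`, `correct_motion()`). The
vendor software's criterion is not public, so the package implements a
transparent two-criterion detector with a 2 s moving window and a
common threshold (default z > 5): (i) a z-score of the first
difference against a running-median centre and a robust (MAD) scale,
and (ii) a complementary amplitude z-score of the residual from a
running median of the signal itself. The second criterion exists
because a transient whose rise is split across two samples halves its
derivative z while its level excursion is intact; two-criterion
designs (derivative plus amplitude) are standard in fNIRS motion
detection. Flags are dilated by half a window on each side. Repair
replaces flagged spans by shape-preserving monotone-Hermite cubic
interpolation through the flanking clean samples: exact on ramps, and
bounded by the neighbouring data so that long merged spans cannot
overshoot (an ordinary global cubic spline can swing by an order of
magnitude over a 25-sample gap and did, in development). Both the
method and thresholds are configuration; `"none"` disables repair.

**Rest-window detrending** (`detrend_rest()`, default on). Slow
instrumental drift corrupts the task-window statistics: it inflates
channel variance (attenuating correlations) and adds spurious
inter-channel correlation with random sign. The vendor's description
of the filtering step includes removal of slow-drifting interference,
but a high-pass filter sharp enough to remove drift would also
attenuate the single-block task response, whose fundamental lies below
0.01 Hz — and the package guarantees >0.99 transmission at 0.01 Hz.
The resolution is a linear trend fitted per channel by least squares
through the *rest* samples only (the pre-task rest plus the post-task
rest after a 20 s washout for the hemodynamic tail) and subtracted
from the whole recording: drift is removed, the task response is
untouched by construction.

**Low-pass filter** (`lowpass()`). A 0.1 Hz Butterworth, default
order 4, applied forward–backward (zero phase), so the effective
magnitude response is the squared (8th-order) Butterworth. At 5 Hz
sampling this passes the task-locked response (fundamental below
0.02 Hz) essentially untouched (>0.99 at 0.01 Hz) and suppresses
cardiac pulsation at 1.1 Hz below 1e-2. The application is
mean-anchored (channel means are removed before filtering and
restored after), which makes the DC gain exactly 1, and uses
odd-reflection padding of about three cutoff periods to suppress edge
transients; the inner loop is compiled (Rcpp) because the Monte-Carlo
test suite filters tens of thousands of recordings. No high-pass is
applied by default — offset removal is the panning step's job — but
`highpass_cutoff_hz` exists for sensitivity checks.

**Baseline panning** (`baseline_pan()`). Each channel is re-zeroed by
subtracting its minimum over the last 10 s of the *pre-task* rest.
The source description says only "the baseline state"; the pre-task
rest is the only baseline that precedes the task, so it is used, and
the choice is flagged here. After panning that window's minimum is
exactly 0 and the operation is idempotent.

**Quality gating** (`assess_quality()`, `subject_quality_gate()`).
"High signal quality" is not publicly defined, so a composite rule is
used: a channel is good iff finite everywhere, not flat (SD above
1e-6), and artifact-flagged on less than 20% of samples. Thresholds
are configuration; the subject-level rule — at least 36 good channels
at *both* timepoints, boundary inclusive — is fixed, since it is the
published inclusion criterion.

## Activation analysis

`block_contrast()` computes, per channel, the mean HbO2 over the full
25 s pre-task rest (baseline), the mean over the 60 s task period, and
their difference — the activation contrast. Bad channels yield missing
values, never zeros. Inference is group-level throughout: per-subject
contrasts are computed first and tested across subjects
(`channel_activation_tests()`), either against zero per group ×
timepoint ("activation") or pre vs post per group ("change", a paired
t-test). Per-subject single-session tests are deliberately not used —
the quantities the trial reports are group maps. Benjamini–Hochberg
FDR correction (`benjamini_hochberg()`, an explicit step-up
implementation cross-checked against `p.adjust`) is applied within
each family of up to 48 channels per group (× timepoint); all-missing
channels shrink the family size rather than being imputed.
Significance is `q < 0.05`. The ROI table (`roi_tests()`) averages
member-channel contrasts per subject, applies the normality-gated
within-group and between-group machinery of the clinical module, and
reports raw p-values for the 9 regions (the published region table's
presentation) with BH q-values alongside.

For the paired activation baseline there is a second open point: the
vendor's "baseline" could be the pre-task rest mean or the panning
window. The pre-task rest mean is used, consistent with the contrast
definition above, and flagged here.

## Connectivity analysis

`fc_matrix()` computes Pearson correlations between all channel pairs
over the *task window only* (300 samples); rest windows are excluded.
Zero-variance or gated-out channels give missing rows with pairwise
deletion downstream (families shrink accordingly). All averaging and
inference on correlations happens on the Fisher z scale
(`atanh`), back-transformed for reporting: variance stabilisation is
the defensible default where the source is silent, and the choice is
isolated in two one-line functions so a raw-r sensitivity variant is
trivial. `roi_fc()` aggregates to the 9×9 region level (mean z over
member channel pairs; within-ROI diagonal over distinct pairs);
`mean_fc()` averages all 1128 off-diagonal pairs. `fc_change_tests()`
runs within-group paired t-tests on `z_post - z_pre` and between-group
pooled t-tests on the change, with BH correction within each family
(1128 channel pairs; 45 region entries; the single mean-FC comparison
is reported uncorrected, mirroring a single-statistic group test).
Cohen's d for connectivity changes is computed on the z scale —
another point the source leaves open, flagged here.
`correlate_outcome()` relates per-subject connectivity change to
clinical change with the t-transform p-value and a Fisher-z CI.

## Clinical statistics

The scale analysis mirrors a standard two-arm trial report. Tests are
gated by Shapiro–Wilk at alpha 0.05 (`normality_gate()`): paired
t vs Wilcoxon signed-rank within groups, pooled t vs Mann–Whitney
between groups. Rank statistics use the normal approximation with tie
correction (exact for n ≤ 10 without ties); R's `wilcox.test` does not
expose the Z statistic, which the rank effect size `r = |Z|/sqrt(N)`
(N = total observations) requires, so the Z machinery is implemented
directly and cross-checked against `wilcox.test` p-values. Effect
sizes are Cohen's d on change scores with a pooled, df-weighted SD and
a noncentral-t 95% CI (the d CI method is not stated in trial reports
of this kind; noncentral-t inversion is the exact choice), negative
when the first group improves more. A reproduction mode
(`between_group_from_summary()`, `sd_from_ci()`) recovers change-score
SDs from printed means and t-based CIs, which reproduces published
effect sizes to three decimals. The 2×2 chi-square
(`chi_square_2x2()`) is Pearson's formula *without* continuity
correction — validated by exact reproduction of three published
statistics — and errors on zero marginals. The power analysis
(`sample_size_two_t()`) iterates n upward through the exact
noncentral-t power of the two-sample two-tailed test
(`ncp = d sqrt(n/2)`, df = 2n-2) and `inflate_dropout()` applies the
multiplicative ceiling rule `ceil(n (1 + rate))` — the only rule
consistent with 31 evaluable per group becoming 76 recruited at a 20%
dropout allowance (dividing by 1 - rate would give 78).

## The synthetic cohort generator

The generator exists so that the pipeline's operating characteristics
are testable without access to trial data. It emulates the
*statistical structure* the analysis assumes, not the device physics.

**Task response.** A canonical double-gamma HRF (difference of gamma
densities with unit rate; response mode 6 s, undershoot mode 16 s,
ratio 1:6) convolved with the three-block boxcar and normalized to
unit peak. The source never specifies an HRF; this is
simulator-internal and not claimed to match the instrument.
Activation amplitudes are per (group × timepoint × ROI), defaulting to
zero at baseline with post-treatment gains that mirror the published
qualitative pattern (largest intervention gains in mPFC, lDLPFC,
rVLPFC and lSFC; a broad smaller control gain peaking in rVLPFC), at
the published magnitudes (0.01–0.075 mmol/L·mm). Per-subject,
per-timepoint ROI amplitude deviations (SD 0.10) reproduce realistic
between-subject spread (~0.12 at the ROI level).

**Connectivity.** Inter-channel correlation comes from a latent-factor
model: each community is a channel set sharing a unit-variance latent
AR(1) signal; a channel with loading `w` against passband
idiosyncratic noise of SD `s` correlates with a same-community partner
at `w_a w_b / sqrt((w_a^2+s^2)(w_b^2+s^2))`. Two default communities:
a *global* community over all 48 channels (systemic physiology,
carrying the group difference in mean FC, ~0.35 baseline rising to
~0.47 post-intervention vs ~0.38 post-control) and a *frontal*
community (lSFC, lDLPFC, mPFC, rDLPFC) whose post-intervention loading
increment produces the region-pair gains. The latent and the
idiosyncratic AR(1) share one spectrum, so low-pass filtering leaves
their correlation essentially unchanged; oscillation and white-noise
residuals attenuate measured correlations by only a few percent.

**Treatment-response heterogeneity.** Each subject carries a response
multiplier on the pre-to-post loading increment, `1 + N(0, resp_sd)`
with `resp_sd = 3.5` by default (responders, non-responders, and some
decliners). This value is a deliberate identifiability calibration:
the mean-FC estimate from one 60 s task window carries irreducible
estimation noise of about 0.12 z-units per session, so the true
between-subject spread of the FC change must dominate it (here ~0.3 z)
for any brain–behaviour correlation to be recoverable at n = 27. A
generator with the small printed intervention-arm spread would make
the published correlation unrecoverable by construction; the default
therefore targets identifiability and documents the tension.

**Physiological noise and artifacts.** Defaults per channel: AR(1)
background (marginal SD 0.08 mmol/L·mm, coefficient 0.95 at 5 Hz),
white noise (SD 0.02), Mayer-wave / respiratory / cardiac sinusoids
(0.10 / 0.25 / 1.10 Hz, amplitudes 0.04 / 0.06 / 0.08, random phase
per channel), and a random linear drift (slope SD 0.002 per second).
Motion spikes (default 2 per minute, amplitude SD 2 mmol/L·mm — an
order of magnitude above the noise floor, the regime scalp-coupling
events occupy and the regime a z > 5 detector is designed for) are
injected *after* signal composition, so preprocessing must genuinely
remove them. Step-like baseline shifts exist in the model but default
to rate 0: interpolation repair cannot undo a persistent level change,
and that limitation is deliberate and documented rather than hidden.

**Scales.** PSQI sub-dimensions are integer 0–3 scores (rounded,
clamped — hence discrete and skewed, giving the normality gate real
work); SDS/SAS/PSS-14 are Gaussian with published baseline and change
moments. The PSQI total change is linearly coupled to each subject's
*true* change in mean Fisher-z connectivity:
`change = group_mean + slope (dz_i - mean dz) + noise`, with the noise
SD set from the realized spread of `dz_i` so the population
correlation between improvement and true FC gain is 0.5 (slope −6
points per z-unit; clamping to the 0–21 instrument range costs a few
hundredths of correlation). The full ground truth (per-subject
loadings, response multipliers, true mean-z changes, the realized
noise SD) is returned for recovery tests.

**Determinism.** All randomness flows from one seed through named
substreams keyed by subject, timepoint and stage, so any recording can
be regenerated in isolation and a full cohort is byte-identical on
rerun.

## What the simulations do and do not show

The generator reproduces the data structure the analysis assumes:
block-locked hemodynamic responses, community-structured correlations,
physiological oscillations at the right frequencies, heavy-tailed
motion transients, instrument-ranged scale scores, and a known
behavioural coupling. Passing tests therefore show that the pipeline's
statistics are calibrated (type-I error, FDR control) and its
estimators consistent (amplitude, connectivity-change and coupling
recovery) *under this model*. They do not show robustness to what the
model omits: deoxy-haemoglobin dynamics beyond a fixed anticorrelated
ratio, superficial/scalp signal contamination, baseline drifts that
are nonlinear in time, step artifacts (off by default, see above),
serially dependent scale measurement error, or montage registration
error. Real-data conclusions inherit those caveats.

## Numerical and testing choices

Windows are `[start, end)` with `sample = round(t fs)` boundaries;
correlations are clamped to `|r| <= 1 - 1e-15` before `atanh`;
BH q-values use the same floating-point association as `p.adjust` so
the oracle comparison is exact; the noncentral-t inversions use
`uniroot` at 1e-10 on a bracket around the observed statistic;
loadings are clamped to `[0, 0.999]`. Degenerate inputs are defined,
not accidental: zero-spread differences give t = 0 and p = 1; a
zero-variance channel is excluded, not zeroed; all-zero differences
under the signed-rank test are flagged; n = 2 samples skip the
normality gate (parametric by convention).

The Monte-Carlo test suite uses 500 null cohorts (n = 12, single arm)
for the type-I check, 500 partial-null cohorts (n = 16, 25 of 48
channels active at 0.15 mmol/L·mm) for the FDR check, one full
two-arm cohort at n = 32 per group for parameter recovery, and 200
single-arm cohorts at n = 27 for coupling-recovery coverage — sizes
chosen to give the binomial error of each estimated rate a comfortable
margin against its acceptance band.

## Worked example

```{r example}
library(nirsvft)
run <- run_pipeline(sim = sim_config(seed = 1, n_per_group = 32))
glance(run)
run$correlation
autoplot(run)
```
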