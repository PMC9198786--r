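---
title: "Ultra-short-term HRV in mice: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultra-short-term HRV in mice: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailhrv)
```

## The problem

Frequency-domain heart-rate variability (HRV) partitions the spectral power
of beat-to-beat interval fluctuations into bands that reflect autonomic
modulation. Standard human practice uses minutes of ECG. A mouse heart
beats about eight times faster (~600 vs ~75 bpm), so its HRV spectrum is
shifted up in frequency by roughly the same factor, and seconds of mouse
data should contain the information that a minute of human data does. That
matters practically because non-invasive tail-cuff plethysmography yields
clean beat-by-beat records only for stretches of a few seconds at a time.

`tailhrv` provides the simulation and analysis machinery to work in this
ultra-short regime: a tachogram simulator with a controlled spectrum, beat
extraction from pulse-like waveforms, Lomb–Scargle spectral estimation for
uneven sampling, a Monte-Carlo record-length study, and the two-group
comparison statistics for band-power vectors.

## The RR spectral model and simulator

RR fluctuations are generated to follow a bimodal Gaussian one-sided power
spectral density,

$$S(f) = \frac{\sigma_1^2}{\sqrt{2\pi c_1^2}}\,
  e^{-(f-f_1)^2/2c_1^2} +
  \frac{\sigma_2^2}{\sqrt{2\pi c_2^2}}\, e^{-(f-f_2)^2/2c_2^2},$$

the classic two-peak (LF + HF) description used in McSharry-style synthetic
heartbeat generators. The parameters, with defaults:

| parameter | meaning | human default | mouse default (κ = 8) |
|---|---|---|---|
| $f_1$ | LF peak centre (Hz) | 0.1 | 0.8 |
| $f_2$ | HF peak centre (Hz) | 0.25 | 2.0 |
| $c_1, c_2$ | Gaussian widths (Hz) | 0.01 | 0.08 |
| $\sigma_1^2/\sigma_2^2$ | LF/HF power ratio | 0.5 | 0.5 |
| mean RR | mean interval (s) | 0.8 | 0.1 |
| SD RR | interval spread (s) | 0.048 | 0.006 |

Species scaling is a single factor κ: frequencies and widths are multiplied
by κ and the mean interval (and its SD, preserving the coefficient of
variation) divided by κ. κ = 8 encodes the ~8× mouse/human heart-rate
ratio; the 0.1 s mouse mean interval corresponds to 600 bpm, and 6 ms
interval SD is a realistic sedated-mouse variability. These defaults were
fixed once, up front, as the study conditions for every simulation in the
package.

`simulate_rr()` samples $S(f)$ on an even grid, attaches one independent
uniform phase per positive-frequency bin (conjugate-symmetric, so the
signal is real), inverse-FFTs to a continuous evenly sampled tachogram
$r(t)$, affinely rescales to the target mean and SD, and converts to
discrete beats by iterative interval sampling: $t_0 = 0$,
$t_{k+1} = t_k + r(t_k)$, with linear interpolation of $r$. We chose
iterative sampling over integral-pulse-frequency modulation because it is
simpler and spectrally faithful at HRV frequencies far below the beat rate;
the conversion is isolated in one internal function so it can be swapped.
The internal tachogram is sampled at `mean_rr/4`, i.e. a Nyquist frequency
of twice the heart rate, far above both spectral peaks.

Degenerate inputs behave predictably: zero `sd_rr` (or zero total power)
gives a perfectly regular tachogram; an `sd_rr` large enough to drive
$r(t)$ non-positive is an error naming the offending parameters rather than
a silently clipped record.

## Waveforms and beat detection

`synth_waveform()` places one Gaussian pressure pulse (SD = pulse width / 4)
at each beat time and adds a slow sinusoidal baseline drift plus white
noise — the features of a tail-cuff volume-pressure trace that matter for
beat extraction. It does not attempt pulse morphology (dicrotic notches,
occlusion-cycle artefacts), so detector performance on real traces must be
validated separately; what the synthetic test bed establishes is correctness
of the extraction machinery against known ground truth.

`detect_beats()` detrends with a moving-average baseline (window 0.5 s),
smooths (4 ms), and thresholds local maxima at `threshold_k` (default 3)
times the robust spread, estimated as MAD × 1.4826 so the threshold reads
in Gaussian-SD units. Candidates closer than the refractory period
(default 50 ms) are resolved by keeping the larger peak. Peak times get
sub-sample precision by parabolic interpolation through the three samples
around each maximum. Intervals outside the plausibility gate
[0.05, 0.3] s — a 200–1200 bpm envelope for sedated mice — are treated as
artefacts: the smaller beat of a too-short pair is removed, a too-long
interval is counted as a missed beat, and the artefact count is reported.
Because the baseline is subtracted and the threshold is relative, detection
is invariant to offset and gain.

## Lomb–Scargle estimation and band powers

The tachogram is inherently unevenly sampled, so spectral estimation uses
the classical Scargle periodogram with the per-frequency time offset τ that
orthogonalises the sine and cosine bases — equivalently, a least-squares
sinusoid fit at each frequency. Intervals are mean-centred and located at
their left beat times (midpoints are selectable; at these frequencies the
difference is negligible). Raw output uses Scargle's variance
normalization. Two further conventions are recorded as flags on the object:
unit-sum normalization (power sums to one — the scale used for all
averaging and convergence computations) and an optional max-to-one display
scaling used only for surface plots. Absolute calibration is deliberately
not claimed; band powers are reported in arbitrary units.

A grid beyond the pseudo-Nyquist frequency `0.5/median(interval)` warns
rather than errors, since uneven sampling has no hard Nyquist limit. A
zero-variance interval series returns an all-zero periodogram with a
degenerate flag (not an error), with a relative tolerance on the variance
so that floating-point jitter from accumulated beat times cannot
masquerade as variability.

Band powers are trapezoidal integrals over contiguous bands. The default
ten 0.2 Hz-wide bands spanning 0–2 Hz put the band centres at 0.1, 0.3,
…, 1.9 Hz, the bandings in which ultra-short mouse HRV is reported. The
default frequency grid (0.05–2.0 Hz, step 0.025 Hz) gives ≥ 8 grid points
per band; bands are clipped to the grid span where they extend past it.

## The record-length convergence study

`run_duration_study()` asks how short a record can be while still yielding
a stable periodogram. Each of `n_sims` simulations draws one
reference-length record (default 64 s) and prefix-truncates it to every
duration in the grid (default 2, 4, 8, 16, 32, 64 s). Nested prefixes were
chosen over independent per-duration simulations: they are cheaper and
give lower-variance convergence curves, since each short record is
contained in its own reference. Divergence is the L1 distance between
unit-sum periodograms — bounded in [0, 2] and directly interpretable as
total redistributed power fraction; Jensen–Shannon or other divergences
can be computed from the stored rows if preferred. The surface stores the
per-duration mean and SD of the normalized power across simulations, and
additionally the median across simulations of each truncation's L1
distance to its own reference periodogram.

The full-scale study uses 3000 simulations; the packaged tests and the
acceptance script run 300, which reproduces the qualitative convergence
shape at a tenth of the cost. At mouse scaling the divergence falls
monotonically with duration and most of the drop is complete by ~8 s —
the quantitative form of the claim that a few seconds of mouse record
suffice, and the mouse-equivalent of the 1 min human standard.

## Group statistics

Band-power vectors are compared between two groups (control vs drug) with
MANOVA: Wilks' lambda $\Lambda = \det(E)/\det(E+H)$ from the within- and
between-group cross-product matrices, with Rao's F approximation — exact in
the two-group case through the Hotelling $T^2$ equivalence, which the test
suite exploits by cross-checking against an independent implementation.
Temperature is recorded as metadata but not modelled as a MANOVA factor by
default: the design treats treatment as the sole grouping factor, because a
single control-vs-drug Wilks' lambda over the pooled temperature range is
the quantity of interest; callers can subset or stratify by temperature
explicitly. Univariate per-band one-way ANOVAs are always reported
alongside the multivariate test, unprotected — the output notes both so
users can apply their preferred gating convention.

Pairwise comparisons over the temperature × treatment factorial use
pooled-variance cell means: all unordered pairs of cell means (a full
6 × 2 grid gives choose(12, 2) = 66 contrasts), pooled-MSE standard
errors, a two-sided t reference, and Benjamini–Hochberg adjustment. These
are not mixed-model estimated marginal means — with repeated measures on
the same animals the standard errors would differ — but the comparison
grid and the multiplicity machinery are exactly the analysis of interest.
The BH step-up is implemented from its definition (sorted
$p_{(j)} m / j$, suffix minimum, capped at one) and cross-checked against
`p.adjust`. One property sometimes assumed of it is false and deliberately
not asserted: BH is not idempotent on its own output
(p = (0.3, 0.9) adjusts to (0.6, 0.9), which re-adjusts to (0.9, 0.9)).

The synthetic group fixture (`simulate_band_power_study()`) draws
band-power vectors as a common baseline (10 AU) plus unit-SD Gaussian
noise, with the drug group shifted by 0.8 SD in every band except the
0.5 Hz banding. That effect size gives the two-group MANOVA (10 bands,
n = 15 per group) power above 0.9 while leaving the spared band's
univariate test at its nominal level — a parameter-recovery fixture for
the whole comparison pipeline.

## What the synthetic data do and do not establish

The generator reproduces the features that drive the analysis: mouse-scale
beat intervals, a bimodal RR spectrum with controlled LF/HF ratio,
pulse-shaped waveforms with drift and noise, and a factorial group
structure with a known effect. It does not emulate sedation dynamics,
temperature dependence of heart rate, occlusion-cycle artefacts of real
tail-cuff hardware, ectopic beats, or non-stationarity within a record.
Passing tests therefore demonstrate that the machinery is correct and
calibrated under its stated model, not that any physiological conclusion
transfers to real recordings.

## Numerical choices and problem sizes

Simulations are deterministic given a single integer seed; Monte-Carlo
drivers seed once and consume the RNG stream sequentially. The packaged
test suite and acceptance script use scaled problem sizes chosen to keep a
full run around a minute on one CPU while leaving every Monte-Carlo margin
wide: 500 × 60 s records for spectral-ratio recovery, 300 simulations for
the convergence surface, 10 000 replicates for MANOVA type-I calibration,
200 for power, 100 seeds for detector sensitivity. Tolerances follow the
quantity's noise scale: exact identities (DFT equivalence, Wilks' lambda
affine invariance) at 1e-8 or tighter, Monte-Carlo rates at binomial-SE
margins, spectral peak locations within one grid step (0.025 Hz).

## Limitations

- The beat detector is designed for clean synthetic pulses; real VPR traces
  with occlusion cycles will need parameter retuning and possibly artefact
  models the package does not ship.
- Pairwise contrasts are pooled-variance, not repeated-measures; with
  per-animal correlation the raw p-values are approximate.
- The MANOVA treats records as independent observations; repeated records
  per animal violate that and call for a mixed model outside this
  package's scope.
- Absolute spectral power is uncalibrated (arbitrary units throughout);
  only relative and normalized quantities are comparable across records.
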