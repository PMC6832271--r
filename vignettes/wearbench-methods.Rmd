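---
title: "Benchmarking wearable physiological sensors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking wearable physiological sensors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearbench)
```

## The problem

Consumer wearables promise laboratory-grade physiology at a fraction of the
cost, but a study built on their output is only as good as their agreement
with calibrated reference equipment. `wearbench` implements a benchmark
pipeline for simultaneously recorded physiological time series: a reference
recorder (called VP throughout, the gold standard), a chest-belt wearable
(BH) and a wrist-band wearable (E4) measure heart rate (HR, bpm), inter-beat
interval (IBI, ms), ECG (mV) and skin conductance (GSR, µS) on the same
participant at the same time, and the package quantifies — per participant
and per channel pair — how well the devices agree.

Agreement is deliberately plural. A single correlation hides whether two
series disagree in scale, in timing, or in shape, so the pipeline computes a
battery of complementary statistics:

* **Correlation battery** (original scale): the coefficient of
  determination $R^2$, the lagged cross-correlation (±15 s, 1 s steps), the
  maximal information coefficient (MIC), and the nonlinearity score
  $\mathrm{MIC} - R^2$ with its three-way classification.
* **Similarity battery** (each series rescaled to $[0,1]$): the dynamic
  time warping (DTW) distance, the global discrete Fréchet distance, and a
  1-minute moving-window Fréchet profile.

Results are assembled into participant × pair matrices whose rows and
columns are sorted by agreement, so the best-behaved pairs and participants
read off the top-left corner.

## Pipeline and containers

Raw streams (`sensor_stream`) are timestamped samples per (platform,
parameter); a capability table restricts the combinations (VP records all
four parameters, BH lacks GSR, E4 provides only IBI and GSR). Loggers that
pack one second of samples into a single row are unpacked so every sample
carries its own sub-second timestamp. `transpose_align()` turns the
vertical records into a wide regular frame: each sample lands in the
half-open grid cell $[t, t+\Delta)$ anchored at the session start, cells
with several samples hold their mean, cells with none are missing. The
general grid is 100 ms; ECG uses 10 ms so R-peak timing survives
aggregation. The choice of which channels use which resolution is
configurable because nothing forces one global value.

`spline_fill()` closes the alignment gaps with a natural cubic spline —
the low-oscillation choice among interpolants — leaving observed cells
bit-identical and trimming unfillable leading/trailing gaps. Each channel
then exists in a raw and a ±5 s moving-averaged variant (time-defined
window, truncated at the edges so the series keeps its length), and skin
conductance additionally in band-filtered variants (first-order Butterworth
high-pass 0.05 Hz and low-pass 0.5 Hz, run forward–backward so the filtered
channel carries no artificial lag into the cross-correlation).

The metric battery itself runs on a common 1 s analysis grid (cell means of
the fine grids). Two considerations drive this: reported lags are integer
seconds, so nothing is lost for the cross-correlation; and the MIC grid
search scales super-linearly in sample length, so the 100 ms grid would
spend minutes per channel pair without changing the scientific content of a
20-minute session. The grid is a config entry (`analysis_resolution_ms`),
not a constant.

## Cardiac derivations

From each ECG channel the package derives IBI and three
heart-rate-variability band amplitudes. R peaks are detected by a
derivative–square–integrate scheme: band-pass 5–15 Hz, differentiate,
square, integrate over 150 ms, take local maxima above an
amplitude-relative threshold with a 250 ms refractory period, then refine
each peak to the band-passed ECG maximum. The threshold is relative, so
halving the electrode gain does not change the detected beat count.
Successive peak gaps give IBI; intervals outside 250–3000 ms are dropped as
artifacts; the beat-stamped sequence is spline-resampled at 4 Hz (twice the
upper HF edge). HR and IBI interconvert through
$\mathrm{IBI\,[ms]} = 60000 / \mathrm{HR\,[bpm]}$, an exact involution.

Band amplitudes use complex demodulation. For a band $[f_{lo}, f_{hi}]$
(VLF 0.025–0.07 Hz, LF 0.07–0.14 Hz, HF 0.14–0.5 Hz) the centred IBI series
is multiplied by $e^{-2\pi i f_c t}$ at the band centre $f_c$ and low-passed
at half the band width; twice the modulus is the amplitude envelope. The
low-pass is a 4th-order Butterworth applied in two zero-phase passes. One
pass is not enough: the HF half-width (0.18 Hz) barely exceeds the distance
from the HF carrier to the LF centre (0.215 Hz), so a single 4th-order pass
leaks ~20% of an LF tone into the HF estimate. The cascade (an 8th-order-
equivalent response built from a stable 4th-order section, which matters at
the very small normalized VLF cutoff) pushes that leak below 2 ms per 50 ms
of tone while leaving a tone at the carrier untouched.

## Correlation battery

$R^2$ is the squared Pearson correlation — identical to the OLS coefficient
of determination — computed on original scales so systematic offsets remain
visible in the residuals rather than being normalized away.

Raw physiological series are trend-dominated, and cross-correlating trends
manufactures spurious peaks. Both series are therefore differenced (at most
twice) until an augmented Dickey–Fuller test accepts stationarity for both,
then Pearson correlations are computed at every integer-second lag in
±15 s. The ADF test is the standard constant-term unit-root regression with
AIC-selected augmentation order (Schwert's rule bounds the order) and
MacKinnon (1994) response-surface p-values; its rejection behaviour was
cross-checked against an independent reference implementation on identical
series. The sign convention: `cross_correlation(x, y)` treats `x` as the
independent reference, and a positive best lag means `y` runs behind `x` —
with the reference listed first, wearable lags come out positive.

The MIC is the maximum over axis-aligned grids, subject to
$\mathrm{rows}\times\mathrm{cols} \le n^{0.6}$, of the table's mutual
information normalized by $\log_2 \min(\mathrm{rows},\mathrm{cols})$. It is
1 for any noiseless functional relationship and depends only on ranks. The
implementation optimizes the column axis exactly by a dynamic program over
clump boundaries (candidate cuts capped at $c \times \mathrm{cols}$
superclumps, $c = 15$); the row axis is enumerated exhaustively for small
samples ($n \le 40$, where the enumeration is cheap and the result provably
equals the global grid optimum) and otherwise fixed to the mass
equipartition heuristic with both variable orderings tried. Tests compare
the small-sample path against an independent brute-force search over both
axes, and the heuristic path is verified never to exceed the exact optimum.

Subtracting $R^2$ from MIC gives the nonlinearity score: below $-\epsilon$
the linear fit is not confirmed by the information coefficient ("false"
linear); within $\pm\epsilon$ the two agree ("true" linear); above
$+\epsilon$ the relationship is functional but not linear. The band width
$\epsilon$ defaults to 0.1 — the source analysis says only "approximately
zero", and 0.1 comfortably exceeds the MIC's sampling null at the cohort's
analysis length while staying far from the scores of genuinely nonlinear
pairs. One caution: the MIC's sampling null decays slowly with sample
size and sits above 0.1 for short series (the type-I property test
verifies that it has fallen below $\epsilon$ by 3000 samples), so
classifications of short series lean toward "nonlinear" and $\epsilon$
should be raised accordingly if the analysis is run on few points.
Per-pair MIC profiles across participants are clustered with k-means
($k = 3$, 25 restarts, Euclidean distance on the raw profiles since MIC is
already unit-scaled), and clusters are relabelled low/moderate/high by
ascending centroid mean so labels are reproducible.

## Similarity battery

Both elastic distances run on unit-rescaled series so that a distance of
0.1 means a tenth of the signal's own range regardless of units. DTW
accumulates $|a-b|$ along the optimal monotone warping path (standard step
set, anchored endpoints, no band constraint by default, no path-length
normalization — so values should only be compared between equal-length
pairs). The discrete Fréchet distance minimizes, over monotone couplings,
the maximum pointwise distance — the shortest leash. Because both series
share a grid after alignment, the leash is measured on values only; adding
the (identical) time coordinate would only dilute the value differences and
would put DTW and Fréchet on different scales. The moving-window local
profile applies the global Fréchet distance to aligned 60 s windows stepped
every 10 s, which localizes disagreement to activity phases.

Both dynamic programs are small Rcpp kernels ($O(nm)$ time, $O(m)$ memory)
and are tested against exhaustive enumeration of every warping path /
coupling: completely, for all series pairs up to length 4 over a 3-value
alphabet, and on seeded samples up to the full 8×8 path lattice. One
property often assumed of these distances is false and deliberately not
asserted: appending a shared tail can *reduce* either distance, because the
tail points open new couplings for earlier points; the tests assert the
provable direction (a shared tail never increases either distance).

## The synthetic cohort

The raw study data behind the original 18-participant experiment were never
deposited, so the package ships a seeded generator that emulates the study
conditions and makes every pipeline claim testable against known ground
truth. The protocol is fixed: 5 min seated rest, 10 min cycling with the
load stepped through 35/65/100/133/165 W every 2 min, 5 min cool-down;
18 participants by default.

Heart rate follows a first-order exponential approach to a load-dependent
target (rest baseline drawn from 62–78 bpm, gain 0.38–0.52 bpm/W, onset
time constant 30 s, recovery 60 s — plausible values for healthy adults;
the source describes only the protocol and qualitative curves). IBI is
$60000/\mathrm{HR}$ plus sinusoidal LF (0.105 Hz, 50 ms) and HF (0.30 Hz,
20 ms) modulation with per-participant phases, clipped to the 45–200 bpm
range; HR is re-derived from IBI so the two trajectories are exact
reciprocals. R peaks are placed so successive gaps equal the local true IBI
with 2 ms Gaussian jitter. Skin conductance is a tonic baseline (2–10 µS)
plus a slow load-driven drift (first-order low-pass of the load, 90 s time
constant, 1–3 µS at peak load) plus sparse phasic responses
(biexponential rise 1.5 s / decay 6 s shapes at Poisson event times, one
per ~45 s).

Sensor error models then degrade the truth per platform: sampling at the
device rate (VP GSR 25 Hz, E4 GSR 4 Hz, E4 IBI 64 Hz, ECG 250 Hz), a
constant acquisition lag (BH 1 s, E4 2 s — the reference leads), a
reciprocal range-dependent offset $a/v + b$ on BH heart rate (maximal at low
rates, vanishing at high rates), additive Gaussian noise, per-sample
dropouts, and for the E4 a larger phasic skin-conductance gain (the wrist
band responds more strongly to sweating than the gel-electrode reference).
ECG is rendered as a Gaussian R-wave pulse train — sufficient for the
detector contract, with no PQRST morphology. One cohort member (`RP 1-2`)
is deliberately degraded — 20% dropout, eightfold noise, slow wander, a
weak and noisy ECG — to emulate failing electrode contact; the pipeline
must flag it as the worst column of the R² matrix, and does.

What the generator does **not** emulate is worth stating: no real ECG
morphology or ectopic beats, no motion artifacts correlated with pedalling,
no heteroscedastic or non-Gaussian sensor noise, no clock drift (the lag is
constant), and phasic skin-conductance events are independent of the load.
Passing the recovery tests therefore shows the pipeline is correct and
sensitive under the stated error structure, not that real wearables meet
any particular agreement level.

All randomness flows from one master seed: participant seeds are drawn from
it, and each participant's stream rendering continues that participant's
RNG stream in a fixed order, so cohorts regenerate byte-identically.

## Numerical and design notes

* Grid cells are half-open and anchored at the session start: every sample
  lands in exactly one cell, deterministically.
* The session start is the earliest timestamp across a participant's
  streams (device clocks are assumed synchronized).
* Constant series: rescaling maps them to zero with a warning; the ADF test
  declares them stationary by convention; MIC returns 0 with a warning.
* Cross-correlation ties are broken toward the smallest |lag|; row/column
  sorts in benchmark matrices are stable, so ties keep enumeration order.
* Missing cells propagate as missing and are excluded from matrix averages,
  never imputed — a failed channel should look failed, not average.
* Distance matrices sort ascending (most similar on top/left), correlation
  matrices descending; both carry row averages as a final pseudo-column and
  per-group column averages as group rows.
* The default channel roster yields 17 moving-averaged parameters
  (7 direct, 8 ECG-derived, 2 band-filtered GSR variants), i.e.
  $\binom{17}{2} = 136$ correlation-battery pairs and 16 same-parameter
  similarity pairs per smoothing level; the roster is configuration, not a
  constant, and the counts are reported by `enumerate_pairs()`.

## Problem sizes used in the shipped checks

The test suite and the acceptance script validate at sizes chosen to keep a
complete run in minutes while leaving every mechanism exercised end to end:
the full 18-participant cohort under the default 1200 s protocol for lag,
amplitude and degraded-member recovery (with the per-pair battery reduced
to $R^2$ + cross-correlation for the cohort-wide run); exhaustive
oracle comparisons at small series lengths; MIC-vs-oracle at $n = 30$; and
null-pair sanity at $n = 10^4$. The full battery including MIC, DTW and the
Fréchet profile is exercised per participant rather than across the whole
cohort.

## Known limitations

* The MIC large-sample path is the standard equipartition heuristic; it is
  exact only on the small-sample path. Its value can sit a few percent
  below the true grid optimum on adversarial data.
* The ADF p-value surface is asymptotic; for very short series (n < 50) the
  stationarity decision is rough, which mainly affects how often the
  cross-correlation differences once more than strictly needed.
* DTW values are not comparable across pairs of different lengths (no
  normalization, by design).
* The R-peak detector assumes an upright dominant R wave, which the
  generator guarantees; inverted-lead real ECG would need a polarity check.
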