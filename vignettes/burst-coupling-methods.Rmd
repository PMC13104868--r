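---
title: "Methods: burst-resolved cortico-subthalamic beta coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst-resolved cortico-subthalamic beta coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question the pipeline answers

Beta-band (13–30 Hz) activity in the subthalamic nucleus (STN) of people
with Parkinson's disease is dominated by brief high-amplitude *bursts*.
Cortico-STN coherence is known to rise during bursts; the question this
pipeline addresses is whether measurable cortico-STN coupling *persists
outside* bursts, or collapses to what shared spectral structure alone would
produce. The pipeline therefore (1) detects bursts from the STN beta
envelope, (2) estimates coupling separately inside and outside bursts,
(3) compares non-burst coupling against circular time-shift surrogate
nulls, and (4) resolves coupling in time around burst onset.

## Processing chain

Every channel passes through a fixed chain: a zero-phase fourth-order
Butterworth high-pass at 1 Hz, a zero-phase fourth-order Butterworth
band-pass at 13–30 Hz, then trimming (the first 60 s of a clinical
recording are discarded once per recording, and 2 s are cut from each end
of each filtered signal). Zero-phase filtering is forward–backward
application; both passes use steady-state initial conditions (the filter
state that would hold had the signal been at its first value forever), so
start-up transients are far below the trimmed-away edges: a DC input leaves
a residual below 1e-8 of its level. "Fourth-order" is read as the overall
filter order (two poles per band edge for the band-pass), the conventional
meaning of a designed IIR filter order. The 1 Hz high-pass runs before the
band-pass; with a 13 Hz lower band edge it is nearly redundant, but it
protects the band-pass from large drifts and is applied in that order by
construction.

When a recording comes from the synthetic generator, the 60 s head discard
defaults to 0 s: the generator has no electrode-settling transient, so there
is nothing to discard.

## Burst detection

The STN beta envelope is the magnitude of the analytic (Hilbert) signal,
smoothed with a centered 50 ms moving average whose window shrinks at the
signal edges. Bursts are maximal runs of samples *strictly above* the 75th
percentile of the envelope; non-burst epochs are runs *strictly below* the
50th percentile; both must last at least 100 ms. Samples between the two
thresholds are transitional and deliberately unlabeled, which keeps
non-burst epochs away from burst boundaries. Percentiles use linear
interpolation between order statistics (R type 7) and are computed per STN
contact over the whole trimmed signal. Intervals are 0-based, half-open, in
trimmed-signal coordinates.

Two consequences of the percentile rule matter for interpretation. First, a
constant envelope makes both thresholds equal and yields no epochs (this is
reported, not an error). Second, the detector labels the top quartile of
*samples* regardless of how much of the recording truly contains bursts, so
when true burst occupancy differs from 25% the sample-level overlap
(Jaccard) between detected and true bursts is structurally capped below 1
even at high burst gain: with threefold burst gain and low background noise
the generator's bursts are recovered with Jaccard ≈ 0.45–0.6, limited by
occupancy mismatch and the ~30 ms boundary smear contributed by filtering,
envelope smoothing and burst ramps — not by missed bursts. The package's
recovery tests use 0.45 as the floor and, more importantly, verify that the
downstream *coupling* dissociation is recovered in ≥ 95% of simulated
pairs, which is the quantity the detector feeds.

## Coupling estimators

Both metrics are built from one pooled Welch decomposition per condition.
Within each epoch, Hamming-tapered, mean-removed sub-windows of length
`min(256, shortest segment)` samples are taken at 50% overlap, and
sub-windows are pooled across all epochs of a condition before the
estimators are formed. Pooling is the only way 100–400 ms epochs can supply
the multiple "trials" both estimators require; treating every epoch as an
independent realization of the same stationary condition is exactly the
assumption the burst/non-burst split encodes. To avoid bias from unequal
segment counts, at most 100 non-burst segments per pair enter the estimate
(sampled uniformly without replacement, deterministically per pair).

Magnitude-squared coherence is
`C(f) = |Σ_j X_j conj(Y_j)|² / (Σ_j |X_j|² Σ_j |Y_j|²)` over pooled
sub-windows `j`. The debiased weighted phase lag index uses only the
imaginary cross-spectrum `I_j = Im(X_j conj(Y_j))`:

```
dwPLI(f) = ( (Σ I_j)² − Σ I_j² ) / ( (Σ |I_j|)² − Σ I_j² )
```

which is insensitive to zero-lag (volume-conduction-like) and purely
amplitude-driven coupling, and removes the `j = j'` self-terms responsible
for small-sample bias. Negative values are legitimate under the null and
are reported as computed, never clipped; when every `I_j` is exactly zero
(strictly zero-lag coupling) the value is defined as 0 and flagged. Note
the debiasing argument assumes independent sub-windows; 50%-overlapping
windows share data, leaving a small positive residual under the null. This
residual cancels in the surrogate comparison below, because the null is
built from identically overlapping windows — the calibration tests confirm
it.

Both metrics are averaged over the beta-band bins of the frequency grid
implied by the pair's Welch window (`k · fs / window_len`, bins with
13 ≤ f ≤ 30 Hz), and the same bin set is reused verbatim for burst,
non-burst and surrogate estimates of that pair.

## Surrogate testing

The null hypothesis is "the two channels share spectral content but no
temporal alignment". Each of 200 surrogates rotates the STN beta signal
relative to the cortical signal by a uniform random 0.5–5 s offset (rounded
to whole samples, circular wrap), then recomputes the condition's
band-averaged coupling with identical epoch boundaries, Welch settings,
frequency bins and non-burst subset. The empirical p-value is the
proportion of surrogate values greater than or equal to the observed value
(`k/n`, so `p = 0` is possible and printed as "< 1/200").

A design point that matters: the relative rotation is implemented on the
*cortical* channel. Rotating the STN channel while keeping the
STN-envelope-defined epoch boundaries fixed would put burst-amplitude STN
content inside "non-burst" windows, giving the surrogate statistic a
different amplitude-weight structure than the observed one; the resulting
dwPLI null is wider than the observed statistic's sampling distribution and
the p-values become conservative (measured: type-I error 0.013 instead of
0.05). Rotating the cortical channel applies the same relative shift while
preserving the STN envelope/epoch alignment, and calibrates: on 500
uncoupled synthetic pairs, type-I error at α = 0.05 is 0.054–0.07 and the
p-value distribution is indistinguishable from uniform (KS p ≈ 0.25).
Surrogate RNG streams are derived deterministically from (seed, pair,
condition); both metrics are computed from the same 200 rotations, as both
are computed from the same segments.

## Burst-adjacent and peri-burst analyses

*Burst-adjacent:* each burst of length L is matched with the last L samples
of the nearest earlier non-burst interval at least L long and the first L
samples of the nearest later such interval. Shorter intervening non-burst
intervals are skipped, not shrunk, so durations stay exactly matched.
Requiring the *immediately adjacent* interval to be long enough was tried
first and rejected: long bursts rarely have equally long immediate
neighbours, so the valid set collapses onto short bursts — in synthetic
data, onto false-positive detections with no coupling — inverting the
expected contrast. Pairs with fewer than two bursts are excluded from this
analysis; coupling is pooled per role (burst / pre / post) across valid
triplets with a shared frequency-bin set.

*Peri-burst:* 15 ms windows centred at burst onset + offset, offsets
−50…+50 ms in 5 ms steps (21 windows). A 15 ms window holds under half a
beta cycle and cannot be subdivided into Welch sub-windows, so each window
contributes one Hamming-tapered DFT zero-padded to 256 points (the zero
padding interpolates the spectrum onto a grid fine enough to contain beta
bins), and the across-burst collection at each offset is the averaging
dimension. The matched baseline draws an equal number of windows at least
50 ms from any burst; 20 replicate draws give the baseline mean and SD, and
traces are read against mean ± 2 SD. Bursts whose ±50 ms context leaves
the recording are dropped and counted. Single-pair traces at this window
length are noisy; like the group analyses they are interpreted averaged
across contact pairs.

## Statistics

Burst vs non-burst comparisons across pairs use the two-sided Wilcoxon
signed-rank test (exact up to 25 non-zero differences without ties,
otherwise the tie-corrected normal approximation; zero differences are
dropped) with the paired t-test reported alongside. The paired effect size
is `dz = mean(diff) / sd(diff)` (sample SD); it is labelled `dz` in all
outputs. Observed-versus-surrogate association uses Spearman rank
correlation with the two-sided t-approximation p-value. Per-pair surrogate
p-values are reported uncorrected with α = 0.05 as a configurable summary
threshold; contact-level summaries report, per cortical contact, the
fraction of pairs exceeding surrogate expectations per condition and
metric, plus a "none" category for pairs significant in neither condition.
The report flags statistically significant contrasts whose |dz| < 0.3 as
negligible-effect rather than suppressing them.

## The synthetic generator

Each pair is two channels at 1 kHz. The STN channel is 1/f²-shaped Gaussian
background (RMS 1, flattened below 1 Hz) plus a narrow-band beta carrier
(white noise band-passed to 20 ± 3 Hz, baseline RMS 0.5) whose envelope is
multiplied by 3 inside bursts. Bursts are a homogeneous Poisson process
(0.8 onsets/s) with truncated-normal durations (mean 300 ms, SD 100 ms,
floor 120 ms), merged when overlapping, with 20 ms raised ramps shared by
the envelope gain and the coupling weight. The cortical channel is an
independent 1/f background plus a beta component mixing a phase-locked copy
of the STN carrier (constant lag, default π/4, built from the carrier and
its Hilbert quadrature) with an independent carrier at weight
`coupling_strength` (default 0.8) — inside bursts only (`burst_locked`),
everywhere (`tonic`) or nowhere (`none`). Implementing coupling on the
carrier phase keeps coherence/dwPLI targets controllable independently of
amplitude. Everything derives from one seed; the same seed reproduces the
pair bit-for-bit.

Defaults were chosen once to represent the targeted regime: bursts occupy
roughly a quarter of the recording (matching the 75th-percentile detection
rule), carrier bandwidth 6 Hz gives realistic envelope fluctuation, and the
in-band background-to-carrier ratio (~0.2 RMS in-band noise against 0.5
carrier) keeps detection non-trivial without burying the signal. The
generator does **not** emulate line noise, movement or electrode artifacts,
non-stationary burst rates, cortical-side bursting, multi-contact spatial
structure, or volume conduction; passing tests therefore demonstrate the
pipeline's statistical behaviour under its own assumptions, not robustness
to real-world artifacts.

## Numerical choices and degenerate inputs

- Trim arithmetic uses `floor(seconds × fs)` samples; all interval
  coordinates are 0-based half-open.
- Coherence from a single pooled sub-window is identically 1; it is flagged
  degenerate with a warning. dwPLI is an error below two sub-windows.
- dwPLI denominators exactly zero (all imaginary parts zero) yield 0 with a
  flag; the check is exact, keeping the estimator scale-invariant.
- Band-bin selection errors out, naming the minimum window length, when the
  Welch grid has no bin inside 13–30 Hz.
- Non-burst subsampling keeps original temporal order; the sampled subset,
  surrogate shifts and baseline windows all derive from named RNG
  sub-streams of one master seed, so results are independent of execution
  order.
- TSV fixtures are written with 17 significant digits and round-trip
  bit-exactly; EDF stores 16-bit integers and round-trips to within one
  quantization step of each channel's physical range.

## Problem sizes used in validation

Simulated cohorts use 30 s recordings (≈ 26 s analyzed after edge trims,
~20 bursts per pair): 500 uncoupled pairs for null calibration, 100–120
burst-locked pairs for dissociation recovery, 30 tonic zero-lag pairs for
the coherence/dwPLI contrast, and a 600 s noise signal for the
spectral-preservation check. These sizes give the binomial and KS checks
the resolution their acceptance bands assume.

## Known limitations

- The percentile detector's fixed 25% sample budget makes sample-level
  burst recovery depend on true occupancy (discussed above).
- Short beta bursts yield few Welch sub-windows; per-pair estimates at the
  default settings carry O(1/K) coherence bias, which cancels in
  burst-minus-non-burst differences and surrogate comparisons but makes raw
  band values scale with segment counts.
- The 15 ms peri-burst window trades frequency resolution for time
  resolution to an extreme degree; only across-burst, across-pair averages
  of those traces are interpretable.
- On fully synchronized synthetic cohorts the across-pair Spearman
  correlation between observed non-burst coupling and its surrogate mean is
  small, because pairs are exchangeable replicates; in heterogeneous real
  recordings that correlation instead tracks per-pair spectral structure.
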