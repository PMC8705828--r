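---
title: "Methods: signal models, detectors and statistics in slicephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal models, detectors and statistics in slicephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicephys)
```

slicephys implements the analysis chain used to characterise grafted
GABAergic interneurons in epileptic hippocampal tissue: detection of
spontaneous postsynaptic currents (sPSCs) in voltage clamp, detection and
scoring of epileptiform discharges in local field potential (LFP)
recordings with paired dark/light optogenetic stimulation analysis,
extraction of passive membrane and action-potential (AP) properties, and
summary statistics for behavioural seizure diaries. Because the raw
recordings behind such studies are typically not public, the package
pairs every analysis stage with a synthetic-signal generator whose ground
truth is known exactly, so the detectors can be validated end to end.

This vignette documents the models, the tunable constants and their
provenance, the numerical choices, and the known limitations.

## Signal containers and conventions

All signals are `trace` objects: uniformly sampled vectors with units
(pA, mV or µV), a sampling rate, and a start time. Sample *k* (1-based)
maps to time `t0 + (k-1)/rate`; every window in the package is half-open
`[start, end)` in seconds. These two conventions remove off-by-one
ambiguity between modules. Text and binary file containers carry the same
`key=value` header (`rate_hz`, `units`, `t0_s`); the binary container
round-trips doubles bit-exactly.

## Synthetic data: what is emulated, and what is not

The generators reproduce the statistical structure the detectors rely
on, with defaults chosen to match the study conditions they emulate:

* **sPSC traces** (`gen_psc_trace`): Poisson-timed events on a Gaussian
  baseline, each a difference-of-exponentials kernel
  $A(e^{-t/\tau_d} - e^{-t/\tau_r})$ normalised so its peak equals the
  drawn amplitude ($\tau_r$ = 0.5 ms, $\tau_d$ = 5 ms). Events are
  injected as inward (negative) deflections: the high-chloride internal
  solution used in these recordings inverts chloride currents inward,
  so a single polarity suffices. Default rate 1.4 Hz and mean amplitude
  15 pA sit in the range reported for grafted interneurons (1.4–2.5 Hz,
  8–15 pA). Amplitudes are lognormal with CV 0.3.
* **LFP traces** (`gen_lfp_trace`): sharp biphasic Gabor-like transients
  (40 Hz carrier under a Gaussian envelope, σ = 8 ms, ≈ 30–50 ms
  footprint) normalised to a stated peak-to-peak amplitude (default
  168 µV) on a background of white + 1/f noise with 50 Hz hum. Timing is
  a gamma renewal process with interval CV 0.2 — "pseudo-regular",
  between clock-like and Poisson — whose local rate switches between a
  dark and a light value according to the stimulation schedule. A
  short burn-in in operational time starts the process near
  equilibrium, so window counts are unbiased.
* **Test pulses** (`gen_test_pulse_response`): the analytic current
  response of the series-resistance/membrane circuit
  (Rs in series with Rm ∥ Cm) to 5 mV, 100 ms steps: instantaneous peak
  ΔV/Rs, steady state ΔV/(Rs+Rm), relaxation constant
  τ = Cm·RsRm/(Rs+Rm).
* **AP waveforms** (`gen_ap_waveform`): piecewise-smooth spikes whose
  true threshold, peak, width at threshold and AHP depth equal the
  inputs exactly on the sample grid, with a slow (2 mV/ms) approach ramp
  so any reasonable dV/dt criterion fires at the constructed threshold.
* **Seizure diaries** (`gen_seizure_diary`): per-animal Poisson onsets
  over a 7-day continuous monitoring window, exponential durations, and
  modified-Racine severities on grades 3–5 (milder stages are not
  registered from video).

Two calibration notes. First, the noise levels are package choices — the
study reports none. For the LFP background we use 0.5 µV white +
0.5 µV 1/f (≈ 0.7 µV RMS in-band). This is deliberately quiet, for a
substantive reason: the adaptive detection threshold
(4 × median × kurtosis, below) requires the discharges to dominate the
power distribution. The kurtosis of a power series containing rare
strong events saturates near the reciprocal of the fraction of time they
occupy, so at 0.1–0.5 Hz the threshold sits two orders of magnitude
above the background median; discharges of 168 µV on a µV-level
background clear it, which is exactly the regime the published
recordings show (threshold far below discharge peaks, and a per-event
coastline of ≈ 2.8 µV — our defaults reproduce that scale). Second, the
generators do not emulate slow electrode drift, unstable series
resistance, seal breakdown, or non-stationary discharge waveforms;
passing recovery tests on synthetic data therefore demonstrates
correctness of the algorithms under the stated signal model, not
robustness to every pathology of real rigs.

## sPSC detection

The detector low-pass filters the current trace at 400 Hz (zero-phase
4th-order Butterworth with reflection padding), then computes the
Pearson correlation between an inward unit-peak template and every
trace window of the template's length — a sliding, per-window-detrended
correlation evaluated with running sums and one FFT convolution.
Candidate onsets are local maxima of the correlation at or above the
acceptance threshold (default 0.6). Because the correlation of a single
event stays high along its decay, a weaker maximum is only kept when
the correlation dips clearly below it (prominence 0.05) between it and
every stronger accepted peak; genuinely overlapping events separated by
a valley survive, plateau wiggles do not. A 2 ms minimum separation (the
template rise window) prevents double-marking.

Per candidate, the onset is refined by walking back from the peak along
a lightly smoothed copy of the trace to where the deflection started
(protecting the baseline estimate when the mark is late, e.g. with a
mismatched template), the baseline is the median of the 5 ms before
onset, amplitude is baseline-to-extremum, and rise time is 10–90% with
sub-sample interpolation, crossings taken walking backwards from the
peak. Events with amplitude < 3 pA or rise time > 5 ms are excluded, as
in the published protocol; both cutoffs, the correlation threshold, the
template kinetics and the window lengths are configuration
(`analysis_config`). "Rise time" is not further specified in the
protocol; 10–90% is the standard convention and is used here. Detection
operates on the filtered signal (the protocol states filtering for
template generation; applying it at detection too is our default).
For distribution comparisons, `equal_n_subsample` draws an equal number
of events (default 42) per cell — a seeded uniform subsample; whether
the original analysis took a random or the first *n* events is not
stated, and random is the less biased default.

On synthetic traces with all amplitudes ≥ 10 pA and 2 pA noise, pooled
sensitivity and precision across 20 seeds exceed 0.98 and 0.99; the
residual misses are event pairs < 15 ms apart whose earlier member
genuinely fails the 0.6 correlation inside a 20 ms template window —
an intrinsic resolution limit of window-correlation detection, not a
tuning artifact.

## LFP discharge detection and light-effect analysis

Preprocessing follows the published order exactly: zero-phase band-pass
2–400 Hz, comb filter (2nd-order zero-phase notches at 50 Hz and every
harmonic up to 400 Hz, ±2 Hz), then decimation to 1 kHz (the band edge
doubles as the anti-alias filter). Signal power is the mean of squares
in a 50 ms window sliding sample-by-sample; the value is assigned to the
window's start sample. Mean-of-squares (rather than sum) keeps the units
µV²; both are available. The detection threshold is
4 × median × kurtosis of the power series, with kurtosis in the
non-excess (Pearson) form m₄/m₂² — the product is then guaranteed
positive (Gaussian → 3); the excess form is available for sensitivity
analysis, as the original convention is unstated.

Contiguous supra-threshold regions closer than 25 ms are merged (one
biphasic discharge would otherwise be marked twice), each region is
marked at its power maximum, and three per-event parameters are computed
on the filtered signal over a 200 ms window centred on the mark (or the
region, if longer): peak-to-peak amplitude, peak power, and the
coastline index $\frac{1}{N}\sum_{n=1}^{N-1}|y_{n+1}-y_n|$ — note the
normalisation by N, not N−1, per the printed formula. The 200 ms window
and 25 ms merge gap are package conventions (unstated in the protocol)
and are configurable.

One printed quantity does not cross-check: a mean "peak power" of
8.08 µV² is inconsistent with mean-of-squares over 50 ms of a 168 µV
peak-to-peak transient under any unit convention we could identify (the
rate, amplitude and coastline scales all reproduce). We report our
computed peak power as-is.

The light-effect analysis mirrors the published procedure: for each of
the 30 runs of a protocol, the event rate and mean per-event metrics are
computed within the 5 s light episode and within the paired 35 s dark
period preceding it; runs are averaged per slice; the per-slice
light-minus-dark differences are tested across slices with the Wilcoxon
signed-rank test. Runs with no events in a state contribute a rate of 0
but are excluded from that state's metric average. The single 3-minute
train protocol is analysed as one light period against the preceding
2 min of baseline. In validation we run the per-slice difference
pipeline on 100 seeded replicates of 9 slices × 30 runs at the event
level (ground-truth event times), having validated the signal→event
stage separately at full signal resolution; running all 100 replicates
through the filter chain at acquisition rate would cost hours for no
additional inferential content. At the study's effect size (dark 0.5 Hz,
light 0.45 Hz) the pipeline recovers the −0.05 Hz difference without
bias and the Wilcoxon test detects it in ≈ 100% of replicates — the
quasi-regular timing (CV 0.2) makes per-window counts far less variable
than Poisson counting would suggest.

## Intrinsic properties

From averaged test-pulse responses: Rs = ΔV/I_peak (the peak is exact at
the step-onset sample), Ri = ΔV/I_ss − Rs, and Cm by charge integration
of the transient, Q = ∫(I − I_ss)dt (trapezoid rule, integrated until
the current first settles within 2 noise-SDs of steady state). The raw
quotient Q/ΔV underestimates Cm by (Ri/(Rs+Ri))² — the capacitive charge
is attenuated by the series-resistance divider — so the estimate is
corrected by the inverse factor using the Rs and Ri estimated from the
same pulse. Without the correction the error reaches 17% at
Rs = 20 MΩ / Ri = 200 MΩ; with it, noiseless recovery is within 5%
(Cm within 1.4%) across Rs 5–20 MΩ × Rm 200–1000 MΩ × Cm 50–300 pF.
The resting membrane potential is taken from a zero-current voltage
reading (median), or passed through directly; it is not derivable from
the current response itself.

AP features use a dV/dt threshold criterion (default 20 mV/ms; 10 and
50 are common alternatives and configurable — the original criterion is
unstated): threshold is the voltage at the first sample whose forward
difference reaches the criterion before the first peak above 0 mV;
amplitude is threshold-to-peak; duration is the width at the threshold
voltage with sub-sample interpolated crossings; AHP amplitude is
threshold minus the post-AP minimum, reported positive. All features are
exactly invariant to a constant voltage offset. Light-evoked responses
report the peak baseline deviation within the pulse and the mean over
the final 100 ms as the steady state (measuring at pulse offset instead
is a one-line change); the latency to the first delayed synaptic event
reuses the sPSC detector after excluding a 5 ms direct-response window.

## Seizure-diary statistics

Per animal: seizures/hour over the monitoring window, total time in
seizures (min), mean duration and mean severity (ordinal grades averaged
as numbers, following the field's own practice). Group comparisons use
the Mann-Whitney test per metric; both "percent change of group medians"
and "median of per-animal percent changes" are reported, since either
reading of a published median decrease is defensible. Status epilepticus
is flagged when ≥ 4 onsets fall within any rolling hour, windows
anchored at each onset (no binning artifacts), overlapping flags merged.

## Statistics

The test battery is implemented from first principles with exact
small-sample modes, each validated in the test suite against brute-force
enumeration oracles and against the independent base-R implementations:

* Mann-Whitney: exact p by enumerating all rank assignments for combined
  n ≤ 12 without ties (at most 924 arrangements — instantaneous; the
  study's group sizes exceed this range anyway); otherwise normal
  approximation with tie and continuity correction.
* Wilcoxon signed-rank: zeros dropped and counted; exact null
  distribution of the positive-rank sum by generating-function
  convolution for n ≤ 20 without ties; otherwise corrected normal
  approximation. The reported statistic is the smaller signed-rank sum.
* Binomial proportion: exact by pmf summation. Two two-sided
  conventions are provided: summing all outcomes with pmf ≤ the observed
  outcome's (the common "exact two-sided" definition) and doubling the
  smaller tail. `binomial_convention_report` documents which convention
  reproduces a set of reported p-values; for the proportions analysed
  here the small-p convention matches both printed values (0.0098,
  0.0073) to printed precision, without asserting the original intent.
* Kolmogorov-Smirnov: two-sample D computed directly from the ECDFs;
  asymptotic p from the Kolmogorov series; significance is the compound
  criterion p < 0.01 AND D > 0.1, as specified for the distribution
  comparisons in this workflow.
* Spearman: midranks, Pearson correlation of ranks; exact two-sided p by
  full permutation enumeration for n ≤ 9, else the t-approximation.

A note on type-I error: exact tests on discrete statistics cannot reject
at exactly 5%; the test suite verifies that the empirical rejection rate
under the null equals the *attainable* level of the discrete null
distribution (e.g. ≈ 3.2% for the signed-rank test at n = 10) rather
than a nominal 5%.

## Problem sizes and determinism

Every generator is a pure function of its parameters and a seed. The
validation suite uses 2 kHz synthesis for LFP recovery checks (the band
of interest ends at 400 Hz; 10 kHz acquisition-rate tests cover the
preprocessing itself), 20–30 s sPSC traces, 100 event-level replicates
for the stimulation power analysis, and a 27-point RC grid — sizes
chosen so the full suite and the acceptance script each run in minutes
on one core while keeping every Monte-Carlo standard error well below
the tolerance it is compared against.

## Known limitations

* The discharge detector's adaptive threshold is fragile at very low
  event rates (≲ 0.1 Hz) on loud backgrounds — a structural property of
  median × kurtosis scaling, discussed above, not an implementation
  artifact.
* Template-correlation PSC detection cannot resolve overlapping events
  closer than roughly the template rise-plus-peak span, and a
  data-derived template that is much slower than the true kinetics
  shifts detection marks; the onset walk-back refinement compensates for
  metric purposes but the marks themselves inherit the template's bias.
* Decay-kinetics fitting, excitatory/inhibitory separation by kinetics,
  spectral analysis of discharges, and acquisition-hardware formats are
  out of scope.
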