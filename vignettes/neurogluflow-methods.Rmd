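---
title: "Methods: event-locked glutamate transients and behavioral phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-locked glutamate transients and behavioral phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurogluflow)
```

`neurogluflow` implements an analysis chain for dual-channel fixed-potential
amperometry of extracellular glutamate recorded in behaving animals, together
with the behavioral screening and scoring the analysis is stratified by. This
vignette explains the models and procedures, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the numerical and
design choices made where the procedure left them open.

## The measurement model

A glutamate-sensing microelectrode array carries two kinds of recording
sites. *Active* sites are coated with glutamate oxidase: enzymatic breakdown
of glutamate produces hydrogen peroxide, which is oxidized at a fixed 0.7-V
potential, yielding current proportional to the local glutamate
concentration. *Sentinel* sites carry no enzyme and record everything else —
baseline current, slow drift, and electrostatic interference. The processing
model is therefore linear:

```
active(t)   = shared(t) + S * glutamate(t) + noise_a(t)
sentinel(t) = shared(t)                    + noise_s(t)
```

where `S` is the electrode's sensitivity in pA/µM. Subtracting the sentinel
channel (`sentinel_subtract()`) removes `shared(t)`; dividing by the
calibration slope (`to_concentration()`) converts net current to µM. For
electrodes whose exclusion layer passes dopamine (in-vitro dopamine response
above 0.1 pA), net currents are first divided by that response
(`dopamine_normalize()`), which corrects for variable barrier efficacy.

**Normalization and the slope.** Whether the conversion slope should also be
rescaled when currents are dopamine-normalized is not fully determined by the
procedure's description. We divide the slope by the same dopamine response,
so that concentration estimates are invariant to normalization when the
electrode constants match. This reading keeps the two processing paths
mutually consistent; it is configurable via the `normalized` argument of
`to_concentration()`.

## Calibration

`fit_calibration()` reduces an in-vitro beaker calibration — baseline, then
additions of ascorbic acid (AA, 250 µM), glutamate to 20/40/60 µM cumulative,
then dopamine (2 µM) — to the electrode figures of merit:

* **sensitivity** — intercept-free least-squares slope of plateau current
  change versus cumulative glutamate concentration, referenced to the plateau
  immediately preceding the first glutamate addition (so the AA response does
  not contaminate the slope);
* **linearity** — Pearson correlation R of those plateau shifts against
  concentration (R² is also reported);
* **limit of detection** — `3 × SD(baseline current) / sensitivity`, the
  conventional 3σ criterion; the procedure names no formula, and this
  convention reproduces the magnitudes reported for accepted electrodes;
* **selectivity** — sensitivity divided by the AA plateau shift per µM AA;
  a non-positive AA shift is reported as `Inf` and flagged rather than
  silently passed;
* **dopamine response** — plateau shift after the dopamine addition.

Plateaus are the mean of the last `plateau_window` seconds (default 10 s)
of each addition segment; the source procedure measures "changes after each
solution" without a window length, and 10 s of settled signal at 5 Hz (50
samples) makes the plateau estimate's noise negligible relative to the steps.
Acceptance criteria (`evaluate_criteria()`) are: sensitivity > 5 pA/µM,
LOD < 1.0 µM, selectivity > 50:1, |dopamine response| < 3 pA (strict), and
linearity R > 0.95. The stated linearity range (20–80 µM) is inconsistent
with the 20/40/60 µM addition schedule; the fit uses whatever glutamate
additions are present.

## Event windows and baseline correction

Windows are anchored to behavioral events: a 2.5-s baseline before cue
onset, a 2-s cue window from cue onset, and a 2-s reward window from reward
delivery. Windows are half-open `[anchor, anchor + duration)`, with the
anchor snapped to the first sample at or after the event, giving fixed
sample counts at 5 Hz (12 / 10 / 10). Each cue and reward window is corrected
by subtracting the mean of its own trial's baseline window; no further
detrending is applied (drift across a 2-s window is negligible at the default
drift rates, and per-trial correction absorbs slow variation). Sample times
within a window are reported relative to the *true* event time rather than
the snapped anchor sample, so latencies read from windows are unbiased by the
sub-sample anchor offset (which would otherwise shift all latencies early by
up to one sample period, 0.1 s on average).

A baseline SD of exactly zero can occur only for noiseless synthetic input;
it is floored at machine epsilon and flagged, keeping the peak threshold
defined. In that degenerate regime any float-level wiggle clears the
threshold, so noiseless traces are useful for amplitude-recovery checks but
not for peak-count statistics.

## Peak identification

`detect_peaks()` implements the three written criteria: (1) a peak exceeds
the baseline mean by more than 3 baseline SDs; (2) the signal drops to at
least 1 SD below the peak value on both sides before exceeding it; (3) a run
of consecutive supra-threshold samples containing no criterion-2 peak, whose
values lie within 1 SD of each other, contributes its highest sample once.
Criterion 2 is evaluated with an alternating max/min scan with drop
tolerance 1 SD — the classic `peakdet` scheme, which is the tool family the
criteria were designed around. Numerical conventions, chosen to resolve
boundaries toward fewer peaks: strict `>` for the threshold, `<=` for drops,
earliest sample on tied maxima, no sub-sample interpolation at 5 Hz. Window
edges: the pre-cue side is baseline by construction and satisfies the drop;
the trailing edge also satisfies it, so a rising transient at the window end
is not spuriously deleted. The run-range reading of criterion 3 ("within
1 SD from each other" as `max − min < 1 SD`) is the strictest reading that
still rescues the sustained elevations the criterion was written for.

The test suite checks the scan against an independently written brute-force
reference that walks outward from every sample, on thousands of randomized
windows, as well as against hand-traced examples.

Per-trace features (`peak_features()`): maximum peak concentration, peak
count, time to the maximum peak from the window anchor, and the second
peak's apex time. Traces with no identified peak yield missing values,
never zeros — zero-filling would bias amplitude comparisons downward.

## Behavioral scoring

**PCA.** The Pavlovian Conditioned Approach index is the mean of three
components: probability difference `P(lever) − P(port)`, response bias
`(lever − port)/(lever + port)`, and latency score
`(port latency − lever latency)/8` over the 8-s CS. Session-level latency
means include non-responding trials at the 8-s cap; this convention is
forced by the requirement that a lever response on every trial at CS onset
gives exactly +1 (and the goal-tracking converse −1). The response bias at
0/0 is defined as 0 (a session with no CS-period responses is behaviorally
neutral). Classification uses the averaged index of sessions 4–5: GT in
[−1, −0.5], ST in [+0.5, +1], IN otherwise, boundaries inclusive toward
GT/ST.

**CTTT.** Trials present a 2-s turn or stop cue; the treadmill stops 1 s
after cue offset and restarts after a 5-s pause. A cued turn requires turn
initiation within 8 s of cue onset (inclusive — "within 8 s" reads as `<=`);
a turn during the pause on a stop trial is a false turn. "70% correct to
either cue for two consecutive sessions" is read as *both* cue types at or
above 0.70 in both sessions, matching the companion phrasing "70% cued turns
and cued stops". A stop trial with neither a stop nor a turn recorded is
emitted as a flagged, unclassified cued-stop record rather than guessed.

## Contingency analyses

The threshold sweep restricts turn-cue traces to those with maximum peak at
or above a threshold (the at-or-above convention matches the sweep's axis
labeling; strict `>` is available via an argument) and, per curve, to
single-peak (`n = 1`) or multi-peak (`n ∈ {2, 3}`) traces. Each condition's
2×2 turn/miss table by phenotype yields a two-sided Fisher exact p
(probability-mass convention, via `stats::fisher.test`) and the relative
turn probability with a Koopman asymptotic-score interval. Conditions with
any cell below 10 are flagged excluded. No multiplicity correction is
applied within the sweep (per-threshold significance is reported as such).

The Koopman interval inverts the score test for the ratio of two binomial
proportions: for a hypothesized ratio ρ, the constrained maximum-likelihood
proportions solve a quadratic, and the interval is the set of ρ whose score
chi-square does not exceed the 95% quantile. Endpoints are found by
bisection (`uniroot`, bracket expanded geometrically from the point
estimate, tolerance 1e-9) with a log-grid fallback on numerical failure.
Degenerate cells produce flagged one-sided results (`rr = 0` or `Inf` with
the corresponding open endpoint) rather than errors. The implementation is
cross-checked in the tests against a profile-likelihood grid inversion and
by simulated interval coverage.

## The synthetic-data generator

The generator exists so that every downstream stage is testable with known
ground truth. It emulates:

* **calibration series** — plateau steps with exponential approach
  (τ = 1.5 s) and additive Gaussian current noise;
* **two-channel 5 Hz traces** — shared baseline (200 pA), linear drift
  (0.005 pA/s), shared rectangular artifacts (0.2/min, 50 pA, 1 s), and
  glutamate transients injected into the active channel only as
  double-exponential pulses scaled by the electrode sensitivity;
* **behavioral sessions** — 18 cue trials, tone/light with at most two
  successive same-modality cues (rejection sampling of balanced sequences),
  ITIs uniform on [15, 105] s (the "60 ± 45 s" interval; the distribution is
  not named, and uniform is the least-informative choice on a stated range),
  Bernoulli trial outcomes per phenotype with no trial-history dependence,
  reward 3.6 ± 1 s (uniform jitter) after cue offset on rewarded trials;
* **phenotype structure** — GT traces mostly single cue-locked peaks
  (`single_peak_prob = 0.8`) with larger amplitudes (8.5 ± 2.5 µM, matching
  the scale of reported cue-locked maxima), later turn initiation
  (2.5 ± 1.0 s) and a higher turn rate (0.75); ST traces mostly two or three
  peaks (`single_peak_prob = 0.2`, reflecting the reported >80% multi-peak
  prevalence), smaller cue-locked but larger reward-locked amplitudes
  (8.0 ± 2.0 µM, drawn with probability 0.9), earlier initiation
  (1.5 ± 0.8 s), lower turn rate (0.65). Second and third peak latencies are
  drawn from normal laws with means 1.58 s and 1.83 s (SDs 0.39 and 0.25)
  after cue onset — the reported timing of ST secondary peaks.

**Pulse shape.** The transient is `(exp(−t/τ_d) − exp(−t/τ_r))`, normalized
to a unit apex, with τ_r = 0.25 s and τ_d = 0.45 s by default. The decay was
deliberately set faster than a 1-s clearance: at 5 Hz, two transients 0.8–1.2
s apart merge into a single local maximum when the decay constant reaches
1 s, and multi-peak traces with secondary peaks at 1.58/1.83 s inside a 2-s
cue period would be unresolvable by construction. 0.45 s is the slowest
round value that keeps the configured secondary-peak spacing resolvable;
both constants are configurable.

**Separation floor.** Secondary-peak latency draws are truncated to at least
`min_peak_separation` (0.5 s) after the previous apex, because two apexes
closer than two sample periods cannot both be local maxima at 5 Hz. The
first peak of a multi-peak trace is drawn earlier (0.3 ± 0.08 s, range
[0.2, 0.5]) than a lone peak (0.4 ± 0.1 s, range [0.2, 0.7]), which keeps
the truncation's effect on the secondary-latency distribution small.

**Noise level.** The per-channel current noise default is 3.6 pA — 0.3 µM at
the default 12 pA/µM sensitivity. No baseline noise SD is reported in
concentration units anywhere in the source material; 0.3 µM equals the
reported limit of detection and is therefore the natural scale for an
accepted electrode. It is a free parameter of `default_generator_config()`.

**What is not emulated.** No biophysics of glutamate diffusion, uptake, or
receptor kinetics; no kinematics or video; no trial-history effects; no
electrode degradation over days; artifacts are rectangles, modeled only well
enough to exercise sentinel subtraction and QC flags. Passing tests on this
generator therefore demonstrate that the *pipeline* recovers what was
injected under the stated statistical structure — not that the structure
itself is a faithful biophysical model of striatal glutamate release.

## Latency recovery and window duration

The mean second-peak latency experiment (in the tests and the acceptance
script) uses a 3-s cue-locked analysis window rather than the 2-s default.
A normal law centered at 1.58 s with SD 0.39 s places roughly a quarter of
its mass beyond the last 5 Hz sample of a 2-s window; measuring the mean of
detected second peaks through a 2-s window would estimate a truncated mean,
not the distribution's mean. The 3-s window covers the distribution's
effective support; window duration is an explicit argument of
`extract_windows()` and the pipeline default remains 2 s.

## Problem sizes and reproducibility

Simulation sizes were chosen so that every stochastic check is decisively
powered while the whole suite runs in well under a minute of compute: 100
seeds for schedule invariants, 200 replicate calibration series for
estimator bias, 1,000–1,200 random windows against the peak oracle, 2,000
simulated binomial pairs for interval coverage, 500 traces for latency
recovery, and 20 sessions per phenotype for the sweep contrast. All
generators take explicit integer seeds; a single run seed fans out to stages
through `child_seed()` (a stable string hash below 2³¹), so any stage can be
re-run independently and identical configurations yield byte-identical
outputs.

## Known limitations

* The peak-count statistics depend on the noise level relative to peak
  amplitude: near-apex samples sit within ~5% of the apex at 5 Hz, so
  baseline SDs approaching that scale can split a wide peak in two. This is
  a property of the 1-SD drop criterion itself, not of the implementation.
* Koopman intervals are asymptotic; with cells near the exclusion floor of
  10 their coverage is close to, but not exactly, nominal.
* The generator's phenotype parameters are means and spreads on printed
  summary scales; they do not reproduce animal-level variance components,
  so mixed-model analyses of the synthetic output are out of scope (the
  pipeline emits tidy per-trace tables for external statistics tooling).
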