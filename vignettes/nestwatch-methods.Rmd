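---
title: "Methods: behavioural scoring, spike-train statistics and photometry in nestwatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioural scoring, spike-train statistics and photometry in nestwatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestwatch)
library(dplyr)
```

## Overview

`nestwatch` analyses long home-cage recordings of a mouse dam co-housed with
a virgin female and a litter, through the period in which the virgin
acquires alloparental pup retrieval. The pipeline has five stages, each
usable on its own:

1. **Ethogram scoring** — nest crossings, chases, shepherding, time in
   nest, retrieval onset, ultrasonic call-bout classification, from tabular
   trajectories and event logs.
2. **Spike-train statistics** — event-aligned firing-rate modulation with a
   shift-permutation null and Benjamini–Hochberg false-discovery control,
   z-scored peri-event histograms, photo-tagging classification, pairwise
   zero-lag synchrony, playback responses.
3. **Population statistics** — exact tests on activated fractions, relative
   risk with Koopman score confidence intervals, log-rank comparison of
   retrieval-onset curves.
4. **Photometry** — lock-in demodulation, ΔF/F, per-call and per-trial
   responses, and joint single-trial spike–calcium correlation.
5. **Synthetic data** — a cage-session generator with known ground truth
   that exercises every stage without any recorded data.

All user-facing functions take data frames first and return tibbles, so
stages chain with the pipe; fitted objects provide `tidy()`, `glance()` and
`autoplot()` methods.

## Behavioural scoring

Positions are centroids in cm, origin at the bottom-left cage corner; times
are seconds from session start and intervals are half-open `[start, end)`.
The nest is a circle (default radius 10 cm).

* **Nest crossings.** An entry is the first sample inside the circle after
  being outside, an exit the first sample outside after inside, so entries
  and exits strictly alternate. Pose-based scoring distinguishes the head
  entering from the rear leaving; with centroid tracking both collapse to
  the circle crossing, and we flag this explicitly: analyses that depend on
  the head/rear asymmetry need pose data the package does not model.
* **Chases.** Manual scoring has no algorithmic definition, so
  `detect_chases()` uses three interpretable criteria, all configurable:
  inter-animal distance ≤ 8 cm, both speeds ≥ 10 cm/s, and the dam behind
  the virgin's heading (positive projection of the dam→virgin vector on the
  virgin's velocity). A contact-based chase start cannot be detected from
  centroids; the speed-threshold onset approximates the variant in which
  the virgin starts fleeing as the dam approaches. Pre-scored event logs
  can be supplied directly, bypassing detection.
* **Shepherding.** A chase is shepherding exactly when the virgin ends
  nearer the nest centre than she started, `d(start) > d(end)`
  (`classify_shepherding()`). The rule is invariant to rigid rotations,
  translations and uniform time shifts, which the tests check.
* **Shepherding rate.** Events per hour per cage, with a one-sample t test
  against a reference of 0.2 events/h — the rate of dam→virgin chases when
  no pups are present, i.e. the rate expected if chasing had nothing to do
  with pups. Both the two-sided p and its halved directional version are
  reported, and which one is used should be stated by the analyst.
* **Retrieval onset.** Daily blocks of ten 2-minute trials. Co-housed
  subjects reach onset on the first day with ≥ 2/10 successes; observation
  subjects (watching an experienced dam retrieve) on the first day with
  ≥ 1 success. Subjects never reaching the criterion are right-censored at
  their last observed day, which feeds the log-rank comparison.
* **USV bouts.** A bout is a pup distress (isolation) call if its median
  syllable rate lies in 4–8 Hz and the median peak frequency in 40–90 kHz;
  with fewer than two syllables the rate, and hence the class, is
  undefined and an error is raised rather than guessing.

## Event-aligned modulation and its null

For each behavioural episode the firing rate over the episode is compared
with a matched baseline:

* nest entries: analysis window capped at 40 s (longer dwells mix in
  grooming, sleeping and nest building) and an equal-duration baseline
  immediately preceding the entry;
* shepherding and dam retrievals: the full episode against the 10 s before
  onset.

The modulation index is the signed percentage contrast

$$M = 100\,\frac{r_\text{behaviour} - r_\text{baseline}}
                {r_\text{behaviour} + r_\text{baseline}} \in [-100, 100],$$

antisymmetric in its arguments, with $M = 0$ when both rates are zero (no
evidence either way). A unit with zero spikes in every analysis and
baseline window carries no information and is excluded from its family
before multiple-testing correction (minimum-activity filter, configurable).

**Shift-permutation null.** The observed statistic is the mean per-event
$M$. Under the null the behaviour times are unrelated to the spike train,
so we shift *all* event intervals together by a single uniform draw from
±500 s and recompute the mean $M$; 1,000 such shifts form the null sample.
Three design points deserve mention because the procedure is often
described loosely:

* one common shift per shuffle (not per event) preserves the inter-event
  structure — shuffling events independently would destroy correlations
  between nearby events and make the null too easy;
* shifted windows wrap circularly around the recording, and the observed
  statistic is computed with the same circular counting, so observed and
  shuffled statistics are exchangeable under a stationary null — this is
  what makes the p value exactly calibrated, which the test suite verifies
  by a KS test on 500 simulated null units;
* p values use the add-one estimator $p = (1 + \#\{M_\text{shuf} \ge
  M_\text{obs}\})/(N+1)$, which can never be zero. The classical criterion
  "observed modulation exceeds 950 of 1,000 shuffles" corresponds to
  $p_\text{act} \le 51/1001 \approx 0.051$ under this estimator; both the
  p values and the count-based flags are returned.

**FDR.** Activation and suppression give two one-sided p values per unit;
a single two-sided value $p = \min(1, 2\min(p_\text{act}, p_\text{sup}))$
enters a Benjamini–Hochberg step-up within each family — a family being
the natural analysis batch, e.g. all PVN units or all opsin-tagged OT
units recorded in one day. Significant units (q ≤ 0.05) are labelled by
the direction of the smaller one-sided p. With 1,000 shuffles the smallest
attainable two-sided p is 2/1001, which limits how many tests a family can
carry before true effects become undetectable after correction; at the
family sizes used here (tens of units) this is not binding.

## Photo-tagging

A unit is opsin-tagged when at least 70% of 5-ms light pulses (delivered
at 2 or 5 Hz) are followed by a spike within 4 ms of pulse onset. The
latency bound is inclusive; reliability is the fraction of pulses with at
least one spike in the window, and the median first-spike latency is
reported. For an untagged Poisson unit at rate $\lambda$ the expected
reliability is $1 - e^{-4\lambda/1000}$ (≈ 2% at 5 Hz), far below
threshold, so chance tagging is negligible at any plausible rate.

## Population statistics

* **Non-zero activated fraction.** The comparison behind "is the fraction
  of activated units meaningful" is a one-sided Fisher exact test; the 2×2
  construction is not uniquely determined by that description, so the
  package uses `[[k, n-k], [0, n]]` (observed population against an
  equal-sized all-null reference) and isolates it in
  `fraction_activated_test()` so an alternative construction can be swapped
  in one place.
* **Two-population comparison.** Two-sided Fisher exact test (the
  point-probability rule for two-sidedness, the most common convention —
  conventions differ, hence documented), relative risk
  $(k_1/n_1)/(k_2/n_2)$ as effect size, and a Koopman asymptotic score
  confidence interval: the CI endpoints are the values of
  $\rho = p_1/p_2$ at which the score statistic, with the constrained MLE
  of the proportions under $p_1 = \rho p_2$ in closed form, equals the
  $\chi^2_1$ critical value. Roots are found by bisection on $\log\rho$ to
  1e−8. When the denominator group has zero events the upper limit is
  unbounded; with no events anywhere the interval is undefined. The tests
  verify the defining equation to 1e−6 and ~95% simulated coverage at a
  true relative risk of 2.
* **Onset curves.** Retrieval-onset days with right censoring are compared
  by the standard log-rank (Mantel–Cox) test via `survival::survdiff`;
  ties are handled by the discrete-day hypergeometric formulation, which
  is the natural one when onsets are whole days. A six-subject worked
  example in the tests reproduces the O−E table by hand.
* **Dose arithmetic.** `chronic_dose_rate()` converts a drinking-water
  concentration, daily intake and body mass into mg/kg/day (25 mg/l ×
  6 ml/day ÷ 30 g = 5 mg/kg/day).

## Photometry

The excitation LED is sinusoidally modulated (400 Hz); the emitted
fluorescence is recovered by quadrature demodulation: mixing with sine and
cosine references, low-pass filtering both products at 20 Hz with a
4th-order Butterworth applied forwards and backwards (zero-phase, so trial
alignment is not biased by group delay), and taking
$2\sqrt{I^2 + Q^2}$. The sampling rate must exceed twice the carrier.

ΔF/F for an interval uses $F_0$ = median of the 1 s immediately preceding
the interval — the median resists transients bleeding into the baseline —
and reports the mean of $(F - F_0)/F_0$ over the interval. No baseline
rule is canonical; this one is a documented default and both the window
and the statistic are arguments. ΔF/F is exactly invariant to overall
gain, which the tests assert to machine precision. Only a single recording
condition is modelled (no restrained/unrestrained distinction, no
isosbestic motion correction).

Joint analysis: `population_trial_modulation()` reduces a recorded
population to one mean modulation value per observation trial, and
`joint_trial_correlation()` correlates that with the per-trial cortical
ΔF/F, pooled and per animal.

## The synthetic generator

The generator exists so that every stage has a ground truth. It emulates:

* an 80 × 40 cm cage with a 10-cm-radius nest circle;
* centroid trajectories as a mean-reverting random walk clipped to the
  cage, with the nest treated as an obstacle outside scripted visits —
  spontaneous baseline wandering through the nest would otherwise swamp
  the deliberate nest entries;
* scripted episodes that override the walk: chases at ~25 cm/s with the
  dam 3 cm behind the virgin (80% steered to end nearer the nest, i.e.
  shepherding, including a post-chase nest dwell), spontaneous dam
  retrievals (pup drop, pause, carry to nest), nest visits, and pup call
  bouts. Episodes reserve their time slots globally so overrides never
  collide, and nest entry/exit events are derived from the realized
  trajectories, so the event log is consistent with the positions by
  construction;
* spike populations as inhomogeneous Poisson processes: baseline rates
  log-uniform on 1–10 Hz (baseline firing statistics of this hypothalamic
  population are not well characterised; this is a stated default, not a
  claim), a 30% modulated fraction with gain 3 (suppressed units use the
  reciprocal), and ~4% opsin-tagged units emitting evoked spikes at ~2 ms
  after 90% of pulses;
* calcium traces with a difference-of-exponentials kernel (rise 0.2 s,
  decay 1.5 s, GCaMP6s-like documented constants), optional 400-Hz
  carrier, drift and Gaussian noise;
* four-day observational learning cohorts of sizes 15/19/18/10 with
  per-day learning hazards 0.28/0.22/0.03/0.09 (no barrier, transparent
  barrier, opaque barrier, oxytocin-receptor knockout), chosen so the
  expected four-day learner fractions are roughly 73%, 63%, 11% and 30%;
  a learned subject succeeds at 0.6 per trial thereafter, and subjects
  never learning are censored at day 4.

The default session length is 2 h at 5 Hz trajectory sampling — long
enough for tens of scripted episodes while keeping simulation studies
fast; real co-housing runs for days and all analysis code is
duration-agnostic.

What the generator deliberately does **not** emulate: pose (head/rear),
video or audio signals, pup biology, multi-animal social structure beyond
one dam–virgin dyad, electrode drift, bursting or refractory spike-train
structure, photobleaching, or motion artefacts. Passing tests therefore
demonstrate statistical correctness and recovery of scripted structure,
not robustness to every artefact of real recordings.

## Numerical choices and degenerate inputs

* Both rates zero ⇒ $M = 0$; negative rates are errors.
* Permutation seeds: each unit in a scan derives its own seed from the
  scan seed, so results are reproducible and units are independent.
* Synchrony: per-event Pearson r of 10-ms bin counts; events where either
  unit has zero count variance are skipped (r undefined); |r| is capped at
  0.9999 before the Fisher z-transform so identical trains stay finite;
  the combined value is `tanh(mean(atanh(r)))`.
* PSTH z-scores use the pre-event bins of the same event-averaged
  histogram as reference (the reference distribution is not otherwise
  determined); a zero pre-event SD flags the z values as undefined rather
  than dividing by zero. The ±3 clip is applied only in plots; raw z is
  kept.
* Spike-train QC: refractory default 2 ms (the stricter end of the 2–3 ms
  convention), coincidence window 0.5 ms across ≥ 10 channels; without a
  channel map the coincidence rule is skipped with a warning rather than
  silently dropped.
* Playback ratios with a silent 1-s baseline are undefined and skipped
  (counted), not set to an arbitrary large value.
* All file formats are plain TSV/JSON; bundles carry MD5 checksums that
  are verified on load.

## Validation scale

The simulation studies used by the test suite and `scripts/acceptance.R`
run at a scale chosen to estimate each property precisely while staying
fast: 500 null units × 1,000 shuffles for calibration (KS against
uniform), 100 replicates of a 40-unit population (10 modulated at gain 3)
for the mean false-discovery proportion (Monte-Carlo SE ≈ 0.006), 100
units with 50 at gain 2 over 50 events for sensitivity, six 2-h simulated
sessions for shepherding recovery, every 2×2 table with N ≤ 40 against an
enumeration oracle, and 2,000 replicates for Koopman coverage.

## Known limitations

* Centroid-only geometry: snout-based distances and head/rear crossing
  semantics are approximated by the centroid.
* The chase detector is a stand-in for manual scoring; its thresholds are
  sensible defaults, not fitted to annotated video.
* The permutation null assumes stationarity over the ±500-s shift range;
  strong slow drifts in firing rate would widen the null legitimately but
  are not modelled by the generator.
* One family definition (class × day) is implemented for FDR; other
  partitions are possible by passing different metadata columns.
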