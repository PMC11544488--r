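---
title: "Benchmarking ward early warning scores: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking ward early warning scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewsbench)
```

## The problem

An early warning score maps a patient's charted vital signs to a single
number meant to rise (or, for some indices, fall) before clinical
deterioration. Comparing such scores fairly is harder than it looks: they
update at different frequencies, live on different scales, and a naive
observation-level analysis lets long encounters with many observations
dominate. `ewsbench` packages the evaluation protocol that addresses each
of these: carry-forward alignment to a common grid, a
one-observation-per-encounter bootstrap, threshold matching to a common
comparator (NEWS), and encounter-level efficiency and lead-time analyses.

## Outcome model

The composite outcome is **clinical deterioration**: death on a
medical-surgical ward, or direct transfer from a ward to an ICU, within a
horizon of 12, 24 (primary) or 48 hours of a score. Event times are
anchored to documentation rather than administrative timestamps, which is
how such events are observable in an EHR:

* a ward-to-ICU transfer is timed at the **last ward-located observation**
  preceding the ICU interval;
* a ward death is timed at the **last recorded vital sign** (the charted
  discharge time is not used for event timing);
* a death after an ICU transfer produces only the transfer event — the
  composite requires death *on a ward*.

A score at time $t$ receives label 1 iff the encounter's first qualifying
event time $e$ satisfies $t < e \le t + h$. The window is half-open on the
left by design: a score charted simultaneously with the event cannot
*predict* it, and an open left endpoint prevents that label leakage. Rows
at or after the first event are dropped entirely, so an encounter that
returns to the ward after ICU care does not mix pre- and post-event
epochs (a config flag re-enables per-event epoching as a sensitivity
analysis). For the secondary death outcome only ward-death events qualify.

## Scoring engines

MEWS, NEWS and NEWS2 are sums of integer subscores looked up from
half-open bands $[lo, hi)$ over each vital. The bands ship as YAML data
files (`inst/extdata/band_tables/`) rather than code, so a site variant
can be swapped in without touching logic; the loader validates that each
component's bands are disjoint and cover its declared range. Choices worth
stating:

* **MEWS variant.** The 5-component ward variant (systolic BP, heart
  rate, respiratory rate, temperature, AVPU) — the common bedside form;
  the urine-output component requires charted intake/output and is
  omitted. New confusion (`C`) is scored 1, like a voice-level
  disturbance.
* **NEWS consciousness.** Any non-alert ACVPU level scores 3; NEWS2
  differs from NEWS only in the dual SpO2 scale (and formally in treating
  new confusion as non-alert, which the NEWS table here already does).
* **Missing components.** A component never documented contributes 0, and
  an observation with no documented component at all scores `NA`. This
  matches how deployed scores behave on real charts and avoids discarding
  encounters; the alternative (propagate `NA` if anything is missing)
  would delete most of a real ward cohort.
* **Carry-forward rescoring.** A stream re-scores at every observation
  time using the latest value of every component, so a new heart rate
  triggers rescoring with the standing blood pressure, oxygen settings,
  etc. Duplicate timestamps keep the last-written row (and are flagged by
  the reader).

### The NEWS2 SpO2 scale rule

NEWS2 scores oxygen saturation on scale 2 (the hypercapnic respiratory
failure scale, target 88–92 %) once hypercapnia on supplemental oxygen is
demonstrated: the switch time is the first observation with
PaCO2 > 45 mm Hg and FiO2 > 21 % at the same timestamp; scale 2 then
applies through discharge. Blood gases and oxygen settings are charted
asynchronously, so by default "same timestamp" uses the carried-forward
FiO2 standing at the blood-gas time — the clinically concurrent value. A
`strict_simultaneous` flag restricts the rule to rows documenting both
values, for sites whose interfaces guarantee paired charting. A PaCO2 of
48 on room air (FiO2 21 %) does **not** switch the scale.

## Alignment and the bootstrap

Streams update at different rates, so all scores are carried forward onto
the reference grid — the densest stream's observation times — taking each
score's most recent value at or before each grid time (`NA` before its
first value). Carry-forward is unconditional by default (no staleness
limit), with a `max_age_hours` option.

AUROC is the rank-based (Mann–Whitney) probability that a random event
observation outranks a random non-event observation, ties counting one
half; low-is-risk scores are rank-reversed first so every AUROC reads
"higher = better discrimination". Because encounters contribute very
different numbers of observations, the estimate uses $B = 100$ bootstrap
iterations, each drawing **exactly one aligned row per encounter**
uniformly at random; all scores are evaluated on the identical draw so
comparisons are paired. The point estimate is the mean of per-iteration
AUROCs and the CI the 2.5/97.5 percentiles across iterations — a
percentile summary was chosen over a normal approximation because the
per-iteration values are bounded and can be skewed near 1. Iterations
whose draw contains a single outcome class are redrawn (aborting after 10
consecutive failures). The paired DeLong test is computed inside each
draw and summarised by the median p across iterations; a single-sample
mode is available. These aggregation choices are stated here because the
protocol itself fixes only "bootstrapped AUROC with 95 % CIs".

## Threshold matching and test characteristics

NEWS has clinically established triggers: 5 (moderate) and 7 (high). A
candidate score is matched at the observation level by scanning every
observed unique value as a threshold and choosing the one whose
sensitivity (moderate) or specificity (high) is closest to the NEWS
anchor's. Ties break toward the more specific — higher-risk — threshold,
so a coarse score errs on the side of fewer alerts. Trigger conditions
are inclusive: value ≥ threshold for high-is-risk scores, ≤ for
low-is-risk (thresholds always stay on the native scale, so a
Rothman-style report reads "RI ≤ 41", never a negated value). Positivity,
sensitivity, specificity, PPV and NPV at the matched thresholds carry
bootstrap percentile CIs from the same one-per-encounter scheme. No
multiplicity adjustment is applied; $\alpha = .05$ two-sided throughout.

Encounter-level analyses use each encounter's extreme pre-event value
(maximum, or minimum for low-is-risk) over rows strictly before the first
event or discharge: the efficiency curve plots the fraction of all
encounters whose extreme crosses each threshold against the fraction of
event encounters caught. Lead time is first-trigger-to-event in hours per
event encounter, with 0 h imputed when the threshold is never crossed
before the event — an imputation that deliberately penalises scores that
alert late or never — and compared across scores by Wilcoxon rank sum
(unpaired, as named in the protocol, although the samples share
encounters).

## The synthetic ward generator

The generator exists so every stage is testable with known ground truth;
it emulates the *structure* of a multi-campus ward cohort, not real
physiology. Defaults (all overridable in `generator_config()`):

| parameter | default | meaning |
|---|---|---|
| `base_event_rate` | 0.046 | composite deterioration probability per encounter |
| `death_share` | 7600/16693 ≈ 0.455 | fraction of events that are ward deaths |
| `los_median_hours`, `los_log_sd` | 96, 0.79 | log-normal stay; IQR ≈ 59–171 h |
| `vitals_interval_hours` | 4 | mean exponential gap between vitals |
| `reference_interval_hours` | 1 | dense reference stream grid |
| `pre_event_ramp_hours` | 24 | duration of pre-event drift |
| `drift_magnitude` | 1 | scale of displacement toward abnormal |
| `lab_rate` | 0.1 | expected blood gases per encounter |
| campuses | A/B/C, weights .4/.35/.25 | event-rate multipliers 1.0/0.7/1.3 |

The event rate, death share and length-of-stay quantiles are set to the
published characteristics of large multicenter ward cohorts; the sampling
intervals and three-campus structure are a deliberately small emulation
of a multi-hospital system (`los_log_sd = 0.79` reproduces the 59–171 h
IQR of a median-96 h log-normal). Each event encounter carries a latent
risk $r(t)$ ramping linearly from 0.03 to 1 over the final
`pre_event_ramp_hours`; vitals are drawn from standard adult norms
(HR 75±10, RR 14±2, SBP 120±15, T 36.8±0.3, SpO2 97±1.5) displaced toward
abnormal by `drift_magnitude` · $r(t)$ per-vital displacements. Event
times fall uniformly in the second half of the ward stay so pre-event
observations always exist and lead-time analysis is nondegenerate. The
reference stream (`SEDI`) is a noisy readout of $r(t)$ on the dense grid,
standing in for a frequently updating EHR index; the exact $r(t)$ is
exported only as ground truth, which the evaluation path never reads.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: chronically abnormal but stable patients
(atrial fibrillation, end-stage kidney disease), circadian rhythms,
medication effects, documentation artifacts, and correlated missingness.
Because every abnormal vital here signals genuine risk, observation-level
PPVs on synthetic cohorts are far higher than on real wards, and MEWS is
not handicapped relative to NEWS the way it is in practice (all vitals
drift jointly, so missing the oxygen components costs little). The
synthetic cohort validates the *machinery* — labeling, alignment,
statistics, determinism — not the clinical performance ranking.

## Numerical choices and degenerate inputs

* Timestamps are ISO-8601 in files and minute-resolution POSIXct (UTC) in
  memory; durations are hours as reals.
* AUROC and DeLong require both outcome classes (DeLong ≥ 2 per class for
  its covariance); violations raise errors rather than returning `NA`.
* `threshold_sweep()` computes all-threshold test characteristics by
  cumulative counts; PPV is `NA` when nothing is predicted positive, NPV
  when nothing is predicted negative.
* DeLong's z is defined as 0 (p = 1) when the paired difference and its
  variance are both exactly zero (self-comparison).
* The precision-recall curve has one point per observed unique threshold;
  at a shared sensitivity the higher-threshold point dominates.
* The DeLong validity check in the test suite uses balanced (30/30)
  exchangeable paired datasets with independent Gaussian noise — the
  setting where the sign-swap permutation distribution and DeLong's
  normal reference target the same null — and problem sizes throughout
  the suite (2000-encounter cohorts, 100-iteration bootstraps, 20-seed
  ordering experiments) were chosen to make the statistical checks sharp
  at desk scale.

## Known limitations

* eCART, EDI and the Rothman Index are handled only as externally
  supplied score streams; their models are proprietary and out of scope.
* Encounters with ICU stays before the first ward stay contribute only
  their ward intervals; pre-ward physiology is not scored.
* Campus stratification repeats the bootstrapped AUROC per campus;
  campuses whose labeled rows contain a single outcome class are skipped
  rather than reported as `NA` rows.
* The published AUROCs and test-characteristic tables of large
  proprietary EHR cohorts cannot be reproduced from synthetic data; the
  pipeline reproduces the protocol, and its outputs on synthetic cohorts
  are validated against the generator's ground truth instead.
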