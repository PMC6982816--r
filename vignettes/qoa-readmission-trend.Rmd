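---
title: "Quality-of-activity trend analysis for 30-day readmission alerting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-of-activity trend analysis for 30-day readmission alerting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qoatrend)
```

## The problem

COPD patients discharged from hospital carry a high risk of returning —
to the emergency room or to a ward — within 30 days. Because a worsening
patient usually moves less, and moves *less regularly*, continuous
wrist-worn accelerometry offers a passive early-warning signal.
`qoatrend` implements a complete processing chain from raw tri-axial
acceleration to rule-based readmission alerts and their evaluation
against clinical event logs.

The chain is deliberately self-referential: every statistic compares a
patient with their own recent past, never with other patients, because
absolute activity volume differs enormously between individuals even in
good health. All alerting quantities are therefore percent changes,
invariant to rescaling a patient's overall activity level (a property
the test suite asserts).

## From raw signal to daily metrics

**Days.** A monitoring day runs noon-to-noon so one night's sleep falls
inside a single day, and day *i* counts days since discharge. A day is
*valid* only if the device was off-wrist for at most 60 minutes
("more than one hour" read strictly) and the recording covers the whole
window; partial first/last days are excluded because a total over fewer
than 1440 minutes is not comparable day to day.

**Non-wear.** The validity rule needs a wear-time detector, which we
implement as standard actigraphy practice: a minute is *stationary* when
every axis has standard deviation < 0.013 g and range < 0.05 g within
the minute, and runs of ≥ 30 consecutive stationary (or sample-free)
minutes are non-wear. Short still periods (reading, dozing) stay wear.
The detector only feeds the >60-minute validity rule; its parameters
live in `nonwear_params()`. Whether the budget is cumulative (default)
or per-run is switchable in `is_valid_day()`.

**Activity index (AI).** Each minute is summarised by a non-negative
scalar: the minute is split into 1-second epochs, each epoch scores
$\sqrt{\max(0, \overline{\sigma^2_{axis}} - \sigma^2_{noise})}$ (mean
over the three axes of the within-epoch variance, optionally noise
corrected), and the 60 epoch scores are summed. With `noise_sd = 0`
(default — calibration optional) the index is homogeneous: scaling the
signal by *k* scales the AI by *k*. The AI definition sits behind a
plain function interface so an alternative index can be substituted
without touching the rest of the chain.

**Regularity index (RI).** Day-to-day behavioural regularity is the
Pearson correlation between today's and yesterday's 1440-minute AI
vectors, restricted to mutually worn minutes (at least 720 required).
RI ∈ [−1, 1]; it is only defined between *calendar-consecutive valid
days*. Missing minutes inside a valid day contribute 0 to the daily
total (bounded distortion, ≤ 60 minutes) but are excluded from the
correlation, which zero-filling would bias.

**Sleep.** Sleep bouts are detected by a deterministic
threshold-and-bout rule (centred 11-minute moving average below a
threshold, gaps under 20 minutes merged, bouts ≥ 60 minutes kept). The
default threshold adapts to the patient — 20% of the day's 90th AI
percentile, floored at 0.1 — because absolute levels vary so widely.
Sleep duration and sleep/awake AI per hour are descriptive outputs; they
do not enter the alerting statistics, so any documented deterministic
rule suffices here.

## The trend model

Writing $Total\_AI_i$ and $RI_i$ for day *i*:

$$QoA_i = Total\_AI_i \,(1 + RI_i)$$

$$\Delta QoA_i = \frac{QoA_i - QoA_{i-1}}{QoA_{i-1}} \times 100
\qquad
WQoA_i = 0.4\,QoA_i + 0.3\,QoA_{i-1} + 0.2\,QoA_{i-2} + 0.1\,QoA_{i-3}$$

$$\Delta WQoA_i = \frac{WQoA_i - WQoA_{i-1}}{WQoA_{i-1}} \times 100
\qquad
\sum\Delta QoA_i = \sum_{j=0}^{6} \Delta QoA_{i-j}$$

QoA rewards doing the usual amount *on the usual schedule*; the
regularity factor spans [0, 2]. The WQoA weights and the 7-day window
are part of the published model, not tuning knobs, and are fixed.
Percent quantities are carried on the ×100 scale the thresholds compare
on (−30 means a 30% drop).

Missing-data propagation is strict: RI (hence QoA) is undefined on a
first or post-gap day; each Δ needs both neighbouring values; WQoA
needs four consecutive QoA days; the 7-day sum needs seven consecutive
Δ values. An invalid day therefore silences $\sum\Delta QoA$ for a full
week — gaps suppress the statistics rather than bridging them, which is
also why non-continuous monitoring shows up as missed events rather
than spurious alerts. A config switch (`ri_missing = "zero"`) instead
substitutes RI = 0 where it is undefined; the default leaves QoA
missing because the model provides no regularity default and the value
affects nothing before the 7-day warm-up anyway.

## Alert criteria

An alert is raised on day *i* (earliest day 7 — the model needs a week
of history) when both hold:

* strictly more than `min_drop_days` of the past 7 days had
  $\Delta WQoA < 0$ ("dropping" means WQoA fell versus the previous
  day, not that $\Delta WQoA$ itself decreased), and
* $\sum\Delta QoA_i$ exists and is strictly below the threshold.

The shipped profiles are **proposed** (> 4 drop days, < −30),
**loosened** (> 3, < −25) and **stricter** (proposed plus three
consecutive drop days ending on the alert day). "More than *n*" is read
literally, which keeps proposed and loosened distinct. Missing
statistics never qualify (fail-silent).

Qualifying-day sets are nested by construction:
stricter ⊆ proposed ⊆ loosened for any series. Consecutive qualifying
days are merged into one alert *episode* anchored at the first day
(default; `merge = FALSE` emits one prediction per day). One subtlety
is worth recording: with merging on, *sensitivity* need not be ordered
across profiles even though the day sets are nested, because a looser
profile can start a run earlier and the merged anchor may fall outside
an event's 30-day window. The ordering is provable at day level, so the
validation suite scores profile ordering with unmerged predictions.

## Evaluation

A prediction on day *d* is a true positive when an ER visit or
rehospitalization occurs strictly after *d* and within 30 days
(*d* < *e* ≤ *d* + 30); same-day events are concurrent admissions, not
predictions. An event is a false negative when no prediction preceded
it by 1–30 days (the mirror window). Several predictions may be
credited to one event; each is counted once. There is no true-negative
count — uneventful days are not enumerable trials — so sensitivity,
precision, miss rate and false discovery rate are reported and
specificity-type measures deliberately are not. Routine outpatient
(OPD) visits never enter the confusion counts; false positives with an
OPD visit in their horizon are annotated, since a treatment change at
such a visit can avert the predicted event.

The percentages are kept as exact rationals internally and rounded only
for reporting. `reproduce_paper_arithmetic()` recomputes all metrics
from the published confusion counts of the original 16-patient study
(shipped as plain-CSV fixtures) and prints them beside the published
values; one published value (the loosened-profile false discovery rate)
disagrees with its own counts by one rounding step and is flagged
rather than matched.

## The synthetic cohort generator

No real recordings are distributable, so validation rests on synthetic
patients with known ground truth. A patient is a smooth circadian
template (high daytime plateau, soft evening wind-down, low-but-nonzero
night floor), scaled by a lognormally distributed per-patient amplitude,
with i.i.d. multiplicative lognormal minute noise (sdlog 0.12) and a
small daily schedule shift (sd 4 minutes). These defaults were chosen
once as a plausible stable regime: they yield day-to-day correlations
around 0.9+, i.e. a patient in steady rhythm.

Deterioration before a planted event has two independent knobs:
amplitude decay (total activity shrinks by a fixed percentage per day
into the onset) and regularity decay (a smooth random time-warp whose
magnitude grows through the onset, degrading the day-to-day correlation
while roughly preserving the total — modelling the patient whose
*volume* looks fine while their *rhythm* disintegrates). Abrupt events
have no antecedent signal and are undetectable by design.

Raw-signal rendering inverts the AI computation: a worn minute with
target AI *a* becomes tri-axial Gaussian jitter around gravity with
per-axis sd *a*/60, non-wear minutes a constant gravity vector, sample
timestamps at interval centres (so epoch assignment is immune to
floating-point edge effects). The night floor of the circadian template
keeps worn minutes above the non-wear thresholds, so planted gaps are
recovered exactly at minute resolution.

What the generator does *not* emulate: gait microstructure, posture,
device-specific noise spectra, autocorrelated within-day behaviour, or
multi-event clinical histories. Passing tests therefore demonstrate the
pipeline's arithmetic, propagation rules and detection logic under a
controlled regime — not clinical performance on real cohorts.

## Numerical and design choices

* Timestamps are local wall-clock in a fixed zone; the 1440-minute grid
  is a clock construct, so daylight-saving days map by clock labels.
* Timestamp gaps under 1 s are tolerated; minutes absorb jitter.
* Variance thresholds use strict `<`; validity uses `≤ 60` minutes;
  criteria use strict `<` and `>` as the wording dictates.
* Epochs with fewer than two samples contribute 0 to a minute's AI;
  minutes with no samples are missing, not zero.
* Validation problem sizes: cohort studies use 16–200 patients at
  45–60 days (minute-level generation), raw round trips 1–2 full days
  at 20 Hz, chosen to exercise every code path at desk scale.

## Limitations

The alert rule is deliberately simple (two thresholds on hand-built
statistics); it produces many false alarms by design — acceptable for a
nurse-call workflow, not for patient-facing notification. RI and AI
definitions are pragmatic defaults behind pluggable interfaces, not the
only defensible choices. Evaluation treats every event independently;
time-to-event structure, competing risks and repeated-event correlation
are out of scope.
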