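---
title: "Models and methods of the CPMC motility bioassay pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the CPMC motility bioassay pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay and what the package computes

Isolated segments of mouse colon mounted in a perfused organ bath generate
spontaneous, regularly recurring propagating contractions — colonic
peristaltic motor complexes (CPMCs) — recorded as intraluminal pressure
waves on a ~5 mmHg resting baseline, sampled at 100 Hz. A blinded safety
screen perfuses each tissue through four successive 15-min phases (vehicle,
then three incremental drug concentrations, typically 0.3/3/30 µM,
followed by a washout) and asks whether the compound measurably perturbs
CPMC activity. Because the raw tissue recordings behind the published
screen are proprietary, this package pairs a fully specified synthetic
trace generator with the complete downstream analysis, so that every stage
— event detection, the five motility metrics, the vehicle-relative 2-SD
decision rule, and translational concordance scoring — is executable and
testable end to end.

## The trace generator

A simulated phase is

> baseline + Gaussian sensor noise + one raised-cosine pulse per CPMC +
> sub-threshold contractions,

with ground-truth annotations for every generated complex.

**Event timing.** CPMC onsets follow a *stationary* gamma renewal process:
the first onset is an equilibrium residual (a uniform fraction of a
length-biased interval) and subsequent onset-to-onset intervals are gamma
draws with mean `mean_interval` and shape `interval_shape`. The
stationary start matters: an ordinary renewal process undercounts events
in a finite window by roughly `(CV^2 - 1)/2` (about −0.37 events per
900 s at shape 4), whereas the stationary process gives an expected count
of exactly `duration / mean_interval`. Shape 4 (interval CV = 0.5) encodes
the sub-Poisson regularity of the observed pacing; a Poisson process would
be far too irregular for the small between-tissue spread of observed
frequencies. Intervals shorter than the pulse width are redrawn, so
complexes never overlap — they are discrete events in real recordings too.

**Pulse shape.** A raised cosine of width `event_duration` and peak
`event_amplitude × lognormal(mean 1, cv amplitude_cv)`. The smooth,
compactly supported shape avoids gifting the detector any discontinuities.
A complex starting near the end of a phase is truncated at the phase
boundary and flagged `truncated` in the annotations.

**Sub-threshold contractions.** Real recordings show small non-propagating
contractions between complexes. These are modelled as sparse raised-cosine
"blips" (defaults: ~7 mmHg peak, 15 s wide, ~8.9 per 900 s) placed in the
gaps between complexes. They sit below the 10-mmHg detection threshold, so
they never create events, but they do spend time above the 5-mmHg
quiescence band and add area under the curve — which is exactly their
role in the calibration (below).

**Vehicle drift.** Time-matched control experiments show a small
systematic amplitude change over successive phases. The generator applies
`(1 + drift_per_phase)^phase_index` (default −2 %/phase) to the event
amplitude in *every* run, drug and control alike, so the decision rule has
to control for the confound rather than being spared it.

**Drug effects.** Concentration–response is an Emax/Hill scaling
`s(c) = 1 + (emax − 1)·c^n / (c^n + ec50^n)` applied to a targeted
generator parameter — multiplied for `direction = "excitatory"`, divided
for `"inhibitory"` (which keeps parameters positive at any concentration).
Note the direction names refer to the *parameter*, so a compound that
slows pacing is an *excitatory* effect on `mean_interval`. The published
screen reports only empirical concentration dependence; the Hill form is
this package's modelling choice, chosen as the field's default saturating
dose–response.

### Calibration of the defaults

The published baseline cohort (99 tissues, one 900-s phase each) reports
five reference statistics: frequency 5.6 CPMCs/900 s, inter-complex
interval (TI) 161.4 s, time in quiescence (TIQ) 661 s, amplitude 49 mmHg,
AUC 6410 mmHg·s. The generator defaults are derived to satisfy these
jointly:

* `baseline_pressure = 5` mmHg, `mean_interval = 161.4` s and
  `event_amplitude = 49` mmHg are taken directly from the reference
  values;
* `event_duration` and `blip_rate` are solved from the TIQ and AUC moment
  equations. For a raised cosine of width *w* and peak *A*, the time spent
  above a band *h* is `w·(1 − arccos(1 − 2h/A)/π)` and the area is
  `A·w/2`; requiring the cohort expectations of TIQ and AUC to hit 661 s
  and 6410 mmHg·s simultaneously gives `w ≈ 44.2` s and ~8.9 blips per
  phase. A single-component generator cannot satisfy both at once — with
  amplitude pinned at 49 mmHg, TIQ = 661 s forces a per-event area about
  15 % larger than AUC = 6410 allows — which is the quantitative reason
  the sub-threshold component exists;
* `noise_sd = 1` mmHg sets the hysteresis thresholds at 5–10 noise SDs;
* `amplitude_cv = 0.1` and `interval_shape = 4` are within-tissue
  variability choices that no published statistic pins down; they control
  only the Monte-Carlo spread of the cohort means.

A 600-phase pilot at these defaults reproduces all five reference values
within Monte-Carlo error (the largest deviation, frequency ≈ 5.45–5.5, is
the detector's loss of end-truncated complexes with under 5 s of
visible support plus the no-overlap redraw, and stays well inside the
cohort's 3-SEM band at n = 99).

## Detection and the five metrics

Detection runs on a copy of the trace smoothed by a centred 1-s moving
average — standard practice for pressure channels; it suppresses
sample-level noise (SD 1 mmHg → 0.1 mmHg) while a ~44-s wave loses under
0.1 % of its peak. All metrics are measured on the same smoothed signal so
their identities hold exactly.

* **Baseline**: the 10th percentile of the smoothed phase samples. If
  fewer than 5 % of samples lie within the quiescence band of the
  estimate, the phase has no quiescent plateau and a warning flags the
  estimate as likely biased high.
* **Events**: hysteresis — open above baseline + 10 mmHg, close below
  baseline + 5 mmHg; events closer than 2 s are merged (a complex with a
  brief sub-threshold dip is one complex), then events shorter than 5 s
  are dropped. Merging precedes the duration filter. Events truncated at
  a phase edge are kept when they meet the duration criterion inside the
  phase.
* **Amplitude** is the peak excursion *above baseline*, not absolute
  pressure (49 mmHg on a 5-mmHg baseline makes the two readings
  materially different). Edge-truncated events are excluded from the
  amplitude mean, since their peak may lie outside the phase.
* **TI** is the mean onset-to-onset difference; it carries an explicit
  `NA` marker when fewer than two events exist, as does the amplitude
  mean with no measurable event. The markers propagate to the decision
  stage as "not assessable" — never silently zero.
* **TIQ** is the total time the smoothed pressure sits at or below
  baseline + 5 mmHg ("at baseline activity" has no published numeric
  definition; the band equals the closing threshold). TIQ plus time above
  the band equals the phase duration exactly.
* **AUC** integrates the baseline-subtracted, zero-clipped smoothed
  pressure over the full phase by the trapezoid rule. Baseline
  subtraction makes the statistic robust to slow drift. The reference
  tables print the unit as mmHg/s, but an area under a pressure–time
  curve is mmHg·s, which is what the package reports.

Phases use 0-based, half-open time indexing `[start, end)`.

## The decision rule

Amplitude and TIQ for each drug phase are expressed as percentage changes
relative to the experiment's *own* vehicle phase (phase 1 serves all drug
phases; the running-vehicle alternative is not what "their corresponding
vehicles" most simply describes). Time-matched vehicle-only experiments
(default cohort size 4) provide, per phase position and metric, a null
mean and sample SD (n − 1). A phase/metric is **positive** when its
relative change lies strictly more than 2 control SDs from the control
mean — two-sided, because the reference analysis plots the ±2 SD band on
both sides, and a motility *decrease* is as much a liability signal as an
increase. A compound is positive when **either** metric is positive.

Compound-level calls are read at two dose positions: the highest
concentration tested, and the highest concentration within the clinically
relevant window (concentrations ≤ 50 × the maximum clinical plasma
exposure). When no tested concentration falls inside the window the
clinical-dose call is *negative-by-window*: the screen cannot have flagged
the compound at a relevant exposure, and the reference scoring treats
exactly this situation as a true negative. A compound positive at the
lowest tested concentration triggers the dose-lowering planner, which
requests a rerun at one-tenth the concentrations (it does not merge runs).

No multiplicity correction is applied across phases or metrics — the 2-SD
rule is used exactly as the screen defines it. Its empirical false-positive
rate with a 4-experiment control cohort is appreciable; the synthetic
end-to-end panel reports (not asserts) that rate honestly.

## Concordance scoring

Clinical findings are restricted to a controlled vocabulary; only
diarrhea, constipation and loose stools count as motility GADRs — nausea
does not (this single choice drives one compound's true-negative status).
Crossing the assay call with the clinical flag yields TP/FN/FP/TN, and

> predictive capacity = (TP + TN) / compounds tested.

The packaged tables transcribe the published 15-compound clinical,
in vitro and charcoal-meal summaries. `reproduce_paper()` recomputes every
category from the underlying flags — never copying the printed outcome
columns, which serve only as a verification oracle; any disagreement is a
hard error naming the compounds. Three compounds whose protein binding was
unknown anchor their windows on total rather than free exposure, as the
source tables do. The two in vitro dosing schemes are compared by Fisher's
exact conditional test on the correct/incorrect 2×2 table; the test used
in the original analysis is unnamed, so the exact test is asserted only at
the published "p > 0.05" level.

## The charcoal-meal arm

Transit is the charcoal front's travel distance as a percentage of
small-intestine length; the gastric-emptying index (full − empty stomach
weight) is computed and reported but never classifies compounds.
Treated-vs-vehicle comparisons use the two-sided Wilcoxon Mann–Whitney
test — exact for tie-free groups up to size 12 (the study used n = 8),
normal approximation with continuity and tie correction otherwise — at
α = 0.05; sidedness is unstated in the source, and two-sided is the
conservative default. Effect direction comes from group medians, matching
the source's median-based reporting. A compound is positive when any dose
group with measured plasma concentration inside the 50-fold window shows a
significant effect. The synthetic transit generator (truncated normal,
median 53.3 %, spread 12.2 %) encodes the historical vehicle baseline of
the assay; that baseline summarises a proprietary database, so it is a
calibration value, not a verification target.

## What the synthetic data can and cannot show

The generator emulates baseline CPMC physiology, concentration-dependent
drug action, vehicle drift, and sensor noise. It does not model spatial
propagation (the assay records one pressure channel), bath concentration
kinetics (perfusate concentration is assumed instantly at steady state),
washout pharmacodynamics beyond an instantaneous return to zero
concentration, or between-tissue heterogeneity beyond per-event
variability. Green tests therefore demonstrate that the *analysis* is
correct and calibrated — detector agrees with ground truth, metrics
satisfy their identities, the decision rule has its stated operating
characteristics — not that real tissues behave like the model. The
15-compound concordance results, by contrast, are exact arithmetic over
the published tables and do not depend on the simulator at all.

## Numerical choices and problem sizes

Tolerances and sizes used by the test suite and reproduction scripts, all
chosen as the package's own working defaults: renewal calibration over 600
simulated phases (2 % band); the 99-phase baseline cohort compared to the
five reference values within 3 cohort SEMs; detector/annotation
equivalence over 100 random noise-free configurations (exact counts, 1 %
amplitude agreement, enforced event separation); rank-sum exactness
against full enumeration for group sizes ≤ 6 and null size over 2000
vehicle-vs-vehicle pairs (±0.01 of α). Ties in rank-sum inputs switch to
the corrected normal approximation; identical groups return p = 1 and
"NC". Degenerate inputs carry explicit markers: empty traces refuse a
baseline, zero-event phases yield `NA` TI/amplitude, empty exposure
windows yield negative-by-window, zero-denominator rates are `NA`.

## Known limitations

* The five reference baseline statistics cannot identify the pulse shape;
  any sufficiently smooth unimodal wave with the right width/area/peak
  trade-off (given the sub-threshold component) fits them equally well.
* Frequency inherits a small negative bias (~0.15 events/phase) from
  edge-truncated complexes with insufficient visible support; it is well
  inside the cohort's sampling spread but visible at very large n.
* With only four control experiments the 2-SD rule's null SD estimate is
  noisy, so compound-level false-positive rates are high — a property of
  the screen being modelled, reproduced rather than repaired here.
* Amplitude suppression beyond roughly threefold pushes complexes under
  the detection threshold; the amplitude metric then goes not-assessable
  and positivity rests on TIQ alone (see the synthetic panel script).
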