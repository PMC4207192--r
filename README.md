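# cpmcassay

Safety-pharmacology screens would like to catch motility-related
gastrointestinal adverse drug reactions (GADRs) — diarrhea, constipation,
loose stools — before a compound reaches Phase I. One proposed biomarker
is the colonic peristaltic motor complex (CPMC): isolated mouse colon in a
perfused organ bath produces stereotyped propagating pressure waves, and a
compound's effect on them can be read out from a single intraluminal
pressure channel. `cpmcassay` implements that bioassay's complete analysis
pipeline, together with the in vivo charcoal-meal transit assay it is
benchmarked against, for an audience of GI physiologists and safety
pharmacologists who want the decision logic of such screens executable,
calibrated and testable.

The pipeline:

* **Trace simulation** — 100-Hz intraluminal-pressure phases built from a
  stationary gamma renewal process of raised-cosine CPMC waves on a
  5-mmHg baseline, plus sub-threshold contractions, sensor noise, a
  per-phase vehicle amplitude drift, and Emax/Hill concentration–response
  scaling `s(c) = 1 + (emax − 1)·cⁿ/(cⁿ + ec50ⁿ)` of generator
  parameters, with ground-truth event annotations.
* **Quantification** — hysteresis event detection (open at baseline +
  10 mmHg, close at +5 mmHg) on a 1-s-smoothed trace, and the five
  per-phase metrics: frequency, inter-complex interval (TI), time in
  quiescence (TIQ), amplitude, and area under the baseline-subtracted
  curve (AUC).
* **Decision rule** — amplitude and TIQ as percentage changes relative to
  the run's vehicle phase; a compound is positive when either change lies
  strictly beyond 2 SDs of the time-matched vehicle-control distribution
  (two-sided).
* **Concordance** — calls crossed with clinical GADR labels inside a
  50-fold plasma-exposure window give TP/FP/TN/FN and
  `predictive capacity = (TP + TN) / compounds`, for the in vitro assay
  (at maximum and at therapeutic dose) and for the charcoal-meal transit
  assay (exact Wilcoxon Mann–Whitney comparisons of transit percentages).

The packaged 15-compound clinical/assay tables are transcribed fixtures;
`reproduce_paper()` recomputes every per-compound category from the
underlying flags and window logic and treats the transcribed outcome
columns purely as a verification oracle (any mismatch is a hard error).

## Worked example

Simulate one baseline phase, quantify it, and reproduce the concordance
analysis:

```r
library(cpmcassay)

ph <- simulate_phase(generator_config(), duration = 900, seed = 42)
quantify_phase(ph)$metrics
#>   phase_label frequency  ti_mean    tiq amplitude_mean      auc
#> 1     vehicle         5 143.0325 681.86       56.33268 6076.461

reproduce_paper()
#> Concordance of assay calls with clinical GADR labels (50-fold exposure window)
#>   invitro_max          TP 6  FP 6  TN 1  FN 2   predictive capacity 7/15 = 47%
#>   invitro_therapeutic  TP 5  FP 3  TN 4  FN 3   predictive capacity 9/15 = 60%
#>   charcoal             TP 4  FP 4  TN 3  FN 4   predictive capacity 7/15 = 47%
#>   max-dose vs therapeutic-dose scheme: Fisher exact p = 0.715
#>   in vitro (therapeutic): sensitivity 0.62, specificity 0.57
```

The single 900-s phase happened to catch five complexes (frequency 5)
whose mean amplitude drew high (56 mmHg; the per-event spread is ~10 %) —
cohort means over many phases sit at the calibrated 5.6 / 161 s / 661 s /
49 mmHg / 6410 mmHg·s. The concordance block is the package's central
result: restricting calls to clinically relevant exposures trades false
positives for true negatives (47 % → 60 % correct), the two dosing schemes
are statistically indistinguishable (exact p = 0.715), and both assays
hover near coin-flip accuracy — the quantitative case that such screens
need better models, not better thresholds.

The `analysis/` directory holds the numbered workflow drivers
(`01_baseline_cohort.R` … `04_transit_calibration.R`) that generate the
tables under `results/`.

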