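# ocsplus

Scoring, age-stratified normative cut-offs, and psychometric validation for
the OCS-Plus tablet-based cognitive screen.

The OCS-Plus is a brief (~24 min) tablet screen of ten subtasks covering
naming, semantics, orientation, verbal memory encoding and delayed recall,
trail-making with set switching, incidental episodic memory, figure
copy/recall, rule finding, and visual cancellation under feedback and
no-feedback conditions. This package implements, for researchers and
clinical neuropsychologists working with its data:

- **Trial-level scoring** of all ten subtasks from structured session logs
  (a versioned JSON schema with per-event responses, correctness,
  timestamps, and tap coordinates), including the two derived trail
  measures:

  - executive (switching) score
    `100 × min(1, switch_prop / baseline_prop)`, where `baseline_prop` is
    the proportion correct over both baseline trails (14 connections) and
    `switch_prop` the proportion correct on the switching trail;
  - accuracy-corrected processing speed
    `(t_circle + t_square) / baseline_prop` in seconds (higher = worse),
    which penalises fast-but-inaccurate responding.

- **Normative impairment cut-offs**: `mean ± 1.65·SD` for wide-range
  measures (a one-tailed 5% rule under normality) and empirical 5th/95th
  centiles for restricted-range measures, with conservative floors for error
  counts; stratified by age band (<60, 60–70, >70) and pooled. Cognitive
  domain summative scores (executive function, praxis, delayed memory,
  attention, encoding, naming/semantics).

- **Psychometrics**: bootstrapped split-half reliability with
  Spearman–Brown correction (`2r/(1+r)` averaged over 5000 random splits),
  attenuation-corrected validity (`r_corrected = r / sqrt(rel_x · rel_y)`)
  with family-wise Bonferroni thresholds, paired Wilcoxon test–retest
  analysis with Jacobson–Truax reliable change indices
  `RCI = (x2 − x1) / (SD_baseline · √2 · √(1 − r_xx))`, and Mann–Whitney
  cohort-harmonisation checks.

- **A synthetic-data module** that generates cohorts, trial-level sessions,
  retest pairs and external-battery scores with known ground truth, so the
  whole pipeline is testable end-to-end without any real data.

- **Automated impairment reports** (the per-participant "wheel") as
  deterministic JSON plus a plain-text rendering.

## Worked example

```r
library(ocsplus)

# simulate a normative cohort and derive age-banded cut-offs
sim <- simulate_cohort(default_generator_config(320), seed = 7)
tab <- build_normative_table(sim$cohort)
subset(tab, measure == "rule_accuracy" & age_band == "all")
#>        measure age_band   n     mean       sd median min max method cutoff_value cutoff_operator
#> 44 rule_accuracy      all 320 26.97812 8.115708     28   3  45      z        13.59               <

# score a trial-level session and classify it
log <- simulate_session(sim$truth[3, ], seed = 3)
scores <- score_session(log)
profile <- classify_scores(scores, log$age, tab)
generate_report(profile, log)
#> OCS-Plus impairment report (schema 1.0)
#> participant: sim_0003   age band: <60
#>
#>   [ok] picture_naming               score 4 (cut-off < 3)
#>   ...
#>   [ok] rule_accuracy                score 37 (cut-off < 16.85)
#>   ...
```

The cut-off row above is the cohort mean minus 1.65 SDs, rounded to two
decimals; a score strictly below it is flagged impaired relative to the
normative sample. The report lists one segment per measure (`[ok]` spared,
`[X]` impaired, `[--]` not assessed, `[..]` unscored) plus the six domain
sums.

A thin command-line wrapper is shipped at `inst/cli/ocsplus.R`:

```sh
Rscript inst/cli/ocsplus.R simulate cohort.csv --n 320 --seed 7
Rscript inst/cli/ocsplus.R norms cohort.csv --out norms.json
Rscript inst/cli/ocsplus.R report session.json --norms norms.json --out report.json
```

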