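---
title: "Methods: scoring, norms and psychometrics in ocsplus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, norms and psychometrics in ocsplus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocsplus)
```

This vignette documents the models and conventions behind `ocsplus`: how each
subtask is scored from trial-level data, how normative impairment cut-offs
are derived and applied, how the psychometric toolkit is defined, what the
synthetic-data generator does and does not emulate, and the numerical
decisions taken where the instrument's published description leaves the
design open.

## The session data model

A session is a versioned JSON document (schema `1.0`): demographics plus ten
subtask blocks in administration order, each block carrying ordered trial
events (stimulus id, response, ternary correctness, millisecond timestamp
from session start, and optional tap coordinates in screen pixels, origin
top-left). Timestamps must be non-decreasing within a block; trial indices
unique. A skipped block must be empty and must carry a free-text reason; all
of its measures are propagated downstream as *not assessed* — missing and
zero are never conflated. Optional fields are omitted on disk, not
null-filled, and `write_session()`/`read_session()` round-trip bit-exactly.

## Scoring rules

- **Choice tasks** (picture naming, semantics, orientation, episodic
  recognition): count of correct responses out of four.
- **Word memory**: the five-word target list is fixed (`bicycle, mist,
  wardrobe, teacher, rectangle`, or a configured translation). Each encoding
  attempt is scored independently as the size of the intersection between
  the normalized (case-folded, trimmed) responses and the target list;
  duplicates collapse, intrusions score nothing. Matching is exact after
  normalization — no fuzzy matching, since the instrument defines none.
- **Delayed recall**: free recall 0–5; forced-choice recognition is offered
  only for missed words, and the recall-and-recognition total adds correct
  recognitions, so the total never falls below free recall and the surplus
  is bounded by the number of misses. Supplying a recognition outcome for a
  freely recalled word is a validation error.
- **Trails**: both baseline trails have seven connections. The executive
  (switching) score is the ratio of the switching-trail proportion correct
  over the summed baseline proportion, scaled to 0–100 and capped at 100.
  The published score range (0–100, median near ceiling) motivates the cap;
  it is configurable. The switching-trail length is not published; it is a
  configuration value with default 13. Processing speed divides the summed
  baseline time by the baseline accuracy proportion (denominator: both
  baseline maxima, 14), correcting the artefactually fast times of
  participants who connect only a few shapes. A zero-accuracy baseline makes
  both measures explicitly *unscorable*, never infinite.
- **Rule finding**: five rules in contiguous segments; the trial immediately
  after each rule change is excluded, leaving 46 scoreable trials under the
  default layout (5 × 10 trials). Accuracy is the number of correct
  anticipations over scoreable trials. A rule is detected when at least two
  consecutive correct responses occur within its segment; whether a run may
  span an excluded trial is unstated in the instrument's description, so the
  package adopts the convention that exclusions *break no runs but count
  toward none* (runs are evaluated over the scoreable subsequence). This is
  configurable via `rule_config()`.
- **Figure copy/recall**: twenty specified elements, each scored 0/1 for
  presence, position and accuracy (no partial credit is defined), summing to
  60 per drawing. Element scores are supplied by a human rater or the
  simulator; the package performs no image analysis.
- **Cancellation**: taps are hit-tested against axis-aligned item bounding
  boxes (smallest enclosing box wins; taps outside every box are ignored).
  Hits are distinct targets (0–30). The feedback condition scores one false
  positive per distractor selection; the no-feedback condition scores one
  correct revisit per re-selection of an already-found target.

## Normative cut-offs and classification

Wide-range measures (trails-derived scores, rule-finding accuracy, figure
drawings, cancellation accuracies) use the z rule: impaired beyond
`mean ± 1.65·SD` of the normative stratum, in the direction of impairment —
a one-tailed 5% design under normality. Restricted-range measures (the
0–4/0–5 tasks, rules learned, error counts) use empirical centiles (5th for
low-bad scores, 95th for error counts), because near-ceiling discrete
distributions make SD-based rules meaningless. When an error-count centile
reaches the degenerate end of the scale, the cut-off is conservatively
raised to one with an inclusive comparison (a single error is flagged).

Numerical conventions, fixed and documented because the published tables do
not state them:

- z cut-offs are rounded *half-up* to two decimals and the rounded value is
  used in comparisons; this reproduces the published thresholds exactly
  (e.g. `33.83 + 1.65 × 18.70 = 64.6855 → 64.69`, where IEEE half-even
  rounding would print 64.68).
- centiles use the type-7 (linear interpolation) empirical quantile, and
  per-age-band centile cut-offs are rounded to whole numbers as the
  published banded tables are.
- age bands are `<60`, `60–70`, `>70`; ages exactly 60 and 70 are not
  covered by the published band headers, and the package assigns the closed
  interval [60, 70] to the middle band (configurable).

Figure copy carries a `uk_only` registry flag: when the cohort has a `site`
column, its norms are computed on the UK subset, mirroring the decision to
norm that task on the larger sub-cohort after a site difference; it is a
per-measure stratification filter, not nationality logic. Education-based
norms are not implemented (the underlying normative sample is too
education-skewed for a 3 × 2 stratification); the education band is retained
in the data model for users.

Domain summative scores are fixed sums of assessed constituents: delayed
memory = delayed recall + recall-and-recognition (0–10); attention = visible
+ invisible cancellation hits (0–60); encoding = attempt 1 + attempt 2
(0–10); naming/semantics = picture naming + semantics (0–8); praxis = figure
copy + recall (0–120). The executive-function combination is published only
as a list of constituent measures, so the package declares a default —
rule accuracy + rules learned + executive score − false positives — with
configurable weights; domain cut-offs are always derived from a user's
cohort (`build_normative_table(..., domains = TRUE)`), never hard-coded,
because the published domain centile column is internally inconsistent with
its own note.

## Psychometrics

**Split-half reliability.** The published analysis bootstraps split-half
consistency over trial-level data; the exact resampling scheme is ambiguous,
so the package provides both variants and defaults to split-only: at each of
5000 iterations the items are randomly partitioned into halves, half scores
correlated, and Spearman–Brown applied; a `resample = TRUE` flag additionally
resamples participants each iteration. Zero-variance halves are skipped and
counted; when most iterations are degenerate — as for few-item tasks at
ceiling, where a single error dominates the rankings — the estimate is
flagged uninterpretable rather than reported as a trustworthy coefficient.

**Attenuation correction.** `corrected = coeff / sqrt(rel_x · rel_y)`.
Values above one in magnitude are flagged (non-random measurement error) and
never clamped. Time-based measures that cannot generate an internal
consistency may be assigned a declared reliability of 1; this replicates the
convention of treating such corrections as assumptions, not computations.

**Validity tables.** Kendall tau-b (tie-corrected) per mapped pair over
pairwise-complete observations; family-wise Bonferroni thresholds with
family sizes taken from the mapping itself (e.g. 0.05/13 convergent,
0.05/26 divergent for the published battery layout); corrected coefficients
with magnitude above 0.20 are flagged as acceptable convergence.

**Test–retest.** Two-sided paired Wilcoxon signed-rank test with continuity
correction; exact distribution below 20 non-tied pairs when ranks are
untied, normal approximation otherwise; zeros discarded (standard
signed-rank convention); matched rank-biserial effect size. Reliable change
uses the Jacobson–Truax form `(x2 − x1) / (SD_baseline √2 √(1 − r_xx))` —
the underlying publication references RCI data without printing a formula,
so the package declares this standard one. When every pair is tied the test
is undefined and the result says so explicitly, with all RCIs zero by
definition. Cohort harmonisation uses two-sided Mann–Whitney tests with
Bonferroni correction.

**Detectable-effect power.** `correlation_power()` estimates by simulation
the power of a Pearson test on bivariate normal data. The validity design's
stated bound — detecting latent correlations down to 0.19 at n = 159 (up to
0.26 at n = 85) with 80% power at α = 0.05 — reproduces under a
*directional* test (simulated power ≈ 0.78 at r = 0.19, n = 159; the
80%-power detectable r is 0.197 at n = 159 and 0.268 at n = 85). Under a
two-sided test the same bound would require r ≈ 0.22–0.30, so the package
reads the design as directional; `alternative = "two.sided"` is available.

## The synthetic-data generator

`simulate_cohort()` draws, per age band: truncated normals for the
continuous measures (means/SDs defaulting to the published banded patterns,
e.g. figure-recall means declining 47.02 / 42.43 / 41.25 across bands, and a
near-ceiling cancellation accuracy around 29.7 ± 0.6), binomial hit-count
models for the restricted-range tasks, and Poisson error counts. Band sizes
default to 111/101/108 of n = 320. Trail times are drawn so that the derived
processing speed follows its configured band distribution; the executive
score *emerges* from binomial switch performance over baseline accuracy and
is therefore skewed and capped, like the real measure. These defaults are
illustrative calibrations, not the instrument's data.

`simulate_session()` constructs trial-level events — including a
rule-finding anticipation sequence built constructively to realize any
feasible (accuracy, rules-learned) pair, and cancellation tap streams
replayed against the shipped layout — such that `score_session()` recovers
the intended scores *exactly* (bit-identically for the derived trail
measures, which share the scorer's floating-point operation order). Retest
pairs use a Gaussian latent model per measure to hit a target test–retest
correlation with a configurable practice shift; external batteries share a
configured latent correlation, attenuated by declared reliabilities so the
attenuation correction can be validated in a round trip.

What the generator does *not* emulate: real response-time dynamics within
tasks, spatial search paths in cancellation, item-level difficulty structure
within choice tasks, clinical pathology profiles, or practice effects beyond
a mean shift. Passing tests therefore demonstrate the correctness of the
scoring/norming machinery and the internal consistency of the statistical
toolkit on data of known structure — not the clinical validity of the
instrument on real populations.

Two consequences of faithful generation are worth stating. First, the
1.65-SD rule yields ≈5% impaired only where the generating distribution is
continuous and unconstrained near the impairment tail (processing speed,
rule accuracy, figure copy/recall); for integer-valued ceiling measures
(cancellation accuracies, the capped executive ratio) the achieved tail
probability deviates from the nominal 5% by construction — e.g. an integer
score distributed N(29.67, 0.63) and cut at 28.63 is impaired with
probability P(X < 28.5) ≈ 3% — which is precisely why restricted-range
measures are normed by centiles. Second, clamping and rounding slightly
attenuate targeted correlations near ceilings; the retest recovery tests use
continuous measures and tolerances of ±0.05 accordingly.

## Problem sizes and determinism

Every stochastic routine takes a mandatory seed and is bit-reproducible
under it. The test suite uses parameter-recovery cohorts of n = 2000,
retest recovery at n = 500, 1000 random sequences for the rule-detection
oracle, exhaustive enumeration oracles up to n = 10 (signed-rank) and
n = 12 (Mann–Whitney relabelling), and 2000 Monte-Carlo replicates for the
power bound; these sizes give sampling error comfortably inside the asserted
tolerances while keeping the default run fast.

## Known limitations

- Figure-drawing element scores must be supplied externally; the package
  deliberately performs no image-based scoring (matching the instrument,
  which greys these segments in its automated report).
- The rule-finding trial layout and switching-trail length are configuration
  values; published constraints fix only the totals (46 scoreable trials,
  five rules, post-change exclusion).
- Output is per-measure impairment relative to norms, with domain sums as a
  coarse aid; the package assigns no diagnostic labels, which the screen is
  not designed to support.
- Published cohort-level coefficients that depend on the original raw data
  (per-task alphas, validity coefficients, the site-difference U statistic)
  are not recomputable from summaries; the property suites validate the
  machinery on synthetic data of known structure instead.
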