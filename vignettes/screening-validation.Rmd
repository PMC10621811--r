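---
title: "Screening for CVI-related visual search issues: models, thresholds and validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for CVI-related visual search issues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cviscreen)
```

## The problem

Cerebral visual impairment (CVI) is brain-based visual dysfunction that
cannot be attributed to the anterior visual pathways or to ocular disease.
Children with CVI-related deficits of the higher visual functions --
visual search, visuospatial attention, processing of crowded scenes --
frequently have normal visual acuity, so standard school vision screening
misses them.  One proposed screening instrument is a timed card-matching
task on a tablet: five levels of increasing complexity, from 4 cards and 1
pair at level one to 12 cards and 5 pairs at level five, in a multi-colored
and a single-colored variant.  Three variables are measured per run:

* **overall time** -- seconds to complete all five levels;
* **accuracy** -- for each level, whether every matched pair was a true
  pair ("accurate round", 0-5 per run);
* **dwell time** -- seconds from level onset to the first matched pair,
  averaged over the five levels.

A child is flagged for further assessment when *any one* of the six
thresholds (2 versions x 3 variables) is exceeded.  This package
implements the full analysis pipeline around that rule: a cohort
simulator, age-stratified normative thresholds, the screening rule, the
scorers of two reference cancellation tests, and the agreement and
diagnostic-accuracy statistics used to validate the screener.

## The generative model

No individual-level raw data are distributable, so every downstream stage
is exercised against a simulator whose defaults state the conditions the
screener's development cohort reported.

**Serial self-terminating search.**  A run is modelled as a sequence of
card inspections.  Locating pair *k* of a level with *C* cards costs
`C - 2(k-1)` inspections (each still-unmatched card is inspected once on
average before the pair closes), so the five levels cost 4, 10, 18, 28 and
40 inspections and a complete run costs 100.  Each inspection consumes a
lognormal time (`inspection_lognormal_sigma = 0.35`): response times are
positive and right-skewed, which reproduces the long upper tails observed
in young children.  The dwell time of a level is its first pair's search
time, so dwell, level time and accuracy all emerge from one mechanism --
the development study describes the *indicators* (slower search, worse
with complexity) but no mechanism, and serial search is the simplest
process producing all three measured variables.

**Age calibration.**  The development cohort's overall time fell linearly
by 3.34 s per year of age (single-colored) and 2.83 s per year
(multi-colored).  The simulator scales the per-card inspection median by an
age factor chosen so that the *expected* overall time is exactly linear in
age with the configured slope, anchored at `reference_age = 11` years with
`per_card_inspection_median_s = 0.38` (a ~40 s expected run, the centre of
the reported 9-12-year-old range).  Ordinary least squares on a simulated
typical cohort therefore recovers the configured slope without bias; the
calibration acceptance test demands recovery within +/-0.5 s/yr in at
least 95 of 100 replicates at n = 700.

**Between-child variability.**  A child-level lognormal speed factor
(`child_speed_sigma = 0.30`) is shared by both versions of that child's
assessment -- the within-child correlation between versions is not
reported anywhere, so a shared latent speed is the default rather than an
asserted correlation value.  The 30% coefficient of variation reproduces
the roughly 16-141 s range reported for 5-8-year-olds around a ~60 s mean.

**The latent deficit.**  A deficit child's inspection median is multiplied
by `1 + severity * (deficit_time_multiplier - 1)`; the default multiplier
2 encodes the reported characterisation that affected children took twice
as long to match the pairs at each level.  Severity defaults to 1 for all
deficit children because the doubling describes the deficit group as a
whole.  Pair placements are incorrect with probability
`plogis(qlogis(0.01) + 3 * severity + 0.12 * (cards - 4))` -- logistic
because it is bounded in [0,1] and monotone in both severity and display
complexity.  Deficit prevalence defaults to 0.034, the reported prevalence
of CVI-related visual issues in mainstream education.  The default age
weights are the development cohort's age composition (n = 724).

**What the simulator does not emulate.**  Eye movements, touch kinematics,
distraction and frustration behaviours, practice effects between the two
versions, and any non-linearity of the age trend.  A green test therefore
establishes that the pipeline's statistics behave correctly on data with
the stated structure -- not that the screener works on real children.

## Normative thresholds

Thresholds are always an artifact of the supplied reference cohort (the
published cutoffs are proprietary to the screening app and were never
printed).  For each age group (5-8, 9-12, 13-18 -- the groupings visible
in the development cohort's scatter) and version:

* the overall-time and dwell thresholds are the cell's 85th percentile
  (5-8 years, whose distribution is much more dispersed) or 95th
  percentile (9-12 and 13-18) -- policy defaults, overridable per group;
* the accuracy rule is fixed: fewer than 4 accurate rounds flags, in
  every age group.

Percentiles use linear interpolation between closest ranks,
`h = (n-1)p/100 + 1` (`stats::quantile` type 7), the most widespread
statistical-software default; the convention and the reference cohort's
MD5 hash are stored in the threshold set's provenance so cutoffs are
reproducible bit-for-bit.  Time triggers are *strict* (`value >
threshold`): a child exactly at the normative percentile is not flagged.
This boundary choice is documented precisely so that it is testable.
Cells with fewer than 20 runs are refused by name rather than silently
extrapolated.

## Cancellation-test scoring

Two paper-and-pencil visual search tests serve as reference instruments.

**Teddy bear cancellation (ages 5-8, untimed).**  15 targets and 60
distractors in five columns with nominal values -1, -1, 0, +1, +1.
Omissions `O`, location of omissions `LO-S` (sum of nominal values over
omitted targets; an empty sum is 0) and start location `START-S` (sum
over the first three *marked targets*; marks on distractors do not count
toward the first three -- the protocol wording "the first three targets
crossed out" is taken literally).  One or more omissions puts the result
outside the normative range.  Responses are scored exactly as recorded:
the test ends when the child says they have finished, so no imputation of
unfinished sheets is attempted.

**Six-letter cancellation (ages 9+, 90 s).**  A 22 x 14 letter grid with
six target letters; net score = total cancellations - wrong cancellations.
Duplicate marks on one cell are rejected at the type level rather than
guessed to be wrong cancellations.  The out-of-norm rule is "at the 5th
percentile or less", implemented as `net <= ` the reference distribution's
5th-percentile cutoff (closest-ranks convention).  The reported
`percentile_in_reference` uses midpoint tie correction, which makes the
rank percentile well defined on discrete scores; on heavily tied
references the cutoff rule, not the rank percentile, governs the decision
(on a degenerate all-equal reference, an equal net is out of norm, which
the midpoint rank alone would not give).  The published normative tables
are not redistributable, so the reference is pluggable: load a published
table from JSON, or build a simulated typical reference, which is flagged
`synthetic` and echoed as such in every report.

## Agreement and diagnostic statistics

The validation statistics are computed from 2x2 cross-classifications of
a reference classification (cancellation-test result, or known condition
status) against the screener's flag:

* **Cohen's kappa** `(po - pe)/(1 - pe)` with the marginal null-variance
  significance test: `se0 = sqrt(pe + pe^2 - sum(p_i. p_.i (p_i. +
  p_.i))) / ((1 - pe) sqrt(n))`, `z = kappa/se0`, two-sided normal p, no
  continuity correction.  This formula was chosen -- and is pinned by
  tests -- because it reproduces the study's printed p-values (0.347,
  < 0.001, 0.032) from the printed tables.  Bands follow Landis-Koch.
* **Sensitivity and specificity** with *Wald* intervals `p +/- 1.96
  sqrt(p(1-p)/m)`, reported unclipped.  Wald rather than Wilson or
  Clopper-Pearson because it exactly reproduces every printed interval,
  including a printed upper bound of 1.151; reports keep the unclipped
  bounds for fidelity and say so.  Zero margins yield an explicit
  `undefined` status instead of a number.
* Degenerate kappa (`pe = 1`, only possible in 2x2 when all mass sits in
  one agreement cell) is defined as 1 if `po = 1` and 0 otherwise and
  flagged; when the null variance collapses to zero (e.g. all
  reference-positive, all index-negative), kappa is reported without a
  p-value.

The bundled `validation_tables()` give the six published 2x2 tables.  The
known-condition kappas recompute from their own tables as 0.339 (5-8),
0.571 (9-12) and 0.475 (13-18), whereas the study's running text attaches
each of these values to a neighboring age group; the package computes
from the tables and leaves the discrepancy visible rather than silently
reconciling it.  The printed sensitivities and specificities match their
tables exactly.

Similarly, `screening_findings()` bundles the follow-up findings of the 23
flagged children from the school screening campaign.  Counting with
`checklist_classify()` reproduces the reported 5 children with all three
CVI checklist criteria met and 17 of 23 with clinical findings.  The
11-question inventory flag is strict (`score > 15`, "over 15"); among the
10 children with checklist >= 2 the strict rule captures 7, the inclusive
`>= 15` reading 8 (the count the running text reports).  The cutoff is a
parameter so either reading is available; the discrepancy is flagged, not
resolved.

## Numerical and design choices

* Times are stored at millisecond resolution; derived per-run summaries
  (overall time, mean dwell, accurate rounds) are stored redundantly in
  the CSV for human readability and *re-validated on read* -- a mismatch
  is an error naming the row and field, never a silent fix.
* All randomness flows through R's global RNG; `simulate_cohort()` seeds
  it from the config, so identical configs give byte-identical cohort
  files, and the pipeline writes no timestamps, so full re-runs are
  byte-identical too.
* Pipeline stages communicate only through files (CSV/JSON); a real
  cohort export can replace the simulated file without code changes.
* A child with only one completed version is screened on the available
  version and marked `partial` rather than rejected.
* Intermediate level card counts (6, 8, 10) are interpolated from the
  stated endpoints (4 at level one, 12 at level five); only the endpoints
  are documented for the instrument.
* Ages are whole completed years; all groupings and thresholds are
  year-resolved, and simulated ages are drawn at year resolution.

## Known limitations

* Thresholds estimated from a mixed (deficit-containing) cohort are
  slightly inflated relative to a pure typical reference; the pipeline
  follows the development protocol, which normed on an unscreened school
  population.
* The TBCT/SLCT response models are stand-ins with the right monotone
  behaviour (omissions and net scores worsen with severity and improve
  with age), not fitted psychometric models.
* Wald intervals are known to undercover at small n; they are used for
  fidelity with the validation study's reporting, not as the
  recommendation of this package.
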