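---
title: "Virtual evaluation of clinical decision algorithms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual evaluation of clinical decision algorithms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(algopath)
```

## The problem

Clinical algorithms — flowchart guidelines of serial, dichotomous steps —
are widely used to standardise diagnostic work-up, especially where
first-line care is delivered by non-specialists. Competing guidelines for
the same complaint typically differ in which diagnoses they can reach, in
what order they sequence investigations, and in how complex they are to
follow. `algopath` makes those differences measurable before any
prospective trial: it encodes flowcharts in a declarative document format,
"dry-runs" a patient cohort through each of them, and scores every chart
for fit, sensitivity, theoretical delay to management, harm-weighted error
burden, structural complexity (CASA) and pairwise similarity (CAPA).

The motivating application is the tertiary-level management of chronic
cough in hospitalised, HIV-positive adults in a low-income setting, where
the differential spans a dozen treatable diagnoses dominated by
tuberculosis and pneumocystosis. The packaged fixtures carry that study
world: a 201-patient disease spectrum, three competing flowchart
reconstructions, per-diagnosis serial delays and clinician-elicited harm
weights.

## The flowchart model

A `clinical_algorithm` is a directed graph of typed boxes:

* a single **clinical state** entry box;
* **decision** boxes carrying a three-valued predicate over a patient's
  findings (`TRUE`, `FALSE`, or unknown);
* **diagnostic action** boxes, the only boxes that assign a diagnosis;
* **other action** boxes (tests, referrals, empiric treatment).

Transition is strictly dichotomous out of decision boxes (exactly one
yes- and one no-edge) and serial elsewhere (exactly one next-edge).
Polychotomous questions must be encoded as chained binary decisions; this
keeps traversal and pairwise comparison well defined. **Backward edges**
return the clinician to an earlier box (re-testing, re-imaging); they are
detected from the entry-rooted depth-first ordering, and an explicit
`backward` flag in the document overrides detection so that a chart author
can assert a loop that the drawing marks graphically.

Each box may carry `delay_days`, the serial turnaround consumed when the
box is *entered* — a box re-entered through a loop costs its turnaround
again. Delays therefore live on nodes, not edges, matching how
per-investigation serial accounting is done.

## Virtual application

`traverse()` routes one patient through one chart: start at the entry,
answer each decision from the findings map, accrue each box's delay,
stop at a terminal action box. All failure modes are *statuses*, not
errors:

* `NO_FIT_MISSING_FINDING` — a decision queried an unknown finding.
  Unknowns never default to a branch: "fit" is a substantive outcome and
  its complement must be well defined.
* `NO_FIT_LOOP_LIMIT` — the traversal took more backward edges than the
  allowance (default 3, configurable). Clinical loops are bounded in
  practice but no bound is published; three re-tries is a conservative
  ward-level choice and guarantees termination within
  `|nodes| * (max_loop_iterations + 1)` steps.
* `NO_FIT_DEAD_END` — defensive only; a validated chart cannot produce it.

A patient **fits** when a terminal box is reached. Fitting at a
*non-diagnostic* terminal (e.g. "refer to clinician judgement") is a fit
without a diagnosis — an important case, because published fit counts can
exceed published true-positive plus misroute counts only if such
terminals exist.

## Scoring

The accounting rule is deliberately asymmetric. For each *case* (a
patient with two diagnoses expands into two cases):

* reaching the true diagnosis is a **true positive**;
* reaching a different diagnosis is a **false negative** for the true
  condition *and* a **false positive** for the wrongly assigned one;
* not fitting, or fitting without a diagnosis, is a false negative only.

True negatives are derived by conservation (`tn = N - tp - fp - fn`), so
every per-diagnosis row sums to the case total. Sentinel cases (no final
diagnosis, rare diagnosis) are excluded from the restricted analysis; in
the inclusive analysis they enlarge only the denominator:

* restricted sensitivity `= 100 * sum(tp) / (sum(tp) + sum(fn))`;
* inclusive sensitivity `= 100 * sum(tp) / n_enrolled`.

**Harm** multiplies each diagnosis's false positives by its commission
weight and its false negatives by its omission weight (both 0–10,
clinician-elicited relative to natural death) and sums; the total splits
exactly into a commission and an omission component. **Mean delay** is
reported case-weighted (`sum(delay_d * n_d) / sum(n_d)`); the unweighted
mean over diagnoses is also emitted, because the two can differ
materially and published averages do not always state their weighting.

Reporting rounds percentages to 1 decimal and days/harm to 2; all
internal comparisons are done unrounded.

## Nosology

`casa_score()` computes the content-independent complexity
`2 * n1Dx + 1 * n2D0 + sum(Lp)`, where `n1Dx` counts diagnostic boxes,
`n2D0` all other boxes, and each backward edge contributes a loop
parameter. The source methodology does not pin down the loop valuation,
so it is a pluggable rule: `"unit"` (1 per loop, the default — the most
conservative reading) or `"enclosed"` (the number of boxes the loop spans
in the canonical depth-first order). Neither is asserted as ground truth.

`capa_compare()` abstracts each patient's management under two charts to
the pair (ordered test sequence, terminal decision) and scores:
identical (10), similar (8: same tests and decision, different order),
different (0: different decision — or different steps; the published
scale leaves the same-decision/different-steps cell undefined, and we
score it 0 as "not the same steps"). Cases that do not fit both charts
are excluded from the distribution and reported as a count. The aggregate
is the modal category score, ties broken toward the lower score; the full
distribution is always available alongside.

## The synthetic cohort generator

Patient-level study data were never published, so the generator stands in
for them. Its stated world, fixed as defaults:

* prevalence proportional to the printed per-diagnosis counts over 201
  enrolled patients (the counts sum to 202 because one patient carried
  two diagnoses; the default vector is normalised over that total);
* sex 119/201 female; the printed six-band age distribution, ages uniform
  within bands and all > 15 (the study's inclusion bound);
* one second diagnosis per 183 patients (`multi_dx_rate = 1/183`);
* a 39% marginal death rate, sampled into `outcome` but driving no score;
* `noise_rate` 0.05 by default — no noise level is published; 5% is a
  plausible per-finding error/missingness rate for retrospective chart
  data, and the acceptance properties that depend on noise sweep it
  explicitly rather than trusting the default.

Findings are conditionally independent given the diagnosis. Per-diagnosis
archetypes come from `calibrate_profiles()`, which back-propagates the
path constraints from the entry to each diagnostic box and solves the
conjunction per finding (flags, pinned/excluded categories, numeric
intervals); a contradictory path is reported as an error. Noise then
corrupts each finding independently: with probability `noise_rate/2` it
becomes unknown (producing no-fits) and with `noise_rate/2` it is
replaced by a wrong value drawn from the other archetypes (producing
misroutes) — the two failure modes observed downstream.

What a green synthetic test does establish: the routing, accounting and
scoring machinery is exact (noise-free calibrated cohorts score 100%
sensitivity and zero harm, and sensitivity degrades monotonically in
noise on average). What it does not establish: anything about the *real*
per-diagnosis finding frequencies or finding–finding correlations, which
are not identifiable from the published tables. Consequently the
generator cannot — and is not used to — reproduce the published
per-algorithm error pattern; that replication runs directly off the
printed count tables.

## Replication of the published metrics

`replicate_study()` recomputes, from the packaged tables alone: the three
restricted sensitivities (95.7 / 88.0 / 70.1%), the inclusive sensitivity
of the simplest chart (64.2%), its fit count (171), the harm splits and
totals (27/63; 64/176 with total 240; 487.5), the mean commission weight
(4.5) and the case-weighted mean serial delay of the locally tailored
chart (1.86 days). All thirteen reproduce exactly at printed precision.

Two published numbers are knowingly *not* targeted:

* the locally tailored chart's total harm is printed as 91, but its own
  printed split is 27 + 63 = 90; the package reports the computed sum;
* the second chart's printed mean delay 3.46 is not exactly reproduced by
  either weighting of the printed per-diagnosis delays (case-weighted
  ≈ 3.48, unweighted ≈ 3.67); the averaging rule used by the authors is
  unclear, so only the first chart's delay (which the case-weighted rule
  reproduces exactly) is asserted.

## Fixture provenance and limitations

The flowchart encodings (`*_synthetic.json`) and the patient-level cohort
(`table1_cohort_synthetic.csv`) are best-effort synthetic
reconstructions: the published figures are not machine-readable and the
raw data were not deposited. Their marginals are study-shaped, but
box-level content is the package's own; in particular the published CASA
scores (80/73/40) and the cross-chart CAPA of 0 depend on box-level
content and are therefore *reported* for the reconstructions but never
asserted. The same applies to the clinician-concordance split
(61%/38%/1%): the per-patient observed-management data behind it were not
published, so `concordance()` is implemented and tested on constructed
examples only.

Scope semantics deserve one note: each algorithm's default denominator is
restricted to the diagnoses it can itself reach, but
`evaluate_algorithm(covered = ...)` accepts a wider study-level scope, in
which cases the chart cannot diagnose count as false negatives — this is
the accounting under which the published tables were built.

## Worked example

```{r example}
chuk <- study_algorithm("chuk")
profiles <- calibrate_profiles(chuk)
cohort <- generate_cohort(cohort_spec(n_patients = 201,
                                      finding_profiles = profiles,
                                      noise_rate = 0.05, seed = 1))
evaluate_algorithm(chuk, cohort, weights = study_harm())
replicate_study()
```
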