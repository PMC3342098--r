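# algopath

Virtual evaluation of clinical decision algorithms: encode flowchart
guidelines, dry-run patient cohorts through them, and score each chart
for accuracy, delay, harm, complexity and mutual similarity — before
anyone risks using it on real patients.

## The problem

Serial, dichotomous flowcharts are the standard form of clinical
guideline in settings where first-line care is task-shifted to
non-specialists. Several competing charts usually exist for the same
complaint (here: chronic cough in hospitalised HIV-positive adults, where
the differential spans tuberculosis in five forms, pneumocystosis,
bacterial pneumonias, Kaposi's sarcoma and more). Choosing between charts
is an empirical question that can be answered retrospectively: route a
cohort of diagnosed patients through each chart and measure what each one
would have done.

## What is computed

For an algorithm applied to `N` cases (a patient with two diagnoses
contributes two cases), with per-diagnosis counters:

* **fit** — cases reaching any terminal action box; non-fit cases stall
  on an unknown finding or exceed the loop allowance.
* **confusion accounting** — reaching the true diagnosis: `TP`; reaching
  a different one: `FN` for the true condition *and* `FP` for the wrong
  one; no fit (or fit without a diagnosis): `FN` only.
  `TN = N − TP − FP − FN` by conservation.
* **sensitivity** — restricted: `100·ΣTP/(ΣTP+ΣFN)`; inclusive:
  `100·ΣTP/n_enrolled` (undiagnosed and rare-diagnosis patients enlarge
  the denominator only).
* **serial delay** — each box consumes its turnaround when entered
  (again on re-entry through a loop); cohort summary is the case-weighted
  mean `Σ(delay_d·n_d)/Σn_d`.
* **harm** — `ΣFP_d·w_commission,d + ΣFN_d·w_omission,d` with 0–10
  clinician-elicited weights; reported as commission + omission = total.
* **CASA complexity** — `2·n1Dx + 1·n2D0 + Σ(Lp)` over diagnostic boxes,
  all other boxes, and loop parameters (rule pluggable: 1 per loop, or
  the loop's box span).
* **CAPA similarity** — per patient, two charts' managements abstracted
  to (ordered test list, terminal decision) and scored identical (10) /
  similar (8) / different (0).

A synthetic-cohort generator (`cohort_spec()`, `generate_cohort()`,
`calibrate_profiles()`) reproduces the study's disease spectrum and
derives, for any chart, noise-free finding archetypes that traverse to
each diagnosis — so the whole pipeline is testable end to end without
patient data.

## Worked example

```r
library(algopath)
chuk <- study_algorithm("chuk")              # packaged reconstruction
profiles <- calibrate_profiles(chuk)         # per-diagnosis archetypes
cohort <- generate_cohort(cohort_spec(n_patients = 201,
                                      finding_profiles = profiles,
                                      noise_rate = 0.05, seed = 1))
evaluate_algorithm(chuk, cohort, weights = study_harm())
#> Evaluation of algorithm 'chuk'
#>   cases: 186 in scope (19 excluded) of 201 enrolled patients
#>   fit: 174 (93.5%)
#>   sensitivity: 86.0% restricted, 79.6% inclusive
#>   mean serial delay: 2.34 days (case-weighted), 1.95 (unweighted)
#>   harm: 64.50 commission + 205.00 omission = 269.50
casa_score(chuk)
#> CASA complexity of 'chuk': 45  (2x12 diagnostic + 19 other + 2 loop, rule=unit)
```

Reading: of 201 generated patients, 19 are out of scope (no diagnosis or
a rare one); at a 5% per-finding noise rate, 174 of the 186 in-scope
cases still fit a pathway and 86% reach their true diagnosis; errors cost
269.5 harm points, dominated by omissions. At zero noise the same
pipeline scores 100% sensitivity and zero harm — the calibration
property the test suite asserts.

`replicate_study()` runs the replication path instead: it recomputes all
thirteen headline metrics (three restricted sensitivities, the inclusive
sensitivity and fit count of the simplest chart, six harm components,
the mean commission weight, and the case-weighted mean delay) directly
from the packaged count/delay/weight tables and checks each at printed
precision.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the replication path and, with the given seed, a full synthetic
end-to-end comparison of the three packaged charts (evaluation + CASA +
pairwise CAPA), then writes the results file.

## Package layout

* `R/flowchart.R` — flowchart model, validation, JSON document I/O, census
* `R/cohort.R` — patient/cohort model, case expansion, harm weights
* `R/synthetic.R` — cohort generator and archetype calibration
* `R/engine.R` — traversal engine and serial-delay accounting
* `R/evaluation.R` — confusion/sensitivity/delay/harm/concordance scoring
* `R/nosology.R` — CASA and CAPA
* `R/fixtures.R`, `R/replicate.R` — packaged study tables, replication and
  comparison workflows
* `inst/extdata/` — plain-text fixtures; files suffixed `_synthetic` are
  best-effort reconstructions, not transcriptions
* `vignettes/algorithm-evaluation.Rmd` — methods, assumptions, design
  choices and known limitations
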