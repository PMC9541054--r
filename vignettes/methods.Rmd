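---
title: "Adapting and validating a SNOMED CT coding algorithm for the Charlson comorbidity index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adapting and validating a SNOMED CT coding algorithm for the Charlson comorbidity index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The Charlson comorbidity index (CCI) summarizes a patient's disease burden
as a weighted count over 17 comorbid conditions and is the most widely used
comorbid risk score for predicting one-year mortality among hospitalized
patients. In administrative claims research the conditions are detected from
diagnosis codes, classically via the Quan enhanced ICD-9-CM and ICD-10 code
lists. Databases standardized to the OMOP common data model, however, record
standard concepts in SNOMED CT, so an ICD-based algorithm cannot be applied
to standard codes directly. `snomedcci` implements the machinery for
adapting the ICD code lists to SNOMED CT through the vocabulary's "maps to"
relationships, auditing what the translation gains and loses, and validating
that the adapted algorithm identifies the same patients and predicts
mortality equally well.

## The adaptation procedure

Given a vocabulary snapshot (concept, concept-relationship and
concept-ancestor tables) and an ICD codeset per condition, `adapt_codeset()`
performs three steps:

1. **Forward translation.** Every ICD code is mapped to its SNOMED standard
   concept(s) via "maps to" edges. A source code with several edges
   contributes all targets; no "best map" is selected, because the
   diagnostics below must count every mapping path.
2. **Back-translation and diff.** The SNOMED set is mapped back to all ICD
   codes whose standard target lies in it (by default after descendant
   expansion, the usual OMOP codeset-expansion convention). The union of the
   original and back-translated codesets is partitioned into *both*,
   *SNOMED-only* and *ICD-only* codes; a code captured by exactly one side
   is *discrepant*.
3. **Expert curation.** Clinical relevance is never inferred by the
   toolkit. An adjudication file (read with `read_adjudication()`) can
   label multiple-to-one discrepancies as *information gain* or *added
   noise*, and can exclude an over-broad SNOMED concept outright.
   Unadjudicated multiple-to-one records stay `pending`.

Every discrepant code receives exactly one diagnostic category, and the
three categories are exhaustive for discrepant codes:

* `multiple_icd_to_one_snomed` — a SNOMED-only code, pulled in because its
  standard target is shared with an in-set code (e.g. codes for persistent
  migraine aura with cerebral infarction entering a cerebrovascular-disease
  set through the shared cerebral-infarction concept);
* `deprecated_unmapped` — an ICD-only code with no "maps to" edge in the
  snapshot (deprecated codes);
* `specificity` — an ICD-only code lost because its every standard target
  was excluded for back-mapping too broadly (e.g. a hypertensive heart and
  chronic kidney disease *with heart failure* code whose only target also
  captures the *without heart failure* form).

`diagnostics_report()` turns the ledger into per-condition overlap and
category tables with row and grand totals. Percentages are half-up rounded
to one decimal, matching the convention of published audit tables; full
precision is retained internally. The package bundles the per-condition
counts of a published audit of a Quan-to-SNOMED crosswalk built on the July
2021 SNOMED CT International Edition (`reference_audit_counts()`) purely as
report-arithmetic input; those counts are vocabulary-version dependent and
are not a target the toolkit regenerates.

## Scoring

`detect_conditions()` flags a condition when at least one diagnosis dated at
or within 365 days prior to the index date — a window closed on both ends —
matches the condition's codeset in the vocabulary the algorithm reads. Day
arithmetic is in whole days. Codes are compared after uppercasing and
stripping dots, so `I13.2` and `i132` are the same code; the bundled Quan
lists (`quan_codesets()`) are printed as prefixes and matched with
`match = "prefix"`, while exact matching is the default for explicit
codesets. The SNOMED algorithm matches standard-concept records, optionally
expanding each codeset concept to its hierarchy descendants via the store.

Weights follow the familiar claims convention: 1 for the first ten
conditions, 2 for diabetes with chronic complications,
hemiplegia/paraplegia, renal disease and malignancy, 3 for moderate or
severe liver disease, 6 for metastatic solid tumor and AIDS/HIV. The
severity hierarchy (diabetes without → with complications, mild → moderate
or severe liver disease, malignancy → metastatic solid tumor) is applied to
the score by default, giving a maximum of 29 (33 without). Because some
published cohort tables report both severities of a pair at high prevalence,
flag reporting and hierarchy application are configurable independently:
`score_cohort()` always reports raw flags and applies the hierarchy only to
the score, and `apply_hierarchy = FALSE` disables it entirely.

## Cohorts and validation statistics

`build_cohort()` indexes each patient at their earliest inpatient visit of
the calendar year (same-day ties broken by lowest visit id), requires age 18
or older at index (age is `calendar_year − year_of_birth`, as claims carry
year of birth only) and 365 days of *continuous* prior observation, read
strictly: a single observation period must span `[index − 365, index]`;
gaps disqualify. Exclusions are tallied per filter so that input persons
equal eligible plus exclusions. One-year mortality is a death within
`[index, index + 365]`, both ends inclusive; a death recorded before index
is treated as a data anomaly and the person excluded with a reported count.

Two algorithms are compared on:

* **Balance.** Classical two-group standardized mean differences —
  `|p_a − p_b| / sqrt((p_a(1−p_a) + p_b(1−p_b))/2)` for binary covariates,
  the pooled-SD analogue for continuous ones — with SMD < 0.10 read as
  balanced. The two arms share patients, but the classical two-group form
  is reported deliberately, faithful to how such validations are published.
* **Patient overlap.** Per condition, the exact 2×2 partition of patients
  flagged by both, neither, or only one algorithm.
* **Discrimination.** A univariable logistic model of one-year mortality on
  the CCI, fitted by IRLS (tolerance 1e−8, at most 25 iterations; a
  constant predictor yields the stationary slope 0). The c statistic is the
  rank-sum concordance — exactly the all-pairs probability with ties at one
  half — computed from fitted probabilities; by monotonicity of the link it
  equals the concordance of the raw scores, so the percentile bootstrap CI
  (2,000 resamples by default, seeded, global RNG state restored) resamples
  patients and recomputes the rank-based c without refitting.

## What the generators emulate — and what they do not

`gen_vocabulary()` engineers a miniature vocabulary in which every
discrepancy category occurs a configurable number of times per condition,
each instance labeled, and plants replicas of the three worked audit cases
(the specificity trap, the information-gain fan-out, and the
diabetic-kidney fan-out that drags in secondary and drug-induced diabetes
as noise). The crosswalk classifier is required by test to recover 100% of
these labels.

`gen_claims()` plants condition flags directly from per-condition
prevalences (flags → codes, not a disease model, so ground truth is exact),
realizes every planted condition as at least one in-window condition
occurrence, and draws deaths from `plogis(intercept + slope × true CCI)`
placed uniformly in the follow-up year. Discordance between algorithms is
injected by code choice: a SNOMED-only plant uses a fan-out extra code the
ICD list lacks, a Quan-only plant uses a deprecated or specificity-lost
code. Default prevalences follow the pattern of a large Medicaid inpatient
population (about a quarter of patients with heart failure, vascular and
cerebrovascular disease, half with chronic pulmonary disease, rare severe
liver disease and HIV), which puts the mean CCI near 3.7; the mortality
model defaults to intercept −3 and slope 0.25. A configurable fraction of
patients receives too short an observation period (default 10%) or an
under-18 age (default 2%) so the attrition logic is exercised.

The generators do **not** model disease co-occurrence, coding intensity,
visit structure beyond one inpatient visit, or incomplete death capture.
Passing tests therefore demonstrate correctness of the machinery — set
algebra, classification, windowing, scoring, statistics — under known
ground truth, not performance characteristics of any real database.

## Numerical and design choices

* Determinism: generators and the orchestrated pipeline derive all
  randomness from one seed; identical specs give byte-identical outputs,
  and ledgers serialize sorted by (condition, side, code).
* Descendant expansion defaults **on** for back-translation and SNOMED
  detection, as in OMOP codeset expansion; it is a flag because published
  codesets may be either leaf lists or ancestor lists.
* A specificity classification requires that *every* target of the lost
  code was excluded; a retained target with the code still ICD-only is an
  integrity error, not a category.
* Zero-spread SMD comparisons return 0 when means agree and `Inf` as a
  sentinel otherwise.
* Problem sizes in the shipped tests and acceptance script — 100 seeded
  vocabularies, 1,000 round-trip cases, 500-patient scoring cohorts, and
  20,000-patient model-recovery cohorts — were chosen as the smallest sizes
  at which the respective checks are sharp (binomial error on a 0.25 slope
  at n = 20,000 is about 0.01, well inside the ±0.03 recovery band).

## Known limitations

Only the "maps to" relationship is consumed; no other relationship types,
no SQL connectivity, and no redistribution of SNOMED CT or UMLS content.
The toolkit consumes whatever vocabulary snapshot the user supplies, and
crosswalk results are snapshot-dependent by design. Clinical adjudication
is an input file, never automated. No Elixhauser or age-adjusted CCI
variants are provided.
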