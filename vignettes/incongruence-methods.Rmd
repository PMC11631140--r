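---
title: "Sex-incongruence rates as an EHR data-quality metric: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-incongruence rates as an EHR data-quality metric: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexcheck)
library(dplyr)
```

## The measurement problem

Electronic health record (EHR) extracts accumulate logging, curation and
extraction errors that are hard to audit directly. Conditions that are
anatomically exclusive to one sex offer a rare opportunity for an automatic
plausibility check: a prostate-cancer record attached to a person whose sex
at birth is female is either a logging error or a genuinely unusual record
worth review, and a survey- plus genomics-backed sex attribute gives an
independent reference to check against. `sexcheck` turns this idea into a
pipeline: screen a condition-occurrence table for prevalently sex-specific
conditions, compute incongruence rates with confidence intervals, and
profile the affected persons to separate systematic curation problems from
isolated ones.

The package works on an "OMOP-lite" extract: `person` (sex at birth, gender
identity), `condition_occurrence` (person, concept, start date), `concept`
(id to name), and optional `genomic_sex` and `zip3` tables. All analysis
functions count *distinct participants*, never raw records, except where a
record-level view is the point (the temporal profile).

## Cohort selection

Two filters define the primary cohort. First, sex at birth must be binary
(female/male) — the incongruence definition needs a reference sex. Second,
under the default `cisgender_only` policy, the gender identity must conform
to sex at birth (woman with female, man with male); every other answer,
including skips and declines, is excluded. The rationale is ambiguity
control: gender-affirming care can produce clinically true cross-sex
condition records, which would be indistinguishable from logging errors.
The cost is that genuine logging errors in the excluded group go unexamined;
the `include_all_binary_sex` policy re-admits them for the sensitivity
analysis. Finally the cohort is restricted to persons with at least one
condition record, since persons without EHR data cannot contribute to any
denominator.

## Screening sex-specific conditions

The screen is deliberately data-driven rather than ontology-driven, so it
transfers to any vocabulary. For each condition we count distinct female and
male carriers and apply, in order:

1. **Support filter** — at least 20 distinct participants (exactly 20 is
   kept). Below this, the sex split is too noisy to interpret.
2. **Bias filter** — the majority-sex fraction must *strictly* exceed 0.95,
   mirroring the conventional 5% significance level. A condition carried by
   950 of 1000 females is rejected; 0.95 is not greater than 0.95. Ties
   (equal counts) have no majority sex and can never pass.
3. **Name exclusions** — case-insensitive substrings, by default `breast`
   and `mammary`: breast findings are strongly female-biased yet occur in
   males, so a bias threshold alone misclassifies them.
4. **Prevalence cut** — at least 1000 distinct participants (exactly 1000 is
   kept). Low-count conditions produce wildly unstable per-condition rates;
   `plot_cir()` makes this visible.
5. **Manual exclusions** — a concept-id list for conditions that clinical
   review rejects as not truly exclusive (for example hirsutism-like
   sex-*biased* conditions).

The bias filter runs before the name exclusions; both stage counts are
logged (`screen_stages()`), so either ordering is auditable. Raising any
threshold can only shrink the selected set — the test suite checks this
monotonicity over a threshold grid.

## Incongruence rates

For one screened condition with specific sex $s$, let $N_{inc}$ be the
distinct carriers whose sex at birth differs from $s$ and $N_{con}$ those
whose sex matches. The condition-specific incongruence rate is

$$\mathrm{CIR} = \frac{N_{inc}}{N_{inc} + N_{con}}.$$

Per-condition rates are heterogeneous and their intervals often span zero,
so the primary metric treats the screened set collectively: the overall
incongruence rate (OIR) counts each person once per sex-specific subset,
however many listed conditions they carry. The combined OIR sums the
female-specific and male-specific counts — a person carrying conditions of
both specificities contributes to both components. This summation convention
is what makes the combined counts exactly the sums of the per-sex rows in
published reports.

Intervals are Wald: $p \pm z\sqrt{p(1-p)/n}$ with $z = 1.96$ by default.
Two conventions for $n$ coexist in published tables, and the package
supports both explicitly rather than silently choosing: `ci_n_mode =
"total"` (the formula's natural sample size, used for all collective rates)
and `ci_n_mode = "incongruent"` ($n$ equal to the incongruent count, the
only convention under which certain published per-condition intervals are
reproducible). Every rate row records which convention produced its
interval. Bounds are *not* clamped to $[0,1]$ by default: a negative lower
bound is informative about how weak a small-count rate is, and clamping
would hide it. A `clamp` flag exists for presentation.

Wald intervals are known to undercover for small $np$; at the scales the
collective rates operate ($p \approx 0.01$, $n \gtrsim 10^4$) coverage is
close to nominal (the suite checks 93–97% empirical coverage at $p = 0.01$,
$n = 10^4$). Alternative intervals (Wilson, Clopper–Pearson) are out of
scope.

For public reporting, `mask_small_counts()` replaces every count strictly
below 20 with `"<20"` and masks the derived rates of affected rows, matching
small-cell suppression policies of controlled-access programs; exactly 20 is
never masked.

## Profiling incongruent persons

`flag_incongruent_persons()` returns each person carrying at least one
cross-sex screened condition, with the distinct offending concepts. The
profile operations then ask *why*:

- **Genomic concordance** — if survey sex were unreliable, incongruence
  would be a survey problem, not an EHR problem. The check counts flagged
  persons whose genomic-inferred sex is retrievable and matches their survey
  sex. A missing genomic table is an explicit error, never a silent skip.
- **Concurrence** — the fraction of flagged persons who *also* carry
  conditions congruent to their own sex. High concurrence indicates a mix of
  accurate and erroneous records within one chart — the signature of
  record-level misassignment rather than a wholesale sex swap. "Congruent
  condition" means membership in the screened list, not any EHR condition,
  so both classes are measured with the same instrument.
- **Multiplicity** — per sex and congruence class, the fraction of persons
  with more than one distinct condition of that class.
- **Geography** — per zip3 (first three zip digits), the fraction of the
  profiled population versus the fraction of flagged persons. Pearson
  correlation between the two fraction columns summarises whether
  incongruence mirrors population size (systemic) or concentrates in
  particular regions (site-specific); the choice of Pearson on fractions
  matches the quantities actually plotted. Population-size quantiles are
  reported separately for zip3s with and without flagged persons, since
  small zip3s can lack flagged persons purely through sample size.
- **Temporal** — record counts by condition start year, split by sex
  specificity and congruence class. Similar shapes across classes indicate
  errors spread over the whole period. Records, not persons, are counted
  here because a person contributes every dated record.
- **Sensitivity** — recompute the combined OIR under
  `include_all_binary_sex` and tabulate gender-identity composition among
  all binary-sex persons versus flagged persons (skips and declines are
  dropped from the composition table, as they carry no identity
  information). Enrichment of gender-crossing identities among flagged
  persons quantifies how much the cisgender-only restriction protects the
  metric.

## The synthetic cohort generator

Real controlled-tier EHR extracts cannot be redistributed, so the package
ships a generator whose output has the statistical structure the analysis
assumes, making every pipeline stage and the parameter-recovery tests
runnable from scratch.

For each person: sex at birth is Bernoulli(`female_fraction` = 0.5); gender
identity is drawn per sex from a categorical distribution whose default puts
96.1% on the sex-conforming category, 1.1% on gender-crossing categories
(opposite gender plus transgender) and the rest on nonbinary/other/skip/
decline — proportions chosen to match the composition a large US research
cohort reports. Each catalogue condition is carried by members of its target
sex with the configured prevalence; the default catalogue mixes prevalent
and rare female- and male-specific conditions with sex-neutral ones, with
prevalences calibrated to the per-sex carrier fractions of the corresponding
real conditions (e.g. pregnancy-related findings ~15% of females,
prostate cancer ~6% of males). A carrier receives $1 + \mathrm{Poisson}(m-1)$
records ($m$ = `records_per_carrier`, default 2), dated uniformly over
`year_range` (default 2000–2022). Each person with any record gets a zip3
drawn from `zip3_weights` (default: 40 codes with Zipf-like weights, so a
few populous areas dominate, as in real geography). Genomic sex equals sex
at birth except with probability `genomic_mismatch_rate` (default 0: survey
and genomic sex agree in practice).

**The error model is record-level misassignment**: each sex-specific
condition record independently lands on a uniformly chosen person of the
opposite sex with probability `error_rate`. This choice, rather than
flipping a person's recorded sex, is deliberate: flagged persons then retain
their own congruent records — reproducing the observed concurrence signature
— and flagged persons are spread across geography in proportion to
population. A `person_swap` mode exists for contrast experiments; under it,
the cisgender filter removes most swapped persons (their gender no longer
conforms), which is itself an instructive property. The
`noncis_cross_rate` knob (default 0) lets gender-crossing persons carry
opposite-sex conditions as *true* diagnoses, to study how re-admitting
non-cisgender participants inflates the sensitivity OIR.

The generator does **not** emulate: disease co-occurrence structure, age
(the method is for adult cohorts), visit-level longitudinal structure, or
vocabulary hierarchies. Passing tests on synthetic cohorts therefore
validate the *counting and inference machinery* under a known error process,
not the clinical validity of any screened list on real data.

## The closed-form expected OIR

`expected_oir()` gives the analytic expectation of the pipeline's combined
OIR under record misassignment, used as the recovery target. With $e$ the
error rate, $\lambda = m - 1$, per-condition prevalence $q$, carrier-sex
size $N$ and receiving-sex size $M$:

- a carrier's record count is $R = 1 + \mathrm{Poisson}(\lambda)$, so the
  carrier loses *all* records with probability
  $E[e^R] = e\,\exp(-\lambda(1-e))$, and retains at least one otherwise;
- one carrier's records all miss a fixed opposite-sex person with
  probability $a = E[(1-e/M)^R] = (1-e/M)\exp(-\lambda e/M)$, so that
  person receives at least one record of the condition with probability
  $1 - (1 - q(1-a))^{N}$.

Independence across conditions gives the expected incongruent and congruent
person counts per sex-specific subset; each is scaled by the cisgender
fraction of its sex (misassignment targets all opposite-sex persons, but
only cisgender ones remain in the cohort, and with symmetric cisgender
fractions the ratio is nearly unaffected). The combined OIR is the ratio of
summed expected counts — an expected-count approximation to the expectation
of a ratio, accurate to $O(1/N)$ at the cohort sizes used. Two checks back
the derivation: the mean of 200 simulated OIRs at $n = 5000$ falls within
three standard errors of the formula, and across 100 seeded 50 000-person
cohorts the pipeline's 95% Wald interval covers the formula's value 94
times with a mean relative error below 1%.

## Numerical and design decisions

- **Strict versus inclusive thresholds** are fixed as: keep exactly 20
  (support), reject exactly 0.95 (bias, strict), keep exactly 1000
  (prevalence). The boundary tests pin these.
- **Duplicate `person_id` rows are an error** at load. Survey curation
  conflicts have no principled automatic resolution, and silently keeping
  one row would change counts.
- **Duplicate person–condition records are retained** at load;
  deduplication happens inside each counting operation, because the unit of
  analysis is the participant.
- **Unknown enum spellings**: common survey literals (`"Male"`, `"Woman"`,
  `"Skip"`, `"PreferNotToAnswer"`) are normalised case-insensitively; truly
  unknown values are fatal under `strict`, otherwise mapped to
  `other_or_unknown`/`other` with a warning — loading never silently changes
  counts.
- **Empty denominators are errors**, never silent zeros: a rate over zero
  persons is undefined, and returning 0 would fake perfect quality.
- **Determinism**: the generator seeds a local RNG stream and restores the
  caller's state, so identical configs give bit-identical datasets and
  pipeline bundles (manifest hashes are compared in the tests).

## Problem sizes in the test suite

The suite exercises brute-force oracle equivalence on 20 seeded cohorts of
400 persons (where exhaustive recounting is instant), Monte-Carlo validation
of the closed form at 5000 persons with 200 replicates, and parameter
recovery at 50 000 persons with 100 replicates — sizes chosen so the
statistical assertions have narrow sampling bands while the whole suite runs
in about a minute.

## Limitations

The method applies to adult cohorts; paediatric sex-specific conditions
follow different dynamics. It measures only errors visible through
sex-exclusive conditions: a random record-misassignment error is detectable
only when it crosses sexes (roughly half of misassignments of sex-specific
records) and only through the screened conditions, so measured OIRs are a
lower bound on the underlying record-error rate. The screened list itself is
data-driven and dataset-specific: transferring it to another vocabulary or
population requires re-screening. Finally, the generator's uniform
misassignment is the simplest null; real curation errors may cluster by
site or pipeline in ways the geographic and temporal profiles are designed
to reveal, not to simulate.
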