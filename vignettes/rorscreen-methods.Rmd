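---
title: "Disproportionality screening of spontaneous report databases with rorscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening of spontaneous report databases with rorscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rorscreen)
```

## The problem

Spontaneous adverse-event reporting databases — JADER in Japan, FAERS in the
US — collect case reports in which clinicians or manufacturers link one or
more drugs to one or more adverse events. They are passive surveillance
instruments: there is no denominator of drug users, so absolute risks cannot
be estimated. What can be estimated is *disproportionality*: whether a given
adverse event is reported relatively more often with a given drug than with
everything else in the database. rorscreen implements that analysis as a
reusable pipeline, from the raw three-table database layout to a covariate-
adjusted logistic model, and ships a synthetic database generator so every
stage can be exercised and calibrated without access to a real download.

The motivating application is drug-induced hiccups: a rare event (on the
order of 160 event records in a table of nearly one million suspected-
medicine records), strongly male-skewed, and concentrated in chemotherapy
regimens — which is why the stratified analyses single out dexamethasone,
its administration routes, and anti-cancer co-treatment.

## Data model and table construction

A database is three tables joined by a case identifier:

* demographics — one row per case: sex, age as a decade code ("50s"),
  height and weight as 10-unit range codes ("160-169"), report year;
* drug — one row per (case, drug): generic name, reporter-assigned
  involvement (*suspected*, *concomitant*, or *interaction*), optional
  administration route;
* reaction — one row per (case, adverse-event term).

Construction follows the standard flow: remove duplicated drug and reaction
rows, inner-join the three tables on the case identifier (each case
contributes one record per drug x event pair — the "all data table"), then
keep rows whose involvement is *suspected* (the "suspected medicine
table"), which is the primary screening population. Two conventions are
deliberate and configurable:

* **a duplicate is a row identical on all fields of its table** — the most
  conservative reading of "duplicated data"; a key subset can be supplied
  when a looser definition is wanted;
* **drug and reaction rows whose case has no demographics row are dropped
  with a logged count** — the strict inner-join reading; an error policy is
  available.

Name matching is exact after whitespace trimming; collapsing
formulation-specific registered names ("dexamethasone sodium phosphate")
onto one generic name is the job of an explicit synonym map, never of fuzzy
matching.

## The screen

For every exposure (each drug; or, in the generalized screens, each event
term against a fixed gender or route stratum) the table is cross-tabulated
into the 2x2 with cells `a` (exposed, event), `b` (exposed, other events),
`c` (unexposed, event), `d` (unexposed, other events). Three quantities are
computed per exposure:

* the reporting odds ratio `ROR = ad/bc`, undefined when `b = 0` or
  `c = 0` (an optional Haldane–Anscombe +0.5 correction keeps it defined);
* the Woolf (log-normal) interval
  `exp(ln ROR ± z·sqrt(1/a + 1/b + 1/c + 1/d))` — the standard ROR interval
  in pharmacovigilance. No interval formula is canonical for the ROR; Woolf
  is used because it is what the field's signal-detection literature uses
  and it requires nothing beyond the four cells;
* a two-sided Fisher exact p, by minimum-likelihood summation: the total
  probability, under the hypergeometric distribution fixed by the margins,
  of all tables no more likely than the observed one, within relative
  tolerance `1 + 1e-7` (which protects probability ties against floating-
  point noise). When a margin is zero the observed table is the only
  admissible one and p = 1 falls out of the same rule. The summation is
  authored in-package (vectorized over exposures) because a screen
  evaluates thousands of tables; the test suite checks it against both an
  exhaustive enumeration oracle and `stats::fisher.test` on every 2x2 table
  with total at most 60.

A **signal** is flagged when the lower 95% confidence limit exceeds 1 —
strictly: a limit of exactly 1, or an undefined limit, is not a signal. The
volcano plot places each exposure at `x = ln ROR`, `y = -log10 p`, with the
p = 0.05 baseline at y = 1.301; points are colored blue-to-red by the number
of event reports. Raw p-values are the primary output, matching the
screening convention of this analysis family; a Benjamini–Hochberg column is
available behind a flag and is clearly an extension.

The analysis unit is the *record* by default — the published totals this
package's fixtures replay are record-level counts — with case-level
counting (a case is exposed/an event case when any of its records is)
available everywhere via a `unit` argument. The strict report-count filter
(`n > 3` event reports) is applied before predictor selection so that
one-off reports cannot drive the model.

## Patient background and trend

Sex is compared between event and non-event cases with the same Fisher
test; age, height and weight are decoded from their range codes to numbers
and compared with a two-sided t-test. Two decisions here were genuinely
open:

* **decoding** uses the leading integer (the range's lower bound), reading
  the codes "as absolute numbers"; the midpoint is available as an option
  and shifts every decoded value by a constant, so group *differences* are
  unaffected;
* **the t-test defaults to Welch** (unequal variances). The event and
  non-event groups in this kind of data have materially different spreads
  (the event group is small and homogeneous), which is exactly where the
  pooled test is fragile; the pooled variant remains available since the
  original analyses of record used default statistical-suite settings that
  cannot be recovered.

All comparisons use only non-missing values and report the n actually used.
The reporting-year trend is the Spearman rank correlation between year and
the per-year event fraction (counts available as an option), with average
ranks for ties and a two-sided p from the t approximation; an exact
permutation p is available for small year counts. Constant fractions are a
degenerate all-ties case and return rho = 0, p = 1 by convention.

## The multivariate model

Predictors are the four patient covariates plus every drug that passed the
univariate screen (p < 0.05 and more than 3 event reports). Before fitting,
every pair of explanatory columns is screened for internal correlation with
pairwise-complete Spearman rho; a pair with rho² > 0.9 is flagged and
should not enter together. Constant columns have undefined correlations and
are reported as such rather than silently.

The model itself is a maximum-likelihood logistic regression (IRLS,
relative tolerance 1e-8, at most 100 iterations; non-convergence is an
error, never silent) on one row per complete case: listwise deletion of
cases with any missing covariate, the event indicator set when any of the
case's records reports the event, drug indicators aggregated over the
case's suspected medicines. Case-level rows are the epidemiologically
defensible unit (demographics are case properties); record-level rows are
available via configuration. Inference is Wald — per-term z tests and
intervals on the log-odds scale, exponentiated to odds ratios. Wald
intervals are extremely wide under near-separation (a rare event carried
almost entirely by one covariate level produces intervals spanning two
orders of magnitude), which is accepted behavior here; *complete*
separation, where the estimate diverges, is detected (diverging coefficient
with exploding standard error) and raised as an error naming the term. A
Jeffreys-penalized (Firth) fit, which stays finite under separation, is
available behind `method = "firth"`.

## Stratified analyses

The route analysis forms, for each administration route of the index drug,
the 2x2 of that route's records against **the remainder of the whole
suspected-medicine table** — not against the drug's other routes. This is
the construction under which the published per-route Fisher values are
reproducible from the printed totals, and it is the one implemented.
Records of the drug with a missing route are grouped as "unknown" so the
per-route counts always sum to the drug's totals.

The co-treatment analysis deliberately widens the population to all
involvement categories: restricting to suspected medicines would hide a
co-administered drug recorded as concomitant. Event cases are deduplicated
by case identifier (each patient counted once), classified by (index drug
present?, co-treatment class present?), and summarized as integer
percentages; the co-treatment class (anti-cancer agents) is a configurable
name list because no canonical enumeration exists.

## The synthetic generator

`synthetic_spec()` + `generate_database()` emulate the database's structure
with known ground truth: many cases; one-to-many case-to-drug and
case-to-reaction links; involvement labels; injected exact-copy duplicate
rows; per-field missing demographics; and configurable drug-event
reporting odds. Design choices, and what they imply:

* **the event model is multiplicative on the odds scale**: a case's event
  log-odds are `logit(background rate) + male·ln(male multiplier) + sum of
  ln(drug multiplier)` over its exposures. At low event rates the planted
  multiplier is therefore directly comparable to the marginal ROR the
  screen estimates; this is an approximation (odds ratios are not
  collapsible in general) that degrades as the event rate or covariate
  effects grow;
* **latent-then-mask missingness**: sex and range codes are drawn first,
  used by the event model, and then masked missing-completely-at-random —
  the neutral choice given the pipeline's complete-case analysis;
* **exact-copy duplicates**: a fixed fraction of drug and reaction rows is
  re-emitted verbatim, consistent with the pipeline's duplicate
  definition, and the base rows are constructed collision-free (one
  background medicine per case, second reaction term forced distinct) so
  deduplication provably removes exactly the injected rows;
* **defaults** (50% male, decade/range distributions centered on an
  older-skewed population, ~4%/50%/45% missing age/height/weight, years
  2004–2015, 5% duplicates) are fixed once to resemble the reporting
  population the pipeline targets; the male odds multiplier defaults to 1
  and is raised in demonstration configurations that emulate the male-
  skewed target event.

What the generator does **not** emulate: drug co-prescription correlation
structure, notoriety/competition reporting biases, within-case duplicate
reports under different identifiers. Tests passing on synthetic data
therefore validate the *computational* pipeline and its statistical
calibration, not robustness to the reporting biases of real spontaneous
data.

Calibration checks run at designed sizes chosen to make their Monte-Carlo
error small relative to the asserted bands: interval coverage over 1,000
simulated tables with all expected cells at least 5; planted-multiplier
recovery at 50,000 cases, prevalence 0.05, background rate 0.01,
multipliers 5 and 1, across dozens of seeds. The recovery check uses
suspected-only involvement for the planted drugs and a neutral male
multiplier, decided a priori: involvement misclassification attenuates the
record-level exposure and a strong exposure-independent covariate biases
the marginal ROR away from the conditional multiplier (non-collapsibility),
so either would test the approximation rather than the pipeline.

## Numerical conventions

* Fisher ties: relative tolerance `1 + 1e-7` on the observed table's
  probability, matching the convention of reference implementations.
* Screen ordering: `(p value, -ROR, label)` so ties cannot reorder output
  between runs.
* Undefined RORs/intervals are values (`NA`), not errors, and are excluded
  from volcano plots with a note; an undefined lower limit never flags a
  signal.
* Degenerate t-test (identical constant groups) returns p = 1; degenerate
  Spearman (zero variance) returns rho = 0, p = 1.
* All generation is reproducible: a spec plus a seed yields byte-identical
  tables, and generation restores the caller's RNG state.

## Limitations

Disproportionality is relative reporting, not risk: a signal is a prompt
for pharmacological review, never a causal claim. The ROR ≈ OR reading
requires the event to be rare among both exposed and unexposed reports.
Real published totals from any specific database snapshot are not exactly
reproducible without that snapshot; the package instead replays printed
contingency tables through the full pipeline and verifies the statistical
machinery by construction and calibration.
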