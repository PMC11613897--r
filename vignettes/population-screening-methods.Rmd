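---
title: "Methods: simulating and evaluating population genetic screening for breast cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating population genetic screening for breast cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brcascreen)
```

`brcascreen` studies a question of screening policy: in an unselected
population of women, how well do different combinations of rare-variant
carrier status (BRCA1, BRCA2, PALB2, ATM, CHEK2), a common-variant
polygenic risk score (PRS), and EHR-recorded family history identify the
women who will be diagnosed with breast cancer — and at what cost in false
positives? Because the health-system cohorts in which such analyses are run
are access-restricted, the package is built around a calibrated synthetic
cohort: every downstream stage (variant classification, PRS
normalization, survival modelling, family-history timing, strategy
evaluation) is exercised, tested and reproduced on data whose generative
parameters are known.

This vignette records the model, the parameter choices, the numerical
conventions, and the places where a design decision was genuinely open.

## The synthetic cohort

`simulate_cohort()` draws one woman per row. The components:

**Genetic-similarity group.** Multinomial over six ancestry-like groups
(Africa, Americas, East Asia, Europe, Other, South Asia) with default
proportions 499 / 3,728 / 832 / 19,484 / 929 / 119 out of 25,591 — the
composition of the cohort the defaults emulate. PRS percentiles are always
computed within group, so the group sizes matter for percentile
granularity and for which groups can support case–control discrimination
estimates.

**Current age and EHR span.** Age at simulation time is a two-component
normal mixture, weights 0.68/0.32, means 45/71, SD 12/7, truncated to
[19, 89]. The mixture reproduces a bimodal health-system age structure
with mean ≈ 53 years and ≈ 19% of women aged 70+, which controls how many
women are observable to age 70 (and hence the precision of every
KM-at-70 read-out). EHR length is normal with mean 12 and SD 5 years,
truncated below at 6 months and above at `current_age − 1`.

**Carrier status.** Independent Bernoulli per gene at rate
`expected_count / 25591`, so smaller cohorts keep the same carrier rates.
The default expected counts are BRCA1 = 70, BRCA2 = 89, PALB2 = 39,
ATM = 94, CHEK2 = 118 (total 410). The BRCA1+BRCA2 total of 159 and the
PALB2-inclusive total of 198 are constrained by the published group-level
counts the defaults emulate; the split of the remaining 212 between ATM
and CHEK2 is not published anywhere we know of, so the default gives
CHEK2 the larger share (its recurrent c.1100del founder allele is an
order of magnitude more common than typical loss-of-function alleles) and
is configurable.

**Disease onset.** A proportional-hazards model with a piecewise-constant
baseline hazard over the age bands [0,40), [40,50), [50,60), [60,70),
[70,90), with relative per-year rates 0.15 / 1 / 1.4 / 1.8 / 2.0 —
a low premenopausal rate rising monotonically with age, the coarsest
shape consistent with population incidence curves. Two calibrations pin
the absolute scale and the PRS effect:

* the global hazard scale is found by 1-D root finding
  (`stats::uniroot`) so that a carrier-free woman at the median PRS has
  cumulative incidence `baseline_cuminc_70` (default 0.093) by age 70;
  a target ≥ 1 fails explicitly as infeasible;
* the PRS log-hazard slope β solves, again by root finding,
  \( \mathbb{E}[e^{\beta Z} \mid Z > q_{0.9}] \,/\,
     \mathbb{E}[e^{\beta Z} \mid q_{0.3} < Z < q_{0.7}] = \mathrm{HR}_{10} \)
  with Z standard normal and \(\mathrm{HR}_{10}\) = 2.4 by default, using
  the closed form
  \( \mathbb{E}[e^{\beta Z} \mid a<Z<b] = e^{\beta^2/2}\,
     \frac{\Phi(b-\beta)-\Phi(a-\beta)}{\Phi(b)-\Phi(a)} \).

A woman's hazard multiplier is the **maximum** multiplier over her carried
genes (defaults 16.2 / 8.5 / 6.3 / 4.3 / 2.6) times \(e^{\beta z}\).
Maximum rather than product mirrors how a dual-gene carrier is analyzed:
she is assigned to the single highest-risk group. Onset is drawn by
inverting the piecewise cumulative hazard at an Exp(1) deviate; onset
after the current age means the diagnosis is never observed (censoring at
the current age; there is no competing mortality). Because both onset and
censoring ages are continuous, ties in the simulated data are negligible,
but the fitting layer still uses a tie-robust method (below) because real
EHR ages are often recorded in whole years.

**Family history.** A Z80.3 (family history of breast cancer) indicator
with logistic dependence on carrier status (log odds `log(3.5)` by
default) and on the PRS z-score (slope 0.25 by default — the association
is reported in the emulated cohort as positive and significant without an
effect size, so the default is a deliberately modest choice, exposed in
the configuration). The intercept is solved by root finding on the
realized cohort so the marginal prevalence is 6.9%. For women with a
diagnosis, the age of the first Z80.3 code is drawn from a three-part
mixture relative to the diagnosis: *before* (uniform 8 days–15 years
prior), *simultaneous* (uniform within −7…+30 days), *after* (uniform
31 days–15 years later, capped at the censoring age), with default
weights 0.22 / 0.30 / 0.48; the 0.30 and 0.48 are the published
simultaneous/after fractions and 0.22 is their complement. The rare
affected woman censored within 31 days of onset cannot have an *after*
code, and such draws are reassigned to the simultaneous window; at
default rates this affects of order 1% of affected FHx-positive women,
well inside the binomial noise the recovery tests allow. Undiagnosed
FHx-positive women get a code age uniform over their adult EHR span.

**Code streams.** Each woman's record is a dated ICD-10-CM list: a first
breast-cancer code (C50.911/C50.912/D05.11 at onset, with a Z85.3
personal-history code two years later for half of survivors), the Z80.3
code, other-family-history codes (Z80/Z82/Z83, prevalence 0.268), and
comparator phenotypes (E11.9 type 2 diabetes, prevalence 0.12; I10
hypertension, 0.35) placed uniformly over the adult span. The comparators
exist so the timing-enrichment analysis has a null to compare against.

All randomness flows from the single configured seed; the caller's RNG
state is restored afterwards, and the same seed yields byte-identical
written cohorts.

### What the generator does and does not emulate

Passing recovery tests on this generator demonstrates that the analysis
layer measures what the generative model encodes: hazard ratios, the
baseline cumulative incidence, the FHx–carrier odds ratio and the timing
mixture are all recovered within their sampling error. Three features of
real data are deliberately absent, and results on synthetic data should
not be read as evidence about them:

* **Ascertainment-driven family history.** The FHx indicator is drawn
  independently of the outcome given carrier status and PRS. Real EHR
  family history is heavily enriched among diagnosed women *because* it
  is ascertained at diagnosis; the inflated apparent hazard ratios that
  motivates the timing analysis (and the published value near 4.9) are
  therefore not reproduced here — the synthetic marginal FHx HR is close
  to the modest value implied by its carrier and PRS dependence alone.
  Relatedly, removing simultaneous/after records from synthetic data
  *overcorrects* (the remaining FHx+ cases are only the ~22% coded
  before diagnosis), an overcorrection the emulated analysis itself
  acknowledges.
* **SNV-level PRS structure.** The cohort carries a raw score per woman
  drawn from group-shifted normals; dosage computation, the
  allele-frequency fallback and callability QC are exercised on explicit
  genotype observations in unit tests and with the shipped synthetic
  scoring file, not inside the default cohort.
* **EHR messiness.** No coding errors, no gaps, no competing mortality,
  no left truncation of observed codes. Diagnoses that predate the EHR
  span are assumed visible (as personal-history codes make them in
  practice).

## The variant interpretation cascade

`classify_variants()` implements a first-match-wins rule chain designed
for population screening, where most diagnostic-grade evidence types are
unavailable: variants failing the gnomAD quality filter (or an optional
manual-QC flag) are excluded outright; then (a) the recurrent CHEK2
c.1100del allele rs555607708 is always pathogenic/likely pathogenic
(P/LP); (b) an expert-panel ClinVar review is kept as-is, mapped onto
{P/LP, B/LB, VUS}; (c)/(d) multi-submitter no-conflict records map benign
and uncertain labels; (e) a high-confidence LOFTEE loss-of-function call
is P/LP; (f) everything else is not pathogenic. Rule order is load-bearing
and tested: an expert-panel benign with a high-confidence LOF annotation
is benign.

String handling: ClinVar values are matched case-insensitively with
underscores as spaces; combined values ("Pathogenic/Likely_pathogenic")
map to the combined class; unknown review-status strings are treated as
absent with a message, and expert-panel significance values outside the
three classes fall through to not-pathogenic with a warning. The engine
consumes one annotation row per variant; when several ClinVar records
exist upstream, the caller is expected to supply the most recent one.
CNVs are handled separately (`classify_cnvs()`): only PASS deletions
overlapping a coding exon of the MANE transcript are P/LP. Coordinates
are taken as 1-based GRCh38 and never recomputed.

Carrier derivation (`carrier_table()`) requires at least one het/hom
genotype on a P/LP variant; excluded variants never contribute.
Multi-gene carriers keep all genes but are analyzed in one group by the
precedence BRCA1 > BRCA2 > PALB2 > ATM > CHEK2, which orders the genes by
their hazard multipliers. `af_sanity_report()` flags any P/LP call at
cohort allele frequency ≥ 0.1% — other than rs555607708, the known
common exception — for review, without reclassifying.

## PRS conventions

Dosage per variant is genotype probabilities when present
(`GP1 + 2·GP2`), else the hard-call allele count, else `2 × AF` from the
reference panel of the woman's closest group (the Hardy–Weinberg
expectation). The raw score is the weighted dosage sum over the scoring
model (PGS-Catalog flat format). A callability filter drops model
variants missing (no GP, no GT) in more than 10% of participants,
mirroring the reduction of a 313-SNV model to ~300 well-called SNVs.

Percentiles are computed within genetic-similarity group as
`100 × rank / N` with average ranks for ties — so a one-woman group is
100, two tied women in a group of two are both 75, and for distinct
scores the multiset of percentiles depends only on N. "Top X%" uses the
strict inequality `percentile > 100·(1 − X)`: the boundary woman (e.g.
percentile exactly 90 for the top decile) is *not* flagged. Neither the
tie rule nor the boundary convention is forced by the emulated analysis,
which states only "top 10%"; both are declared here and used
consistently. Group-wise z-scores standardize against undiagnosed women
only when the correlation analyses call for it. The rank AUC equals the
Mann–Whitney U statistic normalized by `n_case × n_control`, counting
ties as one half.

## Survival layer

The time scale is **age with time zero at birth**, matching
"% diagnosed by age" curves; censoring is at the current age. Whether
women should instead enter the risk set at their EHR start (left
truncation) is genuinely unclear in the emulated analysis; both are
implemented (`left_truncate = TRUE` uses the counting-process form with
entry at the EHR start age) and birth entry is the default. Under the
generator the default is exactly right — women's onsets are observable
from birth via history codes — so the flag matters for real data, not
for the tests.

Kaplan–Meier estimation, Cox partial-likelihood fitting and the log-rank
test are delegated to the `survival` package, the canonical R
implementation, behind thin module functions (`km_fit()`, `km_risk_at()`,
`cox_fit()`, `logrank()`); the test suite checks them against
hand-computed product-limit tables, an O−E log-rank oracle and
closed-form null cases, so the package's use of the library is itself
verified. Conventions: Efron tie handling (ages in years produce heavy
ties in real data); Newton iteration with convergence tolerance 1e-9 and
at most 100 iterations; Wald 95% intervals with z = 1.959964; KM curves
are right-continuous step functions, read out at the largest step time at
or before the target age, 0 before the first event and carried forward
beyond the last. Degenerate inputs are defined, not fatal: an event-free
curve is identically 1 with a warning; constant covariates and
fewer-than-two-event fits are rejected with messages.

## Family-history timing

First-code extraction is prefix-based: breast cancer is C50/D05/Z85.3
(secondary neoplasms such as C79.81 never match), family history of
breast cancer is Z80.3, and other family history is Z80–Z84 *after*
removing Z80.3 codes, so the two FHx phenotypes cannot overlap. The
simultaneity window is −7 to +30 days around the first breast-cancer
code. Two analyses in the emulated study use slightly different words
for the exclusion ("within 1 week" vs the −7…+30-day window); this
package deliberately uses the single [−7, +30] window for both the
timing histogram and the debiasing exclusion, so one definition governs
both, and the window is a parameter for anyone wanting the narrower
reading. A day-scale tolerance of 1e-6 absorbs year→day conversion noise
at the window boundaries. Enrichment of simultaneous recording around
breast cancer versus a comparator phenotype is a Pearson chi-square
without continuity correction on the 2×2 (simultaneous vs not) table.
`debias_cohort()` removes women whose first FHx code is simultaneous
or after; retained rows are untouched.

## Screening strategies and their metrics

A strategy is a disjunction of clauses: family history (any-time code, or
pre-diagnosis-only under the worse-case mode), an always-referred gene
panel, a conditional panel requiring a top-fraction PRS, and a standalone
top-fraction PRS. The two headline strategies are (1) FHx or
BRCA1/BRCA2/PALB2 carrier or ATM/CHEK2 carrier with top-50% PRS, and
(2) any-of-five carrier or top-10% PRS. Metrics:

* **PPV** — the KM probability of diagnosis by age 70 among
  screen-positives (a bounds-checked identity on that read-out);
* **specificity** — `TN/(TN+FP)` with `TN = n_neg·(1 − p_event_neg)` and
  `FP = n_pos·p_noevent_pos`, all KM-at-70 quantities;
* **NNS** — `1 / ((n_pos/n_total) · p_event_by50_pos)`, the number
  screened per pre-age-50 diagnosis among positives, rounded to an
  integer for reporting;
* **false negatives** — women diagnosed before 50 and not flagged.

The reference arithmetic reproduces the published chains exactly:
specificity 23,593×0.924 / (23,593×0.924 + 1,998×0.66) = 94.3% and
22,682×0.919 / (22,682×0.919 + 2,909×0.77) = 90.3%; NNS
1/((1,998/25,591)×0.070) = 183. The published second-strategy NNS of 213
is reproducible only through its intermediate rounding
(1/(0.114×0.041) ≈ 213.9); direct computation gives
1/((2,909/25,591)×0.041) ≈ 214.5 → 215 (hence 213 is documented here, not
asserted). The 20%-cumulative-risk-by-70 constant labels strategies as
identifying a "high risk" group in reports; it never enters flag logic.
Percentages are reported to one decimal, NNS as an integer.

## Association analyses

Restricted to undiagnosed women of the Europe genetic-similarity group —
the only group large enough, and the restriction makes normalized PRS
values comparable. Fisher's exact test uses the two-sided
point-probability method; the reported odds ratio is the sample
`ad/bc` (infinite on a zero denominator, error on a zero margin), not the
conditional-MLE estimate. The Welch t statistic uses Satterthwaite
degrees of freedom. Test oracles: exhaustive hypergeometric enumeration
and the hand-written Welch formula.

## Problem sizes and test design

The recovery tests run at the full default size (25,591 women) because
carrier counts in the low hundreds are the science: smaller cohorts make
the per-gene hazard-ratio checks vacuous. Coverage of the generating
hazard ratios by fitted Wald intervals is assessed over 100 replicate
cohorts, enough to hold the Monte-Carlo error on a ~95%-coverage
proportion well below the 90% acceptance bound. Oracle tests (cascade
truth table, product-limit, log-rank, Fisher enumeration) are exhaustive
or closed-form at toy sizes. The pipeline smoke tests intentionally run
tiny cohorts (≤1,500 women) and tolerate the package's own
degenerate-stratum warnings.

## Known limitations

* The generator's hazard bands are coarse; absolute incidence below 40
  and above 70 is schematic, so only the calibrated age-70 (and
  derived age-50) read-outs should be compared across configurations.
* Family-history timing is modeled only for the index phenotype; the
  comparator phenotypes get uniform code placement, which makes the
  enrichment test conservative rather than calibrated.
* The per-gene split of ATM/CHEK2 carriers and the FHx–PRS slope are
  conventions, not estimates; conclusions that depend on them should be
  re-run across the configurable range.
* No ovarian cancer, no competing risks, no time-varying covariates, no
  absolute-risk integration of the monogenic and polygenic components
  beyond the maximum-multiplier rule.
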