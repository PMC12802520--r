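---
title: "Disproportionality signal detection on spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
library(tibble)
```

## The problem

Spontaneous reporting systems (SRS) such as FAERS collect voluntary
adverse-event reports with no exposure denominator: we observe how often a
drug–event pair is *reported*, never how often it *occurs*. The only
available inferential handle is disproportionality — comparing the pair's
reporting frequency against the background formed by all other drugs in
the same database. `pvsignal` implements that analysis end to end: data
cleaning (deduplication, role filtering, term validation), 2×2 tables,
four detection algorithms with significance gates and intensity grades,
signal post-processing, descriptive summaries, and Naranjo causality
scoring, together with a synthetic-report generator that makes every stage
testable against planted ground truth.

A disproportionality signal is a hypothesis, not a verdict: reporting is
subject to notoriety bias, confounding by indication, and under-reporting,
none of which the statistics can remove. The package is therefore careful
to separate *detection* (the algorithms) from *qualification* (exclusion
lists, label novelty, case-by-case causality review).

## The counting model

All counting is at the level of the deduplicated report. A report "has
the drug" iff the drug appears with the primary-suspect role code (a drug
appearing additionally in another role counts once); it "has the event"
iff the validated PT list contains the term. Each report then falls in
exactly one cell of the 2×2 table, so `a + b + c + d` equals the total
report count for every pair from one set — a conservation law the test
suite checks against a naive double-loop recount. The comparator
population is "all other drugs within the supplied report set"; users who
want a different background (e.g. the full database rather than a
post-cleaning subset) simply supply that set.

Deduplication follows the conventional SRS case-versioning rule: one
report per case id, keeping the latest receipt date, ties broken by the
lexicographically greatest report id. This makes the operation
deterministic and idempotent.

## The four algorithms

With `T = a + b + c + d` and the shared standard error
`s = sqrt(1/a + 1/b + 1/c + 1/d)`:

| method | point estimate | lower bound | positivity gate |
|--------|----------------|-------------|-----------------|
| ROR    | `ad/bc`        | `exp(ln ROR − 1.96 s)` | lower bound > 1, N ≥ 3 |
| PRR    | `a(c+d)/(c(a+b))`, plus `χ²` | `exp(ln PRR − 1.96 s)` | lower bound > 1, PRR ≥ 2, χ² ≥ 4, N ≥ 3 |
| BCPNN  | `IC = log2(aT/((a+c)(a+b)))` | `IC025 = exp(ln IC − 1.96 s)` | IC > 0, IC025 > 0, N ≥ 3 |
| MGPS   | `EBGM = aT/((a+c)(a+b))` | `EBGM05 = exp(ln EBGM − 1.64 s)` | EBGM05 > 2, N ≥ 3 |

Three numerical points deserve emphasis.

**The EBGM here is unshrunk.** `EBGM = aT/((a+c)(a+b))` is the observed
relative reporting ratio, identical to `2^IC` — an exact algebraic
identity the tests assert to machine precision. A true multi-item
gamma-Poisson shrinker fits a mixture prior and shrinks small counts
towards 1; that estimator is deliberately out of scope, because the
reference tables this package mirrors are consistent with the unshrunk
ratio throughout, and silently substituting a shrunk estimator would
change every reported value.

**The IC025 form is multiplicative.** The lower bound applies the
multiplicative interval to the IC point value itself
(`exp(ln IC − 1.96 s)`), not the conventional additive form
(`IC − 1.96 s`). The multiplicative form is what the package's reference
tables use, and it is the default. It has a consequence worth stating
plainly: `exp(·)` is positive, so IC025 > 0 whenever IC > 0, and the
BCPNN positivity gate degenerates to `IC > 0` — roughly a coin flip under
the null. The conventional additive interval is available via
`signal_statistics(..., bcpnn_interval = "additive")`; the test suite
verifies that the additive variant has calibrated (< 10%) null
false-positive behaviour while the multiplicative gate sits near 50%, and
that the *combined* all-four rule remains calibrated either way because
ROR, PRR and MGPS carry the specificity.

**Zero cells.** Any zero cell makes `s` infinite; affected statistics are
flagged undefined and undefined statistics are never significant (the
N ≥ 3 gate screens most such pairs anyway). An optional Haldane–Anscombe
correction (`continuity = TRUE`) adds 0.5 to every cell before computing.
The χ² uses the printed product form with no Yates correction. Full
precision is retained internally; rounding (half-up, two decimals)
happens only in `format_signal_table()` and the descriptive summaries.

Intensity grades are band memberships per method — ROR/PRR at 2, 10, 50;
BCPNN on IC025 at 0, 1.5, 3; MGPS on EBGM05 at 2, 10, 30 — with
nonsignificant pairs always graded `none`.

## Signal post-processing

Statistical positivity is filtered through four configurable exclusion
lists (primary disease, disease outcome, non-reference terms, unspecified
events); the shipped defaults cover canonical examples such as "Disease
progression", "Death", "Investigation" and "Oncologic complication" and
are meant to be extended per study. Accounting is conservative in both PT
units and report units (`retained = detected − excluded`), mirroring the
flow diagrams of published analyses.

SOC aggregation sums the report counts `n` of positive PT signals within
each system organ class and expresses shares of the positive total.
Ranking is by `n` (frequency) or by ROR (strength) with deterministic
tie-breaks; strength ranking on ROR is the package's choice because it
matches how published strength tables are ordered, and can be re-sorted on
`ic025` by the user if preferred. Novelty is a set difference against a
label PT list, rendered as `§` in exports.

Descriptive summaries use the full deduplicated report total as the
denominator for every percentage, including not-specified levels (so a
female share of 29,650 of 38,061 prints as 77.90). Age bands are fixed at
< 18, 18–64 (lower bound inclusive), ≥ 65, and not specified. Outcome
classes count once per report per class, so outcome percentages need not
sum to 100.

## The Naranjo module

The ten canonical questions are scored with the published weight table
(shipped as an editable TSV; maximum attainable score 13) and mapped to
categories with fixed cut-offs: ≥ 9 definite, 5–8 probable, 1–4 possible,
≤ 0 doubtful. The top category is labelled `definite` even though some
sources call it "highly probable or definite"; the cut-off is what
matters and it is hard-coded. Dual-rater adjudication is a human process:
`rater_disagreements()` surfaces category conflicts between two scored
answer sets but implements no automated resolution.

## The synthetic-report generator

`simulate_reports()` emulates the record classes of a FAERS-style extract:
demographics (female-skewed, configurable missingness), drug records (one
primary suspect plus an optional concomitant), a dominant-indication
population with an unknown-indication level, multi-PT reports, the six
outcome classes, receipt years, and superseded duplicate case versions.

Signals are planted on the odds scale: for a planted `(drug, pt, lambda)`
the per-report odds of listing the term among the drug's primary-suspect
reports are multiplied by `lambda`, so the population reporting odds ratio
equals `lambda` by construction and recovery targets are analytic. Each
PT is included independently with probability `prob × events_per_report`;
reports that draw no term receive one drawn from their own
inclusion-probability row, which keeps the planted odds calibrated to
within ~1–2% (verified by the coverage test: the realized 95% CI covers a
planted `lambda = 10` in ≥ 93 of 100 seeded replicates).

Two deliberate departures from realism matter for interpretation:

* **Drug share.** The default drug of interest contributes 5% of reports.
  In a real full-scale database a single drug is orders of magnitude
  rarer, which makes `EBGM ≈ ROR`; at 5% the relative reporting ratio is
  visibly attenuated relative to the odds ratio (a planted ROR of 10
  yields EBGM around 6–7). Keeping the share small is what lets all four
  detectors agree on true signals at desk-scale sample sizes; pushing it
  higher suppresses MGPS positivity — a property of the statistic, not a
  bug.
* **Independence.** Drug co-prescription structure, time-varying
  reporting rates and notoriety bias are not modelled. Passing tests on
  this generator demonstrate algorithmic correctness and calibration
  under a clean reporting model, not robustness to the biases of real
  spontaneous data.

Problem sizes in the test suite were chosen to give the planted pairs
expected counts in the tens (e.g. 11,000 cases for an expected `a ≈ 52`
in the recovery study; a 20-drug × 50-PT grid of 5,000 cases for null
calibration; 100 seeded replicates of each), which keeps Monte-Carlo
error comfortably below the tolerances being asserted.

## A complete run

```{r pipeline}
cfg <- sim_config(n_cases = 5000, seed = 23,
                  planted = tibble(drug = "TYVERINE", pt = "Milia", lambda = 10),
                  duplicate_fraction = 0.1)
sim <- simulate_reports(cfg)
res <- run_pipeline(sim$reports, "TYVERINE", demo_meddra_map(),
                    label_pts = system.file("extdata", "label_pts_synthetic.txt",
                                            package = "pvsignal"))
res$accounting[c("reports_read", "duplicates_removed", "drug_primary_reports",
                 "detected_reports", "retained_reports")]
format_signal_table(head(res$by_strength, 5))
head(res$soc)
```

## Known limitations

* The generator's clean reporting model (above): calibration results do
  not transfer to biased real-world reporting.
* No gamma-Poisson shrinkage; small-count EBGM values are noisy exactly
  where shrinkage would stabilise them — the N ≥ 3 gate is the only
  small-count guard.
* Exclusion lists and drug-name synonyms are configuration, not
  knowledge: the shipped defaults are starting points.
* Indication roll-ups (grouping related indication strings) are left to
  the user; the descriptive summary reports the raw levels.
* Raw FAERS quarterly ASCII/XML files and RxNorm drug normalisation are
  out of scope; inputs are the two documented CSV dialects.
```
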