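---
title: "Methods: disproportionality analysis of spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality analysis of spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The model and its assumptions

Spontaneous-report databases record which adverse events were *reported*
together with which drugs, not incidence. Disproportionality analysis asks
whether an event is reported more often with the target drug than the rest
of the database predicts, on a fourfold table of counting units:

|  | event of interest | all other events |
|---|---|---|
| target-drug reports | `a` | `b` |
| all other reports | `c` | `d` |

The counting unit in this package is the **unique (deduplicated report,
Preferred Term) pair**, with reports partitioned into target (at least one
drug row matching the synonym list in an accepted role, primary suspect by
default) and background (every other deduplicated report). Two properties
make this the coherent choice: summed over all PTs, `a` recovers the number
of target pairs exactly, so the margins are interpretable; and the four
statistics below are mutually consistent on the same table, which is what
`reconstruct_fourfold()` exploits to audit published rows. Reports whose
only matching drug rows carry an excluded role remain in the background —
the comparator is "all other reports", not "reports never mentioning the
drug". At SOC level a report contributes at most one pair per SOC
(mirroring the PT-level per-report uniqueness); the sum-of-PTs alternative
is available via `map_pt_to_soc(per_report_unique = FALSE)`.

The four statistics share the observed/expected logic but differ in the
margin they condition on: ROR (odds ratio, the primary metric here for its
transparency), PRR (proportion ratio), the information component IC
(base-2 log of observed/expected under independence) and EBGM (the same
observed/expected ratio on the natural scale, so `IC = log2(EBGM)`
identically in this unshrunk form). Association is assessed per term by the
Pearson chi-square (1 df, no continuity correction) with
Benjamini–Hochberg adjustment across the tested family, and flagging uses
strict thresholds: `a >= 3`, CI lower bounds above 1, `IC025 > 0`,
`EBGM05 > 1`, adjusted p below 0.05, combined per the chosen policy
(`ror_primary` default; `all_four`; `any`). All of this measures reporting
association only — confounding by indication, stimulated reporting and
channeling are not addressed, and no flag is evidence of causation.

## Deliberate deviations from common textbook presentations

* **EBGM05 is the 5th percentile**, `exp(ln EBGM − 1.645·SE)`, not a
  two-sided 1.96 bound. Published tables in this field are internally
  consistent with 1.645 (a row printing EBGM 3.82 with EBGM05 3.66 implies
  1.645; 1.96 would give 3.63), and a lower *threshold* bound is one-sided
  by construction. `ebgm_percentile_z = 1.96` restores the two-sided
  variant.
* **IC defaults to the simplified point estimate** with
  `IC025 = IC − 2·SE/ln 2`. The full Bayesian credibility version
  (`ic_mode = "bayes"`, standard priors `alpha = beta = 2`,
  `alpha1 = beta1 = gamma11 = 1`) is implemented but not default: printed
  IC/IC025 values in the literature this package targets match the
  simplified form, and the simplified form keeps the `IC = log2(EBGM)`
  identity exact.
* **EBGM is the unshrunk relative reporting ratio.** Full MGPS fits a
  gamma-mixture prior by empirical Bayes and shrinks small counts; that
  estimator is out of scope here, which matters mainly for `a` below ~10.
* **Zero cells yield undefined statistics** with an explicit reason, not a
  silent continuity correction. The `a >= 3` rule makes `a = 0` irrelevant
  for flagging, and inflating a zero background cell (`c = 0`) can fabricate
  huge RORs; Haldane–Anscombe `+0.5` is opt-in (`zero_cells = "haldane"`).
* **The FDR family** is all terms at the analyzed level (PT and SOC
  separately) with `a >= min_a` and a defined p-value; terms below the
  count threshold are not tested rather than diluting the family. The
  choice is recorded in the run manifest.

## Data handling choices

* **Partial dates** (`yyyymmdd`, `yyyymm`, `yyyy`) keep an explicit
  precision tag; implausible components degrade precision (month 13 keeps
  the year) rather than inventing a date. Operations declare the precision
  they need: deduplication compares dates at any precision via a padded
  sort key, while time-to-onset requires day precision on both anchors.
  Missingness is the norm in this data, not an edge case.
* **Deduplication** keeps, per case id, the version with the latest receipt
  date, ties broken toward the larger zero-padded report id — a
  deterministic, idempotent rule. A version with no receipt date survives
  only if it is the sole version.
* **Ages** normalize to years (`YR`×1, `DEC`×10, `MON`÷12, `WK`÷52.18,
  `DY`÷365.25, `HR`÷8766); age bins are left-closed (`[60, 75)` etc.), so
  exactly 60 falls in 60–74. Time-to-onset bins are likewise left-closed
  (`[7, 28)` …).
* **Time to onset** anchors on the DEMO event date minus the earliest
  day-precision therapy start among rows matching the target drug in an
  accepted role. Negative onsets (present in real data) are tallied
  separately and treated as unknown. Quartiles use linear interpolation
  (`quantile` type 7); the published medians this was checked against do
  not disambiguate the quartile method, so it is configurable by
  post-processing the returned records.
* **Outcome percentages** default to counting each outcome code once per
  report with counted codes as denominator — the structure published
  outcome tables follow — with a worst-outcome-per-report policy
  (death > life-threatening > disability > hospitalization > other)
  selectable.
* **SOC exclusions** (six SOCs conventionally attributed to underlying
  disease progression in the treated population) are applied at PT level
  only; the SOC-level table is never filtered. Exclusion commutes with
  ranking.
* **Column maps are configuration** because the quarterly file layout
  drifted over the years; defaults follow the modern layout.

## The synthetic generator

`simulate_faers()` exists so that every stage — parsing, deduplication,
extraction, counting, statistics, descriptives — can be tested against
known ground truth without shipping licensed MedDRA content or bulky real
extracts. Each simulated report draws one primary-suspect drug; counts of
PTs and drug rows per report are Poisson truncated at 1; PTs within a
report are drawn *without replacement* (REAC rows are unique per report by
construction, and generated REAC rows exactly equal the sum of events per
report). Planted associations multiply the PT weights of the affected
drug's reports by the relative risk and renormalize, so `rr = 1` is the
exact null. Duplicate case versions are injected with strictly earlier
receipt dates and copied child rows, making correct dedup output known
exactly.

Defaults mirror the composition of real target-drug reports where a value
was available: ~1.56 events per report, 12.9% missing sex, 32.9% missing
age, 51.5% missing event date, a 16.5% duplicate-version rate (the
database-wide shrinkage removed by dedup), therapy-start years 2004–2024,
and a lognormal onset with `meanlog = log(82)`, `sdlog = 2` — chosen to
match a published median onset of 82 days and its upper quartile
(~315 days); a lognormal cannot match the median and *both* quartiles of
that distribution simultaneously, and the lower quartile is the casualty.
Where no value was available (drug-count mixture, reporter/country/outcome
weights, age distribution) a single realistic choice was fixed and is not
a tuning surface.

`expected_fourfold()` returns analytic expected cells using the
first-order inclusion probability `E[k]·w` — exact under
sampling-with-replacement, an approximation for the without-replacement
draws actually generated. The approximation is accurate when events per
report are few relative to the number of PTs; more importantly,
**unique-pair counting itself saturates**: a report can contribute a given
PT only once, so when a PT's weight is large and reports carry many
events, the realized ROR sits below the planted relative risk. This is a
property of the counting unit (real databases included), not an artifact
of the generator. The recovery validation therefore runs at roughly 1.6
events per report and per-PT weights below 10%, where the planted relative
risk equals the generative reporting odds ratio to well within estimation
error — and, with one planted signal per run, the odds transformation
makes them equal *exactly* (target odds `w·rr/(1−w)` over background odds
`w/(1−w)`).

What the generator does **not** emulate: free-text drug-name chaos beyond
formulation suffixes, country- and time-varying reporting dynamics,
indication-driven channeling, correlated event clusters (syndromes), or
the true margin sizes of a full database (tens of millions of reports).
Passing tests therefore demonstrate correctness of the computation and
calibration under the stated generative model, not robustness to every
real-data pathology.

## Validation problem sizes

The shipped suite validates at sizes chosen to make Monte-Carlo error
small relative to the tolerances while keeping a full run comfortably
interactive: published-row reconstruction (three rows, exact arithmetic);
algebraic identities and reconstruction round-trips on 1,000 random
tables (round-trip relative error below 1e-10); planted-signal recovery
with relative risks 2, 5 and 10 at 7,000 reports × 100 replicates each
(expected `a` ≥ 50 verified from the analytic expectation; coverage of the
planted value by the ROR's own 95% CI required ≥ 90%); null calibration on
8,000 reports × 200 candidate PTs with the `all_four` composite
(flag rate ≤ 2%); byte-identical pipeline reruns; and hand-computed
descriptive fixtures.

## Known limitations

Signals are reporting associations, not risks; the unshrunk EBGM
overstates small-count signals relative to MGPS; stratified (age/sex/year)
and drug–interaction disproportionality are not implemented; the XML and
openFDA JSON dialects are not read; and PT→SOC mapping quality is entirely
that of the user-supplied map (unmapped PTs are reported and excluded from
SOC-level tables only).
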