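---
title: "Disproportionality screening of spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening of spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Spontaneous-report databases such as the FDA Adverse Event Reporting System
(FAERS) collect voluntarily submitted case reports of suspected drug adverse
events. They have no denominator — the number of treated patients is
unknown — so incidence cannot be estimated. What can be estimated is
*disproportionality*: whether a drug–event pair is co-reported more often
than the database's margins predict. pvsignal implements a complete
record-level screening pipeline for such databases: ingestion and
deduplication of report tables, MedDRA-based event grouping,
shrinkage-corrected disproportionality statistics with signal
classification, time-to-onset (TTO) and outcome summaries, and a synthetic
report generator with known ground truth against which every stage is
validated.

# The statistical model

For a target drug and a target event set, counting deduplicated reports:

* $N_{observed}$ — reports listing both the drug and the event,
* $N_{drug}$, $N_{event}$ — reports listing each alone,
* $N_{total}$ — all reports,
* $N_{expected} = N_{drug} N_{event} / N_{total}$ — the count expected
  under independence of drug and event reporting.

The two statistics are shrinkage-corrected versions of the
observed-to-expected ratio:

$$IC = \log_2 \frac{N_{observed} + 0.5}{N_{expected} + 0.5}, \qquad
  ROR = \frac{N_{observed} + 0.5}{N_{expected} + 0.5}$$

The 0.5 pseudo-counts pull small-count ratios toward 1 (IC toward 0),
trading a little downward bias for stability: a pair observed once against
an expectation near zero no longer produces an explosive ratio. The two
statistics are the same shrunken ratio on two scales, so $ROR = 2^{IC}$
holds exactly — an identity the test suite asserts to machine precision.
Note this ROR is a record-level observed/expected ratio, not the classical
2×2 odds ratio; at the small drug- and event-margins typical of screening
the two are numerically close.

## Interval bounds

The 95% bounds for the IC use the standard closed-form approximation to the
shrinkage-IC posterior (in bits, with $n = N_{observed}$):

$$IC_{025} = IC - 3.3\,(n+0.5)^{-1/2} - 2\,(n+0.5)^{-3/2}$$
$$IC_{975} = IC + 2.4\,(n+0.5)^{-1/2} - 0.5\,(n+0.5)^{-3/2}$$

The ROR bounds are log-normal: $ROR \cdot e^{\pm 1.96/\sqrt{n}}$, with the
degenerate case $n = 0$ mapped to $(0, \infty)$. Both approximations were
checked against a published 16-SMQ cardiovascular screen of ibrutinib
(shipped as `ibrutinib_cv_smq_reference.tsv`): every printed bound is
reproduced within ±0.01 of the value implied by the printed two-decimal
point estimates. Interval half-widths shrink as $n^{-1/2}$, so cumulative
IC trends (`ic_trend()`) narrow as reports accrue.

## Signal classification

A pair is a *signal* under the default criterion when $IC_{025} > 0$ **and**
$ROR_{025} > 1$, with $N_{expected} > 3$. The expected-count gate suppresses
pairs whose evidence rests on a handful of reports; it is applied at
classification, not at computation, so sub-threshold rows still appear in
screen output. An `or` combination of the two disproportionality bounds is
available (`signal_criteria(combine = "or")`). No multiplicity correction
is applied across event sets: the shrinkage of the statistics is the guard
against spurious small-count signals, and the null-calibration suite
(below) verifies it is conservative.

# Data handling rules

**Deduplication.** Reports with the same sex, age, reporting country,
adverse-event PT set, set of reported drug names, earliest therapy start
date and latest therapy end date are treated as one case. The kept
representative is the report with the latest receive date (ties broken by
smallest report id), and survivor order is input order, which makes the
operation idempotent and stable. Missing key fields compare equal to
missing.

**Partial dates.** FAERS dates are frequently year- or month-precision.
They are kept as reported (`"2020"`, `"202004"`, `"20200409"`) and never
completed: two partial dates are equal for deduplication only if their
known components agree, and any computation needing a day (TTO) simply
excludes partial dates.

**Drug identification.** Generic and brand names both identify the target
drug. Matching is token-based after case-folding: `"IMBRUVICA (ibrutinib)
420mg"` matches, while `"acalabrutinib"` does not match `ibrutinib` (no raw
substring matching).

**MedDRA mapping.** MedDRA is licensed content and is not shipped; the user
supplies PT→SMQ (with narrow/broad scope) and PT→SOC tables. The bundled
`smq_map.tsv`/`soc_map.tsv` are a small *synthetic* toy dictionary — real
SMQ names and codes for 16 cardiovascular SMQs, invented PT memberships —
sufficient for tests and examples only. SMQ scope defaults to narrow+broad
because published screens rarely state their scope; it is a configuration
knob.

**Time to onset.** Days from the earliest *complete* start date of a
matching drug entry to the complete event onset date; negative differences
(onset before start) and partial dates are excluded, never imputed.
Quartiles use linear interpolation between order statistics
(`quantile(type = 7)`), the convention pinned so that
`summarize_tto(1:5)` gives Q1–Q3 = 2–4.

**Outcomes.** A report listing several outcome codes contributes once, to
its most severe category, ordered death > life-threatening > disability >
hospitalisation > other serious. This mirrors how published outcome tables
sum to ~100%. Descriptive blocks (sex, age bands <45/45–59/≥60, country,
indication, dose bands 140/280/420/560 mg) each use their own
data-available denominator.

# The synthetic report generator

`simulate_reports()` emulates the features of a spontaneous-report database
that the pipeline must survive: multi-table structure, duplicate records,
partial missingness, therapy and onset dates, outcome codes — with known
association strengths so recovery can be verified.

**Association semantics.** The configured ratio $r$ for a PT is the *lift*
of the drug-exposed reporting rate over the database-marginal rate: exposed
reports list the PT with probability $r p$ and unexposed reports with
$p(1 - \pi r)/(1 - \pi)$, where $p$ is the background probability and
$\pi$ the drug prevalence. This keeps the marginal rate at $p$ exactly, so
the observed/expected ratio converges to $r$ and $\log_2 r$ is the exact
asymptotic IC — closed-form ground truth for tests. The construction
requires $r \le 1/\pi$; probabilities that leave $[0,1]$ are capped and
flagged `truncated` in the ground-truth table. (Under the naive alternative
— exposed rate $r p$, unexposed rate $p$ — the marginal is inflated and the
asymptotic IC is $\log_2\frac{r}{1 + \pi(r-1)}$, which at $\pi = 0.05$,
$r = 8$ is 2.57 bits rather than 3; the lift construction removes that
dilution.)

**Defaults as study conditions.** Drug prevalence 0.05 and per-PT
backgrounds 0.01 give desk-scale databases the margin structure of a
moderately reported drug. Demographics, outcome probabilities
(death 21.0%, hospitalisation 41.4%, …), dose and indication mixes and
missingness rates (age 45%, sex 7%, outcomes 21%, therapy start 50%, onset
50%) follow the published characteristics table of ibrutinib reports. The
TTO model is log-normal with median 99 days and $\sigma_{\log} = 1.8$,
chosen so the implied Q1–Q3 (≈29–335 days) matches the published onset
spread. Every report receives one filler event from a pool disjoint from
the modelled PTs, so the "a report has at least one adverse event"
invariant holds without disturbing modelled margins.

**What it does not emulate.** Reports are independent — no within-patient
correlation, no polypharmacy confounding, no co-prescription or masking
structure, no country-specific reporting cultures, no secular reporting
trends. Passing recovery tests therefore shows the estimator chain is
correct under the model the statistics themselves assume (independent
record-level reporting), not that real-data biases are overcome — the usual
caveat of disproportionality analysis.

# Validation suites and problem sizes

The test suite validates each stage at sizes chosen to keep the whole run
in a few minutes while leaving negligible Monte-Carlo slack:

* *Counting oracle*: `build_contingency()` agrees with a per-record
  brute-force loop on 20-record stores.
* *Null calibration*: 1000 replicate screens of 2000 reports × 16 null PTs;
  the fraction of sets with $IC_{025} > 0$ stays below the nominal 2.5%
  (empirically ≈0.1% — the shrinkage interval is conservative).
* *Planted recovery*: at 200,000 reports, a PT with ratio 8 yields an IC
  within ±0.15 bits of 3 and is the only flagged set; across ratios
  {1, 2, 4, 8} (three PTs each) the median estimated shrunken ratio lands
  within 10% of truth.
* *TTO recovery*: the planted 99-day median is recovered within ±5%
  (median over five replicate databases of 2592 computable TTOs, the
  size at which the sample median's relative standard error is ≈4.4%).
* *Duplicate injection*: with fully observed key fields, injecting
  duplicates and deduplicating restores the original count exactly.

# Numerical and degenerate-input choices

* $N_{observed} = 0$: IC and ROR are defined (shrinkage), ROR bounds
  degenerate to $(0, \infty)$.
* Empty event sets produce a zero-count row, never an error; unknown PTs
  map to the empty SMQ set, never an error.
* An empty database (`n_total = 0`) is an error, as is a report table
  whose event table is empty.
* FAERS case versioning keeps the highest `caseversion` per `caseid`
  before the 7-field deduplication.
* Ages are harmonised to years from FAERS `age_cod` units; values outside
  [0, 130] become missing.
* Integer counts are promoted to double before forming
  $N_{drug} N_{event}$, which overflows 32-bit integers at realistic
  database sizes.

# Known limitations

The screen is record-level and unadjusted: no stratification, no
EBGM/MGPS-style hierarchical Bayes, no correction for co-prescription or
masking. The dedup key treats "adverse events" as the PT set (verbatim
terms are not modelled). These mirror the scope of the published screens
this package operationalises; signals it raises are hypothesis-generating
flags, not causal claims.
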