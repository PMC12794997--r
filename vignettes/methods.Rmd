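---
title: "Methods: disproportionality signal detection and time-to-onset modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection and time-to-onset modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersdpa)
```

This vignette is the package's own account of its statistical machinery:
what is modelled, which knobs matter, what the synthetic-data generator
does and does not emulate, and where genuinely open design choices were
resolved.

## The pipeline in one paragraph

Spontaneous-report databases record suspected drug–event pairs without an
exposure denominator. The pipeline ingests FAERS-style quarterly ASCII
tables, collapses report versions to one per case, harmonizes drug names,
restricts exposure to primary-suspect (PS) mentions, and then screens
every drug against a target preferred term (PT) with four
disproportionality statistics on the drug–event 2×2 table. Drugs that
satisfy all four positivity criteria simultaneously are composite
signals; composite signals absent from the drug's labeling are novel.
Onset dynamics are characterized per drug by a two-parameter Weibull fit
to the interval from therapy start to event.

## Cleaning rules

- **Deduplication.** One report per `caseid`, keeping the latest version
  date. The rule alone does not define a total order, so ties are broken
  deterministically: an absent date loses to any present date, and within
  equal dates the larger `primaryid` (numeric-aware) wins. Deduplication
  precedes role filtering, following the narrative order of the standard
  cleaning procedure.
- **Name normalization.** A raw name is looked up case-insensitively
  (after trimming) in a user-supplied synonym table; misses are
  upper-cased verbatim and tallied. No fuzzy matching: edit-distance
  matching on drug names creates silent false merges, and the synonym
  table makes the mapping auditable.
- **Event filtering.** Exact case-insensitive PT equality. PTs are a
  controlled vocabulary; substring matching would conflate e.g. a term
  with its "aggravated" variant.
- **Unit conversions.** Ages: YR as-is, MON ÷ 12, WK ÷ 52.18,
  DY ÷ 365.25; the decade code is passed through unconverted. Weights:
  KG as-is, LBS × 0.453592. Partial dates (YYYY, YYYYMM) are floored to
  their period start and carry a precision flag; any analysis needing day
  resolution (time-to-onset) treats coarser dates as absent.

## Disproportionality statistics

With cells a, b, c, d and N = a+b+c+d:

| statistic | estimate | 95% bound | positivity |
|---|---|---|---|
| ROR  | ad/(bc) | exp(ln ROR ± 1.96·se), se² = 1/a+1/b+1/c+1/d | lower > 1, a ≥ 3 |
| PRR  | a(c+d)/(c(a+b)) | χ² = (ad−bc)²N/((a+b)(c+d)(a+c)(b+d)) | PRR ≥ 2, χ² ≥ 4, a ≥ 3 |
| IC   | log₂(aN/((a+c)(a+b))) | IC025 = IC − 2√V(IC) | IC025 > 0 |
| EBGM | aN/((a+c)(a+b)) | EBGM05 = exp(ln EBGM − 1.96·se) | EBGM05 > 2 |

Numerical choices:

- **Zero cells.** No Haldane/continuity correction anywhere. A zero cell
  makes the affected CI (and for ROR the estimate) non-evaluable; flags
  from non-evaluable statistics are `FALSE`. This keeps small-count rows
  faithful to the raw closed forms rather than silently shifting them.
- **IC variance.** The delta-method approximation
  V(IC) = (1/ln 2)²·(1/a − 1/(a+b) − 1/(a+c) + 1/N), clipped at 0. The
  Bayesian (Dirichlet-posterior) variance used by some implementations
  differs in the third decimal at typical counts; the delta form is
  documented, monotone in a, and exactly reproducible.
- **EBGM without shrinkage.** The EBGM column here is the plain
  observed-to-expected ratio; no Gamma–Poisson mixture is fitted. The
  conventional name is kept because the positivity threshold (EBGM05 > 2)
  is quoted against this quantity in routine practice; the docstring
  flags the distinction. Consequently IC ≡ log₂(EBGM), which the test
  suite enforces as an algebraic cross-check.
- **Rounding.** Exports round half-up at 2 decimals (published tables use
  commercial rounding); internal values stay full precision.
- **Exposure definition.** A report is "exposed" to a drug only through
  PS mentions; secondary-suspect and concomitant mentions of the same
  drug leave the report in the comparator cells. This matches the tie of
  suspect status to PS roles and makes per-drug tables partition the
  corpus (a+b+c+d equals the corpus size for every drug).

Small-count rankings are reported both raw and criteria-filtered: tables
in the field list drugs at n = 1–2 among top signals even though the
ROR/PRR criteria require n ≥ 3, so the package computes rankings by raw
strength (`top_drugs(..., "by_signal")` on composite rows) without
guessing intent beyond the stated thresholds.

## Weibull time-to-onset

The onset interval is event date minus the *earliest* day-precision
therapy start of the matching PS drug, in days; same-day onset is coded
as 1 day (a zero duration has no finite Weibull log-likelihood), negative
intervals and missing/partial dates are excluded and tallied. The
endpoints (first therapy start → event date) are a documented choice; the
data do not record per-dose timing.

The two-parameter Weibull is fitted by maximum likelihood through an
uncensored accelerated-failure-time fit (`survival::survreg`), which
parameterizes (log α, log 1/β) natively; 95% CIs are Wald intervals on
the log parameters, back-transformed. A profile-likelihood option was
considered and not taken: at the fit floor of n = 30 the two differ
little, and Wald-on-log is orders of magnitude faster for per-drug sweeps
(the CI method is isolated in `fit_weibull`, so swapping it is local).
No right-censoring model is fitted — only observed onsets enter, which
over-represents short intervals; the classification should be read as a
description of reported onsets, not a hazard model for the treated
population. The reported median is the empirical 50th percentile, as in
published onset tables.

Classification from the shape CI: entirely below 1 → early failure
(declining hazard), entirely above 1 → wear-out, containing 1 → random,
non-evaluable → indeterminate.

## The synthetic-data generator

The generator is first-class, tested code: it is the only way to exercise
the full pipeline without multi-gigabyte downloads, and its planted
structure makes recovery provable.

Per case: a quarter is drawn uniformly over the configured range
(2004Q1–2024Q3 by default), the version date uniformly within the
quarter, the event date 0–90 days earlier. One PS drug is drawn from
background drugs (by their weights) and signal drugs (each at
`signal_prob`, default 0.005); 0–3 concomitant mentions are added.
A background report lists the target PT with probability
`target_event_rate` (default 0.0143, the target event's share of the full
reporting corpus); a signal-drug report with probability p_s solved from
the planted reporting odds ratio R via p_s/(1−p_s) = R·p₀/(1−p₀), so the
truth is analytically known. Onset intervals are Weibull: the planted
(α, β) for signal-drug event cases, Weibull(120 d, 1) background
otherwise, day-ceiled (dates are day-granular, so a ≤ 1-day discretization
is inherent). Demographics follow configurable mixtures whose defaults
reproduce the observed composition of the depression-reporting population
(61.2% female, 47.8% aged 18–65, 65.1% missing weight, 67.1% US, each
axis with an explicit missing category). With probability
`duplicate_rate` (default 0.10 — FAERS publishes no official rate; ~10%
is a realistic order for version resubmission) a case emits a strictly
earlier-dated extra version whose reaction list is a noise placeholder,
so failing to deduplicate visibly distorts counts. Raw-name variants
(case changes and `BRAND-` aliases resolvable only through the synonym
table) appear at `name_variant_rate` = 0.30.

What the generator does **not** emulate — and hence what green tests do
not show about real data: secular reporting growth (quarters are uniform,
so the annual trend on synthetic data is flat noise and its polynomial R²
is low, unlike the strong growth in real corpora), drug–indication dependence (indications are independent per
drug row), correlated polypharmacy, country- or age-specific reporting
propensities, MedDRA hierarchy effects, and notoriety spikes.

One interaction is worth knowing: a planted ROR is defined against the
*pure background* odds. With several signal drugs in one corpus, each
drug's comparator cells contain the other elevated drugs, so its measured
ROR is mildly attenuated; the expected measured value follows in closed
form from the mixture weights (computed in `analysis/03_signals.R`).
Single-signal recovery tests use the planted value directly.

## Problem sizes and determinism

The test and analysis corpora are sized for a laptop-class run:
recovery properties use 20 independent 100,000-case corpora (ROR CI
coverage and composite-flag sensitivity), 20 × 20,000-case null corpora
(specificity ≤ 5%), n = 5,000 draws for shape recovery (±0.05), and 200
replicates × n = 1,000 for bias (< 0.03). The workflow corpus is 60,000
cases over 83 quarters. All randomness flows through a single
configuration seed (`withr::with_seed`), and identical configurations
produce byte-identical quarterly files.

## Known limitations

- Disproportionality measures reporting, not incidence; composite
  signals are hypothesis-generating, not causal.
- No multiple-testing adjustment is applied across drugs (none is applied
  in the practice this pipeline mirrors); the four-way conjunction is the
  de-facto specificity control, and the null suite verifies its false
  composite rate stays ≤ 5%.
- No stratified (age/sex) disproportionality and no shrinkage EBGM.
- Desk-scale, in-memory only; quarterly files are read whole.
- Printed lower bounds for EBGM05/IC025 in some published tables are not
  reproducible from their own stated formulas at small n; this package
  reports its documented forms instead of chasing unexplained values.
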