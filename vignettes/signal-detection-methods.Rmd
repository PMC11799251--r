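---
title: "Disproportionality signal detection and onset-time modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection and onset-time modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous reporting systems such as FAERS collect voluntary adverse-event
reports. They have no denominator: one cannot estimate incidence, only ask
whether a drug-event pair is reported *disproportionately* often relative to
the rest of the database. `faersignal` implements the standard
pharmacovigilance workflow around that question for a single target drug:

1. parse the quarterly `'$'`-delimited ASCII tables (DEMO, DRUG, REAC, THER);
2. deduplicate case versions;
3. select the target-drug cohort and optionally strip co-medicated cases;
4. build 2x2 contingency tables per MedDRA preferred term (PT) and system
   organ class (SOC);
5. score each table with four disproportionality estimators and threshold
   rules;
6. model the time from therapy start to event onset with a Weibull law.

Because real FAERS extracts are large downloads and MedDRA is proprietary,
the package ships a synthetic spontaneous-reporting-system generator with
known ground truth; every stage of the pipeline is validated against it.

## Deduplication

FAERS re-publishes a case under the same CASEID whenever it is amended. The
pipeline retains, per CASEID, the version with the latest FDA receipt date
(`FDA_DT`); ties are broken by the highest PRIMARYID. PRIMARYIDs are compared
numerically when both are all-digit strings and lexicographically otherwise —
FAERS identifiers are numeric in practice, but the defensive branch costs
nothing. A missing `FDA_DT` sorts lowest, so an undated version never
displaces a dated one. The operation is idempotent.

## Contingency structure

The counting unit is the unique *(case, term)* pair, not the case: a report
listing five PTs contributes five PT-level pairs. SOC-level tables collapse
to at most one pair per case per SOC, so a case with many sibling PTs is not
double-counted; a pair-sum variant (no collapse) is available by flag since
either convention appears in the literature. PTs missing from the
user-supplied PT-to-SOC mapping pool into the sentinel class `UNMAPPED`
rather than being dropped. The comparator is the full cleaned extract (all
other drugs), the convention in FAERS disproportionality studies; the
quarter window applies to the whole extract.

## The four estimators

With cells `a` (target drug and term), `b` (target drug, other terms), `c`
(other drugs and term), `d` (neither), and `N = a+b+c+d`:

**ROR.** `ROR = ad/bc`, with the Wald interval
`exp(log ROR ± 1.96 √(1/a+1/b+1/c+1/d))`. A zero cell leaves the statistic
undefined — no Haldane/continuity correction is applied, because the flag
rule already requires `a ≥ 3` and a corrected estimate would only blur the
threshold semantics.

**PRR.** `PRR = [a/(a+b)] / [c/(c+d)]` with the Pearson chi-square. The
default chi-square carries the Yates continuity correction
`(|ad−bc| − N/2)² N / [(a+b)(c+d)(a+c)(b+d)]`; the uncorrected variant is a
flag away. Which variant a given published analysis used is rarely stated,
so both are first-class and tested.

**BCPNN information component.** `IC = log2 p11/(p1. p.1)` under the
Bayesian confidence propagation neural network model with Beta margins and
priors `α1 = β1 = γ11 = 1`, `α = β = 2`, and the joint prior weight `γ`
tuned to prior independence. The closed form reports the IC of the posterior
means and the delta-method variance `V` (the summed squared coefficients of
variation of the three Beta posteriors); `IC025 = IC − 2√V`, matching the
`IC025 > 0` threshold convention. A Monte-Carlo helper (`bcpnn_ic_mc()`)
samples the same posteriors for validation; note that the *mean of* `log2`
differs from the closed form by a Jensen term of order `1/(2a ln 2)`, which
is material below a few hundred counts — the closed form is the ratio-of-means
summary, which is what the tests validate.

**MGPS.** The multi-item gamma Poisson shrinker places a two-component gamma
mixture prior on the rate ratio `λ = μ/E`, with `E = (a+b)(a+c)/N`, and fits
the five hyperparameters by marginal maximum likelihood (the marginal of the
count is a two-component negative binomial mixture). Optimization runs on
log/logit-transformed parameters, Nelder-Mead followed by a BFGS polish,
from the start point `(0.2, 0.1, 2.0, 4.0, 1/3)`. Scores are
`EBGM = 2^{E[log2 λ | a, E]}` via digamma, and `EBGM05`, the 5th percentile
of the posterior mixture found by bisection on the mixture CDF to
`|ΔCDF| ≤ 1e-10`. The prior is fitted once on the PT-level universe and
reused for SOC scoring, so shrinkage is consistent across levels. With only
a few hundred tables the five-parameter mixture is weakly identified and the
MLE can drift toward near-degenerate components; scoring remains stable, but
the fitted hyperparameters should not be interpreted on small universes
(a warning fires below 100 tables).

**Thresholds.** ROR: lower 95% bound > 1 and `a ≥ 3`; PRR: PRR ≥ 2,
chi-square ≥ 4, `a ≥ 3`; BCPNN: IC025 > 0; MGPS: EBGM05 > 2. A term
flagged by *any* method is a potential signal (`any_flag`). No multiplicity
adjustment is applied beyond these rules — that matches standard
pharmacovigilance practice and is a known limitation: the family-wise
false-positive rate is controlled only empirically (measured at well under
5% on null synthetic databases in the test suite).

## Weibull time-to-onset

TTO is the event date minus the *earliest complete* start date of the target
drug in the primary-suspect role, per case (the analysis is pooled, not
per-PT). Partial dates (`YYYYMM`, `YYYY`) are excluded rather than imputed —
imputation would cluster onsets artificially at month boundaries — and
exclusion counts are always reported. A same-day onset (0 days) is promoted
to 1 day since the Weibull support is positive; an event dated before the
start is excluded as non-positive. No censoring model is used: spontaneous
reports exist only when an event occurred, so plain MLE is appropriate.

The fit maximizes the Weibull likelihood in `(log scale, log shape)`; 95%
Wald intervals come from the observed information on that scale and are
exponentiated, which keeps them positive and close to profile intervals at
these sample sizes. The failure type is called on the shape interval: upper
bound below 1 is `early` (decreasing hazard — risk concentrated just after
treatment start), lower bound above 1 is `wear-out`, anything else
`random`. The call is invariant to rescaling the time unit. The empirical
median and IQR (standard type-7 quantiles) are reported alongside the
parametric fit.

One numerical caveat the synthetic experiments make visible: onset *days*
are inherently ceiling-discretized (dates have day resolution), so a
continuous-Weibull fit on day data is mildly biased upward in the shape when
the true shape is well below 1 (a few percent at shape 0.6). Parameter-recovery
tests therefore draw continuous samples; the pipeline estimate on day data
is the honest day-resolution answer.

## The synthetic generator

`sim_config()` defines the study conditions; `generate_database()` emits
DEMO/DRUG/REAC/THER in the FAERS dialect plus a ground-truth record.
Defaults encode a recent-approval biologic cohort: a 16-quarter window
(2020Q3–2024Q2), 73.4% female / 4.6% missing sex, 51.5% missing age with
reported ages concentrated in 18–65, consumer-dominated reporting (82.8%),
US-dominated geography (79.8%), Weibull(scale 86.8 days, shape 0.617) onset
times, and 10% duplicate case versions. These match the descriptive margins
of a published FAERS cohort for a drug of this class, so that "realistic"
has a concrete referent; all are configurable.

Background drug-event co-occurrence is generated under independence: each
case draws a zero-truncated Poisson number of PT slots (mean 3, about the
FAERS average), fills them i.i.d. from a mildly skewed PT frequency vector
(`w_j ∝ j^{-1/2}`), and de-duplicates. Independence makes "no signal" the
provable null. A planted signal of relative risk `rr` raises the per-case
report probability of that PT among target-drug cases from its background
value `q_j` (available in closed form from the slot-count generating
function) to `rr·q_j`; a configuration where that exceeds 1 is rejected
rather than silently capped, keeping the planted RR interpretable.
Duplicates re-emit a case under a new PRIMARYID with a perturbed receipt
date (30% keep the same date to exercise the tie-break); the intended
survivor is recorded. A configurable fraction of therapy start dates is
truncated to `YYYYMM` to exercise the TTO completeness filter, and one
concomitant co-medication (role `C`) is attached to a fraction of cases to
exercise the sensitivity filter.

What the generator does **not** emulate: reporter-propensity differences
(consumer vs physician reporting behaviour), drug-drug interaction signals,
secular trends within the window, correlated PT co-occurrence (real
syndromes), and country effects beyond a categorical label. Passing tests
on synthetic data therefore demonstrate correctness of the *computation*
under a known model, not robustness to those real-data phenomena.

## Subgroups and sensitivity

Subgroup runs stratify by sex or age and rebuild the pair universe *within
the stratum*, so the comparator is the same-stratum background — stratum
composition then cannot masquerade as a drug effect. (A full-background
option is retained since published analyses are often silent on this
point.) Age is harmonized to years from the FAERS unit code (decades ×10,
months ÷12, ...) before binning; the descriptive bins are
`<18 / 18–65 / 66–85 / >85` with an alternate subgroup preset
`18–44 / 45–65 / >65`. The sensitivity analysis drops every cohort case
listing an excluded co-medication (default list: gabapentin, baclofen,
duloxetine, vitamin B, vitamin D) in any role, recomputes all signals, and
reports the persistent set (flagged before and after). No subset relation
is asserted between the two flag sets: they are computed on nested but
different data.

## Determinism and problem sizes

All randomness flows from a single integer seed; identical configuration
and seed reproduce every output file bit for bit (`bundle_hash()` checks
this). The bundled experiments use 50,000-case databases with 210 PTs and
10 planted signals at RR 4 — large enough that planted-signal recall,
null false-positive rates, and Weibull recovery are sharp, small enough to
run in seconds; Weibull recovery uses 200 replicates of n = 500, and the
estimator oracles use 1,000 random tables (closed forms), 20 tables with
10^6 posterior draws (BCPNN), and 100 random posteriors (MGPS quantiles).

## Known limitations

- Disproportionality is not causality; no confounding adjustment is
  attempted (and none is standard in this workflow).
- MedDRA content is not bundled; SOC aggregation is only as good as the
  user-supplied PT-to-SOC mapping.
- The MGPS hyperparameter fit needs a reasonably large pair universe to be
  well identified (warning below 100 tables; interpret the prior itself
  with care below a few thousand).
- The indication field (INDI) is parsed but not used by default; an
  indication filter is exposed for drugs approved in multiple diseases.
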