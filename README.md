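# faersignal

Pharmacovigilance signal detection for spontaneous adverse-event reporting
data, built for analysts working with FDA Adverse Event Reporting System
(FAERS) quarterly extracts — and for methodologists who need every stage of
that workflow to be testable without multi-gigabyte downloads or a MedDRA
license.

The package covers the full pipeline for a single target drug:

- **IO and cleaning** — parse the `'$'`-delimited FAERS ASCII tables
  (DEMO/DRUG/REAC/THER), deduplicate case versions (latest `FDA_DT`, ties
  to the highest `PRIMARYID`), and assemble a case-level database.
- **Cohort** — select cases where the target drug is the primary suspect
  (substring matching on free-text drug names and active ingredients),
  apply a quarter window, exclude co-medicated cases, stratify by sex or
  age, and tabulate descriptives.
- **Disproportionality** — 2×2 tables per preferred term (PT) and system
  organ class (SOC) against the full-database comparator, scored with four
  estimators and the standard thresholds:

  | method | statistic | signal rule |
  |---|---|---|
  | ROR | ad/bc with Wald 95% CI | CI lower bound > 1, a ≥ 3 |
  | PRR | [a/(a+b)]/[c/(c+d)] + Yates χ² | PRR ≥ 2, χ² ≥ 4, a ≥ 3 |
  | BCPNN | information component IC = log₂ p₁₁/(p₁.p.₁) | IC025 > 0 |
  | MGPS | empirical-Bayes geometric mean (2-component gamma mixture) | EBGM05 > 2 |

  A term flagged by any method is a potential signal.
- **Time to onset** — days from the earliest complete therapy start to the
  event, Weibull maximum likelihood with Wald intervals on the log scale,
  and failure-type classification (`early` / `random` / `wear-out` from the
  shape CI against 1).
- **Synthetic generator** — a spontaneous-reporting-system simulator that
  emits FAERS-dialect tables with planted drug–event signals of known
  relative risk, injected duplicates, partial dates and Weibull onset
  times, plus a ground-truth sidecar, so the whole pipeline is verifiable
  end to end.

## Worked example

```r
library(faersignal)

cfg <- sim_config(n_cases = 10000, n_pts = 120,
                  planted_signals = data.frame(pt_id = c(8, 77), rr = 5),
                  seed = 2026)
rc  <- run_config(sim = cfg, out_dir = file.path(tempdir(), "demo"),
                  seed = 2026)
res <- run_main(rc)

rank_report(res$pt_signals, 5)[, .(term, a, ror, ror_lo95, prr, chi2,
                                   ic025, ebgm05)]
#>       term     a   ror ror_lo95   prr   chi2     ic025 ebgm05
#> 1: PT_0008   253  4.99     4.26  4.68 473.20  1.507191  3.257
#> 2: PT_0077    77  4.09     3.11  4.02 115.48  1.172040  3.257
#> 3: PT_0025    43  1.45     1.04  1.44   4.55 -0.027882  0.889
#> 4: PT_0089    28  1.65     1.09  1.64   5.26 -0.000645  0.885
```

Both planted terms (`PT_0008`, `PT_0077`, true RR = 5) surface at the top
with all four statistics past threshold; the remaining two rows are
borderline chance flags (ROR CI barely above 1, every other method
negative) — exactly the behaviour the `any_flag` union rule implies.

```r
w <- res$weibull
sprintf("TTO median %.0f d (IQR %.0f-%.0f); Weibull shape %.3f (%.3f-%.3f) -> %s",
        w$median_days, w$iqr[1], w$iqr[2],
        w$shape, w$shape_ci[1], w$shape_ci[2], w$failure_type)
#> "TTO median 52 d (IQR 16-147); Weibull shape 0.700 (0.661-0.741) -> early"
```

The shape estimate sits below 1 with its whole interval, so onsets
concentrate early after therapy start (decreasing hazard), consistent with
the generator's Weibull(86.8, 0.617) truth up to day-discretization.

## Analysis workflow

Numbered drivers under `analysis/` run the full study on a 50,000-case
synthetic database and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R              # generate + write FAERS tables
Rscript analysis/02_clean_cohort.R          # dedup, cohort, descriptives
Rscript analysis/03_signals.R               # PT/SOC disproportionality
Rscript analysis/04_subgroups_sensitivity.R # strata + co-medication filter
Rscript analysis/05_onset.R                 # Weibull time-to-onset
```

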