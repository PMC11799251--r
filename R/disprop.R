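## Frequentist and Bayesian disproportionality statistics on 2x2 tables,
## and the signal-classification rules.
##
## Conventions (the canonical literature forms):
##   ROR   : Wald interval on the log odds ratio; undefined on zero cells
##           (no continuity correction).
##   PRR   : row-conditional rate ratio, with the Yates-corrected Pearson
##           chi-square by default (uncorrected available).
##   BCPNN : closed-form posterior moments of the information component
##           with priors alpha1 = beta1 = gamma11 = 1, alpha = beta = 2;
##           IC025 = IC - 2*sqrt(V).
##   MGPS  : see mgps.R.

#' Reporting odds ratio with Wald 95% interval
#'
#' `ROR = (a d)/(b c)`; the interval is
#' `exp(log ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell
#' leaves all three values `NA` (no continuity correction is applied; the
#' case-count rule `a >= 3` governs flagging anyway).
#'
#' @param a,b,c,d cell counts (vectorized).
#' @return `data.table` with `ror`, `ror_lo95`, `ror_hi95`.
#' @export
ror_stats <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  ror <- lo <- hi <- rep(NA_real_, length(a))
  ror[ok] <- (a[ok] * d[ok]) / (b[ok] * c[ok])
  se <- sqrt(1 / a[ok] + 1 / b[ok] + 1 / c[ok] + 1 / d[ok])
  lo[ok] <- exp(log(ror[ok]) - 1.96 * se)
  hi[ok] <- exp(log(ror[ok]) + 1.96 * se)
  data.table(ror = ror, ror_lo95 = lo, ror_hi95 = hi)
}

#' Proportional reporting ratio and Pearson chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`. The chi-square statistic is the
#' Yates-continuity-corrected Pearson statistic
#' `(|ad - bc| - n/2)^2 n / [(a+b)(c+d)(a+c)(b+d)]` by default; set
#' `correct = FALSE` for the uncorrected form. Zero denominators give `NA`.
#'
#' @param a,b,c,d cell counts (vectorized).
#' @param correct apply the Yates continuity correction (default `TRUE`).
#' @return `data.table` with `prr`, `chi2`.
#' @export
prr_chi2 <- function(a, b, c, d, correct = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  prr <- rep(NA_real_, length(a))
  ok_p <- (a + b) > 0 & c > 0 & (c + d) > 0
  prr[ok_p] <- (a[ok_p] / (a[ok_p] + b[ok_p])) / (c[ok_p] / (c[ok_p] + d[ok_p]))
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- rep(NA_real_, length(a))
  ok_c <- denom > 0
  dev <- abs(a * d - b * c)
  if (correct) dev <- pmax(dev - n / 2, 0)
  chi2[ok_c] <- dev[ok_c]^2 * n[ok_c] / denom[ok_c]
  data.table(prr = prr, chi2 = chi2)
}

#' BCPNN information component (closed-form posterior moments)
#'
#' The information component `IC = log2 p11 / (p1. p.1)` under the
#' Bayesian confidence propagation neural network model with priors
#' `alpha1 = beta1 = gamma11 = 1`, `alpha = beta = 2` and the joint prior
#' parameter `gamma` tuned so the prior expects independence:
#' `gamma = gamma11 (N+alpha)(N+beta) / [(a+b+alpha1)(a+c+beta1)]`.
#' The lower credibility bound is the two-standard-deviation form
#' `IC025 = IC - 2 sqrt(V)`, matching the `IC025 > 0` threshold
#' convention.
#'
#' @param a,b,c,d cell counts (vectorized); requires `N > 0`. The formulas
#'   are defined even at `a = 0`.
#' @return `data.table` with `ic`, `ic_v` (the variance `V`), `ic025`.
#' @export
bcpnn_ic <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  a1 <- 1; b1 <- 1; g11 <- 1
  al <- 2; be <- 2
  r1 <- a + b + a1
  c1 <- a + c + b1
  gam <- g11 * (N + al) * (N + be) / (r1 * c1)
  ic <- log2((a + g11) * (N + al) * (N + be) / ((N + gam) * r1 * c1))
  v <- (1 / log(2)^2) * (
    (N - a + gam - g11) / ((a + g11) * (1 + N + gam)) +
    (N - (a + b) + al - a1) / (r1 * (1 + N + al)) +
    (N - (a + c) + be - b1) / (c1 * (1 + N + be)))
  data.table(ic = ic, ic_v = v, ic025 = ic - 2 * sqrt(v))
}

#' Monte-Carlo posterior check for the BCPNN information component
#'
#' Samples the three Beta posterior margins of the BCPNN model
#' independently and returns Monte-Carlo summaries: the IC implied by the
#' posterior means (the estimand of the closed form), the mean and SD of
#' per-draw IC values, and delta-method / SD standard errors. Used as a
#' validation option, not in the default pipeline.
#'
#' @param a,b,c,d scalar cell counts.
#' @param n_draws number of posterior draws.
#' @return list with `ic_of_means`, `ic_of_means_se`, `ic_mean`, `ic_sd`,
#'   `ic_mean_se`, `ic_sd_se`.
#' @export
bcpnn_ic_mc <- function(a, b, c, d, n_draws = 1e5) {
  N <- a + b + c + d
  r1 <- a + b + 1
  c1 <- a + c + 1
  gam <- (N + 2) * (N + 2) / (r1 * c1)
  p11 <- stats::rbeta(n_draws, a + 1, N - a + gam - 1)
  px <- stats::rbeta(n_draws, r1, N - (a + b) + 2 - 1)
  py <- stats::rbeta(n_draws, c1, N - (a + c) + 2 - 1)
  draws <- log2(p11 / (px * py))
  m11 <- mean(p11); mx <- mean(px); my <- mean(py)
  ## delta-method SE of log2(m11/(mx my)) with independent margins
  rel_var <- stats::var(p11) / (n_draws * m11^2) +
    stats::var(px) / (n_draws * mx^2) + stats::var(py) / (n_draws * my^2)
  list(ic_of_means = log2(m11 / (mx * my)),
       ic_of_means_se = sqrt(rel_var) / log(2),
       ic_mean = mean(draws),
       ic_sd = stats::sd(draws),
       ic_mean_se = stats::sd(draws) / sqrt(n_draws),
       ic_sd_se = stats::sd(draws) / sqrt(2 * (n_draws - 1)))
}

#' Apply the per-method signal thresholds
#'
#' Threshold rules: ROR lower 95% bound > 1 with `a >= 3`; PRR >= 2 with
#' chi-square >= 4 and `a >= 3`; IC025 > 0; EBGM05 > 2. An undefined
#' statistic makes that method's flag `FALSE`. `any_flag` is the OR of
#' the four.
#'
#' @param stats a data.frame/data.table with columns `a`, `ror_lo95`,
#'   `prr`, `chi2`, `ic025`, `ebgm05` (missing columns are treated as
#'   all-`NA`).
#' @return `data.table` with `ror_flag`, `prr_flag`, `bcpnn_flag`,
#'   `mgps_flag`, `any_flag`.
#' @export
classify_signal <- function(stats) {
  s <- as.data.table(stats)
  get0 <- function(nm) if (nm %in% names(s)) s[[nm]] else rep(NA_real_, nrow(s))
  a <- get0("a")
  f <- function(x) !is.na(x) & x
  ror_flag <- f(get0("ror_lo95") > 1 & a >= 3)
  prr_flag <- f(get0("prr") >= 2 & get0("chi2") >= 4 & a >= 3)
  bcpnn_flag <- f(get0("ic025") > 0)
  mgps_flag <- f(get0("ebgm05") > 2)
  data.table(ror_flag = ror_flag, prr_flag = prr_flag,
             bcpnn_flag = bcpnn_flag, mgps_flag = mgps_flag,
             any_flag = ror_flag | prr_flag | bcpnn_flag | mgps_flag)
}

#' Full signal table for a pair universe
#'
#' Computes all four disproportionality statistics and the per-method and
#' combined flags for every term.
#'
#' @param universe a `pair_universe` (or a data.table of tables with
#'   columns `term`, `a`, `b`, `c`, `d`).
#' @param prior an [fit_mgps_prior()] result; if `NULL`, fitted on the
#'   given tables. Fitting once on the PT-level universe and reusing the
#'   prior for SOC scoring keeps shrinkage consistent.
#' @param chi2_correct Yates correction for the PRR chi-square.
#' @return `data.table`: one row per term with `a`, `ror`, `ror_lo95`,
#'   `ror_hi95`, `prr`, `chi2`, `ic`, `ic025`, `ebgm`, `ebgm05` and the
#'   flags.
#' @export
signal_table <- function(universe, prior = NULL, chi2_correct = TRUE) {
  tab <- if (inherits(universe, "pair_universe")) all_tables(universe)
         else as.data.table(universe)
  if (is.null(prior)) prior <- fit_mgps_prior(tab)
  E <- (tab$a + tab$b) * (tab$a + tab$c) / (tab$a + tab$b + tab$c + tab$d)
  res <- cbind(
    tab[, .(term, a)],
    ror_stats(tab$a, tab$b, tab$c, tab$d),
    prr_chi2(tab$a, tab$b, tab$c, tab$d, correct = chi2_correct),
    bcpnn_ic(tab$a, tab$b, tab$c, tab$d)[, .(ic, ic025)],
    mgps_scores(tab$a, E, prior)
  )
  cbind(res, classify_signal(res))
}

#' Rank flagged signals by case count
#'
#' Filters to flagged terms, sorts by `a` descending with a deterministic
#' alphabetical tie-break on the term name, and truncates to `top_k`.
#'
#' @param results a [signal_table()] result.
#' @param top_k number of rows to keep (default all).
#' @param by flag column to filter on: `"any"` (default) or one of
#'   `"ror"`, `"prr"`, `"bcpnn"`, `"mgps"`.
#' @return the ordered, truncated `data.table`.
#' @export
rank_report <- function(results, top_k = Inf, by = "any") {
  flag_col <- paste0(by, "_flag")
  stopifnot(flag_col %in% names(results))
  out <- as.data.table(results)[get(flag_col) == TRUE]
  out <- out[order(-a, term)]
  if (is.finite(top_k)) out <- head(out, top_k)
  out
}
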