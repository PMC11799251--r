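## Multi-item gamma Poisson shrinker (MGPS): a two-component gamma
## mixture prior on the reporting-rate ratio lambda = mu/E, fitted by
## marginal maximum likelihood over all drug-event tables, then used to
## score each table by the empirical-Bayes geometric mean (EBGM) and its
## 5th posterior percentile (EBGM05).

## log of the marginal mixture likelihood of the observed counts:
## a | E ~ p NB(size = a1, prob = b1/(b1+E)) + (1-p) NB(size = a2, ...)
mgps_loglik <- function(a, E, alpha1, beta1, alpha2, beta2, p) {
  l1 <- dnbinom(a, size = alpha1, prob = beta1 / (beta1 + E), log = TRUE)
  l2 <- dnbinom(a, size = alpha2, prob = beta2 / (beta2 + E), log = TRUE)
  m <- pmax(l1, l2)
  sum(m + log(p * exp(l1 - m) + (1 - p) * exp(l2 - m)))
}

#' Fit the MGPS prior hyperparameters
#'
#' Maximizes the marginal likelihood of the observed counts over the
#' five prior parameters `(alpha1, beta1, alpha2, beta2, p)`, with the
#' expected count of each table `E = (a+b)(a+c)/N`. Optimization runs on
#' log / logit transformed parameters from the documented start point
#' `(0.2, 0.1, 2.0, 4.0, 1/3)`.
#'
#' @param tables a data.table with columns `a`, `b`, `c`, `d` (e.g. from
#'   [all_tables()]), or a list with numeric vectors `a` and `E`.
#' @param start numeric start point `(alpha1, beta1, alpha2, beta2, p)`.
#' @return an `mgps_prior`: list with the five parameters, `converged`,
#'   `loglik` and `n_tables`. Fewer than 100 tables triggers a warning
#'   (the prior is then weakly identified); non-convergence falls back to
#'   the best iterate with a warning.
#' @export
fit_mgps_prior <- function(tables, start = c(0.2, 0.1, 2.0, 4.0, 1 / 3)) {
  if (!is.null(tables$E)) {
    a <- tables$a
    E <- tables$E
  } else {
    tab <- as.data.table(tables)
    N <- tab$a + tab$b + tab$c + tab$d
    a <- tab$a
    E <- (tab$a + tab$b) * (tab$a + tab$c) / N
  }
  keep <- is.finite(E) & E > 0
  a <- a[keep]
  E <- E[keep]
  if (length(a) < 100)
    warning("fit_mgps_prior: only ", length(a),
            " drug-event pairs; the prior is weakly identified")
  nll <- function(par) {
    -mgps_loglik(a, E, exp(par[1]), exp(par[2]), exp(par[3]), exp(par[4]),
                 plogis(par[5]))
  }
  par0 <- c(log(start[1:4]), qlogis(start[5]))
  opt <- optim(par0, nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  opt <- optim(opt$par, nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  converged <- opt$convergence == 0
  if (!converged)
    warning("fit_mgps_prior: optimizer did not converge; ",
            "returning best iterate")
  structure(list(alpha1 = exp(opt$par[1]), beta1 = exp(opt$par[2]),
                 alpha2 = exp(opt$par[3]), beta2 = exp(opt$par[4]),
                 mix_p = plogis(opt$par[5]),
                 converged = converged, loglik = -opt$value,
                 n_tables = length(a)),
            class = "mgps_prior")
}

#' Prior mean reporting-rate ratio implied by an MGPS prior
#' @param prior an `mgps_prior`.
#' @return `p alpha1/beta1 + (1-p) alpha2/beta2`.
#' @export
mgps_prior_mean <- function(prior) {
  prior$mix_p * prior$alpha1 / prior$beta1 +
    (1 - prior$mix_p) * prior$alpha2 / prior$beta2
}

## posterior mixture weight of component 1 given (a, E)
mgps_posterior_weight <- function(a, E, prior) {
  l1 <- dnbinom(a, size = prior$alpha1,
                prob = prior$beta1 / (prior$beta1 + E), log = TRUE) +
    log(prior$mix_p)
  l2 <- dnbinom(a, size = prior$alpha2,
                prob = prior$beta2 / (prior$beta2 + E), log = TRUE) +
    log(1 - prior$mix_p)
  m <- pmax(l1, l2)
  exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
}

## 5th percentile of the two-component gamma posterior mixture by
## bisection on the mixture CDF to |delta CDF| <= 1e-10
mgps_quantile <- function(q1, s1, r1, s2, r2, p = 0.05, tol = 1e-10) {
  cdf <- function(x) q1 * pgamma(x, s1, rate = r1) +
    (1 - q1) * pgamma(x, s2, rate = r2) - p
  lo <- min(qgamma(p / 10, s1, rate = r1), qgamma(p / 10, s2, rate = r2))
  hi <- max(qgamma(1 - (1 - p) / 10, s1, rate = r1),
            qgamma(1 - (1 - p) / 10, s2, rate = r2))
  flo <- cdf(lo)
  fhi <- cdf(hi)
  while (flo > 0) { lo <- lo / 2; flo <- cdf(lo) }
  while (fhi < 0) { hi <- hi * 2; fhi <- cdf(hi) }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- cdf(mid)
    if (abs(fm) <= tol || (hi - lo) < .Machine$double.eps * max(1, mid))
      return(mid)
    if (fm > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' EBGM and EBGM05 scores under a fitted MGPS prior
#'
#' The posterior of the rate ratio lambda given `(a, E)` is a
#' two-component gamma mixture with components
#' `Gamma(alpha_k + a, beta_k + E)` and data-dependent weights. Scores:
#' `EBGM = 2^{E[log2 lambda | a, E]}` (via the digamma function) and
#' `EBGM05`, the 5th percentile of the posterior mixture obtained by
#' bracketed root-finding on the mixture CDF to `|delta CDF| <= 1e-10`.
#'
#' @param a observed counts (vectorized).
#' @param E expected counts; `E = 0` gives `NA` scores.
#' @param prior an `mgps_prior` from [fit_mgps_prior()].
#' @return `data.table` with `ebgm`, `ebgm05`.
#' @export
mgps_scores <- function(a, E, prior) {
  stopifnot(inherits(prior, "mgps_prior"))
  n <- length(a)
  ebgm <- ebgm05 <- rep(NA_real_, n)
  ok <- which(is.finite(E) & E > 0)
  if (length(ok)) {
    q1 <- mgps_posterior_weight(a[ok], E[ok], prior)
    s1 <- prior$alpha1 + a[ok]
    r1 <- prior$beta1 + E[ok]
    s2 <- prior$alpha2 + a[ok]
    r2 <- prior$beta2 + E[ok]
    elog <- q1 * (digamma(s1) - log(r1)) + (1 - q1) * (digamma(s2) - log(r2))
    ebgm[ok] <- exp(elog)
    ebgm05[ok] <- vapply(seq_along(ok), function(i)
      mgps_quantile(q1[i], s1[i], r1[i], s2[i], r2[i]), numeric(1))
  }
  data.table(ebgm = ebgm, ebgm05 = ebgm05)
}

#' Simulate counts from a known MGPS prior
#'
#' Draws `lambda` from the two-component gamma mixture and counts
#' `a ~ Poisson(lambda E)`; used to validate hyperparameter recovery.
#'
#' @param n number of drug-event pairs.
#' @param prior list/`mgps_prior` with `alpha1`, `beta1`, `alpha2`,
#'   `beta2`, `mix_p`.
#' @param E_range expected counts drawn log-uniformly in this range.
#' @return list with `a`, `E`, `lambda`.
#' @export
simulate_mgps_counts <- function(n, prior, E_range = c(0.5, 200)) {
  E <- exp(runif(n, log(E_range[1]), log(E_range[2])))
  comp1 <- runif(n) < prior$mix_p
  lambda <- ifelse(comp1,
                   stats::rgamma(n, prior$alpha1, rate = prior$beta1),
                   stats::rgamma(n, prior$alpha2, rate = prior$beta2))
  a <- rpois(n, lambda * E)
  list(a = a, E = E, lambda = lambda)
}
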