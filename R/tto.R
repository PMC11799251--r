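## Time-to-onset (TTO): days from the earliest complete primary-suspect
## therapy start date to the event date, Weibull maximum likelihood with
## Wald intervals on the log scale, and failure-type classification.

#' Compute per-case time to onset
#'
#' TTO is the event date minus the earliest full-precision start date of
#' a target drug in the required role, in days. A case is retained iff
#' both dates are complete `YYYYMMDD` and the difference is non-negative
#' (a same-day onset of 0 is promoted to 1 day, the Weibull support being
#' positive). Partial or missing dates are excluded, not imputed, to
#' avoid artificial clustering at month starts.
#'
#' @param db a `faers_case_db` (normally the selected cohort).
#' @param target_drug_synonyms synonyms identifying the target drug rows
#'   whose start dates qualify.
#' @param role_required role those rows must carry (default `"PS"`).
#' @return a `tto_sample`: list with `days` (integer vector), `n_usable`,
#'   `n_excluded_missing`, `n_excluded_nonpositive`, `n_promoted`.
#' @export
compute_tto <- function(db, target_drug_synonyms = c("OFATUMUMAB", "KESIMPTA",
                                                     "ARZERRA"),
                        role_required = "PS") {
  stopifnot(inherits(db, "faers_case_db"))
  target_ids <- match_target_cases(db$drugs, target_drug_synonyms,
                                   role_required)
  nm <- toupper(ifelse(is.na(db$drugs$drugname), "", db$drugs$drugname))
  ai <- toupper(ifelse(is.na(db$drugs$prod_ai), "", db$drugs$prod_ai))
  hit <- rep(FALSE, nrow(db$drugs))
  for (s in toupper(target_drug_synonyms))
    hit <- hit | grepl(s, nm, fixed = TRUE) | grepl(s, ai, fixed = TRUE)
  rl <- toupper(ifelse(is.na(db$drugs$role_cod), "", db$drugs$role_cod))
  dr <- db$drugs[hit & rl == toupper(role_required)]
  dr <- dr[is_complete_date(start_dt)]
  starts <- dr[, .(start = min(parse_faers_date(start_dt))), by = caseid]

  cs <- db$cases[, .(caseid, event_dt)]
  cs <- starts[cs, on = "caseid"]
  ev_ok <- is_complete_date(cs$event_dt)
  st_ok <- !is.na(cs$start)
  usable_dates <- ev_ok & st_ok
  n_missing <- sum(!usable_dates)
  tto <- as.integer(parse_faers_date(cs$event_dt[usable_dates]) -
                      cs$start[usable_dates])
  n_nonpos <- sum(tto < 0)
  n_promoted <- sum(tto == 0)
  days <- pmax(tto[tto >= 0], 1L)
  if (n_promoted > 0)
    message("compute_tto: promoted ", n_promoted, " zero-day onset(s) to 1")
  structure(list(days = days, n_usable = length(days),
                 n_excluded_missing = n_missing,
                 n_excluded_nonpositive = n_nonpos,
                 n_promoted = n_promoted),
            class = "tto_sample")
}

## Weibull log-likelihood, density (b/s)(t/s)^(b-1) exp(-(t/s)^b)
weibull_loglik <- function(t, scale, shape) {
  sum(log(shape) - shape * log(scale) + (shape - 1) * log(t) -
        (t / scale)^shape)
}

#' Fit a Weibull onset-time model by maximum likelihood
#'
#' Plain (uncensored) MLE: spontaneous reports only exist when an event
#' was observed, so no censoring model applies. 95% Wald intervals are
#' computed on `(log scale, log shape)` from the observed information and
#' exponentiated. The empirical median and IQR of the raw sample are
#' reported alongside (standard type-7 quantiles).
#'
#' @param sample a `tto_sample` or a positive numeric vector of onset days.
#' @param fix_shape optional fixed shape; `fix_shape = 1` gives the
#'   exponential closed form (scale = sample mean).
#' @return a `weibull_fit`: list with `scale`, `scale_ci`, `shape`,
#'   `shape_ci`, `median_days`, `iqr`, `failure_type`, `n`, `loglik`,
#'   `converged`. Errors when n < 3, on degenerate (all identical)
#'   samples, or on non-convergence; warns when n < 30.
#' @export
fit_weibull <- function(sample, fix_shape = NULL) {
  t <- if (inherits(sample, "tto_sample")) sample$days else sample
  t <- as.numeric(t)
  if (length(t) < 3) stop("need at least 3 onset times to fit a Weibull")
  if (any(!is.finite(t)) || any(t <= 0)) stop("onset times must be positive")
  if (length(unique(t)) == 1)
    stop("degenerate sample: all onset times identical")
  if (length(t) < 30)
    warning("fit_weibull: n = ", length(t), " is small; estimates unstable")

  if (!is.null(fix_shape)) {
    stopifnot(fix_shape > 0)
    ## profile MLE of scale at fixed shape: scale = (mean(t^shape))^(1/shape)
    scale <- mean(t^fix_shape)^(1 / fix_shape)
    fit <- list(scale = scale, shape = fix_shape,
                scale_ci = c(NA_real_, NA_real_),
                shape_ci = c(fix_shape, fix_shape),
                loglik = weibull_loglik(t, scale, fix_shape),
                converged = TRUE, vcov = NULL)
  } else {
    sdl <- stats::sd(log(t))
    b0 <- if (sdl > 0) 1.2825 / sdl else 1
    s0 <- exp(mean(log(t)) + 0.5772 / b0)
    nll <- function(par) -weibull_loglik(t, exp(par[1]), exp(par[2]))
    opt <- optim(c(log(s0), log(b0)), nll, method = "BFGS", hessian = TRUE,
                 control = list(maxit = 500, reltol = 1e-12))
    if (opt$convergence != 0)
      stop("Weibull fit did not converge (code ", opt$convergence, ")")
    vc <- tryCatch(solve(opt$hessian), error = function(e)
      stop("Weibull fit: singular information matrix"))
    se <- sqrt(pmax(diag(vc), 0))
    est <- exp(opt$par)
    fit <- list(scale = est[1], shape = est[2],
                scale_ci = exp(opt$par[1] + c(-1, 1) * 1.96 * se[1]),
                shape_ci = exp(opt$par[2] + c(-1, 1) * 1.96 * se[2]),
                loglik = -opt$value, converged = TRUE, vcov = vc)
  }
  qs <- quantile(t, c(0.25, 0.5, 0.75), names = FALSE)
  out <- c(fit, list(median_days = qs[2], iqr = c(qs[1], qs[3]),
                     n = length(t)))
  class(out) <- "weibull_fit"
  out$failure_type <- classify_failure(out)
  out
}

#' Classify the temporal failure pattern of a Weibull fit
#'
#' Shape < 1 means decreasing hazard (risk concentrated early), shape = 1
#' constant hazard, shape > 1 increasing hazard. The call is made on the
#' 95% interval of the shape: `early` if its upper bound is below 1,
#' `wear-out` if its lower bound is above 1, `random` otherwise. The
#' classification is invariant to rescaling the time unit, which moves
#' only the scale parameter.
#'
#' @param fit a `weibull_fit` (or any list with `shape_ci`).
#' @return `"early"`, `"random"` or `"wear-out"`.
#' @export
classify_failure <- function(fit) {
  ci <- fit$shape_ci
  if (any(is.na(ci))) {
    ci <- c(fit$shape, fit$shape)
  }
  if (ci[2] < 1) "early" else if (ci[1] > 1) "wear-out" else "random"
}

#' Onset histogram and empirical cumulative incidence
#'
#' @param sample a `tto_sample` or positive numeric vector of onset days.
#' @param bin_edges increasing numeric bin edges for the histogram
#'   (right-open bins `[e_i, e_{i+1})`, final bin closed).
#' @return list with `hist` (data.table `bin_lo`, `bin_hi`, `count`) and
#'   `ecdf` (data.table `days`, `cum_frac`, right-continuous, reaching 1
#'   at the maximum).
#' @export
onset_curves <- function(sample, bin_edges = seq(0, 720, by = 30)) {
  t <- if (inherits(sample, "tto_sample")) sample$days else sample
  if (length(t) == 0) stop("empty onset sample")
  stopifnot(!is.unsorted(bin_edges, strictly = TRUE))
  edges <- bin_edges
  if (max(t) >= edges[length(edges)])
    edges <- c(edges, max(t) + 1)
  cnt <- as.integer(table(cut(t, breaks = edges, right = FALSE,
                              include.lowest = FALSE)))
  hist <- data.table(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                     count = cnt)
  ux <- sort(unique(t))
  ec <- data.table(days = ux, cum_frac = ecdf(t)(ux))
  list(hist = hist, ecdf = ec)
}
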