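tto_db <- function(starts, events) {
  n <- length(starts)
  ids <- sprintf("t%02d", seq_len(n))
  tiny_case_db(
    cases = data.table(caseid = ids, primaryid = ids, sex = "F",
                       age_years = 30, reporter = "CN", country = "US",
                       fda_dt = "20230601", fda_quarter = "2023Q2",
                       event_dt = events),
    drugs = data.table(caseid = ids, drugname = "KESIMPTA",
                       prod_ai = "OFATUMUMAB", role_cod = "PS",
                       start_dt = starts),
    events = data.table(caseid = ids, pt = "HEADACHE"))
}

test_that("time to onset is event date minus earliest complete start date", {
  db <- tto_db(
    starts = c("20230101", "202301", NA, "20230301", "20230505"),
    events = c("20230214", "20230214", "20230214", "20230214", "20230505"))
  s <- suppressMessages(compute_tto(db))
  ## 2023-01-01 -> 2023-02-14 is 44 days; partial/missing starts excluded;
  ## event before start excluded; same-day onset promoted to 1
  expect_setequal(s$days, c(44L, 1L))
  expect_equal(s$n_usable, 2L)
  expect_equal(s$n_excluded_missing, 2L)
  expect_equal(s$n_excluded_nonpositive, 1L)
  expect_equal(s$n_promoted, 1L)
})

test_that("earliest qualifying start date wins when therapy rows repeat", {
  db <- tto_db("20230201", "20230214")
  db$drugs <- rbind(db$drugs,
                    data.table(caseid = "t01", drugname = "KESIMPTA",
                               prod_ai = "OFATUMUMAB", role_cod = "PS",
                               start_dt = "20230101"),
                    data.table(caseid = "t01", drugname = "BACLOFEN",
                               prod_ai = "BACLOFEN", role_cod = "C",
                               start_dt = "20220101"))
  s <- compute_tto(db)
  ## earliest *target PS* start (2023-01-01) counts; the co-medication's
  ## earlier date does not
  expect_equal(s$days, 44L)
})

test_that("the constrained-shape fit recovers the exponential closed form", {
  expect_warning(fit <- fit_weibull(c(1, 2, 3), fix_shape = 1), "small")
  expect_equal(fit$scale, 2)
  expect_equal(fit$shape, 1)
})

test_that("degenerate and undersized samples are rejected", {
  expect_error(fit_weibull(c(5, 5)), "at least 3")
  expect_error(suppressWarnings(fit_weibull(c(5, 5, 5))), "degenerate")
  expect_error(suppressWarnings(fit_weibull(c(1, -2, 3))), "positive")
})

test_that("maximum likelihood recovers known Weibull parameters", {
  set.seed(86)
  x <- rweibull(10000, shape = 0.617, scale = 86.8)
  fit <- fit_weibull(x)
  se_scale <- sqrt(fit$vcov[1, 1])
  se_shape <- sqrt(fit$vcov[2, 2])
  expect_lt(abs(log(fit$scale) - log(86.8)), 3 * se_scale)
  expect_lt(abs(log(fit$shape) - log(0.617)), 3 * se_shape)
  expect_equal(fit$failure_type, "early")
  ## independent cross-check against fitdistrplus
  skip_if_not_installed("fitdistrplus")
  ref <- fitdistrplus::fitdist(x, "weibull",
                               start = list(shape = 1, scale = 50))
  expect_equal(fit$shape, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(fit$scale, unname(ref$estimate["scale"]), tolerance = 1e-3)
  ## optimizer sanity: the MLE cannot be beaten by the truth
  expect_gte(fit$loglik, faersignal:::weibull_loglik(x, 86.8, 0.617))
})

test_that("median and IQR use the standard quantile definition", {
  set.seed(1)
  x <- c(10, 44, 155, rweibull(100, 0.6, 80))
  fit <- fit_weibull(x)
  qs <- unname(quantile(x, c(0.25, 0.5, 0.75)))
  expect_equal(fit$median_days, qs[2])
  expect_equal(fit$iqr, qs[c(1, 3)])
  expect_lte(fit$iqr[1], fit$median_days)
  expect_lte(fit$median_days, fit$iqr[2])
})

test_that("failure classification follows the shape interval", {
  mk <- function(lo, hi) list(shape = sqrt(lo * hi), shape_ci = c(lo, hi))
  expect_equal(classify_failure(mk(0.598, 0.635)), "early")
  expect_equal(classify_failure(mk(0.9, 1.2)), "random")
  expect_equal(classify_failure(mk(1.1, 1.4)), "wear-out")
})

test_that("failure classification is invariant to time-unit rescaling", {
  set.seed(5)
  x <- rweibull(2000, shape = 0.7, scale = 60)
  fd <- fit_weibull(x)
  fw <- fit_weibull(x / 7)
  expect_equal(fw$shape, fd$shape, tolerance = 1e-6)
  expect_equal(fw$scale * 7, fd$scale, tolerance = 1e-4)
  expect_equal(classify_failure(fw), classify_failure(fd))
})

test_that("onset histograms and the ECDF match brute-force counting", {
  oc <- onset_curves(c(5, 20, 40), bin_edges = c(0, 30, 60))
  expect_equal(oc$hist$count, c(2L, 1L))
  expect_equal(oc$ecdf[days == max(days), cum_frac], 1)

  set.seed(9)
  for (i in 1:1000) {
    x <- sample.int(300, sample(3:40, 1), replace = TRUE)
    t0 <- sample.int(300, 1)
    oc <- onset_curves(x, bin_edges = c(0, 100, 200, 300))
    ec <- oc$ecdf
    val <- if (any(ec$days <= t0)) ec[days <= t0, cum_frac[.N]] else 0
    expect_equal(val, mean(x <= t0))
  }
  expect_error(onset_curves(numeric(0)), "empty")
})
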