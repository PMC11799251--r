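test_that("duplicate injection is controlled by duplicate_frac", {
  cfg <- sim_config(n_cases = 500L, duplicate_frac = 0, seed = 3L)
  db <- generate_database(cfg)
  expect_equal(uniqueN(db$tables$demo$caseid), 500L)
  expect_equal(nrow(db$tables$demo), 500L)

  cfg2 <- sim_config(n_cases = 500L, duplicate_frac = 0.2, seed = 3L)
  db2 <- generate_database(cfg2)
  expect_equal(uniqueN(db2$tables$demo$caseid), 500L)
  expect_equal(nrow(db2$tables$demo), 600L)
  expect_equal(nrow(db2$truth$duplicates), 100L)
})

test_that("generation is deterministic in the seed and varies across seeds", {
  cfg <- sim_config(n_cases = 300L, seed = 7L)
  a <- generate_database(cfg)
  b <- generate_database(cfg)
  expect_identical(a$tables, b$tables)
  cfg8 <- sim_config(n_cases = 300L, seed = 8L)
  c <- generate_database(cfg8)
  expect_false(identical(a$tables$demo, c$tables$demo))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(duplicate_frac = 1.2), "fraction")
  expect_error(sim_config(age_bin_probs = c(0.5, 0.4)), "sum to 1")
  expect_error(sim_config(planted_signals = data.frame(pt_id = 999, rr = 2)),
               "out of range")
  expect_error(sim_config(planted_signals = data.frame(pt_id = 1, rr = 0.5)),
               ">= 1")
  expect_error(sim_config(planted_signals = data.frame(pt_id = 1, rr = 500)),
               "RR too large")
  expect_error(sim_config(pts_per_case_mean = 0.5), "> 1")
})

test_that("planted per-case report rates converge to the configured RR", {
  fx <- planted_db_50k()
  truth <- fx$truth
  tgt <- truth$target_caseids
  ev <- fx$db$events
  n_t <- length(tgt)
  for (j in planted_pt_ids) {
    ptn <- sprintf("PT_%04d", j)
    p_true <- 4 * truth$background_rate[[ptn]]
    p_hat <- sum(ev$pt == ptn & ev$caseid %in% tgt) / n_t
    se <- sqrt(p_true * (1 - p_true) / n_t)
    expect_lt(abs(p_hat - p_true), 3 * se)
  }
})

test_that("an all-null database shows no disproportionality beyond chance", {
  fx <- null_db_50k()
  spec <- cohort_spec()
  cohort <- select_cohort(fx$db, spec)
  uni <- build_pair_universe(fx$db, cohort$cases$caseid)
  tab <- all_tables(uni)
  ok <- tab[a > 0 & b > 0 & c > 0 & d > 0]
  ## 99.9% Wald band around log OR = 0 under the independence null
  z <- with(ok, abs(log(as.numeric(a) * d / (as.numeric(b) * c))) /
              sqrt(1 / a + 1 / b + 1 / c + 1 / d))
  expect_true(all(z < 3.2905))
})

test_that("injected duplicate groups are exactly recoverable from CASEID", {
  fx <- planted_db_50k()
  demo <- fx$raw$tables$demo
  grp <- demo[, .N, by = caseid][N > 1, caseid]
  expect_setequal(grp, fx$truth$duplicates$caseid)
})

test_that("onset times follow the configured Weibull law", {
  raw <- generate_database(sim_config(n_cases = 25000L,
                                      target_drug_share = 0.45,
                                      duplicate_frac = 0, seed = 99L))
  x <- raw$truth$tto$raw_days
  expect_gte(length(x), 10000)
  ks <- suppressWarnings(stats::ks.test(x, "pweibull", shape = 0.617,
                                        scale = 86.8))
  expect_lt(unname(ks$statistic), 1.628 / sqrt(length(x)))

  ## emitted day values follow the exact ceiling-discretized law
  days <- pmax(1, ceiling(x))
  dgrid <- 1:1000
  gap <- max(abs(ecdf(days)(dgrid) - stats::pweibull(dgrid, 0.617, 86.8)))
  expect_lt(gap, 1.628 / sqrt(length(x)))
})

test_that("contingency ensembles respect margin constraints", {
  tabs <- generate_contingency_ensemble(1000, seed = 1)
  expect_equal(nrow(tabs), 1000L)
  expect_true(all(tabs$a >= 0 & tabs$b >= 0 & tabs$c >= 0 & tabs$d >= 0))
  expect_true(all(tabs$a <= pmin(tabs$a + tabs$b, tabs$a + tabs$c)))

  again <- generate_contingency_ensemble(1000, seed = 1)
  expect_identical(tabs, again)

  sym <- generate_contingency_ensemble(
    5, margin_ranges = list(n = c(400L, 400L), row1 = c(200L, 200L),
                            col1 = c(200L, 200L), a = c(100L, 100L)),
    seed = 2)
  expect_true(all(sym$a == 100 & sym$b == 100 & sym$c == 100 & sym$d == 100))
  expect_true(all(ror_stats(sym$a, sym$b, sym$c, sym$d)$ror == 1))

  expect_error(generate_contingency_ensemble(0), "positive")
})
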