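make_sel_db <- function() {
  tiny_case_db(
    cases = data.table(
      caseid = c("k1", "k2", "k3", "k4"),
      primaryid = paste0("p", 1:4),
      sex = c("F", "M", "F", "missing"),
      age_years = c(17, 30, 70, NA),
      reporter = c("CN", "MD", "CN", "missing"),
      country = c("US", "US", "GB", "US"),
      fda_dt = c("20210315", "20210315", "20200401", "20210315"),
      fda_quarter = c("2021Q1", "2021Q1", "2020Q2", "2021Q1"),
      event_dt = "20210101"),
    drugs = data.table(
      caseid = c("k1", "k2", "k3", "k4", "k4"),
      drugname = c("KESIMPTA PEN", "OFATUMUMAB", "KESIMPTA", "BKG", "OFATUMUMAB"),
      prod_ai = c("OFATUMUMAB", "OFATUMUMAB", "OFATUMUMAB", "BKG", "OFATUMUMAB"),
      role_cod = c("PS", "C", "PS", "PS", "C"),
      start_dt = NA_character_),
    events = data.table(caseid = c("k1", "k2", "k3", "k4"),
                        pt = c("HEADACHE", "FEVER", "RASH", "NAUSEA"))
  )
}

test_that("cohort selection enforces synonym match, role and window", {
  db <- make_sel_db()
  spec <- cohort_spec(window = c("2020Q3", "2024Q2"))
  sel <- select_cohort(db, spec)
  ## k1: substring match on free-text name, PS, in window -> kept
  ## k2/k4: target drug only as concomitant -> dropped
  ## k3: PS match but 2020Q2 predates the window -> dropped
  expect_equal(sel$cases$caseid, "k1")
  expect_error(cohort_spec(target_drug_synonyms = character(0)), "non-empty")
})

test_that("co-medication exclusion drops cases by drug name in any role", {
  db <- tiny_case_db(
    cases = data.table(caseid = c("a", "b"), primaryid = c("1", "2"),
                       sex = "F", age_years = 30, reporter = "CN",
                       country = "US", fda_dt = "20210101",
                       fda_quarter = "2021Q1", event_dt = "20210101"),
    drugs = data.table(caseid = c("a", "a", "b"),
                       drugname = c("KESIMPTA", "BACLOFEN", "KESIMPTA"),
                       prod_ai = c("OFATUMUMAB", "BACLOFEN", "OFATUMUMAB"),
                       role_cod = c("PS", "C", "PS"),
                       start_dt = NA_character_),
    events = data.table(caseid = c("a", "b"), pt = c("X", "Y")))
  res <- apply_comedication_exclusion(db, c("BACLOFEN"))
  expect_equal(res$kept$cases$caseid, "b")
  expect_equal(res$n_excluded, 1L)
  noop <- apply_comedication_exclusion(db, character(0))
  expect_identical(noop$kept, db)
  expect_equal(noop$n_excluded, 0L)
})

test_that("partitioning assigns each case to exactly one stratum", {
  db <- make_sel_db()
  parts <- partition_cohort(db, "age", age_bins("table1"))
  lab <- vapply(names(parts), function(nm) parts[[nm]]$cases$caseid[1], "")
  expect_equal(parts[["<18"]]$cases$caseid, "k1")
  expect_equal(parts[["18-65"]]$cases$caseid, "k2")
  expect_equal(parts[["66-85"]]$cases$caseid, "k3")
  expect_equal(parts[["missing"]]$cases$caseid, "k4")
  sizes <- vapply(parts, function(p) nrow(p$cases), 0L)
  expect_equal(sum(sizes), nrow(db$cases))

  bad_bins <- data.frame(label = c("18-65", "45-65"), lo = c(18, 45),
                         hi = c(65, 65))
  expect_error(partition_cohort(db, "age", bad_bins), "overlap")

  all_missing <- db
  all_missing$cases$sex <- "missing"
  pm <- partition_cohort(all_missing, "sex")
  expect_equal(names(pm), "missing")
  expect_equal(nrow(pm$missing$cases), 4L)
})

test_that("descriptives report per-characteristic percentages that sum to 100", {
  db <- tiny_case_db(
    cases = data.table(caseid = as.character(1:10), primaryid = as.character(1:10),
                       sex = c(rep("F", 7), rep("M", 2), "missing"),
                       age_years = NA_real_, reporter = "CN",
                       country = c(rep("US", 6), rep("GB", 3), "CA"),
                       fda_dt = "20210101", fda_quarter = "2021Q1",
                       event_dt = NA_character_),
    drugs = data.table(caseid = character(0), drugname = character(0),
                       prod_ai = character(0), role_cod = character(0),
                       start_dt = character(0)),
    events = data.table(caseid = as.character(1:10), pt = "X"))
  d <- describe_cohort(db, top_k_countries = 5)
  sex <- d[characteristic == "sex"]
  expect_equal(sex[level == "F", pct], 70)
  expect_equal(sex[level == "M", pct], 20)
  expect_equal(sex[level == "missing", pct], 10)
  for (ch in c("sex", "age", "reporter"))
    expect_equal(d[characteristic == ch, sum(pct)], 100, tolerance = 1e-10)
  ## 3 distinct countries with k = 5 -> 3 rows, count-descending
  expect_equal(d[characteristic == "country", level], c("US", "GB", "CA"))
  expect_error(describe_cohort(tiny_case_db(
    cases = data.table(), drugs = data.table(), events = data.table())),
    "empty")
})

test_that("demographic margins of a large synthetic run match the configuration", {
  fx <- null_db_50k()
  d <- describe_cohort(fx$db)
  n <- nrow(fx$db$cases)
  pf <- d[characteristic == "sex" & level == "F", pct] / 100
  se <- sqrt(0.734 * (1 - 0.734) / n)
  expect_lt(abs(pf - 0.734), 3 * se)
})

test_that("case-level filters commute with partitioning", {
  raw <- generate_database(sim_config(n_cases = 2000L, seed = 11L))
  db <- suppressMessages(assemble_cases(raw$tables$demo, raw$tables$drug,
                                        raw$tables$reac, raw$tables$ther))
  spec <- cohort_spec()
  path1 <- lapply(partition_cohort(db, "sex"), function(p)
    apply_comedication_exclusion(select_cohort(p, spec),
                                 spec$excluded_comedications)$kept)
  sel <- apply_comedication_exclusion(select_cohort(db, spec),
                                      spec$excluded_comedications)$kept
  path2 <- partition_cohort(sel, "sex")
  for (nm in names(path2)) {
    expect_setequal(path1[[nm]]$cases$caseid, path2[[nm]]$cases$caseid)
  }
})
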