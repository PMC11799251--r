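test_that("the '$'-delimited dialect is parsed with missing-field semantics", {
  f <- write_faers_lines(c(
    "primaryid$caseid$fda_dt$sex$age$age_cod$occp_cod$reporter_country",
    "101$11$20210101$F$34$YR$CN$US",
    "102$12$20210202$M$4.1$DEC$MD$"
  ))
  d <- read_faers_table(f, "demo")
  expect_equal(nrow(d), 2L)
  expect_equal(d$sex, c("F", "M"))
  ## trailing empty field is missing, not empty string
  expect_true(is.na(d$reporter_country[2]))
  expect_equal(attr(d, "skipped"), 0L)
})

test_that("malformed lines are skipped and counted", {
  lines <- c("primaryid$caseid$fda_dt",
             sprintf("%d$%d$20210101", 100 + 1:100, 1:100))
  lines[51] <- "broken$line"
  f <- write_faers_lines(lines)
  expect_message(d <- read_faers_table(f, "demo"), "skipped 1")
  expect_equal(nrow(d), 99L)
  expect_equal(attr(d, "skipped"), 1L)
})

test_that("unknown headers and unreadable files are hard errors", {
  f <- write_faers_lines(c("foo$bar", "1$2"))
  expect_error(read_faers_table(f, "demo"), "schema")
  expect_error(read_faers_table(file.path(tempdir(), "no_such.txt"), "demo"),
               "cannot read")
})

test_that("deduplication keeps the latest FDA_DT, then the highest PRIMARYID", {
  demo <- data.table(caseid = "123",
                     primaryid = c("9001", "9000"),
                     fda_dt = c("20230101", "20230301"))
  expect_equal(deduplicate(demo)$primaryid, "9000")

  tie <- data.table(caseid = "123",
                    primaryid = c("9000", "9011"),
                    fda_dt = "20230101")
  expect_equal(deduplicate(tie)$primaryid, "9011")

  single <- data.table(caseid = "9", primaryid = "90", fda_dt = "20230101")
  expect_equal(deduplicate(single)$primaryid, "90")

  ## numeric comparison when both ids are all-digit ("10000" > "9999")
  num <- data.table(caseid = "5", primaryid = c("9999", "10000"),
                    fda_dt = "20230101")
  expect_equal(deduplicate(num)$primaryid, "10000")

  ## missing FDA_DT sorts lowest
  miss <- data.table(caseid = "7", primaryid = c("70", "71"),
                     fda_dt = c("20230101", NA))
  expect_equal(deduplicate(miss)$primaryid, "70")
})

test_that("deduplication is idempotent", {
  demo <- data.table(caseid = rep(as.character(1:50), each = 3),
                     primaryid = as.character(1000 + 1:150),
                     fda_dt = sprintf("202301%02d", sample.int(28, 150,
                                                               replace = TRUE)))
  once <- deduplicate(demo)
  twice <- deduplicate(once)
  expect_identical(once, twice)
})

test_that("case assembly joins, normalizes PTs and drops eventless cases", {
  demo <- data.table(primaryid = c("1", "2", "3"), caseid = c("a", "b", "z"),
                     fda_dt = "20210101", sex = c("F", "M", "F"),
                     age = "30", age_cod = "YR", occp_cod = "CN",
                     reporter_country = "US", event_dt = "20210101")
  drug <- data.table(primaryid = c("1", "2", "99"), caseid = c("a", "b", "q"),
                     drug_seq = "1", role_cod = "PS",
                     drugname = "KESIMPTA", prod_ai = "OFATUMUMAB")
  reac <- data.table(primaryid = c("1", "1", "1", "2"),
                     caseid = c("a", "a", "a", "b"),
                     pt = c("headache ", "HEADACHE", "fever", "rash"))
  db <- suppressMessages(assemble_cases(demo, drug, reac))
  ## duplicate PT collapses; case z has no events and is dropped
  expect_equal(sort(db$events[caseid == "a", pt]), c("FEVER", "HEADACHE"))
  expect_equal(db$events[, .N, by = caseid][order(caseid)]$N, c(2L, 1L))
  expect_equal(nrow(db$cases), 2L)
  expect_equal(db$log$n_no_event, 1L)
  expect_equal(db$log$n_orphan_drug, 1L)
  expect_equal(db$cases$age_years, c(30, 30))
})

test_that("write/read round trip recovers the ground-truth survivor set", {
  raw <- generate_database(sim_config(n_cases = 2000L, duplicate_frac = 0.1,
                                      seed = 5L))
  dir <- file.path(tempdir(), "roundtrip_fixture")
  write_faers_tables(raw, dir)
  db <- suppressMessages(read_faers_dir(dir))
  expect_equal(nrow(db$cases), 2000L)
  got <- db$cases[, paste(caseid, primaryid)]
  want <- raw$truth$survivors[, paste(caseid, primaryid)]
  expect_setequal(got, want)

  ## dedup of the raw demo table agrees with the generator's intent
  surv <- deduplicate(raw$tables$demo)
  expect_identical(surv[raw$truth$duplicates$caseid, primaryid, on = "caseid"],
                   raw$truth$duplicates$survivor)
})
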