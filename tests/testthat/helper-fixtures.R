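library(data.table)

## ---- shared synthetic databases (memoised: generated once per run) -------

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

## ten planted PTs at RR 4 among 210 PTs, 50k cases, 10% duplicates
planted_pt_ids <- c(5L, 27L, 49L, 71L, 93L, 115L, 137L, 159L, 181L, 203L)

planted_cfg_50k <- function() {
  sim_config(n_cases = 50000L, n_pts = 210L,
             planted_signals = data.frame(pt_id = planted_pt_ids, rr = 4),
             duplicate_frac = 0.1, seed = 20260925L)
}

planted_db_50k <- function() memo("planted_50k", {
  raw <- generate_database(planted_cfg_50k())
  db <- suppressMessages(assemble_cases(raw$tables$demo, raw$tables$drug,
                                        raw$tables$reac, raw$tables$ther))
  list(raw = raw, db = db, truth = raw$truth)
})

## all-null database (every RR = 1), 50k cases, seed 7
null_db_50k <- function() memo("null_50k", {
  raw <- generate_database(sim_config(n_cases = 50000L, n_pts = 200L,
                                      duplicate_frac = 0, seed = 7L))
  db <- suppressMessages(assemble_cases(raw$tables$demo, raw$tables$drug,
                                        raw$tables$reac, raw$tables$ther))
  list(raw = raw, db = db, truth = raw$truth)
})

## ---- tiny hand-built fixtures --------------------------------------------

## a minimal case database built directly (post-assembly shape)
tiny_case_db <- function(cases, drugs, events) {
  structure(list(cases = as.data.table(cases),
                 drugs = as.data.table(drugs),
                 events = as.data.table(events),
                 log = list()),
            class = "faers_case_db")
}

## write '$'-delimited FAERS fixture lines to a temp file
write_faers_lines <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

## four cases: two target (KESIMPTA PS), two background; used by the
## contingency enumeration example
enumeration_db <- function() {
  tiny_case_db(
    cases = data.table(caseid = c("c1", "c2", "c3", "c4"),
                       primaryid = paste0("p", 1:4),
                       sex = c("F", "M", "F", "F"),
                       age_years = c(30, 40, 50, 60),
                       reporter = "CN", country = "US",
                       fda_dt = "20210105", fda_quarter = "2021Q1",
                       event_dt = "20210101"),
    drugs = data.table(caseid = c("c1", "c2", "c3", "c4"),
                       drugname = c("KESIMPTA", "KESIMPTA", "BKG1", "BKG2"),
                       prod_ai = c("OFATUMUMAB", "OFATUMUMAB", "BKG1", "BKG2"),
                       role_cod = "PS", start_dt = NA_character_),
    events = data.table(caseid = c("c1", "c1", "c2", "c3", "c4", "c4"),
                        pt = c("HEADACHE", "FEVER", "HEADACHE",
                               "HEADACHE", "FEVER", "RASH"))
  )
}

## independent brute-force 2x2 oracles (log-space arithmetic on purpose:
## a different computational path than the implementation)
oracle_ror <- function(a, b, c, d) {
  est <- exp(log(a) + log(d) - log(b) - log(c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(est = est, lo = exp(log(est) - 1.96 * se), hi = exp(log(est) + 1.96 * se))
}
oracle_prr <- function(a, b, c, d) {
  exp(log(a) - log(a + b) - log(c) + log(c + d))
}

## numerical-integration oracle for the MGPS posterior-mixture quantile:
## integrates the mixture density and inverts by bisection
oracle_mix_quantile <- function(q1, s1, r1, s2, r2, p = 0.05) {
  dens <- function(x) q1 * stats::dgamma(x, s1, rate = r1) +
    (1 - q1) * stats::dgamma(x, s2, rate = r2)
  cdf_num <- function(x) stats::integrate(dens, 0, x, rel.tol = 1e-12,
                                          abs.tol = 1e-14)$value
  lo <- 0
  hi <- max(stats::qgamma(0.999, s1, rate = r1),
            stats::qgamma(0.999, s2, rate = r2))
  while (cdf_num(hi) < p) hi <- hi * 2
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (cdf_num(mid) > p) hi <- mid else lo <- mid
    if (hi - lo < 1e-9 * max(1, mid)) break
  }
  (lo + hi) / 2
}
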