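## Synthetic spontaneous-reporting-system (SRS) generator.
##
## Emulates a multi-quarter FAERS extract with demographic strata, one
## primary-suspect drug per case, multiple preferred terms (PTs) per case,
## injected duplicate case versions, partial therapy dates, planted
## drug-event signals of known relative risk, and Weibull-distributed
## onset times -- together with a ground-truth record so every downstream
## stage can be validated without any download.

#' Build and validate a simulation configuration
#'
#' The defaults encode the study conditions of a recent-approval
#' biologic in FAERS: a 16-quarter window, a mostly-female cohort with
#' heavy age missingness, consumer-dominated reporting, and an
#' early-failure (shape < 1) onset-time law. See the methods vignette for
#' the rationale behind each value.
#'
#' Background drug-event co-occurrence is generated under independence:
#' each case draws a zero-truncated Poisson number of PT slots, filled
#' i.i.d. from a fixed PT frequency vector and de-duplicated, so "no
#' signal" is the provable null. A planted signal with relative risk
#' `rr` raises the per-case report probability of that PT among
#' target-drug cases from its background value `q` to `rr * q`
#' (configurations where `rr * q > 1` are rejected).
#'
#' @param n_cases number of distinct cases (before duplicate injection).
#' @param n_background_drugs number of comparator primary-suspect drugs.
#' @param n_pts number of distinct preferred terms.
#' @param target_drug_share fraction of cases whose primary-suspect drug is
#'   the target drug.
#' @param planted_signals `NULL`, or a data.frame with columns `pt_id`
#'   (1-based index `<= n_pts`) and `rr` (relative risk, `>= 1`).
#' @param pts_per_case_mean mean number of PT slots per case (zero-truncated
#'   Poisson; must be > 1).
#' @param pt_weight_skew exponent `s >= 0` of the background PT frequency
#'   vector `w_j` proportional to `j^-s`; 0 gives uniform PTs.
#' @param sex_female_frac,missing_demo_frac marginal probabilities of sex
#'   `F` and missing sex; `M` takes the remainder.
#' @param age_bin_probs probabilities over the age bins `<18`, `18-65`,
#'   `66-85`, `>85`, conditional on age being reported; must sum to 1.
#' @param age_missing_frac probability that age is missing.
#' @param reporter_probs named probabilities over `CN`, `HP`, `MD`, `PH` and
#'   `missing`.
#' @param country_probs named probabilities over reporter country codes;
#'   the name `OTHER` spreads uniformly over a fixed set of minor codes.
#' @param duplicate_frac fraction of cases re-emitted as a second version
#'   with the same CASEID, a new PRIMARYID and a perturbed FDA receipt date.
#' @param comed_frac fraction of cases carrying one concomitant (role `C`)
#'   co-medication drawn from `comed_names`.
#' @param comed_names co-medication name pool.
#' @param tto_scale_days,tto_shape Weibull scale (days) and shape of the
#'   onset-time law for target-drug cases.
#' @param date_window inclusive quarter window `c(first, last)`.
#' @param partial_date_frac fraction of therapy start dates truncated to
#'   `YYYYMM`, exercising the completeness filter of the onset analysis.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_cases = 10000L,
                       n_background_drugs = 50L,
                       n_pts = 200L,
                       target_drug_share = 0.10,
                       planted_signals = NULL,
                       pts_per_case_mean = 3,
                       pt_weight_skew = 0.5,
                       sex_female_frac = 0.734,
                       missing_demo_frac = 0.046,
                       age_bin_probs = c("<18" = 0.0016, "18-65" = 0.9493,
                                         "66-85" = 0.0488, ">85" = 0.0003),
                       age_missing_frac = 0.515,
                       reporter_probs = c(CN = 0.828, HP = 0.080, MD = 0.077,
                                          PH = 0.008, missing = 0.007),
                       country_probs = c(US = 0.798, GB = 0.030, CA = 0.021,
                                         DE = 0.014, AU = 0.013, OTHER = 0.124),
                       duplicate_frac = 0.10,
                       comed_frac = 0.15,
                       comed_names = c("GABAPENTIN", "BACLOFEN", "DULOXETINE",
                                       "VITAMIN B", "VITAMIN D"),
                       tto_scale_days = 86.8,
                       tto_shape = 0.617,
                       date_window = c("2020Q3", "2024Q2"),
                       partial_date_frac = 0.30,
                       seed = 1L) {
  cfg <- list(
    n_cases = as.integer(n_cases),
    n_background_drugs = as.integer(n_background_drugs),
    n_pts = as.integer(n_pts),
    target_drug_share = target_drug_share,
    planted_signals = planted_signals,
    pts_per_case_mean = pts_per_case_mean,
    pt_weight_skew = pt_weight_skew,
    sex_female_frac = sex_female_frac,
    missing_demo_frac = missing_demo_frac,
    age_bin_probs = age_bin_probs,
    age_missing_frac = age_missing_frac,
    reporter_probs = reporter_probs,
    country_probs = country_probs,
    duplicate_frac = duplicate_frac,
    comed_frac = comed_frac,
    comed_names = comed_names,
    tto_scale_days = tto_scale_days,
    tto_shape = tto_shape,
    date_window = date_window,
    partial_date_frac = partial_date_frac,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

## mean of a zero-truncated Poisson with rate lambda
ztpois_mean <- function(lambda) lambda / (1 - exp(-lambda))

## rate of a zero-truncated Poisson with a given mean (> 1)
ztpois_lambda <- function(mean) {
  stopifnot(mean > 1)
  uniroot(function(l) ztpois_mean(l) - mean, c(1e-8, 10 * mean),
          tol = 1e-12)$root
}

## draw n zero-truncated Poisson variates by inverse CDF on (P(0), 1]
rztpois <- function(n, lambda) {
  u <- runif(n, min = exp(-lambda), max = 1)
  stats::qpois(u, lambda)
}

## background PT frequency vector w_j prop. to j^-skew
pt_weights <- function(n_pts, skew) {
  w <- seq_len(n_pts)^(-skew)
  w / sum(w)
}

#' Per-case background report probability of each preferred term
#'
#' Under the generator's null model (zero-truncated Poisson number of PT
#' slots, i.i.d. weighted draws, de-duplication) the probability that PT j
#' appears on a case is `1 - G(1 - w_j)` with `G` the probability
#' generating function of the slot count.
#'
#' @param config a [sim_config()].
#' @return numeric vector of length `n_pts`.
#' @export
background_pt_rate <- function(config) {
  lambda <- ztpois_lambda(config$pts_per_case_mean)
  w <- pt_weights(config$n_pts, config$pt_weight_skew)
  1 - (exp(lambda * (1 - w)) - 1) / (exp(lambda) - 1)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_cases >= 1L, cfg$n_background_drugs >= 1L, cfg$n_pts >= 1L)
  fr <- c(cfg$target_drug_share, cfg$sex_female_frac, cfg$missing_demo_frac,
          cfg$age_missing_frac, cfg$duplicate_frac, cfg$comed_frac,
          cfg$partial_date_frac)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (cfg$target_drug_share <= 0 || cfg$target_drug_share >= 1)
    stop("target_drug_share must lie strictly inside (0, 1)")
  if (cfg$duplicate_frac >= 1) stop("duplicate_frac must be < 1")
  if (abs(sum(cfg$age_bin_probs) - 1) > 1e-9)
    stop("age_bin_probs must sum to 1")
  if (abs(sum(cfg$reporter_probs) - 1) > 1e-9)
    stop("reporter_probs must sum to 1")
  if (abs(sum(cfg$country_probs) - 1) > 1e-9)
    stop("country_probs must sum to 1")
  if (cfg$pts_per_case_mean <= 1) stop("pts_per_case_mean must be > 1")
  if (cfg$tto_scale_days <= 0 || cfg$tto_shape <= 0)
    stop("Weibull scale and shape must be positive")
  quarter_seq(cfg$date_window[1], cfg$date_window[2])  # validates ordering
  ps <- cfg$planted_signals
  if (!is.null(ps)) {
    ps <- as.data.frame(ps)
    if (!all(c("pt_id", "rr") %in% names(ps)))
      stop("planted_signals needs columns pt_id and rr")
    if (any(ps$pt_id < 1 | ps$pt_id > cfg$n_pts))
      stop("planted pt_id out of range")
    if (anyDuplicated(ps$pt_id)) stop("duplicate planted pt_id")
    if (any(ps$rr < 1)) stop("planted relative_risk must be >= 1")
    q <- background_pt_rate(cfg)
    if (any(ps$rr * q[ps$pt_id] > 1))
      stop("RR too large for base rate: planted report probability exceeds 1")
  }
  invisible(cfg)
}

minor_countries <- c("FR", "IT", "ES", "NL", "SE", "CH")

sample_cat <- function(n, probs) {
  lv <- names(probs)
  lv[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

#' Generate a synthetic FAERS-like database with known ground truth
#'
#' Emits DEMO/DRUG/REAC/THER tables in the FAERS column dialect together
#' with a `ground_truth` record: the per-PT true relative risk of the
#' target drug, the true Weibull onset-time parameters and raw draws, the
#' injected duplicate groups with their intended surviving PRIMARYID, and
#' the PT-to-SOC mapping used. Identical seeds give identical output.
#'
#' @param config a [sim_config()].
#' @return a list of class `srs_database` with elements `tables` (named
#'   list of data.tables `demo`, `drug`, `reac`, `ther`), `truth`, and
#'   `config`.
#' @export
generate_database <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_cases

  lambda <- ztpois_lambda(config$pts_per_case_mean)
  w <- pt_weights(config$n_pts, config$pt_weight_skew)
  q <- 1 - (exp(lambda * (1 - w)) - 1) / (exp(lambda) - 1)
  pt_names <- sprintf("PT_%04d", seq_len(config$n_pts))

  caseid <- 20000000 + seq_len(n)
  is_target <- runif(n) < config$target_drug_share

  ## --- events: background independence model -----------------------------
  k <- rztpois(n, lambda)
  slot_case <- rep.int(seq_len(n), k)
  slot_pt <- sample.int(config$n_pts, sum(k), replace = TRUE, prob = w)
  events <- unique(data.table(case = slot_case, pt_id = slot_pt))

  ## --- planted signals: extra inclusion among target cases ---------------
  rr_true <- rep(1, config$n_pts)
  if (!is.null(config$planted_signals)) {
    ps <- as.data.frame(config$planted_signals)
    rr_true[ps$pt_id] <- ps$rr
    tgt <- which(is_target)
    extra <- list()
    for (i in seq_len(nrow(ps))) {
      j <- ps$pt_id[i]
      p_extra <- (ps$rr[i] - 1) * q[j] / (1 - q[j])
      hit <- tgt[runif(length(tgt)) < p_extra]
      if (length(hit))
        extra[[length(extra) + 1L]] <- data.table(case = hit, pt_id = j)
    }
    if (length(extra))
      events <- unique(rbind(events, rbindlist(extra)))
  }
  setkey(events, case, pt_id)

  ## --- demographics -------------------------------------------------------
  p_f <- config$sex_female_frac
  p_miss <- config$missing_demo_frac
  sex <- sample_cat(n, c(F = p_f, M = 1 - p_f - p_miss, missing = p_miss))
  sex[sex == "missing"] <- ""

  age_missing <- runif(n) < config$age_missing_frac
  bin <- sample_cat(n, config$age_bin_probs)
  age_lo <- c("<18" = 6, "18-65" = 18, "66-85" = 66, ">85" = 86)[bin]
  age_hi <- c("<18" = 17, "18-65" = 65, "66-85" = 85, ">85" = 95)[bin]
  age_yr <- floor(runif(n, age_lo, age_hi + 1))
  use_dec <- runif(n) < 0.05
  age_val <- ifelse(age_missing, "",
                    ifelse(use_dec, formatC(age_yr / 10, format = "fg"),
                           as.character(age_yr)))
  age_cod <- ifelse(age_missing, "", ifelse(use_dec, "DEC", "YR"))

  occp <- sample_cat(n, config$reporter_probs)
  occp[occp == "missing"] <- ""
  country <- sample_cat(n, config$country_probs)
  other <- country == "OTHER"
  country[other] <- minor_countries[sample.int(length(minor_countries),
                                               sum(other), replace = TRUE)]

  ## --- dates ---------------------------------------------------------------
  win_first <- quarter_bounds(config$date_window[1])$first
  win_last <- quarter_bounds(config$date_window[2])$last
  n_days <- as.integer(win_last - win_first) + 1L
  event_date <- win_first + floor(runif(n, 0, n_days))

  tto_raw <- rweibull(n, shape = config$tto_shape, scale = config$tto_scale_days)
  tto_days <- pmax(1L, as.integer(ceiling(tto_raw)))
  start_date <- rep(as.Date(NA), n)
  start_date[is_target] <- event_date[is_target] - tto_days[is_target]
  bkg_lag <- 1L + floor(runif(n, 0, 365))
  start_date[!is_target] <- event_date[!is_target] - bkg_lag[!is_target]

  fda_date <- pmin(event_date + floor(runif(n, 0, 46)), win_last)

  start_str <- format_faers_date(start_date)
  partial <- runif(n) < config$partial_date_frac
  start_str[partial] <- substr(start_str[partial], 1, 6)

  ## --- drugs ---------------------------------------------------------------
  target_pool <- c("OFATUMUMAB", "KESIMPTA", "KESIMPTA PEN")
  bkg_names <- sprintf("BKGDRUG_%03d", seq_len(config$n_background_drugs))
  ps_name <- character(n)
  ps_ai <- character(n)
  ps_name[is_target] <- target_pool[sample.int(3, sum(is_target),
                                               replace = TRUE,
                                               prob = c(0.5, 0.3, 0.2))]
  ps_ai[is_target] <- "OFATUMUMAB"
  bidx <- sample.int(config$n_background_drugs, sum(!is_target), replace = TRUE)
  ps_name[!is_target] <- bkg_names[bidx]
  ps_ai[!is_target] <- bkg_names[bidx]

  has_comed <- runif(n) < config$comed_frac
  comed <- rep(NA_character_, n)
  comed[has_comed] <- config$comed_names[
    sample.int(length(config$comed_names), sum(has_comed), replace = TRUE)]

  ## --- assemble primary version tables ------------------------------------
  pid1 <- caseid * 10 + 1
  demo <- data.table(
    primaryid = as.character(pid1),
    caseid = as.character(caseid),
    fda_dt = format_faers_date(fda_date),
    event_dt = format_faers_date(event_date),
    sex = sex, age = age_val, age_cod = age_cod,
    occp_cod = occp, reporter_country = country
  )
  drug <- data.table(
    primaryid = as.character(rep(pid1, 1 + has_comed)),
    caseid = as.character(rep(caseid, 1 + has_comed)),
    drug_seq = "1", role_cod = "PS",
    drugname = ps_name[rep(seq_len(n), 1 + has_comed)],
    prod_ai = ps_ai[rep(seq_len(n), 1 + has_comed)]
  )
  ## rows beyond the first per case are the concomitant co-medication
  dup_rows <- which(duplicated(drug$primaryid))
  drug[dup_rows, `:=`(drug_seq = "2", role_cod = "C",
                      drugname = comed[has_comed],
                      prod_ai = comed[has_comed])]
  reac <- data.table(
    primaryid = as.character(caseid[events$case] * 10 + 1),
    caseid = as.character(caseid[events$case]),
    pt = pt_names[events$pt_id]
  )
  ther <- data.table(
    primaryid = as.character(pid1),
    caseid = as.character(caseid),
    dsg_drug_seq = "1",
    start_dt = start_str
  )

  ## --- duplicate injection -------------------------------------------------
  n_dup <- as.integer(round(config$duplicate_frac * n))
  dup_groups <- data.table(caseid = character(0), primaryid_v1 = character(0),
                           primaryid_v2 = character(0), survivor = character(0))
  if (n_dup > 0) {
    di <- sort(sample.int(n, n_dup))
    same_dt <- runif(n_dup) < 0.3
    delta <- ifelse(same_dt, 0L,
                    sample(c(-30:-1, 1:30), n_dup, replace = TRUE))
    fda2 <- pmin(pmax(fda_date[di] + delta, win_first), win_last)
    pid2 <- caseid[di] * 10 + 2
    demo2 <- demo[di]
    demo2[, `:=`(primaryid = as.character(pid2),
                 fda_dt = format_faers_date(fda2))]
    old_pid <- as.character(caseid[di] * 10 + 1)
    remap <- setNames(as.character(pid2), old_pid)
    drug2 <- drug[primaryid %in% old_pid]
    drug2[, primaryid := remap[primaryid]]
    reac2 <- reac[primaryid %in% old_pid]
    reac2[, primaryid := remap[primaryid]]
    ther2 <- ther[primaryid %in% old_pid]
    ther2[, primaryid := remap[primaryid]]
    demo <- rbind(demo, demo2)
    drug <- rbind(drug, drug2)
    reac <- rbind(reac, reac2)
    ther <- rbind(ther, ther2)
    ## v2 has the larger primaryid, so it survives unless its date is older
    surv <- ifelse(fda2 >= fda_date[di], as.character(pid2), old_pid)
    dup_groups <- data.table(caseid = as.character(caseid[di]),
                             primaryid_v1 = old_pid,
                             primaryid_v2 = as.character(pid2),
                             survivor = surv)
  }
  setkey(demo, caseid, primaryid)
  setkey(drug, caseid, primaryid, drug_seq)
  setkey(reac, caseid, primaryid, pt)
  setkey(ther, caseid, primaryid)

  survivors <- data.table(caseid = as.character(caseid),
                          primaryid = as.character(pid1))
  if (n_dup > 0)
    survivors[dup_groups, primaryid := i.survivor, on = "caseid"]
  setkey(survivors, caseid)

  n_soc <- max(5L, ceiling(config$n_pts / 20L))
  pt_to_soc <- data.table(
    pt = pt_names,
    soc = sprintf("SOC_%02d", (seq_len(config$n_pts) - 1L) %% n_soc + 1L)
  )

  truth <- list(
    rr_true = setNames(rr_true, pt_names),
    background_rate = setNames(q, pt_names),
    tto = list(scale = config$tto_scale_days, shape = config$tto_shape,
               raw_days = tto_raw[is_target]),
    duplicates = dup_groups,
    survivors = survivors,
    target_caseids = as.character(caseid[is_target]),
    pt_to_soc = pt_to_soc,
    n_cases = n
  )
  structure(list(tables = list(demo = demo, drug = drug, reac = reac,
                               ther = ther),
                 truth = truth, config = config),
            class = "srs_database")
}

#' Write a synthetic database in the FAERS ASCII dialect
#'
#' One `'$'`-delimited text file per table (header line, one record per
#' line), plus a JSON ground-truth sidecar and a two-column PT-to-SOC
#' mapping CSV.
#'
#' @param db an `srs_database` from [generate_database()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written file paths.
#' @export
write_faers_tables <- function(db, dir) {
  stopifnot(inherits(db, "srs_database"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(demo = file.path(dir, "DEMO.txt"),
             drug = file.path(dir, "DRUG.txt"),
             reac = file.path(dir, "REAC.txt"),
             ther = file.path(dir, "THER.txt"))
  for (nm in names(paths)) {
    fwrite(db$tables[[nm]], paths[nm], sep = "$", quote = FALSE,
           na = "", col.names = TRUE)
  }
  map_path <- file.path(dir, "pt_to_soc.csv")
  fwrite(db$truth$pt_to_soc, map_path)
  truth_path <- file.path(dir, "ground_truth.json")
  tr <- db$truth
  ## named vectors serialize as name/value frames so the JSON keeps the keys
  tr$rr_true <- data.frame(pt = names(tr$rr_true), rr = unname(tr$rr_true))
  tr$background_rate <- data.frame(pt = names(tr$background_rate),
                                   rate = unname(tr$background_rate))
  tr$survivors <- as.data.frame(tr$survivors)
  tr$duplicates <- as.data.frame(tr$duplicates)
  tr$pt_to_soc <- as.data.frame(tr$pt_to_soc)
  jsonlite::write_json(tr, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(paths, pt_to_soc = map_path, truth = truth_path))
}

#' Random ensemble of 2x2 contingency tables
#'
#' Draws tables by sampling the grand total, both first margins and then a
#' feasible `a` cell, so that every table satisfies
#' `a <= min(a + b, a + c)` and all cells are non-negative.
#'
#' @param n_tables number of tables (`>= 1`).
#' @param margin_ranges list with inclusive integer ranges: `n` for the
#'   grand total (default `c(200, 20000)`), optional `row1`, `col1` and `a`
#'   (clamped to feasibility).
#' @param seed integer seed.
#' @param positive_cells if `TRUE`, every cell is at least 1 (needed by the
#'   odds-ratio interval).
#' @return a `data.table` with columns `a`, `b`, `c`, `d`.
#' @export
generate_contingency_ensemble <- function(n_tables,
                                          margin_ranges = list(n = c(200L, 20000L)),
                                          seed = 1L,
                                          positive_cells = FALSE) {
  if (length(n_tables) != 1 || is.na(n_tables) || n_tables < 1)
    stop("n_tables must be a positive integer")
  rng_n <- margin_ranges$n %||% c(200L, 20000L)
  if (any(rng_n < 4)) stop("margin range for n must allow at least 4")
  set.seed(seed)
  draw_in <- function(rng) {
    if (rng[2] <= rng[1]) rep(rng[1], 1) else rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
  }
  out <- vector("list", n_tables)
  for (i in seq_len(n_tables)) {
    repeat {
      N <- draw_in(rng_n)
      r_rng <- margin_ranges$row1 %||% c(1L, N - 1L)
      c_rng <- margin_ranges$col1 %||% c(1L, N - 1L)
      row1 <- draw_in(c(max(r_rng[1], 1L), min(r_rng[2], N - 1L)))
      col1 <- draw_in(c(max(c_rng[1], 1L), min(c_rng[2], N - 1L)))
      lo <- max(0L, row1 + col1 - N)
      hi <- min(row1, col1)
      if (positive_cells) {
        lo <- max(lo, 1L, row1 + col1 - N + 1L)
        hi <- min(row1 - 1L, col1 - 1L)
      }
      a_rng <- margin_ranges$a
      if (!is.null(a_rng)) {
        lo <- max(lo, a_rng[1])
        hi <- min(hi, a_rng[2])
      }
      if (hi >= lo) break
    }
    a <- draw_in(c(lo, hi))
    out[[i]] <- data.table(a = a, b = row1 - a, c = col1 - a,
                           d = N - row1 - col1 + a)
  }
  rbindlist(out)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
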