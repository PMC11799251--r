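## End-to-end orchestration: main run, subgroup runs, sensitivity run.
## Every artifact is a plain CSV/JSON file; a machine-readable manifest
## records the configuration digest, the seed and the row count at every
## filter step, so identical configuration + seed implies an identical
## output bundle.

#' Assemble a run configuration
#'
#' Exactly one input source: a FAERS table directory, or a [sim_config()]
#' for a synthetic run.
#'
#' @param faers_dir directory of FAERS ASCII tables (with a
#'   `pt_to_soc.csv` mapping), or `NULL`.
#' @param sim a [sim_config()], or `NULL`.
#' @param cohort a [cohort_spec()].
#' @param pt_to_soc optional PT-to-SOC mapping data.frame; defaults to the
#'   `pt_to_soc.csv` beside the input (synthetic runs carry their own).
#' @param chi2_correct Yates correction for the PRR chi-square.
#' @param top_k number of rows in the ranked PT signal table.
#' @param subgroup_by strata for [run_subgroups()]: `"sex"`, `"age"` or both.
#' @param age_bin_preset [age_bins()] preset for age subgroups.
#' @param out_dir output directory.
#' @param seed integer seed governing all randomness (simulation only).
#' @return a `run_config` list.
#' @export
run_config <- function(faers_dir = NULL, sim = NULL,
                       cohort = cohort_spec(),
                       pt_to_soc = NULL,
                       chi2_correct = TRUE,
                       top_k = 50L,
                       subgroup_by = "sex",
                       age_bin_preset = "subgroup",
                       out_dir = tempfile("faersignal_run_"),
                       seed = 1L) {
  if (is.null(faers_dir) == is.null(sim))
    stop("exactly one of faers_dir or sim must be given")
  structure(list(faers_dir = faers_dir, sim = sim, cohort = cohort,
                 pt_to_soc = pt_to_soc, chi2_correct = chi2_correct,
                 top_k = top_k, subgroup_by = subgroup_by,
                 age_bin_preset = age_bin_preset,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

## deterministic digest of the configuration (seed included)
config_digest <- function(config) {
  cfg <- config
  cfg$out_dir <- NULL
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  as.character(tools::md5sum(local({
    f <- tempfile()
    writeLines(json, f)
    f
  })))
}

## load (or generate) the raw inputs and assemble the cleaned database
load_inputs <- function(config) {
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed
    db_raw <- generate_database(sim)
    dir <- file.path(config$out_dir, "raw")
    write_faers_tables(db_raw, dir)
    truth <- db_raw$truth
  } else {
    dir <- config$faers_dir
    truth <- NULL
  }
  demo <- read_faers_table(file.path(dir, "DEMO.txt"), "demo")
  drug <- read_faers_table(file.path(dir, "DRUG.txt"), "drug")
  reac <- read_faers_table(file.path(dir, "REAC.txt"), "reac")
  ther_path <- file.path(dir, "THER.txt")
  ther <- if (file.exists(ther_path)) read_faers_table(ther_path, "ther") else NULL
  map <- config$pt_to_soc
  map_path <- file.path(dir, "pt_to_soc.csv")
  if (is.null(map) && file.exists(map_path)) map <- fread(map_path)
  list(db = assemble_cases(demo, drug, reac, ther),
       n_raw_versions = nrow(demo), pt_to_soc = map, truth = truth)
}

#' Run the main end-to-end analysis
#'
#' Generates or loads the input tables, deduplicates and assembles cases,
#' selects the cohort, applies the co-medication exclusion, builds the
#' PT- and SOC-level pair universes against the full-database comparator,
#' scores all four disproportionality statistics, fits the onset-time
#' Weibull model, and writes descriptives, signal tables, the TTO summary
#' and a manifest under `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory artifacts (`db`,
#'   `cohort`, `descriptives`, `soc_signals`, `pt_signals`, `pt_ranked`,
#'   `tto`, `weibull`, `manifest`, `truth`).
#' @export
run_main <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- load_inputs(config)
  db <- inp$db

  cohort <- select_cohort(db, config$cohort)
  if (nrow(cohort$cases) == 0) stop("stage cohort: no cases selected")
  excl <- apply_comedication_exclusion(cohort,
                                       config$cohort$excluded_comedications)

  desc <- describe_cohort(cohort)

  uni_pt <- build_pair_universe(db, cohort$cases$caseid, level = "PT")
  prior <- fit_mgps_prior(all_tables(uni_pt))
  pt_sig <- signal_table(uni_pt, prior, chi2_correct = config$chi2_correct)
  pt_rank <- rank_report(pt_sig, config$top_k)

  soc_sig <- NULL
  if (!is.null(inp$pt_to_soc)) {
    uni_soc <- aggregate_to_soc(uni_pt, inp$pt_to_soc)
    soc_sig <- signal_table(uni_soc, prior, chi2_correct = config$chi2_correct)
  }

  tto <- compute_tto(cohort, config$cohort$target_drug_synonyms,
                     config$cohort$role_required)
  wfit <- if (tto$n_usable >= 3) fit_weibull(tto) else NULL

  manifest <- list(
    config_digest = config_digest(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("faersignal")),
    counts = list(raw_versions = inp$n_raw_versions,
                  deduplicated_cases = nrow(db$cases),
                  cohort = nrow(cohort$cases),
                  after_comedication_exclusion = nrow(excl$kept$cases),
                  n_excluded_comedication = excl$n_excluded,
                  tto_usable = tto$n_usable,
                  tto_excluded_missing = tto$n_excluded_missing,
                  tto_excluded_nonpositive = tto$n_excluded_nonpositive)
  )

  fwrite(desc, file.path(config$out_dir, "descriptives.csv"))
  fwrite(pt_sig, file.path(config$out_dir, "pt_signals.csv"))
  fwrite(pt_rank, file.path(config$out_dir, "pt_signals_top.csv"))
  if (!is.null(soc_sig))
    fwrite(soc_sig, file.path(config$out_dir, "soc_signals.csv"))
  if (!is.null(wfit)) {
    tt <- data.table(n = wfit$n, median_days = wfit$median_days,
                     q1 = wfit$iqr[1], q3 = wfit$iqr[2],
                     scale = wfit$scale, scale_lo = wfit$scale_ci[1],
                     scale_hi = wfit$scale_ci[2],
                     shape = wfit$shape, shape_lo = wfit$shape_ci[1],
                     shape_hi = wfit$shape_ci[2],
                     failure_type = wfit$failure_type)
    fwrite(tt, file.path(config$out_dir, "tto_summary.csv"))
    oc <- onset_curves(tto)
    fwrite(oc$hist, file.path(config$out_dir, "onset_hist.csv"))
    fwrite(oc$ecdf, file.path(config$out_dir, "onset_ecdf.csv"))
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(db = db, cohort = cohort, exclusion = excl,
                 descriptives = desc, pt_signals = pt_sig,
                 pt_ranked = pt_rank, soc_signals = soc_sig,
                 prior = prior, tto = tto, weibull = wfit,
                 manifest = manifest, truth = inp$truth))
}

#' Subgroup (stratified) signal detection
#'
#' Re-runs the disproportionality analysis inside each stratum, with the
#' comparator restricted to the same stratum so that stratum composition
#' cannot confound the contrast. Strata with no target case are skipped
#' with a warning.
#'
#' @param config a [run_config()].
#' @param main optional result of [run_main()] on the same config (reused
#'   to avoid recomputation).
#' @param by `"sex"` or `"age"`.
#' @return named list of per-stratum [signal_table()] results (also
#'   written as `subgroup_<by>_<stratum>.csv`).
#' @export
run_subgroups <- function(config, main = NULL, by = c("sex", "age")) {
  by <- match.arg(by)
  if (is.null(main)) main <- run_main(config)
  db <- main$db
  bins <- age_bins(config$age_bin_preset)
  strata <- partition_cohort(db, by, bins)
  cohort_ids <- main$cohort$cases$caseid
  out <- list()
  for (nm in names(strata)) {
    sdb <- strata[[nm]]
    ids <- intersect(sdb$cases$caseid, cohort_ids)
    if (length(ids) == 0) {
      warning("subgroup ", by, "=", nm, ": no target cases; skipped")
      next
    }
    uni <- tryCatch(build_pair_universe(sdb, ids, level = "PT"),
                    error = function(e) {
                      warning("subgroup ", by, "=", nm, ": ",
                              conditionMessage(e), "; skipped")
                      NULL
                    })
    if (is.null(uni)) next
    sig <- signal_table(uni, main$prior, chi2_correct = config$chi2_correct)
    out[[nm]] <- sig
    fwrite(sig, file.path(config$out_dir,
                          paste0("subgroup_", by, "_", gsub("[^A-Za-z0-9]", "",
                                                            nm), ".csv")))
  }
  invisible(out)
}

#' Sensitivity analysis: recompute signals after co-medication exclusion
#'
#' Drops every cohort case listing an excluded co-medication (any role),
#' recomputes the full signal table on the filtered cohort against the
#' correspondingly filtered background, and reports which main-analysis
#' signals persist (flagged both before and after). No subset relation is
#' asserted: flags are recomputed on nested but different data.
#'
#' @param config a [run_config()]; its cohort spec must carry a non-empty
#'   exclusion list.
#' @param main optional result of [run_main()] on the same config.
#' @return list with `signals` (the post-exclusion [signal_table()]),
#'   `persistent` (terms flagged in both runs), `n_excluded`.
#' @export
run_sensitivity <- function(config, main = NULL) {
  if (length(config$cohort$excluded_comedications) == 0)
    stop("sensitivity run needs a non-empty exclusion list")
  if (is.null(main)) main <- run_main(config)
  excl_cohort <- apply_comedication_exclusion(
    main$cohort, config$cohort$excluded_comedications)
  if (nrow(excl_cohort$kept$cases) == 0)
    stop("co-medication exclusion removed every cohort case")
  excl_db <- apply_comedication_exclusion(
    main$db, config$cohort$excluded_comedications)
  uni <- build_pair_universe(excl_db$kept, excl_cohort$kept$cases$caseid,
                             level = "PT")
  sig <- signal_table(uni, main$prior, chi2_correct = config$chi2_correct)
  before <- main$pt_signals[any_flag == TRUE, term]
  after <- sig[any_flag == TRUE, term]
  persistent <- sort(intersect(before, after))
  fwrite(sig, file.path(config$out_dir, "sensitivity_signals.csv"))
  fwrite(data.table(term = persistent),
         file.path(config$out_dir, "persistent_signals.csv"))
  invisible(list(signals = sig, persistent = persistent,
                 n_excluded = excl_cohort$n_excluded))
}

#' Hash of an output bundle
#'
#' MD5 of every regular file under `dir` (sorted relative paths), folded
#' into a single digest. Identical configuration + seed must reproduce
#' this hash exactly.
#'
#' @param dir bundle directory.
#' @return named character: per-file md5 plus the combined digest in
#'   attribute `bundle`.
#' @export
bundle_hash <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  files <- files[file.info(files)$isdir == FALSE]
  h <- tools::md5sum(files)
  names(h) <- substring(files, nchar(dir) + 2)
  combined <- local({
    f <- tempfile()
    writeLines(paste(names(h), unname(h)), f)
    as.character(tools::md5sum(f))
  })
  attr(h, "bundle") <- combined
  h
}
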