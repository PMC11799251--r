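## Cohort selection, exclusion filters, subgrouping and descriptives.

#' Specify an analysis cohort
#'
#' @param target_drug_synonyms non-empty character vector of drug name
#'   synonyms; matching is case-insensitive substring on both the verbatim
#'   drug name and the active-ingredient field (FAERS free-text names such
#'   as "KESIMPTA PEN" defeat exact matching).
#' @param role_required FAERS drug role code the target drug must carry
#'   (default `"PS"`, primary suspect).
#' @param window inclusive quarter window `c(first, last)` applied to the
#'   FDA receipt quarter.
#' @param excluded_comedications drug names whose presence (any role)
#'   excludes a case in the sensitivity filter.
#' @param indication_filter optional character vector of indication terms;
#'   `NULL` (the default) disables indication filtering.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(target_drug_synonyms = c("OFATUMUMAB", "KESIMPTA",
                                                 "ARZERRA"),
                        role_required = "PS",
                        window = c("2020Q3", "2024Q2"),
                        excluded_comedications = c("GABAPENTIN", "BACLOFEN",
                                                   "DULOXETINE", "VITAMIN B",
                                                   "VITAMIN D"),
                        indication_filter = NULL) {
  if (length(target_drug_synonyms) == 0 || all(!nzchar(target_drug_synonyms)))
    stop("target_drug_synonyms must be non-empty")
  quarter_seq(window[1], window[2])  # validates ordering
  structure(list(target_drug_synonyms = toupper(target_drug_synonyms),
                 role_required = toupper(role_required),
                 window = window,
                 excluded_comedications = toupper(excluded_comedications),
                 indication_filter = indication_filter),
            class = "cohort_spec")
}

## case ids whose drug list matches any synonym (substring, case-insensitive)
## on drugname or prod_ai, with the required role
match_target_cases <- function(drugs, synonyms, role = "PS") {
  nm <- toupper(ifelse(is.na(drugs$drugname), "", drugs$drugname))
  ai <- toupper(ifelse(is.na(drugs$prod_ai), "", drugs$prod_ai))
  hit <- rep(FALSE, nrow(drugs))
  for (s in toupper(synonyms)) {
    hit <- hit | grepl(s, nm, fixed = TRUE) | grepl(s, ai, fixed = TRUE)
  }
  if (!is.null(role)) {
    rl <- toupper(ifelse(is.na(drugs$role_cod), "", drugs$role_cod))
    hit <- hit & rl == toupper(role)
  }
  unique(drugs$caseid[hit])
}

#' Select the analysis cohort
#'
#' Keeps cases having at least one drug matching a synonym with the
#' required role, whose FDA receipt quarter falls inside the window.
#'
#' @param db a `faers_case_db`.
#' @param spec a [cohort_spec()].
#' @return a `faers_case_db` restricted to the cohort.
#' @export
select_cohort <- function(db, spec) {
  stopifnot(inherits(db, "faers_case_db"), inherits(spec, "cohort_spec"))
  target_ids <- match_target_cases(db$drugs, spec$target_drug_synonyms,
                                   spec$role_required)
  in_win <- db$cases$caseid[quarter_in_window(db$cases$fda_quarter,
                                              spec$window)]
  subset_cases(db, intersect(target_ids, in_win))
}

#' Apply the co-medication exclusion (sensitivity filter)
#'
#' Drops any case listing a drug -- in any role -- whose name or active
#' ingredient matches the exclusion list, isolating the target drug's
#' standalone profile.
#'
#' @param db a `faers_case_db` (normally the selected cohort).
#' @param excluded_comedications character vector of drug names; empty
#'   vector is a no-op.
#' @return list with `kept` (a `faers_case_db`) and `n_excluded`.
#' @export
apply_comedication_exclusion <- function(db, excluded_comedications) {
  if (length(excluded_comedications) == 0)
    return(list(kept = db, n_excluded = 0L))
  bad <- match_target_cases(db$drugs, excluded_comedications, role = NULL)
  bad <- intersect(bad, db$cases$caseid)
  keep <- setdiff(db$cases$caseid, bad)
  list(kept = subset_cases(db, keep), n_excluded = length(bad))
}

#' Default age bins
#'
#' `table1` follows the descriptive convention `<18 / 18-65 / 66-85 / >85`;
#' `subgroup` is the alternate preset `18-44 / 45-65 / >65` used for
#' age-stratified signal detection.
#'
#' @param preset `"table1"` or `"subgroup"`.
#' @return data.frame with `label`, `lo`, `hi` (inclusive bounds in years).
#' @export
age_bins <- function(preset = c("table1", "subgroup")) {
  preset <- match.arg(preset)
  if (preset == "table1")
    data.frame(label = c("<18", "18-65", "66-85", ">85"),
               lo = c(-Inf, 18, 66, 86), hi = c(17, 65, 85, Inf))
  else
    data.frame(label = c("<18", "18-44", "45-65", ">65"),
               lo = c(-Inf, 18, 45, 66), hi = c(17, 44, 65, Inf))
}

## assign each age to a bin label (or "missing"); bins validated disjoint
assign_age_bin <- function(age_years, bins) {
  bins <- bins[order(bins$lo), , drop = FALSE]
  if (nrow(bins) > 1 && any(bins$lo[-1] <= bins$hi[-nrow(bins)]))
    stop("age bins overlap")
  lab <- rep("missing", length(age_years))
  for (i in seq_len(nrow(bins))) {
    inb <- !is.na(age_years) & age_years >= bins$lo[i] & age_years <= bins$hi[i]
    lab[inb] <- bins$label[i]
  }
  lab
}

#' Partition a cohort into labelled strata
#'
#' Every case falls in exactly one stratum or `"missing"`; the strata are
#' a partition of the cohort.
#'
#' @param db a `faers_case_db`.
#' @param by `"sex"` or `"age"`.
#' @param bins for `by = "age"`, a data.frame as returned by [age_bins()];
#'   overlapping bins are an error.
#' @return named list of `faers_case_db` strata (empty strata omitted,
#'   `"missing"` included when present).
#' @export
partition_cohort <- function(db, by = c("sex", "age"),
                             bins = age_bins("table1")) {
  by <- match.arg(by)
  lab <- if (by == "sex") db$cases$sex
         else assign_age_bin(db$cases$age_years, bins)
  ids <- split(db$cases$caseid, lab)
  lapply(ids, function(x) subset_cases(db, x))
}

#' Table-1 style cohort descriptives
#'
#' Counts and percentages for sex, age bins, reporter type and the top-k
#' reporter countries. Percentages within one characteristic (including
#' its missing row) sum to 100.
#'
#' @param db a non-empty `faers_case_db`.
#' @param bins age bins, see [age_bins()].
#' @param top_k_countries number of countries to report (descending count,
#'   alphabetical tie-break).
#' @return a `data.table` with columns `characteristic`, `level`, `n`, `pct`.
#' @export
describe_cohort <- function(db, bins = age_bins("table1"),
                            top_k_countries = 5L) {
  n <- nrow(db$cases)
  if (n == 0) stop("cannot describe an empty cohort")
  one <- function(charac, lab, levels_order = NULL) {
    tt <- table(lab)
    dt <- data.table(characteristic = charac, level = names(tt),
                     n = as.integer(tt))
    if (!is.null(levels_order)) {
      ord <- match(dt$level, c(levels_order, "missing"))
      dt <- dt[order(ord)]
    }
    dt[, pct := 100 * n / sum(n)]
    dt
  }
  sex_tab <- one("sex", db$cases$sex, c("F", "M"))
  age_tab <- one("age", assign_age_bin(db$cases$age_years, bins), bins$label)
  rep_tab <- one("reporter", db$cases$reporter, c("CN", "HP", "MD", "PH"))
  ct <- as.data.table(table(db$cases$country))
  setnames(ct, c("level", "n"))
  ct <- ct[order(-n, level)][seq_len(min(top_k_countries, nrow(ct)))]
  ct[, `:=`(characteristic = "country", pct = 100 * n / nrow(db$cases))]
  rbind(sex_tab, age_tab, rep_tab,
        ct[, .(characteristic, level, n = as.integer(n), pct)])
}
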