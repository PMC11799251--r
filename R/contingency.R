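## Drug-event pair universe and 2x2 contingency tables.
##
## The counting unit is the unique (case, term) pair -- event level, not
## case level -- against a full-database comparator: all other drugs in
## the same cleaned extract.

#' Build the drug-event pair universe
#'
#' Every unique (caseid, PT) pair in the cleaned database is counted
#' once; `N` is the grand total over target and comparator cases alike.
#'
#' @param db the full cleaned `faers_case_db` (target and background).
#' @param cohort_ids character vector of caseids flagged as target-drug
#'   cases (normally `select_cohort(db, spec)$cases$caseid`).
#' @param level label for the term level, `"PT"` or `"SOC"`.
#' @return a `pair_universe`: list with `pairs` (data.table `caseid`,
#'   `term`, `is_target`), `counts` (per-term `a` and `term_total`), `N`,
#'   `target_total`, `level`.
#' @export
build_pair_universe <- function(db, cohort_ids, level = "PT") {
  stopifnot(inherits(db, "faers_case_db"))
  pairs <- unique(db$events[, .(caseid, term = pt)])
  pairs[, is_target := caseid %in% cohort_ids]
  if (!any(pairs$is_target))
    stop("no target-drug pairs in universe")
  if (all(pairs$is_target))
    stop("no comparator pairs in universe (background empty)")
  new_pair_universe(pairs, level)
}

new_pair_universe <- function(pairs, level) {
  counts <- pairs[, .(a = sum(is_target), term_total = .N), by = term]
  setkey(counts, term)
  structure(list(pairs = pairs, counts = counts,
                 N = nrow(pairs), target_total = sum(pairs$is_target),
                 level = level),
            class = "pair_universe")
}

#' Aggregate a PT-level universe to SOC level
#'
#' Each case contributes at most one pair per system organ class however
#' many of its PTs map there (per-case collapse). PTs absent from the
#' mapping pool into the sentinel class `"UNMAPPED"`.
#'
#' @param universe a PT-level `pair_universe`.
#' @param pt_to_soc data.frame/data.table with columns `pt` and `soc`.
#' @param collapse if `TRUE` (default) apply the per-case collapse; if
#'   `FALSE`, sum PT pairs within each SOC instead.
#' @return a SOC-level `pair_universe`.
#' @export
aggregate_to_soc <- function(universe, pt_to_soc, collapse = TRUE) {
  stopifnot(inherits(universe, "pair_universe"))
  map <- as.data.table(pt_to_soc)
  if (nrow(map) == 0) stop("empty PT-to-SOC mapping")
  stopifnot(all(c("pt", "soc") %in% names(map)))
  map <- unique(map[, .(term = toupper(trimws(pt)), soc = as.character(soc))])
  pr <- copy(universe$pairs)
  pr <- map[pr, on = "term"]
  pr[is.na(soc), soc := "UNMAPPED"]
  pr <- pr[, .(caseid, term = soc, is_target)]
  if (collapse) pr <- unique(pr)
  new_pair_universe(pr, "SOC")
}

#' 2x2 contingency table for one term
#'
#' Cells: `a` target drug & term, `b` target drug & other terms, `c`
#' other drugs & term, `d` other drugs & other terms; `a+b+c+d = N`.
#'
#' @param universe a `pair_universe`.
#' @param term term id present in the universe.
#' @return a one-row `data.table` with `term`, `level`, `a`, `b`, `c`, `d`.
#' @export
table_for_term <- function(universe, term) {
  stopifnot(inherits(universe, "pair_universe"))
  tm <- term
  row <- universe$counts[J(tm)]
  if (nrow(row) != 1 || is.na(row$a))
    stop("unknown term: ", term)
  data.table(term = term, level = universe$level,
             a = row$a, b = universe$target_total - row$a,
             c = row$term_total - row$a,
             d = universe$N - universe$target_total - (row$term_total - row$a))
}

#' All 2x2 tables of a universe
#'
#' @param universe a `pair_universe`.
#' @return a `data.table` with one row per term: `term`, `level`, `a`,
#'   `b`, `c`, `d`.
#' @export
all_tables <- function(universe) {
  stopifnot(inherits(universe, "pair_universe"))
  ct <- copy(universe$counts)
  ct[, `:=`(level = universe$level,
            b = universe$target_total - a,
            c = term_total - a,
            d = universe$N - universe$target_total - (term_total - a))]
  ct[, .(term, level, a, b, c, d)]
}
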