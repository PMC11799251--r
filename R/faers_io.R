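## Reading FAERS quarterly ASCII tables and building a deduplicated
## case-level database.

faers_schemas <- list(
  demo = c("primaryid", "caseid", "fda_dt"),
  drug = c("primaryid", "caseid", "role_cod", "drugname"),
  reac = c("primaryid", "caseid", "pt"),
  ther = c("primaryid", "caseid", "start_dt"),
  indi = c("primaryid", "caseid"),
  outc = c("primaryid", "caseid"),
  rpsr = c("primaryid", "caseid")
)

#' Read one FAERS ASCII table
#'
#' Parses the `'$'`-delimited FAERS quarterly dialect: a header line naming
#' the columns, one record per line. Empty fields become `NA`. Lines whose
#' field count does not match the header are skipped; the number skipped is
#' attached as the attribute `skipped` and reported via a message.
#'
#' @param path file path.
#' @param table_kind one of `"demo"`, `"drug"`, `"reac"`, `"ther"`,
#'   `"indi"`, `"outc"`, `"rpsr"`; the header must contain that table's
#'   required columns (extra columns are preserved).
#' @return a `data.table` with lower-cased column names and attribute
#'   `skipped`.
#' @export
read_faers_table <- function(path, table_kind = c("demo", "drug", "reac",
                                                  "ther", "indi", "outc",
                                                  "rpsr")) {
  table_kind <- match.arg(table_kind)
  if (!file.exists(path)) stop("cannot read FAERS table: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) stop("empty FAERS table: ", path)
  header <- tolower(strsplit(lines[1], "$", fixed = TRUE)[[1]])
  required <- faers_schemas[[table_kind]]
  if (!all(required %in% header))
    stop("header of ", basename(path), " does not name a known ", table_kind,
         " schema; missing: ", paste(setdiff(required, header), collapse = ", "))
  nf <- length(header)
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "$", fixed = TRUE)
  ## a trailing empty field is dropped by strsplit; restore it
  cnt <- lengths(parts)
  trail <- cnt == nf - 1L & endsWith(body, "$")
  parts[trail] <- lapply(parts[trail], function(p) c(p, ""))
  cnt[trail] <- nf
  ok <- cnt == nf
  n_skip <- sum(!ok)
  if (n_skip > 0)
    message("read_faers_table: skipped ", n_skip, " malformed line(s) in ",
            basename(path))
  mat <- matrix(unlist(parts[ok], use.names = FALSE), ncol = nf, byrow = TRUE)
  dt <- as.data.table(mat)
  setnames(dt, header)
  for (j in seq_along(dt))
    set(dt, i = which(dt[[j]] == ""), j = j, value = NA_character_)
  setattr(dt, "skipped", n_skip)
  dt[]
}

## numeric-aware comparison key for PRIMARYID: numeric when all-digit,
## else lexicographic (padded so the two sorts interleave sensibly)
primaryid_order_key <- function(pid) {
  num <- grepl("^[0-9]+$", pid)
  key <- pid
  key[num] <- sprintf("%030.0f", as.numeric(pid[num]))
  key
}

#' Deduplicate FAERS case versions
#'
#' FAERS re-publishes a case under the same CASEID each time it is
#' amended. Per the FDA-recommended practice, the version with the most
#' recent FDA receipt date (`FDA_DT`) is retained; ties on the date are
#' broken by the highest PRIMARYID (numeric comparison when both sides are
#' all-digit strings). Missing `FDA_DT` sorts lowest.
#'
#' @param demo a data.table with columns `caseid`, `primaryid`, `fda_dt`.
#' @return a `data.table` with one row per `caseid`: the surviving
#'   `primaryid` (and its `fda_dt`).
#' @export
deduplicate <- function(demo) {
  stopifnot(all(c("caseid", "primaryid", "fda_dt") %in% names(demo)))
  d <- as.data.table(demo)[, .(caseid, primaryid, fda_dt)]
  d[, `:=`(dt_key = ifelse(is.na(fda_dt), "", fda_dt),
           pid_key = primaryid_order_key(primaryid))]
  setorder(d, caseid, -dt_key, -pid_key)
  out <- d[, .SD[1], by = caseid][, .(caseid, primaryid, fda_dt)]
  setkey(out, caseid)
  out[]
}

#' Assemble a deduplicated case-level database
#'
#' Joins DEMO, DRUG, REAC and THER restricted to the surviving case
#' versions. Preferred terms are upper-cased and whitespace-normalized and
#' stored with set semantics (one row per case-PT). Cases with no REAC row
#' are dropped (counted), as are DRUG/REAC/THER rows whose `primaryid` has
#' no DEMO match (orphans).
#'
#' @param demo,drug,reac,ther data.tables from [read_faers_table()].
#' @return a list of class `faers_case_db`:
#' \describe{
#'   \item{cases}{one row per case: `caseid`, `primaryid`, `sex`,
#'     `age_years`, `reporter`, `country`, `fda_dt`, `fda_quarter`,
#'     `event_dt`.}
#'   \item{drugs}{`caseid`, `drugname`, `prod_ai`, `role_cod`, `start_dt`.}
#'   \item{events}{`caseid`, `pt` (unique pairs).}
#'   \item{log}{dropped/orphan counters.}
#' }
#' @export
assemble_cases <- function(demo, drug, reac, ther = NULL) {
  demo <- as.data.table(demo)
  drug <- as.data.table(drug)
  reac <- as.data.table(reac)
  surv <- deduplicate(demo)
  keep_pid <- surv$primaryid

  demo_s <- demo[primaryid %in% keep_pid]
  ## one row per surviving primaryid (defensive against raw duplicates)
  demo_s <- demo_s[!duplicated(primaryid)]

  n_orphan_drug <- sum(!drug$primaryid %in% demo$primaryid)
  drug_s <- drug[primaryid %in% keep_pid]
  reac_s <- reac[primaryid %in% keep_pid]

  if (!is.null(ther)) {
    ther <- as.data.table(ther)
    seq_col <- intersect(c("dsg_drug_seq", "drug_seq"), names(ther))[1]
    dseq_col <- intersect(c("drug_seq", "drug_seq1"), names(drug_s))[1]
    if (!is.na(seq_col) && !is.na(dseq_col)) {
      th <- ther[, .(primaryid, seqk = get(seq_col), start_dt)]
      th <- th[!duplicated(paste(primaryid, seqk))]
      drug_s[, seqk := get(dseq_col)]
      drug_s <- th[drug_s, on = c("primaryid", "seqk")]
      drug_s[, seqk := NULL]
    } else {
      drug_s[, start_dt := NA_character_]
    }
  } else {
    drug_s[, start_dt := NA_character_]
  }
  if (!"prod_ai" %in% names(drug_s)) drug_s[, prod_ai := NA_character_]

  reac_s[, pt := toupper(gsub("\\s+", " ", trimws(pt)))]
  events <- unique(reac_s[!is.na(pt) & nzchar(pt), .(caseid, pt)])

  has_event <- unique(events$caseid)
  n_no_reac <- sum(!demo_s$caseid %in% has_event)
  if (n_no_reac > 0)
    message("assemble_cases: dropped ", n_no_reac, " case(s) with no event")
  demo_s <- demo_s[caseid %in% has_event]
  keep_case <- demo_s$caseid
  drug_s <- drug_s[caseid %in% keep_case]
  events <- events[caseid %in% keep_case]

  getcol <- function(dt, nm) if (nm %in% names(dt)) dt[[nm]] else rep(NA_character_, nrow(dt))
  sex_raw <- toupper(trimws(getcol(demo_s, "sex")))
  sex <- ifelse(is.na(sex_raw) | !sex_raw %in% c("F", "M"), "missing", sex_raw)
  reporter_raw <- toupper(trimws(getcol(demo_s, "occp_cod")))
  reporter <- ifelse(is.na(reporter_raw) | !reporter_raw %in% c("CN", "HP", "MD", "PH"),
                     "missing", reporter_raw)
  country <- getcol(demo_s, "reporter_country")
  country <- ifelse(is.na(country), "missing", toupper(trimws(country)))

  cases <- data.table(
    caseid = demo_s$caseid,
    primaryid = demo_s$primaryid,
    sex = sex,
    age_years = age_in_years(getcol(demo_s, "age"), getcol(demo_s, "age_cod")),
    reporter = reporter,
    country = country,
    fda_dt = demo_s$fda_dt,
    fda_quarter = quarter_of(demo_s$fda_dt),
    event_dt = getcol(demo_s, "event_dt")
  )
  setkey(cases, caseid)
  drugs <- drug_s[, .(caseid, drugname, prod_ai, role_cod, start_dt)]
  setkey(drugs, caseid)
  setkey(events, caseid)
  structure(list(cases = cases, drugs = drugs, events = events,
                 log = list(n_orphan_drug = n_orphan_drug,
                            n_no_event = n_no_reac,
                            skipped = c(demo = attr(demo, "skipped") %||% 0L,
                                        drug = attr(drug, "skipped") %||% 0L,
                                        reac = attr(reac, "skipped") %||% 0L))),
            class = "faers_case_db")
}

#' Read a directory of FAERS tables and assemble cases
#'
#' Convenience wrapper: expects `DEMO.txt`, `DRUG.txt`, `REAC.txt` and
#' optionally `THER.txt` under `dir` (case-insensitive prefix match).
#'
#' @param dir directory containing the ASCII tables.
#' @return a `faers_case_db`, see [assemble_cases()].
#' @export
read_faers_dir <- function(dir) {
  find1 <- function(prefix) {
    f <- list.files(dir, pattern = paste0("(?i)^", prefix, ".*\\.txt$"),
                    full.names = TRUE)
    if (length(f) == 0) return(NULL)
    sort(f)[1]
  }
  demo <- read_faers_table(find1("demo"), "demo")
  drug <- read_faers_table(find1("drug"), "drug")
  reac <- read_faers_table(find1("reac"), "reac")
  ther_path <- find1("ther")
  ther <- if (is.null(ther_path)) NULL else read_faers_table(ther_path, "ther")
  assemble_cases(demo, drug, reac, ther)
}

#' Number of cases in a case database
#' @param db a `faers_case_db`.
#' @return integer count of deduplicated cases.
#' @export
n_cases_db <- function(db) nrow(db$cases)

#' Subset a case database by caseid
#' @param db a `faers_case_db`.
#' @param caseids character vector of caseids to keep.
#' @return a `faers_case_db` restricted to those cases.
#' @export
subset_cases <- function(db, caseids) {
  structure(list(cases = db$cases[caseid %in% caseids],
                 drugs = db$drugs[caseid %in% caseids],
                 events = db$events[caseid %in% caseids],
                 log = db$log),
            class = "faers_case_db")
}

#' Export the cleaned case table
#'
#' Writes one row per (caseid, PT) with the case-level covariates, the
#' shape used downstream by the contingency stage.
#'
#' @param db a `faers_case_db`.
#' @param path output CSV path.
#' @return invisibly, the written path.
#' @export
write_case_table <- function(db, path) {
  out <- db$events[db$cases, on = "caseid"]
  fwrite(out, path)
  invisible(path)
}
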