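#' Table-layout dialect for a spontaneous-report database
#'
#' Describes how the four report tables (case list, drug information,
#' adverse-event information, primary disease) are laid out on disk: column
#' names, the sex and drug-involvement vocabularies, the date format and the
#' field separator. The default profile mirrors the JADER table structure
#' with romanized column names; real PMDA extracts (Japanese column headers,
#' `YYYYMMDD` dates, CP932 encoding) are accommodated by overriding fields.
#'
#' @param case_id Column holding the case identifier (shared by all tables).
#' @param sex,report_quarter Columns in the case-list (demo) table.
#' @param generic_name,involvement,admin_start_date Columns in the drug table.
#' @param pt_name,onset_date,outcome Columns in the adverse-event (reac) table.
#' @param sex_values Named character vector mapping raw (case-folded) sex
#'   values to the levels `"women"`, `"men"`, `"unknown"`. Raw values outside
#'   this vocabulary are mapped to `"unknown"` with a warning.
#' @param involvement_values Named character vector mapping raw involvement
#'   values to `"suspect"`, `"concomitant"`, `"interaction"`.
#' @param date_format Date format string; values not matching it exactly
#'   (including partial year-month dates) are treated as missing.
#' @param sep Field separator.
#' @param encoding File encoding passed to [utils::read.csv()].
#'
#' @return A list of class `srs_dialect`.
#' @export
#' @examples
#' d <- srs_dialect(sex_values = c(male = "men", female = "women"))
#' d$date_format
srs_dialect <- function(case_id = "case_id",
                        sex = "sex",
                        report_quarter = "report_quarter",
                        generic_name = "generic_name",
                        involvement = "involvement",
                        admin_start_date = "admin_start_date",
                        pt_name = "pt_name",
                        onset_date = "onset_date",
                        outcome = "outcome",
                        sex_values = c(women = "women", female = "women",
                                       f = "women",
                                       men = "men", male = "men", m = "men",
                                       unknown = "unknown"),
                        involvement_values = c(suspect = "suspect",
                                               concomitant = "concomitant",
                                               interaction = "interaction"),
                        date_format = "%Y-%m-%d",
                        sep = ",",
                        encoding = "UTF-8") {
  structure(list(case_id = case_id, sex = sex,
                 report_quarter = report_quarter,
                 generic_name = generic_name, involvement = involvement,
                 admin_start_date = admin_start_date, pt_name = pt_name,
                 onset_date = onset_date, outcome = outcome,
                 sex_values = sex_values,
                 involvement_values = involvement_values,
                 date_format = date_format, sep = sep, encoding = encoding),
            class = "srs_dialect")
}

sex_levels <- c("women", "men", "unknown")
involvement_levels <- c("suspect", "concomitant", "interaction")

#' Construct a validated spontaneous-report database
#'
#' Assembles case-level demographics, drug mentions and adverse-event
#' mentions into a single validated object. The counting unit throughout the
#' package is the case (report): `n_reports` is the number of distinct cases
#' and is the grand total of every downstream contingency table.
#'
#' @param cases data.frame with columns `case_id`, `sex` (one of
#'   `"women"`, `"men"`, `"unknown"`) and optionally `report_quarter`.
#' @param drugs data.frame with columns `case_id`, `generic_name`
#'   (normalized), `involvement` (one of `"suspect"`, `"concomitant"`,
#'   `"interaction"`) and `admin_start_date` (`Date`, may be `NA`).
#' @param events data.frame with columns `case_id`, `pt_name` (non-empty),
#'   `onset_date` (`Date`, may be `NA`) and optionally `outcome`.
#' @param hist Optional primary-disease data.frame; stored but not used by
#'   any statistic.
#'
#' @return An object of class `srs_database`: a list with elements `cases`,
#'   `drugs`, `events`, `hist` and `n_reports`.
#' @seealso [load_database()] to read the four CSV tables from disk.
#' @export
srs_database <- function(cases, drugs, events, hist = NULL) {
  cases <- as.data.frame(cases)
  drugs <- as.data.frame(drugs)
  events <- as.data.frame(events)
  cases$case_id <- as.character(cases$case_id)
  drugs$case_id <- as.character(drugs$case_id)
  events$case_id <- as.character(events$case_id)
  if (is.null(cases$report_quarter))
    cases$report_quarter <- rep(NA_character_, nrow(cases))
  if (is.null(events$outcome))
    events$outcome <- rep(NA_character_, nrow(events))
  db <- structure(list(cases = cases, drugs = drugs, events = events,
                       hist = hist, n_reports = nrow(cases)),
                  class = "srs_database")
  validate_database(db)
  db
}

#' Validate the invariants of a report database
#'
#' Checks identifier uniqueness, vocabulary levels, referential integrity of
#' drug and event mentions, and that `n_reports` equals the number of cases.
#' Called by every constructor; exported so that user-assembled objects can
#' be re-checked after manual edits.
#'
#' @param db An `srs_database`.
#' @return `db`, invisibly; errors describe the first violated invariant.
#' @export
validate_database <- function(db) {
  stopifnot(inherits(db, "srs_database"))
  if (anyDuplicated(db$cases$case_id))
    stop("duplicate case_id in case table")
  if (any(is.na(db$cases$case_id) | !nzchar(db$cases$case_id)))
    stop("missing case_id in case table")
  if (!all(db$cases$sex %in% sex_levels))
    stop("sex must be one of: ", paste(sex_levels, collapse = ", "))
  if (!all(db$drugs$involvement %in% involvement_levels))
    stop("involvement must be one of: ",
         paste(involvement_levels, collapse = ", "))
  if (nrow(db$events) && any(is.na(db$events$pt_name) |
                             !nzchar(db$events$pt_name)))
    stop("pt_name must be non-empty")
  bad <- setdiff(db$drugs$case_id, db$cases$case_id)
  if (length(bad))
    stop("referential-integrity error: drug mentions reference unknown case_id: ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- setdiff(db$events$case_id, db$cases$case_id)
  if (length(bad))
    stop("referential-integrity error: event mentions reference unknown case_id: ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (db$n_reports != nrow(db$cases))
    stop("n_reports does not equal the number of cases")
  invisible(db)
}

read_one_table <- function(path, dialect, what) {
  if (is.null(path) || !file.exists(path))
    stop("required table '", what, "' not found: ",
         if (is.null(path)) "<missing path>" else path)
  read.csv(path, sep = dialect$sep, fileEncoding = dialect$encoding,
           stringsAsFactors = FALSE, check.names = FALSE,
           colClasses = "character")
}

need_cols <- function(tab, cols, what) {
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    stop("table '", what, "' is missing required column(s): ",
         paste(miss, collapse = ", "))
}

#' Load a JADER-layout report database from four CSV tables
#'
#' Reads the case list (demo), drug information, adverse-event information
#' and optional primary-disease tables, applies the dialect's vocabularies,
#' and returns a validated [srs_database()]. Rows with unparseable (empty)
#' case identifiers are dropped and counted; sex values outside the
#' dialect's vocabulary become `"unknown"` with a warning; dates that do not
#' match the dialect's format exactly (including partial year-month dates)
#' are treated as missing but do not exclude the row.
#'
#' @param paths Named list or vector with elements `demo`, `drug`, `reac`
#'   and optionally `hist`, each a file path.
#' @param dialect An [srs_dialect()].
#' @param synonyms Optional named character vector mapping brand/salt name
#'   variants to a generic name; applied after trimming and case-folding.
#'
#' @return An `srs_database`; the attribute `dropped_rows` records how many
#'   rows per table were discarded for unparseable case identifiers.
#' @export
load_database <- function(paths, dialect = srs_dialect(), synonyms = NULL) {
  paths <- as.list(paths)
  demo <- read_one_table(paths$demo, dialect, "demo")
  drug <- read_one_table(paths$drug, dialect, "drug")
  reac <- read_one_table(paths$reac, dialect, "reac")
  hist <- if (!is.null(paths$hist) && file.exists(paths$hist))
    read_one_table(paths$hist, dialect, "hist") else NULL

  need_cols(demo, c(dialect$case_id, dialect$sex), "demo")
  need_cols(drug, c(dialect$case_id, dialect$generic_name,
                    dialect$involvement), "drug")
  need_cols(reac, c(dialect$case_id, dialect$pt_name), "reac")

  dropped <- c(demo = 0L, drug = 0L, reac = 0L)
  drop_bad_ids <- function(tab, what) {
    id <- trimws(tab[[dialect$case_id]])
    bad <- is.na(id) | !nzchar(id)
    dropped[[what]] <<- sum(bad)
    tab[[dialect$case_id]] <- id
    tab[!bad, , drop = FALSE]
  }
  demo <- drop_bad_ids(demo, "demo")
  drug <- drop_bad_ids(drug, "drug")
  reac <- drop_bad_ids(reac, "reac")
  if (any(dropped > 0))
    warning(sum(dropped), " row(s) dropped for unparseable case identifiers")

  raw_sex <- normalize_name(demo[[dialect$sex]])
  sex <- unname(dialect$sex_values[raw_sex])
  out_of_vocab <- is.na(sex) & !is.na(raw_sex) & nzchar(raw_sex) &
    raw_sex != "na"
  if (any(out_of_vocab))
    warning(sum(out_of_vocab),
            " sex value(s) outside the vocabulary set to 'unknown'")
  sex[is.na(sex)] <- "unknown"

  raw_inv <- normalize_name(drug[[dialect$involvement]])
  inv <- unname(dialect$involvement_values[raw_inv])
  if (any(is.na(inv))) {
    warning(sum(is.na(inv)),
            " involvement value(s) outside the vocabulary set to 'concomitant'")
    inv[is.na(inv)] <- "concomitant"
  }

  cases <- data.frame(
    case_id = demo[[dialect$case_id]],
    sex = sex,
    report_quarter = if (dialect$report_quarter %in% names(demo))
      demo[[dialect$report_quarter]] else NA_character_,
    stringsAsFactors = FALSE)
  drugs <- data.frame(
    case_id = drug[[dialect$case_id]],
    generic_name = apply_synonyms(drug[[dialect$generic_name]], synonyms),
    involvement = inv,
    admin_start_date = if (dialect$admin_start_date %in% names(drug))
      parse_date(drug[[dialect$admin_start_date]], dialect$date_format)
    else as.Date(rep(NA_character_, nrow(drug))),
    stringsAsFactors = FALSE)
  events <- data.frame(
    case_id = reac[[dialect$case_id]],
    pt_name = trimws(reac[[dialect$pt_name]]),
    onset_date = if (dialect$onset_date %in% names(reac))
      parse_date(reac[[dialect$onset_date]], dialect$date_format)
    else as.Date(rep(NA_character_, nrow(reac))),
    outcome = if (dialect$outcome %in% names(reac))
      reac[[dialect$outcome]] else NA_character_,
    stringsAsFactors = FALSE)

  db <- srs_database(cases, drugs, events, hist)
  attr(db, "dropped_rows") <- dropped
  db
}

#' Write a report database as four JADER-layout CSV tables
#'
#' Inverse of [load_database()] under the same dialect: writes `demo.csv`,
#' `drug.csv`, `reac.csv` and (if present) `hist.csv` into `dir`.
#'
#' @param db An `srs_database`.
#' @param dir Output directory (created if needed).
#' @param dialect An [srs_dialect()] providing column names and date format.
#' @return The directory path, invisibly.
#' @export
write_database <- function(db, dir, dialect = srs_dialect()) {
  validate_database(db)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(d) ifelse(is.na(d), "", format(d, dialect$date_format))
  demo <- setNames(
    data.frame(db$cases$case_id, db$cases$sex, db$cases$report_quarter,
               stringsAsFactors = FALSE),
    c(dialect$case_id, dialect$sex, dialect$report_quarter))
  drug <- setNames(
    data.frame(db$drugs$case_id, db$drugs$generic_name, db$drugs$involvement,
               fmt(db$drugs$admin_start_date), stringsAsFactors = FALSE),
    c(dialect$case_id, dialect$generic_name, dialect$involvement,
      dialect$admin_start_date))
  reac <- setNames(
    data.frame(db$events$case_id, db$events$pt_name,
               fmt(db$events$onset_date), db$events$outcome,
               stringsAsFactors = FALSE),
    c(dialect$case_id, dialect$pt_name, dialect$onset_date, dialect$outcome))
  write.csv(demo, file.path(dir, "demo.csv"), row.names = FALSE, na = "")
  write.csv(drug, file.path(dir, "drug.csv"), row.names = FALSE, na = "")
  write.csv(reac, file.path(dir, "reac.csv"), row.names = FALSE, na = "")
  if (!is.null(db$hist))
    write.csv(db$hist, file.path(dir, "hist.csv"), row.names = FALSE, na = "")
  invisible(dir)
}

#' Keep only suspect-drug mentions
#'
#' Restricts the drug table to mentions whose involvement is `"suspect"`.
#' Cases and event mentions are untouched, so a case whose only drug
#' mentions were concomitant still counts toward `n_reports` (it simply can
#' no longer be exposed to any drug). Idempotent.
#'
#' @param db An `srs_database`.
#' @return An `srs_database` with only suspect drug mentions.
#' @export
restrict_to_suspect <- function(db) {
  validate_database(db)
  db$drugs <- db$drugs[db$drugs$involvement == "suspect", , drop = FALSE]
  rownames(db$drugs) <- NULL
  db
}

#' Per-case exposure indicator for a drug
#'
#' A case is exposed if at least one of its *suspect* drug mentions matches
#' the (normalized, synonym-mapped) generic name.
#'
#' @param db An `srs_database`.
#' @param drug Generic drug name (matching is trimmed and case-folded).
#' @param synonyms Optional named character vector of name variants.
#' @return Named logical vector, one element per case (names are case ids).
#' @export
flag_drug_exposure <- function(db, drug, synonyms = NULL) {
  target <- apply_synonyms(drug, synonyms)
  sus <- db$drugs[db$drugs$involvement == "suspect", , drop = FALSE]
  hit <- unique(sus$case_id[apply_synonyms(sus$generic_name,
                                           synonyms) == target])
  setNames(db$cases$case_id %in% hit, db$cases$case_id)
}

#' Summarize a report database
#'
#' Row counts per table and missingness rates for sex and the two date
#' fields — the validation summary emitted by the orchestrated run.
#'
#' @param db An `srs_database`.
#' @return A one-row data.frame.
#' @export
database_summary <- function(db) {
  data.frame(
    n_reports = db$n_reports,
    n_drug_mentions = nrow(db$drugs),
    n_suspect_mentions = sum(db$drugs$involvement == "suspect"),
    n_event_mentions = nrow(db$events),
    frac_sex_unknown = mean(db$cases$sex == "unknown"),
    frac_start_date_missing =
      if (nrow(db$drugs)) mean(is.na(db$drugs$admin_start_date)) else NA_real_,
    frac_onset_date_missing =
      if (nrow(db$events)) mean(is.na(db$events$onset_date)) else NA_real_)
}

#' @export
print.srs_database <- function(x, ...) {
  cat("Spontaneous-report database (srs_database)\n")
  cat("  reports (N++):      ", x$n_reports, "\n")
  cat("  drug mentions:      ", nrow(x$drugs),
      sprintf(" (%d suspect)", sum(x$drugs$involvement == "suspect")), "\n")
  cat("  event mentions:     ", nrow(x$events), "\n")
  cat("  sex: ", sum(x$cases$sex == "women"), "women /",
      sum(x$cases$sex == "men"), "men /",
      sum(x$cases$sex == "unknown"), "unknown\n")
  invisible(x)
}
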