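#' The 2x2 contingency table of a drug-event pair
#'
#' Cell counts over distinct cases: `n11` cases reporting both the target
#' drug and the target event group, `n10` drug only, `n01` event only,
#' `n00` neither. Margins `n1plus = n11 + n10` (drug total),
#' `nplus1 = n11 + n01` (event total) and the grand total `nplusplus` are
#' derived; `nplusplus` always equals the database's `n_reports` because
#' every case falls in exactly one cell.
#'
#' @param n11,n10,n01,n00 Non-negative integer cell counts.
#' @return A list of class `contingency_table` with the four cells and the
#'   derived margins.
#' @export
contingency_table <- function(n11, n10, n01, n00) {
  cells <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  if (any(is.na(cells)) || any(cells < 0))
    stop("cell counts must be non-negative")
  structure(list(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
                 n1plus = n11 + n10, nplus1 = n11 + n01,
                 nplusplus = n11 + n10 + n01 + n00),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$n11, x$n10, x$n01, x$n00), 2, byrow = TRUE,
              dimnames = list(c("target drug", "other drugs"),
                              c("target event", "other events")))
  print(m)
  cat("N++ =", x$nplusplus, "\n")
  invisible(x)
}

count_2x2 <- function(exposed, flagged) {
  contingency_table(n11 = sum(exposed & flagged),
                    n10 = sum(exposed & !flagged),
                    n01 = sum(!exposed & flagged),
                    n00 = sum(!exposed & !flagged))
}

#' Build the 2x2 table for one (drug, event-group) pair
#'
#' Each case contributes to exactly one cell. A case counts as exposed if
#' any of its suspect drug mentions matches the target drug; duplicated
#' mentions of the same drug or PT within a case have no effect. The
#' comparator is all other reports in the database, so the table's grand
#' total is always `n_reports`. A drug absent from the database yields a
#' valid table with `n11 = n10 = 0`.
#'
#' @param db An `srs_database` (suspect-drug restriction is applied to
#'   exposure internally, so [restrict_to_suspect()] is optional here).
#' @param drug Generic drug name.
#' @param event_flag Per-case logical indicator from [flag_event_group()]
#'   (or any named logical vector aligned with `db$cases$case_id`).
#' @param synonyms Optional drug-name synonym vector.
#' @return A [contingency_table()].
#' @export
build_2x2 <- function(db, drug, event_flag, synonyms = NULL) {
  stopifnot(length(event_flag) == db$n_reports)
  exposed <- flag_drug_exposure(db, drug, synonyms)
  count_2x2(unname(exposed), unname(event_flag))
}

#' Build women and men 2x2 tables for one (drug, event-group) pair
#'
#' Stratifies [build_2x2()] by sex. Cases with unknown sex enter neither
#' stratum and are counted in `n_unknown_sex`, so
#' `women$nplusplus + men$nplusplus + n_unknown_sex = n_reports`.
#'
#' @inheritParams build_2x2
#' @return A list of class `sex_tables` with elements `women`, `men` (each
#'   a [contingency_table()]) and `n_unknown_sex`.
#' @export
build_sex_tables <- function(db, drug, event_flag, synonyms = NULL) {
  stopifnot(length(event_flag) == db$n_reports)
  exposed <- unname(flag_drug_exposure(db, drug, synonyms))
  flagged <- unname(event_flag)
  sex <- db$cases$sex
  structure(list(
    women = count_2x2(exposed[sex == "women"], flagged[sex == "women"]),
    men = count_2x2(exposed[sex == "men"], flagged[sex == "men"]),
    n_unknown_sex = sum(sex == "unknown")),
    class = "sex_tables")
}

#' Long-format cell counts for every (drug, HLT) pair
#'
#' @param db An `srs_database`.
#' @param drugs Character vector of target generic names.
#' @param hlt_names Character vector of target HLT groups.
#' @param map A [term_map()].
#' @param synonyms Optional drug-name synonym vector.
#' @return A data.frame with one row per pair, in the given drug-major
#'   order, holding the four cells and margins.
#' @export
contingency_long <- function(db, drugs, hlt_names, map, synonyms = NULL) {
  flags <- lapply(hlt_names, function(h) flag_event_group(db, map, h))
  names(flags) <- hlt_names
  rows <- list()
  for (d in drugs) for (h in hlt_names) {
    ct <- build_2x2(db, d, flags[[h]], synonyms)
    rows[[length(rows) + 1L]] <-
      data.frame(drug = d, hlt = h, n11 = ct$n11, n10 = ct$n10,
                 n01 = ct$n01, n00 = ct$n00, n1plus = ct$n1plus,
                 nplus1 = ct$nplus1, nplusplus = ct$nplusplus,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
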