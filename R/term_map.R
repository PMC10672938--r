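#' Preferred-term to high-level-term mapping
#'
#' A two-column table mapping MedDRA preferred terms (PTs) to high-level
#' terms (HLTs). MedDRA is licensed content, so no terminology ships with
#' the package: users supply their own extract (or a synthetic one) as two
#' character vectors or a CSV file. Within one map each PT must map to
#' exactly one HLT; lookups of unmapped PTs return `NA` so they stay
#' detectable.
#'
#' @param pt_name Character vector of preferred terms.
#' @param hlt_name Character vector of high-level terms, same length.
#' @return A data.frame of class `term_map` with columns `pt_name`,
#'   `hlt_name`.
#' @export
#' @examples
#' tm <- term_map(c("hypopituitarism", "diabetes insipidus"),
#'                c("anterior pituitary hypofunction",
#'                  "posterior pituitary disorder"))
#' pt_to_hlt(tm, "hypopituitarism")
term_map <- function(pt_name, hlt_name) {
  pt_name <- trimws(as.character(pt_name))
  hlt_name <- trimws(as.character(hlt_name))
  stopifnot(length(pt_name) == length(hlt_name))
  if (any(!nzchar(pt_name)) || any(!nzchar(hlt_name)))
    stop("term_map entries must be non-empty")
  m <- unique(data.frame(pt_name = pt_name, hlt_name = hlt_name,
                         stringsAsFactors = FALSE))
  if (anyDuplicated(m$pt_name))
    stop("each PT must map to exactly one HLT; conflicting entries for: ",
         paste(unique(m$pt_name[duplicated(m$pt_name)]), collapse = ", "))
  class(m) <- c("term_map", "data.frame")
  m
}

#' Read a PT-to-HLT map from a two-column CSV file
#'
#' @param path CSV file with columns `pt_name` and `hlt_name`.
#' @return A [term_map()].
#' @export
read_term_map <- function(path) {
  if (!file.exists(path)) stop("term-map file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need_cols(tab, c("pt_name", "hlt_name"), "term map")
  term_map(tab$pt_name, tab$hlt_name)
}

#' Look up the HLT group of preferred terms
#'
#' @param map A [term_map()].
#' @param pts Character vector of PT names.
#' @return Character vector of HLT names; `NA` where a PT is unmapped.
#' @export
pt_to_hlt <- function(map, pts) {
  stopifnot(inherits(map, "term_map"))
  map$hlt_name[match(trimws(as.character(pts)), map$pt_name)]
}

#' Per-case indicator for an HLT event group
#'
#' A case is flagged when at least one of its event mentions carries a PT
#' belonging to the HLT group. The indicator depends only on the *set* of a
#' case's PTs: duplicate mentions of the same PT count once.
#'
#' @param db An `srs_database`.
#' @param map A [term_map()].
#' @param hlt_name One HLT label; must occur in the map's codomain.
#' @return Named logical vector, one element per case (names are case ids).
#' @export
flag_event_group <- function(db, map, hlt_name) {
  stopifnot(inherits(map, "term_map"), length(hlt_name) == 1)
  if (!hlt_name %in% map$hlt_name)
    stop_config("HLT '", hlt_name, "' is not in the term map")
  pts <- map$pt_name[map$hlt_name == hlt_name]
  hit <- unique(db$events$case_id[db$events$pt_name %in% pts])
  setNames(db$cases$case_id %in% hit, db$cases$case_id)
}
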