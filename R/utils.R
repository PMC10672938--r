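# Internal helpers shared across modules.

# Round half away from zero (display convention for reported statistics;
# threshold comparisons always use unrounded values).
round_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Normalize a drug generic name: trim whitespace, fold case.
normalize_name <- function(x) {
  tolower(trimws(as.character(x)))
}

# Apply a synonym table (named character vector variant -> generic) after
# normalization; unmatched names pass through.
apply_synonyms <- function(x, synonyms = NULL) {
  x <- normalize_name(x)
  if (length(synonyms)) {
    names(synonyms) <- normalize_name(names(synonyms))
    hit <- match(x, names(synonyms))
    x[!is.na(hit)] <- normalize_name(synonyms[hit[!is.na(hit)]])
  }
  x
}

# Parse dates, mapping partial or malformed values to NA. A fully specified
# date must match the dialect's date format exactly (e.g. "2020-01" under
# "%Y-%m-%d" is partial and becomes NA).
parse_date <- function(x, format = "%Y-%m-%d") {
  x <- as.character(x)
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & nzchar(trimws(x))
  if (any(ok)) {
    d <- as.Date(trimws(x[ok]), format = format)
    # round-trip check guards against partial dates silently parsing
    rt <- !is.na(d) & format(d, format) == trimws(x[ok])
    d[!rt] <- NA
    out[ok] <- d
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("srsignal_config_error", "error")))
}
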