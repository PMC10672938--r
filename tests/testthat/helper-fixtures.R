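# Hand-built fixtures and small builders shared across the test files.
# Everything is constructed in code; no data files are read.

# Minimal case/drug/event builder with sensible defaults.
make_db <- function(cases, drugs = NULL, events = NULL) {
  cases <- as.data.frame(cases)
  if (is.null(drugs))
    drugs <- data.frame(case_id = character(0), generic_name = character(0),
                        involvement = character(0),
                        admin_start_date = as.Date(character(0)))
  if (is.null(events))
    events <- data.frame(case_id = character(0), pt_name = character(0),
                         onset_date = as.Date(character(0)))
  drugs <- as.data.frame(drugs)
  events <- as.data.frame(events)
  if (is.null(drugs$involvement)) drugs$involvement <- "suspect"
  if (is.null(drugs$admin_start_date)) drugs$admin_start_date <- as.Date(NA)
  if (is.null(events$onset_date)) events$onset_date <- as.Date(NA)
  srs_database(cases, drugs, events)
}

# PT -> HLT map used by the hand fixtures.
toy_map <- term_map(
  pt_name = c("hypopituitarism", "hypophysitis", "diabetes insipidus",
              "nausea"),
  hlt_name = c("anterior pituitary hypofunction",
               "anterior pituitary hypofunction",
               "posterior pituitary disorder",
               "background"))

# Eight cases: 2 with drug+event, 1 drug only, 2 event only, 3 neither.
toy_8case_db <- function() {
  make_db(
    cases = data.frame(
      case_id = paste0("c", 1:8),
      sex = c("women", "men", "women", "men", "women", "men", "women",
              "unknown")),
    drugs = data.frame(
      case_id = c("c1", "c2", "c3"),
      generic_name = "ipilimumab",
      involvement = "suspect"),
    events = data.frame(
      case_id = c("c1", "c2", "c4", "c5"),
      pt_name = c("hypopituitarism", "hypophysitis", "hypopituitarism",
                  "hypophysitis")))
}

# The synthetic miniature database used by the broader pipeline tests;
# built once per test run.
example_fixture <- make_example_database()
example_drugs <- names(example_fixture$truth$config$drug_catalog)
example_hlts <- setdiff(unique(example_fixture$truth$config$event_catalog$hlt_name),
                        "background")

# Generator configuration helpers used by property and acceptance tests.
null_config <- function(seed, n_reports = 50000) {
  cfg <- example_fixture$truth$config
  cfg$n_reports <- as.integer(n_reports)
  cfg$associations <- NULL
  cfg$seed <- as.integer(seed)
  cfg
}

single_assoc_config <- function(seed, n_reports, exposure, margin,
                                rate_ratio, women_multiplier = 1,
                                onset_alpha = NA, onset_beta = NA,
                                missing_date_rate = 0) {
  generator_config(
    n_reports = n_reports,
    drug_catalog = c(targetdrug = exposure),
    event_catalog = data.frame(pt_name = "targetpt",
                               hlt_name = "targethlt",
                               margin = margin),
    associations = data.frame(drug = "targetdrug", hlt = "targethlt",
                              rate_ratio = rate_ratio,
                              women_multiplier = women_multiplier,
                              onset_alpha = onset_alpha,
                              onset_beta = onset_beta),
    missing_sex_rate = 0.05,
    missing_date_rate = missing_date_rate,
    concomitant_rate = 0,
    seed = seed)
}
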