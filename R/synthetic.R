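#' Configuration for the synthetic report-database generator
#'
#' Describes a study population of spontaneous reports with known ground
#' truth: marginal drug-exposure and event-reporting probabilities, a set
#' of true drug-event associations (reporting-rate ratios, optionally
#' sex-specific, with a Weibull onset model), and missingness rates for sex
#' and dates. Drugs and events are independent except through the
#' configured associations, so the null behaviour of every downstream
#' statistic is exactly testable.
#'
#' @param n_reports Number of cases to generate.
#' @param drug_catalog Named numeric vector: marginal exposure probability
#'   per generic drug name.
#' @param event_catalog data.frame with columns `pt_name`, `hlt_name`,
#'   `margin` (marginal reporting probability per PT).
#' @param associations Optional data.frame with columns `drug`, `hlt`,
#'   `rate_ratio` (> 0), `women_multiplier` (> 0, applied on top of the
#'   rate ratio when the exposed case is a woman), `onset_alpha`,
#'   `onset_beta` (Weibull scale/shape of the onset latency in days; `NA`
#'   for no onset model).
#' @param p_women Probability that a case with known sex is a woman.
#' @param missing_sex_rate Probability that sex is recorded as unknown.
#' @param missing_date_rate Probability that any individual date field
#'   (administration start, event onset) is missing.
#' @param concomitant_rate Probability that a case carries one additional
#'   concomitant-role drug mention (exercises the suspect-only rule).
#' @param date_window Two `Date`s bounding administration start dates.
#' @param seed Integer seed; identical configurations generate identical
#'   databases.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_reports,
                             drug_catalog,
                             event_catalog,
                             associations = NULL,
                             p_women = 0.5,
                             missing_sex_rate = 0.05,
                             missing_date_rate = 0.1,
                             concomitant_rate = 0.1,
                             date_window = as.Date(c("2010-01-01",
                                                     "2019-12-31")),
                             seed = 1L) {
  stopifnot(n_reports > 0, is.numeric(drug_catalog),
            !is.null(names(drug_catalog)))
  event_catalog <- as.data.frame(event_catalog)
  need_cols(event_catalog, c("pt_name", "hlt_name", "margin"),
            "event_catalog")
  if (any(drug_catalog < 0 | drug_catalog > 1) ||
      any(event_catalog$margin < 0 | event_catalog$margin > 1) ||
      p_women < 0 || p_women > 1 ||
      missing_sex_rate < 0 || missing_sex_rate > 1 ||
      missing_date_rate < 0 || missing_date_rate > 1)
    stop("probabilities must lie in [0, 1]")
  if (!is.null(associations)) {
    associations <- as.data.frame(associations)
    need_cols(associations, c("drug", "hlt", "rate_ratio"), "associations")
    if (is.null(associations$women_multiplier))
      associations$women_multiplier <- 1
    if (is.null(associations$onset_alpha)) associations$onset_alpha <- NA_real_
    if (is.null(associations$onset_beta)) associations$onset_beta <- NA_real_
    if (any(associations$rate_ratio <= 0) ||
        any(associations$women_multiplier <= 0))
      stop("rate ratios and women multipliers must be > 0")
    if (!all(associations$drug %in% names(drug_catalog)))
      stop("association drug not in drug_catalog")
    if (!all(associations$hlt %in% event_catalog$hlt_name))
      stop("association hlt not in event_catalog")
  }
  structure(list(n_reports = as.integer(n_reports),
                 drug_catalog = drug_catalog,
                 event_catalog = event_catalog,
                 associations = associations,
                 p_women = p_women,
                 missing_sex_rate = missing_sex_rate,
                 missing_date_rate = missing_date_rate,
                 concomitant_rate = concomitant_rate,
                 date_window = date_window,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic spontaneous-report database
#'
#' Draws each case's sex (with missingness), each drug exposure
#' independently from its margin, and each event with probability
#' `margin x rate_ratio (if an exposed association applies) x
#' women_multiplier (if additionally sex = women)`, capped at 1 with a
#' warning. Events tied to an association with an onset model receive
#' `onset_date = admin_start_date + ceiling(Weibull(alpha, beta))` days, so
#' extracted latencies are at least 1 day; all other onset and start dates
#' are uniform over the date window. Date fields are then blanked
#' independently at `missing_date_rate`.
#'
#' @param config A [generator_config()].
#' @return A list with `db` (an [srs_database()]), `map` (the [term_map()]
#'   implied by the event catalog), and `truth` (the configuration plus
#'   realized exposure/event counts).
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_reports
  case_id <- sprintf("C%07d", seq_len(n))
  window <- as.integer(config$date_window[2] - config$date_window[1])

  sex <- ifelse(runif(n) < config$p_women, "women", "men")
  sex[runif(n) < config$missing_sex_rate] <- "unknown"

  drugs <- names(config$drug_catalog)
  exposed <- matrix(FALSE, n, length(drugs), dimnames = list(NULL, drugs))
  start_day <- matrix(NA_integer_, n, length(drugs),
                      dimnames = list(NULL, drugs))
  for (d in drugs) {
    exposed[, d] <- runif(n) < config$drug_catalog[[d]]
    k <- sum(exposed[, d])
    if (k) start_day[exposed[, d], d] <-
        as.integer(floor(runif(k, 0, window + 1)))
  }

  ec <- config$event_catalog
  assoc <- config$associations
  occurs <- matrix(FALSE, n, nrow(ec))
  onset_day <- matrix(NA_integer_, n, nrow(ec))
  clamped <- 0L
  for (k in seq_len(nrow(ec))) {
    p <- rep(ec$margin[k], n)
    src_drug <- rep(NA_character_, n)  # first applicable association's drug
    if (!is.null(assoc)) {
      for (a in which(assoc$hlt == ec$hlt_name[k])) {
        hit <- exposed[, assoc$drug[a]]
        p[hit] <- p[hit] * assoc$rate_ratio[a]
        hw <- hit & sex == "women"
        p[hw] <- p[hw] * assoc$women_multiplier[a]
        src_drug[hit & is.na(src_drug)] <- assoc$drug[a]
      }
    }
    clamped <- clamped + sum(p > 1)
    p <- pmin(p, 1)
    occ <- runif(n) < p
    occurs[, k] <- occ
    # onset: association-driven latency where an onset model applies,
    # otherwise uniform over the window
    od <- as.integer(floor(runif(n, 0, window + 1)))
    if (!is.null(assoc)) {
      for (a in which(assoc$hlt == ec$hlt_name[k])) {
        if (is.na(assoc$onset_alpha[a])) next
        sel <- occ & !is.na(src_drug) & src_drug == assoc$drug[a]
        if (any(sel)) {
          lat <- as.integer(ceiling(rweibull(sum(sel),
                                             shape = assoc$onset_beta[a],
                                             scale = assoc$onset_alpha[a])))
          od[sel] <- start_day[sel, assoc$drug[a]] + pmax(lat, 1L)
        }
      }
    }
    onset_day[, k] <- od
  }
  if (clamped > 0)
    warning(clamped, " event probability value(s) exceeded 1 and were clamped")

  # assemble mention tables
  di <- which(exposed, arr.ind = TRUE)
  drug_tab <- data.frame(
    case_id = case_id[di[, 1]],
    generic_name = drugs[di[, 2]],
    involvement = "suspect",
    admin_start_date = config$date_window[1] + start_day[exposed],
    stringsAsFactors = FALSE)
  conc <- which(runif(n) < config$concomitant_rate)
  if (length(conc)) {
    drug_tab <- rbind(drug_tab, data.frame(
      case_id = case_id[conc],
      generic_name = drugs[1L + (conc %% length(drugs))],
      involvement = "concomitant",
      admin_start_date = as.Date(NA),
      stringsAsFactors = FALSE))
  }
  drug_tab$admin_start_date[runif(nrow(drug_tab)) <
                              config$missing_date_rate] <- NA

  ei <- which(occurs, arr.ind = TRUE)
  event_tab <- data.frame(
    case_id = case_id[ei[, 1]],
    pt_name = ec$pt_name[ei[, 2]],
    onset_date = config$date_window[1] + onset_day[occurs],
    outcome = NA_character_,
    stringsAsFactors = FALSE)
  event_tab$onset_date[runif(nrow(event_tab)) <
                         config$missing_date_rate] <- NA

  cases <- data.frame(case_id = case_id, sex = sex,
                      report_quarter = NA_character_,
                      stringsAsFactors = FALSE)
  db <- srs_database(cases, drug_tab, event_tab)
  truth <- list(config = config,
                n_women = sum(sex == "women"),
                n_men = sum(sex == "men"),
                exposure_counts = colSums(exposed),
                event_counts = setNames(colSums(occurs), ec$pt_name),
                n_clamped = clamped)
  list(db = db, map = term_map(ec$pt_name, ec$hlt_name), truth = truth)
}

#' A deterministic miniature study database
#'
#' About 2,000 synthetic cases covering six immune checkpoint inhibitors
#' and four pituitary HLT groups (each with several preferred terms, plus
#' background events), with one embedded association — ipilimumab with
#' anterior pituitary hypofunction at reporting-rate ratio 32, a two-fold
#' female excess, and Weibull(120, 1.6) onset — used throughout the test
#' suite and examples as a stand-in for a licensed database extract.
#'
#' @param seed Integer seed (fixed default for reproducibility).
#' @return As [generate_reports()]: list with `db`, `map`, `truth`.
#' @export
#' @examples
#' fx <- make_example_database()
#' fx$db
make_example_database <- function(seed = 20231L) {
  drugs <- c(ipilimumab = 0.05, nivolumab = 0.06, pembrolizumab = 0.04,
             avelumab = 0.005, atezolizumab = 0.02, durvalumab = 0.01)
  events <- data.frame(
    pt_name = c("hypopituitarism", "hypophysitis",
                "secondary adrenocortical insufficiency",
                "hyperprolactinaemia", "inappropriate antidiuresis",
                "diabetes insipidus", "pituitary tumour benign",
                "nausea", "rash", "interstitial lung disease",
                "pyrexia", "diarrhoea"),
    hlt_name = c(rep("anterior pituitary hypofunction", 3),
                 "anterior pituitary hyperfunction",
                 rep("posterior pituitary disorder", 2),
                 "pituitary neoplasm",
                 rep("background", 5)),
    margin = c(0.004, 0.004, 0.004,
               0.002, 0.002, 0.003, 0.001,
               0.15, 0.12, 0.05, 0.08, 0.1),
    stringsAsFactors = FALSE)
  assoc <- data.frame(drug = "ipilimumab",
                      hlt = "anterior pituitary hypofunction",
                      rate_ratio = 32, women_multiplier = 2,
                      onset_alpha = 120, onset_beta = 1.6,
                      stringsAsFactors = FALSE)
  cfg <- generator_config(n_reports = 2000, drug_catalog = drugs,
                          event_catalog = events, associations = assoc,
                          p_women = 0.5, missing_sex_rate = 0.05,
                          missing_date_rate = 0.15, seed = seed)
  generate_reports(cfg)
}

#' Write a generated database plus term map and ground truth to disk
#'
#' Emits the four JADER-layout CSV tables (via [write_database()]), the
#' PT-to-HLT map as `term_map.csv`, and the ground truth as
#' `ground_truth.json`.
#'
#' @param generated Output of [generate_reports()].
#' @param dir Output directory.
#' @param dialect An [srs_dialect()].
#' @return `dir`, invisibly.
#' @export
write_generated <- function(generated, dir, dialect = srs_dialect()) {
  write_database(generated$db, dir, dialect)
  write.csv(as.data.frame(generated$map), file.path(dir, "term_map.csv"),
            row.names = FALSE)
  truth <- generated$truth
  truth$config$date_window <- format(truth$config$date_window)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
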