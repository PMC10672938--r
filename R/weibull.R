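#' Extract time-to-onset latencies for one (drug, event-group) pair
#'
#' For each case that is both exposed to the drug (suspect mention) and
#' flagged for the event group, the latency is
#' `(earliest matching event onset date - earliest suspect administration
#' start date) + 1` day, so same-day onset maps to day 1 and latencies live
#' on the positive support of the Weibull model. Cases with either date
#' entirely missing are counted in `n_excluded_missing`; onsets strictly
#' before the first administration are data errors counted in
#' `n_excluded_nonpositive`.
#'
#' @param db An `srs_database`.
#' @param drug Generic drug name.
#' @param event_flag Per-case indicator from [flag_event_group()].
#' @param map Optional [term_map()] plus `hlt_name`: when given, only event
#'   mentions whose PT belongs to `hlt_name` contribute onset dates;
#'   otherwise any event mention of a flagged case does.
#' @param hlt_name Optional HLT label, see `map`.
#' @param synonyms Optional drug-name synonym vector.
#' @return A list of class `tto_sample` with `days` (positive integers),
#'   `n_used`, `n_excluded_missing`, `n_excluded_nonpositive`, `drug`,
#'   `event_group`.
#' @export
extract_tto <- function(db, drug, event_flag, map = NULL, hlt_name = NULL,
                        synonyms = NULL) {
  stopifnot(length(event_flag) == db$n_reports)
  exposed <- flag_drug_exposure(db, drug, synonyms)
  ids <- db$cases$case_id[unname(exposed) & unname(event_flag)]

  target <- apply_synonyms(drug, synonyms)
  sus <- db$drugs[db$drugs$involvement == "suspect" &
                    apply_synonyms(db$drugs$generic_name,
                                   synonyms) == target &
                    db$drugs$case_id %in% ids, , drop = FALSE]
  ev <- db$events[db$events$case_id %in% ids, , drop = FALSE]
  if (!is.null(map) && !is.null(hlt_name)) {
    pts <- map$pt_name[map$hlt_name == hlt_name]
    ev <- ev[ev$pt_name %in% pts, , drop = FALSE]
  }

  first_date <- function(tab, col) {
    ok <- !is.na(tab[[col]])
    if (!any(ok)) return(setNames(numeric(0), character(0)))
    tapply(as.numeric(tab[[col]][ok]), tab$case_id[ok], min)
  }
  starts <- first_date(sus, "admin_start_date")
  onsets <- first_date(ev, "onset_date")

  days <- integer(0)
  n_missing <- 0L
  n_nonpos <- 0L
  for (id in ids) {
    s <- starts[id]
    o <- onsets[id]
    if (is.na(s) || is.na(o) || !length(s) || !length(o)) {
      n_missing <- n_missing + 1L
    } else {
      lat <- as.integer(o - s) + 1L
      if (lat >= 1L) days <- c(days, lat) else n_nonpos <- n_nonpos + 1L
    }
  }
  structure(list(days = days, n_used = length(days),
                 n_excluded_missing = n_missing,
                 n_excluded_nonpositive = n_nonpos,
                 drug = drug, event_group = hlt_name %||% NA_character_),
            class = "tto_sample")
}

weibull_loglik <- function(days, alpha, beta) {
  sum(dweibull(days, shape = beta, scale = alpha, log = TRUE))
}

not_available_fit <- function(n, reason, drug = NA_character_,
                              event_group = NA_character_) {
  structure(list(alpha = NA_real_, beta = NA_real_, gamma_loc = 0,
                 alpha_ci = c(NA_real_, NA_real_),
                 beta_ci = c(NA_real_, NA_real_),
                 log_likelihood = NA_real_, n = n,
                 pattern = "not_available", reason = reason,
                 drug = drug, event_group = event_group),
            class = "weibull_fit")
}

#' Fit a two-parameter Weibull model to onset latencies
#'
#' Maximum-likelihood fit of the Weibull scale `alpha` (days) and shape
#' `beta` (dimensionless) with the location fixed at 0; spontaneous reports
#' contain only realized events, so the likelihood is uncensored. 95%
#' confidence bounds are Wald intervals built on the log-transformed
#' parameters from the observed information (standard errors mapped to the
#' log scale by the delta method) and exponentiated back, which keeps the
#' bounds positive and respects the parameters' skew at small n.
#'
#' The hazard implied by the fit is
#' \deqn{\lambda(t) = \frac{\beta}{\alpha}\left(\frac{t}{\alpha}\right)^{\beta - 1},}
#' increasing in `t` when `beta > 1`, constant at `beta = 1`, decreasing
#' when `beta < 1` — the basis of [classify_pattern()].
#'
#' @param sample A `tto_sample` from [extract_tto()], or a bare numeric
#'   vector of latencies in days.
#' @param min_n Minimum sample size to attempt a fit (default 5); below it
#'   the fit is marked not available.
#' @param level Confidence level for the Wald bounds.
#' @return A list of class `weibull_fit` with `alpha`, `beta`, `gamma_loc`,
#'   `alpha_ci`, `beta_ci`, `log_likelihood`, `n`, `pattern`.
#' @export
#' @examples
#' set.seed(1)
#' fit_weibull(rweibull(200, shape = 1.5, scale = 100))
fit_weibull <- function(sample, min_n = 5, level = 0.95) {
  days <- if (inherits(sample, "tto_sample")) sample$days else sample
  drug <- if (inherits(sample, "tto_sample")) sample$drug else NA_character_
  evg <- if (inherits(sample, "tto_sample"))
    sample$event_group else NA_character_
  days <- as.numeric(days)
  if (any(days <= 0)) stop("latencies must be positive")
  n <- length(days)
  if (n < min_n)
    return(not_available_fit(n, sprintf("n = %d below min_n = %d", n, min_n),
                             drug, evg))
  if (length(unique(days)) == 1L)
    stop("degenerate sample: all ", n, " latencies equal ", days[1],
         "; the Weibull shape is unidentifiable (zero variance)")
  fd <- fitdistrplus::fitdist(days, "weibull")
  beta <- unname(fd$estimate["shape"])
  alpha <- unname(fd$estimate["scale"])
  se <- fd$sd
  z <- qnorm(1 - (1 - level) / 2)
  ci_log <- function(est, se) est * exp(c(-1, 1) * z * se / est)
  beta_ci <- ci_log(beta, unname(se["shape"]))
  structure(list(alpha = alpha, beta = beta, gamma_loc = 0,
                 alpha_ci = ci_log(alpha, unname(se["scale"])),
                 beta_ci = beta_ci,
                 log_likelihood = fd$loglik, n = n,
                 pattern = classify_pattern_impl(beta_ci), reason = NULL,
                 drug = drug, event_group = evg),
            class = "weibull_fit")
}

classify_pattern_impl <- function(beta_ci) {
  if (any(is.na(beta_ci))) return("not_available")
  if (beta_ci[1] > 1) "wear_out"
  else if (beta_ci[2] < 1) "early_failure"
  else "indeterminate"
}

#' Classify the onset pattern from the Weibull shape parameter
#'
#' `wear_out` (onset rate increasing with time) when the whole confidence
#' interval of `beta` lies above 1; `early_failure` (rate decreasing) when
#' it lies below 1; `indeterminate` when the interval covers 1 (the random,
#' constant-rate pattern cannot be excluded); `not_available` when there is
#' no fit.
#'
#' @param fit A `weibull_fit` from [fit_weibull()].
#' @return One of `"wear_out"`, `"early_failure"`, `"indeterminate"`,
#'   `"not_available"`.
#' @export
classify_pattern <- function(fit) {
  stopifnot(inherits(fit, "weibull_fit"))
  classify_pattern_impl(fit$beta_ci)
}

#' Onset-time quantile of a fitted Weibull model
#'
#' Returns `alpha * (-log(1 - p))^(1/beta)`, the day by which a fraction
#' `p` of onsets has occurred. At `p = 1 - exp(-1)` (about 63.2%) the
#' quantile equals the scale parameter `alpha` exactly, which is the usual
#' reading of "most onsets occur around alpha days".
#'
#' @param fit A `weibull_fit`, or a list with `alpha` and `beta`.
#' @param p Probability in (0, 1).
#' @return Days.
#' @export
weibull_quantile <- function(fit, p) {
  if (any(p <= 0) || any(p >= 1)) stop("p must be in (0, 1)")
  qweibull(p, shape = fit$beta, scale = fit$alpha)
}

#' @export
print.weibull_fit <- function(x, ...) {
  if (x$pattern == "not_available" && is.na(x$alpha)) {
    cat("Weibull fit: not available (", x$reason %||% "no data", ")\n",
        sep = "")
    return(invisible(x))
  }
  cat(sprintf("Weibull fit (n = %d): alpha = %.1f (%.1f-%.1f) days, beta = %.2f (%.2f-%.2f)\n",
              x$n, x$alpha, x$alpha_ci[1], x$alpha_ci[2],
              x$beta, x$beta_ci[1], x$beta_ci[2]))
  cat("  onset pattern:", x$pattern, "\n")
  invisible(x)
}

#' Time-to-onset screen for selected (drug, HLT) pairs
#'
#' Extracts latencies and fits the Weibull model for each pair. By default
#' only pairs classified `"signal"` in `screen` are fitted (mirroring the
#' practice of profiling onset only for detected signals); `force_all`
#' fits every pair with enough data.
#'
#' @param db An `srs_database`.
#' @param screen Output of [run_signal_screen()] for the same pairs.
#' @param map A [term_map()].
#' @param min_n Minimum latency count for a fit.
#' @param force_all Fit all pairs, not only signals.
#' @param synonyms Optional drug-name synonym vector.
#' @return A data.frame with columns `drug`, `hlt`, `n_used`, `alpha`,
#'   `alpha_low`, `alpha_high`, `beta`, `beta_low`, `beta_high`, `pattern`.
#' @export
run_tto_screen <- function(db, screen, map, min_n = 5, force_all = FALSE,
                           synonyms = NULL) {
  validate_database(db)
  db <- restrict_to_suspect(db)
  keep <- if (force_all) rep(TRUE, nrow(screen))
  else screen$classification == "signal"
  rows <- list()
  for (i in which(keep)) {
    d <- screen$drug[i]
    h <- screen$hlt[i]
    flag <- flag_event_group(db, map, h)
    tto <- extract_tto(db, d, flag, map = map, hlt_name = h,
                       synonyms = synonyms)
    fit <- if (tto$n_used >= min_n && length(unique(tto$days)) > 1L)
      fit_weibull(tto, min_n = min_n)
    else not_available_fit(tto$n_used, "too few usable latencies", d, h)
    rows[[length(rows) + 1L]] <- data.frame(
      drug = d, hlt = h, n_used = tto$n_used,
      alpha = fit$alpha, alpha_low = fit$alpha_ci[1],
      alpha_high = fit$alpha_ci[2],
      beta = fit$beta, beta_low = fit$beta_ci[1],
      beta_high = fit$beta_ci[2],
      pattern = fit$pattern, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(drug = character(0), hlt = character(0),
                      n_used = integer(0), alpha = numeric(0),
                      alpha_low = numeric(0), alpha_high = numeric(0),
                      beta = numeric(0), beta_low = numeric(0),
                      beta_high = numeric(0), pattern = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
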