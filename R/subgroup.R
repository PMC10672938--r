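#' Women-versus-men subgroup contrast of the observed-to-expected ratio
#'
#' Computes the subgroup disproportionality statistic IC delta from a pair
#' of sex-stratified 2x2 tables. Within each stratum the expected count
#' uses that stratum's own margins,
#' \deqn{E_{sex} = N_{sex,1+} \, N_{sex,+1} / N_{sex,++}.}
#' The men stratum's observed-to-expected ratio is then used to form the
#' reference expectation for women, \eqn{E^* = E_{women} \times
#' (O_{men}/E_{men})}, and
#' \deqn{IC_\Delta = \log_2 \frac{O_{women} + 0.5}{E^* + 0.5}.}
#' A positive IC delta means the drug-event association is reported more
#' strongly in women than in men (about `log2 m` bits for a true
#' reporting-rate ratio `m` between the sexes).
#'
#' When `o_men = 0` or `e_men = 0` the men reference ratio is degenerate and
#' the result is flagged not computable (`computable = FALSE`, all derived
#' fields `NA`) rather than silently zero.
#'
#' @param sex_tables A `sex_tables` object from [build_sex_tables()].
#' @param level Credible level (0.95 for the closed-form interval).
#' @param interval_method `"closed_form"` or `"monte_carlo"`.
#' @param n_draws Posterior draws for the Monte-Carlo method.
#' @return A list of class `ic_delta_result` with `o_women`, `e_women`,
#'   `o_men`, `e_men`, `oe_women`, `oe_men`, `e_star`, `ic_delta`,
#'   `ic_delta025`, `ic_delta975`, `ic_women`, `ic_women025`, `ic_men`,
#'   and `computable`.
#' @export
ic_delta <- function(sex_tables, level = 0.95,
                     interval_method = c("closed_form", "monte_carlo"),
                     n_draws = 1e5) {
  stopifnot(inherits(sex_tables, "sex_tables"))
  interval_method <- match.arg(interval_method)
  w <- sex_tables$women
  m <- sex_tables$men
  if (w$nplusplus == 0 || m$nplusplus == 0)
    stop("both sex strata must be non-empty")
  icw <- information_component(w)
  icm <- information_component(m)
  out <- list(o_women = icw$observed_o, e_women = icw$expected_e,
              o_men = icm$observed_o, e_men = icm$expected_e,
              oe_women = NA_real_, oe_men = NA_real_, e_star = NA_real_,
              ic_delta = NA_real_, ic_delta025 = NA_real_,
              ic_delta975 = NA_real_,
              ic_women = icw$ic, ic_women025 = NA_real_,
              ic_men = icm$ic, computable = FALSE)
  class(out) <- "ic_delta_result"
  if (icw$observed_o > 0 && icw$expected_e > 0) {
    wci <- credible_interval(icw$observed_o, icw$expected_e, level = level,
                             method = interval_method, n_draws = n_draws)
    out$ic_women025 <- wci[[1]]
  }
  if (icm$observed_o == 0 || icm$expected_e == 0)
    return(out)   # degenerate men reference ratio
  out$oe_men <- icm$observed_o / icm$expected_e
  out$oe_women <- if (icw$expected_e > 0)
    icw$observed_o / icw$expected_e else NA_real_
  out$e_star <- icw$expected_e * out$oe_men
  if (out$e_star > 0) {
    out$ic_delta <- ic_value(out$o_women, out$e_star)
    dci <- ic_delta_interval(out$o_women, out$e_star, level = level,
                             method = interval_method, n_draws = n_draws)
    out$ic_delta025 <- dci[[1]]
    out$ic_delta975 <- dci[[2]]
    out$computable <- TRUE
  }
  out
}

#' Credible interval for IC delta
#'
#' The same interval machinery as [credible_interval()], applied to the
#' women observed count against the men-referenced expectation `E*`.
#'
#' @param o_women Women observed count.
#' @param e_star Men-referenced expected count, `> 0`.
#' @inheritParams credible_interval
#' @return `c(ic025, ic975)` in bits.
#' @export
ic_delta_interval <- function(o_women, e_star, level = 0.95,
                              method = c("closed_form", "monte_carlo"),
                              n_draws = 1e6) {
  credible_interval(o_women, e_star, level = level,
                    method = match.arg(method), n_draws = n_draws)
}

#' IC delta from published per-sex counts and ICs
#'
#' Reconstructs the subgroup contrast from a table that prints only the
#' per-sex observed counts and IC point estimates: each sex's expected
#' count is back-derived with [invert_expected()], then `E*` and IC delta
#' are formed as in [ic_delta()].
#'
#' @param o_women,ic_women Women observed count and IC (bits).
#' @param o_men,ic_men Men observed count and IC (bits).
#' @return A list with `e_women`, `e_men`, `e_star`, `ic_delta`,
#'   `ic_delta025`, `ic_delta975` (closed-form 95% bounds).
#' @export
#' @examples
#' # published row: women 105 cases at IC 5.35, men 292 at IC 4.50
#' ic_delta_from_ic(105, 5.35, 292, 4.50)$ic_delta   # approx 1.09
ic_delta_from_ic <- function(o_women, ic_women, o_men, ic_men) {
  e_women <- invert_expected(o_women, ic_women)
  e_men <- invert_expected(o_men, ic_men)
  if (o_men <= 0 || e_men <= 0)
    stop("men reference ratio is degenerate (o_men or e_men is zero)")
  e_star <- e_women * (o_men / e_men)
  ci <- ic_delta_interval(o_women, e_star)
  list(e_women = e_women, e_men = e_men, e_star = e_star,
       ic_delta = ic_value(o_women, e_star),
       ic_delta025 = ci[[1]], ic_delta975 = ci[[2]])
}

#' Three-part women-signal criterion
#'
#' A (drug, event-group) pair is a significant women signal when all of:
#' the lower IC delta bound is above 0, more than 2 women cases were
#' reported, and the women-stratum IC lower bound is above 0.
#'
#' @param delta An `ic_delta_result` from [ic_delta()].
#' @param women_ic A list with at least `ic025` (the women-stratum IC lower
#'   bound); defaults to the bound carried inside `delta`.
#' @return `TRUE`/`FALSE`; `NA` when the contrast was not computable.
#' @export
women_signal <- function(delta, women_ic = NULL) {
  stopifnot(inherits(delta, "ic_delta_result"))
  ic_women025 <- if (is.null(women_ic)) delta$ic_women025 else women_ic$ic025
  if (!isTRUE(delta$computable)) return(NA)
  if (is.na(ic_women025)) return(FALSE)
  isTRUE(delta$ic_delta025 > 0) && delta$o_women > 2 && ic_women025 > 0
}

#' Sex-subgroup screen over every (drug, HLT) pair
#'
#' Builds sex-stratified tables, computes per-sex ICs, IC delta with its
#' credible interval, and the women-signal flag, for each pair in
#' deterministic drug-major order. Cases with unknown sex enter neither
#' stratum.
#'
#' @inheritParams run_signal_screen
#' @return A data.frame with columns `drug`, `hlt`, `o_women`, `ic_women`,
#'   `ic_women025`, `o_men`, `ic_men`, `ic_delta`, `ic_delta025`,
#'   `ic_delta975`, `women_signal`.
#' @export
run_subgroup_screen <- function(db, drugs, hlt_names, map,
                                thresholds = signal_thresholds(),
                                interval_method = c("closed_form",
                                                    "monte_carlo"),
                                n_draws = 1e5, synonyms = NULL) {
  interval_method <- match.arg(interval_method)
  validate_database(db)
  db <- restrict_to_suspect(db)
  flags <- lapply(hlt_names, function(h) flag_event_group(db, map, h))
  names(flags) <- hlt_names
  rows <- list()
  for (d in drugs) for (h in hlt_names) {
    st <- build_sex_tables(db, d, flags[[h]], synonyms)
    dl <- ic_delta(st, level = thresholds$credible_level,
                   interval_method = interval_method, n_draws = n_draws)
    rows[[length(rows) + 1L]] <- data.frame(
      drug = d, hlt = h,
      o_women = dl$o_women, ic_women = dl$ic_women,
      ic_women025 = dl$ic_women025,
      o_men = dl$o_men, ic_men = dl$ic_men,
      ic_delta = dl$ic_delta, ic_delta025 = dl$ic_delta025,
      ic_delta975 = dl$ic_delta975,
      women_signal = women_signal(dl),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
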