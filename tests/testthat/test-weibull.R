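tto_db <- function() {
  # six exposed+flagged cases: c1 same-day onset, c2 onset 30 days later,
  # c3 onset before start (data error), c4 missing onset, c5 missing start,
  # c6 onset 9 days later
  make_db(
    cases = data.frame(case_id = paste0("c", 1:6), sex = rep("women", 6)),
    drugs = data.frame(
      case_id = paste0("c", 1:6),
      generic_name = "ipilimumab",
      involvement = "suspect",
      admin_start_date = as.Date(c("2020-01-01", "2020-01-01", "2020-01-10",
                                   "2020-01-01", NA, "2020-02-01"))),
    events = data.frame(
      case_id = paste0("c", 1:6),
      pt_name = "hypopituitarism",
      onset_date = as.Date(c("2020-01-01", "2020-01-31", "2020-01-05",
                             NA, "2020-03-01", "2020-02-10"))))
}

test_that("latency extraction applies the same-day and exclusion rules", {
  db <- tto_db()
  f <- flag_event_group(db, toy_map, "anterior pituitary hypofunction")
  tto <- extract_tto(db, "ipilimumab", f, map = toy_map,
                     hlt_name = "anterior pituitary hypofunction")
  expect_equal(sort(tto$days), c(1, 10, 31))
  expect_equal(tto$n_used, 3)
  expect_equal(tto$n_excluded_missing, 2)
  expect_equal(tto$n_excluded_nonpositive, 1)
})

test_that("earliest dates are used when a case has several mentions", {
  db <- make_db(
    cases = data.frame(case_id = "c1", sex = "men"),
    drugs = data.frame(case_id = c("c1", "c1"),
                       generic_name = "ipilimumab",
                       involvement = "suspect",
                       admin_start_date = as.Date(c("2020-02-01",
                                                    "2020-01-01"))),
    events = data.frame(case_id = c("c1", "c1"),
                        pt_name = c("hypopituitarism", "hypophysitis"),
                        onset_date = as.Date(c("2020-03-01", "2020-01-20"))))
  f <- flag_event_group(db, toy_map, "anterior pituitary hypofunction")
  tto <- extract_tto(db, "ipilimumab", f, map = toy_map,
                     hlt_name = "anterior pituitary hypofunction")
  expect_equal(tto$days, 20)
})

test_that("only event mentions of the target HLT supply onset dates", {
  db <- make_db(
    cases = data.frame(case_id = "c1", sex = "men"),
    drugs = data.frame(case_id = "c1", generic_name = "ipilimumab",
                       involvement = "suspect",
                       admin_start_date = as.Date("2020-01-01")),
    events = data.frame(case_id = c("c1", "c1"),
                        pt_name = c("nausea", "hypopituitarism"),
                        onset_date = as.Date(c("2020-01-02", NA))))
  f <- flag_event_group(db, toy_map, "anterior pituitary hypofunction")
  tto <- extract_tto(db, "ipilimumab", f, map = toy_map,
                     hlt_name = "anterior pituitary hypofunction")
  expect_equal(tto$n_used, 0)
  expect_equal(tto$n_excluded_missing, 1)
})

test_that("maximum likelihood recovers known Weibull parameters", {
  set.seed(7)
  x <- rweibull(500, shape = 1.5, scale = 100)
  fit <- fit_weibull(x)
  expect_lt(abs(fit$alpha - 100) / 100, 0.1)
  expect_lt(abs(fit$beta - 1.5) / 1.5, 0.1)
  expect_true(fit$alpha_ci[1] < 100 && 100 < fit$alpha_ci[2])
  expect_true(fit$beta_ci[1] < 1.5 && 1.5 < fit$beta_ci[2])
  expect_equal(fit$gamma_loc, 0)
  # the reported optimum beats the likelihood at perturbed parameters
  ll <- function(a, b) sum(dweibull(x, shape = b, scale = a, log = TRUE))
  expect_equal(fit$log_likelihood, ll(fit$alpha, fit$beta), tolerance = 1e-6)
  set.seed(8)
  for (i in 1:100) {
    a <- fit$alpha * exp(runif(1, -0.3, 0.3))
    b <- fit$beta * exp(runif(1, -0.3, 0.3))
    expect_gte(fit$log_likelihood, ll(a, b))
  }
})

test_that("the fit agrees with an independent survival-model route", {
  skip_if_not_installed("survival")
  set.seed(21)
  x <- rweibull(300, shape = 2, scale = 150)
  fit <- fit_weibull(x)
  sr <- survival::survreg(survival::Surv(x) ~ 1, dist = "weibull")
  expect_equal(fit$beta, 1 / sr$scale, tolerance = 1e-3)
  expect_equal(fit$alpha, unname(exp(sr$coefficients)), tolerance = 1e-3)
})

test_that("Wald intervals for an exponential sample cover beta = 1", {
  covered <- sapply(1:100, function(seed) {
    set.seed(seed)
    fit <- fit_weibull(rweibull(200, shape = 1, scale = 50))
    fit$beta_ci[1] < 1 && 1 < fit$beta_ci[2]
  })
  expect_gte(mean(covered), 0.9)
})

test_that("degenerate and undersized samples are refused or marked NA", {
  expect_error(fit_weibull(rep(7, 20)), "zero variance")
  fit <- fit_weibull(c(3, 9, 20), min_n = 5)
  expect_equal(fit$pattern, "not_available")
  expect_true(is.na(fit$alpha))
  expect_error(fit_weibull(c(-1, 2, 3)), "positive")
})

test_that("the fit is scale-equivariant", {
  set.seed(12)
  x <- rweibull(200, shape = 1.3, scale = 80)
  f1 <- fit_weibull(x)
  f2 <- fit_weibull(x * 3)
  expect_equal(f2$alpha, 3 * f1$alpha, tolerance = 1e-3)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-3)
})

test_that("onset patterns follow the shape-parameter interval rule", {
  mk <- function(lo, hi) structure(list(beta_ci = c(lo, hi)),
                                   class = "weibull_fit")
  expect_equal(classify_pattern(mk(1.36, 1.73)), "wear_out")
  expect_equal(classify_pattern(mk(0.92, 4.49)), "indeterminate")
  expect_equal(classify_pattern(mk(0.30, 0.80)), "early_failure")
  expect_equal(classify_pattern(mk(NA, NA)), "not_available")
})

test_that("onset quantiles are definitional and monotone", {
  fit <- list(alpha = 97.3, beta = 1.54)
  expect_equal(weibull_quantile(fit, 1 - exp(-1)), 97.3)
  # closed-form median alpha * log(2)^(1/beta)
  expect_equal(weibull_quantile(fit, 0.5), 97.3 * log(2)^(1 / 1.54))
  expect_equal(weibull_quantile(fit, 0.5), 76.7, tolerance = 1e-2)
  p <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(weibull_quantile(fit, p)) > 0))
  expect_error(weibull_quantile(fit, 1), "in \\(0, 1\\)")
})

test_that("the TTO screen fits signal pairs and honors force_all", {
  sc <- run_signal_screen(example_fixture$db, example_drugs, example_hlts,
                          example_fixture$map)
  tt <- run_tto_screen(example_fixture$db, sc, example_fixture$map)
  expect_equal(nrow(tt), sum(sc$classification == "signal"))
  expect_equal(names(tt), c("drug", "hlt", "n_used", "alpha", "alpha_low",
                            "alpha_high", "beta", "beta_low", "beta_high",
                            "pattern"))
  # the embedded Weibull(120, 1.6) onset is recovered to within 20%
  row <- tt[tt$drug == "ipilimumab", ]
  expect_lt(abs(row$alpha - 120) / 120, 0.2)
  expect_lt(abs(row$beta - 1.6) / 1.6, 0.2)
  tt_all <- run_tto_screen(example_fixture$db, sc, example_fixture$map,
                           force_all = TRUE)
  expect_equal(nrow(tt_all), nrow(sc))
  expect_true(any(tt_all$pattern == "not_available"))
})
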