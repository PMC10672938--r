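---
title: "Methods: disproportionality signals and onset patterns in spontaneous reports"
author: "srsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signals and onset patterns in spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srsignal)
```

## The problem

Spontaneous reporting systems (SRS) such as Japan's JADER or the FDA's
FAERS collect voluntarily submitted suspected adverse-drug-reaction
reports. They have no denominator — the number of patients *using* a drug
is unknown — so incidence rates cannot be computed. What can be computed is
*disproportionality*: whether a drug–event pair is co-reported more often
than expected if drug and event were mentioned independently across the
database. `srsignal` implements one complete disproportionality pipeline
for databases in the four-table JADER layout (case list, drug information,
adverse-event information, primary disease), aimed at questions like the
pituitary-related adverse events of immune checkpoint inhibitors: which
drug–event pairs signal, whether women and men differ, and how onset
latency is distributed.

The counting unit everywhere is the *case* (one report). A case is exposed
to a drug if it carries at least one **suspect**-role mention of it
(concomitant and interaction mentions never create exposure), and it has
the event if at least one of its MedDRA preferred terms (PTs) belongs to
the target high-level term (HLT) group under a user-supplied PT→HLT map.
MedDRA is licensed, so no terminology ships with the package; the map is
an input.

## The information component

For a pair, the 2×2 contingency table over distinct cases gives the
observed co-report count $O = N_{11}$ and the expected count under
independence from the table's own margins,

$$E = \frac{N_{1+}\,N_{+1}}{N_{++}},$$

and the BCPNN information component is the shrunk log ratio

$$IC = \log_2 \frac{O + 0.5}{E + 0.5}.$$

The $+0.5$ terms are the shrinkage of the Bayesian confidence propagation
neural network: they keep the statistic finite at $O = 0$ and pull
small-count pairs toward 0, so a single co-report can never produce an
extreme score. `invert_expected()` inverts this formula, which is how the
worked examples reconstruct $E$ from published $(O, IC)$ pairs.

Uncertainty is a 95% credible interval for the shrunk observed-to-expected
ratio, with two interchangeable methods:

* **Closed form** (default): $IC_{025} = IC - 3.3\,(O+0.5)^{-1/2} -
  2.4\,(O+0.5)^{-1}$ and $IC_{975} = IC + 2.4\,(O+0.5)^{-1/2} -
  0.5\,(O+0.5)^{-1}$. Deterministic and instantaneous; defined at the 95%
  level only.
* **Monte Carlo**: the posterior of the shrunk ratio is drawn as
  $\Gamma(O + 0.5,\ 1)/(E + 0.5)$, log2-transformed, and empirical
  quantiles are taken. Any level; accuracy limited by the number of draws.

The two methods agree to a few hundredths of a bit for counts in the
hundreds, with the closed form slightly wider at the lower tail; at
$O = 100$ the lower bounds differ by about 0.056 bits, shrinking to 0.016
by $O = 1000$. This known small-count divergence is why the package keeps
both: the closed form reproduces published screening tables, the gamma
posterior is the transparent reference distribution.

**Classification.** `signal` when $IC_{025} > 1$; `inverse` when
$IC_{975} < 0$; `not_available` when $O = 0$; otherwise `none`. The
inverse threshold is 0 rather than mirroring the signal threshold at 1: an
upper bound between 0 and 1 means the interval still covers 0, i.e. no
evidence of *under*-reporting, and published screens flag inverse signals
only for intervals wholly below 0. Both thresholds are arguments of
`signal_thresholds()`. Displayed statistics are rounded half-away-from-zero
to two decimals; classification always uses unrounded values.

## The women-versus-men contrast (IC delta)

Sex subgroups use a 4×2 table: a 2×2 per stratum, with unknown-sex cases
in neither stratum (they remain in the overall screen). Each stratum gets
its own expected count from its own margins,
$E_{sex} = N_{sex,1+} N_{sex,+1} / N_{sex,++}$. The men stratum's
observed-to-expected ratio defines the reference expectation for women,

$$E^* = E_{women} \times \frac{O_{men}}{E_{men}}, \qquad
IC_\Delta = \log_2 \frac{O_{women} + 0.5}{E^* + 0.5},$$

so $IC_\Delta$ is the shrunk log2 ratio of the two strata's
observed-to-expected ratios: about $\log_2 m$ bits for a true sex-specific
reporting-rate ratio $m$, and 0 when the sexes report alike. If
$O_{men} = 0$ or $E_{men} = 0$ the reference ratio is degenerate; the
result is flagged not-computable rather than coerced to zero. The interval
machinery is the same as for the plain IC, applied to
$(O_{women}, E^*)$; because the published interval procedure for this
statistic is not identifiable from printed values, acceptance of the
contrast rests on point estimates, and the interval method remains
configurable.

A pair is a **significant women signal** when all three hold:
$IC_{\Delta 025} > 0$, $N_{women11} > 2$, and the women-stratum
$IC_{women025} > 0$. The count criterion is strict (exactly 2 women cases
fails).

## Weibull time-to-onset

For cases exposed to the drug and flagged for the event group, latency is

$$T = (\text{earliest matching event onset} -
       \text{earliest suspect administration start}) + 1\ \text{day}.$$

The $+1$ makes same-day onset representable ($T = 1$) on the positive
support of the Weibull model. Cases missing either date are excluded and
counted (`n_excluded_missing`) — which is why onset-analysis sample sizes
are smaller than screening counts in real data — and onsets strictly
before first administration are excluded as data errors
(`n_excluded_nonpositive`).

The two-parameter Weibull (location fixed at 0; a free location is not
identifiable at typical sample sizes, and published analyses report only
scale and shape) is fitted by maximum likelihood — delegated to
`fitdistrplus::fitdist()` — with 95% Wald intervals on the log-transformed
parameters mapped back by exponentiation, so bounds stay positive and
respect the skew of small samples. The hazard
$\lambda(t) = (\beta/\alpha)(t/\alpha)^{\beta-1}$ gives the onset-pattern
taxonomy on the shape parameter's interval:

* `wear_out` — whole interval above 1 (onset rate increases with time);
* `early_failure` — whole interval below 1 (rate decreases);
* `indeterminate` — interval covers 1 (constant-rate, random failure
  cannot be excluded);
* `not_available` — fewer than `min_n` (default 5) usable latencies, or no
  fit.

Degenerate samples (all latencies equal, shape unidentifiable) are refused
with a diagnostic rather than fitted. There is no censoring model:
spontaneous reports contain only realized events, so the likelihood is an
uncensored MLE. By default onset models are fitted only for pairs
classified `signal`; `force_all` overrides. `weibull_quantile()` returns
$\alpha(-\ln(1-p))^{1/\beta}$; at $p = 1 - e^{-1} \approx 63.2\%$ it
equals $\alpha$ exactly, which is the precise reading of "most onsets
occur by around $\alpha$ days".

## The synthetic-report generator

Real SRS extracts are not redistributable, so the generator emulates the
statistical structure the pipeline assumes, with known ground truth: per
case, sex (configurable women fraction, missingness to `unknown`),
independent drug exposures from marginal probabilities, and events drawn
per PT with probability `margin × rate_ratio` (when the case is exposed to
an associated drug) `× women_multiplier` (when additionally the case is a
woman), capped at 1 with a warning. Associated events get
`onset = start + ceiling(Weibull(α, β))` days; other dates are uniform
over a window; date fields are blanked independently at
`missing_date_rate`. Drugs and events are otherwise independent, so null
behaviour is exactly testable. One seed fixes the whole database.

What it deliberately does **not** model: co-medication and confounding by
indication, masking by other strong signals, the Weber and notoriety
reporting dynamics, duplicate or updated versions of the same case, dose.
Passing tests on generated data therefore validate the *estimators* under
the independence-plus-association model, not robustness to real-world
reporting biases; real extracts must be deduplicated upstream.

`make_example_database()` is a fixed miniature (2,000 cases, six
checkpoint-inhibitor names, four pituitary HLT groups plus background
terms, one embedded association at rate ratio 32 with a two-fold female
excess and Weibull(120, 1.6) onset) used across the test suite and
examples.

## Numerical and design choices

* Drug matching is exact on trimmed, case-folded generic names, with an
  optional synonym table for brand/salt variants; the table dialect
  (column names, sex vocabulary, date format, separator, encoding) is
  configurable for real PMDA files.
* Partial dates (year-month) parse as missing but never drop the case
  from counting.
* Out-of-vocabulary sex becomes `unknown` with a warning; unparseable
  case identifiers are dropped and counted; referential-integrity
  violations are fatal.
* A case with both suspect and concomitant mentions of the target drug is
  exposed via the suspect mention; concomitant-only cases are unexposed.
* All orchestrated output is deterministically ordered (configured drug ×
  HLT order) and a rerun with the same configuration and seed is
  byte-identical; Monte-Carlo intervals draw from the single run seed.
* Validation problem sizes: worked examples are desk-scale; simulation
  checks use 50,000-report databases (10 seeds) for null and
  signal-recovery behaviour, 200,000 reports for sex-contrast recovery
  (so the women stratum holds a few hundred co-reports while exposure
  stays rare enough that the comparator margin is barely diluted), 150
  latencies × 50 seeds for Weibull recovery, and $10^6$ posterior draws
  for interval cross-validation.

One estimator subtlety the generator makes visible: the expected count $E$
is computed from whole-database margins, which *include* the exposed
cases. A strong association therefore inflates the event margin and the
measured IC converges to $\log_2\!\big(RR / (1 + p_{exp}(RR - 1))\big)$,
slightly below $\log_2 RR$ unless exposure is rare. The recovery checks
choose exposure small enough that this dilution is negligible; analysts
comparing drugs with very different market penetration should keep it in
mind.

## Limitations

* No reporting-odds-ratio, PRR or EBGM alternatives, and no
  multiple-comparison adjustment: the screen mirrors single-statistic
  practice, and its thresholds are calibrated conventions, not
  error-controlled tests.
* The closed-form interval is a 95%-level approximation; for small counts
  (tens) its lower bound is conservative by up to ~0.06 bits relative to
  the gamma posterior.
* The women-signal criterion inherits the missing-sex problem of real SRS
  data: unknown-sex cases are simply excluded from both strata.
* Incidence cannot be estimated from SRS data at all; a signal is a
  hypothesis for pharmacoepidemiologic follow-up, not a risk estimate.
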