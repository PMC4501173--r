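#' Population risk stratification under lognormal polygenic risk
#'
#' Closed-form arithmetic for how disease risk concentrates when the
#' lifetime log relative risk is Normal(0, sigma^2) across the population
#' (so relative risk is lognormal). Under the rare-disease approximation
#' (`model = "rare_approx"`, the default) absolute risk is proportional to
#' relative risk, cases' log relative risk is Normal(sigma^2, sigma^2),
#' and every quantity below has a closed form. The `"nonlinear"` variant
#' instead uses the saturating risk `1 - exp(-Lambda e^P)` with `Lambda`
#' calibrated so the population mean lifetime risk equals `F0`, and
#' evaluates the same quantities by numerical integration.
#'
#' With the fitted total polygenic SD (1.434) and a population lifetime
#' ovarian-cancer risk of 0.02 by age 80, the rare approximation gives the
#' familiar headline figures: 92.4% of cases arise in the upper-risk half
#' of the population, half of all cases arise in the ~7.6% of the
#' population with lifetime risk above ~5.6%, the median woman's risk is
#' ~0.72%, and the lower-risk half of the population contains about 1 in
#' 13 cases.
#'
#' @param q Population risk quantile in (0, 1) (e.g. 0.5 = median).
#' @param share Fraction of cases in (0, 1).
#' @param sigma SD of the polygenic log relative risk (1.434 for the full
#'   polygene; `sqrt(0.0915)` for the 17-SNP risk score).
#' @param F0 Population mean lifetime risk (default 0.02 by age 80).
#' @param model `"rare_approx"` or `"nonlinear"`.
#' @return A scalar (vectorised over the first argument).
#' @name stratification
NULL

#' @describeIn stratification Fraction of all cases arising in individuals
#'   above the population risk quantile `q`.
#' @export
#' @examples
#' case_fraction_above_quantile(0.5, 1.434)        # 0.924
#' case_fraction_above_quantile(0.5, sqrt(0.0915)) # 0.62
case_fraction_above_quantile <- function(q, sigma, F0 = 0.02,
                                         model = c("rare_approx", "nonlinear")) {
  model <- match.arg(model)
  stopifnot(all(q > 0 & q < 1), sigma >= 0)
  if (sigma == 0) return(1 - q)
  z <- stats::qnorm(q)
  if (model == "rare_approx") {
    stats::pnorm(sigma - z)
  } else {
    lam <- nonlinear_lambda(sigma, F0)
    vapply(z, function(zz) nl_case_share_above(zz * sigma, sigma, lam, F0), 0)
  }
}

#' @describeIn stratification Smallest population fraction (highest-risk
#'   individuals) containing the given share of cases.
#' @export
#' @examples
#' population_fraction_for_case_share(0.5, 1.434)  # ~ 0.076
population_fraction_for_case_share <- function(share, sigma, F0 = 0.02,
                                               model = c("rare_approx", "nonlinear")) {
  model <- match.arg(model)
  stopifnot(all(share > 0 & share < 1), sigma >= 0)
  if (sigma == 0) return(share)
  if (model == "rare_approx") {
    1 - stats::pnorm(sigma - stats::qnorm(share))
  } else {
    lam <- nonlinear_lambda(sigma, F0)
    vapply(share, function(s) {
      x <- stats::uniroot(function(x) nl_case_share_above(x, sigma, lam, F0) - s,
                          interval = c(-12 * sigma, 12 * sigma), tol = 1e-10)$root
      1 - stats::pnorm(x / sigma)
    }, 0)
  }
}

#' @describeIn stratification Lifetime risk of the individual at
#'   population risk quantile `q`.
#' @export
#' @examples
#' absolute_risk_at_quantile(0.5, 1.434)           # ~ 0.0072
absolute_risk_at_quantile <- function(q, sigma, F0 = 0.02,
                                      model = c("rare_approx", "nonlinear")) {
  model <- match.arg(model)
  stopifnot(all(q > 0 & q < 1), sigma >= 0)
  z <- stats::qnorm(q)
  if (model == "rare_approx") {
    F0 * exp(sigma * z - sigma^2 / 2)
  } else {
    lam <- nonlinear_lambda(sigma, F0)
    1 - exp(-lam * exp(sigma * z))
  }
}

# Lambda such that E_P[1 - exp(-Lambda e^P)] = F0 for P ~ N(0, sigma^2)
nonlinear_lambda <- function(sigma, F0) {
  mean_risk <- function(loglam) {
    stats::integrate(function(p) stats::dnorm(p, 0, sigma) *
                       (1 - exp(-exp(loglam) * exp(p))),
                     -10 * sigma, 10 * sigma, rel.tol = 1e-10)$value
  }
  # rare-approximation value F0 * exp(-sigma^2/2) as bracket centre
  lo <- log(F0) - sigma^2 / 2 - 5
  hi <- log(F0) + 2
  exp(stats::uniroot(function(l) mean_risk(l) - F0, c(lo, hi), tol = 1e-12)$root)
}

# share of cases with polygenic log-risk above x, saturating risk model
nl_case_share_above <- function(x, sigma, lam, F0) {
  stats::integrate(function(p) stats::dnorm(p, 0, sigma) *
                     (1 - exp(-lam * exp(p))),
                   x, 12 * sigma, rel.tol = 1e-10)$value / F0
}

#' Risk concentration curve
#'
#' For a grid of log-risk thresholds, the fraction of the population above
#' the threshold, the fraction of cases arising in that group, and the
#' absolute lifetime risk at the threshold. The curve runs from (1, 1) to
#' (0, 0) and dominates the diagonal whenever `sigma > 0`.
#'
#' @inheritParams stratification
#' @param z Grid of standardised thresholds (threshold = `sigma * z`).
#' @return A tibble of class `ova_concentration` with columns `threshold`
#'   (log relative risk), `pop_fraction`, `case_fraction`,
#'   `absolute_risk`, plus `sigma`, `F0`, `model` as attributes columns.
#' @export
concentration_curve <- function(sigma, F0 = 0.02,
                                model = c("rare_approx", "nonlinear"),
                                z = seq(-5, 5, by = 0.01)) {
  model <- match.arg(model)
  pop <- 1 - stats::pnorm(z)
  if (sigma == 0) {
    cf <- pop
    ar <- rep(F0, length(z))
  } else if (model == "rare_approx") {
    cf <- stats::pnorm(sigma - z)
    ar <- F0 * exp(sigma * z - sigma^2 / 2)
  } else {
    lam <- nonlinear_lambda(sigma, F0)
    cf <- vapply(z, function(zz) nl_case_share_above(zz * sigma, sigma, lam, F0), 0)
    ar <- 1 - exp(-lam * exp(sigma * z))
  }
  out <- tibble::tibble(threshold = sigma * z, pop_fraction = pop,
                        case_fraction = cf, absolute_risk = ar,
                        sigma = sigma, F0 = F0, model = model)
  class(out) <- c("ova_concentration", class(out))
  out
}

#' Headline stratification figures
#'
#' The summary quantities usually quoted for a lognormal risk
#' distribution, rounded the way they are customarily reported
#' (percentages to 1 decimal place, "1 in N" to the nearest integer).
#'
#' @inheritParams stratification
#' @return A one-row tibble: `cases_in_top_half` (fraction), the
#'   population fraction containing half of cases and the risk threshold
#'   defining it, the median absolute risk, and `one_in_n_lower_half`
#'   (cases in the lower-risk half as "1 in N").
#' @export
stratification_summary <- function(sigma, F0 = 0.02,
                                   model = c("rare_approx", "nonlinear")) {
  model <- match.arg(model)
  top_half <- case_fraction_above_quantile(0.5, sigma, F0, model)
  popfrac <- population_fraction_for_case_share(0.5, sigma, F0, model)
  thr_q <- 1 - popfrac
  tibble::tibble(
    cases_in_top_half = top_half,
    pop_fraction_half_cases = popfrac,
    risk_threshold_half_cases = absolute_risk_at_quantile(thr_q, sigma, F0, model),
    median_risk = absolute_risk_at_quantile(0.5, sigma, F0, model),
    one_in_n_lower_half = round(1 / (1 - top_half))
  )
}
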