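#' Akaike information criterion
#'
#' `AIC = -2 (loglik - k)` for `k` free parameters; lower is more
#' parsimonious.
#'
#' @param loglik Log-likelihood at the maximum.
#' @param k Number of free parameters (>= 0).
#' @return The AIC value.
#' @export
#' @examples
#' aic(-2879.186, 3)   # 5764.372
aic <- function(loglik, k) {
  if (any(k < 0)) stop("`k` must be >= 0", call. = FALSE)
  -2 * (loglik - k)
}

#' Likelihood ratio test
#'
#' Upper-tail chi-squared probability of `2 (loglik1 - loglik0)` on `df`
#' degrees of freedom.
#'
#' @param loglik0,loglik1 Log-likelihoods of the nested (null) and richer
#'   model.
#' @param df Degrees of freedom (>= 1).
#' @return The p-value.
#' @export
#' @examples
#' lrt(-2892.237, -2877.283, 4)   # ~ 5.1e-06
lrt <- function(loglik0, loglik1, df) {
  if (any(df <= 0)) stop("`df` must be >= 1", call. = FALSE)
  if (any(loglik1 < loglik0)) {
    warning("loglik1 < loglik0: richer model fits worse; returning p = 1")
  }
  stats::pchisq(pmax(2 * (loglik1 - loglik0), 0), df, lower.tail = FALSE)
}

# Model battery: free parameters and inheritance mode per model. The free
# counts fix the AIC/LRT arithmetic (base 2; major dom/rec 4, general 5;
# polygenic 3; mixed dom/rec 5, general 6).
ova_model_specs <- function() {
  list(
    base            = list(mode = "none",      free = c("f1", "f2")),
    major_dominant  = list(mode = "dominant",  free = c("f1", "f2", "fM", "logRR1")),
    major_recessive = list(mode = "recessive", free = c("f1", "f2", "fM", "logRR1")),
    major_general   = list(mode = "general",   free = c("f1", "f2", "fM", "logRR1", "logRR2")),
    polygenic       = list(mode = "none",      free = c("f1", "f2", "sigma")),
    mixed_dominant  = list(mode = "dominant",  free = c("f1", "f2", "fM", "logRR1", "sigma")),
    mixed_recessive = list(mode = "recessive", free = c("f1", "f2", "fM", "logRR1", "sigma")),
    mixed_general   = list(mode = "general",   free = c("f1", "f2", "fM", "logRR1", "logRR2", "sigma"))
  )
}

# parameter vector (named) -> ova_params for a given model spec
assemble_params <- function(vals, mode, n_poly) {
  logRR <- switch(mode,
    none = numeric(0),
    general = c(vals[["logRR1"]], vals[["logRR2"]]),
    vals[["logRR1"]]
  )
  ova_params(
    f1 = vals[["f1"]], f2 = vals[["f2"]],
    fM = if (mode == "none") NA_real_ else vals[["fM"]],
    major_mode = mode, major_logRR = logRR,
    sigma = vals[["sigma"]], sigma_k2 = 0, n_poly = n_poly
  )
}

# log transform for frequencies and sigma, identity for log relative risks
to_theta <- function(vals, free) {
  th <- unlist(vals[free])
  for (nm in free) if (nm %in% c("f1", "f2", "fM", "sigma")) th[nm] <- log(th[nm])
  th
}
from_theta <- function(theta, free, base_vals) {
  vals <- base_vals
  for (i in seq_along(free)) {
    nm <- free[i]
    vals[[nm]] <- if (nm %in% c("f1", "f2", "fM", "sigma")) exp(theta[i]) else theta[i]
  }
  vals
}

#' Fit a genetic susceptibility model by maximum likelihood
#'
#' Maximises the ascertainment-corrected data-set log-likelihood over the
#' free parameters of the chosen model, on a transformed scale (log for
#' allele frequencies and the polygenic SD, identity for log relative
#' risks) with a Nelder-Mead search. The constrained baseline incidences
#' are rebuilt at every parameter vector. Standard errors come from the
#' observed information matrix (central-difference Hessian on the
#' transformed scale); 95% CIs are computed on the transformed scale and
#' back-transformed, so they respect the parameter ranges.
#'
#' @param peds Pedigree tibble.
#' @param model One of `"base"`, `"major_dominant"`, `"major_recessive"`,
#'   `"major_general"`, `"polygenic"`, `"mixed_dominant"`,
#'   `"mixed_recessive"`, `"mixed_general"`.
#' @param fixed Named list of parameters to hold fixed (removed from the
#'   free set), e.g. `list(f1 = 0.0008)`.
#' @param init Named list of starting values for free parameters.
#' @param incidence,carrier_rr Incidence inputs (see [ova_context()]).
#' @param n_poly Polygene grid half-locus count used during fitting.
#' @param control List: `reltol` (convergence tolerance on the relative
#'   log-likelihood change, default 1e-8), `maxit`, `n_restarts` (jittered
#'   restarts attempted when the first search fails to converge), `se`
#'   (compute standard errors, default TRUE).
#' @return An object of class `ova_fit`; see [tidy.ova_fit()] and
#'   [glance.ova_fit()].
#' @export
fit_model <- function(peds, model = "polygenic", fixed = list(), init = list(),
                      incidence = default_incidence(),
                      carrier_rr = default_carrier_rr(),
                      n_poly = 4L, control = list()) {
  spec <- ova_model_specs()[[match.arg(model, names(ova_model_specs()))]]
  ctl <- utils::modifyList(list(reltol = 1e-8, maxit = 2000, n_restarts = 1L, se = TRUE),
                           control)
  defaults <- list(f1 = 5e-4, f2 = 1.5e-3, fM = 1e-3, logRR1 = 2, logRR2 = 3, sigma = 1)
  base_vals <- utils::modifyList(defaults, list(sigma = if ("sigma" %in% spec$free) 1 else 0))
  base_vals <- utils::modifyList(base_vals, fixed)
  free <- setdiff(spec$free, names(fixed))
  base_vals <- utils::modifyList(base_vals, init[names(init) %in% free])
  # a model without a polygene needs no fine polygene grid
  npol <- if ("sigma" %in% spec$free || (!is.null(fixed$sigma) && fixed$sigma > 0)) n_poly else 1L

  plans <- dataset_plans(peds)
  n_evals <- 0L
  negll <- function(theta) {
    vals <- from_theta(theta, free, base_vals)
    p <- try(assemble_params(vals, spec$mode, npol), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    ctx <- try(ova_context(p, incidence, carrier_rr), silent = TRUE)
    if (inherits(ctx, "try-error")) return(1e10)
    n_evals <<- n_evals + 1L
    ll <- sum(dataset_loglik_planned(ctx, plans))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  if (!length(free)) {
    params <- assemble_params(base_vals, spec$mode, npol)
    ll <- -negll(numeric(0))
    return(new_ova_fit(model, params, ll, free = character(0),
                       est = NULL, converged = TRUE, n_evals = n_evals,
                       n_families = length(plans$plans)))
  }

  theta0 <- to_theta(base_vals, free)
  best <- NULL
  set_jitter <- 0
  for (r in seq_len(max(1L, ctl$n_restarts))) {
    start <- theta0 + set_jitter * stats::rnorm(length(theta0))
    opt <- if (length(start) == 1L) {
      stats::optim(start, negll, method = "Brent", lower = start - 12,
                   upper = start + 6,
                   control = list(reltol = ctl$reltol, maxit = ctl$maxit))
    } else {
      stats::optim(start, negll, method = "Nelder-Mead",
                   control = list(reltol = ctl$reltol, maxit = ctl$maxit))
    }
    if (is.null(best) || opt$value < best$value) best <- opt
    if (best$convergence == 0) break
    set_jitter <- 0.3
  }
  theta_hat <- best$par
  vals_hat <- from_theta(theta_hat, free, base_vals)
  params <- assemble_params(vals_hat, spec$mode, npol)
  loglik <- -best$value

  est <- tibble::tibble(term = free,
                        estimate = unlist(vals_hat[free]),
                        se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_)
  if (isTRUE(ctl$se)) {
    H <- central_hessian(negll, theta_hat)
    cov <- try(solve(H), silent = TRUE)
    if (!inherits(cov, "try-error") && all(diag(cov) > 0)) {
      se_t <- sqrt(diag(cov))
      lo_t <- theta_hat - 1.959964 * se_t
      hi_t <- theta_hat + 1.959964 * se_t
      for (i in seq_along(free)) {
        nm <- free[i]
        if (nm %in% c("f1", "f2", "fM", "sigma")) {
          est$se[i] <- exp(theta_hat[i]) * se_t[i]   # delta method
          est$ci_lo[i] <- exp(lo_t[i]); est$ci_hi[i] <- exp(hi_t[i])
        } else {
          est$se[i] <- se_t[i]
          est$ci_lo[i] <- lo_t[i]; est$ci_hi[i] <- hi_t[i]
        }
      }
    } else {
      warning("observed information matrix not positive definite; SEs unavailable")
    }
  }
  new_ova_fit(model, params, loglik, free, est,
              converged = best$convergence == 0, n_evals = n_evals,
              n_families = length(plans$plans))
}

central_hessian <- function(fn, x, h = 1e-3) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(x)
  hh <- pmax(h, h * abs(x))
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, hh[i])
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / hh[i]^2
    if (i < p) for (j in seq((i + 1), p)) {
      ej <- replace(numeric(p), j, hh[j])
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) /
        (4 * hh[i] * hh[j])
    }
  }
  H
}

new_ova_fit <- function(model, params, loglik, free, est, converged, n_evals,
                        n_families) {
  structure(list(
    model = model, params = params, loglik = loglik,
    free_param_names = free, estimates = est, k = length(free),
    aic = aic(loglik, length(free)), converged = converged,
    n_evals = n_evals, n_families = n_families
  ), class = "ova_fit")
}

#' @export
print.ova_fit <- function(x, ...) {
  cat(sprintf("<ova_fit> model \"%s\": loglik %.3f, AIC %.3f (k = %d, %s, %d evals)\n",
              x$model, x$loglik, x$aic, x$k,
              if (x$converged) "converged" else "NOT converged", x$n_evals))
  if (!is.null(x$estimates)) print(x$estimates)
  invisible(x)
}

#' Tidy a fitted susceptibility model
#'
#' @param x An `ova_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `se`, `ci_lo`,
#'   `ci_hi`.
#' @export
tidy.ova_fit <- function(x, ...) {
  if (is.null(x$estimates)) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          se = numeric(), ci_lo = numeric(), ci_hi = numeric()))
  }
  x$estimates
}

#' @rdname tidy.ova_fit
#' @return `glance()`: a one-row tibble with `model`, `loglik`, `k`,
#'   `aic`, `converged`, `n_evals`, `n_families`.
#' @export
glance.ova_fit <- function(x, ...) {
  tibble::tibble(model = x$model, loglik = x$loglik, k = x$k, aic = x$aic,
                 converged = x$converged, n_evals = x$n_evals,
                 n_families = x$n_families)
}

#' Fit the full battery of susceptibility models
#'
#' Fits all eight models (baseline BRCA1/2 only; dominant, recessive and
#' general third major gene; polygenic; and the three mixed models) and
#' compares them: AIC per model and a likelihood ratio test of each model
#' against the richest (mixed general) model, with degrees of freedom
#' equal to the difference in free-parameter counts.
#'
#' @inheritParams fit_model
#' @param models Character vector of models to fit (default: all eight).
#' @return An object of class `ova_battery`: a tibble (one row per model:
#'   estimates, `loglik`, `k`, `aic`, `lrt_p`, `converged`, `error`) with
#'   the individual `ova_fit` objects in attribute `"fits"` and the
#'   minimum-AIC model name in attribute `"best"`.
#' @export
run_model_battery <- function(peds, models = names(ova_model_specs()),
                              fixed = list(), incidence = default_incidence(),
                              carrier_rr = default_carrier_rr(), n_poly = 4L,
                              control = list()) {
  models <- match.arg(models, names(ova_model_specs()), several.ok = TRUE)
  fits <- list()
  rows <- list()
  for (m in models) {
    fit <- tryCatch(
      fit_model(peds, m, fixed = fixed, incidence = incidence,
                carrier_rr = carrier_rr, n_poly = n_poly, control = control),
      error = function(e) e
    )
    fits[[m]] <- fit
    if (inherits(fit, "error")) {
      rows[[m]] <- tibble::tibble(model = m, error = conditionMessage(fit))
    } else {
      g <- function(term) {
        i <- match(term, fit$free_param_names)
        if (is.na(i)) NA_real_ else fit$estimates$estimate[i]
      }
      rows[[m]] <- tibble::tibble(
        model = m, f1 = fit$params$f1, f2 = fit$params$f2,
        fM = g("fM"), logRR1 = g("logRR1"), logRR2 = g("logRR2"),
        sigma = g("sigma"),
        loglik = fit$loglik, k = fit$k, aic = fit$aic,
        converged = fit$converged, error = NA_character_
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  ok <- is.na(out$error)
  if ("mixed_general" %in% out$model[ok]) {
    ll_rich <- out$loglik[out$model == "mixed_general"]
    k_rich <- out$k[out$model == "mixed_general"]
    out$lrt_p <- NA_real_
    for (i in which(ok)) {
      if (out$model[i] != "mixed_general" && out$k[i] < k_rich) {
        out$lrt_p[i] <- lrt(out$loglik[i], max(ll_rich, out$loglik[i]),
                            k_rich - out$k[i])
      }
    }
  }
  best <- if (any(ok)) out$model[ok][which.min(out$aic[ok])] else NA_character_
  structure(out, fits = fits, best = best, class = c("ova_battery", class(out)))
}

#' @export
print.ova_battery <- function(x, ...) {
  cat("<ova_battery> minimum-AIC model:", attr(x, "best"), "\n")
  NextMethod()
}
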