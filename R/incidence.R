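#' Birth-cohort labels
#'
#' The eight birth cohorts used throughout: pre-1920, the six decades
#' 1920s-1970s, and post-1980.
#'
#' @return Character vector of cohort labels, oldest first.
#' @export
ova_cohorts <- function() {
  c("pre1920", "1920s", "1930s", "1940s", "1950s", "1960s", "1970s", "post1980")
}

#' Map birth years to cohorts
#'
#' @param birth_year Integer vector of birth years (`NA` allowed).
#' @return Character vector of cohort labels; `NA` years map to `NA`.
#' @export
cohort_of <- function(birth_year) {
  labs <- ova_cohorts()
  idx <- findInterval(birth_year, c(1920, 1930, 1940, 1950, 1960, 1970, 1980)) + 1L
  out <- labs[idx]
  out[is.na(birth_year)] <- NA_character_
  out
}

#' Illustrative population incidence tables
#'
#' Synthetic smooth per-year hazards for ovarian and breast cancer by birth
#' cohort, calibrated so that the 1940s cohort has a cumulative risk to age
#' 80 of 0.02 (ovarian) and 0.10 (breast), with a mild linear trend of
#' +/- ~10% across cohorts. Ovarian hazard rises quadratically from age 20,
#' breast hazard as power 1.5 from age 25 -- shapes chosen to mimic the
#' age-incidence curves of registry data while remaining fully synthetic.
#'
#' @return A tibble with columns `disease` (`"ovarian"`/`"breast"`),
#'   `cohort`, `age` (0..79) and `hazard` (per-year).
#' @export
default_incidence <- function() {
  ages <- 0:79
  shape_ov <- pmax(ages - 20, 0)^2
  shape_bc <- pmax(ages - 25, 0)^1.5
  h_ov <- shape_ov * (-log(1 - 0.02) / sum(shape_ov))
  h_bc <- shape_bc * (-log(1 - 0.10) / sum(shape_bc))
  cohorts <- ova_cohorts()
  trend <- 1 + 0.03 * (seq_along(cohorts) - 4L) # 1940s cohort = 1 exactly
  purrr::map2_dfr(cohorts, trend, function(coh, tr) {
    tibble::tibble(
      disease = rep(c("ovarian", "breast"), each = length(ages)),
      cohort = coh, age = rep(ages, 2L),
      hazard = c(h_ov, h_bc) * tr
    )
  })
}

#' Illustrative BRCA1/BRCA2 carrier relative risks
#'
#' Age-band relative risks of ovarian and breast cancer for mutation
#' carriers versus population incidence, expanded to per-year values.
#' These emulate the magnitude and age pattern of published external
#' carrier-risk estimates (strong mid-life excess for BRCA1 ovarian
#' cancer, later and weaker for BRCA2) but are illustrative values
#' shipped for self-contained use.
#'
#' @return A tibble with columns `gene`, `disease`, `age` (0..79), `rr`.
#' @export
default_carrier_rr <- function() {
  band <- function(gene, disease, lo, hi, rr) {
    tibble::tibble(gene = gene, disease = disease, age = lo:(hi - 1L), rr = rr)
  }
  dplyr::bind_rows(
    band("brca1", "ovarian", 0, 40, 5), band("brca1", "ovarian", 40, 50, 40),
    band("brca1", "ovarian", 50, 60, 35), band("brca1", "ovarian", 60, 70, 20),
    band("brca1", "ovarian", 70, 80, 10),
    band("brca2", "ovarian", 0, 40, 2), band("brca2", "ovarian", 40, 50, 8),
    band("brca2", "ovarian", 50, 60, 12), band("brca2", "ovarian", 60, 70, 10),
    band("brca2", "ovarian", 70, 80, 6),
    band("brca1", "breast", 0, 40, 15), band("brca1", "breast", 40, 50, 10),
    band("brca1", "breast", 50, 60, 7), band("brca1", "breast", 60, 80, 4),
    band("brca2", "breast", 0, 40, 10), band("brca2", "breast", 40, 50, 8),
    band("brca2", "breast", 50, 60, 6), band("brca2", "breast", 60, 80, 4)
  )
}

#' Read incidence / carrier relative-risk tables from CSV
#'
#' `read_incidence()` expects columns `disease, cohort, age_lo, age_hi,
#' hazard_per_year`; `read_carrier_rr()` expects `gene, disease, age_lo,
#' age_hi, rr`. Age bands `[age_lo, age_hi)` are expanded to per-year rows
#' by replication.
#'
#' @param path CSV file path.
#' @return A per-year tibble in the format of [default_incidence()] or
#'   [default_carrier_rr()].
#' @export
read_incidence <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("disease", "cohort", "age_lo", "age_hi", "hazard_per_year")
  if (!all(need %in% names(x))) {
    stop("incidence CSV must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(x$hazard_per_year < 0)) stop("hazards must be >= 0", call. = FALSE)
  tidyr::uncount(x, weights = .data$age_hi - .data$age_lo, .id = "off") |>
    dplyr::mutate(age = .data$age_lo + .data$off - 1L, hazard = .data$hazard_per_year) |>
    dplyr::select("disease", "cohort", "age", "hazard") |>
    dplyr::arrange(.data$disease, .data$cohort, .data$age)
}

#' @rdname read_incidence
#' @export
read_carrier_rr <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("gene", "disease", "age_lo", "age_hi", "rr")
  if (!all(need %in% names(x))) {
    stop("carrier RR CSV must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(x$rr <= 0)) stop("relative risks must be > 0", call. = FALSE)
  tidyr::uncount(x, weights = .data$age_hi - .data$age_lo, .id = "off") |>
    dplyr::mutate(age = .data$age_lo + .data$off - 1L) |>
    dplyr::select("gene", "disease", "age", "rr") |>
    dplyr::arrange(.data$gene, .data$disease, .data$age)
}

# per-cohort hazard matrix [cohort, age 0..79] for one disease
incidence_matrix <- function(inc, disease) {
  cohorts <- ova_cohorts()
  sub <- inc[inc$disease == disease, ]
  m <- matrix(NA_real_, length(cohorts), 80, dimnames = list(cohorts, NULL))
  for (i in seq_along(cohorts)) {
    s <- sub[sub$cohort == cohorts[i], ]
    s <- s[order(s$age), ]
    if (nrow(s) != 80L || !identical(as.integer(s$age), 0:79)) {
      stop(sprintf("incidence table for %s / %s must cover ages 0..79", disease, cohorts[i]),
           call. = FALSE)
    }
    m[i, ] <- s$hazard
  }
  m
}

rr_vector <- function(rr_tbl, gene, disease) {
  s <- rr_tbl[rr_tbl$gene == gene & rr_tbl$disease == disease, ]
  s <- s[order(s$age), ]
  if (nrow(s) != 80L) stop(sprintf("carrier RR table for %s / %s must cover ages 0..79",
                                   gene, disease), call. = FALSE)
  s$rr
}

#' Constrain genotype-specific baseline incidences to population rates
#'
#' Given population incidences, external carrier relative risks and model
#' parameters, computes baseline hazards for the non-carrier, BRCA1-carrier
#' and BRCA2-carrier strata such that, at every age and in every cohort,
#' the model-averaged incidence over all genetic effects (major genotypes x
#' polygene, weighted by founder priors and survival from the modelled
#' disease) equals the population incidence, and the averaged incidence
#' within each carrier stratum equals the population incidence times the
#' external carrier relative risk. The breast-cancer channel is constrained
#' the same way, except that its incidence depends only on BRCA1/BRCA2
#' status (polygene and third-gene relative risk identically 1).
#'
#' Ages are iterated forward: the at-risk genotype distribution at age t is
#' the founder prior reweighted by genotype-specific survival to t from the
#' modelled disease only (no competing mortality, matching follow-up that
#' stops at age 80).
#'
#' @param pop Population incidence tibble ([default_incidence()] format).
#' @param carrier Carrier relative-risk tibble ([default_carrier_rr()]
#'   format).
#' @param params An [ova_params()] object.
#' @param grid A [polygene_grid()]; defaults to the grid implied by
#'   `params`.
#' @return An object of class `ova_baselines`: arrays
#'   `lambda0_ovc[stratum, cohort, age]` and `lambda0_bc[...]` with strata
#'   `none`, `brca1`, `brca2`, plus cumulative versions `cum_ovc`,
#'   `cum_bc` (`[stratum, cohort, age 0..80]`, cumulative hazard from
#'   birth to the start of each age).
#' @export
constrain_baselines <- function(pop, carrier, params,
                                grid = polygene_grid(params$n_poly, params$sigma)) {
  validate_params(params)
  cohorts <- ova_cohorts()
  strata <- c("none", "brca1", "brca2")
  st <- major_states(params)
  G <- nrow(st); R <- length(grid$levels)

  lam_ovc <- constrain_channel(
    hazmat = incidence_matrix(pop, "ovarian"),
    rr1 = rr_vector(carrier, "brca1", "ovarian"),
    rr2 = rr_vector(carrier, "brca2", "ovarian"),
    prior = as.vector(outer(st$prior, grid$pop_probs)),
    mult = as.vector(outer(exp(st$logM), exp(grid$values))),
    stratum = rep(st$stratum, times = R)
  )
  lam_bc <- constrain_channel(
    hazmat = incidence_matrix(pop, "breast"),
    rr1 = rr_vector(carrier, "brca1", "breast"),
    rr2 = rr_vector(carrier, "brca2", "breast"),
    prior = st$prior,
    mult = rep(1, G),
    stratum = st$stratum
  )
  dimnames(lam_ovc) <- dimnames(lam_bc) <- list(strata, cohorts, NULL)
  cum <- function(lam) {
    out <- array(0, dim = c(3L, length(cohorts), 81L), dimnames = list(strata, cohorts, NULL))
    out[, , 2:81] <- aperm(apply(lam, c(1, 2), cumsum), c(2, 3, 1))
    out
  }
  structure(list(
    lambda0_ovc = lam_ovc, lambda0_bc = lam_bc,
    cum_ovc = cum(lam_ovc), cum_bc = cum(lam_bc)
  ), class = "ova_baselines")
}

# Forward-in-age constraint for one disease channel. States are described
# by founder prior, multiplicative (third gene x polygene) relative risk
# and BRCA stratum; returns lambda0[stratum, cohort, age].
constrain_channel <- function(hazmat, rr1, rr2, prior, mult, stratum) {
  ncoh <- nrow(hazmat)
  if (any(hazmat < 0)) stop("negative population hazard", call. = FALSE)
  lam0 <- array(NA_real_, dim = c(3L, ncoh, 80L))
  is1 <- stratum == "brca1"; is2 <- stratum == "brca2"; is0 <- stratum == "none"
  # fallback conditional mean multiplier when a stratum has zero prior mass
  e_fallback <- sum(prior[is0] * mult[is0]) / sum(prior[is0])
  S <- length(prior)
  surv <- matrix(1, S, ncoh)   # all cohorts advanced in lockstep
  pm <- prior * mult
  for (t in 1:80) {
    lp <- hazmat[, t]
    A <- .colSums(prior * surv, S, ncoh)
    if (any(A <= 0)) stop("all survival probabilities underflowed in baseline constraint",
                          call. = FALSE)
    A1 <- .colSums(prior[is1] * surv[is1, , drop = FALSE], sum(is1), ncoh)
    W1 <- .colSums(pm[is1] * surv[is1, , drop = FALSE], sum(is1), ncoh)
    A2 <- .colSums(prior[is2] * surv[is2, , drop = FALSE], sum(is2), ncoh)
    W2 <- .colSums(pm[is2] * surv[is2, , drop = FALSE], sum(is2), ncoh)
    W0 <- .colSums(pm[is0] * surv[is0, , drop = FALSE], sum(is0), ncoh)
    l1 <- ifelse(A1 > 0, lp * rr1[t] * A1 / W1, lp * rr1[t] / e_fallback)
    l2 <- ifelse(A2 > 0, lp * rr2[t] * A2 / W2, lp * rr2[t] / e_fallback)
    l0 <- lp * (A - rr1[t] * A1 - rr2[t] * A2) / W0
    if (any(l0 < 0)) {
      stop("carrier burden exceeds population incidence; baseline would be negative",
           call. = FALSE)
    }
    lam0[1, , t] <- l0; lam0[2, , t] <- l1; lam0[3, , t] <- l2
    lam_strat <- rbind(l0, l1, l2)[match(stratum, c("none", "brca1", "brca2")), ,
                                   drop = FALSE]
    surv <- surv * exp(-mult * lam_strat)
  }
  lam0
}

#' Cumulative risk from a per-year hazard vector
#'
#' `1 - exp(-sum(hazard over [from_age, to_age)))` under piecewise-constant
#' per-year hazards.
#'
#' @param hazard Per-year hazard vector for ages `0..(length(hazard) - 1)`.
#' @param from_age,to_age Integer ages with
#'   `0 <= from_age < to_age <= length(hazard)`.
#' @return Cumulative risk in \[0, 1\].
#' @export
#' @examples
#' cumulative_risk(rep(2.5e-4, 80), 0, 80)  # ~ 0.02 lifetime risk
cumulative_risk <- function(hazard, from_age, to_age) {
  if (from_age >= to_age) stop("`from_age` must be < `to_age`", call. = FALSE)
  if (from_age < 0 || to_age > length(hazard)) stop("ages out of range", call. = FALSE)
  1 - exp(-sum(hazard[(from_age + 1):to_age]))
}
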