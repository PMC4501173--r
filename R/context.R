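#' Penetrance context
#'
#' Precomputes everything a likelihood evaluation needs for a fixed set of
#' model parameters: the major-genotype state table, the polygene grid,
#' the constrained baseline incidences, founder priors and transmission
#' matrices over the combined genotype x polygene state space. Baselines
#' are (re)constrained inside this constructor, so a fresh context must be
#' built whenever parameters change -- fitting code does exactly that for
#' every parameter vector it visits.
#'
#' Combined states are laid out genotype-fastest: state `s = g + (r-1) * G`
#' for major genotype `g` of `G` and polygene level index `r` of `R`.
#'
#' @param params An [ova_params()] object.
#' @param incidence Population incidence tibble ([default_incidence()]
#'   format).
#' @param carrier_rr Carrier relative-risk tibble ([default_carrier_rr()]
#'   format).
#' @return An object of class `ova_ctx`.
#' @export
ova_context <- function(params, incidence = default_incidence(),
                        carrier_rr = default_carrier_rr()) {
  validate_params(params)
  grid <- polygene_grid(params$n_poly, params$sigma)
  st <- major_states(params)
  G <- nrow(st)
  R <- length(grid$levels)
  baselines <- constrain_baselines(incidence, carrier_rr, params, grid)

  TM <- major_transmission(params)                 # [child, mother, father]
  TP <- grid$transmission
  TMmat <- matrix(aperm(TM, c(2, 3, 1)), G * G, G) # rows (gm,gf), col gc
  TPmat <- matrix(aperm(TP, c(2, 3, 1)), R * R, R)
  priorG <- st$prior
  popR <- grid$pop_probs
  # father-averaged single-parent transmissions (founder prior built in)
  TMavg <- apply(TM, c(1, 2), function(x) sum(x * priorG)) # [gc, gm]
  TPavg <- apply(TP, c(1, 2), function(x) sum(x * popR))   # [rc, rm]

  stratum_idx <- match(st$stratum, c("none", "brca1", "brca2"))
  S2 <- (G * R)^2
  structure(list(
    params = params, grid = grid, states = st, G = G, R = R,
    nstates = G * R, baselines = baselines,
    incidence = incidence, carrier_rr = carrier_rr,
    prior = as.vector(outer(priorG, popR)),
    priorG = priorG, popR = popR,
    TMmat = TMmat, TPmat = TPmat, TMavg = TMavg, TPavg = TPavg,
    # index permutations replacing aperm() in the peeling inner loop
    perm_K = as.vector(aperm(array(seq_len(S2), c(G, G, R, R)), c(1, 3, 2, 4))),
    perm_W = as.vector(aperm(array(seq_len(S2), c(G, R, G, R)), c(2, 4, 1, 3))),
    stratum_idx = stratum_idx, logM = st$logM, values = grid$values,
    cohorts = ova_cohorts()
  ), class = "ova_ctx")
}

#' @export
print.ova_ctx <- function(x, ...) {
  cat(sprintf("<ova_ctx> %d major genotypes x %d polygene levels (%d states)\n",
              x$G, x$R, x$nstates))
  print(x$params)
  invisible(x)
}

# Per-individual data needed by the penetrance, derived from a pedigree row
ped_pen_data <- function(peds) {
  coh <- cohort_of(peds$birth_year)
  coh[is.na(coh)] <- "1940s"
  ovc_event <- !is.na(peds$ovca_age)
  t_ovc <- ifelse(ovc_event, peds$ovca_age, peds$status_age)
  bc_event <- !is.na(peds$brca_age)
  t_bc <- ifelse(bc_event, peds$brca_age, peds$status_age)
  tibble::tibble(
    female = peds$sex == "F",
    k = match(coh, ova_cohorts()),
    ovc_event = ovc_event, t_ovc = t_ovc,
    bc_event = bc_event, t_bc = t_bc,
    test1 = peds$brca1_test, test2 = peds$brca2_test
  )
}

# Penetrance matrix [nstates x n individuals].
#
# Per state (g, r) and individual i the value is the product of
#  - the ovarian-cancer channel: survival to the censoring age under hazard
#    lambda0[stratum(g)] * exp(M_g + P_r), times the hazard at the event
#    age if affected; females with a usable age only,
#  - the breast-cancer channel: same with the BRCA-stratum baseline and no
#    polygene / third-gene multiplier,
#  - mutation-test factors per gene: P(pos|carrier) = sensitivity,
#    P(neg|carrier) = 1 - sensitivity, P(pos|non-carrier) = 0.
# Individuals with no usable phenotype contribute test factors only.
#
# `override_values`: optional list(idx =, values =) replacing the polygene
# log relative risks of one individual (PRS conditioning of a counselee).
pen_matrix <- function(ctx, peds, override_values = NULL) {
  pd <- ped_pen_data(peds)
  N <- nrow(pd)
  G <- ctx$G; R <- ctx$R
  PEN <- matrix(1, ctx$nstates, N)
  bl <- ctx$baselines
  sens <- c(ctx$params$sensitivity1, ctx$params$sensitivity2)
  test_factor <- function(test, carrier, s) {
    f <- rep(1, length(test))
    f[test == "P"] <- ifelse(carrier, s, 0)
    f[test == "N"] <- ifelse(carrier, 1 - s, 1)
    f
  }
  ovc_on <- pd$female & !is.na(pd$t_ovc)
  bc_on <- pd$female & !is.na(pd$t_bc)
  t_ovc <- pmin(pd$t_ovc, 80); t_bc <- pmin(pd$t_bc, 80)
  a_ovc <- pmin(t_ovc, 79)     # hazard lookup for events recorded at 80
  a_bc <- pmin(t_bc, 79)
  for (g in seq_len(G)) {
    si <- ctx$stratum_idx[g]
    mu <- exp(ctx$logM[g] + ctx$values)        # length R
    carrier1 <- ctx$states$b1[g] >= 1L
    carrier2 <- ctx$states$b2[g] >= 1L
    fac <- test_factor(pd$test1, carrier1, sens[1]) *
      test_factor(pd$test2, carrier2, sens[2])
    # breast-cancer channel (no polygene)
    if (any(bc_on)) {
      i <- which(bc_on)
      cb <- bl$cum_bc[cbind(si, pd$k[i], floor(t_bc[i]) + 1L)]
      f <- exp(-cb)
      ev <- pd$bc_event[i]
      if (any(ev)) {
        f[ev] <- f[ev] * bl$lambda0_bc[cbind(si, pd$k[i][ev], floor(a_bc[i][ev]) + 1L)]
      }
      fac[i] <- fac[i] * f
    }
    # ovarian-cancer channel: N x R block
    block <- matrix(fac, N, R)
    if (any(ovc_on)) {
      i <- which(ovc_on)
      cb <- bl$cum_ovc[cbind(si, pd$k[i], floor(t_ovc[i]) + 1L)]
      srv <- exp(-outer(cb, mu))               # length(i) x R
      ev <- pd$ovc_event[i]
      if (any(ev)) {
        l0 <- bl$lambda0_ovc[cbind(si, pd$k[i][ev], floor(a_ovc[i][ev]) + 1L)]
        srv[ev, ] <- srv[ev, , drop = FALSE] * outer(l0, mu)
      }
      block[i, ] <- block[i, ] * srv
    }
    PEN[seq(g, by = G, length.out = R), ] <- t(block)
  }
  if (!is.null(override_values)) {
    i <- override_values$idx
    PEN[, i] <- pen_vector_one(ctx, pd[i, ], override_values$values)
  }
  PEN
}

# Penetrance vector for a single individual with custom polygene values.
pen_vector_one <- function(ctx, pd, values) {
  G <- ctx$G; R <- ctx$R
  bl <- ctx$baselines
  sens <- c(ctx$params$sensitivity1, ctx$params$sensitivity2)
  out <- matrix(1, G, R)
  for (g in seq_len(G)) {
    si <- ctx$stratum_idx[g]
    mu <- exp(ctx$logM[g] + values)
    f <- 1
    tf <- function(test, carrier, s) {
      if (test == "P") { if (carrier) s else 0 }
      else if (test == "N") { if (carrier) 1 - s else 1 }
      else 1
    }
    f <- f * tf(pd$test1, ctx$states$b1[g] >= 1L, sens[1]) *
      tf(pd$test2, ctx$states$b2[g] >= 1L, sens[2])
    if (pd$female && !is.na(pd$t_bc)) {
      t <- min(pd$t_bc, 80)
      f <- f * exp(-bl$cum_bc[si, pd$k, floor(t) + 1L])
      if (pd$bc_event) f <- f * bl$lambda0_bc[si, pd$k, floor(min(t, 79)) + 1L]
    }
    row <- rep(f, R)
    if (pd$female && !is.na(pd$t_ovc)) {
      t <- min(pd$t_ovc, 80)
      row <- row * exp(-bl$cum_ovc[si, pd$k, floor(t) + 1L] * mu)
      if (pd$ovc_event) row <- row * bl$lambda0_ovc[si, pd$k, floor(min(t, 79)) + 1L] * mu
    }
    out[g, ] <- row
  }
  as.vector(out)
}

#' Penetrance of one individual across the genetic state space
#'
#' The likelihood contribution of a single individual's phenotype and test
#' results for every major genotype x polygene level, given a penetrance
#' context.
#'
#' @param peds Pedigree tibble.
#' @param id Individual id (with `family_id` if ambiguous).
#' @param ctx An [ova_context()].
#' @param family_id Optional family id to disambiguate.
#' @return A tibble with the state columns of [major_states()], the
#'   polygene `level`, its log relative risk `value` and the penetrance
#'   `pen`.
#' @export
individual_penetrance <- function(peds, id, ctx, family_id = NULL) {
  row <- peds[peds$id == id &
                (if (is.null(family_id)) TRUE else peds$family_id == family_id), ]
  if (nrow(row) != 1L) stop("individual not uniquely identified", call. = FALSE)
  v <- pen_matrix(ctx, row)[, 1]
  out <- tidyr::expand_grid(
    level = ctx$grid$levels,
    g = seq_len(ctx$G)
  )
  st <- ctx$states[out$g, setdiff(names(ctx$states), c("prior", "logM"))]
  dplyr::bind_cols(st, tibble::tibble(
    level = out$level, value = ctx$grid$values[out$level + 1L], pen = v
  ))
}
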