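#' Simulation design for ascertained families
#'
#' Describes the generative process for families ascertained through an
#' ovarian-cancer proband, emulating a population-based case series with
#' relatives reported by questionnaire: probands recruited 1999-2010 at
#' ages 40-70 (uniform), mothers with recorded phenotype for ~87% of
#' probands, and sister/daughter counts with means matching roughly 0.9
#' sisters and 0.74 daughters per proband.
#'
#' @param n_families Number of ascertained families to generate.
#' @param params True [ova_params()] generating the data.
#' @param incidence,carrier_rr Incidence inputs (see [ova_context()]).
#' @param p_mother Probability the mother's phenotype is observed.
#' @param mean_sisters,mean_daughters Poisson means for sister/daughter
#'   counts.
#' @param recruit_years,recruit_ages Ranges the proband's recruitment
#'   year and age are drawn from (uniform).
#' @return A list of class `ova_sim_design`.
#' @export
sim_design <- function(n_families, params = ova_params(),
                       incidence = default_incidence(),
                       carrier_rr = default_carrier_rr(),
                       p_mother = 0.87, mean_sisters = 0.91,
                       mean_daughters = 0.74,
                       recruit_years = 1999:2010, recruit_ages = 40:70) {
  structure(list(
    n_families = n_families, params = params, incidence = incidence,
    carrier_rr = carrier_rr, p_mother = p_mother, mean_sisters = mean_sisters,
    mean_daughters = mean_daughters, recruit_years = recruit_years,
    recruit_ages = recruit_ages
  ), class = "ova_sim_design")
}

# sample onset ages (integer, NA = no event by 80) given per-individual
# cumulative-hazard rows [n x 81]
sample_onset <- function(cumhaz) {
  E <- stats::rexp(nrow(cumhaz))
  onset <- rowSums(cumhaz[, 2:81, drop = FALSE] <= E)
  onset[E >= cumhaz[, 81]] <- NA
  onset
}

# per-individual cumulative baseline hazard rows times multiplier
cum_rows <- function(cum, stratum, k, mult = 1) {
  out <- matrix(0, length(stratum), 81L)
  for (s in unique(stratum)) for (kk in unique(k)) {
    i <- which(stratum == s & k == kk)
    if (length(i)) out[i, ] <- outer(rep(1, length(i)), cum[s, kk, ])
  }
  out * mult
}

hwe_draw <- function(n, f) {
  sample.int(3L, n, replace = TRUE, prob = c((1 - f)^2, 2 * f * (1 - f), f^2)) - 1L
}

transmit_locus <- function(cm, cf) {
  stats::rbinom(length(cm), 1L, cm / 2) + stats::rbinom(length(cf), 1L, cf / 2)
}

stratum_of <- function(b1, b2) ifelse(b1 >= 1L, 2L, ifelse(b2 >= 1L, 3L, 1L))

#' Simulate ascertained pedigrees
#'
#' Forward simulation under the full genetic model: founder genotypes from
#' Hardy-Weinberg and Binomial(2n, 1/2) priors, Mendelian plus
#' hypergeometric transmission, ovarian- and breast-cancer onset ages
#' drawn from the genotype-specific hazards (constrained baselines times
#' relative risks), censoring at the questionnaire, and ascertainment by
#' rejection: a family enters the sample only if its designated proband
#' has ovarian cancer by her recruitment age -- the generative mirror of
#' the proband-conditioned likelihood. Probands receive BRCA1/2 test
#' results generated with the screening sensitivities, and a polygenic
#' risk score consistent with their simulated polygene; relatives are
#' untested.
#'
#' @param design A [sim_design()].
#' @param seed Integer seed; the output is fully determined by it.
#' @param max_batches Safety cap on rejection-sampling batches.
#' @return A validated pedigree tibble ([pedigree-format]).
#' @export
simulate_pedigrees <- function(design, seed = 1L, max_batches = 400L) {
  stopifnot(inherits(design, "ova_sim_design"))
  set.seed(seed)
  par <- design$params
  ctx <- ova_context(par, design$incidence, design$carrier_rr)
  n <- ctx$grid$n
  acc <- list()
  got <- 0L
  batch <- max(2000L, design$n_families * 2L)
  for (b in seq_len(max_batches)) {
    cand <- sim_proband_batch(batch, design, ctx)
    keep <- which(!is.na(cand$onset) & cand$onset <= cand$recruit_age)
    if (length(keep)) {
      acc[[length(acc) + 1L]] <- cand[keep, ]
      got <- got + length(keep)
    }
    if (got >= design$n_families) break
  }
  if (got < design$n_families) {
    stop("ascertainment failed: too few affected probands; increase `max_batches`",
         call. = FALSE)
  }
  pros <- dplyr::bind_rows(acc)[seq_len(design$n_families), ]
  pros$family_id <- sprintf("F%05d", seq_len(design$n_families))
  as_pedigrees(sim_members_batch(pros, design, ctx))
}

# Stage 2 (vectorised): relatives of all accepted probands at once,
# conditional on the parent genotypes drawn in stage 1.
sim_members_batch <- function(pros, design, ctx) {
  par <- design$params
  n <- ctx$grid$n
  has_m3 <- par$major_mode != "none"
  nf <- nrow(pros)
  qyear <- pros$recruit_year

  blank <- function(fid, id, sex, fa, mo, rel, by = NA_real_) {
    tibble::tibble(family_id = fid, id = id, father_id = fa, mother_id = mo,
                   sex = sex, birth_year = by, ovca_age = NA_real_,
                   brca_age = NA_real_, status_age = NA_real_, vital = "U",
                   brca1_test = "U", brca2_test = "U", prs_value = NA_real_,
                   proband = FALSE, relation = rel)
  }
  onset_within <- function(b1, b2, m3, r, k, cens, disease) {
    on <- sample_onset(indiv_cumhaz(ctx, b1, b2, m3, r, k, disease))
    ifelse(!is.na(on) & on < cens, on, NA_real_)
  }
  kof <- function(by) match(cohort_of(by), ova_cohorts())

  # probands: breast-cancer history to recruitment, tests, PRS
  bc <- onset_within(pros$b1, pros$b2, pros$m3, pros$r, pros$k,
                     pros$recruit_age, "breast")
  pval <- ctx$grid$values[pros$r + 1L]
  sk2 <- par$sigma_k2; s2 <- par$sigma^2
  prs <- if (sk2 > 0 && s2 > 0) {
    stats::rnorm(nf, (sk2 / s2) * pval, sqrt(sk2 * (s2 - sk2) / s2))
  } else NA_real_
  pro_rows <- tibble::tibble(
    family_id = pros$family_id, id = "pro", father_id = "dad", mother_id = "mum",
    sex = "F", birth_year = pros$birth_year, ovca_age = as.numeric(pros$onset),
    brca_age = bc, status_age = as.numeric(pros$recruit_age), vital = "A",
    brca1_test = test_result(pros$b1 >= 1L, par$sensitivity1),
    brca2_test = test_result(pros$b2 >= 1L, par$sensitivity2),
    prs_value = prs, proband = TRUE, relation = "proband"
  )

  # mothers: phenotype observed with probability p_mother
  mo_by <- pros$birth_year - sample(20:35, nf, replace = TRUE)
  seen <- stats::runif(nf) < design$p_mother
  mo_cens <- pmin(80, qyear - mo_by)
  mo_ov <- onset_within(pros$mb1, pros$mb2, pros$mm3, pros$mr, kof(mo_by),
                        mo_cens, "ovarian")
  mo_bc <- onset_within(pros$mb1, pros$mb2, pros$mm3, pros$mr, kof(mo_by),
                        mo_cens, "breast")
  mum_rows <- blank(pros$family_id, "mum", "F", NA_character_, NA_character_, "mother")
  mum_rows$birth_year[seen] <- mo_by[seen]
  mum_rows$ovca_age[seen] <- mo_ov[seen]
  mum_rows$brca_age[seen] <- mo_bc[seen]
  mum_rows$status_age[seen] <- mo_cens[seen]
  mum_rows$vital[seen] <- "A"
  dad_rows <- blank(pros$family_id, "dad", "M", NA_character_, NA_character_, "father")

  # sisters: full siblings of the proband
  ns <- stats::rpois(nf, design$mean_sisters)
  si <- rep(seq_len(nf), ns)
  sis_rows <- NULL
  if (length(si)) {
    by <- pros$birth_year[si] + sample(c(-8:-1, 1:8), length(si), replace = TRUE)
    cens <- pmin(80, qyear[si] - by)
    b1 <- transmit_locus(pros$mb1[si], pros$fb1[si])
    b2 <- transmit_locus(pros$mb2[si], pros$fb2[si])
    m3 <- if (has_m3) transmit_locus(pros$mm3[si], pros$fm3[si]) else rep(0L, length(si))
    r <- stats::rhyper(length(si), pros$mr[si], 2L * n - pros$mr[si], n) +
      stats::rhyper(length(si), pros$fr[si], 2L * n - pros$fr[si], n)
    keep <- cens > 0
    if (any(keep)) {
      si2 <- si[keep]
      sis_rows <- blank(pros$family_id[si2],
                        paste0("sis", sequence(ns)[keep]), "F", "dad", "mum",
                        "sister", by[keep])
      sis_rows$ovca_age <- onset_within(b1[keep], b2[keep], m3[keep], r[keep],
                                        kof(by[keep]), cens[keep], "ovarian")
      sis_rows$brca_age <- onset_within(b1[keep], b2[keep], m3[keep], r[keep],
                                        kof(by[keep]), cens[keep], "breast")
      sis_rows$status_age <- cens[keep]
      sis_rows$vital <- "A"
    }
  }

  # daughters, through an unobserved partner
  nd <- stats::rpois(nf, design$mean_daughters)
  hb1 <- hwe_draw(nf, par$f1); hb2 <- hwe_draw(nf, par$f2)
  hm3 <- if (has_m3) hwe_draw(nf, par$fM) else rep(0L, nf)
  hr <- stats::rbinom(nf, 2L * n, 0.5)
  di <- rep(seq_len(nf), nd)
  dau_rows <- NULL
  hub_fams <- character(0)
  if (length(di)) {
    by <- pros$birth_year[di] + sample(20:35, length(di), replace = TRUE)
    cens <- pmin(80, qyear[di] - by)
    b1 <- transmit_locus(pros$b1[di], hb1[di])
    b2 <- transmit_locus(pros$b2[di], hb2[di])
    m3 <- if (has_m3) transmit_locus(pros$m3[di], hm3[di]) else rep(0L, length(di))
    r <- stats::rhyper(length(di), pros$r[di], 2L * n - pros$r[di], n) +
      stats::rhyper(length(di), hr[di], 2L * n - hr[di], n)
    keep <- cens > 0
    if (any(keep)) {
      di2 <- di[keep]
      dau_rows <- blank(pros$family_id[di2],
                        paste0("dau", sequence(nd)[keep]), "F", "hub", "pro",
                        "daughter", by[keep])
      dau_rows$ovca_age <- onset_within(b1[keep], b2[keep], m3[keep], r[keep],
                                        kof(by[keep]), cens[keep], "ovarian")
      dau_rows$brca_age <- onset_within(b1[keep], b2[keep], m3[keep], r[keep],
                                        kof(by[keep]), cens[keep], "breast")
      dau_rows$status_age <- cens[keep]
      dau_rows$vital <- "A"
      hub_fams <- unique(pros$family_id[di2])
    }
  }
  hub_rows <- if (length(hub_fams)) {
    blank(hub_fams, "hub", "M", NA_character_, NA_character_, "partner")
  } else NULL

  out <- dplyr::bind_rows(pro_rows, mum_rows, dad_rows, sis_rows, dau_rows, hub_rows)
  out[order(match(out$family_id, pros$family_id)), ]
}

# Stage 1: candidate probands with their parents' genotypes (vectorised).
sim_proband_batch <- function(m, design, ctx) {
  par <- design$params
  n <- ctx$grid$n
  has_m3 <- par$major_mode != "none"
  d <- tibble::tibble(
    recruit_year = sample(design$recruit_years, m, replace = TRUE),
    recruit_age = sample(design$recruit_ages, m, replace = TRUE),
    fb1 = hwe_draw(m, par$f1), fb2 = hwe_draw(m, par$f2),
    mb1 = hwe_draw(m, par$f1), mb2 = hwe_draw(m, par$f2),
    fm3 = if (has_m3) hwe_draw(m, par$fM) else 0L,
    mm3 = if (has_m3) hwe_draw(m, par$fM) else 0L,
    fr = stats::rbinom(m, 2L * n, 0.5), mr = stats::rbinom(m, 2L * n, 0.5)
  )
  d$birth_year <- d$recruit_year - d$recruit_age
  d$b1 <- transmit_locus(d$mb1, d$fb1)
  d$b2 <- transmit_locus(d$mb2, d$fb2)
  d$m3 <- if (has_m3) transmit_locus(d$mm3, d$fm3) else 0L
  d$r <- stats::rhyper(m, d$mr, 2L * n - d$mr, n) +
    stats::rhyper(m, d$fr, 2L * n - d$fr, n)
  d$k <- match(cohort_of(d$birth_year), ova_cohorts())
  d$onset <- sample_onset(indiv_cumhaz(ctx, d$b1, d$b2, d$m3, d$r, d$k, "ovarian"))
  d
}

# cumulative ovarian (or breast) hazard rows for given genotypes
indiv_cumhaz <- function(ctx, b1, b2, m3, r, k, disease) {
  stratum <- stratum_of(b1, b2)
  par <- ctx$params
  if (disease == "ovarian") {
    logM <- major3_logRR(par, m3)
    mult <- exp(logM + ctx$grid$values[r + 1L])
    cum_rows(ctx$baselines$cum_ovc, stratum, k, mult)
  } else {
    cum_rows(ctx$baselines$cum_bc, stratum, k, 1)
  }
}

major3_logRR <- function(par, m3) {
  switch(par$major_mode,
    none = rep(0, length(m3)),
    dominant = ifelse(m3 >= 1L, par$major_logRR[1], 0),
    recessive = ifelse(m3 == 2L, par$major_logRR[1], 0),
    general = c(0, par$major_logRR)[m3 + 1L]
  )
}

test_result <- function(carrier, sens) {
  ifelse(carrier, ifelse(stats::runif(length(carrier)) < sens, "P", "N"), "N")
}

# Stage 2: build the accepted family around the proband (conditional on
# the parents' genotypes drawn in stage 1).
sim_family_members <- function(pr, fid, design, ctx) {
  par <- design$params
  n <- ctx$grid$n
  qyear <- pr$recruit_year
  row <- function(id, sex, fa, mo, by, ov, bc, st, t1, t2, pro, rel, prs = NA_real_) {
    tibble::tibble(family_id = fid, id = id, father_id = fa, mother_id = mo, sex = sex,
                   birth_year = by, ovca_age = ov, brca_age = bc, status_age = st,
                   vital = ifelse(is.na(st), "U", "A"), brca1_test = t1,
                   brca2_test = t2, prs_value = prs, proband = pro, relation = rel)
  }
  phenotype <- function(b1, b2, m3, r, by) {
    cens <- min(80, qyear - by)
    if (cens <= 0) return(NULL)
    k <- match(cohort_of(by), ova_cohorts())
    ov <- sample_onset(indiv_cumhaz(ctx, b1, b2, m3, r, k, "ovarian"))
    bc <- sample_onset(indiv_cumhaz(ctx, b1, b2, m3, r, k, "breast"))
    ov <- if (!is.na(ov) && ov < cens) ov else NA
    bc <- if (!is.na(bc) && bc < cens) bc else NA
    list(ov = ov, bc = bc, st = cens)
  }
  # proband: breast-cancer history up to recruitment; PRS consistent with
  # the simulated polygene value
  kpro <- pr$k
  bc <- sample_onset(indiv_cumhaz(ctx, pr$b1, pr$b2, pr$m3, pr$r, kpro, "breast"))
  bc <- if (!is.na(bc) && bc < pr$recruit_age) bc else NA
  pval <- ctx$grid$values[pr$r + 1L]
  sk2 <- par$sigma_k2; s2 <- par$sigma^2
  prs <- if (sk2 > 0 && s2 > 0) {
    stats::rnorm(1, (sk2 / s2) * pval, sqrt(sk2 * (s2 - sk2) / s2))
  } else NA_real_
  out <- list(
    row("pro", "F", "dad", "mum", pr$birth_year, pr$onset, bc, pr$recruit_age,
        test_result(pr$b1 >= 1, par$sensitivity1),
        test_result(pr$b2 >= 1, par$sensitivity2), TRUE, "proband", prs)
  )
  # mother (phenotype observed with probability p_mother) and father
  mo_by <- pr$birth_year - sample(20:35, 1)
  if (stats::runif(1) < design$p_mother) {
    ph <- phenotype(pr$mb1, pr$mb2, pr$mm3, pr$mr, mo_by)
    out[[length(out) + 1L]] <- row("mum", "F", NA, NA, mo_by, ph$ov, ph$bc, ph$st,
                                   "U", "U", FALSE, "mother")
  } else {
    out[[length(out) + 1L]] <- row("mum", "F", NA, NA, NA, NA, NA, NA,
                                   "U", "U", FALSE, "mother")
  }
  out[[length(out) + 1L]] <- row("dad", "M", NA, NA, NA, NA, NA, NA, "U", "U",
                                 FALSE, "father")
  # sisters
  ns <- stats::rpois(1, design$mean_sisters)
  if (ns > 0) for (j in seq_len(ns)) {
    by <- pr$birth_year + sample(c(-8:-1, 1:8), 1)
    b1 <- transmit_locus(pr$mb1, pr$fb1); b2 <- transmit_locus(pr$mb2, pr$fb2)
    m3 <- if (par$major_mode != "none") transmit_locus(pr$mm3, pr$fm3) else 0L
    r <- stats::rhyper(1, pr$mr, 2L * n - pr$mr, n) +
      stats::rhyper(1, pr$fr, 2L * n - pr$fr, n)
    ph <- phenotype(b1, b2, m3, r, by)
    if (!is.null(ph)) {
      out[[length(out) + 1L]] <- row(paste0("sis", j), "F", "dad", "mum", by,
                                     ph$ov, ph$bc, ph$st, "U", "U", FALSE, "sister")
    }
  }
  # daughters (through an unobserved partner)
  nd <- stats::rpois(1, design$mean_daughters)
  if (nd > 0) {
    pb1 <- hwe_draw(1, par$f1); pb2 <- hwe_draw(1, par$f2)
    pm3 <- if (par$major_mode != "none") hwe_draw(1, par$fM) else 0L
    prr <- stats::rbinom(1, 2L * n, 0.5)
    made <- 0L
    for (j in seq_len(nd)) {
      by <- pr$birth_year + sample(20:35, 1)
      if (qyear - by <= 0) next
      b1 <- transmit_locus(pr$b1, pb1); b2 <- transmit_locus(pr$b2, pb2)
      m3 <- if (par$major_mode != "none") transmit_locus(pr$m3, pm3) else 0L
      r <- stats::rhyper(1, pr$r, 2L * n - pr$r, n) +
        stats::rhyper(1, prr, 2L * n - prr, n)
      ph <- phenotype(b1, b2, m3, r, by)
      if (!is.null(ph)) {
        made <- made + 1L
        out[[length(out) + 1L]] <- row(paste0("dau", j), "F", "hub", "pro", by,
                                       ph$ov, ph$bc, ph$st, "U", "U", FALSE, "daughter")
      }
    }
    if (made > 0L) {
      out[[length(out) + 1L]] <- row("hub", "M", NA, NA, NA, NA, NA, NA, "U", "U",
                                     FALSE, "partner")
    }
  }
  dplyr::bind_rows(out)
}

#' Simulate an unascertained female cohort
#'
#' Independent women drawn from the population genotype priors with
#' ovarian-cancer onset sampled from the genotype-specific hazards and
#' follow-up to age 80 -- the generative mirror of the baseline
#' constraint, used to check that the model-averaged incidence reproduces
#' the population tables.
#'
#' @param n Number of women.
#' @param params True [ova_params()].
#' @param incidence,carrier_rr Incidence inputs.
#' @param birth_year Birth year (sets the cohort).
#' @param seed Integer seed.
#' @return A tibble with genotype columns (`b1`, `b2`, `m3`, `polygene`)
#'   and `ovca_age` (`NA` if no event by 80).
#' @export
simulate_cohort <- function(n, params = ova_params(),
                            incidence = default_incidence(),
                            carrier_rr = default_carrier_rr(),
                            birth_year = 1945, seed = 1L) {
  set.seed(seed)
  ctx <- ova_context(params, incidence, carrier_rr)
  np <- ctx$grid$n
  has_m3 <- params$major_mode != "none"
  b1 <- hwe_draw(n, params$f1); b2 <- hwe_draw(n, params$f2)
  m3 <- if (has_m3) hwe_draw(n, params$fM) else rep(0L, n)
  r <- stats::rbinom(n, 2L * np, 0.5)
  k <- rep(match(cohort_of(birth_year), ova_cohorts()), n)
  onset <- sample_onset(indiv_cumhaz(ctx, b1, b2, m3, r, k, "ovarian"))
  tibble::tibble(b1 = b1, b2 = b2, m3 = m3, polygene = ctx$grid$values[r + 1L],
                 birth_year = birth_year, ovca_age = onset)
}

#' Familial relative risk of ovarian cancer in first-degree relatives
#'
#' Standardised incidence ratio of ovarian cancer among the probands'
#' first-degree female relatives (mothers, sisters, daughters) versus the
#' population incidence tables: observed events divided by the events
#' expected from each relative's cohort-specific population hazard over
#' her follow-up, with an exact Poisson confidence interval.
#'
#' @param peds Pedigree tibble (>= 100 families).
#' @param incidence Population incidence tibble.
#' @param conf_level Confidence level for the Poisson interval.
#' @return A one-row tibble: `observed`, `expected`, `rr`, `rr_lo`,
#'   `rr_hi`, `person_years`.
#' @export
familial_rr_summary <- function(peds, incidence = default_incidence(),
                                conf_level = 0.95) {
  if (length(unique(peds$family_id)) < 100) {
    stop("need at least 100 families for a familial relative-risk summary",
         call. = FALSE)
  }
  rel <- peds |>
    dplyr::filter(!.data$proband, .data$sex == "F",
                  .data$relation %in% c("mother", "sister", "daughter"),
                  !is.na(.data$status_age) | !is.na(.data$ovca_age))
  exit <- pmin(ifelse(is.na(rel$ovca_age), rel$status_age, rel$ovca_age), 80)
  keep <- !is.na(exit) & exit > 0
  rel <- rel[keep, ]; exit <- exit[keep]
  if (!nrow(rel) || sum(exit) == 0) stop("no person-years among relatives", call. = FALSE)
  hz <- incidence_matrix(incidence, "ovarian")
  coh <- cohort_of(rel$birth_year); coh[is.na(coh)] <- "1940s"
  k <- match(coh, ova_cohorts())
  cumh <- t(apply(hz, 1, cumsum))                   # [cohort, age 1..80]
  expected <- sum(cumh[cbind(k, pmax(floor(exit), 1))])
  observed <- sum(!is.na(rel$ovca_age))
  a <- (1 - conf_level) / 2
  lo <- if (observed == 0) 0 else stats::qgamma(a, observed) / expected
  hi <- stats::qgamma(1 - a, observed + 1) / expected
  tibble::tibble(observed = observed, expected = expected,
                 rr = observed / expected, rr_lo = lo, rr_hi = hi,
                 person_years = sum(exit))
}
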