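flat_incidence <- function(h = 1e-4) {
  inc <- default_incidence()
  inc$hazard <- h
  inc
}

unit_rr <- function() {
  rr <- default_carrier_rr()
  rr$rr <- 1
  rr
}

# direct-summation oracle: model-averaged incidence among survivors at
# every age, never using the package's constraint bookkeeping
marginal_residual <- function(bl, params, pop_hazard, cohort = 4L,
                              carrier = default_carrier_rr()) {
  grid <- polygene_grid(params$n_poly, params$sigma)
  st <- major_states(params)
  prior <- as.vector(outer(st$prior, grid$pop_probs))
  mult <- as.vector(outer(exp(st$logM), exp(grid$values)))
  stratum <- rep(match(st$stratum, c("none", "brca1", "brca2")), length(grid$levels))
  surv <- rep(1, length(prior))
  worst <- 0
  for (t in 1:80) {
    lam <- bl$lambda0_ovc[stratum, cohort, t] * mult
    marg <- sum(prior * surv * lam) / sum(prior * surv)
    worst <- max(worst, abs(marg - pop_hazard[t]) / max(pop_hazard[t], 1e-300))
    surv <- surv * exp(-lam)
  }
  worst
}

test_that("constraint is the identity when all relative risks are 1 and sigma 0", {
  p0 <- ova_params(sigma = 0, sigma_k2 = 0)
  bl <- constrain_baselines(flat_incidence(), unit_rr(), p0)
  expect_equal(max(abs(bl$lambda0_ovc - 1e-4)), 0, tolerance = 1e-12)
  expect_equal(max(abs(bl$lambda0_bc - 1e-4)), 0, tolerance = 1e-12)
})

test_that("constrained baselines reproduce the population marginal incidence", {
  params <- ova_params()
  bl <- constrain_baselines(flat_incidence(), default_carrier_rr(), params)
  expect_lt(marginal_residual(bl, params, rep(1e-4, 80)), 1e-8)
  # age-varying synthetic table, every cohort
  inc <- default_incidence()
  bl2 <- constrain_baselines(inc, default_carrier_rr(), params)
  hz <- ovarisk:::incidence_matrix(inc, "ovarian")
  for (k in c(1L, 4L, 8L)) {
    expect_lt(marginal_residual(bl2, params, hz[k, ], cohort = k), 1e-8)
  }
  # with a third major gene in the model
  pm <- ova_params(fM = 0.005, major_mode = "dominant", major_logRR = 3)
  bl3 <- constrain_baselines(inc, default_carrier_rr(), pm)
  expect_lt(marginal_residual(bl3, pm, hz[4, ]), 1e-8)
})

test_that("polygenic burden depresses the non-carrier baseline monotonically", {
  inc <- flat_incidence()
  lam_at <- function(sigma) {
    p <- ova_params(sigma = sigma, sigma_k2 = 0)
    constrain_baselines(inc, default_carrier_rr(), p)$lambda0_ovc[1, 4, ]
  }
  l0 <- lam_at(0); l1 <- lam_at(0.7); l2 <- lam_at(1.43)
  expect_true(all(l1 < l0))
  expect_true(all(l2 < l1))
  expect_true(all(l2 < 1e-4))
})

test_that("cumulative risk has the closed form and composes over age splits", {
  expect_equal(cumulative_risk(rep(0, 80), 0, 80), 0)
  expect_equal(cumulative_risk(rep(2.5e-4, 80), 0, 80), 1 - exp(-0.02))
  h <- seq(1e-5, 1e-3, length.out = 80)
  s_split <- (1 - cumulative_risk(h, 0, 40)) * (1 - cumulative_risk(h, 40, 80))
  expect_equal(1 - s_split, cumulative_risk(h, 0, 80), tolerance = 1e-12)
  expect_error(cumulative_risk(h, 50, 40), "from_age")
})

test_that("incidence and carrier-RR CSVs expand age bands to years", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- tidyr::expand_grid(disease = c("ovarian", "breast"), cohort = ova_cohorts(),
                           age_lo = seq(0, 75, by = 5))
  df$age_hi <- df$age_lo + 5
  df$hazard_per_year <- 1e-4
  readr::write_csv(df, path)
  inc <- read_incidence(path)
  expect_equal(nrow(inc), 2 * 8 * 80)
  expect_true(all(inc$hazard == 1e-4))
  expect_equal(ovarisk:::incidence_matrix(inc, "ovarian")[3, ], rep(1e-4, 80))

  path2 <- withr::local_tempfile(fileext = ".csv")
  rr <- tidyr::expand_grid(gene = c("brca1", "brca2"), disease = c("ovarian", "breast"),
                           age_lo = c(0, 40))
  rr$age_hi <- ifelse(rr$age_lo == 0, 40, 80)
  rr$rr <- ifelse(rr$age_lo == 0, 10, 20)
  readr::write_csv(rr, path2)
  tab <- read_carrier_rr(path2)
  v <- ovarisk:::rr_vector(tab, "brca1", "ovarian")
  expect_equal(v, rep(c(10, 20), each = 40))
  rr$rr[1] <- -1
  readr::write_csv(rr, path2)
  expect_error(read_carrier_rr(path2), "> 0")
})

test_that("cohort assignment covers the eight cohorts", {
  expect_equal(cohort_of(c(1910, 1925, 1945, 1972, 1990)),
               c("pre1920", "1920s", "1940s", "1970s", "post1980"))
  expect_equal(length(ova_cohorts()), 8L)
  expect_true(is.na(cohort_of(NA)))
})
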