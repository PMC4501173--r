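test_that("PRS variance and score follow the closed forms", {
  one <- tibble::tibble(snp_id = "s1", locus = "x", maf = 0.5, or_per_allele = exp(1))
  expect_equal(prs_variance(one), 0.5)
  flat <- tibble::tibble(snp_id = letters[1:5], locus = "x", maf = 0.3,
                         or_per_allele = 1)
  expect_equal(prs_variance(flat), 0)
  expect_equal(prs_score(c(s1 = 2), one), 1)      # homozygous risk at p = 0.5
  expect_equal(prs_score(c(s1 = 1), one), 0)      # population mean dosage
  expect_error(prs_score(c(bad = 1), one), "match")
  expect_error(prs_score(c(s1 = 3), one), "0, 1 or 2")
})

test_that("bundled 17-SNP table reproduces the known score variance", {
  tab <- ova_snp17()
  expect_equal(nrow(tab), 17L)
  expect_equal(prs_variance(tab), 0.0915, tolerance = 1e-8)
  expect_equal(100 * prs_variance(tab) / 1.43^2, 4.5, tolerance = 0.02)
})

test_that("population variance of simulated scores matches the formula", {
  set.seed(99)
  tab <- ova_snp17()
  g <- vapply(seq_len(4000), function(i) {
    prs_score(stats::rbinom(17, 2, tab$maf), tab)
  }, 0)
  expect_equal(stats::var(g), prs_variance(tab), tolerance = 0.1)
  expect_equal(mean(g), 0, tolerance = 0.02)
})

test_that("carrier posterior reduces to the prior without data", {
  inc0 <- default_incidence(); inc0$hazard <- 0
  rr <- default_carrier_rr()
  ctx0 <- ova_context(ova_params(n_poly = 1), inc0, rr)
  solo <- mkped(ind("w", "F", pro = TRUE))
  cp <- carrier_posterior(solo, "w", ctx0)
  expect_equal(cp$p_brca1, carrier_frequency(0.00079), tolerance = 1e-10)
  expect_equal(cp$p_brca2, carrier_frequency(0.0026), tolerance = 1e-10)
})

test_that("an ovarian-cancer diagnosis raises the carrier posterior", {
  ctx <- ova_context(ova_params())
  aff <- trio(pro_ov = 45)
  cp <- carrier_posterior(aff, "pro", ctx)
  expect_gt(cp$p_brca1, carrier_frequency(0.00079))
  expect_gt(cp$p_brca2, carrier_frequency(0.0026))
  expect_true(cp$p_brca1 < 1 && cp$p_brca2 < 1)
})

test_that("including a positive own test drives the posterior to one", {
  ctx <- ova_context(ova_params(n_poly = 1))
  p <- trio(pro_ov = 50, t1 = "P")
  cp <- carrier_posterior(p, "pro", ctx, include_own_tests = TRUE)
  expect_equal(cp$p_brca1, 1)
  # excluded by default: posterior stays below 1
  cp2 <- carrier_posterior(p, "pro", ctx)
  expect_lt(cp2$p_brca1, 0.5)
})

test_that("expected carrier counts and the chi-squared match direct arithmetic", {
  expect_equal(carrier_count_chi2(c(44, 62), c(56.95, 63.59)), 2.98, tolerance = 0.01)
  expect_equal(carrier_count_chi2(c(44, 62), c(45.76, 23.03)), 66.01, tolerance = 0.001)
  expect_equal(carrier_count_chi2(c(10, 20), c(10, 20)), 0)
  expect_equal(carrier_count_chi2(c(1, 0), c(0, 1)), Inf)

  peds <- simulate_pedigrees(sim_design(40), seed = 21)
  ctx <- ova_context(ova_params())
  obs <- c(brca1 = sum(peds$proband & peds$brca1_test == "P"),
           brca2 = sum(peds$proband & peds$brca2_test == "P"))
  ec <- expected_carrier_counts(peds, ctx, obs)
  expect_gte(ec$expected_brca1, 0); expect_lte(ec$expected_brca1, 40)
  expect_gte(ec$expected_brca2, 0); expect_lte(ec$expected_brca2, 40)
  direct <- sum((c(obs[["brca1"]], obs[["brca2"]]) -
                   c(ec$expected_brca1, ec$expected_brca2))^2 /
                  c(ec$expected_brca1, ec$expected_brca2))
  expect_equal(ec$chi2, direct, tolerance = 1e-12)
})

test_that("future risk collapses to the baseline for an isolated non-carrier", {
  # sensitivity 1 and a negative test exclude carrier states; sigma = 0
  # removes the polygene, so the curve is the population non-carrier curve
  p0 <- ova_params(sigma = 0, sigma_k2 = 0, sensitivity1 = 1, sensitivity2 = 1,
                   n_poly = 1)
  ctx <- ova_context(p0)
  solo <- mkped(ind("w", "F", by = 1940, st = 50, t1 = "N", t2 = "N", pro = TRUE))
  rc <- future_risk(solo, "w", ctx, 50, 80)
  k <- match("1940s", ova_cohorts())
  lam0 <- ctx$baselines$lambda0_ovc[1, k, ]
  expected <- 1 - exp(-(cumsum(lam0)[80] - cumsum(lam0)[50]))
  expect_equal(rc$risk[rc$age == 80], expected, tolerance = 1e-10)
  expect_equal(rc$risk[1], 0)
})

test_that("risk increases with the burden of family history", {
  ctx <- ova_context(ova_params())
  r_none <- future_risk(fam_history("a"), "target", ctx, 50, 80)
  r_mum <- future_risk(fam_history("b", mum_ov = 60), "target", ctx, 50, 80)
  r_both <- future_risk(fam_history("c", mum_ov = 60, sis_ov = 45), "target", ctx, 50, 80)
  at80 <- function(r) r$risk[r$age == 80]
  expect_gt(at80(r_mum), at80(r_none))
  expect_gt(at80(r_both), at80(r_mum))
  # curves are monotone and within [0, 1]
  for (r in list(r_none, r_mum, r_both)) {
    expect_true(all(diff(r$risk) >= 0))
    expect_true(all(r$risk >= 0 & r$risk <= 1))
  }
})

test_that("risk increases monotonically with the measured PRS", {
  ctx <- ova_context(ova_params())
  at80 <- vapply(c(-0.8, -0.496, 0, 0.496, 0.8), function(s) {
    r <- future_risk(fam_history("a"), "target", ctx, 50, 80, prs = s)
    r$risk[r$age == 80]
  }, 0)
  expect_true(all(diff(at80) > 0))
})

test_that("averaging over the PRS distribution recovers the no-PRS curve", {
  ctx <- ova_context(ova_params())
  fam <- fam_history("a", mum_ov = 60)
  base <- future_risk(fam, "target", ctx, 50, 80)
  sk <- sqrt(ctx$params$sigma_k2)
  gq <- statmod_gauss_hermite(15)
  avg <- rep(0, nrow(base))
  for (i in seq_along(gq$nodes)) {
    prs <- sqrt(2) * sk * gq$nodes[i]
    r <- future_risk(fam, "target", ctx, 50, 80, prs = prs)
    avg <- avg + gq$weights[i] / sqrt(pi) * r$risk
  }
  expect_lt(max(abs(avg - base$risk)), 1e-3)
})

test_that("risk curves are bounded by the always- and never-carrier curves", {
  ctx <- ova_context(ova_params())
  fam <- fam_history("a", mum_ov = 60, target_t1 = "U", target_t2 = "U")
  r <- future_risk(fam, "target", ctx, 50, 80)
  k <- match("1940s", ova_cohorts())
  # carrier (BRCA1) upper envelope at the highest polygene level vs
  # non-carrier lower envelope at the lowest level
  cum <- ctx$baselines$cum_ovc
  up <- 1 - exp(-(cum[2, k, 81] - cum[2, k, 51]) * exp(max(ctx$values)))
  lo <- 1 - exp(-(cum[1, k, 81] - cum[1, k, 51]) * exp(min(ctx$values)))
  expect_lt(r$risk[r$age == 80], up)
  expect_gt(r$risk[r$age == 80], lo)
})

test_that("future risk validates its inputs", {
  ctx <- ova_context(ova_params(n_poly = 1))
  fam <- fam_history("a")
  expect_error(future_risk(fam, "target", ctx, 60, 50), "from_age")
  expect_error(future_risk(fam, "dad", ctx, 50, 80), "female")
  ctx0 <- ova_context(ova_params(sigma_k2 = 0, n_poly = 1))
  expect_error(future_risk(fam, "target", ctx0, 50, 80, prs = 0.3), "sigma_k2")
  aff <- fam_history("b", sis_ov = 45)
  expect_error(future_risk(aff, "sis", ctx, 50, 80), "affected")
})
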