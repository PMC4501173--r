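test_that("polygene grid has exact moments and closed-form small cases", {
  g <- polygene_grid(1, 1)
  expect_equal(g$levels, 0:2)
  expect_equal(g$pop_probs, c(0.25, 0.5, 0.25))
  expect_equal(g$values, c(-sqrt(2), 0, sqrt(2)))
  expect_equal(sum(g$pop_probs * g$values^2), 1)

  expect_equal(polygene_grid(3, 0)$values, rep(0, 7))

  for (n in c(2, 4, 6)) {
    for (s in c(0.5, 1.43)) {
      g <- polygene_grid(n, s)
      expect_equal(sum(g$pop_probs), 1, tolerance = 1e-12)
      expect_equal(sum(g$pop_probs * g$values), 0, tolerance = 1e-12)
      expect_equal(sum(g$pop_probs * g$values^2), s^2, tolerance = 1e-10)
      expect_equal(sum(g$pop_probs * g$values^3), 0, tolerance = 1e-10)
      expect_equal(g$values, -rev(g$values)) # symmetric about 0
    }
  }
  expect_error(polygene_grid(0, 1), "n")
})

test_that("gamete distribution is hypergeometric with mean r/2", {
  expect_equal(gamete_distribution(2, 1), c(0, 1))    # r = 2n: point mass at s = n
  expect_equal(gamete_distribution(1, 1), c(0.5, 0.5))
  # direct-summation oracle for the mean at n = 4
  for (r in 0:8) {
    d <- gamete_distribution(r, 4)
    expect_equal(sum(d), 1, tolerance = 1e-12)
    expect_equal(sum((0:4) * d), r / 2, tolerance = 1e-12)
  }
  expect_error(gamete_distribution(9, 4), "0..2n")
})

test_that("level transmission preserves the binomial population distribution", {
  tens <- child_transmission_tensor(1)
  expect_equal(tens[, 3, 1], c(0, 1, 0))  # parents at levels 2 and 0 -> child at 1
  for (n in 1:6) {
    tens <- child_transmission_tensor(n)
    R <- 2 * n + 1
    pop <- stats::dbinom(0:(2 * n), 2 * n, 0.5)
    expect_equal(apply(tens, c(2, 3), sum), matrix(1, R, R), tolerance = 1e-12)
    # stationarity by direct summation
    new <- rep(0, R)
    for (m in 1:R) for (f in 1:R) new <- new + pop[m] * pop[f] * tens[, m, f]
    expect_equal(new, pop, tolerance = 1e-12)
  }
})

test_that("parent-offspring correlation of grid values is one half", {
  set.seed(42)
  g <- polygene_grid(4, 1.3)
  n <- 4
  rm <- stats::rbinom(2e5, 2 * n, 0.5)
  rf <- stats::rbinom(2e5, 2 * n, 0.5)
  rc <- stats::rhyper(2e5, rm, 2 * n - rm, n) + stats::rhyper(2e5, rf, 2 * n - rf, n)
  expect_equal(stats::cor(g$values[rm + 1], g$values[rc + 1]), 0.5, tolerance = 0.02)
})

test_that("grid distribution approaches normality as n grows", {
  ks_dist <- vapply(1:8, function(n) {
    g <- polygene_grid(n, 1.43)
    cdf <- cumsum(g$pop_probs)
    max(abs(cdf - stats::pnorm(g$values, 0, 1.43)))
  }, 0)
  expect_true(all(diff(ks_dist) <= 1e-12))
})

test_that("carrier frequency follows Hardy-Weinberg", {
  expect_equal(carrier_frequency(0.00079), 1 - (1 - 0.00079)^2)
  expect_equal(signif(1 / carrier_frequency(0.00079), 2), 630)
  expect_equal(carrier_frequency(0), 0)
  expect_equal(carrier_frequency(0.0026), 0.00519324, tolerance = 1e-8)
})

test_that("founder priors are Hardy-Weinberg products and sum to one", {
  p <- ova_params(f1 = 0.00079, f2 = 0.0026)
  st <- major_prior(p)
  expect_equal(sum(st$prior), 1, tolerance = 1e-12)
  expect_equal(sum(st$prior[st$b1 >= 1]), carrier_frequency(0.00079), tolerance = 1e-12)

  set.seed(7)
  for (i in 1:5) {
    f <- stats::runif(2, 0.001, 0.4)
    st <- major_prior(ova_params(f1 = f[1], f2 = f[2]))
    expect_equal(sum(st$prior), 1, tolerance = 1e-12)
  }
  # degenerate: no mutated alleles
  st0 <- major_prior(ova_params(f1 = 0, f2 = 0))
  expect_equal(st0$prior[st0$b1 == 0 & st0$b2 == 0], 1)
})

test_that("major-gene transmission is Mendelian and keeps HWE stationary", {
  p <- ova_params(f1 = 0.1, f2 = 0.3)
  tens <- major_transmission(p)
  st <- major_states(p)
  G <- nrow(st)
  expect_equal(apply(tens, c(2, 3), sum), matrix(1, G, G), tolerance = 1e-12)
  # all-noncarrier parents -> all-noncarrier child
  nc <- which(st$b1 == 0 & st$b2 == 0)
  expect_equal(tens[nc, nc, nc], 1)
  # het x noncarrier -> child carrier with probability 1/2
  het <- which(st$b1 == 1 & st$b2 == 0)
  expect_equal(sum(tens[st$b1 >= 1, het, nc]), 0.5)
  # stationarity under random mating (direct summation)
  new <- rep(0, G)
  for (m in 1:G) for (f in 1:G) new <- new + st$prior[m] * st$prior[f] * tens[, m, f]
  expect_equal(new, st$prior, tolerance = 1e-12)
})

test_that("third major gene modes assign the right relative risks", {
  pd <- ova_params(fM = 0.01, major_mode = "dominant", major_logRR = 2)
  std <- major_states(pd)
  expect_equal(unique(std$logM[std$m3 >= 1]), 2)
  expect_equal(unique(std$logM[std$m3 == 0]), 0)
  pr <- ova_params(fM = 0.1, major_mode = "recessive", major_logRR = 3)
  str_ <- major_states(pr)
  expect_equal(unique(str_$logM[str_$m3 == 2]), 3)
  expect_equal(unique(str_$logM[str_$m3 <= 1]), 0)
  pg <- ova_params(fM = 0.01, major_mode = "general", major_logRR = c(1.5, 4))
  stg <- major_states(pg)
  expect_equal(unique(stg$logM[stg$m3 == 1]), 1.5)
  expect_equal(unique(stg$logM[stg$m3 == 2]), 4)
  expect_equal(nrow(stg), 27)
})

test_that("parameter validation enforces ranges", {
  expect_error(ova_params(f1 = 1.2), "f1")
  expect_error(ova_params(sigma = -1), "sigma")
  expect_error(ova_params(sigma = 1, sigma_k2 = 2), "sigma_k2")
  expect_error(ova_params(major_mode = "dominant"), "fM")
  expect_error(ova_params(fM = 0.01, major_mode = "general", major_logRR = 2), "2 log")
})
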