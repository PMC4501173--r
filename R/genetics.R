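#' Hardy-Weinberg carrier frequency
#'
#' Probability that an individual carries at least one copy of an allele of
#' frequency `f` under Hardy-Weinberg equilibrium, `1 - (1 - f)^2`.
#'
#' @param f Allele frequency in \[0, 1).
#' @return Carrier frequency.
#' @export
#' @examples
#' carrier_frequency(0.00079)    # ~ 1 in 630
carrier_frequency <- function(f) {
  stopifnot(all(f >= 0), all(f < 1))
  1 - (1 - f)^2
}

#' Hypergeometric polygene grid
#'
#' Discretises the Normal(0, sigma^2) polygenic component onto `2n + 1`
#' levels using the n-locus binary model: level `r` (the count of "high"
#' alleles, 0..2n) has population mass Binomial(2n, 1/2) and log relative
#' risk `sigma * (r - n) / sqrt(n / 2)`, so the grid has mean 0 and
#' variance sigma^2 exactly. Transmission of levels follows hypergeometric
#' gamete sampling, which keeps the model compatible with pedigree peeling
#' and preserves the additive-genetics parent-offspring correlation of 1/2.
#'
#' @param n Half-locus count (>= 1).
#' @param sigma Polygenic standard deviation (>= 0).
#' @return A list of class `polygene_grid` with elements `n`, `levels`
#'   (0..2n), `values` (log relative risks), `pop_probs`
#'   (Binomial(2n, 1/2) masses) and `transmission`, an array
#'   `T[child, mother, father]` of level-transmission probabilities.
#' @export
#' @examples
#' g <- polygene_grid(4, 1.43)
#' sum(g$pop_probs * g$values^2)  # = 1.43^2
polygene_grid <- function(n, sigma) {
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  levels <- 0:(2L * n)
  values <- sigma * (levels - n) / sqrt(n / 2)
  pop_probs <- stats::dbinom(levels, 2L * n, 0.5)
  structure(list(
    n = n, levels = levels, values = values, pop_probs = pop_probs,
    transmission = child_transmission_tensor(n)
  ), class = "polygene_grid")
}

#' Gamete distribution of the hypergeometric polygene
#'
#' A parent at polygene level `r` (out of 2n) transmits a gamete carrying
#' `s` of its high alleles, with `s` drawn without replacement:
#' `P(s) = choose(r, s) choose(2n - r, n - s) / choose(2n, n)`.
#'
#' @param r Parent level, 0..2n.
#' @param n Half-locus count.
#' @return Numeric vector of probabilities over `s = 0..n` (sums to 1,
#'   mean r/2).
#' @export
gamete_distribution <- function(r, n) {
  n <- as.integer(n)
  if (length(r) != 1L || r < 0 || r > 2L * n) {
    stop("`r` must be a single level in 0..2n", call. = FALSE)
  }
  stats::dhyper(0:n, m = r, n = 2L * n - r, k = n)
}

#' Polygene level transmission tensor
#'
#' Child level = maternal gamete + paternal gamete, each gamete
#' hypergeometric given the parent's level. The Binomial(2n, 1/2)
#' population distribution is stationary under this transmission.
#'
#' @param n Half-locus count.
#' @return Array `T[child, mother, father]` of dimension
#'   `(2n+1) x (2n+1) x (2n+1)`; each `T[, m, f]` sums to 1.
#' @export
child_transmission_tensor <- function(n) {
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  R <- 2L * n + 1L
  gam <- vapply(0:(2L * n), gamete_distribution, numeric(n + 1L), n = n) # (s, r)
  tens <- array(0, dim = c(R, R, R))
  for (m in seq_len(R)) {
    for (f in seq_len(R)) {
      conv <- stats::convolve(gam[, m], rev(gam[, f]), type = "open") # length 2n+1
      conv[conv < 0] <- 0 # FFT round-off
      tens[, m, f] <- conv / sum(conv)
    }
  }
  tens
}

# --- major-gene state space -------------------------------------------------

# Genotypes are tracked as allele copy counts (0/1/2) per locus so that
# Mendelian transmission is exact; risk depends only on carrier status for
# BRCA1/BRCA2 (double heterozygotes take the BRCA1 risk) and on the mode of
# inheritance for the optional third gene.

#' Major-genotype state table
#'
#' Enumerates the joint BRCA1 x BRCA2 (x third major gene) genotype space
#' as allele copy counts with Hardy-Weinberg founder priors, the baseline
#' stratum used by the constrained incidences (BRCA1 carrier, BRCA2-only
#' carrier, non-carrier), and the third-gene log relative risk of each
#' state.
#'
#' @param params An [ova_params()] object.
#' @return A tibble with columns `b1`, `b2`, `m3` (copy counts; `m3` absent
#'   when `major_mode = "none"`), `prior`, `stratum` (`"none"`, `"brca1"`,
#'   `"brca2"`) and `logM`.
#' @export
major_states <- function(params) {
  validate_params(params)
  hwe <- function(f) c((1 - f)^2, 2 * f * (1 - f), f^2)
  if (params$major_mode == "none") {
    st <- tidyr::expand_grid(b2 = 0:2, b1 = 0:2)
    st <- tibble::tibble(b1 = st$b1, b2 = st$b2)
    st$prior <- hwe(params$f1)[st$b1 + 1L] * hwe(params$f2)[st$b2 + 1L]
    st$logM <- 0
  } else {
    st <- tidyr::expand_grid(m3 = 0:2, b2 = 0:2, b1 = 0:2)
    st <- tibble::tibble(b1 = st$b1, b2 = st$b2, m3 = st$m3)
    st$prior <- hwe(params$f1)[st$b1 + 1L] * hwe(params$f2)[st$b2 + 1L] *
      hwe(params$fM)[st$m3 + 1L]
    st$logM <- switch(params$major_mode,
      dominant  = ifelse(st$m3 >= 1L, params$major_logRR[1], 0),
      recessive = ifelse(st$m3 == 2L, params$major_logRR[1], 0),
      general   = c(0, params$major_logRR)[st$m3 + 1L]
    )
  }
  st$stratum <- ifelse(st$b1 >= 1L, "brca1", ifelse(st$b2 >= 1L, "brca2", "none"))
  st
}

#' Founder prior over major genotype states
#'
#' Product of independent per-locus Hardy-Weinberg priors.
#'
#' @param params An [ova_params()] object.
#' @return A tibble: the [major_states()] table (its `prior` column sums
#'   to 1).
#' @export
major_prior <- function(params) {
  major_states(params)
}

# Mendelian per-locus transmission: T[child+1, mother+1, father+1] for copy
# counts 0/1/2; each parent transmits the allele with probability copies/2.
mendelian_locus_tensor <- function() {
  tens <- array(0, dim = c(3, 3, 3))
  for (m in 0:2) {
    for (f in 0:2) {
      pm <- m / 2; pf <- f / 2
      p <- c((1 - pm) * (1 - pf), pm * (1 - pf) + (1 - pm) * pf, pm * pf)
      tens[, m + 1L, f + 1L] <- p
    }
  }
  tens
}

#' Major-genotype transmission probabilities
#'
#' Mendelian segregation, independent across loci.
#'
#' @param params An [ova_params()] object.
#' @return Array `T[child, mother, father]` over the [major_states()]
#'   indices; each `T[, m, f]` sums to 1.
#' @export
major_transmission <- function(params) {
  st <- major_states(params)
  loc <- mendelian_locus_tensor()
  G <- nrow(st)
  tens <- array(1, dim = c(G, G, G))
  loci <- intersect(c("b1", "b2", "m3"), names(st))
  for (l in loci) {
    cc <- st[[l]] + 1L
    tens <- tens * loc[cbind(
      rep(cc, times = G * G),
      rep(rep(cc, each = G), times = G),
      rep(cc, each = G * G)
    )]
  }
  array(tens, dim = c(G, G, G))
}
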