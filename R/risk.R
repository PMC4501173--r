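get_family <- function(peds, target_id, family_id = NULL) {
  if (!is.null(family_id)) {
    p <- peds[peds$family_id == family_id, ]
  } else {
    fams <- unique(peds$family_id[peds$id == target_id])
    if (length(fams) != 1L) {
      stop("target id not unique across families; supply `family_id`", call. = FALSE)
    }
    p <- peds[peds$family_id == fams, ]
  }
  if (!target_id %in% p$id) stop("target individual not in family", call. = FALSE)
  p
}

#' Posterior BRCA1/BRCA2 carrier probabilities
#'
#' Probability that the target individual carries a BRCA1 (resp. BRCA2)
#' mutation given the whole family's phenotypes and the other members'
#' test results, computed by peeling the pedigree onto the target. By
#' default the target's own test results are excluded, which is the
#' prediction mode used to compare expected with observed carrier counts;
#' set `include_own_tests = TRUE` to condition on them as well.
#'
#' @param peds Pedigree tibble.
#' @param target_id Individual id of the target.
#' @param ctx An [ova_context()].
#' @param include_own_tests Condition on the target's own test results?
#' @param family_id Optional family id (needed if `target_id` is not
#'   unique across families).
#' @return A one-row tibble: `family_id`, `id`, `p_brca1`, `p_brca2`.
#' @export
carrier_posterior <- function(peds, target_id, ctx, include_own_tests = FALSE,
                              family_id = NULL) {
  p <- get_family(peds, target_id, family_id)
  i <- which(p$id == target_id)
  if (!include_own_tests) {
    p$brca1_test[i] <- "U"
    p$brca2_test[i] <- "U"
  }
  post <- family_posterior(ctx, p, target_id)
  tibble::tibble(
    family_id = p$family_id[1], id = target_id,
    p_brca1 = sum(post[rep(ctx$states$b1 >= 1L, times = ctx$R)]),
    p_brca2 = sum(post[rep(ctx$states$b2 >= 1L, times = ctx$R)])
  )
}

# normalised posterior state vector of `root_id` given the family data
family_posterior <- function(ctx, p, root_id, override_values = NULL) {
  plan <- plan_family(p, root_id = root_id)
  res <- family_loglik(ctx, p, plan = plan,
                       PEN = pen_matrix(ctx, p, override_values))
  if (is.null(res$post)) stop("family data have zero probability under the model",
                              call. = FALSE)
  res$post / sum(res$post)
}

#' Expected mutation-carrier counts and goodness of fit
#'
#' Sums the predicted BRCA1 and BRCA2 carrier probabilities of every
#' proband (excluding each proband's own test result) and compares them
#' with the observed carrier counts by a Pearson chi-squared statistic.
#'
#' @param peds Pedigree tibble (any number of families).
#' @param ctx An [ova_context()].
#' @param observed Named numeric vector `c(brca1 = , brca2 = )` of
#'   observed carrier counts among probands.
#' @return A one-row tibble: expected and observed counts per gene and
#'   `chi2`.
#' @export
expected_carrier_counts <- function(peds, ctx, observed) {
  post <- peds |>
    dplyr::filter(.data$proband) |>
    dplyr::group_by(.data$family_id) |>
    dplyr::reframe(carrier_posterior(peds, .data$id, ctx, family_id = .data$family_id[1]))
  exp1 <- sum(post$p_brca1); exp2 <- sum(post$p_brca2)
  tibble::tibble(
    expected_brca1 = exp1, expected_brca2 = exp2,
    observed_brca1 = observed[["brca1"]], observed_brca2 = observed[["brca2"]],
    chi2 = carrier_count_chi2(c(observed[["brca1"]], observed[["brca2"]]),
                              c(exp1, exp2))
  )
}

#' Pearson chi-squared for observed vs expected carrier counts
#'
#' `sum((obs - exp)^2 / exp)`; infinite when an expected count is zero
#' but the observed count is not.
#'
#' @param observed,expected Numeric vectors of counts.
#' @return The chi-squared statistic.
#' @export
#' @examples
#' carrier_count_chi2(c(44, 62), c(56.95, 63.59))  # 2.98
carrier_count_chi2 <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  bad <- expected == 0 & observed > 0
  if (any(bad)) return(Inf)
  keep <- expected > 0
  sum((observed[keep] - expected[keep])^2 / expected[keep])
}

#' Variance of a polygenic risk score
#'
#' For independent SNPs in Hardy-Weinberg equilibrium with minor-allele
#' frequency p and per-allele odds ratio OR, the variance of the centred
#' score is `sum(2 p (1 - p) log(OR)^2)`.
#'
#' @param snp_table Tibble with columns `maf` and `or_per_allele` (see
#'   [read_snp_table()]).
#' @return The PRS variance (sigma_k^2).
#' @export
#' @examples
#' prs_variance(ova_snp17())   # ~ 0.0915
prs_variance <- function(snp_table) {
  stopifnot(all(snp_table$maf > 0 & snp_table$maf < 1),
            all(snp_table$or_per_allele > 0))
  sum(2 * snp_table$maf * (1 - snp_table$maf) * log(snp_table$or_per_allele)^2)
}

#' Polygenic risk score of a SNP profile
#'
#' Centred log relative risk `sum((g_j - 2 p_j) log(OR_j))` for allele
#' counts `g_j` in 0/1/2; the population mean score is 0.
#'
#' @param genotypes Named numeric vector of risk-allele counts (names are
#'   SNP ids), or unnamed in the row order of `snp_table`.
#' @param snp_table Tibble with columns `snp_id`, `maf`, `or_per_allele`.
#' @return The PRS value (scalar).
#' @export
prs_score <- function(genotypes, snp_table) {
  if (!is.null(names(genotypes))) {
    if (!setequal(names(genotypes), snp_table$snp_id)) {
      stop("genotype names do not match the SNP table", call. = FALSE)
    }
    genotypes <- genotypes[snp_table$snp_id]
  } else if (length(genotypes) != nrow(snp_table)) {
    stop("genotype vector length does not match the SNP table", call. = FALSE)
  }
  if (!all(genotypes %in% 0:2)) stop("allele counts must be 0, 1 or 2", call. = FALSE)
  sum((genotypes - 2 * snp_table$maf) * log(snp_table$or_per_allele))
}

#' Read a SNP table
#'
#' CSV with columns `snp_id`, `locus`, `maf`, `or_per_allele`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_snp_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("snp_id", "locus", "maf", "or_per_allele")
  if (!all(need %in% names(x))) {
    stop("SNP CSV must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  x
}

#' Bundled 17-SNP ovarian-cancer risk score table (synthetic)
#'
#' A synthetic stand-in for the published table of 17 common
#' ovarian-cancer susceptibility alleles: locus names follow reported
#' GWAS regions, minor-allele frequencies are plausible values, and the
#' per-allele odds ratios are rescaled so the score variance
#' `sum(2p(1-p) log(OR)^2)` is exactly 0.0915 -- the variance of the
#' 17-SNP polygenic risk score, which explains about 4.5% of the total
#' polygenic variance `1.43^2`.
#'
#' @return A tibble with 17 rows.
#' @export
ova_snp17 <- function() {
  read_snp_table(system.file("extdata", "snp17_synthetic.csv", package = "ovarisk"))
}

#' Predicted future ovarian-cancer risk
#'
#' Cumulative risk of ovarian cancer between `from_age` and `to_age` for
#' an unaffected target individual, conditional on the family's phenotypes
#' and test results. The posterior over the target's major genotype and
#' polygene level at `from_age` is obtained by peeling (with the target's
#' own record replaced by "ovarian-cancer free to `from_age`" plus their
#' test results), and the risk is averaged over that posterior.
#'
#' When a polygenic risk score value is supplied, the target's polygene is
#' decomposed into the measured score plus an unknown residual: the
#' target's polygene level values become `prs + sigma_u (r - n) /
#' sqrt(n/2)` with `sigma_u^2 = sigma^2 - sigma_k^2`. The conditioning is
#' applied to the target only; relatives keep the full-variance polygene.
#'
#' @param peds Pedigree tibble.
#' @param target_id Target individual id.
#' @param ctx An [ova_context()].
#' @param from_age,to_age Integer ages, `from_age < to_age <= 80`.
#' @param prs Optional measured polygenic risk score (log relative risk).
#' @param family_id Optional family id.
#' @return A tibble of class `ova_risk_curve` with columns `age` and
#'   `risk` (cumulative from `from_age`, starting at 0) and a
#'   `conditioning` attribute describing the scenario.
#' @export
future_risk <- function(peds, target_id, ctx, from_age, to_age = 80, prs = NULL,
                        family_id = NULL) {
  if (from_age >= to_age) stop("`from_age` must be < `to_age`", call. = FALSE)
  if (to_age > 80) stop("follow-up ends at age 80", call. = FALSE)
  p <- get_family(peds, target_id, family_id)
  i <- which(p$id == target_id)
  if (p$sex[i] != "F") stop("future ovarian-cancer risk applies to females", call. = FALSE)
  if (!is.na(p$ovca_age[i]) && p$ovca_age[i] <= from_age) {
    stop("target already affected by ovarian cancer at `from_age`", call. = FALSE)
  }
  override <- NULL
  values <- ctx$values
  if (!is.null(prs)) {
    sk2 <- ctx$params$sigma_k2
    if (sk2 <= 0) stop("PRS supplied but `sigma_k2` is zero", call. = FALSE)
    sigma_u <- sqrt(max(ctx$params$sigma^2 - sk2, 0))
    n <- ctx$grid$n
    values <- prs + sigma_u * (ctx$grid$levels - n) / sqrt(n / 2)
    override <- list(idx = i, values = values)
  }
  # condition on: ovarian-cancer free to from_age (+ own test results)
  p$ovca_age[i] <- NA
  p$brca_age[i] <- NA
  p$status_age[i] <- from_age
  post <- family_posterior(ctx, p, target_id, override_values = override)

  coh <- cohort_of(p$birth_year[i]); if (is.na(coh)) coh <- "1940s"
  k <- match(coh, ova_cohorts())
  mult <- as.vector(outer(exp(ctx$logM), exp(values)))
  cb <- ctx$baselines$cum_ovc[ctx$stratum_idx, k, ]   # 3-strata rows indexed per g
  cb_s <- cb[rep(seq_len(ctx$G), times = ctx$R), ]    # nstates x 81
  ages <- from_age:to_age
  risk <- vapply(ages, function(a) {
    s_ratio <- exp(-(cb_s[, a + 1L] - cb_s[, from_age + 1L]) * mult)
    1 - sum(post * s_ratio)
  }, 0)
  out <- tibble::tibble(age = ages, risk = risk)
  attr(out, "conditioning") <- list(
    target = target_id, family_id = p$family_id[1], from_age = from_age,
    prs = prs, n_relatives = nrow(p) - 1L
  )
  class(out) <- c("ova_risk_curve", class(out))
  out
}
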