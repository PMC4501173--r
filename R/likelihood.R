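#' Joint log-likelihood of one family
#'
#' Log of the probability of all phenotypes and test results in a family,
#' summed over every member's unobserved major genotype and polygene level
#' by Elston-Stewart peeling (founder Hardy-Weinberg x Binomial(2n, 1/2)
#' priors, Mendelian and hypergeometric transmission, per-individual
#' penetrances). Per-step rescaling keeps the computation in range for
#' large families.
#'
#' @param peds Pedigree tibble containing exactly one family.
#' @param ctx An [ova_context()].
#' @return Log-likelihood (scalar; `-Inf` for internally inconsistent
#'   data).
#' @export
pedigree_joint_loglik <- function(peds, ctx) {
  if (length(unique(peds$family_id)) != 1L) {
    stop("`peds` must contain exactly one family", call. = FALSE)
  }
  family_loglik(ctx, peds)$loglik
}

#' Ascertainment-corrected family log-likelihood
#'
#' The likelihood of the whole family's data (all phenotypes plus the
#' proband's test results) conditional on the proband's own cancer
#' phenotype -- the ascertainment assumption-free correction for families
#' sampled through an affected index case. Equals
#' [pedigree_joint_loglik()] minus the log-probability of the proband's
#' phenotype computed with population (founder) priors. The proband's
#' mutation-test results stay in the numerator only; conditioning on them
#' too would cancel the carrier-fraction information that identifies the
#' allele frequencies.
#'
#' @inheritParams pedigree_joint_loglik
#' @return Conditional log-likelihood; exactly 0 for a family consisting
#'   only of an untested proband.
#' @export
ascertained_loglik <- function(peds, ctx) {
  if (length(unique(peds$family_id)) != 1L) {
    stop("`peds` must contain exactly one family", call. = FALSE)
  }
  num <- family_loglik(ctx, peds)$loglik
  den <- proband_marginal_loglik(ctx, peds)
  if (!is.finite(den)) {
    stop("proband data have zero probability under the model (inconsistent data)",
         call. = FALSE)
  }
  num - den
}

# Denominator of the ascertainment correction: marginal probability of the
# proband's cancer phenotype (test results excluded) under founder priors.
proband_marginal_loglik <- function(ctx, peds) {
  i <- which(peds$proband)
  if (length(i) != 1L) stop("family must have exactly one proband", call. = FALSE)
  row <- peds[i, ]
  row$brca1_test <- "U"
  row$brca2_test <- "U"
  tot <- sum(ctx$prior * pen_matrix(ctx, row)[, 1])
  if (tot <= 0) return(-Inf)
  log(tot)
}

#' Data-set log-likelihood
#'
#' Sum of [ascertained_loglik()] over independent families.
#'
#' @param peds Pedigree tibble (any number of families).
#' @param ctx An [ova_context()].
#' @param per_family If `TRUE`, return a tibble of per-family values
#'   instead of the total.
#' @param engine `"cpp"` (compiled peeling executor, default) or `"r"`
#'   (reference implementation); both produce identical results.
#' @return Scalar log-likelihood, or a tibble with columns `family_id`,
#'   `loglik` when `per_family = TRUE`.
#' @export
dataset_loglik <- function(peds, ctx, per_family = FALSE, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  plans <- dataset_plans(peds)
  ll <- dataset_loglik_planned(ctx, plans, engine = engine)
  if (per_family) {
    tibble::tibble(family_id = names(plans$plans), loglik = unname(ll))
  } else {
    sum(ll)
  }
}

# Flat integer encoding of one peeling plan for the compiled executor
# (0-based indices; founder flag 2 marks a founder belonging to a single
# nuclear family, eligible for analytic marginalisation).
encode_plan <- function(plan) {
  fflag <- as.integer(plan$founder) + as.integer(plan$founder & plan$single_unit)
  proband <- plan$proband_local
  out <- c(plan$n, plan$root - 1L, proband - 1L, length(plan$steps), fflag)
  for (s in plan$steps) {
    out <- c(out, s$fa - 1L, s$mo - 1L, s$conn - 1L,
             if (s$conn_role == "parent") 0L else 1L,
             length(s$children), s$children - 1L)
  }
  c(out, length(plan$leftover), plan$leftover - 1L)
}

# Precompute per-family peeling plans, row indices and the flat encoding;
# reused across the many likelihood evaluations of a fit.
dataset_plans <- function(peds, root_ids = NULL) {
  rows <- split(seq_len(nrow(peds)), peds$family_id)
  fams <- names(rows)
  plans <- lapply(fams, function(f) {
    p <- peds[rows[[f]], ]
    plan <- plan_family(p, root_id = root_ids[[f]])
    plan$proband_local <- which(p$proband)
    list(rows = rows[[f]], plan = plan, proband = which(p$proband))
  })
  names(plans) <- fams
  codes <- lapply(plans, function(pl) encode_plan(pl$plan))
  list(
    peds = peds, plans = plans,
    code = as.integer(unlist(codes)),
    code_off = as.integer(c(0, cumsum(lengths(codes)))[seq_along(codes)]),
    cols = as.integer(unlist(lapply(plans, `[[`, "rows")) - 1L),
    fam_off = as.integer(c(0, cumsum(vapply(plans, function(p) length(p$rows), 0L))))
  )
}

dataset_loglik_planned <- function(ctx, plans, engine = "cpp", PEN = NULL,
                                   posterior_family = -1L) {
  if (is.null(PEN)) PEN <- pen_matrix(ctx, plans$peds)
  # denominator penetrances: probands' phenotypes without test results,
  # one column per family in plan order
  pro_rows <- vapply(plans$plans, function(pl) pl$rows[pl$proband], 0L)
  pro <- plans$peds[pro_rows, ]
  pro$brca1_test <- "U"
  pro$brca2_test <- "U"
  PENden <- pen_matrix(ctx, pro)
  if (engine == "cpp") {
    res <- peel_dataset_cpp(PEN, PENden, ctx$prior, ctx$TMmat, ctx$TPmat,
                            ctx$TMavg, ctx$TPavg, plans$code, plans$code_off,
                            plans$cols, plans$fam_off, ctx$G, ctx$R,
                            posterior_family = posterior_family)
    ll <- res[, 1] - res[, 2]
    attr(ll, "post") <- attr(res, "post")
    ll
  } else {
    ll <- numeric(length(plans$plans))
    for (i in seq_along(plans$plans)) {
      pl <- plans$plans[[i]]
      pen <- PEN[, pl$rows, drop = FALSE]
      num <- peel_exec(ctx, pl$plan, pen)$loglik
      den <- log(sum(ctx$prior * PENden[, i]))
      ll[i] <- num - den
    }
    names(ll) <- names(plans$plans)
    ll
  }
}
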