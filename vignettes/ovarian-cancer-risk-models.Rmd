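---
title: "Modelling familial ovarian cancer risk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling familial ovarian cancer risk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovarisk)
```

# The model

`ovarisk` fits and applies a mixed major-gene / polygenic model of ovarian
cancer (OvC) susceptibility to pedigree data collected around an affected
index case. The incidence of OvC for woman $i$ born in cohort $k$ is

$$\lambda_i(t) \;=\; \lambda_{0,k}(t)\,
   \exp\!\big(g_i(t) + M_i + P_i\big),$$

where $\lambda_{0,k}(t)$ is a cohort-specific baseline hazard, $g_i(t)$ is
the log relative risk attached to the woman's BRCA1/BRCA2 carrier status
(absorbed into carrier-specific baselines in the implementation), $M_i$ is
the log relative risk of an optional third hypothetical major gene
(dominant, recessive or general two-parameter mode), and $P_i$ is a
polygenic component, Normal$(0, \sigma^2)$ in the population. Breast
cancer is modelled as a second, conditionally independent channel whose
incidence depends on BRCA1/BRCA2 status only; follow-up for OvC continues
after a breast-cancer diagnosis, and all follow-up stops at the first of
OvC diagnosis, death, questionnaire, or age 80.

## The discretised polygene

To keep the likelihood computable by pedigree peeling, the polygene is
discretised with the hypergeometric polygenic model: $2n$ exchangeable
"high" alleles, so an individual's level $r \in \{0,\dots,2n\}$ has
population distribution Binomial$(2n, \tfrac12)$ and value
$P_r = \sigma (r-n)/\sqrt{n/2}$. A parent at level $r$ transmits a gamete
of $s$ high alleles with hypergeometric probability
$\binom{r}{s}\binom{2n-r}{n-s}/\binom{2n}{n}$. This grid has mean 0 and
variance exactly $\sigma^2$ at every $n$, reproduces the additive
parent-offspring correlation of $\tfrac12$, and converges to the normal
as $n$ grows (the test suite asserts the Kolmogorov distance decreases
monotonically over $n = 1..8$). The default is $n = 4$ (nine levels), the
usual accuracy/cost compromise. Refining the grid is not free of effect:
refitting $\sigma$ on identical simulated data at $n = 6$ shifts the
estimate down by a few per cent (about 4% at the fitted scale), because
the finer grid covers more of the tails under a convex penetrance -- a
shift well inside the $\sim$9% estimation standard error, and the test
suite pins it below 8%.

## Genotype bookkeeping

BRCA1 and BRCA2 genotypes are tracked internally as allele copy counts
(0/1/2 per locus) so that Mendelian transmission is exact; risk depends
only on carrier status (double heterozygotes take the BRCA1 risk, and
homozygous carriers are not distinguished from heterozygotes, matching
how screening records carrier status). Founders carry Hardy-Weinberg
priors. The carrier frequency implied by an allele frequency $f$ is
$1-(1-f)^2$.

## Constraining baselines to population incidence

Users supply population incidence tables (eight birth cohorts, per-year
hazards to age 79) and external age-specific relative risks for BRCA1 and
BRCA2 carriers. The package then solves for baseline hazards per stratum
(non-carrier, BRCA1, BRCA2) such that at every age and in every cohort
the model-averaged incidence over the full genotype-by-polygene space
equals the population rate, and the average within each carrier stratum
equals the population rate times the external carrier relative risk.
Ages are swept forward, reweighting the genotype distribution by
survival from the modelled disease only (no competing mortality, matching
the follow-up-to-80 design). The same construction is applied to the
breast-cancer channel with the polygene and third-gene relative risks
identically 1. Constraint residuals are checked to $10^{-8}$ relative at
every age in the tests, and baselines are rebuilt inside every likelihood
evaluation so no stale values can survive a parameter update.

The package ships an illustrative synthetic incidence table (quadratic
OvC hazard rising from age 20, power-1.5 breast hazard from 25,
calibrated to lifetime risks of 0.02 and 0.10 for the 1940s cohort with a
mild $\pm 10\%$ trend across cohorts) because real registry tables are
licensed data the package cannot redistribute; all simulation results in
the tests use it. On the eight-cohort layout: the design calls for eight
cohorts from pre-1920 in ten-year bands; the package labels them
pre-1920, the six decades 1920s-1970s, and post-1980.

## Peeling and the conditional likelihood

The family likelihood sums founder priors x transmission x per-individual
penetrances over every member's latent state (genotype x polygene level;
81 states at the defaults). The sum is organised as Elston-Stewart
peeling over nuclear-family units, collapsing each unit from the
periphery onto the member connecting it to the rest; per-step rescaling
keeps values in range for families of any realistic size. Marriage and
inbreeding loops are detected and rejected rather than approximated. A
founder with no phenotype or test data who appears in a single unit with
a single child is integrated out analytically through a prior-averaged
transmission (this is exact only with one child -- siblings stay
correlated through the shared parent, a subtlety the brute-force oracle
tests pin down). The hot loop is implemented in C++ with an R reference
implementation kept alongside; both are compared to machine precision in
the tests, and to exhaustive enumeration on all small-pedigree shapes.

Penetrances: an unaffected woman contributes survival to her censoring
age; an affected woman contributes survival times the hazard in her year
of diagnosis (1-year resolution; an event recorded at 80 uses the final
hazard year). Males and individuals with unusable ages contribute test
factors only -- the conservative missing-data choice that avoids imputing
onset ages. Mutation tests contribute sensitivity factors
($P(\text{pos}\mid\text{carrier}) = 0.9$ by default per gene;
$P(\text{pos}\mid\text{non-carrier}) = 0$).

Families are ascertained through an affected proband, so the package
maximises the conditional likelihood $P(\mathbf{y} \mid y_\text{proband})$
where $\mathbf{y}$ is everything observed (all phenotypes plus the
proband's test results) and $y_\text{proband}$ is the proband's cancer
phenotype. The denominator deliberately excludes the proband's test
results: the fraction of probands testing positive is the primary
information about the allele frequencies, and conditioning on it removes
f1 and f2 from the likelihood almost entirely -- we verified by
simulation that including tests in the denominator sends the fitted
frequencies to the zero boundary, while the phenotype-only denominator
recovers them.

# Fitting, comparison, uncertainty

Eight models are fitted by maximum likelihood: BRCA1/2 only (2 free
parameters), a third major gene in dominant/recessive (4) or general (5)
mode, polygenic (3), and the three mixed variants (5, 5, 6). Frequencies
and $\sigma$ are optimised on the log scale, log relative risks
untransformed, with a Nelder-Mead search (relative log-likelihood
tolerance $10^{-8}$). Jittered restarts are attempted only when the first
search fails to converge (configurable via `control$n_restarts`):
unconditional multi-start would multiply the cost of every fit, and the
parameter-recovery study -- where every replicate converged from the
single heuristic start with confidence intervals covering the truth --
is the evidence the suite provides that the transformed-scale likelihood
is well behaved at these problem sizes. Standard errors come from the
observed information (central-difference Hessian on the transformed
scale); 95% CIs are formed on the transformed scale and back-transformed
so they always respect parameter ranges. Models are compared by
$\mathrm{AIC} = -2(\ell - k)$ and by likelihood ratio tests against the
richest (mixed general) model with degrees of freedom equal to the
difference in free-parameter counts; the naive $\chi^2$ reference is used
even when $\sigma$ sits on the boundary, which makes those tests
conservative.

# Prediction

Carrier probabilities for any family member are posterior peels onto that
individual; by default the target's own test results are excluded so that
expected carrier counts can be compared with observed test results
(Pearson $\chi^2$). Future-risk curves condition on the family's data and
the target being cancer-free at the starting age, then average
genotype-specific survival over the posterior.

A measured polygenic risk score (PRS) splits the polygene into a known
component of variance $\sigma_k^2 = \sum_j 2p_j(1-p_j)\ln^2 \mathrm{OR}_j$
and an independent residual of variance $\sigma_u^2 = \sigma^2 -
\sigma_k^2$. Conditioning on a PRS value replaces the counselee's
polygene values by $\mathrm{prs} + \sigma_u (r-n)/\sqrt{n/2}$ (an exact
mean shift, not a grid snap); relatives keep the full-variance polygene.
This single-individual conditioning mirrors the established approach for
other cancers; a full two-component familial transmission is a possible
extension. Quadrature over the population PRS distribution recovers the
no-PRS curve to within $10^{-3}$ absolute in the tests, which bounds the
approximation error of the shift at the default grid size. The bundled
17-SNP table is synthetic: locus names follow reported OvC GWAS regions
and frequencies are plausible, but the odds ratios are rescaled so the
score variance is exactly 0.0915 (about 4.5% of the total polygenic
variance $1.43^2$); it stands in for the published table, which is not
redistributable.

# Population stratification arithmetic

With lifetime log relative risk Normal$(0,\sigma^2)$ and mean lifetime
risk $F_0$, the rare-disease approximation gives closed forms: cases'
log risk is Normal$(\sigma^2, \sigma^2)$, the share of cases above
population quantile $q$ is $\Phi(\sigma - z_q)$, the population fraction
containing a case share $s$ is $1 - \Phi(\sigma - \Phi^{-1}(s))$, and the
risk at quantile $q$ is $F_0 e^{\sigma z_q - \sigma^2/2}$. A saturating
variant ($\text{risk} = 1 - e^{-\Lambda e^P}$, $\Lambda$ calibrated so the
mean risk is $F_0$) is provided because at $\sigma \approx 1.43$ the
upper tail of the lognormal exceeds 1 and saturation becomes material
there: the two variants agree to about 0.005 at the median but diverge by
a few hundredths in the top decile, so the closed forms are the default
and the saturating form is the robustness check. At the 17-SNP scale
($\sigma^2 = 0.0915$) the two are indistinguishable.

```{r strat}
stratification_summary(1.434, 0.02)
```

# The simulator

`simulate_pedigrees()` is the generative mirror of the likelihood:
founder genotypes from Hardy-Weinberg and Binomial$(2n,\tfrac12)$ priors,
Mendelian plus hypergeometric transmission, onset ages by inverse-CDF
sampling on the per-year constrained hazards, and ascertainment by
rejection -- a family enters the sample only if its designated proband
has OvC by her recruitment age, which matches the conditional likelihood
being fitted. Defaults emulate a population-based case series:
recruitment 1999-2010 at ages 40-70 (uniform; no recruitment-age
distribution is published, so uniform is the neutral choice), the
mother's phenotype observed for 87% of probands, and Poisson sister and
daughter counts with means 0.91 and 0.74 -- the per-proband relative
counts of such a series. Probands get test results generated with the
screening sensitivities and a PRS value drawn consistently with their
simulated polygene; relatives are untested. Death is not modelled
separately from questionnaire censoring, and relatives born after the
questionnaire date are omitted.

What the simulator deliberately does not emulate: reporting error in
relatives' cancer history, differential participation by prognosis,
risk-reducing surgery, and real registry incidence patterns. Passing
tests therefore demonstrate internal consistency of likelihood and
generative model under the stated conditions, not performance on real
questionnaire data.

# Problem sizes and numerical choices

The validation suite uses: exhaustive-enumeration cross-checks on
pedigrees up to 6 members at reduced state spaces (the enumeration is the
oracle, so its size is capped at $10^6$ joint states); constraint
residual checks at every age and cohort; and a parameter-recovery study
of 20 replicates of 2,000 ascertained families generated under the
fitted values ($f_1 = 0.00079$, $f_2 = 0.0026$, $\sigma = 1.43$),
requiring each parameter's 95% CI to cover the truth in at least 90% of
replicates. Convergence is declared at a relative log-likelihood change
below $10^{-8}$; Hessian steps are $10^{-3}$ on the transformed scale;
peeling rescales per step so log-likelihoods stay finite for any family
that is internally consistent. Degenerate inputs -- zero allele
frequencies, $\sigma = 0$, zero hazards, empty pedigrees -- collapse to
their closed-form special cases and are tested as such.

# Known limitations

* No competing mortality; risks are pure cause-specific cumulative risks
  to 80.
* No RAD51C/RAD51D/BRIP1 or mismatch-repair genes, no reproductive or
  lifestyle covariates, no tumour subtypes.
* Pedigrees with marriage or inbreeding loops are rejected.
* The PRS conditioning applies to the counselee only; relatives keep the
  total-variance polygene.
* The shipped incidence, carrier-relative-risk and SNP tables are
  synthetic illustrations; analyses of real data should substitute
  registry tables and published estimates via `read_incidence()`,
  `read_carrier_rr()` and `read_snp_table()`.
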