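#' Model parameters for the mixed major-gene / polygenic susceptibility model
#'
#' Bundles everything the likelihood depends on: mutated-allele frequencies
#' for BRCA1 (`f1`), BRCA2 (`f2`) and an optional third hypothetical major
#' gene (`fM`); the mode of inheritance and log relative risk(s) of that
#' third gene; the polygenic standard deviation `sigma` (log relative-risk
#' scale); the mutation-screening sensitivities; the variance `sigma_k2` of
#' the measured polygenic risk score; and the half-locus count `n_poly` of
#' the hypergeometric polygene grid.
#'
#' Defaults are the fitted values of the most parsimonious (polygenic)
#' susceptibility model: `f1 = 0.00079`, `f2 = 0.0026`, `sigma = 1.43`,
#' screening sensitivity 0.9 for both genes, and PRS variance 0.0915
#' (the 17-SNP ovarian-cancer risk score).
#'
#' @param f1,f2 Mutated-allele frequencies for BRCA1 and BRCA2, in (0, 1).
#' @param fM Allele frequency of the third major gene, or `NA` when
#'   `major_mode = "none"`.
#' @param major_mode One of `"none"`, `"dominant"`, `"recessive"`,
#'   `"general"`.
#' @param major_logRR Log relative risk of the third major gene: a single
#'   value for dominant/recessive, `c(het, hom)` for general mode.
#' @param sigma Polygenic standard deviation (>= 0).
#' @param sensitivity1,sensitivity2 Probability that a pathogenic mutation,
#'   if present, is detected by the screening assay.
#' @param sigma_k2 Variance of the known polygenic risk score; must not
#'   exceed `sigma^2`.
#' @param n_poly Half-locus count `n` of the polygene grid (the polygene
#'   takes `2n + 1` levels).
#' @return An object of class `ova_params` (a named list).
#' @export
#' @examples
#' p <- ova_params()
#' carrier_frequency(p$f1)
ova_params <- function(f1 = 0.00079, f2 = 0.0026,
                       fM = NA_real_, major_mode = c("none", "dominant", "recessive", "general"),
                       major_logRR = numeric(0),
                       sigma = 1.43,
                       sensitivity1 = 0.9, sensitivity2 = 0.9,
                       sigma_k2 = 0.0915,
                       n_poly = 4L) {
  major_mode <- match.arg(major_mode)
  p <- structure(list(
    f1 = f1, f2 = f2, fM = fM, major_mode = major_mode,
    major_logRR = as.numeric(major_logRR),
    sigma = sigma, sensitivity1 = sensitivity1, sensitivity2 = sensitivity2,
    sigma_k2 = sigma_k2, n_poly = as.integer(n_poly)
  ), class = "ova_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "ova_params"))
  chk_freq <- function(f, nm) {
    if (!is.na(f) && (f < 0 || f >= 1)) {
      stop(sprintf("allele frequency `%s` must be in [0, 1): got %g", nm, f), call. = FALSE)
    }
  }
  chk_freq(p$f1, "f1"); chk_freq(p$f2, "f2")
  if (p$major_mode != "none") {
    if (is.na(p$fM)) stop("`fM` required when major_mode != \"none\"", call. = FALSE)
    chk_freq(p$fM, "fM")
    need <- if (p$major_mode == "general") 2L else 1L
    if (length(p$major_logRR) != need) {
      stop(sprintf("major_mode \"%s\" needs %d log relative risk(s)", p$major_mode, need),
           call. = FALSE)
    }
  }
  if (p$sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  for (s in c(p$sensitivity1, p$sensitivity2)) {
    if (s < 0 || s > 1) stop("sensitivities must be in [0, 1]", call. = FALSE)
  }
  if (p$sigma_k2 < 0) stop("`sigma_k2` must be >= 0", call. = FALSE)
  if (p$sigma_k2 > p$sigma^2 + 1e-12) {
    stop("`sigma_k2` cannot exceed the total polygenic variance sigma^2", call. = FALSE)
  }
  if (p$n_poly < 1L) stop("`n_poly` must be >= 1", call. = FALSE)
  invisible(p)
}

#' @export
print.ova_params <- function(x, ...) {
  cat("<ova_params>\n")
  cat(sprintf("  BRCA1 allele freq f1 : %g (carrier 1 in %d)\n",
              x$f1, round(1 / carrier_frequency(max(x$f1, 1e-12)))))
  cat(sprintf("  BRCA2 allele freq f2 : %g (carrier 1 in %d)\n",
              x$f2, round(1 / carrier_frequency(max(x$f2, 1e-12)))))
  if (x$major_mode != "none") {
    cat(sprintf("  third major gene     : %s, fM = %g, logRR = %s\n",
                x$major_mode, x$fM, paste(signif(x$major_logRR, 3), collapse = "/")))
  }
  cat(sprintf("  polygenic SD sigma   : %g (PRS variance %g)\n", x$sigma, x$sigma_k2))
  cat(sprintf("  screen sensitivity   : %g / %g; polygene grid n = %d\n",
              x$sensitivity1, x$sensitivity2, x$n_poly))
  invisible(x)
}

#' Read / write model parameters as YAML
#'
#' The on-disk schema is a flat named list mirroring the arguments of
#' [ova_params()]; absent keys fall back to the defaults.
#'
#' @param path File path.
#' @return `read_params()` returns an `ova_params` object;
#'   `write_params()` invisibly returns `path`.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(ova_params))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown parameter field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(ova_params, raw)
}

#' @param params An `ova_params` object.
#' @rdname read_params
#' @export
write_params <- function(params, path) {
  validate_params(params)
  x <- unclass(params)
  x$major_logRR <- as.list(x$major_logRR)
  yaml::write_yaml(x, path)
  invisible(path)
}
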