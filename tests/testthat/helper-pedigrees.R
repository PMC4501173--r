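# In-code fixtures: small pedigree builders used across the suite.

ind <- function(id, sex, fa = NA_character_, mo = NA_character_, by = 1940,
                ov = NA_real_, bc = NA_real_, st = NA_real_,
                t1 = "U", t2 = "U", pro = FALSE, fam = "f1", prs = NA_real_,
                rel = "x", vital = "A") {
  tibble::tibble(family_id = fam, id = id, father_id = fa, mother_id = mo,
                 sex = sex, birth_year = by, ovca_age = ov, brca_age = bc,
                 status_age = st, vital = vital, brca1_test = t1,
                 brca2_test = t2, prs_value = prs, proband = pro, relation = rel)
}

mkped <- function(...) as_pedigrees(dplyr::bind_rows(...))

# parents + proband (+ optional affected relatives), proband untested by
# default so the ascertainment denominator identities hold exactly
trio <- function(pro_ov = 50, t1 = "U", t2 = "U", mum_ov = NA_real_) {
  mkped(
    ind("dad", "M", by = 1915, st = 70),
    ind("mum", "F", by = 1918, st = 75, ov = mum_ov),
    ind("pro", "F", "dad", "mum", by = 1945, ov = pro_ov, st = min(pro_ov + 1, 80),
        t1 = t1, t2 = t2, pro = TRUE)
  )
}

# 4-member family for risk prediction scenarios
fam_history <- function(fam = "f1", mum_ov = NA_real_, sis_ov = NA_real_,
                        target_t1 = "N", target_t2 = "N") {
  mkped(
    ind("mum", "F", by = 1915, st = 65, ov = mum_ov, fam = fam),
    ind("dad", "M", by = 1913, fam = fam),
    ind("target", "F", "dad", "mum", by = 1940, st = 50,
        t1 = target_t1, t2 = target_t2, pro = TRUE, fam = fam),
    ind("sis", "F", "dad", "mum", by = 1942, st = 50, ov = sis_ov, fam = fam)
  )
}
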