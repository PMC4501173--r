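#' Pedigree tables
#'
#' Pedigrees are plain tibbles with one row per individual and the columns
#' of the documented TSV dialect (a LINKAGE-style pre-makeped file extended
#' with named phenotype columns):
#'
#' * `family_id`, `id`, `father_id`, `mother_id` -- character; `"0"` /
#'   `NA` mean missing parent,
#' * `sex` -- `"F"` or `"M"`,
#' * `birth_year` -- integer year or `NA`,
#' * `ovca_age`, `brca_age` -- age in completed years at ovarian / breast
#'   cancer diagnosis, `NA` if unaffected,
#' * `status_age` -- censoring age (death or questionnaire),
#' * `vital` -- `"A"`live, `"D"`ead, `"U"`nknown,
#' * `brca1_test`, `brca2_test` -- `"P"`ositive, `"N"`egative,
#'   `"U"`ntested,
#' * `prs_value` -- centred polygenic risk score (log relative risk) or
#'   `NA`,
#' * `proband` -- logical, exactly one `TRUE` per family,
#' * `relation` -- free-text tag, informational only.
#'
#' Follow-up ends at age 80: ages are capped on read and events recorded
#' beyond 80 are converted to censoring at 80.
#'
#' @name pedigree-format
NULL

ped_cols <- c("family_id", "id", "father_id", "mother_id", "sex", "birth_year",
              "ovca_age", "brca_age", "status_age", "vital", "brca1_test",
              "brca2_test", "prs_value", "proband", "relation")

#' Read pedigrees from a TSV file
#'
#' Reads, coerces and validates a pedigree file (see [pedigree-format]).
#' Parents referenced but not present in the file -- including the missing
#' half of a single-parent link -- are materialised as unobserved placeholder
#' founders; event ages beyond 80 become censoring at 80. Structural
#' problems that make the file unusable (duplicate ids, missing proband,
#' malformed rows) raise errors naming the offending family or line;
#' soft issues are attached as the `"issues"` attribute (a
#' [validate_pedigree()] report).
#'
#' @param path TSV file path.
#' @param dialect File dialect; only `"tsv"` is currently implemented.
#' @return A tibble of individuals (all families stacked), with attribute
#'   `"issues"`.
#' @export
read_pedigrees <- function(path, dialect = "tsv") {
  stopifnot(identical(dialect, "tsv"))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character())
  if (!all(ped_cols %in% names(raw))) {
    stop("pedigree file must have columns: ", paste(ped_cols, collapse = ", "), call. = FALSE)
  }
  num <- function(x, field) {
    x[x %in% c("NA", "")] <- NA
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      stop(sprintf("malformed %s at line %d: \"%s\"", field, bad[1] + 1L, x[bad[1]]),
           call. = FALSE)
    }
    out
  }
  peds <- tibble::tibble(
    family_id = raw$family_id,
    id = raw$id,
    father_id = dplyr::na_if(dplyr::na_if(raw$father_id, "0"), "NA"),
    mother_id = dplyr::na_if(dplyr::na_if(raw$mother_id, "0"), "NA"),
    sex = raw$sex,
    birth_year = num(raw$birth_year, "birth_year"),
    ovca_age = num(raw$ovca_age, "ovca_age"),
    brca_age = num(raw$brca_age, "brca_age"),
    status_age = num(raw$status_age, "status_age"),
    vital = raw$vital,
    brca1_test = raw$brca1_test,
    brca2_test = raw$brca2_test,
    prs_value = num(raw$prs_value, "prs_value"),
    proband = num(raw$proband, "proband") == 1,
    relation = raw$relation
  )
  if (!all(peds$sex %in% c("F", "M"))) {
    stop("malformed sex at line ", which(!peds$sex %in% c("F", "M"))[1] + 1L, call. = FALSE)
  }
  as_pedigrees(peds)
}

#' Coerce and finalise a pedigree tibble
#'
#' Applies the same normalisation as [read_pedigrees()] to an in-memory
#' tibble: placeholder founders, the age-80 cap, and structural checks.
#'
#' @param peds A tibble with the [pedigree-format] columns.
#' @return The normalised tibble with attribute `"issues"`.
#' @export
as_pedigrees <- function(peds) {
  peds <- tibble::as_tibble(peds)[, ped_cols]
  for (col in c("family_id", "id", "father_id", "mother_id")) {
    peds[[col]] <- as.character(peds[[col]])
  }
  peds$proband <- as.logical(peds$proband)
  dup <- peds |>
    dplyr::count(.data$family_id, .data$id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop(sprintf("duplicate individual id \"%s\" in family \"%s\"",
                 dup$id[1], dup$family_id[1]), call. = FALSE)
  }
  npro <- peds |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(n = sum(.data$proband, na.rm = TRUE))
  if (any(npro$n == 0)) {
    stop("no proband in family \"", npro$family_id[npro$n == 0][1], "\"", call. = FALSE)
  }

  # materialise missing parents as placeholder founders (both-or-neither)
  fill_parent <- function(peds, role) {
    sexe <- if (role == "father_id") "M" else "F"
    ref <- peds[!is.na(peds[[role]]), c("family_id", role)]
    names(ref)[2] <- "id"
    ref <- dplyr::anti_join(dplyr::distinct(ref), peds[, c("family_id", "id")],
                            by = c("family_id", "id"))
    if (!nrow(ref)) return(peds)
    add <- tibble::tibble(
      family_id = ref$family_id, id = ref$id,
      father_id = NA_character_, mother_id = NA_character_,
      sex = sexe, birth_year = NA_real_, ovca_age = NA_real_, brca_age = NA_real_,
      status_age = NA_real_, vital = "U", brca1_test = "U", brca2_test = "U",
      prs_value = NA_real_, proband = FALSE, relation = "auto_founder"
    )
    dplyr::bind_rows(peds, add)
  }
  # if only one parent is named, invent the other so non-founders have both
  half <- xor(is.na(peds$father_id), is.na(peds$mother_id))
  if (any(half)) {
    i <- which(half & is.na(peds$father_id))
    peds$father_id[i] <- paste0(peds$mother_id[i], ":spouse")
    i <- which(half & is.na(peds$mother_id))
    peds$mother_id[i] <- paste0(peds$father_id[i], ":spouse")
  }
  peds <- fill_parent(fill_parent(peds, "father_id"), "mother_id")

  # follow-up ends at 80
  adj <- (!is.na(peds$ovca_age) & peds$ovca_age > 80) |
    (!is.na(peds$brca_age) & peds$brca_age > 80) |
    (!is.na(peds$status_age) & peds$status_age > 80)
  peds$status_age[!is.na(peds$status_age) & peds$status_age > 80] <- 80
  late_ov <- !is.na(peds$ovca_age) & peds$ovca_age > 80
  peds$ovca_age[late_ov] <- NA
  peds$status_age[late_ov] <- 80
  late_bc <- !is.na(peds$brca_age) & peds$brca_age > 80
  peds$brca_age[late_bc] <- NA
  peds$status_age[late_bc] <- pmax(peds$status_age[late_bc], 80, na.rm = TRUE)

  issues <- validate_pedigree(peds)
  if (any(adj)) {
    issues <- dplyr::bind_rows(issues, tibble::tibble(
      family_id = peds$family_id[adj], id = peds$id[adj],
      rule = "age_capped_at_80", detail = "event/censoring age beyond 80 truncated"
    ))
  }
  attr(peds, "issues") <- issues
  peds
}

#' Validate pedigrees
#'
#' Checks the structural and phenotype invariants of a pedigree table and
#' reports violations without raising: event age beyond the censoring age,
#' multiple or missing probands, unresolved or same-sex parents, cycles
#' through parent links, ages outside 0..80, and missing birth years
#' (which downstream code maps to the 1940s cohort).
#'
#' @param peds A pedigree tibble.
#' @return A tibble of issues with columns `family_id`, `id`, `rule`,
#'   `detail`; zero rows when all invariants hold.
#' @export
validate_pedigree <- function(peds) {
  out <- list()
  add <- function(fam, id, rule, detail) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      family_id = fam, id = id, rule = rule, detail = detail
    )
  }
  bad <- !is.na(peds$ovca_age) & !is.na(peds$status_age) & peds$ovca_age > peds$status_age
  if (any(bad)) add(peds$family_id[bad], peds$id[bad], "event_after_censor",
                    "ovca_age exceeds status_age")
  bad <- !is.na(peds$brca_age) & !is.na(peds$status_age) & peds$brca_age > peds$status_age
  if (any(bad)) add(peds$family_id[bad], peds$id[bad], "event_after_censor",
                    "brca_age exceeds status_age")
  for (col in c("ovca_age", "brca_age", "status_age")) {
    bad <- !is.na(peds[[col]]) & (peds[[col]] < 0 | peds[[col]] > 80)
    if (any(bad)) add(peds$family_id[bad], peds$id[bad], "age_out_of_range",
                      paste(col, "outside 0..80"))
  }
  bad <- is.na(peds$birth_year) &
    (!is.na(peds$ovca_age) | !is.na(peds$brca_age) | !is.na(peds$status_age))
  if (any(bad)) add(peds$family_id[bad], peds$id[bad], "unknown_birth_year",
                    "birth year missing; 1940s cohort assumed")

  for (fam in unique(peds$family_id)) {
    p <- peds[peds$family_id == fam, ]
    np <- sum(p$proband, na.rm = TRUE)
    if (np > 1) add(fam, NA_character_, "multiple_probands", sprintf("%d probands", np))
    if (np == 0) add(fam, NA_character_, "no_proband", "no proband flagged")
    for (role in c("father_id", "mother_id")) {
      miss <- !is.na(p[[role]]) & !(p[[role]] %in% p$id)
      if (any(miss)) add(fam, p$id[miss], "unresolved_parent",
                         paste(role, "not in family"))
    }
    fa <- p$sex[match(p$father_id, p$id)]
    mo <- p$sex[match(p$mother_id, p$id)]
    bad <- (!is.na(fa) & fa != "M") | (!is.na(mo) & mo != "F")
    if (any(bad)) add(fam, p$id[bad], "parent_sex", "father must be male, mother female")
    if (has_parent_cycle(p)) add(fam, NA_character_, "parent_cycle",
                                 "directed cycle through parent links")
  }
  if (!length(out)) {
    return(tibble::tibble(family_id = character(), id = character(),
                          rule = character(), detail = character()))
  }
  dplyr::bind_rows(out)
}

has_parent_cycle <- function(p) {
  # Kahn topological sort over parent -> child edges
  kids <- function(id) p$id[!is.na(p$father_id) & p$father_id == id |
                              !is.na(p$mother_id) & p$mother_id == id]
  indeg <- (!is.na(p$father_id) & p$father_id %in% p$id) +
    (!is.na(p$mother_id) & p$mother_id %in% p$id)
  names(indeg) <- p$id
  queue <- p$id[indeg == 0]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (k in kids(v)) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  seen < nrow(p)
}

#' Write pedigrees to a TSV file
#'
#' Serialises in the dialect read by [read_pedigrees()]: missing parent
#' ids as `"0"`, missing numeric values as `"NA"`, full precision for
#' `prs_value`.
#'
#' @param peds A pedigree tibble.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pedigrees <- function(peds, path) {
  out <- tibble::as_tibble(peds)[, ped_cols]
  fmt_num <- function(x) ifelse(is.na(x), "NA", format(x, digits = 15, scientific = FALSE,
                                                       trim = TRUE))
  out <- out |>
    dplyr::mutate(
      father_id = dplyr::coalesce(.data$father_id, "0"),
      mother_id = dplyr::coalesce(.data$mother_id, "0"),
      dplyr::across(c("birth_year", "ovca_age", "brca_age", "status_age", "prs_value"),
                    fmt_num),
      proband = as.integer(.data$proband)
    )
  readr::write_tsv(out, path)
  invisible(path)
}
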