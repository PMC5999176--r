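#' Record one tumor diagnosis
#'
#' Builds a one-row (or, with vector arguments, multi-row) tibble describing
#' a tumor diagnosis: site, histology, age at diagnosis, and chronology
#' relative to an earlier colorectal cancer of the same person.
#'
#' @param site Tumor site, one of `"colorectum"`, `"endometrium"`,
#'   `"stomach"`, `"small_intestine"`, `"pancreas"`, `"bile_ducts"`,
#'   `"renal_pelvis"`, `"ureter"`, `"ovary"`, `"brain"`,
#'   `"sebaceous_gland"`, `"breast"`, `"other"`.
#' @param kind Histology, `"carcinoma"` or `"adenoma"`. Only the sebaceous
#'   gland admits adenomas as Lynch-associated; adenomas elsewhere are
#'   recordable but never satisfy a referral criterion.
#' @param age_at_diagnosis Integer age in years at diagnosis, or `NA` when
#'   unknown. An unknown age fails every age-bounded condition, so a
#'   criterion never fires on missing data.
#' @param chronology `"first"`, `"synchronous"` or `"metachronous"`, the
#'   latter two relative to an earlier colorectal cancer of the same person.
#'
#' @return A tibble with columns `site`, `kind`, `age_at_diagnosis`,
#'   `chronology`.
#' @examples
#' tumor_diagnosis("colorectum", age_at_diagnosis = 45)
#' tumor_diagnosis("sebaceous_gland", kind = "adenoma", age_at_diagnosis = 60)
#' @export
tumor_diagnosis <- function(site, kind = "carcinoma", age_at_diagnosis = NA,
                            chronology = "first") {
  tibble::tibble(
    site = as.character(site),
    kind = as.character(kind),
    age_at_diagnosis = as.numeric(age_at_diagnosis),
    chronology = as.character(chronology)
  )
}

#' Record a relative in the family history
#'
#' @param relation Kinship code: first degree `"parent"`, `"sibling"`,
#'   `"child"`; second degree `"grandparent"`, `"aunt_uncle"`,
#'   `"half_sibling"`, `"niece_nephew"`, `"grandchild"`.
#' @param lineage `"maternal"`, `"paternal"` or `"direct"`. Second-degree
#'   relatives must sit on one parental side; the proband's own siblings and
#'   children (and a parent entered without a side) are `"direct"` and are
#'   genetically related to both sides, so they satisfy a same-lineage
#'   constraint with either. Defaults to `"direct"` for first-degree
#'   relations; required for second-degree relations.
#' @param diagnoses A tibble of diagnoses built with [tumor_diagnosis()], or
#'   `NULL` for an unaffected relative.
#' @param known_mmr_mutation Whether this relative carries a known mismatch
#'   repair gene mutation.
#'
#' @return A one-row tibble with a `diagnoses` list-column.
#' @examples
#' relative("sibling", diagnoses = tumor_diagnosis("colorectum", age_at_diagnosis = 45))
#' relative("aunt_uncle", lineage = "maternal")
#' @export
relative <- function(relation, lineage = NULL, diagnoses = NULL,
                     known_mmr_mutation = FALSE) {
  relation <- as.character(relation)
  if (length(relation) != 1L || !relation %in% fh_relations) {
    abort(paste0(
      "Unknown relation code: ", paste(relation, collapse = ", "),
      ". Valid codes: ", paste(fh_relations, collapse = ", "), "."
    ))
  }
  if (is.null(lineage)) {
    if (relation %in% fh_relations_degree1) {
      lineage <- "direct"
    } else {
      abort(paste0(
        "A second-degree relative (", relation,
        ") needs an explicit lineage (\"maternal\" or \"paternal\")."
      ))
    }
  }
  if (is.null(diagnoses)) {
    diagnoses <- tumor_diagnosis(character(), character(), numeric(), character())
  }
  tibble::tibble(
    relation = relation,
    lineage = as.character(lineage),
    known_mmr_mutation = isTRUE(known_mmr_mutation),
    diagnoses = list(diagnoses)
  )
}

#' Collect relatives into one table
#'
#' @param ... One-row tibbles from [relative()] (or multi-row tibbles of the
#'   same shape).
#' @return A tibble with one row per relative.
#' @export
relatives <- function(...) {
  rows <- list(...)
  if (length(rows) == 0L) {
    return(relative("sibling")[0, ])
  }
  dplyr::bind_rows(rows)
}

#' Describe the proband
#'
#' The proband is the questionnaire respondent: a patient seen at a
#' colorectal-cancer outpatient clinic (or any person whose family history
#' is being triaged). Demographics are carried for reporting; the rules use
#' only the diagnoses and the prior-testing answer.
#'
#' @param age Current age in years.
#' @param sex `"male"`, `"female"` or `"other"`.
#' @param diagnoses A tibble from [tumor_diagnosis()], or `NULL` if healthy.
#' @param prior_testing_unclear Direct questionnaire answer: is it unclear
#'   whether genetic testing was already done, what its outcome was, or
#'   whether surveillance recommendations were already given? Never
#'   inferred from other fields.
#' @param nationality,educational_level,native_language Optional
#'   demographics (`educational_level` one of `"low"`, `"moderate"`,
#'   `"high"`).
#'
#' @return An object of class `fh_proband` (a named list).
#' @export
proband <- function(age, sex = "other", diagnoses = NULL,
                    prior_testing_unclear = FALSE, nationality = NA_character_,
                    educational_level = NA_character_,
                    native_language = NA_character_) {
  if (is.null(diagnoses)) {
    diagnoses <- tumor_diagnosis(character(), character(), numeric(), character())
  }
  structure(
    list(
      age = as.numeric(age),
      sex = as.character(sex),
      diagnoses = diagnoses,
      prior_testing_unclear = isTRUE(prior_testing_unclear),
      nationality = as.character(nationality),
      educational_level = as.character(educational_level),
      native_language = as.character(native_language)
    ),
    class = "fh_proband"
  )
}

#' Assemble a family history
#'
#' A proband-centric family history reaching first- and second-degree
#' relatives: the sole input of the referral rule engine.
#'
#' @param proband An [proband()] object.
#' @param relatives A tibble of relatives from [relatives()]/[relative()];
#'   may be empty or `NULL`.
#' @return An object of class `family_history`.
#' @examples
#' h <- family_history(
#'   proband(60, "male", tumor_diagnosis("colorectum", age_at_diagnosis = 60)),
#'   relative("sibling", diagnoses = tumor_diagnosis("colorectum", age_at_diagnosis = 55))
#' )
#' evaluate_history(h)
#' @export
family_history <- function(proband, relatives = NULL) {
  if (!inherits(proband, "fh_proband")) {
    abort("`proband` must be built with proband().")
  }
  if (is.null(relatives)) {
    relatives <- relative("sibling")[0, ]
  }
  if (!is.data.frame(relatives)) {
    abort("`relatives` must be a tibble built with relative()/relatives().")
  }
  structure(list(proband = proband, relatives = tibble::as_tibble(relatives)),
            class = "family_history")
}

#' @export
print.family_history <- function(x, ...) {
  p <- x$proband
  cat("<family_history>\n")
  cat(sprintf("  proband: age %s, sex %s, %d diagnosis(es)%s\n",
              format(p$age), p$sex, nrow(p$diagnoses),
              if (p$prior_testing_unclear) ", prior testing unclear" else ""))
  cat(sprintf("  relatives: %d\n", nrow(x$relatives)))
  invisible(x)
}

#' Kinship degree of a relation code
#'
#' @param relation Character vector of relation codes.
#' @return Integer vector of degrees (1 or 2).
#' @examples
#' degree_of(c("sibling", "half_sibling", "aunt_uncle"))
#' @export
degree_of <- function(relation) {
  relation <- as.character(relation)
  bad <- setdiff(unique(relation), fh_relations)
  if (length(bad) > 0L) {
    abort(paste0("Unknown relation code(s): ", paste(bad, collapse = ", "), "."))
  }
  ifelse(relation %in% fh_relations_degree1, 1L, 2L)
}

#' Is a tumor diagnosis Lynch-syndrome associated?
#'
#' Extracolonic tumors counted as Lynch-associated: carcinoma of the
#' endometrium, stomach, small intestine, pancreas, bile ducts, renal
#' pelvis, ureter, ovary or brain, and carcinoma or adenoma of the
#' sebaceous gland. Colorectal cancer is handled separately by the
#' criteria and returns `FALSE` here. The decision depends only on site
#' and histology, never on age.
#'
#' @param site,kind Character vectors (recycled) of tumor site and
#'   histology, or a diagnoses tibble passed as `site` with `kind` missing.
#' @return Logical vector.
#' @examples
#' is_lynch_associated("ovary", "carcinoma")
#' is_lynch_associated("sebaceous_gland", "adenoma")
#' is_lynch_associated("breast", "carcinoma")
#' @export
is_lynch_associated <- function(site, kind = "carcinoma") {
  if (is.data.frame(site)) {
    kind <- site$kind
    site <- site$site
  }
  (site %in% fh_lynch_sites & kind == "carcinoma") | site == "sebaceous_gland"
}

#' Count a relative's qualifying tumors, capped at two
#'
#' A relative with more than one colorectal cancer or Lynch-associated
#' tumor counts as two affected relatives, so criteria that count affected
#' relatives sum this capped tally. Qualifying diagnoses are colorectal
#' carcinomas and Lynch-associated tumors with a known age at diagnosis
#' strictly under `age_limit` (no age restriction when `age_limit` is
#' `NULL`).
#'
#' @param x A one-row relative tibble (with a `diagnoses` list-column) or a
#'   diagnoses tibble.
#' @param age_limit Strict upper bound in years, or `NULL` for none.
#' @return Integer in `0:2`.
#' @examples
#' r <- relative("aunt_uncle", "maternal", dplyr::bind_rows(
#'   tumor_diagnosis("colorectum", age_at_diagnosis = 60),
#'   tumor_diagnosis("endometrium", age_at_diagnosis = 64)
#' ))
#' effective_tumor_count(r, age_limit = 70)
#' @export
effective_tumor_count <- function(x, age_limit = NULL) {
  d <- if (is.data.frame(x) && "diagnoses" %in% names(x)) {
    if (nrow(x) != 1L) abort("Pass a single relative (one row).")
    x$diagnoses[[1L]]
  } else {
    x
  }
  qual <- diag_is_crc(d) | is_lynch_associated(d)
  if (!is.null(age_limit)) {
    qual <- qual & !is.na(d$age_at_diagnosis) & d$age_at_diagnosis < age_limit
  }
  min(sum(qual), 2L)
}

## site == colorectum & kind == carcinoma; colorectal adenomas never count
diag_is_crc <- function(d) {
  d$site == "colorectum" & d$kind == "carcinoma"
}

diag_is_endometrial <- function(d) {
  d$site == "endometrium" & d$kind == "carcinoma"
}

age_lt <- function(age, limit) !is.na(age) & age < limit

age_between <- function(age, lo, hi) !is.na(age) & age >= lo & age <= hi

#' Validate a family history
#'
#' Checks every structural invariant of the data model and returns a tibble
#' of issues rather than raising. `severity = "error"` rows are invariant
#' breaches that make the history unusable for rule evaluation;
#' `severity = "note"` rows flag unknown ages at diagnosis, which are legal
#' but make age-bounded criteria unable to fire, so callers may want to
#' prompt for completion.
#'
#' @param h A [family_history()] object.
#' @return A tibble with columns `field`, `message`, `severity`; zero
#'   error rows iff all invariants hold.
#' @export
validate_history <- function(h) {
  issues <- list()
  add <- function(field, message, severity = "error") {
    issues[[length(issues) + 1L]] <<- tibble::tibble(
      field = field, message = message, severity = severity
    )
  }
  if (!inherits(h, "family_history")) {
    add("", "not a family_history object")
    return(dplyr::bind_rows(issues))
  }
  p <- h$proband
  if (is.na(p$age) || p$age < 0 || p$age > 120) {
    add("proband.age", "age must be in [0, 120]")
  }
  if (!p$sex %in% fh_sexes) {
    add("proband.sex", paste0("unknown sex code: ", p$sex))
  }
  if (!is.na(p$educational_level) && !p$educational_level %in% fh_education_levels) {
    add("proband.educational_level",
        paste0("unknown educational level: ", p$educational_level))
  }
  validate_diagnoses(p$diagnoses, "proband.diagnoses", add)
  rel <- h$relatives
  for (i in seq_len(nrow(rel))) {
    at <- function(f) sprintf("relatives[%d].%s", i, f)
    if (!rel$relation[i] %in% fh_relations) {
      add(at("relation"), paste0("unknown relation code: ", rel$relation[i]))
      next
    }
    if (!rel$lineage[i] %in% fh_lineages) {
      add(at("lineage"), paste0("unknown lineage: ", rel$lineage[i]))
    } else if (rel$lineage[i] == "direct" &&
               !rel$relation[i] %in% fh_relations_degree1) {
      add(at("lineage"),
          "second-degree relatives must have maternal or paternal lineage")
    }
    validate_diagnoses(rel$diagnoses[[i]], at("diagnoses"), add)
  }
  out <- dplyr::bind_rows(issues)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(field = character(), message = character(),
                          severity = character())
  }
  out
}

validate_diagnoses <- function(d, path, add) {
  if (!is.data.frame(d)) {
    add(path, "diagnoses must be a tibble")
    return(invisible())
  }
  for (j in seq_len(nrow(d))) {
    at <- function(f) sprintf("%s[%d].%s", path, j, f)
    if (!d$site[j] %in% fh_sites) {
      add(at("site"), paste0("unknown tumor site: ", d$site[j]))
    }
    if (!d$kind[j] %in% fh_kinds) {
      add(at("kind"), paste0("unknown histology: ", d$kind[j]))
    }
    if (!d$chronology[j] %in% fh_chronologies) {
      add(at("chronology"), paste0("unknown chronology: ", d$chronology[j]))
    } else if (d$chronology[j] != "first" && nrow(d) < 2L) {
      add(at("chronology"),
          "synchronous/metachronous needs at least two diagnoses")
    }
    a <- d$age_at_diagnosis[j]
    if (is.na(a)) {
      add(at("age_at_diagnosis"),
          "unknown age: age-bounded criteria cannot fire on this diagnosis",
          severity = "note")
    } else if (a < 0 || a > 120) {
      add(at("age_at_diagnosis"), "age at diagnosis must be in [0, 120]")
    }
  }
  invisible()
}

#' @rdname validate_history
#' @return `is_valid_history()`: `TRUE` iff no error-severity issues.
#' @export
is_valid_history <- function(h) {
  iss <- validate_history(h)
  !any(iss$severity == "error")
}

stop_if_invalid <- function(h) {
  iss <- validate_history(h)
  err <- iss[iss$severity == "error", , drop = FALSE]
  if (nrow(err) > 0L) {
    abort(paste0(
      "Invalid family history:\n",
      paste0("  - ", err$field, ": ", err$message, collapse = "\n")
    ))
  }
  invisible(h)
}
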