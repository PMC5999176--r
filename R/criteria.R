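#' Referral criteria for Lynch syndrome and familial colorectal cancer
#'
#' The engine evaluates the 13 Dutch nationwide referral criteria for
#' genetic counseling. Criteria 1-8 indicate a Lynch syndrome suspicion,
#' 9-12 familial colorectal cancer (FCC), and 13 covers unclear prior
#' genetic testing. Age comparisons are literal: "< X" is strict and
#' "50-70" is inclusive on both ends, so a diagnosis at 70 satisfies
#' 50-70 but not "< 70". Unknown ages never satisfy an age bound.
#'
#' Counting rules shared by the family-count criteria:
#' * a relative with more than one colorectal cancer (CRC) or
#'   Lynch-associated tumor counts as two affected relatives
#'   ([effective_tumor_count()]);
#' * counted relatives must all be genetically related, i.e. all on the
#'   maternal or all on the paternal side, with the proband's own siblings
#'   and children compatible with either side;
#' * "a person" (as opposed to "a patient with colorectal cancer") means a
#'   healthy proband, a proband whose CRC or Lynch-associated tumors were
#'   all diagnosed over 70, or a proband with only other cancer types at
#'   any age.
#'
#' @name referral_criteria
NULL

criterion_descriptions <- c(
  "Patient with CRC or endometrial cancer < 50 years",
  "First-degree relative with CRC or endometrial cancer < 50 years",
  "Family member with a known mismatch repair mutation",
  "Person with >= 3 first/second-degree relatives with CRC or a Lynch-associated tumor < 70 years (one lineage)",
  "Patient with CRC plus a synchronous or metachronous CRC, both < 70 years",
  "Patient with CRC plus a synchronous or metachronous Lynch-associated tumor < 70 years",
  "Patient with CRC (any age) with a first-degree relative with CRC or a Lynch-associated tumor < 50 years",
  "Patient with CRC or a Lynch-associated tumor with >= 2 first/second-degree relatives with CRC or a Lynch-associated tumor, all < 70 years (one lineage)",
  "Person with two first-degree relatives with CRC 50-70 years (one lineage)",
  "Person with a first-degree relative with CRC 50-70 years and a second-degree relative with CRC < 70 years (one lineage)",
  "Patient with CRC with a first-degree relative with CRC, both 50-70 years",
  "Patient with CRC 50-70 years with a second-degree relative with CRC < 70 years",
  "Unclear whether genetic testing or surveillance advice was already given"
)

#' Evaluate a family history against the referral criteria
#'
#' Runs all 13 criteria (see [referral_criteria]) and derives a single
#' recommendation: `"refer_lynch"` when any Lynch criterion (1-8) matches,
#' else `"refer_fcc"` when any FCC criterion (9-12) matches, else
#' `"refer_other"` when only the prior-testing criterion (13) matches,
#' else `"no_referral"`. All matched criteria are reported, not just the
#' first: one patient can meet several.
#'
#' @param h A valid [family_history()].
#' @return An object of class `referral_result` with elements
#'   `matched_criteria` (sorted integer vector) and `recommendation`.
#' @examples
#' h <- family_history(
#'   proband(45, "female", tumor_diagnosis("colorectum", age_at_diagnosis = 45))
#' )
#' evaluate_history(h)
#' @seealso [oracle_evaluate()] for the independent brute-force referee,
#'   [check_criterion()] for a single criterion.
#' @export
evaluate_history <- function(h) {
  stop_if_invalid(h)
  matched <- which(vapply(1:13, function(k) criterion_holds(h, k), logical(1)))
  referral_result(matched)
}

referral_result <- function(matched) {
  matched <- sort(as.integer(matched))
  recommendation <- if (any(matched <= 8)) {
    "refer_lynch"
  } else if (any(matched >= 9 & matched <= 12)) {
    "refer_fcc"
  } else if (13L %in% matched) {
    "refer_other"
  } else {
    "no_referral"
  }
  structure(list(matched_criteria = matched, recommendation = recommendation),
            class = "referral_result")
}

#' @export
print.referral_result <- function(x, ...) {
  cat("<referral_result>\n")
  cat("  recommendation:", x$recommendation, "\n")
  if (length(x$matched_criteria) == 0L) {
    cat("  matched criteria: none\n")
  } else {
    cat("  matched criteria:", paste(x$matched_criteria, collapse = ", "), "\n")
    for (k in x$matched_criteria) {
      cat(sprintf("    %2d. %s\n", k, criterion_descriptions[k]))
    }
  }
  invisible(x)
}

#' Tidy a referral result into one row per criterion
#'
#' @param x A `referral_result`.
#' @param ... Unused.
#' @return A 13-row tibble with columns `criterion`, `description`,
#'   `matched`, `group` (`"lynch"`, `"fcc"`, `"other"`).
#' @export
#' @exportS3Method generics::tidy
tidy.referral_result <- function(x, ...) {
  tibble::tibble(
    criterion = 1:13,
    description = criterion_descriptions,
    matched = 1:13 %in% x$matched_criteria,
    group = c(rep("lynch", 8), rep("fcc", 4), "other")
  )
}

#' Test a single referral criterion
#'
#' @param h A valid [family_history()].
#' @param k Criterion number, 1 to 13.
#' @return `TRUE` iff criterion `k` is among `evaluate_history(h)$matched_criteria`.
#' @export
check_criterion <- function(h, k) {
  if (length(k) != 1L || is.na(k) || k < 1 || k > 13 || k != as.integer(k)) {
    abort("`k` must be a single integer between 1 and 13.")
  }
  as.integer(k) %in% evaluate_history(h)$matched_criteria
}

## ---- criterion internals ------------------------------------------------

criterion_holds <- function(h, k) {
  p <- h$proband
  pd <- p$diagnoses
  rel <- h$relatives
  switch(k,
    ## 1: proband CRC or endometrial carcinoma < 50
    any((diag_is_crc(pd) | diag_is_endometrial(pd)) &
          age_lt(pd$age_at_diagnosis, 50)),
    ## 2: any first-degree relative with CRC or endometrial carcinoma < 50,
    ##    irrespective of the proband's own status
    any_relative(rel, degree = 1, function(d) {
      any((diag_is_crc(d) | diag_is_endometrial(d)) &
            age_lt(d$age_at_diagnosis, 50))
    }),
    ## 3: known mismatch repair mutation in the family
    nrow(rel) > 0L && any(rel$known_mmr_mutation),
    ## 4: "person" proband + >= 3 affected relatives (effective counts,
    ##    one lineage), qualifying diagnoses < 70
    footnote_person(pd) && max_lineage_count(rel, age_limit = 70) >= 3L,
    ## 5: proband CRC plus synchronous/metachronous CRC, both < 70
    criterion5(pd),
    ## 6: proband CRC plus synchronous/metachronous Lynch tumor < 70
    any(diag_is_crc(pd)) &&
      any(is_lynch_associated(pd) &
            pd$chronology %in% c("synchronous", "metachronous") &
            age_lt(pd$age_at_diagnosis, 70)),
    ## 7: proband CRC at any age + first-degree relative with CRC or
    ##    Lynch tumor < 50
    any(diag_is_crc(pd)) &&
      any_relative(rel, degree = 1, function(d) {
        any((diag_is_crc(d) | is_lynch_associated(d)) &
              age_lt(d$age_at_diagnosis, 50))
      }),
    ## 8: proband CRC or Lynch tumor < 70 + >= 2 affected relatives
    ##    (effective counts, one lineage), all qualifying diagnoses < 70
    any((diag_is_crc(pd) | is_lynch_associated(pd)) &
          age_lt(pd$age_at_diagnosis, 70)) &&
      max_lineage_count(rel, age_limit = 70) >= 2L,
    ## 9: "person" proband + two first-degree relatives with CRC 50-70,
    ##    one lineage
    footnote_person(pd) &&
      max_lineage_relatives(rel, degree = 1, function(d) {
        any(diag_is_crc(d) & age_between(d$age_at_diagnosis, 50, 70))
      }) >= 2L,
    ## 10: "person" proband + first-degree relative CRC 50-70 and
    ##     second-degree relative CRC < 70, one lineage
    footnote_person(pd) && criterion10(rel),
    ## 11: proband CRC 50-70 + first-degree relative CRC 50-70
    any(diag_is_crc(pd) & age_between(pd$age_at_diagnosis, 50, 70)) &&
      any_relative(rel, degree = 1, function(d) {
        any(diag_is_crc(d) & age_between(d$age_at_diagnosis, 50, 70))
      }),
    ## 12: proband CRC 50-70 + second-degree relative CRC < 70
    any(diag_is_crc(pd) & age_between(pd$age_at_diagnosis, 50, 70)) &&
      any_relative(rel, degree = 2, function(d) {
        any(diag_is_crc(d) & age_lt(d$age_at_diagnosis, 70))
      }),
    ## 13: direct questionnaire answer
    isTRUE(h$proband$prior_testing_unclear)
  )
}

## "A person": healthy, or CRC/Lynch tumors all diagnosed over 70, or only
## other cancer types at any age. Equivalent form: every CRC or
## Lynch-associated diagnosis (if any) has a known age strictly over 70.
footnote_person <- function(pd) {
  qual <- diag_is_crc(pd) | is_lynch_associated(pd)
  !any(qual & !(!is.na(pd$age_at_diagnosis) & pd$age_at_diagnosis > 70))
}

any_relative <- function(rel, degree, pred) {
  if (nrow(rel) == 0L) return(FALSE)
  deg <- degree_of(rel$relation)
  any(vapply(which(deg == degree), function(i) pred(rel$diagnoses[[i]]),
             logical(1)))
}

## Largest per-lineage sum of capped qualifying-tumor counts over first- and
## second-degree relatives; "direct" relatives count toward both sides.
max_lineage_count <- function(rel, age_limit) {
  if (nrow(rel) == 0L) return(0L)
  ec <- vapply(seq_len(nrow(rel)), function(i) {
    effective_tumor_count(rel$diagnoses[[i]], age_limit = age_limit)
  }, integer(1))
  maternal <- sum(ec[rel$lineage %in% c("maternal", "direct")])
  paternal <- sum(ec[rel$lineage %in% c("paternal", "direct")])
  max(maternal, paternal)
}

## Largest per-lineage number of distinct relatives of the given degree
## satisfying pred (no double counting: these criteria count persons).
max_lineage_relatives <- function(rel, degree, pred) {
  if (nrow(rel) == 0L) return(0L)
  deg <- degree_of(rel$relation)
  hit <- vapply(seq_len(nrow(rel)), function(i) {
    deg[i] == degree && pred(rel$diagnoses[[i]])
  }, logical(1))
  maternal <- sum(hit & rel$lineage %in% c("maternal", "direct"))
  paternal <- sum(hit & rel$lineage %in% c("paternal", "direct"))
  max(maternal, paternal)
}

criterion5 <- function(pd) {
  crc70 <- diag_is_crc(pd) & age_lt(pd$age_at_diagnosis, 70)
  later <- crc70 & pd$chronology %in% c("synchronous", "metachronous")
  ## a second primary and another CRC, both under 70
  sum(crc70) >= 2L && any(later)
}

criterion10 <- function(rel) {
  if (nrow(rel) == 0L) return(FALSE)
  deg <- degree_of(rel$relation)
  fd <- vapply(seq_len(nrow(rel)), function(i) {
    d <- rel$diagnoses[[i]]
    deg[i] == 1L && any(diag_is_crc(d) & age_between(d$age_at_diagnosis, 50, 70))
  }, logical(1))
  sd <- vapply(seq_len(nrow(rel)), function(i) {
    d <- rel$diagnoses[[i]]
    deg[i] == 2L && any(diag_is_crc(d) & age_lt(d$age_at_diagnosis, 70))
  }, logical(1))
  for (side in c("maternal", "paternal")) {
    ok_fd <- fd & rel$lineage %in% c(side, "direct")
    ok_sd <- sd & rel$lineage == side
    if (any(ok_fd) && any(ok_sd)) return(TRUE)
  }
  FALSE
}
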