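#' Brute-force referee for the referral rule engine
#'
#' Recomputes the referral recommendation by a structurally independent
#' route, mirroring the manual verification loop used when the deployed
#' tool was checked questionnaire by questionnaire: every criterion is
#' tested by literal enumeration -- explicit loops over diagnoses, over
#' pairs and subsets of relatives (after expanding a relative with several
#' qualifying tumors into at most two countable units), and over the two
#' parental lineages -- with no shared rule logic with
#' [evaluate_history()] beyond the domain types themselves. Slow by
#' design; it exists so the fast engine can be checked against it on
#' hundreds of generated histories.
#'
#' @param h A valid [family_history()].
#' @return A `referral_result`, with the same contract as
#'   [evaluate_history()].
#' @export
oracle_evaluate <- function(h) {
  stop_if_invalid(h)
  matched <- integer(0)
  for (k in 1:13) {
    if (oracle_criterion(h, k)) matched <- c(matched, k)
  }
  ## independent recommendation derivation
  rec <- "no_referral"
  for (k in matched) if (k >= 1 && k <= 8) rec <- "refer_lynch"
  if (rec == "no_referral") {
    for (k in matched) if (k >= 9 && k <= 12) rec <- "refer_fcc"
  }
  if (rec == "no_referral" && length(matched) > 0 && all(matched == 13)) {
    rec <- "refer_other"
  }
  out <- structure(list(matched_criteria = sort(matched), recommendation = rec),
                   class = "referral_result")
  out
}

## ---- literal predicates (deliberately re-stated, not shared) ------------

o_is_crc <- function(site, kind) {
  site == "colorectum" && kind == "carcinoma"
}

o_is_lynch <- function(site, kind) {
  if (site == "sebaceous_gland") return(TRUE)  # carcinoma or adenoma
  if (kind != "carcinoma") return(FALSE)
  site %in% c("endometrium", "stomach", "small_intestine", "pancreas",
              "bile_ducts", "renal_pelvis", "ureter", "ovary", "brain")
}

o_degree <- function(relation) {
  switch(relation,
    parent = 1L, sibling = 1L, child = 1L,
    grandparent = 2L, aunt_uncle = 2L, half_sibling = 2L,
    niece_nephew = 2L, grandchild = 2L,
    stop("unknown relation: ", relation)
  )
}

o_age_known_lt <- function(age, x) !is.na(age) && age < x

o_age_in_50_70 <- function(age) !is.na(age) && age >= 50 && age <= 70

## lineage compatibility of a set: all maternal-or-direct, or all
## paternal-or-direct
o_lineages_compatible <- function(lineages) {
  all(lineages %in% c("maternal", "direct")) ||
    all(lineages %in% c("paternal", "direct"))
}

## "A person": literal three-branch disjunction
o_person <- function(pd) {
  n <- nrow(pd)
  if (n == 0L) return(TRUE)                     # healthy
  all_over_70 <- TRUE
  any_crc_or_lynch <- FALSE
  for (j in seq_len(n)) {
    if (o_is_crc(pd$site[j], pd$kind[j]) ||
        o_is_lynch(pd$site[j], pd$kind[j])) {
      any_crc_or_lynch <- TRUE
      a <- pd$age_at_diagnosis[j]
      if (is.na(a) || a <= 70) all_over_70 <- FALSE
    }
  }
  if (!any_crc_or_lynch) return(TRUE)           # only other cancer types
  all_over_70                                   # CRC/Lynch all > 70
}

## Expand relatives into countable units per the double-count rule: one
## unit per qualifying diagnosis under the limit, at most two per relative.
o_units <- function(rel, limit) {
  units <- list()
  for (i in seq_len(nrow(rel))) {
    d <- rel$diagnoses[[i]]
    n_qual <- 0L
    for (j in seq_len(nrow(d))) {
      ok <- (o_is_crc(d$site[j], d$kind[j]) ||
               o_is_lynch(d$site[j], d$kind[j])) &&
        o_age_known_lt(d$age_at_diagnosis[j], limit)
      if (ok) n_qual <- n_qual + 1L
    }
    if (n_qual > 2L) n_qual <- 2L
    if (n_qual > 0L) {
      for (u in seq_len(n_qual)) {
        units[[length(units) + 1L]] <- rel$lineage[i]
      }
    }
  }
  unlist(units) %||% character(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## does any subset of the given size have pairwise-compatible lineages?
o_has_compatible_subset <- function(lineages, size) {
  n <- length(lineages)
  if (n < size) return(FALSE)
  cmb <- combn(n, size)
  for (idx in seq_len(ncol(cmb))) {
    if (o_lineages_compatible(lineages[cmb[, idx]])) return(TRUE)
  }
  FALSE
}

oracle_criterion <- function(h, k) {
  pd <- h$proband$diagnoses
  rel <- h$relatives
  nrel <- nrow(rel)
  if (k == 1L) {
    for (j in seq_len(nrow(pd))) {
      if ((o_is_crc(pd$site[j], pd$kind[j]) ||
           (pd$site[j] == "endometrium" && pd$kind[j] == "carcinoma")) &&
          o_age_known_lt(pd$age_at_diagnosis[j], 50)) {
        return(TRUE)
      }
    }
    return(FALSE)
  }
  if (k == 2L) {
    for (i in seq_len(nrel)) {
      if (o_degree(rel$relation[i]) != 1L) next
      d <- rel$diagnoses[[i]]
      for (j in seq_len(nrow(d))) {
        if ((o_is_crc(d$site[j], d$kind[j]) ||
             (d$site[j] == "endometrium" && d$kind[j] == "carcinoma")) &&
            o_age_known_lt(d$age_at_diagnosis[j], 50)) {
          return(TRUE)
        }
      }
    }
    return(FALSE)
  }
  if (k == 3L) {
    for (i in seq_len(nrel)) if (rel$known_mmr_mutation[i]) return(TRUE)
    return(FALSE)
  }
  if (k == 4L) {
    if (!o_person(pd)) return(FALSE)
    return(o_has_compatible_subset(o_units(rel, 70), 3L))
  }
  if (k == 5L) {
    for (j1 in seq_len(nrow(pd))) {
      for (j2 in seq_len(nrow(pd))) {
        if (j1 == j2) next
        if (o_is_crc(pd$site[j1], pd$kind[j1]) &&
            o_age_known_lt(pd$age_at_diagnosis[j1], 70) &&
            o_is_crc(pd$site[j2], pd$kind[j2]) &&
            pd$chronology[j2] %in% c("synchronous", "metachronous") &&
            o_age_known_lt(pd$age_at_diagnosis[j2], 70)) {
          return(TRUE)
        }
      }
    }
    return(FALSE)
  }
  if (k == 6L) {
    has_crc <- FALSE
    for (j in seq_len(nrow(pd))) {
      if (o_is_crc(pd$site[j], pd$kind[j])) has_crc <- TRUE
    }
    if (!has_crc) return(FALSE)
    for (j in seq_len(nrow(pd))) {
      if (o_is_lynch(pd$site[j], pd$kind[j]) &&
          pd$chronology[j] %in% c("synchronous", "metachronous") &&
          o_age_known_lt(pd$age_at_diagnosis[j], 70)) {
        return(TRUE)
      }
    }
    return(FALSE)
  }
  if (k == 7L) {
    has_crc <- FALSE
    for (j in seq_len(nrow(pd))) {
      if (o_is_crc(pd$site[j], pd$kind[j])) has_crc <- TRUE   # any age
    }
    if (!has_crc) return(FALSE)
    for (i in seq_len(nrel)) {
      if (o_degree(rel$relation[i]) != 1L) next
      d <- rel$diagnoses[[i]]
      for (j in seq_len(nrow(d))) {
        if ((o_is_crc(d$site[j], d$kind[j]) ||
             o_is_lynch(d$site[j], d$kind[j])) &&
            o_age_known_lt(d$age_at_diagnosis[j], 50)) {
          return(TRUE)
        }
      }
    }
    return(FALSE)
  }
  if (k == 8L) {
    proband_ok <- FALSE
    for (j in seq_len(nrow(pd))) {
      if ((o_is_crc(pd$site[j], pd$kind[j]) ||
           o_is_lynch(pd$site[j], pd$kind[j])) &&
          o_age_known_lt(pd$age_at_diagnosis[j], 70)) {
        proband_ok <- TRUE
      }
    }
    if (!proband_ok) return(FALSE)
    return(o_has_compatible_subset(o_units(rel, 70), 2L))
  }
  if (k == 9L) {
    if (!o_person(pd)) return(FALSE)
    hits <- integer(0)
    for (i in seq_len(nrel)) {
      if (o_degree(rel$relation[i]) != 1L) next
      d <- rel$diagnoses[[i]]
      for (j in seq_len(nrow(d))) {
        if (o_is_crc(d$site[j], d$kind[j]) &&
            o_age_in_50_70(d$age_at_diagnosis[j])) {
          hits <- c(hits, i)
          break
        }
      }
    }
    if (length(hits) < 2L) return(FALSE)
    for (a in seq_along(hits)) {
      for (b in seq_along(hits)) {
        if (a >= b) next
        if (o_lineages_compatible(rel$lineage[c(hits[a], hits[b])])) {
          return(TRUE)
        }
      }
    }
    return(FALSE)
  }
  if (k == 10L) {
    if (!o_person(pd)) return(FALSE)
    for (i1 in seq_len(nrel)) {
      if (o_degree(rel$relation[i1]) != 1L) next
      d1 <- rel$diagnoses[[i1]]
      ok1 <- FALSE
      for (j in seq_len(nrow(d1))) {
        if (o_is_crc(d1$site[j], d1$kind[j]) &&
            o_age_in_50_70(d1$age_at_diagnosis[j])) {
          ok1 <- TRUE
        }
      }
      if (!ok1) next
      for (i2 in seq_len(nrel)) {
        if (o_degree(rel$relation[i2]) != 2L) next
        d2 <- rel$diagnoses[[i2]]
        for (j in seq_len(nrow(d2))) {
          if (o_is_crc(d2$site[j], d2$kind[j]) &&
              o_age_known_lt(d2$age_at_diagnosis[j], 70) &&
              o_lineages_compatible(rel$lineage[c(i1, i2)])) {
            return(TRUE)
          }
        }
      }
    }
    return(FALSE)
  }
  if (k == 11L) {
    proband_ok <- FALSE
    for (j in seq_len(nrow(pd))) {
      if (o_is_crc(pd$site[j], pd$kind[j]) &&
          o_age_in_50_70(pd$age_at_diagnosis[j])) {
        proband_ok <- TRUE
      }
    }
    if (!proband_ok) return(FALSE)
    for (i in seq_len(nrel)) {
      if (o_degree(rel$relation[i]) != 1L) next
      d <- rel$diagnoses[[i]]
      for (j in seq_len(nrow(d))) {
        if (o_is_crc(d$site[j], d$kind[j]) &&
            o_age_in_50_70(d$age_at_diagnosis[j])) {
          return(TRUE)
        }
      }
    }
    return(FALSE)
  }
  if (k == 12L) {
    proband_ok <- FALSE
    for (j in seq_len(nrow(pd))) {
      if (o_is_crc(pd$site[j], pd$kind[j]) &&
          o_age_in_50_70(pd$age_at_diagnosis[j])) {
        proband_ok <- TRUE
      }
    }
    if (!proband_ok) return(FALSE)
    for (i in seq_len(nrel)) {
      if (o_degree(rel$relation[i]) != 2L) next
      d <- rel$diagnoses[[i]]
      for (j in seq_len(nrow(d))) {
        if (o_is_crc(d$site[j], d$kind[j]) &&
            o_age_known_lt(d$age_at_diagnosis[j], 70)) {
          return(TRUE)
        }
      }
    }
    return(FALSE)
  }
  if (k == 13L) {
    return(isTRUE(h$proband$prior_testing_unclear))
  }
  stop("criterion out of range: ", k)
}
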