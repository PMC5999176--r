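#' Serialize a family history to canonical JSON
#'
#' The on-disk form is a versioned UTF-8 JSON document whose fields map
#' one-to-one to the questionnaire's data content (`schema_version`,
#' `proband` with demographics and diagnoses, `relatives` array). Output
#' is canonical -- fixed field order, explicit empty arrays, `null` for
#' unknown ages -- so two equal histories serialize to identical bytes.
#'
#' @param h A valid [family_history()].
#' @param path File path to write, or `NULL` to return the JSON string.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @seealso [read_history()]
#' @export
write_history <- function(h, path = NULL) {
  stop_if_invalid(h)
  p <- h$proband
  doc <- list(
    schema_version = "1.0",
    proband = list(
      age = p$age,
      sex = p$sex,
      prior_testing_unclear = p$prior_testing_unclear,
      nationality = p$nationality,
      educational_level = p$educational_level,
      native_language = p$native_language,
      diagnoses = diagnoses_to_list(p$diagnoses)
    ),
    relatives = lapply(seq_len(nrow(h$relatives)), function(i) {
      r <- h$relatives[i, ]
      list(
        relation = r$relation,
        lineage = r$lineage,
        known_mmr_mutation = r$known_mmr_mutation,
        diagnoses = diagnoses_to_list(r$diagnoses[[1L]])
      )
    })
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", na = "null",
                           pretty = TRUE, digits = NA)
  if (is.null(path)) {
    return(as.character(json))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as.character(json), con, useBytes = TRUE)
  invisible(path)
}

diagnoses_to_list <- function(d) {
  lapply(seq_len(nrow(d)), function(j) {
    list(
      site = d$site[j],
      kind = d$kind[j],
      age_at_diagnosis = if (is.na(d$age_at_diagnosis[j])) NULL
                         else d$age_at_diagnosis[j],
      chronology = d$chronology[j]
    )
  })
}

#' Read a family history from JSON
#'
#' Parses a document written by [write_history()] (or hand-written to the
#' same schema), rebuilds it through the domain constructors, and
#' validates it. Schema violations raise an error listing the offending
#' field paths.
#'
#' @param source A file path, or a literal JSON string.
#' @return A valid [family_history()].
#' @export
read_history <- function(source) {
  txt <- if (length(source) == 1L && !grepl("[{]", source)) {
    if (!file.exists(source)) {
      abort(paste0("File not found: ", source))
    }
    paste(readLines(source, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  } else {
    paste(source, collapse = "\n")
  }
  doc <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) abort(paste0("Malformed JSON: ", conditionMessage(e)))
  )
  if (is.null(doc$proband)) abort("Schema violation at proband: missing")
  pr <- doc$proband
  p <- proband(
    age = pr$age %||% NA_real_,
    sex = pr$sex %||% "other",
    diagnoses = diagnoses_from_list(pr$diagnoses, "proband.diagnoses"),
    prior_testing_unclear = isTRUE(pr$prior_testing_unclear),
    nationality = pr$nationality %||% NA_character_,
    educational_level = pr$educational_level %||% NA_character_,
    native_language = pr$native_language %||% NA_character_
  )
  rels <- lapply(seq_along(doc$relatives), function(i) {
    r <- doc$relatives[[i]]
    if (is.null(r$relation) || !r$relation %in% fh_relations) {
      abort(sprintf("Schema violation at relatives[%d].relation: unknown code '%s'",
                    i, r$relation %||% "<missing>"))
    }
    relative(
      relation = r$relation,
      lineage = r$lineage,
      diagnoses = diagnoses_from_list(r$diagnoses,
                                      sprintf("relatives[%d].diagnoses", i)),
      known_mmr_mutation = isTRUE(r$known_mmr_mutation)
    )
  })
  h <- family_history(p, dplyr::bind_rows(rels))
  iss <- validate_history(h)
  err <- iss[iss$severity == "error", , drop = FALSE]
  if (nrow(err) > 0L) {
    abort(paste0("Schema violation:\n",
                 paste0("  - ", err$field, ": ", err$message, collapse = "\n")))
  }
  h
}

diagnoses_from_list <- function(lst, path) {
  if (is.null(lst) || length(lst) == 0L) {
    return(tumor_diagnosis(character(), character(), numeric(), character()))
  }
  dplyr::bind_rows(lapply(seq_along(lst), function(j) {
    d <- lst[[j]]
    if (is.null(d$site)) {
      abort(sprintf("Schema violation at %s[%d].site: missing", path, j))
    }
    tumor_diagnosis(
      site = d$site,
      kind = d$kind %||% "carcinoma",
      age_at_diagnosis = d$age_at_diagnosis %||% NA_real_,
      chronology = d$chronology %||% "first"
    )
  }))
}

#' Write a cohort roster to CSV
#'
#' One row per patient: identifier, stepped-wedge placement (hospital,
#' period, strategy), tool-flow booleans, non-participation reason codes
#' (semicolon-joined), and the family history inlined as a compact JSON
#' string in `history_json` (empty when no questionnaire was completed).
#' RFC 4180 quoting throughout.
#'
#' @param records A tibble of cohort records, e.g. from
#'   [generate_trial_cohort()]; a `history` list-column of
#'   [family_history()] objects is serialized inline.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  records <- validate_cohort(records)
  out <- records
  if ("history" %in% names(out)) {
    out$history_json <- vapply(out$history, function(h) {
      if (is.null(h)) "" else gsub("\\s+", " ", write_history(h))
    }, character(1))
    out$history <- NULL
  } else if (!"history_json" %in% names(out)) {
    out$history_json <- ""
  }
  if (is.list(out[["non_participation_reasons"]])) {
    out$non_participation_reasons <- vapply(
      out$non_participation_reasons,
      function(x) paste(x, collapse = ";"), character(1)
    )
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a cohort roster from CSV
#'
#' @param path CSV path written by [write_cohort()].
#' @return A tibble with one row per patient and a `history` list-column
#'   (`NULL` where no questionnaire was completed).
#' @export
read_cohort <- function(path) {
  records <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("history_json" %in% names(records)) {
    records$history <- lapply(records$history_json, function(s) {
      if (is.na(s) || !nzchar(s)) NULL else read_history(s)
    })
    records$history_json <- NULL
  }
  if ("non_participation_reasons" %in% names(records)) {
    records$non_participation_reasons <- lapply(
      records$non_participation_reasons,
      function(s) {
        if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ";")[[1L]]
      }
    )
  }
  validate_cohort(records)
}

validate_cohort <- function(records) {
  records <- tibble::as_tibble(records)
  if (!"patient_id" %in% names(records)) {
    abort("Cohort roster needs a patient_id column.")
  }
  if (nrow(records) == 0L) {
    return(records)
  }
  dup <- records$patient_id[duplicated(records$patient_id)]
  if (length(dup) > 0L) {
    abort(paste0("Duplicate patient_id: ", paste(unique(dup), collapse = ", ")))
  }
  if (all(c("offered_tool", "used_tool") %in% names(records))) {
    bad <- records$used_tool & !records$offered_tool
    if (any(bad, na.rm = TRUE)) {
      abort(paste0("used_tool without offered_tool for patient_id: ",
                   paste(records$patient_id[which(bad)], collapse = ", ")))
    }
  }
  if (all(c("used_tool", "history") %in% names(records))) {
    has_hist <- !vapply(records$history, is.null, logical(1))
    bad <- xor(records$used_tool, has_hist)
    if (any(bad, na.rm = TRUE)) {
      abort(paste0(
        "used_tool must match the presence of a history; offending patient_id: ",
        paste(records$patient_id[which(bad)], collapse = ", ")
      ))
    }
  }
  records
}
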