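# Shorthand builders for family histories used across the suite.

crc <- function(age, chronology = "first") {
  tumor_diagnosis("colorectum", age_at_diagnosis = age, chronology = chronology)
}

endo <- function(age) {
  tumor_diagnosis("endometrium", age_at_diagnosis = age)
}

hist_of <- function(proband_age = 60, proband_diagnoses = NULL, ...,
                    prior_testing_unclear = FALSE) {
  rels <- list(...)
  family_history(
    proband(proband_age, "female", proband_diagnoses,
            prior_testing_unclear = prior_testing_unclear),
    if (length(rels) > 0) dplyr::bind_rows(rels) else NULL
  )
}

# proband with a single CRC at the given age
crc_proband_hist <- function(age, ...) {
  hist_of(proband_age = max(age, 30), proband_diagnoses = crc(age), ...)
}

matched <- function(h) evaluate_history(h)$matched_criteria
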