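#' Parameters for the synthetic family-history generator
#'
#' Describes the population the generator emulates: a colorectal-cancer
#' outpatient cohort completing the family-history questionnaire. Family
#' size is Poisson per kinship degree; each relative independently carries
#' a lifetime colorectal-cancer and Lynch-tumor risk; ages at diagnosis
#' are truncated-normal. Defaults are calibrated so that roughly 27% of
#' generated completers meet at least one referral criterion, the
#' indication rate observed when the deployed tool was evaluated; they are
#' a calibration choice, not an estimate of any real pedigree
#' distribution.
#'
#' @param n_first_degree_mean,n_second_degree_mean Poisson means for the
#'   number of first- and second-degree relatives.
#' @param p_relative_crc Per-relative lifetime probability of colorectal
#'   carcinoma.
#' @param p_relative_lynch Per-relative lifetime probability of an
#'   extracolonic Lynch-associated tumor.
#' @param p_second_tumor Probability that an affected relative carries one
#'   additional qualifying tumor.
#' @param relative_age_mean,relative_age_sd,relative_age_bounds Truncated
#'   normal age-at-diagnosis distribution for relatives (years).
#' @param p_proband_crc Probability the proband has colorectal carcinoma
#'   (the cohort is recruited at CRC outpatient clinics, so this is high).
#' @param proband_age_mean,proband_age_sd,proband_age_bounds Truncated
#'   normal distribution of the proband's current age; the proband's CRC,
#'   when present, is diagnosed at the current age.
#' @param p_proband_second_crc Probability of a synchronous or
#'   metachronous second colorectal carcinoma in an affected proband.
#' @param p_relative_mmr Per-relative probability of a known mismatch
#'   repair mutation.
#' @param p_prior_testing_unclear Probability the proband answers that
#'   prior genetic testing is unclear.
#' @return A list of class `history_gen_params`.
#' @export
history_gen_params <- function(n_first_degree_mean = 4,
                               n_second_degree_mean = 5,
                               p_relative_crc = 0.058,
                               p_relative_lynch = 0.025,
                               p_second_tumor = 0.12,
                               relative_age_mean = 64,
                               relative_age_sd = 12,
                               relative_age_bounds = c(20, 95),
                               p_proband_crc = 0.97,
                               proband_age_mean = 67,
                               proband_age_sd = 9.9,
                               proband_age_bounds = c(26, 95),
                               p_proband_second_crc = 0.027,
                               p_relative_mmr = 0.001,
                               p_prior_testing_unclear = 0.004) {
  p <- list(
    n_first_degree_mean = n_first_degree_mean,
    n_second_degree_mean = n_second_degree_mean,
    p_relative_crc = p_relative_crc,
    p_relative_lynch = p_relative_lynch,
    p_second_tumor = p_second_tumor,
    relative_age_mean = relative_age_mean,
    relative_age_sd = relative_age_sd,
    relative_age_bounds = relative_age_bounds,
    p_proband_crc = p_proband_crc,
    proband_age_mean = proband_age_mean,
    proband_age_sd = proband_age_sd,
    proband_age_bounds = proband_age_bounds,
    p_proband_second_crc = p_proband_second_crc,
    p_relative_mmr = p_relative_mmr,
    p_prior_testing_unclear = p_prior_testing_unclear
  )
  probs <- c(p$p_relative_crc, p$p_relative_lynch, p$p_second_tumor,
             p$p_proband_crc, p$p_proband_second_crc, p$p_relative_mmr,
             p$p_prior_testing_unclear)
  if (any(probs < 0 | probs > 1)) {
    abort("All probabilities must lie in [0, 1].")
  }
  if (p$n_first_degree_mean < 0 || p$n_second_degree_mean < 0) {
    abort("Family-size means must be non-negative.")
  }
  for (b in list(p$relative_age_bounds, p$proband_age_bounds)) {
    if (length(b) != 2L || b[1] >= b[2] || b[1] < 0 || b[2] > 120) {
      abort("Age bounds must be an increasing pair within [0, 120].")
    }
  }
  structure(p, class = "history_gen_params")
}

## integer truncated-normal draw (rejection sampling)
rtruncnorm_int <- function(n, mean, sd, bounds) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    x <- round(rnorm(length(need), mean, sd))
    ok <- x >= bounds[1] & x <= bounds[2]
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

## extracolonic Lynch-associated site frequencies (endometrium dominant,
## as in Lynch tumor spectra); sebaceous adenomas enter via the kind draw
lynch_site_weights <- c(
  endometrium = 0.40, stomach = 0.12, small_intestine = 0.06,
  pancreas = 0.08, bile_ducts = 0.04, renal_pelvis = 0.05, ureter = 0.04,
  ovary = 0.12, brain = 0.05, sebaceous_gland = 0.04
)

draw_lynch_diagnosis <- function(p) {
  site <- sample(names(lynch_site_weights), 1L, prob = lynch_site_weights)
  kind <- if (site == "sebaceous_gland" && runif(1) < 0.5) "adenoma" else "carcinoma"
  tumor_diagnosis(site, kind,
                  rtruncnorm_int(1, p$relative_age_mean, p$relative_age_sd,
                                 p$relative_age_bounds))
}

#' Generate one synthetic family history
#'
#' Draws a proband and relatives per [history_gen_params()]. All output
#' passes [validate_history()] with no errors; with a fixed RNG state the
#' output is reproducible.
#'
#' @param params A [history_gen_params()] object.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (so callers can `set.seed()` once for a whole batch).
#' @return A [family_history()].
#' @export
generate_history <- function(params = history_gen_params(), seed = NULL) {
  if (!inherits(params, "history_gen_params")) {
    abort("`params` must be built with history_gen_params().")
  }
  if (!is.null(seed)) set.seed(seed)
  p <- params
  age <- rtruncnorm_int(1, p$proband_age_mean, p$proband_age_sd,
                        p$proband_age_bounds)
  pd <- tumor_diagnosis(character(), character(), numeric(), character())
  if (runif(1) < p$p_proband_crc) {
    pd <- tumor_diagnosis("colorectum", age_at_diagnosis = age)
    if (runif(1) < p$p_proband_second_crc) {
      pd <- dplyr::bind_rows(
        pd,
        tumor_diagnosis("colorectum", age_at_diagnosis = age,
                        chronology = "synchronous")
      )
    }
  }
  pr <- proband(
    age = age,
    sex = sample(c("male", "female"), 1L, prob = c(0.55, 0.45)),
    diagnoses = pd,
    prior_testing_unclear = runif(1) < p$p_prior_testing_unclear,
    nationality = "NL",
    educational_level = sample(fh_education_levels, 1L),
    native_language = "nl"
  )
  n1 <- rpois(1, p$n_first_degree_mean)
  n2 <- rpois(1, p$n_second_degree_mean)
  rel_rows <- list()
  add_rel <- function(relation, lineage) {
    d <- tumor_diagnosis(character(), character(), numeric(), character())
    if (runif(1) < p$p_relative_crc) {
      d <- dplyr::bind_rows(
        d,
        tumor_diagnosis("colorectum",
                        age_at_diagnosis = rtruncnorm_int(
                          1, p$relative_age_mean, p$relative_age_sd,
                          p$relative_age_bounds))
      )
    }
    if (runif(1) < p$p_relative_lynch) {
      d <- dplyr::bind_rows(d, draw_lynch_diagnosis(p))
    }
    if (nrow(d) > 0L && runif(1) < p$p_second_tumor) {
      extra <- if (runif(1) < 0.5) {
        tumor_diagnosis("colorectum",
                        age_at_diagnosis = rtruncnorm_int(
                          1, p$relative_age_mean, p$relative_age_sd,
                          p$relative_age_bounds),
                        chronology = "metachronous")
      } else {
        draw_lynch_diagnosis(p)
      }
      d <- dplyr::bind_rows(d, extra)
    }
    rel_rows[[length(rel_rows) + 1L]] <<- relative(
      relation, lineage,
      diagnoses = if (nrow(d) > 0L) d else NULL,
      known_mmr_mutation = runif(1) < p$p_relative_mmr
    )
  }
  for (i in seq_len(n1)) {
    relation <- sample(fh_relations_degree1, 1L, prob = c(0.35, 0.35, 0.30))
    lineage <- if (relation == "parent") {
      sample(c("maternal", "paternal"), 1L)
    } else {
      "direct"
    }
    add_rel(relation, lineage)
  }
  for (i in seq_len(n2)) {
    add_rel(sample(fh_relations_degree2, 1L),
            sample(c("maternal", "paternal"), 1L))
  }
  family_history(pr, dplyr::bind_rows(rel_rows))
}

#' Generate a batch of synthetic family histories
#'
#' @param n Number of histories.
#' @param params A [history_gen_params()].
#' @param seed Optional integer seed for the whole batch.
#' @return A list of [family_history()] objects.
#' @export
generate_histories <- function(n, params = history_gen_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) generate_history(params))
}

#' Flow and outcome parameters for trial simulation
#'
#' Two groups of parameters. The process-flow probabilities describe how
#' patients move through the intervention strategy (offered the tool, used
#' it, referral indicated, counseled); defaults are the rates observed in
#' the reference evaluation (tool offered to 58% of eligible patients,
#' used by 81% of those, 27% of completers with a referral indication, 59%
#' of indicated vs 4.8% of non-indicated completers counseled). The
#' outcome model generates the binary primary outcome (a screening or
#' surveillance recommendation provided by genetic counseling) from a
#' logistic model with a hospital-level random intercept: the intercept
#' variance is chosen so the latent-scale intracluster correlation equals
#' `icc`, i.e. `sigma^2 = icc * (pi^2/3) / (1 - icc)`.
#'
#' @param p_offered Probability an eligible intervention-strategy patient
#'   is offered the tool.
#' @param p_used_given_offered Probability an offered patient uses it.
#' @param p_indicated Probability a completer has a referral indication
#'   (used when histories are not generated; with
#'   `with_histories = TRUE` the indication comes from
#'   [evaluate_history()] instead).
#' @param p_counseled_given_indicated,p_counseled_given_not_indicated
#'   Counseling probabilities for completers by indication status.
#' @param p_counseled_no_tool Counseling probability for
#'   intervention-strategy patients who never completed the tool.
#' @param p_counseled_control Counseling probability under the control
#'   strategy.
#' @param p_outcome_control Control-strategy probability of the primary
#'   outcome.
#' @param or_intervention True conditional odds ratio of the intervention
#'   on the primary outcome.
#' @param icc Latent-scale intracluster correlation of the outcome.
#' @param period_effects Numeric vector of log-odds period effects
#'   (recycled over periods), default none.
#' @param p_non_crc Probability the presumed CRC lesion turns out
#'   non-malignant (used by the sensitivity analysis).
#' @return A list of class `flow_params`.
#' @export
flow_params <- function(p_offered = 0.58,
                        p_used_given_offered = 0.81,
                        p_indicated = 0.27,
                        p_counseled_given_indicated = 0.59,
                        p_counseled_given_not_indicated = 0.048,
                        p_counseled_no_tool = 0.085,
                        p_counseled_control = 0.14,
                        p_outcome_control = 0.12,
                        or_intervention = 0.76,
                        icc = 0.10,
                        period_effects = 0,
                        p_non_crc = 20 / 781) {
  f <- list(
    p_offered = p_offered,
    p_used_given_offered = p_used_given_offered,
    p_indicated = p_indicated,
    p_counseled_given_indicated = p_counseled_given_indicated,
    p_counseled_given_not_indicated = p_counseled_given_not_indicated,
    p_counseled_no_tool = p_counseled_no_tool,
    p_counseled_control = p_counseled_control,
    p_outcome_control = p_outcome_control,
    or_intervention = or_intervention,
    icc = icc,
    period_effects = period_effects,
    p_non_crc = p_non_crc
  )
  probs <- unlist(f[c("p_offered", "p_used_given_offered", "p_indicated",
                      "p_counseled_given_indicated",
                      "p_counseled_given_not_indicated",
                      "p_counseled_no_tool", "p_counseled_control",
                      "p_outcome_control", "p_non_crc")])
  if (any(probs < 0 | probs > 1)) abort("All probabilities must lie in [0, 1].")
  if (f$icc < 0 || f$icc >= 1) abort("`icc` must lie in [0, 1).")
  if (f$or_intervention <= 0) abort("`or_intervention` must be positive.")
  structure(f, class = "flow_params")
}

#' Simulate a full stepped-wedge trial dataset
#'
#' Builds the switching schedule from `design`, enrolls
#' `n_per_cluster_period` fresh patients in every hospital-period cell
#' (cross-sectional sampling), assigns each the cell's strategy, draws the
#' tool-flow booleans per [flow_params()], and draws the binary primary
#' outcome from the logistic outcome model with a hospital random
#' intercept scaled to the requested intracluster correlation.
#'
#' @param design A [trial_design()].
#' @param flow A [flow_params()].
#' @param gen_params A [history_gen_params()], used when
#'   `with_histories = TRUE`.
#' @param n_per_cluster_period Patients enrolled per hospital per period:
#'   a scalar, or a `n_clusters x n_periods` matrix.
#' @param with_histories When `TRUE`, tool completers get a generated
#'   family history and their referral indication comes from
#'   [evaluate_history()]; when `FALSE` (default, much faster) the
#'   indication is drawn as Bernoulli(`p_indicated`).
#' @param seed Optional integer seed.
#' @return A tibble with one row per patient: `patient_id`,
#'   `hospital_id`, `period_index`, `strategy`, `offered_tool`,
#'   `used_tool`, `referral_indicated`, `counseled`, `pathology`,
#'   `outcome`, and (when requested) a `history` list-column.
#' @examples
#' d <- trial_design()
#' cohort <- generate_trial_cohort(d, flow_params(), n_per_cluster_period = 10,
#'                                 seed = 1)
#' dplyr::count(cohort, strategy, outcome)
#' @export
generate_trial_cohort <- function(design, flow = flow_params(),
                                  gen_params = history_gen_params(),
                                  n_per_cluster_period = 26,
                                  with_histories = FALSE, seed = NULL) {
  if (!inherits(design, "trial_design")) {
    abort("`design` must be built with trial_design().")
  }
  if (!inherits(flow, "flow_params")) {
    abort("`flow` must be built with flow_params().")
  }
  if (!is.null(seed)) set.seed(seed)
  sched <- build_schedule(design)
  n_periods <- max(sched$period)
  k <- design$n_clusters
  nmat <- n_per_cluster_period
  if (is.matrix(nmat)) {
    if (!all(dim(nmat) == c(k, n_periods))) {
      abort(sprintf("n_per_cluster_period matrix must be %d x %d.", k, n_periods))
    }
  } else {
    nmat <- matrix(n_per_cluster_period, k, n_periods)
  }
  sigma_u <- sqrt(flow$icc * (pi^2 / 3) / (1 - flow$icc))
  u <- rnorm(k, 0, sigma_u)
  per_eff <- rep_len(flow$period_effects, n_periods)
  rows <- sched
  rows$n <- nmat[cbind(rows$hospital, rows$period)]
  rows <- tidyr::uncount(rows, .data$n)
  n_tot <- nrow(rows)
  rows$patient_id <- sprintf("P%05d", seq_len(n_tot))
  treat <- as.integer(rows$strategy == "intervention")
  eta <- qlogis(flow$p_outcome_control) + log(flow$or_intervention) * treat +
    per_eff[rows$period] + u[rows$hospital]
  outcome <- rbinom(n_tot, 1L, plogis(eta))
  offered <- treat == 1L & runif(n_tot) < flow$p_offered
  used <- offered & runif(n_tot) < flow$p_used_given_offered
  histories <- vector("list", n_tot)
  if (with_histories) {
    indicated <- rep(NA, n_tot)
    for (i in which(used)) {
      histories[[i]] <- generate_history(gen_params)
      indicated[i] <- evaluate_history(histories[[i]])$recommendation != "no_referral"
    }
  } else {
    indicated <- ifelse(used, runif(n_tot) < flow$p_indicated, NA)
  }
  p_couns <- ifelse(
    treat == 0L, flow$p_counseled_control,
    ifelse(!used, flow$p_counseled_no_tool,
           ifelse(indicated, flow$p_counseled_given_indicated,
                  flow$p_counseled_given_not_indicated))
  )
  counseled <- runif(n_tot) < p_couns
  pathology <- ifelse(runif(n_tot) < flow$p_non_crc, "non_crc", "crc")
  out <- tibble::tibble(
    patient_id = rows$patient_id,
    hospital_id = rows$hospital,
    period_index = rows$period,
    strategy = rows$strategy,
    offered_tool = offered,
    used_tool = used,
    referral_indicated = indicated,
    counseled = counseled,
    pathology = pathology,
    outcome = outcome
  )
  if (with_histories) out$history <- histories
  out
}
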