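#' Published counts from the reference stepped-wedge evaluation
#'
#' The multicenter evaluation of the family-history tool (five Dutch
#' hospitals, 781 CRC patients: 292 under the control strategy, 489 under
#' the intervention) reported its group comparisons as counts. This
#' function returns those printed counts as analysis-ready tables so the
#' test statistics can be recomputed from scratch: 2x2 matrices have
#' control and intervention rows and yes/no columns; wider tables keep
#' the printed category order.
#'
#' @return A named list:
#' \describe{
#'   \item{arm_sizes}{Named vector, patients per strategy (292 / 489).}
#'   \item{sex_male}{2x2: male vs not, by strategy (171/292 vs 265/489).}
#'   \item{pathology}{2x3: CRC / no CRC / no pathology, by strategy.}
#'   \item{crc_pattern}{2x4: first / synchronous / recurrence /
#'     metachronous, by strategy.}
#'   \item{counselor_consulted}{2x2: genetic counselor consulted
#'     (41/292 vs 67/489).}
#'   \item{diagnosis_after_testing}{2x2: diagnosis after genetic testing,
#'     identical to the colonoscopy-recommendation outcome counts
#'     (35/292 vs 46/489).}
#'   \item{age_summary}{Tibble of the printed age means and SDs.}
#'   \item{flow}{Tibble of the intervention-strategy tool flow: eligible
#'     489, offered 285, used 231, referral indicated 63, counseled among
#'     indicated 37, counseled among 168 non-indicated completers 8.}
#' }
#' @examples
#' chi_square_2x2(trial_report_tables()$diagnosis_after_testing)
#' @export
trial_report_tables <- function() {
  m2 <- function(a, b, c, d, cols) {
    matrix(c(a, b, c, d), nrow = 2, byrow = TRUE,
           dimnames = list(c("control", "intervention"), cols))
  }
  list(
    arm_sizes = c(control = 292, intervention = 489),
    sex_male = m2(171, 292 - 171, 265, 489 - 265, c("male", "not_male")),
    pathology = matrix(
      c(284, 6, 2,
        473, 14, 2),
      nrow = 2, byrow = TRUE,
      dimnames = list(c("control", "intervention"),
                      c("crc", "no_crc", "no_pathology"))
    ),
    crc_pattern = matrix(
      c(268, 5, 7, 6,
        450, 16, 7, 2),
      nrow = 2, byrow = TRUE,
      dimnames = list(c("control", "intervention"),
                      c("first", "synchronous", "recurrence", "metachronous"))
    ),
    counselor_consulted = m2(41, 292 - 41, 67, 489 - 67, c("yes", "no")),
    diagnosis_after_testing = m2(35, 292 - 35, 46, 489 - 46, c("yes", "no")),
    age_summary = tibble::tibble(
      strategy = c("control", "intervention"),
      mean_age = c(67, 67),
      sd_age = c(9.9, 9.9),
      n = c(292, 489)
    ),
    flow = tibble::tibble(
      stage = c("eligible", "offered_tool", "used_tool",
                "referral_indicated", "counseled_indicated",
                "counseled_not_indicated"),
      count = c(489, 285, 231, 63, 37, 8),
      denominator = c(NA, 489, 285, 231, 63, 168)
    )
  )
}
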