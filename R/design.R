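#' Describe a stepped-wedge trial design
#'
#' A cross-over design in which every cluster (hospital) starts on the
#' control strategy and switches to the intervention exactly once, in a
#' predetermined order, never reverting. With `n_clusters` hospitals
#' switching one per step there are `n_clusters + 1` evaluation periods:
#' in the first all hospitals are on control, in the last all are on the
#' intervention. Each hospital's switch is preceded by a training week
#' that is excluded from evaluation.
#'
#' @param n_clusters Number of hospitals (default 5).
#' @param step_length_weeks Length of one step in weeks (default 9).
#' @param training_weeks_excluded Training weeks at each switch, excluded
#'   from evaluation (default 1).
#' @param switch_order Permutation of `1:n_clusters` giving the switching
#'   order (first element switches first).
#' @param icc Assumed intracluster correlation of the binary outcome.
#' @param design_effect Design-effect multiplier applied to the parallel
#'   sample size (stated planning input).
#' @return A list of class `trial_design`.
#' @export
trial_design <- function(n_clusters = 5, step_length_weeks = 9,
                         training_weeks_excluded = 1,
                         switch_order = seq_len(n_clusters),
                         icc = 0.10, design_effect = 0.45) {
  if (n_clusters < 2) abort("`n_clusters` must be at least 2.")
  if (!setequal(switch_order, seq_len(n_clusters)) ||
      length(switch_order) != n_clusters) {
    abort("`switch_order` must be a permutation of 1:n_clusters.")
  }
  if (icc < 0 || icc >= 1) abort("`icc` must lie in [0, 1).")
  structure(
    list(
      n_clusters = as.integer(n_clusters),
      step_length_weeks = as.integer(step_length_weeks),
      training_weeks_excluded = as.integer(training_weeks_excluded),
      switch_order = as.integer(switch_order),
      n_periods = as.integer(n_clusters) + 1L,
      icc = icc,
      design_effect = design_effect
    ),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat("<trial_design>\n")
  cat(sprintf("  %d clusters, %d periods of %d weeks (+%d training week(s) at each switch)\n",
              x$n_clusters, x$n_periods, x$step_length_weeks,
              x$training_weeks_excluded))
  cat(sprintf("  switch order: %s; ICC %.2f; design effect %.2f\n",
              paste(x$switch_order, collapse = ", "), x$icc, x$design_effect))
  invisible(x)
}

#' Build the per-cluster switching schedule
#'
#' @param design A [trial_design()].
#' @return A tibble of class `fh_schedule` with one row per
#'   hospital-period: `hospital`, `period`, `strategy` (`"control"` /
#'   `"intervention"`), `switch_period` (the period in which that hospital
#'   switches, with its leading training week excluded from evaluation).
#'   For every hospital the strategy is monotone: control strictly before
#'   its switch period, intervention from it on; the final period has all
#'   hospitals on the intervention.
#' @examples
#' build_schedule(trial_design())
#' @export
build_schedule <- function(design) {
  if (!inherits(design, "trial_design")) {
    abort("`design` must be built with trial_design().")
  }
  k <- design$n_clusters
  switch_period <- integer(k)
  switch_period[design$switch_order] <- seq_len(k) + 1L
  out <- tidyr::expand_grid(hospital = seq_len(k),
                            period = seq_len(design$n_periods))
  out$switch_period <- switch_period[out$hospital]
  out$strategy <- ifelse(out$period >= out$switch_period,
                         "intervention", "control")
  class(out) <- c("fh_schedule", class(out))
  out
}

#' Two-proportion sample size (normal approximation)
#'
#' Smallest per-arm size for which the two-sided two-sample test of
#' proportions attains the requested power, using the standard normal
#' approximation with pooled variance under the null and unpooled variance
#' under the alternative:
#' \deqn{n = \frac{\left(z_{1-\alpha/2}\sqrt{2\bar p \bar q} +
#'   z_{power}\sqrt{p_1 q_1 + p_2 q_2}\right)^2}{(p_1-p_2)^2}}
#' rounded up. With the planning inputs of a 4% control referral rate, a
#' 15% anticipated intervention rate, two-sided alpha 0.05 and 80% power,
#' this gives 111 patients per strategy.
#'
#' @param p1,p2 Outcome proportions under control and intervention.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return Integer sample size per arm.
#' @examples
#' two_proportion_sample_size(0.04, 0.15)
#' @export
two_proportion_sample_size <- function(p1, p2, alpha = 0.05, power = 0.80) {
  if (any(c(p1, p2) <= 0) || any(c(p1, p2) >= 1)) {
    abort("`p1` and `p2` must lie strictly in (0, 1).")
  }
  if (p1 == p2) abort("`p1` and `p2` must differ.")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    abort("`alpha` and `power` must lie strictly in (0, 1).")
  }
  pbar <- (p1 + p2) / 2
  za <- qnorm(1 - alpha / 2)
  zb <- qnorm(power)
  n <- (za * sqrt(2 * pbar * (1 - pbar)) +
          zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / (p1 - p2)^2
  as.integer(ceiling(n))
}

#' Power of the two-proportion z-test at a given per-arm size
#'
#' Companion to [two_proportion_sample_size()]: the normal-approximation
#' power of the pooled two-sided test at per-arm size `n`.
#'
#' @param n Per-arm sample size.
#' @param p1,p2 Outcome proportions.
#' @param alpha Two-sided significance level.
#' @return Approximate power in (0, 1).
#' @export
two_proportion_power <- function(n, p1, p2, alpha = 0.05) {
  pbar <- (p1 + p2) / 2
  za <- qnorm(1 - alpha / 2)
  pnorm((abs(p1 - p2) * sqrt(n) - za * sqrt(2 * pbar * (1 - pbar))) /
          sqrt(p1 * (1 - p1) + p2 * (1 - p2)))
}

#' Apply a design effect to a total sample size
#'
#' @param total_n Total parallel-design sample size.
#' @param de Design-effect multiplier.
#' @return `ceiling(total_n * de)` as an integer. With the planning chain
#'   2 x 111 = 222 and the stated design effect 0.45 this gives the
#'   minimum recruitment of 100 patients.
#' @examples
#' apply_design_effect(222, 0.45)
#' @export
apply_design_effect <- function(total_n, de) {
  if (total_n <= 0) abort("`total_n` must be positive.")
  if (de <= 0) abort("`de` must be positive.")
  as.integer(ceiling(total_n * de))
}

#' Stepped-wedge design effect
#'
#' The published correction factor converting a parallel-design total
#' sample size to the stepped-wedge requirement, for a cross-sectional
#' design with `k_steps` steps, `b_baseline_periods` baseline measurement
#' periods, `t_measurements_per_step` measurement periods after each step,
#' `n_per_cluster_period` subjects per cluster-period and intracluster
#' correlation `rho`:
#' \deqn{DE = \frac{1+\rho(ktn+bn-1)}{1+\rho(\tfrac12 ktn+bn-1)}
#'   \cdot \frac{3(1-\rho)}{2t(k-1/k)}}
#' The factor is expressed per recruitment period: the equal-size
#' generalized-least-squares variance ratio of the stepped wedge against
#' an individually randomized parallel trial equals `DE * (b + k t)`,
#' which is the invariant the test suite checks against a direct GLS
#' computation. The factor can exceed 1 for large `rho * n`; no upper
#' bound is asserted.
#'
#' @param k_steps Number of steps (clusters switching one at a time).
#' @param b_baseline_periods Baseline measurement periods before the first
#'   switch.
#' @param t_measurements_per_step Measurement periods after each step.
#' @param n_per_cluster_period Subjects per cluster per period.
#' @param rho Intracluster correlation, in `[0, 1)`.
#' @return The design-effect multiplier.
#' @examples
#' sw_design_effect(5, 1, 1, 15, 0.10)
#' @export
sw_design_effect <- function(k_steps, b_baseline_periods = 1,
                             t_measurements_per_step = 1,
                             n_per_cluster_period, rho) {
  if (k_steps < 2) abort("`k_steps` must be at least 2.")
  if (rho < 0 || rho >= 1) abort("`rho` must lie in [0, 1).")
  k <- k_steps
  b <- b_baseline_periods
  t <- t_measurements_per_step
  n <- n_per_cluster_period
  cluster_corr <- (1 + rho * (k * t * n + b * n - 1)) /
    (1 + rho * (0.5 * k * t * n + b * n - 1))
  cluster_corr * 3 * (1 - rho) / (2 * t * (k - 1 / k))
}
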