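test_that("uncorrected chi-square reproduces the published p-values", {
  p1 <- chi_square_2x2(matrix(c(35, 257, 46, 443), 2, byrow = TRUE))$p_value
  expect_equal(round(p1, 2), 0.25)
  p2 <- chi_square_2x2(matrix(c(41, 251, 67, 422), 2, byrow = TRUE))$p_value
  expect_equal(round(p2, 2), 0.89)
  p3 <- chi_square_2x2(trial_report_tables()$sex_male)$p_value
  expect_equal(round(p3, 2), 0.23)
  # perfectly proportional table: statistic 0, p = 1
  flat <- chi_square_2x2(matrix(c(10, 90, 20, 180), 2, byrow = TRUE))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "margins")
  expect_error(chi_square_2x2(matrix(1:6, 2)), "2x2")
})

test_that("exact test matches a direct hypergeometric enumeration", {
  # oracle for the 2x2 case: enumerate all tables with the observed
  # margins and sum the hypergeometric probabilities of those no more
  # probable than the observed table
  fisher_2x2_oracle <- function(m) {
    r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
    ks <- max(0, c1 - (n - r1)):min(r1, c1)
    probs <- dhyper(ks, r1, n - r1, c1)
    p_obs <- dhyper(m[1, 1], r1, n - r1, c1)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  tables <- list(
    matrix(c(1, 9, 9, 1), 2, byrow = TRUE),
    matrix(c(3, 7, 5, 5), 2, byrow = TRUE),
    matrix(c(12, 2, 4, 9), 2, byrow = TRUE)
  )
  for (m in tables) {
    expect_equal(fisher_exact(m)$p_value, fisher_2x2_oracle(m),
                 tolerance = 1e-6)
  }
  # published 2x3 pathology comparison
  expect_equal(round(fisher_exact(trial_report_tables()$pathology)$p_value, 2),
               0.64)
  # row permutation leaves the p-value unchanged
  m <- matrix(c(8, 3, 2, 5, 6, 1), 2, byrow = TRUE)
  expect_equal(fisher_exact(m)$p_value, fisher_exact(m[2:1, ])$p_value)
  expect_error(fisher_exact(matrix(1, 4, 4)), "too large")
})

test_that("chi-square and exact test agree asymptotically on large tables", {
  set.seed(13)
  for (i in 1:10) {
    p <- runif(1, 0.3, 0.7)
    m <- matrix(c(rbinom(1, 200, p), 0, rbinom(1, 200, p), 0), 2)
    m[, 2] <- 200 - m[, 1]
    if (any(colSums(m) == 0)) next
    expect_lt(abs(chi_square_2x2(m)$p_value - fisher_exact(m)$p_value), 0.03)
  }
})

test_that("summary-statistic t-test equals the raw-data computation", {
  set.seed(19)
  x <- rnorm(40, 10, 2)
  y <- rnorm(55, 11, 2.5)
  ours <- two_sample_t(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter))
  # equal summaries give t = 0, p = 1
  null_t <- two_sample_t(67, 9.9, 292, 67, 9.9, 489)
  expect_equal(null_t$statistic, 0)
  expect_equal(null_t$p_value, 1)
  expect_error(two_sample_t(1, 0, 10, 2, 1, 10), "positive")
  expect_error(two_sample_t(1, 1, 1, 2, 1, 10), "at least 2")
})

test_that("the IRLS logit fit matches glm on a simulated trial", {
  cohort <- generate_trial_cohort(trial_design(), flow_params(),
                                  n_per_cluster_period = 30, seed = 29)
  fit <- fit_logit_linear(cohort)
  ref <- glm(outcome ~ I(strategy == "intervention") + factor(hospital_id) +
               factor(period_index),
             family = binomial(), data = cohort)
  expect_equal(sort(fit$coefficients$estimate), sort(unname(coef(ref))),
               tolerance = 1e-7)
  expect_equal(fit$deviance, ref$deviance, tolerance = 1e-7)
  b <- fit$coefficients[fit$coefficients$term == "intervention", ]
  se_ref <- summary(ref)$coefficients[2, 2]
  expect_equal(b$std_error, se_ref, tolerance = 1e-3)
  expect_equal(fit$odds_ratio, exp(unname(coef(ref)[2])), tolerance = 1e-7)
  expect_true(fit$converged)
  expect_false(fit$separation)
  # block LR tests drop 4 hospital and 5 period dummies
  expect_equal(fit$block_tests$df, c(4L, 5L))
  # tidy/glance shapes
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error", "p_value") %in% names(td)))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$conf_low <= gl$odds_ratio && gl$odds_ratio <= gl$conf_high)
})

test_that("a structureless dataset reproduces the marginal 2x2 odds ratio", {
  # one hospital, one period: dummies drop, the model is outcome ~ treatment
  set.seed(37)
  d <- tibble::tibble(
    outcome = rbinom(400, 1, rep(c(0.12, 0.09), each = 200)),
    strategy = rep(c("control", "intervention"), each = 200),
    hospital_id = 1L,
    period_index = 1L
  )
  fit <- fit_logit_linear(d)
  tab <- table(d$strategy, d$outcome)
  or_marginal <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  expect_equal(fit$odds_ratio, unname(or_marginal), tolerance = 1e-7)
  expect_identical(fit$block_tests$df, c(0L, 0L))
  expect_true(all(is.na(fit$block_tests$p_value)))
})

test_that("balanced null data give an odds ratio of exactly one", {
  d <- tidyr::expand_grid(
    strategy = c("control", "intervention"),
    hospital_id = 1:2,
    period_index = 1:2,
    outcome = c(0, 0, 1)   # identical 1/3 rate in every cell
  )
  fit <- fit_logit_linear(d)
  expect_equal(fit$odds_ratio, 1, tolerance = 1e-8)
})

test_that("separation is flagged rather than silently reported", {
  d <- tibble::tibble(
    outcome = c(rep(0L, 50), rep(1L, 50)),
    strategy = rep(c("control", "intervention"), each = 50),
    hospital_id = 1L,
    period_index = 1L
  )
  fit <- fit_logit_linear(d)
  expect_true(fit$separation)
})

test_that("collinear columns raise an error naming them", {
  d <- tibble::tibble(
    outcome = rbinom(40, 1, 0.3),
    strategy = rep(c("control", "intervention"), each = 20),
    hospital_id = rep(1:2, each = 20),   # aliased with strategy
    period_index = 1L
  )
  expect_error(fit_logit_linear(d), "collinear")
})

test_that("ITT and non-CRC sensitivity analyses run side by side", {
  cohort <- generate_trial_cohort(trial_design(), flow_params(),
                                  n_per_cluster_period = 30, seed = 43)
  res <- itt_analysis(cohort)
  expect_identical(res$n_excluded, sum(cohort$pathology == "non_crc"))
  expect_identical(res$itt$n, nrow(cohort))
  expect_identical(res$crc_only$n, nrow(cohort) - res$n_excluded)
  td <- tidy(res)
  expect_identical(td$analysis, c("intention_to_treat", "crc_confirmed_only"))
  # with no non-CRC rows the two fits coincide
  crc_only <- dplyr::filter(cohort, pathology == "crc")
  res2 <- itt_analysis(crc_only)
  expect_equal(res2$itt$odds_ratio, res2$crc_only$odds_ratio)
})

test_that("plot methods return ggplot objects", {
  expect_s3_class(ggplot2::autoplot(build_schedule(trial_design())), "ggplot")
  expect_s3_class(ggplot2::autoplot(evaluate_history(crc_proband_hist(45))),
                  "ggplot")
  cohort <- generate_trial_cohort(trial_design(), flow_params(),
                                  n_per_cluster_period = 12, seed = 3)
  expect_s3_class(ggplot2::autoplot(fit_logit_linear(cohort)), "ggplot")
})
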