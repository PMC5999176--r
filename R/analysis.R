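#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected (no continuity correction) Pearson chi-square with one
#' degree of freedom and a two-sided p-value; this is the statistic whose
#' p-values the published group comparisons report.
#'
#' @param x A 2x2 matrix of counts, or a data frame coercible to one.
#' @return A one-row tibble: `method`, `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_2x2(matrix(c(35, 257, 46, 443), 2, byrow = TRUE))
#' @export
chi_square_2x2 <- function(x) {
  x <- as_count_matrix(x)
  if (!all(dim(x) == c(2L, 2L))) abort("`x` must be a 2x2 table of counts.")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    abort("All row and column margins must be positive.")
  }
  ht <- stats::chisq.test(x, correct = FALSE)
  tibble::tibble(
    method = "Pearson chi-square (no continuity correction)",
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value
  )
}

#' Fisher-Freeman-Halton exact test for a small r x c table
#'
#' Conditional exact test with both margins fixed: the p-value sums the
#' multivariate hypergeometric probabilities of every margin-compatible
#' table no more probable than the observed one (the Freeman-Halton
#' extension of Fisher's exact test for tables larger than 2x2). Only
#' small tables (r*c <= 12) are accepted; larger tables would need
#' Monte-Carlo approximation, which is out of scope here.
#'
#' @param x An r x c matrix of counts with `r * c <= 12`.
#' @return A one-row tibble: `method`, `statistic` (`NA`; the test has no
#'   single statistic), `df` (`NA`), `p_value`.
#' @examples
#' fisher_exact(matrix(c(284, 6, 2, 473, 14, 2), 2, byrow = TRUE))
#' @export
fisher_exact <- function(x) {
  x <- as_count_matrix(x)
  if (length(x) > 12L) {
    abort("Table too large (r*c > 12): use a Monte-Carlo exact test instead.")
  }
  ht <- stats::fisher.test(x, workspace = 2e7)
  tibble::tibble(
    method = "Fisher-Freeman-Halton exact test",
    statistic = NA_real_,
    df = NA_real_,
    p_value = ht$p.value
  )
}

as_count_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[vapply(x, is.numeric, logical(1))])
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("`x` must be a numeric matrix of counts.")
  }
  if (any(x < 0) || any(x != round(x))) {
    abort("Counts must be non-negative integers.")
  }
  x
}

#' Two-sample pooled t-test from summary statistics
#'
#' Two-sided unpaired t-test with pooled variance, computed from group
#' means, standard deviations and sizes (the form needed to recompute a
#' published baseline comparison from its summary row).
#'
#' @param mean1,sd1,n1 Mean, SD and size of group 1.
#' @param mean2,sd2,n2 Mean, SD and size of group 2.
#' @return A one-row tibble: `method`, `estimate` (mean difference),
#'   `statistic`, `df`, `p_value`.
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) abort("Both group sizes must be at least 2.")
  if (sd1 <= 0 || sd2 <= 0) abort("Standard deviations must be positive.")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (mean1 - mean2) / se
  df <- n1 + n2 - 2
  tibble::tibble(
    method = "Two-sample pooled t-test (summary statistics)",
    estimate = mean1 - mean2,
    statistic = tstat,
    df = df,
    p_value = 2 * pt(-abs(tstat), df)
  )
}

#' Logit-linear stepped-wedge analysis
#'
#' Maximum-likelihood logistic regression of the binary primary outcome on
#' an intervention indicator with hospital and time-period fixed effects
#' (dummy coding, first level as reference), the conventional analysis of
#' a cross-sectional stepped-wedge trial. The fit runs iteratively
#' reweighted least squares until the largest absolute coefficient change
#' is below `1e-8` (at most 100 iterations). The intervention effect is
#' reported as a conditional odds ratio with a two-sided 95% Wald
#' confidence interval; the hospital and period factor blocks get single
#' p-values from likelihood-ratio tests against the model without that
#' block. Complete or quasi-complete separation (a fitted probability
#' within `1e-10` of 0 or 1 alongside a diverging coefficient) is flagged
#' on the result rather than silently reported. Factors with a single
#' observed level are dropped from the model; genuinely collinear columns
#' raise an error naming them.
#'
#' @param data A tibble with one row per patient, e.g. from
#'   [generate_trial_cohort()].
#' @param outcome,treatment,hospital,period Column names (strings) of the
#'   binary outcome (0/1 or logical), strategy (`"control"` /
#'   `"intervention"`, logical, or 0/1), hospital id and period index.
#' @param conf_level Confidence level of the Wald interval.
#' @return An object of class `fh_logit`; see [tidy.fh_logit()] and
#'   [glance.fh_logit()].
#' @examples
#' cohort <- generate_trial_cohort(trial_design(), flow_params(),
#'                                 n_per_cluster_period = 20, seed = 2)
#' fit <- fit_logit_linear(cohort)
#' glance(fit)
#' @export
fit_logit_linear <- function(data, outcome = "outcome", treatment = "strategy",
                             hospital = "hospital_id", period = "period_index",
                             conf_level = 0.95) {
  data <- tibble::as_tibble(data)
  for (col in c(outcome, treatment, hospital, period)) {
    if (!col %in% names(data)) abort(paste0("Column not found: ", col))
  }
  y <- as.numeric(as_binary(data[[outcome]], outcome))
  trt <- as_treatment(data[[treatment]])
  if (length(unique(trt)) < 2L) {
    abort("Both strategies must be present in the data.")
  }
  hosp <- factor(data[[hospital]])
  per <- factor(data[[period]])
  X <- cbind(`(Intercept)` = 1, intervention = trt)
  hosp_cols <- dummy_cols(hosp, "hospital")
  per_cols <- dummy_cols(per, "period")
  X <- cbind(X, hosp_cols, per_cols)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    abort(paste0("Design matrix is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  fit <- irls_logit(X, y)
  full_dev <- fit$deviance
  lr_block <- function(drop_cols, label) {
    if (length(drop_cols) == 0L) {
      return(tibble::tibble(block = label, df = 0L, lr_statistic = NA_real_,
                            p_value = NA_real_))
    }
    Xr <- X[, setdiff(colnames(X), drop_cols), drop = FALSE]
    red <- irls_logit(Xr, y)
    lr <- red$deviance - full_dev
    tibble::tibble(block = label, df = length(drop_cols), lr_statistic = lr,
                   p_value = pchisq(lr, length(drop_cols), lower.tail = FALSE))
  }
  blocks <- dplyr::bind_rows(
    lr_block(colnames(hosp_cols), "hospital"),
    lr_block(colnames(per_cols), "period")
  )
  z <- qnorm(1 - (1 - conf_level) / 2)
  b_trt <- fit$coefficients["intervention"]
  se_trt <- fit$std_errors["intervention"]
  structure(
    list(
      coefficients = tibble::tibble(
        term = names(fit$coefficients),
        estimate = unname(fit$coefficients),
        std_error = unname(fit$std_errors),
        statistic = unname(fit$coefficients / fit$std_errors),
        p_value = 2 * pnorm(-abs(unname(fit$coefficients / fit$std_errors)))
      ),
      odds_ratio = unname(exp(b_trt)),
      conf_low = unname(exp(b_trt - z * se_trt)),
      conf_high = unname(exp(b_trt + z * se_trt)),
      conf_level = conf_level,
      p_value = unname(2 * pnorm(-abs(b_trt / se_trt))),
      block_tests = blocks,
      deviance = full_dev,
      df_residual = length(y) - ncol(X),
      iterations = fit$iterations,
      converged = fit$converged,
      separation = fit$separation,
      n = length(y)
    ),
    class = "fh_logit"
  )
}

as_binary <- function(x, name) {
  if (is.logical(x)) return(as.integer(x))
  if (all(x %in% c(0, 1))) return(as.integer(x))
  abort(paste0("Column ", name, " must be binary (0/1 or logical)."))
}

as_treatment <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x) && all(x %in% c(0, 1))) return(as.integer(x))
  if (all(x %in% c("control", "intervention"))) {
    return(as.integer(x == "intervention"))
  }
  abort("Treatment column must be logical, 0/1, or control/intervention.")
}

## first level is the reference; single-level factors contribute nothing
dummy_cols <- function(f, prefix) {
  lev <- levels(droplevels(f))
  if (length(lev) < 2L) {
    return(matrix(numeric(0), nrow = length(f), ncol = 0))
  }
  out <- vapply(lev[-1L], function(l) as.numeric(f == l), numeric(length(f)))
  colnames(out) <- paste0(prefix, lev[-1L])
  out
}

irls_logit <- function(X, y, tol = 1e-8, max_iter = 100L) {
  beta <- rep(0, ncol(X))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    mu_c <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    w <- mu_c * (1 - mu_c)
    z <- eta + (y - mu_c) / w
    sw <- sqrt(w)
    fit <- qr(sw * X)
    beta_new <- qr.coef(fit, sw * z)
    if (anyNA(beta_new)) {
      abort("IRLS failed: weighted design matrix lost rank.")
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  mu_c <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  w <- mu_c * (1 - mu_c)
  info <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  se <- sqrt(diag(cov))
  deviance <- -2 * sum(y * log(mu_c) + (1 - y) * log(1 - mu_c))
  separation <- any(mu < 1e-10 | mu > 1 - 1e-10) && max(abs(beta)) > 10
  names(beta) <- colnames(X)
  names(se) <- colnames(X)
  list(coefficients = beta, std_errors = se, deviance = deviance,
       iterations = iter, converged = converged, separation = separation)
}

#' @export
print.fh_logit <- function(x, ...) {
  cat("<fh_logit> logit-linear stepped-wedge analysis\n")
  cat(sprintf("  n = %d, deviance = %.2f (%d iterations%s)\n", x$n, x$deviance,
              x$iterations, if (x$converged) "" else ", NOT converged"))
  if (x$separation) cat("  WARNING: separation detected; estimates diverge\n")
  cat(sprintf("  intervention: conditional OR %.2f (%.0f%% CI %.2f-%.2f), p = %.2g\n",
              x$odds_ratio, 100 * x$conf_level, x$conf_low, x$conf_high,
              x$p_value))
  for (i in seq_len(nrow(x$block_tests))) {
    b <- x$block_tests[i, ]
    if (!is.na(b$p_value)) {
      cat(sprintf("  %s block: LR = %.2f on %d df, p = %.2g\n",
                  b$block, b$lr_statistic, b$df, b$p_value))
    }
  }
  invisible(x)
}

#' Tidy a logit-linear fit
#'
#' @param x An `fh_logit` object.
#' @param exponentiate Report odds ratios instead of log-odds.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`.
#' @export
#' @exportS3Method generics::tidy
tidy.fh_logit <- function(x, exponentiate = FALSE, ...) {
  out <- x$coefficients
  if (exponentiate) out$estimate <- exp(out$estimate)
  out
}

#' One-row summary of a logit-linear fit
#'
#' @param x An `fh_logit` object.
#' @param ... Unused.
#' @return A one-row tibble: `odds_ratio`, `conf_low`, `conf_high`,
#'   `p_value`, `p_hospital`, `p_period`, `deviance`, `df_residual`, `n`,
#'   `converged`, `separation`.
#' @export
#' @exportS3Method generics::glance
glance.fh_logit <- function(x, ...) {
  pb <- function(block) {
    v <- x$block_tests$p_value[x$block_tests$block == block]
    if (length(v) == 0L) NA_real_ else v
  }
  tibble::tibble(
    odds_ratio = x$odds_ratio,
    conf_low = x$conf_low,
    conf_high = x$conf_high,
    p_value = x$p_value,
    p_hospital = pb("hospital"),
    p_period = pb("period"),
    deviance = x$deviance,
    df_residual = x$df_residual,
    n = x$n,
    converged = x$converged,
    separation = x$separation
  )
}

#' Intention-to-treat analysis with a non-CRC sensitivity analysis
#'
#' Fits the logit-linear model on all eligible patients (intention to
#' treat) and, side by side, on the subset whose presumed colorectal
#' lesion was histologically confirmed (rows with `pathology ==
#' "non_crc"` removed), the sensitivity analysis reported alongside the
#' primary result.
#'
#' @param data A patient-level tibble as for [fit_logit_linear()], with a
#'   pathology label column.
#' @param pathology Column name holding `"crc"` / `"non_crc"` labels.
#' @param ... Passed to [fit_logit_linear()].
#' @return An object of class `fh_itt` with elements `itt` and
#'   `crc_only`, both `fh_logit`; `tidy()` stacks their glances.
#' @export
itt_analysis <- function(data, pathology = "pathology", ...) {
  data <- tibble::as_tibble(data)
  if (!pathology %in% names(data)) {
    abort(paste0("Column not found: ", pathology))
  }
  itt <- fit_logit_linear(data, ...)
  keep <- data[[pathology]] != "non_crc"
  crc_only <- fit_logit_linear(data[keep, , drop = FALSE], ...)
  structure(
    list(itt = itt, crc_only = crc_only,
         n_excluded = sum(!keep)),
    class = "fh_itt"
  )
}

#' @export
print.fh_itt <- function(x, ...) {
  cat("== Intention to treat ==\n")
  print(x$itt)
  cat(sprintf("== Excluding non-CRC lesions (%d removed) ==\n", x$n_excluded))
  print(x$crc_only)
  invisible(x)
}

#' @rdname itt_analysis
#' @param x An `fh_itt` object.
#' @return `tidy.fh_itt()`: a two-row tibble of [glance.fh_logit()]
#'   summaries with an `analysis` column.
#' @export
#' @exportS3Method generics::tidy
tidy.fh_itt <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance(x$itt), analysis = "intention_to_treat",
                  .before = 1),
    dplyr::mutate(glance(x$crc_only), analysis = "crc_confirmed_only",
                  .before = 1)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
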