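#' Welch's two-sample t-test
#'
#' Unequal-variance comparison of two groups with the Welch-Satterthwaite
#' degrees-of-freedom correction, returned in the package's uniform
#' [stat_result()] shape (estimate = mean of `x` minus mean of `y`).
#' Degenerate inputs where both samples have zero variance follow the
#' convention `p = 1` when the means agree (no evidence of a difference)
#' and `p = 0` otherwise.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param conf_level confidence level for the mean-difference interval.
#' @param effect label stored in the result row.
#' @return A one-row `stat_result`.
#' @export
welch_t <- function(x, y, conf_level = 0.95, effect = "mean_difference") {
  if (length(x) < 2 || length(y) < 2) {
    stop_ivsi("each sample needs at least 2 observations", "sample_size")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_ivsi("samples must be finite", "domain")
  }
  d <- mean(x) - mean(y)
  if (var(x) == 0 && var(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(stat_result("welch_t", effect, estimate = d,
                       ci_low = d, ci_high = d,
                       statistic = if (eq) 0 else sign(d) * Inf,
                       df = length(x) + length(y) - 2,
                       p_value = if (eq) 1 else 0))
  }
  tt <- t.test(x, y, var.equal = FALSE, conf.level = conf_level)
  stat_result("welch_t", effect, estimate = d,
              ci_low = unname(tt$conf.int[1]), ci_high = unname(tt$conf.int[2]),
              statistic = unname(tt$statistic), df = unname(tt$parameter),
              p_value = tt$p.value)
}

#' Cohen's d from group summary statistics
#'
#' Standardised mean difference `|m_a - m_b| / s_pooled` with the equal-n
#' pooled standard deviation `s_pooled = sqrt((sd_a^2 + sd_b^2) / 2)`,
#' appropriate for equally sized pilot groups.
#'
#' @param mean_a,sd_a,mean_b,sd_b group means and standard deviations
#'   (`sd > 0`).
#' @return The effect size d (non-negative).
#' @export
#' @examples
#' round(cohens_d(0.022, 0.017, 0.056, 0.023), 2) # 1.68
cohens_d <- function(mean_a, sd_a, mean_b, sd_b) {
  if (sd_a <= 0 || sd_b <= 0) {
    stop_ivsi("standard deviations must be positive", "domain")
  }
  abs(mean_a - mean_b) / sqrt((sd_a^2 + sd_b^2) / 2)
}

#' Power-analysis specification
#'
#' @param alpha type-I error level.
#' @param power desired power.
#' @param tails 1 or 2 (two-tailed default).
#' @return A list of class `power_spec`.
#' @export
power_spec <- function(alpha = 0.05, power = 0.80, tails = 2) {
  if (alpha <= 0 || alpha >= 1) stop_ivsi("alpha must be in (0, 1)", "domain")
  if (power <= 0 || power >= 1) stop_ivsi("power must be in (0, 1)", "domain")
  if (!tails %in% c(1, 2)) stop_ivsi("tails must be 1 or 2", "domain")
  structure(list(alpha = alpha, power = power, tails = tails),
            class = "power_spec")
}

# exact power of the two-sample t-test at n per group under noncentral t
# with ncp d * sqrt(n/2) and df 2n - 2
t_test_power <- function(n, d, spec) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  if (spec$tails == 2) {
    q <- qt(1 - spec$alpha / 2, df)
    1 - pt(q, df, ncp) + pt(-q, df, ncp)
  } else {
    1 - pt(qt(1 - spec$alpha, df), df, ncp)
  }
}

#' A priori sample size for a two-sample t-test
#'
#' Smallest integer group size `n` such that the two-sample t-test at
#' level `alpha` reaches the requested power for effect size `d`, under
#' the exact noncentral-t distribution (noncentrality `d * sqrt(n/2)`,
#' `df = 2n - 2`). The search starts at `n = 2`, the smallest group size
#' with positive degrees of freedom.
#'
#' @param d Cohen's d effect size (> 0).
#' @param spec a [power_spec()].
#' @return Integer group size.
#' @export
#' @examples
#' required_n_per_group(0.5) # 64
required_n_per_group <- function(d, spec = power_spec()) {
  if (!is.numeric(d) || length(d) != 1 || !is.finite(d) || d <= 0) {
    stop_ivsi("effect size d must be a single positive number", "domain")
  }
  n <- 2L
  while (t_test_power(n, d, spec) < spec$power) {
    n <- n + 1L
    if (n > 1e7) stop_ivsi("required sample size exceeds 1e7", "domain")
  }
  n
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values over one family of tests; order-preserving
#' and capped at 1.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1)) {
    stop_ivsi("p-values must be numeric in [0, 1]", "domain")
  }
  p.adjust(pvalues, method = "BH")
}

#' Linear mixed-effects model specification
#'
#' The longitudinal model of the package: the named response metric
#' regressed on the experimental group and the postoperative day as fixed
#' effects, with a random intercept per animal; inference uses
#' Satterthwaite degrees of freedom and Wald confidence intervals.
#'
#' @param fixed fixed-effect terms drawn from `c("group", "day")`; an
#'   empty vector fits an intercept-only model.
#' @param conf_level confidence level.
#' @return A list of class `lmm_spec`.
#' @export
lmm_spec <- function(fixed = c("group", "day"), conf_level = 0.95) {
  if (!all(fixed %in% c("group", "day"))) {
    stop_ivsi("fixed effects must be drawn from 'group' and 'day'", "parameter")
  }
  structure(list(fixed = fixed, conf_level = conf_level), class = "lmm_spec")
}

#' Fit the longitudinal mixed model to a cohort table
#'
#' REML fit of `value ~ group + day + (1 | animal_id)` (terms per the
#' [lmm_spec()]) via lme4, with Satterthwaite degrees of freedom and
#' p-values via lmerTest. Confidence intervals are Wald intervals on the
#' Satterthwaite df. A singular fit (zero random-intercept variance) is
#' flagged, not fatal; if the mixed fit cannot be computed at all (e.g.
#' zero residual variance in exactly linear data), the model degenerates
#' to ordinary least squares — the correct singular limit — with a
#' warning.
#'
#' @param table a long cohort table (see [validate_cohort_table()]);
#'   supply `metric` to select one metric from a multi-metric table.
#' @param spec an [lmm_spec()].
#' @param metric optional metric name filter.
#' @return A `stat_result` data frame with one row per fixed effect
#'   (`intercept`, `group`, `day`), with attributes `variances`
#'   (random-intercept and residual variance) and `singular`.
#' @export
fit_lmm <- function(table, spec = lmm_spec(), metric = NULL) {
  table <- validate_cohort_table(table)
  df <- as.data.frame(table)
  if (!is.null(metric)) df <- df[df$metric_name == metric, , drop = FALSE]
  if (!nrow(df)) stop_ivsi("no rows to fit (wrong metric name?)", "format")
  if ("group" %in% spec$fixed && length(unique(df$group)) < 2) {
    stop_ivsi("group effect requested but only one group present", "parameter")
  }
  df$group <- factor(df$group, levels = c("sham", "TAC"))
  rhs <- paste(c(spec$fixed, "(1 | animal_id)"), collapse = " + ")
  form <- stats::as.formula(paste("value ~", rhs))

  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(form, data = df, REML = TRUE)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    warning("mixed fit failed (", conditionMessage(fit),
            "); falling back to ordinary least squares")
    return(.lmm_ols_fallback(df, spec))
  }
  singular <- lme4::isSingular(fit)
  co <- summary(fit)$coefficients # Estimate SE df t p (Satterthwaite)
  vc <- as.data.frame(lme4::VarCorr(fit))
  variances <- c(animal = vc$vcov[vc$grp == "animal_id"],
                 residual = vc$vcov[vc$grp == "Residual"])
  res <- .coef_to_results(co, spec$conf_level, method = "lmm_satterthwaite")
  attr(res, "variances") <- variances
  attr(res, "singular") <- singular
  if (singular) {
    message("singular fit: random-intercept variance estimated at zero")
  }
  res
}

.coef_to_results <- function(co, conf_level, method) {
  eff <- rownames(co)
  eff[eff == "(Intercept)"] <- "intercept"
  eff[eff == "groupTAC"] <- "group"
  out <- lapply(seq_len(nrow(co)), function(i) {
    est <- co[i, "Estimate"]
    se <- co[i, "Std. Error"]
    dfree <- if ("df" %in% colnames(co)) co[i, "df"] else NA_real_
    tcrit <- qt(1 - (1 - conf_level) / 2, dfree)
    pv <- co[i, grep("^Pr", colnames(co))]
    stat_result(method, eff[i], estimate = est,
                ci_low = est - tcrit * se, ci_high = est + tcrit * se,
                statistic = co[i, "t value"], df = dfree, p_value = pv)
  })
  do.call(rbind_stat_results, out)
}

.lmm_ols_fallback <- function(df, spec) {
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  fit <- lm(stats::as.formula(paste("value ~", rhs)), data = df)
  co <- summary(fit)$coefficients
  co <- cbind(co[, 1:2, drop = FALSE], df = fit$df.residual,
              `t value` = co[, 3], `Pr(>|t|)` = co[, 4])
  res <- .coef_to_results(co, spec$conf_level, method = "lmm_ols_fallback")
  attr(res, "variances") <- c(animal = 0, residual = summary(fit)$sigma^2)
  attr(res, "singular") <- TRUE
  res
}

#' Two-way absolute-agreement intraclass correlation, ICC(A,1)
#'
#' Single-measure absolute-agreement ICC under the two-way random-effects
#' model (raters and subjects both random), the standard reproducibility
#' statistic for intra-/inter-observer variability of repeated strain
#' measurements. The F-based confidence interval follows the
#' McGraw-Wong formulation.
#'
#' @param ratings numeric matrix, subjects in rows (>= 5), raters in
#'   columns (>= 2), complete.
#' @param conf_level confidence level.
#' @return A one-row `stat_result` (method `"icc_a1"`); the statistic is
#'   the F ratio MSR/MSE testing ICC = 0.
#' @export
icc_agreement <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 5 || k < 2) {
    stop_ivsi("need at least 5 subjects and 2 raters", "sample_size")
  }
  if (anyNA(ratings)) stop_ivsi("ratings matrix must be complete", "data")
  if (var(as.vector(ratings)) == 0) {
    stop_ivsi("ratings are constant; ICC is undefined", "domain")
  }
  g <- mean(ratings)
  rm_ <- rowMeans(ratings)
  cm <- colMeans(ratings)
  msr <- k * sum((rm_ - g)^2) / (n - 1)
  msc <- n * sum((cm - g)^2) / (k - 1)
  sse <- sum((ratings - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm) + g)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  if (mse == 0 && msc == 0) { # raters in perfect agreement
    return(stat_result("icc_a1", "agreement", estimate = 1,
                       ci_low = 1, ci_high = 1, statistic = Inf,
                       df = n - 1, p_value = 0))
  }

  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  fstat <- msr / mse
  p <- pf(fstat, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  stat_result("icc_a1", "agreement", estimate = icc,
              ci_low = min(lower, icc), ci_high = max(upper, icc),
              statistic = fstat, df = n - 1, p_value = p)
}

#' Bland-Altman agreement limits
#'
#' Bias (mean paired difference `x - y`) and 95% limits of agreement
#' `bias +/- 1.96 sd(x - y)`.
#'
#' @param x,y paired measurements, n >= 3.
#' @return A list with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop_ivsi("x and y must be paired", "format")
  if (length(x) < 3) stop_ivsi("need at least 3 pairs", "sample_size")
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, n = length(d))
}
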