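# Replicate-level simulation studies: the package's own checks that the
# pipeline recovers the relaxation phenotype it was designed to detect,
# and that the mixed-model intervals are calibrated.

#' Replicate detection study of the headline metric
#'
#' Simulates independent sham-vs-TAC cohorts, runs each through the
#' standard trace pipeline (filter, differentiate, IVRT window) and tests
#' the across-segment mean |min acceleration of radial strain rate| with
#' a per-day Welch test. Detection on a day means the TAC group mean is
#' lower and the Welch p-value is below `alpha`.
#'
#' @param n_replicates number of independent cohorts.
#' @param params a [cohort_params()] template (its `seed` is replaced per
#'   replicate, derived from `seed`).
#' @param filter a [filter_spec()] or `NULL`.
#' @param alpha per-day test level.
#' @param days_required days on which detection is demanded for a
#'   replicate to count as a success (default: day 4 onward).
#' @param seed base seed for the replicate stream.
#' @return A list with the per-replicate-by-day logical `detected` matrix,
#'   the success rate over `days_required`, and the per-day detection
#'   rates.
#' @export
detection_study <- function(n_replicates = 100, params = cohort_params(),
                            filter = filter_spec(), alpha = 0.05,
                            days_required = NULL, seed = 1) {
  days <- params$days
  days_required <- days_required %||% days[days >= 4]
  detected <- matrix(NA, n_replicates, length(days),
                     dimnames = list(NULL, paste0("day", days)))
  for (r in seq_len(n_replicates)) {
    p <- params
    p$seed <- (seed * 10007L + r) %% .Machine$integer.max
    tab <- headline_cohort_table(simulate_cohort(p), filter = filter)
    for (j in seq_along(days)) {
      d <- tab[tab$day == days[j], ]
      sham <- d$value[d$group == "sham"]
      tac <- d$value[d$group == "TAC"]
      res <- welch_t(tac, sham)
      detected[r, j] <- res$estimate < 0 && res$p_value < alpha
    }
  }
  jreq <- match(paste0("day", days_required), colnames(detected))
  success <- apply(detected[, jreq, drop = FALSE], 1, all)
  list(detected = detected,
       success_rate = mean(success),
       per_day_rate = colMeans(detected),
       days_required = days_required)
}

#' Confidence-interval coverage study for the mixed model
#'
#' Simulates metric-level longitudinal cohorts from a known linear
#' mixed-effects ground truth and records how often the [fit_lmm()]
#' group-effect confidence interval covers the true effect. A calibrated
#' interval covers at its nominal level.
#'
#' @param n_replicates number of simulated cohorts.
#' @param group_effect,day_slope,intercept,intercept_sd,residual_sd ground
#'   truth passed to [simulate_metric_cohort()].
#' @param n_per_group,days cohort design.
#' @param seed base seed.
#' @return A list with `coverage` (group effect), `covered` (logical
#'   vector) and the mean estimated effect.
#' @export
coverage_study <- function(n_replicates = 500, group_effect = -0.14,
                           day_slope = -0.004, intercept = 1,
                           intercept_sd = 0.02, residual_sd = 0.02,
                           n_per_group = 10, days = 1:14, seed = 1) {
  covered <- logical(n_replicates)
  est <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    tab <- simulate_metric_cohort(
      n_per_group = n_per_group, days = days, intercept = intercept,
      group_effect = group_effect, day_slope = day_slope,
      intercept_sd = intercept_sd, residual_sd = residual_sd,
      seed = (seed * 20011L + r) %% .Machine$integer.max
    )
    res <- suppressMessages(fit_lmm(tab))
    g <- res[res$effect == "group", ]
    covered[r] <- g$ci_low <= group_effect && group_effect <= g$ci_high
    est[r] <- g$estimate
  }
  list(coverage = mean(covered), covered = covered, mean_estimate = mean(est))
}
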