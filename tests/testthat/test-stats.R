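test_that("welch_t matches the direct formula and handles degenerate input", {
  x <- c(1, 2, 3, 4); y <- c(3, 4, 5, 6)
  r <- welch_t(x, y)
  o <- welch_oracle(x, y)
  expect_equal(r$statistic, o$t)
  expect_equal(r$df, o$df)
  expect_equal(r$p_value, o$p)
  expect_equal(r$estimate, -2)

  # identical samples: no evidence of a difference
  z <- c(1.2, 3.4, 5.6)
  r0 <- welch_t(z, z)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # equal n and equal variances: Welch reduces to Student's t
  set.seed(10)
  a <- rnorm(8); b <- a + 2 # same sample variance by construction
  rw <- welch_t(a, b)
  st <- t.test(a, b, var.equal = TRUE)
  expect_equal(rw$statistic, unname(st$statistic))
  expect_equal(rw$df, unname(st$parameter))

  # both samples constant
  expect_equal(welch_t(c(1, 1), c(1, 1))$p_value, 1)
  expect_equal(welch_t(c(1, 1), c(2, 2))$p_value, 0)
  expect_error(welch_t(1, c(1, 2)), class = "ivsi_sample_size_error")
})

test_that("welch_t keeps its nominal type-I error under the null", {
  set.seed(2024)
  rej <- 0L
  for (i in 1:2000) {
    if (welch_t(rnorm(6), rnorm(6))$p_value < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 2000, 0.035)
  expect_lte(rej / 2000, 0.065)
})

test_that("Cohen's d uses the equal-n pooled SD", {
  expect_equal(round(cohens_d(0.022, 0.017, 0.056, 0.023), 2), 1.68)
  expect_equal(cohens_d(1, 2, 1, 3), 0)
  expect_equal(cohens_d(0, 1, 1, 1), 1)
  expect_error(cohens_d(0, 0, 1, 1), class = "ivsi_domain_error")
})

test_that("sample-size search matches the noncentral-t power law", {
  # d = 0.5: power crosses 0.80 between n = 63 (0.795) and n = 64 (0.801)
  expect_identical(required_n_per_group(0.5), 64L)
  expect_lt(noncentral_t_power(63, 0.5), 0.80)
  expect_gte(noncentral_t_power(64, 0.5), 0.80)

  # the pilot effect size: 7 two-tailed, 6 one-tailed
  expect_identical(required_n_per_group(1.68), 7L)
  expect_lt(noncentral_t_power(6, 1.68), 0.80)
  expect_identical(required_n_per_group(1.68, power_spec(tails = 1)), 6L)

  # huge effects bottom out at the smallest feasible group size
  expect_identical(required_n_per_group(10), 2L)
  expect_error(required_n_per_group(0), class = "ivsi_domain_error")

  # agreement with stats::power.t.test as an independent oracle
  expect_identical(required_n_per_group(1.68),
                   as.integer(ceiling(power.t.test(delta = 1.68, sd = 1,
                                                   power = 0.8)$n)))
})

test_that("empirical power agrees with the analytic noncentral-t power", {
  set.seed(55)
  hits <- 0L
  n_rep <- 2000L
  for (i in seq_len(n_rep)) {
    if (welch_t(rnorm(6), rnorm(6, mean = 1.68))$p_value < 0.05) hits <- hits + 1L
  }
  expect_equal(hits / n_rep, noncentral_t_power(6, 1.68), tolerance = 0.035)
})

test_that("BH adjustment equals the brute-force step-up on handpicked cases", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.05, 0.05, 0.05)), c(0.05, 0.05, 0.05))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)),
               brute_force_bh(c(0.01, 0.02, 0.03, 0.04)))
  expect_error(bh_fdr(c(0.1, 1.2)), class = "ivsi_domain_error")
})

test_that("BH output is monotone, dominates the input and caps at 1", {
  set.seed(99)
  for (i in 1:50) {
    p <- runif(sample(1:12, 1))
    adj <- bh_fdr(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_equal(adj, brute_force_bh(p))
  }
})

test_that("the mixed model recovers exact linear data and balanced means", {
  ids <- c(sprintf("sham_%02d", 1:3), sprintf("tac_%02d", 1:3))
  tab <- expand.grid(animal_id = ids, day = 1:4, stringsAsFactors = FALSE)
  tab$group <- ifelse(grepl("tac", tab$animal_id), "TAC", "sham")
  tab$metric_name <- "m"
  tab$value <- 1 - 0.14 * (tab$group == "TAC") - 0.004 * tab$day
  r <- suppressWarnings(suppressMessages(fit_lmm(tab)))
  expect_equal(r$estimate[r$effect == "intercept"], 1, tolerance = 1e-6)
  expect_equal(r$estimate[r$effect == "group"], -0.14, tolerance = 1e-6)
  expect_equal(r$estimate[r$effect == "day"], -0.004, tolerance = 1e-6)
  expect_true(all(attr(r, "variances") < 1e-10))

  # intercept-only model on one group: grand mean of a balanced table
  one <- tab[tab$group == "sham", ]
  r1 <- suppressMessages(fit_lmm(one, spec = lmm_spec(fixed = character(0))))
  expect_equal(r1$estimate, mean(one$value), tolerance = 1e-8)
})

test_that("a singular fit degenerates to ordinary least squares", {
  tab <- simulate_metric_cohort(n_per_group = 4, days = 1:6,
                                intercept_sd = 0, residual_sd = 0.05, seed = 2)
  r <- suppressMessages(fit_lmm(tab))
  expect_true(attr(r, "singular"))
  ols <- lm(value ~ factor(group, levels = c("sham", "TAC")) + day,
            data = as.data.frame(tab))
  expect_equal(r$estimate, unname(coef(ols)), tolerance = 1e-8)
})

test_that("the mixed model recovers simulated fixed effects with noise", {
  tab <- simulate_metric_cohort(seed = 42)
  r <- suppressMessages(fit_lmm(tab))
  g <- r[r$effect == "group", ]
  expect_lt(g$ci_low, -0.14 + 0.05)
  expect_gt(g$ci_high, -0.14 - 0.05)
  expect_lt(g$p_value, 1e-6)
  expect_true(is.finite(g$df))
})

test_that("ICC(A,1) matches its frozen cross-implementation oracle", {
  set.seed(42)
  n <- 12
  subj <- rnorm(n, 20, 3)
  m <- round(cbind(subj + rnorm(n, 0.5, 1), subj + rnorm(n, 0, 1)), 6)
  r <- icc_agreement(m)
  # frozen reference values from an independent ICC implementation
  expect_equal(r$estimate, 0.834225, tolerance = 1e-5)
  expect_equal(r$statistic, 10.226001, tolerance = 1e-5)
  expect_equal(r$p_value, 0.000284, tolerance = 1e-2)
  expect_equal(r$ci_low, 0.51, tolerance = 0.01)
  expect_equal(r$ci_high, 0.95, tolerance = 0.01)
})

test_that("ICC hits its analytic limits", {
  set.seed(3)
  base <- rnorm(10, 5, 2)
  perfect <- cbind(base, base, base)
  r1 <- icc_agreement(perfect)
  expect_equal(r1$estimate, 1)
  expect_equal(c(r1$ci_low, r1$ci_high), c(1, 1))

  expect_error(icc_agreement(matrix(1, 10, 2)), class = "ivsi_domain_error")
  expect_error(icc_agreement(matrix(rnorm(8), 4, 2)),
               class = "ivsi_sample_size_error")

  # no subject effect: ICC near zero
  set.seed(11)
  r0 <- icc_agreement(matrix(rnorm(400), 200, 2))
  expect_lt(abs(r0$estimate), 0.15)

  # variance-ratio ground truth: sigma2_subject 9, sigma2_error 1 -> 0.9
  set.seed(12)
  s <- rnorm(500, 0, 3)
  m9 <- cbind(s + rnorm(500), s + rnorm(500))
  expect_equal(icc_agreement(m9)$estimate, 0.9, tolerance = 0.05)
})

test_that("Bland-Altman limits follow the paired-difference distribution", {
  x <- c(1, 2, 3, 4, 5)
  b0 <- bland_altman(x, x)
  expect_equal(b0$bias, 0)
  expect_equal(c(b0$loa_low, b0$loa_high), c(0, 0))

  b2 <- bland_altman(x, x + 2)
  expect_equal(b2$bias, -2)
  expect_equal(c(b2$loa_low, b2$loa_high), c(-2, -2))

  set.seed(21)
  n <- 1e5
  xx <- rnorm(n, 10, 2)
  b <- bland_altman(xx, xx + rnorm(n))
  expect_equal(b$loa_low, -1.96, tolerance = 0.03 / 1.96)
  expect_equal(b$loa_high, 1.96, tolerance = 0.03 / 1.96)

  expect_error(bland_altman(1:2, 1:2), class = "ivsi_sample_size_error")
})
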