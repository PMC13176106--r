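# Independent oracles used across the suite. These deliberately avoid the
# package's own numerical kernels.

# Brute-force Benjamini-Hochberg step-up: adj_(i) = min_{j >= i} p_(j) m / j
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  po <- p[o]
  adj <- vapply(seq_len(m), function(i) min(1, min(po[i:m] * m / (i:m))),
                numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Direct evaluation of the Welch statistic, Welch-Satterthwaite df and
# two-sided p from first principles
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Exact power of the two-sample two-tailed t-test via the noncentral t
noncentral_t_power <- function(n, d, alpha = 0.05, tails = 2) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  if (tails == 2) {
    q <- qt(1 - alpha / 2, df)
    1 - pt(q, df, ncp) + pt(-q, df, ncp)
  } else {
    1 - pt(qt(1 - alpha, df), df, ncp)
  }
}

# Analytic minimum of the second strain derivative inside IVRT for the
# smooth-onset exponential relaxation law S = P exp(-u^3 / (3 w^2 tau)):
# substituting v = u / (w^2 tau)^(1/3) reduces S'' to a universal shape
# whose minimiser solves v^6 - 6 v^3 + 2 = 0, v^3 = 3 - sqrt(7).
closed_form_min_accel <- function(peak, gain, ivrt_s, tau_s) {
  v <- (3 - sqrt(7))^(1 / 3)
  q <- exp(-v^3 / 3) * (v^4 - 2 * v)
  peak * gain * q / (ivrt_s^2 * tau_s)^(2 / 3)
}

# Dense-grid numerical oracle: evaluate the continuous cycle law at
# `fr` Hz, second-difference it, and take the IVRT minimum. Uses plain
# diff() so it shares no code with the pipeline's differentiator.
dense_min_accel_oracle <- function(params, segment_id = 1, fr = 10000) {
  cf <- cycle_strain_closed_form(params)
  lmk <- cf$landmarks
  h <- 1 / fr
  t <- seq(0, lmk$T - h, by = h)
  s <- cf$strain(t, segment_id = segment_id)
  acc <- diff(diff(s)) / h^2 # centred on t[2:(n-1)]
  tc <- t[2:(length(t) - 1)]
  min(acc[tc >= lmk$avc & tc <= lmk$mvo])
}

# trapezoidal cumulative integral on a uniform grid
cumtrapz_vec <- function(x, h) c(0, cumsum((x[-1] + x[-length(x)]) / 2 * h))

# small raw-strain fixture trace
make_sine_trace <- function(freq = 5, fs = 1000, dur = 1, amp = 1,
                            kind = "strain") {
  t <- seq(0, dur, by = 1 / fs)
  strain_trace(t, amp * sin(2 * pi * freq * t), "radial", "midwall", 1, kind)
}
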