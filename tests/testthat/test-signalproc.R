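test_that("the Butterworth filter has unit DC gain and rejects bad cutoffs", {
  t <- seq(0, 0.5, by = 1e-3)
  const <- strain_trace(t, rep(3.7, length(t)), "radial", "midwall", 1, "strain")
  for (mode in c("zero_phase", "single_pass")) {
    out <- butterworth_lowpass(const, filter_spec(application = mode))
    expect_equal(out$values, const$values, tolerance = 1e-6)
  }
  expect_error(butterworth_lowpass(const, filter_spec(cutoff_hz = 500)),
               class = "ivsi_parameter_error")
  expect_error(filter_spec(order = 0), class = "ivsi_parameter_error")
})

test_that("filtering never amplifies signal energy", {
  set.seed(404)
  for (i in 1:15) {
    t <- seq(0, 0.3, by = 1e-3)
    x <- rnorm(length(t), sd = runif(1, 0.1, 5)) + runif(1, -2, 2)
    tr <- strain_trace(t, x, "radial", "midwall", 1, "strain")
    mode <- if (i %% 2) "zero_phase" else "single_pass"
    y <- butterworth_lowpass(tr, filter_spec(application = mode))$values
    expect_lte(sum(y^2), sum(x^2) * (1 + 1e-9))
  }
})

test_that("zero-phase smoothing preserves the peak time of a symmetric pulse", {
  t <- seq(0, 0.2, by = 1e-3)
  pulse <- exp(-((t - 0.1) / 0.01)^2)
  tr <- strain_trace(t, pulse, "radial", "midwall", 1, "strain")
  y <- butterworth_lowpass(tr, filter_spec(application = "zero_phase"))$values
  expect_lte(abs(which.max(y) - which.max(pulse)), 1L)
  # the causal single pass, by contrast, delays the peak
  y1 <- butterworth_lowpass(tr, filter_spec(application = "single_pass"))$values
  expect_gt(which.max(y1), which.max(pulse) + 1L)
})

test_that("differentiation is exact on polynomials and accurate on sinusoids", {
  t <- seq(0, 1, by = 1e-3)
  ramp <- strain_trace(t, 4.2 * t, "radial", "midwall", 1, "strain")
  expect_equal(differentiate(ramp)$values, rep(4.2, length(t)))
  const <- strain_trace(t, rep(1, length(t)), "radial", "midwall", 1, "strain")
  expect_equal(differentiate(const)$values, rep(0, length(t)))

  sine <- make_sine_trace(freq = 5)
  d <- differentiate(sine)
  expect_lt(max(abs(d$values - 10 * pi * cos(2 * pi * 5 * sine$time))),
            1e-3 * 10 * pi)

  # kind and unit tags advance through the derivative chain
  expect_equal(d$kind, "strain_rate")
  expect_equal(d$unit, "%/s")
  dd <- differentiate(d)
  expect_equal(dd$kind, "acceleration")
  expect_equal(dd$unit, "%/s^2")

  short <- strain_trace(c(0, 1e-3), c(0, 1), "radial", "midwall", 1, "strain")
  expect_error(differentiate(short), class = "ivsi_format_error")
})

test_that("differentiate inverts trapezoidal integration to second order", {
  t <- seq(0, 1, by = 1e-3)
  x <- sin(2 * pi * 3 * t) + 0.5 * cos(2 * pi * 7 * t)
  xi <- cumtrapz_vec(x, 1e-3)
  tr <- strain_trace(t, xi, "radial", "midwall", 1, "strain")
  back <- differentiate(tr)$values
  expect_lt(max(abs(back - x)), 5e-4 * max(abs(x)))
})

test_that("phase windows snap to samples and enforce resolution", {
  t <- seq(0, 0.139, by = 1e-3)
  tr <- strain_trace(t, sin(20 * t), "radial", "midwall", 1, "strain")
  ev <- valve_events(0, 0.050, 0.068, 0.139, e_end = 0.095)
  w <- window_trace(tr, ev, "ivrt")
  expect_length(w$trace$values, 19L) # inclusive bounds at 1000 Hz
  expect_equal(w$window$t_start, 0.050)
  expect_equal(w$window$t_end, 0.068)

  sys <- window_trace(tr, ev, "systole")
  expect_equal(sys$trace$time[1], 0)
  ed <- window_trace(tr, ev, "early_diastole")
  expect_equal(ed$window$t_end, 0.095)
  expect_error(window_trace(tr, valve_events(0, 0.050, 0.068, 0.139), "early_diastole"),
               class = "ivsi_event_error")

  # an 18 ms IVRT at 100 Hz spans < 3 samples: unresolvable
  t100 <- seq(0, 0.13, by = 1e-2)
  tr100 <- strain_trace(t100, sin(20 * t100), "radial", "midwall", 1, "strain")
  expect_error(window_trace(tr100, valve_events(0, 0.050, 0.068, 0.130), "ivrt"),
               class = "ivsi_resolution_error")

  # windowed simulator strain starts at the closed-form value at AVC
  p <- cycle_params(noise_sd = 0)
  cyc <- simulate_cycle(p, directions = "radial")
  cf <- cycle_strain_closed_form(p)
  w2 <- window_trace(cyc$traces[[1]], cyc$events, "ivrt")
  expect_equal(w2$trace$values[1],
               cf$strain(w2$trace$time[1], segment_id = 1))
})

test_that("ivsi_extract computes windowed extrema and accelerations", {
  t <- seq(0, 0.139, by = 1e-3)
  ev <- valve_events(0, 0.050, 0.068, 0.139)

  const_sr <- strain_trace(t, rep(1, length(t)), "radial", "midwall", 1,
                           "strain_rate")
  m <- ivsi_extract(list(const_sr), ev)
  seg <- m[!is.na(m$segment_id), ]
  expect_equal(seg$value[seg$metric == "max_value"], 1)
  expect_equal(seg$value[seg$metric == "min_value"], 1)
  expect_equal(seg$value[seg$metric == "max_accel"], 0)
  expect_equal(seg$value[seg$metric == "min_accel"], 0)

  # linear strain rate: acceleration is its constant slope
  lin_sr <- strain_trace(t, 3 * t, "radial", "midwall", 1, "strain_rate")
  m2 <- ivsi_extract(list(lin_sr), ev)
  s2 <- m2[!is.na(m2$segment_id), ]
  expect_equal(s2$value[s2$metric == "min_accel"], 3)
  expect_equal(s2$value[s2$metric == "max_accel"], 3)

  # quadratic strain: acceleration (second derivative) is constant 2
  quad <- strain_trace(t, t^2, "radial", "midwall", 1, "strain")
  m3 <- ivsi_extract(list(quad), ev)
  s3 <- m3[!is.na(m3$segment_id), ]
  expect_equal(s3$value[s3$metric == "min_accel"], 2)
  expect_equal(s3$value[s3$metric == "max_accel"], 2)
  expect_equal(s3$value[s3$metric == "max_value"], 0.068^2)

  # absolute variants mirror signed ones
  neg <- strain_trace(t, -3 - t, "radial", "midwall", 2, "strain_rate")
  m4 <- ivsi_extract(list(neg), ev)
  expect_equal(m4$abs_value, abs(m4$value))
})

test_that("ivsi metrics are scale-equivariant and shift-invariant", {
  p <- cycle_params(noise_sd = 0.3, seed = 77)
  cyc <- simulate_cycle(p, directions = "radial")
  m0 <- process_cycle(cyc$traces, cyc$events, filter = filter_spec())

  # scaling all trace values by c scales every metric by c
  c_ <- 3.5
  scaled <- lapply(cyc$traces, function(tr) { tr$values <- c_ * tr$values; tr })
  m1 <- process_cycle(scaled, cyc$events, filter = filter_spec())
  expect_equal(m1$value, c_ * m0$value, tolerance = 1e-10)

  # shifting trace and events together changes nothing
  dt <- 0.250
  shifted <- lapply(cyc$traces, function(tr) { tr$time <- tr$time + dt; tr })
  ev2 <- valve_events(cyc$events$cycle_start + dt, cyc$events$avc + dt,
                      cyc$events$mvo + dt, cyc$events$cycle_end + dt,
                      e_end = cyc$events$e_end + dt)
  m2 <- process_cycle(shifted, ev2, filter = filter_spec())
  expect_equal(m2$value, m0$value, tolerance = 1e-9)
})

test_that("pipeline metrics match the dense closed-form oracle on noiseless cycles", {
  p <- cycle_params(noise_sd = 0)
  cyc <- simulate_cycle(p, directions = "radial")
  m <- process_cycle(cyc$traces, cyc$events, filter = NULL)
  for (k in c(1L, 4L)) {
    got <- m$value[m$kind == "strain_rate" & m$metric == "min_accel" &
                     !is.na(m$segment_id) & m$segment_id == k]
    expect_equal(got, dense_min_accel_oracle(p, segment_id = k),
                 tolerance = 0.05)
    # and the dense oracle itself matches the analytic minimum
    expect_equal(dense_min_accel_oracle(p, segment_id = k),
                 closed_form_min_accel(p$peak_radial_strain,
                                       p$segment_gains[k],
                                       p$ivrt_ms / 1000, p$tau_active / 1000),
                 tolerance = 1e-3)
  }
})

test_that("peak metrics respect the phase-specific sign conventions", {
  t <- seq(0, 0.139, by = 1e-3)
  ev <- valve_events(0, 0.050, 0.068, 0.139, e_end = 0.100)

  inc <- strain_trace(t, 10 * t, "radial", "midwall", 1, "strain")
  expect_equal(peak_phase_metric(inc, ev, "systole"), 10 * 0.050)

  # E-wave raised cosine dipping to -a peaks at the wave centre
  a <- 4
  ew <- numeric(length(t))
  i <- t >= 0.068 & t <= 0.100
  ew[i] <- -a * (1 - cos(2 * pi * (t[i] - 0.068) / 0.032)) / 2
  sr <- strain_trace(t, ew, "radial", "midwall", 1, "strain_rate")
  expect_equal(peak_phase_metric(sr, ev, "early_diastole"), -a)

  # prolonged relaxation lowers the early-diastolic peak strain rate
  peak_sr <- function(tau) {
    cyc <- simulate_cycle(cycle_params(tau_active = tau, noise_sd = 0),
                          directions = "radial")
    abs(average_peak(lapply(cyc$traces, differentiate), cyc$events,
                     "early_diastole"))
  }
  expect_gt(peak_sr(8), peak_sr(16))
})
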