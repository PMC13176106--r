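# Parametric murine cardiac-cycle simulator.
#
# One cycle is pieced together from C1-continuous phases so that the second
# derivative of strain (the headline IVRT metric) is bounded and stable
# under grid refinement:
#   * systole (IVCT + ejection): cosine ramp 0 -> peak, zero slope at both
#     ends;
#   * active relaxation from AVC: S = peak * exp(-phi(u)/tau) with a cubic
#     onset phi(u) = u^3/(3 w^2) for u <= w (w = IVRT duration) continuing
#     linearly phi(u) = u - 2w/3 beyond MVO. Strain rate is zero at AVC,
#     peaks (most negative) exactly at MVO, and decays exponentially with
#     time constant tau through the E wave;
#   * late diastole: a raised-cosine taper returns strain to exactly zero at
#     cycle end, plus a small raised-cosine atrial-kick bump.
#
# The acceleration of the radial strain rate then attains its minimum inside
# the IVRT window with the exact closed form
#   min accel = -q * peak * gain / (w^2 * tau)^(2/3),
#   q = exp(-v^3/3) * (2 v - v^4), v^3 = 3 - sqrt(7)  (q ~= 1.0346),
# strictly decreasing in magnitude as tau grows: prolonged active
# relaxation (the TAC phenotype) lowers |min accel of radial strain rate|.

#' Cardiac-cycle simulation parameters
#'
#' Defaults describe a healthy anaesthetised mouse: heart rate 420 bpm
#' (target range 400-450), acquisition at 1000 Hz (well above the >200
#' frames/s floor needed to resolve a ~18 ms murine IVRT), peak radial
#' strain 25% and an active-relaxation time constant of 8 ms. Phase
#' fractions are of the full cycle; the IVRT is given in milliseconds and
#' the diastasis absorbs the remainder unless given explicitly.
#'
#' @param heart_rate heart rate in bpm.
#' @param frame_rate sampling rate in Hz; must exceed 200.
#' @param peak_radial_strain systolic radial strain plateau in % (positive;
#'   contraction is positive by the sign convention).
#' @param ivct_frac,ejection_frac,e_wave_frac,a_wave_frac phase durations as
#'   fractions of the cycle.
#' @param ivrt_ms isovolumic relaxation time in ms (AVC to MVO).
#' @param diastasis_frac diastasis fraction; `NULL` (default) derives it as
#'   the remainder. If supplied, all phase durations must sum to the cycle
#'   length.
#' @param tau_active exponential active-relaxation time constant in ms
#'   governing strain decay through IVRT and the E wave; the simulator's
#'   stand-in for the speed of sarcoplasmic-reticulum calcium reuptake.
#' @param segment_gains multiplicative per-segment amplitude factors (length
#'   defines the segment count; default 6 segments with mild heterogeneity).
#' @param layer_gains named gains for endocardial/epicardial layers
#'   (endocardial deformation exceeds epicardial).
#' @param long_ratio ratio of longitudinal to radial strain amplitude;
#'   longitudinal strain is mirrored in sign.
#' @param wall_mm reference wall dimension (mm) converting strain rate to
#'   tissue velocity.
#' @param a_wave_amp_frac atrial-kick bump amplitude as a fraction of peak
#'   strain.
#' @param p_peak,p_avc,p_dia left-ventricular pressures (mmHg) at systolic
#'   peak, at AVC and at the diastolic floor, for the pressure trace.
#' @param noise_sd additive Gaussian noise SD on emitted samples (strain %;
#'   the same numeric SD is applied to velocity traces in mm/s).
#' @param seed optional integer seed making a cycle reproducible on its own;
#'   leave `NULL` to draw from the surrounding RNG stream (as
#'   [simulate_cohort()] does).
#'
#' @return A validated list of class `cycle_params`.
#' @export
cycle_params <- function(heart_rate = 420, frame_rate = 1000,
                         peak_radial_strain = 25,
                         ivct_frac = 0.07, ejection_frac = 0.32,
                         ivrt_ms = 18, e_wave_frac = 0.18,
                         diastasis_frac = NULL, a_wave_frac = 0.10,
                         tau_active = 8,
                         segment_gains = c(1.12, 1.05, 0.97, 0.88, 0.95, 1.03),
                         layer_gains = c(endocardial = 1.1, epicardial = 0.9),
                         long_ratio = 0.6, wall_mm = 2, a_wave_amp_frac = 0.06,
                         p_peak = 100, p_avc = 70, p_dia = 5,
                         noise_sd = 0, seed = NULL) {
  if (frame_rate <= 200) {
    stop_ivsi("frame_rate must exceed 200 Hz to resolve the IVRT window", "parameter")
  }
  if (heart_rate <= 0 || tau_active <= 0 || peak_radial_strain <= 0) {
    stop_ivsi("heart_rate, tau_active and peak_radial_strain must be positive",
              "parameter")
  }
  cycle_s <- 60 / heart_rate
  ivrt_frac <- (ivrt_ms / 1000) / cycle_s
  fr <- c(ivct_frac, ejection_frac, ivrt_frac, e_wave_frac, a_wave_frac)
  if (any(fr <= 0) || ivrt_ms <= 0) {
    stop_ivsi("all phase durations must be positive", "parameter")
  }
  if (is.null(diastasis_frac)) {
    diastasis_frac <- 1 - sum(fr)
    if (diastasis_frac < 0) {
      stop_ivsi("phase fractions exceed the cycle length", "parameter")
    }
  } else if (abs(sum(fr) + diastasis_frac - 1) > 1e-6) {
    stop_ivsi("phase fractions do not sum to 1", "parameter")
  }
  if (noise_sd < 0) stop_ivsi("noise_sd must be non-negative", "parameter")
  if (any(segment_gains <= 0)) stop_ivsi("segment gains must be positive", "parameter")
  structure(list(
    heart_rate = heart_rate, frame_rate = frame_rate,
    peak_radial_strain = peak_radial_strain,
    ivct_frac = ivct_frac, ejection_frac = ejection_frac,
    ivrt_ms = ivrt_ms, e_wave_frac = e_wave_frac,
    diastasis_frac = diastasis_frac, a_wave_frac = a_wave_frac,
    tau_active = tau_active, segment_gains = segment_gains,
    layer_gains = layer_gains, long_ratio = long_ratio, wall_mm = wall_mm,
    a_wave_amp_frac = a_wave_amp_frac,
    p_peak = p_peak, p_avc = p_avc, p_dia = p_dia,
    noise_sd = noise_sd, seed = seed,
    cycle_s = cycle_s
  ), class = "cycle_params")
}

# phase landmarks (seconds) implied by a cycle_params object
cycle_landmarks <- function(p) {
  T <- p$cycle_s
  avc <- (p$ivct_frac + p$ejection_frac) * T
  ivrt <- p$ivrt_ms / 1000
  mvo <- avc + ivrt
  e_end <- mvo + p$e_wave_frac * T
  a_start <- T - p$a_wave_frac * T
  list(T = T, avc = avc, ivrt = ivrt, mvo = mvo, e_end = e_end,
       a_start = a_start)
}

# dimensionless cycle shape and its analytic time derivative (1/s);
# multiplied by the signed amplitude to give strain / strain rate
.cycle_shape <- function(t, p, deriv = FALSE) {
  lm <- cycle_landmarks(p)
  tau <- p$tau_active / 1000
  w <- lm$ivrt
  out <- numeric(length(t))
  sys <- t < lm$avc
  if (deriv) {
    out[sys] <- pi * sin(pi * t[sys] / lm$avc) / (2 * lm$avc)
  } else {
    out[sys] <- (1 - cos(pi * t[sys] / lm$avc)) / 2
  }
  td <- t[!sys]
  u <- td - lm$avc
  phi <- ifelse(u <= w, u^3 / (3 * w^2), u - 2 * w / 3)
  base <- exp(-phi / tau)
  late <- td >= lm$a_start
  x <- (td - lm$a_start) / (lm$T - lm$a_start) # in [0,1] over the A wave
  b <- ifelse(late, (1 + cos(pi * x)) / 2, 1)
  bump <- ifelse(late, p$a_wave_amp_frac * (1 - cos(2 * pi * x)) / 2, 0)
  if (deriv) {
    dphi <- ifelse(u <= w, u^2 / w^2, 1)
    dbase <- -dphi / tau * base
    db <- ifelse(late, -pi * sin(pi * x) / (2 * (lm$T - lm$a_start)), 0)
    dbump <- ifelse(late,
                    p$a_wave_amp_frac * pi * sin(2 * pi * x) / (lm$T - lm$a_start),
                    0)
    out[!sys] <- dbase * b + base * db + dbump
  } else {
    out[!sys] <- base * b + bump
  }
  out
}

signed_amplitude <- function(p, segment_id, direction, layer) {
  g <- p$segment_gains[segment_id]
  lg <- if (layer == "midwall") 1 else unname(p$layer_gains[layer])
  s <- if (direction == "longitudinal") -p$long_ratio else 1
  p$peak_radial_strain * g * lg * s
}

#' Closed-form noiseless cycle kinematics
#'
#' Returns the continuous strain law (and its analytic time derivative)
#' underlying [simulate_cycle()], evaluable on any time grid. This is the
#' reference against which discretised pipeline output can be checked at
#' arbitrary density.
#'
#' @param params a [cycle_params()] object.
#' @return A list with functions `strain(t, segment_id, direction, layer)`
#'   (%) and `strain_rate(t, ...)` (%/s), the [valve_events()] of the
#'   cycle, and the phase landmark times.
#' @export
cycle_strain_closed_form <- function(params) {
  lm <- cycle_landmarks(params)
  ev <- valve_events(0, lm$avc, lm$mvo, lm$T, e_end = lm$e_end)
  list(
    strain = function(t, segment_id = 1, direction = "radial", layer = "midwall") {
      signed_amplitude(params, segment_id, direction, layer) *
        .cycle_shape(t, params, deriv = FALSE)
    },
    strain_rate = function(t, segment_id = 1, direction = "radial", layer = "midwall") {
      signed_amplitude(params, segment_id, direction, layer) *
        .cycle_shape(t, params, deriv = TRUE)
    },
    events = ev, landmarks = lm
  )
}

.cycle_pressure <- function(t, p) {
  lm <- cycle_landmarks(p)
  tau <- p$tau_active / 1000
  t_pk <- 0.55 * lm$avc
  out <- numeric(length(t))
  i1 <- t < t_pk
  out[i1] <- p$p_dia + (p$p_peak - p$p_dia) * (1 - cos(pi * t[i1] / t_pk)) / 2
  i2 <- !i1 & t < lm$avc
  out[i2] <- p$p_avc + (p$p_peak - p$p_avc) *
    (1 + cos(pi * (t[i2] - t_pk) / (lm$avc - t_pk))) / 2
  i3 <- t >= lm$avc & t <= lm$mvo # isovolumic decay: pure exponential
  out[i3] <- p$p_avc * exp(-(t[i3] - lm$avc) / tau)
  i4 <- t > lm$mvo
  p_mvo <- p$p_avc * exp(-lm$ivrt / tau)
  out[i4] <- p$p_dia + (p_mvo - p$p_dia) * exp(-(t[i4] - lm$mvo) / tau)
  out
}

#' Simulate one cardiac cycle
#'
#' Generates per-segment strain traces (and optionally tissue-velocity
#' traces and a left-ventricular pressure trace) for a single cycle, plus
#' the valve events delimiting its phases. With `noise_sd = 0` the sampled
#' traces equal the closed-form kinematics of
#' [cycle_strain_closed_form()] exactly.
#'
#' @param params a [cycle_params()] object.
#' @param directions directions to emit (`"radial"`, `"longitudinal"`).
#' @param layers layers for the strain traces (default midwall).
#' @param include_velocity also emit endocardial and epicardial tissue
#'   velocity traces (analytic strain-rate times the wall dimension).
#' @param include_pressure also emit the pressure trace.
#'
#' @return An object of class `ivsi_cycle`: a list with `traces` (named
#'   list of [strain_trace()]), `events` ([valve_events()] with `e_end`),
#'   `pressure` (or `NULL`) and `params`.
#' @export
#' @examples
#' cyc <- simulate_cycle(cycle_params(noise_sd = 0))
#' cyc$events$ivrt * 1000 # == ivrt_ms
simulate_cycle <- function(params = cycle_params(),
                           directions = c("radial", "longitudinal"),
                           layers = "midwall",
                           include_velocity = FALSE,
                           include_pressure = TRUE) {
  directions <- match.arg(directions, .directions, several.ok = TRUE)
  layers <- match.arg(layers, .layers, several.ok = TRUE)
  lm <- cycle_landmarks(params)
  fr <- params$frame_rate
  n <- floor(fr * lm$T + 1e-9)
  t <- (seq_len(n) - 1) / fr
  shape <- .cycle_shape(t, params, deriv = FALSE)
  dshape <- if (include_velocity) .cycle_shape(t, params, deriv = TRUE) else NULL
  nseg <- length(params$segment_gains)
  ev <- valve_events(0, lm$avc, lm$mvo, lm$T, e_end = lm$e_end)

  with_seed(params$seed, {
    traces <- list()
    for (dir in directions) {
      for (lay in layers) {
        for (k in seq_len(nseg)) {
          v <- signed_amplitude(params, k, dir, lay) * shape
          if (params$noise_sd > 0) v <- v + rnorm(n, 0, params$noise_sd)
          traces[[trace_header(dir, lay, k, "strain")]] <-
            strain_trace(t, v, dir, lay, k, "strain")
        }
      }
      if (include_velocity) {
        for (lay in c("endocardial", "epicardial")) {
          for (k in seq_len(nseg)) {
            v <- signed_amplitude(params, k, dir, lay) * dshape *
              params$wall_mm / 100
            if (params$noise_sd > 0) v <- v + rnorm(n, 0, params$noise_sd)
            traces[[trace_header(dir, lay, k, "velocity")]] <-
              strain_trace(t, v, dir, lay, k, "velocity")
          }
        }
      }
    }
    pressure <- if (include_pressure) {
      pressure_trace(t, .cycle_pressure(t, params))
    }
    structure(list(traces = traces, events = ev, pressure = pressure,
                   params = params),
              class = "ivsi_cycle")
  })
}

#' @export
print.ivsi_cycle <- function(x, ...) {
  cat(sprintf(
    "<ivsi_cycle> %d traces, %d samples @ %g Hz; HR %g bpm, IVRT %.1f ms, tau %.1f ms\n",
    length(x$traces), length(x$traces[[1]]$time), x$params$frame_rate,
    x$params$heart_rate, x$events$ivrt * 1000, x$params$tau_active
  ))
  invisible(x)
}

#' Cohort simulation parameters
#'
#' Defaults mirror the longitudinal study design the pipeline targets: two
#' groups of 10 animals (sham and TAC at 1:1), imaged daily over
#' postoperative days 1-14. Pressure overload is modelled purely as a
#' prolongation of the active-relaxation time constant (sham 8 ms, TAC
#' 16 ms), with optional late-stage systolic decline via
#' `tac_peak_decline`. Biological variability enters as a Gaussian
#' between-animal intercept and a day-level residual on tau; measurement
#' noise as additive Gaussian noise on the traces.
#'
#' @param n_per_group animals per group (>= 2).
#' @param days integer vector of postoperative days.
#' @param tau_sham,tau_tac active-relaxation time constants (ms).
#' @param tau_between_sd between-animal SD of the tau intercept (ms).
#' @param tau_residual_sd day-level residual SD of tau (ms).
#' @param tau_trajectory optional `function(day)` returning an additive tau
#'   offset (ms) applied to TAC animals, for progressive phenotypes.
#' @param tac_peak_decline fractional peak-strain reduction per day in TAC
#'   animals (late-stage systolic decline; default 0 = none).
#' @param noise_sd additive trace noise SD (% strain).
#' @param cycle baseline [cycle_params()] shared by all animals.
#' @param seed integer seed; the whole cohort is reproducible under it.
#' @return A validated list of class `cohort_params`.
#' @export
cohort_params <- function(n_per_group = 10, days = 1:14,
                          tau_sham = 8, tau_tac = 16,
                          tau_between_sd = 0.8, tau_residual_sd = 0.8,
                          tau_trajectory = NULL, tac_peak_decline = 0,
                          noise_sd = 0.5,
                          cycle = cycle_params(), seed = 1) {
  if (n_per_group < 2) stop_ivsi("n_per_group must be at least 2", "parameter")
  if (tau_sham <= 0 || tau_tac <= 0) stop_ivsi("tau values must be positive", "parameter")
  if (!length(days)) stop_ivsi("`days` must be non-empty", "parameter")
  structure(list(
    n_per_group = as.integer(n_per_group), days = as.integer(days),
    tau_sham = tau_sham, tau_tac = tau_tac,
    tau_between_sd = tau_between_sd, tau_residual_sd = tau_residual_sd,
    tau_trajectory = tau_trajectory, tac_peak_decline = tac_peak_decline,
    noise_sd = noise_sd, cycle = cycle, seed = seed
  ), class = "cohort_params")
}

#' Simulate a sham-vs-TAC longitudinal cohort
#'
#' Draws per-animal tau intercepts, then simulates one cardiac cycle per
#' animal and day with day-level tau jitter and trace noise. The full
#' latent ground truth (every realised tau and peak strain) is recorded so
#' downstream recovery can be checked against it.
#'
#' @param params a [cohort_params()] object.
#' @param directions trace directions to emit per cycle (default radial
#'   only, which carries the headline metric).
#' @param write_dir optional directory: per-run trace and event CSVs, a
#'   cohort-skeleton CSV and a `ground_truth.json` are written there in the
#'   package's text dialects.
#' @return An object of class `ivsi_cohort_sim`: `runs` (list with one
#'   element per animal-day holding `animal_id`, `group`, `day` and the
#'   simulated `cycle`), `truth` (data frame of latent parameters) and
#'   `params`.
#' @export
simulate_cohort <- function(params = cohort_params(), directions = "radial",
                            write_dir = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  with_seed(params$seed, {
    ids <- c(sprintf("sham_%02d", seq_len(params$n_per_group)),
             sprintf("tac_%02d", seq_len(params$n_per_group)))
    groups <- rep(c("sham", "TAC"), each = params$n_per_group)
    tau_base <- ifelse(groups == "TAC", params$tau_tac, params$tau_sham) +
      rnorm(length(ids), 0, params$tau_between_sd)
    tau_base <- pmax(tau_base, 1)
    runs <- vector("list", length(ids) * length(params$days))
    truth <- vector("list", length(runs))
    r <- 0L
    for (i in seq_along(ids)) {
      for (d in params$days) {
        tau_id <- tau_base[i] + rnorm(1, 0, params$tau_residual_sd)
        if (groups[i] == "TAC" && !is.null(params$tau_trajectory)) {
          tau_id <- tau_id + params$tau_trajectory(d)
        }
        tau_id <- max(tau_id, 1)
        peak <- params$cycle$peak_radial_strain
        if (groups[i] == "TAC" && params$tac_peak_decline > 0) {
          peak <- peak * max(1 - params$tac_peak_decline * d, 0.2)
        }
        cp <- params$cycle
        cp$tau_active <- tau_id
        cp$peak_radial_strain <- peak
        cp$noise_sd <- params$noise_sd
        cp$seed <- NULL # draw from the cohort stream
        cyc <- simulate_cycle(cp, directions = directions,
                              include_pressure = FALSE)
        r <- r + 1L
        runs[[r]] <- list(animal_id = ids[i], group = groups[i], day = d,
                          cycle = cyc)
        truth[[r]] <- data.frame(animal_id = ids[i], group = groups[i],
                                 day = d, tau_ms = tau_id,
                                 tau_base_ms = tau_base[i],
                                 peak_strain = peak,
                                 stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truth)
    sim <- structure(list(runs = runs, truth = truth, params = params),
                     class = "ivsi_cohort_sim")
    if (!is.null(write_dir)) write_cohort_sim(sim, write_dir)
    sim
  })
}

#' @export
print.ivsi_cohort_sim <- function(x, ...) {
  cat(sprintf(
    "<ivsi_cohort_sim> %d animals x %d days (%d runs); tau sham %.1f / TAC %.1f ms\n",
    2L * x$params$n_per_group, length(x$params$days), length(x$runs),
    x$params$tau_sham, x$params$tau_tac
  ))
  invisible(x)
}

# write a simulated cohort in the package's text dialects
write_cohort_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  skel <- list()
  for (run in sim$runs) {
    stem <- sprintf("%s_day%02d", run$animal_id, run$day)
    write_trace_table(run$cycle$traces, file.path(dir, paste0(stem, "_traces.csv")))
    write_valve_events(run$cycle$events, file.path(dir, paste0(stem, "_events.csv")))
    skel[[stem]] <- data.frame(animal_id = run$animal_id, group = run$group,
                               day = run$day, stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, skel), file.path(dir, "cohort.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Simulate a metric-level longitudinal cohort table
#'
#' Generates a long-format cohort table directly on the metric scale from a
#' linear mixed-effects ground truth: animal-level random intercepts, a
#' group effect, a linear day slope and i.i.d. residuals. Used to check
#' confidence-interval calibration of [fit_lmm()] against known effects
#' without the expense of trace-level simulation.
#'
#' @param n_per_group animals per group.
#' @param days vector of measurement days.
#' @param intercept fixed intercept (sham at day 0).
#' @param group_effect additive TAC effect.
#' @param day_slope additive per-day slope.
#' @param intercept_sd between-animal random-intercept SD.
#' @param residual_sd residual SD.
#' @param metric_name metric label in the emitted table.
#' @param seed optional seed.
#' @return A validated cohort table (see [validate_cohort_table()]).
#' @export
simulate_metric_cohort <- function(n_per_group = 10, days = 1:14,
                                   intercept = 1, group_effect = -0.14,
                                   day_slope = -0.004,
                                   intercept_sd = 0.02, residual_sd = 0.02,
                                   metric_name = "metric", seed = NULL) {
  with_seed(seed, {
    ids <- c(sprintf("sham_%02d", seq_len(n_per_group)),
             sprintf("tac_%02d", seq_len(n_per_group)))
    groups <- rep(c("sham", "TAC"), each = n_per_group)
    u <- rnorm(length(ids), 0, intercept_sd)
    tab <- expand.grid(animal_id = ids, day = days, stringsAsFactors = FALSE)
    i <- match(tab$animal_id, ids)
    tab$group <- groups[i]
    tab$metric_name <- metric_name
    tab$value <- intercept + group_effect * (tab$group == "TAC") +
      day_slope * tab$day + u[i] + rnorm(nrow(tab), 0, residual_sd)
    validate_cohort_table(tab[, c("animal_id", "group", "day", "metric_name", "value")])
  })
}
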