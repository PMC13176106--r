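# numerical differentiation: second-order central differences in the
# interior, second-order one-sided stencils at the ends (the first-order
# one-sided forms would degrade endpoint accuracy to O(dt))
deriv_vec <- function(x, h) {
  n <- length(x)
  if (n < 3) stop_ivsi("differentiation needs at least 3 samples", "format")
  c(
    (-3 * x[1] + 4 * x[2] - x[3]) / (2 * h),
    (x[3:n] - x[1:(n - 2)]) / (2 * h),
    (3 * x[n] - 4 * x[n - 1] + x[n - 2]) / (2 * h)
  )
}

# kind/unit bookkeeping when a trace is differentiated in time
advance_kind <- function(kind) {
  switch(kind,
         strain = "strain_rate",
         strain_rate = "acceleration",
         velocity = "acceleration",
         acceleration = "acceleration")
}
advance_unit <- function(unit) {
  if (grepl("/s\\^([0-9]+)$", unit)) {
    k <- as.integer(sub(".*/s\\^([0-9]+)$", "\\1", unit))
    sub("/s\\^[0-9]+$", sprintf("/s^%d", k + 1L), unit)
  } else if (grepl("/s$", unit)) {
    sub("/s$", "/s^2", unit)
  } else {
    paste0(unit, "/s")
  }
}

#' Differentiate a trace in time
#'
#' Computes the time derivative by second-order finite differences
#' (central in the interior, one-sided at the ends) and advances the kind
#' and unit tags: strain (%) becomes strain rate (%/s), strain rate and
#' velocity become acceleration.
#'
#' @param trace a [strain_trace()] with at least 3 samples.
#' @return A `strain_trace` of the derived kind on the same grid.
#' @export
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' sr <- differentiate(strain_trace(t, 3 * t, "radial", "midwall", 1, "strain"))
#' range(sr$values) # constant 3
differentiate <- function(trace) {
  stopifnot(inherits(trace, "strain_trace"))
  vals <- deriv_vec(trace$values, 1 / trace$sample_rate)
  out <- trace
  out$values <- vals
  out$kind <- advance_kind(trace$kind)
  out$unit <- advance_unit(trace$unit)
  out
}

.phase_labels <- c("ivrt", "early_diastole", "systole", "full_diastole")

# indices of the samples lying inside the closed interval [b1, b2]:
# smallest i with t_i >= b1, largest with t_i <= b2, with a 1e-6-sample
# floating-point guard so boundaries landing on grid points are kept
window_indices <- function(t0, fs, n, bounds) {
  i1 <- ceiling((bounds[1] - t0) * fs - 1e-6) + 1L
  i2 <- floor((bounds[2] - t0) * fs + 1e-6) + 1L
  c(max(1L, i1), min(n, i2))
}

#' Cut a cycle-phase window out of a trace
#'
#' Window boundaries come from the valve events: `ivrt` is `[avc, mvo]`,
#' `systole` is `[cycle_start, avc]`, `early_diastole` is `[mvo, e_end]`
#' (requires `e_end` in the events) and `full_diastole` is
#' `[mvo, cycle_end]`. The sub-trace keeps every sample inside the closed
#' interval (boundary samples included, with a floating-point guard): the
#' IVRT is short and dropping boundary samples would bias the extrema.
#'
#' @param trace a [strain_trace()].
#' @param events a single-cycle [valve_events()] row.
#' @param label one of `"ivrt"`, `"early_diastole"`, `"systole"`,
#'   `"full_diastole"`.
#' @return A list with `window` (label and snapped `t_start`/`t_end`) and
#'   `trace` (the sub-trace). A window spanning fewer than 3 samples is a
#'   resolution error: the acquisition frame rate cannot resolve the
#'   phase.
#' @export
window_trace <- function(trace, events, label = "ivrt") {
  label <- match.arg(label, .phase_labels)
  stopifnot(inherits(events, "valve_events"))
  if (nrow(events) != 1) stop_ivsi("need exactly one cycle of events", "event")
  bounds <- switch(label,
    ivrt = c(events$avc, events$mvo),
    systole = c(events$cycle_start, events$avc),
    early_diastole = {
      if (is.null(events$e_end)) {
        stop_ivsi("early_diastole window requires `e_end` in the events", "event")
      }
      c(events$mvo, events$e_end)
    },
    full_diastole = c(events$mvo, events$cycle_end)
  )
  t0 <- trace$time[1]
  tn <- trace$time[length(trace$time)]
  if (bounds[1] < t0 - 0.5 / trace$sample_rate ||
      bounds[2] > tn + 0.5 / trace$sample_rate) {
    stop_ivsi(sprintf("%s window [%.4g, %.4g] s falls outside the trace span",
                      label, bounds[1], bounds[2]), "event")
  }
  idx <- window_indices(t0, trace$sample_rate, length(trace$time), bounds)
  i1 <- idx[1]
  i2 <- idx[2]
  if (i2 - i1 + 1L < 3L) {
    stop_ivsi(sprintf(
      "%s window spans only %d sample(s) at %.6g Hz; increase the frame rate",
      label, i2 - i1 + 1L, trace$sample_rate
    ), "resolution")
  }
  sub <- trace
  sub$time <- trace$time[i1:i2]
  sub$values <- trace$values[i1:i2]
  list(
    window = list(label = label, t_start = trace$time[i1], t_end = trace$time[i2]),
    trace = sub
  )
}

# how many time derivatives turn a signal into its acceleration:
# the acceleration of a signal is the first derivative of its rate curve,
# so strain needs two (strain -> strain rate -> acceleration) and strain
# rate or velocity need one
n_diff_to_accel <- function(kind) {
  switch(kind, strain = 2L, strain_rate = 1L, velocity = 1L, acceleration = 0L)
}

#' Extract IVRT extrema metrics from a set of traces
#'
#' For every input trace (already smoothed, on a common grid) the four
#' IVRT-windowed quantities are computed: maximal value, minimal value,
#' maximal acceleration and minimal acceleration, each with its absolute
#' value. Acceleration is obtained by differentiating the signal's rate
#' curve over the full cycle before windowing. Across-segment means are
#' appended per (direction, layer, kind, metric) with `segment_id = NA`.
#' The headline diastolic metric is the `min_accel` row of the radial
#' strain rate (see [headline_metric()]).
#'
#' @param traces list of [strain_trace()] objects on one grid.
#' @param events single-cycle [valve_events()].
#' @return A data frame of class `ivsi_metrics` with columns `direction`,
#'   `layer`, `kind`, `segment_id`, `metric`, `value`, `abs_value`.
#' @export
ivsi_extract <- function(traces, events) {
  if (!length(traces)) stop_ivsi("no traces supplied", "format")
  n <- length(traces)
  direction <- layer <- kind <- character(4L * n)
  segment <- integer(4L * n)
  value <- numeric(4L * n)
  metric <- rep(c("max_value", "min_value", "max_accel", "min_accel"), n)
  for (i in seq_len(n)) {
    tr <- traces[[i]]
    wv <- window_trace(tr, events, "ivrt")$trace$values
    acc <- tr
    for (k in seq_len(n_diff_to_accel(tr$kind))) acc <- differentiate(acc)
    wa <- window_trace(acc, events, "ivrt")$trace$values
    j <- 4L * (i - 1L)
    direction[j + 1:4] <- tr$direction
    layer[j + 1:4] <- tr$layer
    kind[j + 1:4] <- tr$kind
    segment[j + 1:4] <- tr$segment_id
    value[j + 1:4] <- c(max(wv), min(wv), max(wa), min(wa))
  }
  out <- data.frame(direction = direction, layer = layer, kind = kind,
                    segment_id = segment, metric = metric, value = value,
                    stringsAsFactors = FALSE)
  means <- stats::aggregate(value ~ direction + layer + kind + metric,
                            data = out, FUN = mean)
  means$segment_id <- NA_integer_
  out <- rbind(out, means[, names(out)])
  out$abs_value <- abs(out$value)
  rownames(out) <- NULL
  class(out) <- c("ivsi_metrics", "data.frame")
  out
}

#' Pull the headline metric from an extracted metrics table
#'
#' Convenience accessor for the minimal acceleration of the radial strain
#' rate during IVRT (across-segment mean by default), the most sensitive
#' early marker of impaired active relaxation.
#'
#' @param metrics an `ivsi_metrics` data frame from [ivsi_extract()].
#' @param segment_id a segment number, or `NA` (default) for the
#'   across-segment mean.
#' @param absolute return the absolute value (default) or the signed one.
#' @return A single numeric value.
#' @export
headline_metric <- function(metrics, segment_id = NA, absolute = TRUE) {
  i <- metrics$direction == "radial" & metrics$kind == "strain_rate" &
    metrics$metric == "min_accel" &
    (if (is.na(segment_id)) is.na(metrics$segment_id)
     else !is.na(metrics$segment_id) & metrics$segment_id == segment_id)
  if (sum(i) != 1) {
    stop_ivsi("headline metric not present (is a radial strain_rate trace included?)",
              "format")
  }
  if (absolute) metrics$abs_value[i] else metrics$value[i]
}

#' Peak value of a trace within a cycle phase
#'
#' Returns the physiologically signed extremum of the windowed signal: in
#' systolic windows the extremum matching the contraction sign of the
#' direction (positive for radial, negative for longitudinal), in
#' diastolic windows the extremum matching relaxation (most negative for
#' radial strain rate in diastole, mirrored for longitudinal).
#'
#' @param trace a [strain_trace()].
#' @param events single-cycle [valve_events()].
#' @param label phase label as in [window_trace()].
#' @param statistic currently only `"peak"`.
#' @return The signed peak value.
#' @export
peak_phase_metric <- function(trace, events, label, statistic = "peak") {
  statistic <- match.arg(statistic, "peak")
  w <- window_trace(trace, events, label)$trace$values
  sgn <- if (trace$direction == "radial") 1 else -1
  if (label == "systole") sgn * max(sgn * w) else -sgn * max(-sgn * w)
}

#' Average peak across segments
#'
#' The "average peak" of a signal is the unweighted mean of the
#' per-segment peaks (not the peak of the segment-averaged curve), keeping
#' segments exchangeable.
#'
#' @param traces list of traces forming one signal across segments.
#' @inheritParams peak_phase_metric
#' @return Mean of per-segment peaks.
#' @export
average_peak <- function(traces, events, label) {
  mean(vapply(traces, peak_phase_metric, numeric(1), events = events,
              label = label))
}

#' Process one cycle: smooth, derive rates, extract IVRT metrics
#'
#' The standard per-cycle pipeline: every raw trace is low-pass filtered
#' once; strain-rate traces are then derived from the filtered strain
#' (derivatives are not re-filtered); and [ivsi_extract()] is run on the
#' combined set.
#'
#' @param traces named list of raw [strain_trace()] objects.
#' @param events single-cycle [valve_events()].
#' @param filter a [filter_spec()], or `NULL` to skip smoothing (useful on
#'   noiseless synthetic cycles).
#' @param derive_rates derive strain-rate traces from strain traces.
#' @return An `ivsi_metrics` data frame.
#' @export
process_cycle <- function(traces, events, filter = filter_spec(),
                          derive_rates = TRUE) {
  if (!is.null(filter)) {
    traces <- lapply(traces, butterworth_lowpass, spec = filter)
  }
  if (derive_rates) {
    rates <- lapply(Filter(function(tr) tr$kind == "strain", traces),
                    differentiate)
    names(rates) <- vapply(rates, function(tr) {
      trace_header(tr$direction, tr$layer, tr$segment_id, tr$kind)
    }, character(1))
    traces <- c(traces, rates)
  }
  ivsi_extract(traces, events)
}

#' Process a simulated or loaded cohort into a long metrics table
#'
#' Runs [process_cycle()] on every animal-day run of an
#' [simulate_cohort()] result and stacks the metrics with the cohort
#' identifiers.
#'
#' @param sim an `ivsi_cohort_sim`.
#' @param filter a [filter_spec()] or `NULL`.
#' @return An `ivsi_metrics` data frame with `animal_id`, `group` and
#'   `day` columns prepended.
#' @export
process_cohort <- function(sim, filter = filter_spec()) {
  stopifnot(inherits(sim, "ivsi_cohort_sim"))
  pieces <- lapply(sim$runs, function(run) {
    m <- process_cycle(run$cycle$traces, run$cycle$events, filter = filter)
    cbind(data.frame(animal_id = run$animal_id, group = run$group,
                     day = run$day, stringsAsFactors = FALSE), m)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("ivsi_metrics", "data.frame")
  out
}

#' Cohort table of the headline metric
#'
#' Fast path from a simulated cohort to a long cohort table of the
#' across-segment mean |min acceleration of radial strain rate|, using the
#' same filter/differentiate/window primitives as [process_cycle()] but
#' skipping the full metric panel. Suitable for replicate studies.
#'
#' @param sim an `ivsi_cohort_sim` whose runs contain radial strain traces.
#' @param filter a [filter_spec()] or `NULL`.
#' @return A validated cohort table with
#'   `metric_name = "radial_strain_rate_min_accel_abs"`.
#' @export
headline_cohort_table <- function(sim, filter = filter_spec()) {
  stopifnot(inherits(sim, "ivsi_cohort_sim"))
  rows <- lapply(sim$runs, function(run) {
    ev <- run$cycle$events
    vals <- vapply(run$cycle$traces, function(tr) {
      if (tr$kind != "strain" || tr$direction != "radial") return(NA_real_)
      if (!is.null(filter)) tr <- butterworth_lowpass(tr, filter)
      acc <- deriv_vec(deriv_vec(tr$values, 1 / tr$sample_rate), 1 / tr$sample_rate)
      idx <- window_indices(tr$time[1], tr$sample_rate, length(tr$values),
                            c(ev$avc, ev$mvo))
      i1 <- idx[1]
      i2 <- idx[2]
      if (i2 - i1 + 1L < 3L) stop_ivsi("IVRT window under-resolved", "resolution")
      min(acc[i1:i2])
    }, numeric(1))
    data.frame(animal_id = run$animal_id, group = run$group, day = run$day,
               metric_name = "radial_strain_rate_min_accel_abs",
               value = abs(mean(vals[!is.na(vals)])),
               stringsAsFactors = FALSE)
  })
  validate_cohort_table(do.call(rbind, rows))
}
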