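#' @keywords internal
.directions <- c("radial", "longitudinal")
.layers <- c("endocardial", "epicardial", "midwall")
.kinds <- c("strain", "strain_rate", "velocity", "acceleration")

# default physical unit carried by each signal kind; strain is carried in
# percent throughout, so its time derivatives are %/s and %/s^2
.kind_units <- c(
  strain = "%", strain_rate = "%/s",
  velocity = "mm/s", acceleration = "%/s^2"
)

#' Uniformly sampled per-segment myocardial deformation signal
#'
#' The central container of the package: one signal (strain, strain rate,
#' velocity or acceleration) for one myocardial segment, on a strictly
#' uniform time grid. Sign convention: contraction during systole is
#' positive, relaxation in diastole negative (so radial strain is positive
#' systolic, longitudinal strain negative systolic).
#'
#' @param time numeric vector of sample times in seconds, strictly
#'   increasing with constant step (relative jitter below `jitter_tol`).
#' @param values numeric vector of samples, same length as `time`, finite.
#' @param direction `"radial"` or `"longitudinal"`.
#' @param layer `"endocardial"`, `"epicardial"` or `"midwall"`.
#' @param segment_id positive integer segment index (1-6 in the default
#'   six-segment single-view model).
#' @param kind `"strain"`, `"strain_rate"`, `"velocity"` or
#'   `"acceleration"`.
#' @param unit unit tag; defaults to the conventional unit for `kind`
#'   (strain %, strain rate %/s, velocity mm/s, acceleration %/s^2). The
#'   tag is free-form for imported data whose exporter does not document
#'   units.
#' @param sample_rate sampling rate in Hz; inferred from `time` when `NULL`
#'   and cross-checked against it otherwise.
#' @param jitter_tol maximum tolerated relative deviation of any time step
#'   from the mean step.
#'
#' @return An object of class `strain_trace`.
#' @export
#' @examples
#' tr <- strain_trace(seq(0, 0.1, by = 1e-3), sin(seq(0, 0.1, by = 1e-3) * 50),
#'                    "radial", "midwall", 1, "strain")
#' tr$sample_rate
strain_trace <- function(time, values, direction, layer, segment_id, kind,
                         unit = NULL, sample_rate = NULL, jitter_tol = 1e-6) {
  if (length(time) != length(values)) {
    stop_ivsi("`time` and `values` must have the same length", "format")
  }
  if (length(time) < 2) stop_ivsi("a trace needs at least 2 samples", "format")
  if (!all(is.finite(time))) stop_ivsi("non-finite sample times", "format")
  if (!all(is.finite(values))) stop_ivsi("non-finite sample values", "data")
  dt <- diff(time)
  if (any(dt <= 0)) stop_ivsi("time must be strictly increasing", "format")
  step <- mean(dt)
  if (max(abs(dt - step)) > jitter_tol * step) {
    stop_ivsi(sprintf(
      "time grid is not uniform (relative jitter %.3g exceeds %.1g)",
      max(abs(dt - step)) / step, jitter_tol
    ), "format")
  }
  direction <- match.arg(direction, .directions)
  layer <- match.arg(layer, .layers)
  kind <- match.arg(kind, .kinds)
  segment_id <- as.integer(segment_id)
  if (length(segment_id) != 1 || is.na(segment_id) || segment_id < 1) {
    stop_ivsi("`segment_id` must be a single positive integer", "format")
  }
  fs <- 1 / step
  if (!is.null(sample_rate) && abs(sample_rate - fs) > 1e-6 * fs) {
    stop_ivsi(sprintf(
      "declared sample_rate %.6g Hz inconsistent with time grid (1/dt = %.6g Hz)",
      sample_rate, fs
    ), "format")
  }
  structure(
    list(
      time = as.numeric(time), values = as.numeric(values),
      direction = direction, layer = layer, segment_id = segment_id,
      kind = kind, unit = unit %||% unname(.kind_units[kind]),
      sample_rate = fs
    ),
    class = "strain_trace"
  )
}

#' @export
print.strain_trace <- function(x, ...) {
  cat(sprintf(
    "<strain_trace> %s %s seg%d %s [%s]\n  %d samples @ %.6g Hz, t = [%.4g, %.4g] s, range [%.4g, %.4g]\n",
    x$direction, x$layer, x$segment_id, x$kind, x$unit,
    length(x$time), x$sample_rate, x$time[1], x$time[length(x$time)],
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
length.strain_trace <- function(x) length(x$values)

#' Cycle-anchored valve-event times
#'
#' Valve events delimit the phases of each analysed cardiac cycle. The
#' isovolumic relaxation time (IVRT) is the interval from aortic valve
#' closure (AVC) to mitral valve opening (MVO) and is derived on
#' construction. All arguments are in seconds and may be vectors (one
#' element per cycle).
#'
#' @param cycle_start,avc,mvo,cycle_end event times in seconds; must satisfy
#'   `cycle_start < avc < mvo <= cycle_end`.
#' @param e_end optional end of the early filling (E) wave, needed for
#'   early-diastole windows; must lie in `(mvo, cycle_end]`.
#'
#' @return A data frame of class `valve_events` with one row per cycle and
#'   a derived `ivrt` column (seconds).
#' @export
#' @examples
#' ev <- valve_events(0, 0.050, 0.068, 0.140)
#' ev$ivrt # 0.018
valve_events <- function(cycle_start, avc, mvo, cycle_end, e_end = NULL) {
  n <- max(length(cycle_start), length(avc), length(mvo), length(cycle_end))
  ev <- data.frame(
    cycle_start = rep_len(as.numeric(cycle_start), n),
    avc = rep_len(as.numeric(avc), n),
    mvo = rep_len(as.numeric(mvo), n),
    cycle_end = rep_len(as.numeric(cycle_end), n)
  )
  if (!is.null(e_end)) ev$e_end <- rep_len(as.numeric(e_end), n)
  if (!all(is.finite(unlist(ev)))) stop_ivsi("non-finite event time", "event")
  bad <- with(ev, cycle_start >= avc | avc >= mvo | mvo > cycle_end)
  if (any(bad)) {
    stop_ivsi(sprintf(
      "event ordering violated in cycle(s) %s: need cycle_start < avc < mvo <= cycle_end",
      paste(which(bad), collapse = ", ")
    ), "event")
  }
  if (!is.null(ev$e_end) && any(ev$e_end <= ev$mvo | ev$e_end > ev$cycle_end)) {
    stop_ivsi("`e_end` must lie in (mvo, cycle_end]", "event")
  }
  ev$ivrt <- ev$mvo - ev$avc
  class(ev) <- c("valve_events", "data.frame")
  ev
}

#' Left-ventricular pressure trace
#'
#' @param time sample times in seconds, uniform grid.
#' @param pressure pressure in mmHg, finite.
#' @param jitter_tol relative uniformity tolerance as in [strain_trace()].
#' @return Object of class `pressure_trace` with an inferred `sample_rate`.
#' @export
pressure_trace <- function(time, pressure, jitter_tol = 1e-6) {
  if (length(time) != length(pressure) || length(time) < 2) {
    stop_ivsi("`time` and `pressure` must be equal-length vectors (n >= 2)", "format")
  }
  if (!all(is.finite(time)) || !all(is.finite(pressure))) {
    stop_ivsi("non-finite pressure samples", "data")
  }
  dt <- diff(time)
  if (any(dt <= 0)) stop_ivsi("time must be strictly increasing", "format")
  step <- mean(dt)
  if (max(abs(dt - step)) > jitter_tol * step) {
    stop_ivsi("pressure time grid is not uniform", "format")
  }
  structure(
    list(time = as.numeric(time), pressure = as.numeric(pressure),
         sample_rate = 1 / step),
    class = "pressure_trace"
  )
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf(
    "<pressure_trace> %d samples @ %.6g Hz, P in [%.4g, %.4g] mmHg\n",
    length(x$time), x$sample_rate, min(x$pressure), max(x$pressure)
  ))
  invisible(x)
}

#' Conventional echocardiographic measurements
#'
#' Container for the directly measured conventional parameters from which
#' [conventional_ratios()] derives ejection fraction, fractional shortening
#' and the transmitral ratios.
#'
#' @param LVIDd,LVIDs left-ventricular internal diameters at end-diastole /
#'   end-systole (mm); `LVIDs < LVIDd`.
#' @param E,A early and late transmitral inflow peak velocities (mm/s).
#' @param Eprime early diastolic annular tissue velocity E' (mm/s).
#' @param IVRT,IVCT,ET isovolumic relaxation / contraction and ejection
#'   times (ms).
#' @param LAA left atrial area (mm^2).
#' @param HR heart rate (bpm).
#' @return Object of class `conventional_echo`.
#' @export
conventional_echo <- function(LVIDd, LVIDs, E, A, Eprime,
                              IVRT = NA_real_, IVCT = NA_real_, ET = NA_real_,
                              LAA = NA_real_, HR = NA_real_) {
  x <- list(LVIDd = LVIDd, LVIDs = LVIDs, E = E, A = A, Eprime = Eprime,
            IVRT = IVRT, IVCT = IVCT, ET = ET, LAA = LAA, HR = HR)
  need_pos <- c("LVIDd", "LVIDs", "E", "A", "Eprime")
  for (nm in need_pos) {
    if (!is.numeric(x[[nm]]) || length(x[[nm]]) != 1 || !is.finite(x[[nm]]) ||
        x[[nm]] <= 0) {
      stop_ivsi(sprintf("`%s` must be a single positive number", nm), "domain")
    }
  }
  if (x$LVIDs >= x$LVIDd) stop_ivsi("LVIDs must be smaller than LVIDd", "domain")
  structure(x, class = "conventional_echo")
}

#' One-row statistical result record
#'
#' Uniform shape for every test and model in the package: estimate with
#' confidence bounds, test statistic, degrees of freedom, raw and (after
#' [bh_fdr()]) adjusted p-values, plus a method tag.
#'
#' @param method short method tag, e.g. `"welch_t"` or `"lmm_satterthwaite"`.
#' @param effect name of the estimated effect.
#' @param estimate,ci_low,ci_high point estimate and confidence bounds
#'   (`ci_low <= estimate <= ci_high`).
#' @param statistic,df test statistic and degrees of freedom.
#' @param p_value raw p-value in `[0, 1]`.
#' @param p_adjusted FDR-adjusted p-value (`NA` until adjustment).
#' @return A one-row data frame of class `stat_result`.
#' @export
stat_result <- function(method, effect, estimate, ci_low, ci_high,
                        statistic = NA_real_, df = NA_real_,
                        p_value = NA_real_, p_adjusted = NA_real_) {
  if (is.finite(ci_low) && is.finite(ci_high) &&
      !(ci_low <= estimate + 1e-12 && estimate <= ci_high + 1e-12)) {
    stop_ivsi("confidence interval must bracket the estimate", "domain")
  }
  if (is.finite(p_value) && (p_value < 0 || p_value > 1)) {
    stop_ivsi("p-value outside [0, 1]", "domain")
  }
  out <- data.frame(
    method = method, effect = effect, estimate = estimate,
    ci_low = ci_low, ci_high = ci_high, statistic = statistic, df = df,
    p_value = p_value, p_adjusted = p_adjusted,
    stringsAsFactors = FALSE
  )
  class(out) <- c("stat_result", "data.frame")
  out
}

rbind_stat_results <- function(...) {
  out <- do.call(rbind, lapply(list(...), function(x) {
    class(x) <- "data.frame"
    x
  }))
  rownames(out) <- NULL
  class(out) <- c("stat_result", "data.frame")
  out
}

#' Validate a long-format cohort table
#'
#' A cohort table holds one measured metric value per animal, postoperative
#' day and metric name, with a fixed group label (`sham` or `TAC`) per
#' animal. This is the exchange format between metric extraction and the
#' statistical layer.
#'
#' @param table data frame with columns `animal_id`, `group`, `day`,
#'   `metric_name`, `value`.
#' @return The validated table (invisibly classed `cohort_table`).
#' @export
validate_cohort_table <- function(table) {
  need <- c("animal_id", "group", "day", "metric_name", "value")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop_ivsi(paste("cohort table lacks column(s):", paste(miss, collapse = ", ")),
              "format")
  }
  if (!all(table$group %in% c("sham", "TAC"))) {
    stop_ivsi("`group` must be 'sham' or 'TAC'", "format")
  }
  key <- paste(table$animal_id, table$day, table$metric_name)
  if (anyDuplicated(key)) {
    stop_ivsi("(animal_id, day, metric_name) must be unique", "format")
  }
  gpa <- tapply(table$group, table$animal_id, function(g) length(unique(g)))
  if (any(gpa > 1)) stop_ivsi("group must be constant within animal_id", "format")
  if (!is.numeric(table$value)) stop_ivsi("`value` must be numeric", "format")
  class(table) <- unique(c("cohort_table", class(table)))
  invisible(table)
}
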