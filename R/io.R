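# Trace tables are wide CSV files mirroring one-column-per-curve instrument
# exports: a `time` column followed by one column per segment/layer/direction
# signal, named by the grammar `<direction>_<layer>_seg<k>_<kind>`.

#' Build / parse trace-table column names
#'
#' Column headers of the wide trace CSV follow the grammar
#' `<direction>_<layer>_seg<k>_<kind>`, e.g. `radial_midwall_seg3_strain`.
#' The grammar is total: every header the package writes parses back to the
#' tuple that generated it.
#'
#' @param direction,layer,segment_id,kind trace identity fields as in
#'   [strain_trace()].
#' @return `trace_header()` returns the header string; `parse_trace_header()`
#'   returns a list with fields `direction`, `layer`, `segment_id`, `kind`.
#' @export
trace_header <- function(direction, layer, segment_id, kind) {
  sprintf("%s_%s_seg%d_%s",
          match.arg(direction, .directions), match.arg(layer, .layers),
          as.integer(segment_id), match.arg(kind, .kinds))
}

#' @rdname trace_header
#' @param header a single column-name string.
#' @export
parse_trace_header <- function(header) {
  pat <- sprintf("^(%s)_(%s)_seg([0-9]+)_(%s)$",
                 paste(.directions, collapse = "|"),
                 paste(.layers, collapse = "|"),
                 paste(.kinds, collapse = "|"))
  m <- regmatches(header, regexec(pat, header))[[1]]
  if (length(m) != 5) {
    stop_ivsi(sprintf("cannot parse trace column header '%s'", header), "header")
  }
  list(direction = m[2], layer = m[3], segment_id = as.integer(m[4]), kind = m[5])
}

fmt_full <- function(x) sprintf("%.17g", x) # round-trips doubles bit-for-bit

#' Write / read wide trace tables
#'
#' `write_trace_table()` writes a list of [strain_trace()] objects sharing a
#' common time grid as a wide CSV (full double precision, so a write/read
#' round trip is bit-identical). `read_trace_table()` parses such a file
#' back into traces, validating time-grid uniformity and interpolating
#' short gaps of missing samples.
#'
#' @param traces list of `strain_trace` objects on one common time grid.
#' @param path file path.
#' @param time_unit unit of the time column: `"s"` (default) or `"ms"`.
#'   Murine IVRT is ~15-25 ms, so millisecond exports are common;
#'   internally everything is seconds.
#' @return `write_trace_table()` returns `path` invisibly;
#'   `read_trace_table()` a named list of `strain_trace` objects.
#' @export
write_trace_table <- function(traces, path, time_unit = c("s", "ms")) {
  time_unit <- match.arg(time_unit)
  if (!length(traces)) stop_ivsi("no traces to write", "format")
  t0 <- traces[[1]]$time
  for (tr in traces) {
    if (!inherits(tr, "strain_trace")) stop_ivsi("not a strain_trace", "format")
    if (length(tr$time) != length(t0) || max(abs(tr$time - t0)) > 1e-9) {
      stop_ivsi("all traces must share one time grid", "format")
    }
  }
  hdr <- vapply(traces, function(tr) {
    trace_header(tr$direction, tr$layer, tr$segment_id, tr$kind)
  }, character(1))
  if (anyDuplicated(hdr)) stop_ivsi("duplicate trace identities", "format")
  tt <- if (time_unit == "ms") t0 * 1000 else t0
  cols <- c(list(time = fmt_full(tt)),
            setNames(lapply(traces, function(tr) fmt_full(tr$values)), hdr))
  df <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_table
#' @param max_gap longest run of missing samples (per column) repaired by
#'   linear interpolation; longer runs, or missing values at the ends, are
#'   a data error. Filtering and differentiation require complete uniform
#'   grids, and longer gaps are not credibly recoverable.
#' @param jitter_tol relative tolerance on time-step uniformity.
#' @export
read_trace_table <- function(path, time_unit = c("s", "ms"), max_gap = 3L,
                             jitter_tol = 1e-6) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop_ivsi(paste("no such file:", path), "format")
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 2 || tolower(names(df)[1]) != "time") {
    stop_ivsi("first column must be `time`", "format")
  }
  tt <- as.numeric(df[[1]])
  if (time_unit == "ms") tt <- tt / 1000
  if (any(!is.finite(tt)) || any(diff(tt) <= 0)) {
    stop_ivsi("time column must be finite and strictly increasing", "format")
  }
  dt <- diff(tt)
  step <- mean(dt)
  if (max(abs(dt - step)) > jitter_tol * step) {
    stop_ivsi("time column is not uniformly sampled", "format")
  }
  out <- list()
  for (nm in names(df)[-1]) {
    id <- parse_trace_header(nm)
    v <- as.numeric(df[[nm]])
    if (anyNA(v)) {
      r <- rle(is.na(v))
      if (any(r$values & r$lengths > max_gap)) {
        stop_ivsi(sprintf(
          "column '%s' has a missing-sample run longer than %d", nm, max_gap
        ), "data")
      }
      if (is.na(v[1]) || is.na(v[length(v)])) {
        stop_ivsi(sprintf("column '%s' is missing boundary samples", nm), "data")
      }
      v <- approx(tt[!is.na(v)], v[!is.na(v)], xout = tt)$y
    }
    out[[nm]] <- strain_trace(tt, v, id$direction, id$layer, id$segment_id,
                              id$kind, jitter_tol = jitter_tol)
  }
  out
}

#' Write / read valve-event tables
#'
#' Plain CSV with columns `cycle_start`, `avc`, `mvo`, `cycle_end` and
#' optionally `e_end` (all seconds); the derived `ivrt` is recomputed on
#' read.
#'
#' @param events a [valve_events()] object.
#' @param path file path.
#' @return `read_valve_events()` returns a validated `valve_events` object.
#' @export
write_valve_events <- function(events, path) {
  stopifnot(inherits(events, "valve_events"))
  keep <- intersect(c("cycle_start", "avc", "mvo", "cycle_end", "e_end"),
                    names(events))
  df <- as.data.frame(lapply(events[keep], fmt_full), check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_valve_events
#' @export
read_valve_events <- function(path) {
  if (!file.exists(path)) stop_ivsi(paste("no such file:", path), "format")
  df <- read.csv(path)
  need <- c("cycle_start", "avc", "mvo", "cycle_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_ivsi(paste("valve-event table lacks column(s):",
                    paste(miss, collapse = ", ")), "event")
  }
  valve_events(df$cycle_start, df$avc, df$mvo, df$cycle_end, e_end = df$e_end)
}

fmt_fixed <- function(x, digits) {
  ifelse(is.na(x), "NA", sprintf("%.*g", digits, x))
}

# canonical column order of the long metrics table
.metrics_cols <- c("animal_id", "group", "day", "direction", "layer", "kind",
                   "segment_id", "metric", "value", "abs_value")

#' Write / read IVRT metrics tables
#'
#' Long-format tab-separated table of [ivsi_extract()] output with a
#' deterministic column order and fixed-precision floats, suitable for
#' diffing across runs.
#'
#' @param metrics an `ivsi_metrics` data frame.
#' @param path file path.
#' @param digits significant digits written for floating-point columns.
#' @return `write_metrics_table()` returns `path` invisibly;
#'   `read_metrics_table()` the parsed data frame.
#' @export
write_metrics_table <- function(metrics, path, digits = 8L) {
  cols <- intersect(.metrics_cols, names(metrics))
  if (!nrow(metrics)) {
    warning("writing an empty metrics table (header only)")
    cat(paste(cols, collapse = "\t"), "\n", sep = "", file = path)
    return(invisible(path))
  }
  df <- metrics[, cols, drop = FALSE]
  for (nm in c("value", "abs_value")) {
    if (nm %in% names(df)) df[[nm]] <- fmt_fixed(df[[nm]], digits)
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  class(df) <- c("ivsi_metrics", "data.frame")
  df
}

#' Write a statistical-results table
#'
#' Tab-separated long table with columns
#' `(metric, effect, estimate, ci_low, ci_high, statistic, df, p, p_fdr)`.
#'
#' @param results a `stat_result` data frame; an optional `metric` column
#'   identifies the response each row belongs to.
#' @param path file path.
#' @param digits significant digits for floats.
#' @export
write_stats_table <- function(results, path, digits = 8L) {
  df <- as.data.frame(results)
  if (is.null(df$metric)) df$metric <- NA_character_
  out <- data.frame(
    metric = df$metric, effect = df$effect,
    estimate = fmt_fixed(df$estimate, digits),
    ci_low = fmt_fixed(df$ci_low, digits),
    ci_high = fmt_fixed(df$ci_high, digits),
    statistic = fmt_fixed(df$statistic, digits),
    df = fmt_fixed(df$df, digits),
    p = fmt_fixed(df$p_value, digits),
    p_fdr = fmt_fixed(df$p_adjusted, digits),
    stringsAsFactors = FALSE
  )
  if (!nrow(out)) warning("writing an empty stats table (header only)")
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read long-format cohort tables
#'
#' CSV with columns `animal_id, group, day, metric_name, value`; validated
#' with [validate_cohort_table()] on both ends.
#'
#' @param table cohort table data frame.
#' @param path file path.
#' @export
write_cohort_table <- function(table, path) {
  table <- validate_cohort_table(table)
  df <- as.data.frame(table)[, c("animal_id", "group", "day", "metric_name", "value")]
  df$value <- fmt_full(df$value)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop_ivsi(paste("no such file:", path), "format")
  validate_cohort_table(read.csv(path, stringsAsFactors = FALSE))
}
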