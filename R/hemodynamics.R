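#' Pressure-derived hemodynamic indices
#'
#' Computes the extrema of the first time derivative of left-ventricular
#' pressure (dP/dt max and min, mmHg/s) over the whole cycle, and the
#' isovolumic relaxation time constant by the Weiss method: ordinary
#' least-squares regression of `ln P` on time over the AVC-to-MVO segment,
#' with `tau = -1/slope`. The log-linear fit makes tau invariant to
#' rescaling the pressure trace.
#'
#' @param pressure a [pressure_trace()].
#' @param events single-cycle [valve_events()] locating the isovolumic
#'   relaxation segment.
#' @return A list of class `hemo_metrics` with `dpdt_max`, `dpdt_min`
#'   (mmHg/s) and `tau_weiss_ms`.
#' @export
#' @examples
#' t <- seq(0, 0.05, by = 1e-4)
#' p <- pressure_trace(t, 40 * exp(-t / 0.010))
#' ev <- valve_events(-0.01, 0, 0.05, 0.05)
#' hemodynamics(p, ev)$tau_weiss_ms # 10
hemodynamics <- function(pressure, events) {
  stopifnot(inherits(pressure, "pressure_trace"), inherits(events, "valve_events"))
  if (nrow(events) != 1) stop_ivsi("need exactly one cycle of events", "event")
  h <- 1 / pressure$sample_rate
  dpdt <- deriv_vec(pressure$pressure, h)
  idx <- window_indices(pressure$time[1], pressure$sample_rate,
                        length(pressure$time), c(events$avc, events$mvo))
  i1 <- idx[1]
  i2 <- idx[2]
  if (i2 - i1 + 1L < 3L) {
    stop_ivsi("isovolumic relaxation segment spans fewer than 3 samples", "resolution")
  }
  p_fit <- pressure$pressure[i1:i2]
  if (any(p_fit <= 0)) {
    stop_ivsi("non-positive pressure inside the Weiss fit window", "domain")
  }
  fit <- lm(log(p_fit) ~ pressure$time[i1:i2])
  slope <- unname(coef(fit)[2])
  if (slope >= 0) {
    stop_ivsi("pressure does not decay over the isovolumic relaxation segment",
              "domain")
  }
  structure(list(dpdt_max = max(dpdt), dpdt_min = min(dpdt),
                 tau_weiss_ms = -1000 / slope),
            class = "hemo_metrics")
}

#' @export
print.hemo_metrics <- function(x, ...) {
  cat(sprintf(
    "<hemo_metrics> dP/dt max %.4g, min %.4g mmHg/s; Weiss tau %.3g ms\n",
    x$dpdt_max, x$dpdt_min, x$tau_weiss_ms
  ))
  invisible(x)
}

#' Conventional echocardiographic ratios
#'
#' Derives the calculated conventional parameters from a
#' [conventional_echo()] measurement set: fractional shortening
#' `FS = 100 (LVIDd - LVIDs) / LVIDd`, ventricular volumes by the
#' Teichholz formula `V = 7.0 / (2.4 + D) * D^3` (microlitres for D in
#' mm), ejection fraction `EF = 100 (Vd - Vs) / Vd`, and the transmitral
#' ratios E/A and E/E'.
#'
#' @param echo a [conventional_echo()] object.
#' @return A list with `FS_pct`, `EF_pct`, `Vd_ul`, `Vs_ul`, `E_over_A`,
#'   `E_over_Eprime`.
#' @export
#' @examples
#' conventional_ratios(conventional_echo(4, 2, 750, 450, 25))$FS_pct # 50
conventional_ratios <- function(echo) {
  stopifnot(inherits(echo, "conventional_echo"))
  teichholz <- function(D) 7.0 / (2.4 + D) * D^3
  Vd <- teichholz(echo$LVIDd)
  Vs <- teichholz(echo$LVIDs)
  list(
    FS_pct = 100 * (echo$LVIDd - echo$LVIDs) / echo$LVIDd,
    EF_pct = 100 * (Vd - Vs) / Vd,
    Vd_ul = Vd, Vs_ul = Vs,
    E_over_A = echo$E / echo$A,
    E_over_Eprime = echo$E / echo$Eprime
  )
}
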