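# Coupled oscillation traces: basal myosin, protrusion area (% of basal
# surface), basal area, and D-V / A-P basal lengths, sharing one phase
# process so their couplings are exact by construction.

#' Uniformly sampled intensity trace
#'
#' @param values numeric vector (a.u., um^2 or %), >= 8 samples.
#' @param dt_s sampling interval in seconds.
#' @param label channel name.
#' @return An `intensity_trace`.
#' @export
intensity_trace <- function(values, dt_s, label = "signal") {
  if (length(values) < 8L)
    stop("an intensity trace needs at least 8 samples", call. = FALSE)
  if (!is.numeric(dt_s) || dt_s <= 0)
    stop("dt_s must be a positive scalar", call. = FALSE)
  structure(list(values = as.numeric(values), dt_s = dt_s, label = label),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat("intensity_trace '", x$label, "': ", length(x$values),
      " samples at dt = ", x$dt_s, " s\n", sep = "")
  invisible(x)
}

# Phase process with per-cycle period jitter: cycle c has period
# T * (1 + jitter * z_c), z ~ N(0,1) truncated at +/-2.5.
jittered_phase <- function(times, period_s, jitter) {
  if (jitter <= 0) return(2 * pi * times / period_s)
  horizon <- max(times)
  bounds <- 0; periods <- numeric(0)
  while (bounds[length(bounds)] < horizon + period_s) {
    z <- max(-2.5, min(2.5, stats::rnorm(1)))
    Tc <- period_s * max(0.2, 1 + jitter * z)
    periods <- c(periods, Tc)
    bounds <- c(bounds, bounds[length(bounds)] + Tc)
  }
  ci <- findInterval(times, bounds, rightmost.closed = FALSE)
  2 * pi * ((ci - 1) + (times - bounds[ci]) / periods[ci])
}

#' Simulate a coupled oscillation trace bundle
#'
#' Myosin oscillates as baseline + amplitude * sin(phase) with optional
#' per-cycle period jitter; protrusion area is phase-locked to myosin via
#' the preset coupling phase; basal area oscillates in anti-phase to myosin
#' (the surface contracts as myosin rises); D-V and A-P basal lengths
#' oscillate in anti-phase with per-cycle fractional changes whose ratio is
#' the preset D-V/A-P anisotropy. White Gaussian noise is added to each
#' trace, scaled to that trace's oscillation amplitude.
#'
#' @param config a [synth_config()].
#' @param preset_name condition preset.
#' @param duration_s total duration (>= 3 oscillation periods).
#' @param seed integer seed.
#' @param noise_frac noise SD as a fraction of each trace's amplitude;
#'   defaults to the preset.
#' @param period_jitter per-cycle period CV; defaults to the preset.
#' @return A `trace_bundle`: intensity traces `myosin`, `protrusion_pct`,
#'   `basal_area`, `dv_length`, `ap_length` plus a `truth` list.
#' @export
simulate_traces <- function(config, preset_name, duration_s = 3600,
                            seed = config$seed, noise_frac = NULL,
                            period_jitter = NULL) {
  p <- get_preset(config, preset_name)
  Tp <- p$oscillation_period_s
  if (duration_s < 3 * Tp)
    stop("duration_s must cover at least 3 oscillation periods",
         call. = FALSE)
  dt <- config$frame_interval_s
  noise_frac <- noise_frac %||% p$trace_noise_frac
  period_jitter <- period_jitter %||% p$period_jitter

  with_seed(seed, {
    n <- floor(duration_s / dt)
    t <- (seq_len(n) - 1L) * dt
    ph <- jittered_phase(t, Tp, period_jitter)
    s <- sin(ph)
    A <- p$oscillation_amplitude
    noise <- function(sd) if (sd > 0) stats::rnorm(n, 0, sd) else 0

    myo <- 2 * A + A * s + noise(noise_frac * A)
    p0 <- max(p$protrusion_area_pct, 1)
    pA <- 0.5 * p0
    prot <- p0 + pA * sin(ph + p$coupling_phase) + noise(noise_frac * pA)
    prot <- pmin(pmax(prot, 0), 100)
    area0 <- 60; aA <- 0.15
    area <- area0 * (1 - aA * s) + noise(noise_frac * area0 * aA)
    dv0 <- 8; ap0 <- 8
    dvA <- p$dv_frac_change / 2
    apA <- p$ap_frac_change / 2
    dv <- dv0 * (1 - dvA * s) + noise(noise_frac * dv0 * dvA)
    ap <- ap0 * (1 - apA * s) + noise(noise_frac * ap0 * apA)

    structure(list(
      myosin = intensity_trace(myo, dt, "myosin"),
      protrusion_pct = intensity_trace(prot, dt, "protrusion_pct"),
      basal_area = intensity_trace(area, dt, "basal_area"),
      dv_length = intensity_trace(dv, dt, "dv_length"),
      ap_length = intensity_trace(ap, dt, "ap_length"),
      truth = list(period_s = Tp, amplitude = A,
                   phase = p$coupling_phase,
                   dv_frac = p$dv_frac_change, ap_frac = p$ap_frac_change,
                   anisotropy = p$dv_frac_change / p$ap_frac_change),
      preset_name = preset_name
    ), class = "trace_bundle")
  })
}

#' Write / read a trace bundle as CSV
#'
#' Columns: `time_s`, `myosin`, `protrusion_pct`, `basal_area`,
#' `dv_length`, `ap_length`.
#' @param bundle a `trace_bundle`.
#' @param path CSV path.
#' @param dt_s frame interval, for `read_trace_bundle` when the time column
#'   is absent.
#' @return the path / a `trace_bundle`.
#' @export
write_trace_bundle <- function(bundle, path) {
  n <- length(bundle$myosin$values)
  df <- data.frame(
    time_s = (seq_len(n) - 1L) * bundle$myosin$dt_s,
    myosin = bundle$myosin$values,
    protrusion_pct = bundle$protrusion_pct$values,
    basal_area = bundle$basal_area$values,
    dv_length = bundle$dv_length$values,
    ap_length = bundle$ap_length$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_bundle
#' @export
read_trace_bundle <- function(path, dt_s = NULL) {
  df <- utils::read.csv(path)
  dt <- if (!is.null(df$time_s) && nrow(df) > 1L)
    df$time_s[2] - df$time_s[1] else dt_s
  if (is.null(dt)) stop("cannot infer frame interval", call. = FALSE)
  mk <- function(col, lab)
    if (!is.null(df[[col]])) intensity_trace(df[[col]], dt, lab) else NULL
  structure(list(
    myosin = mk("myosin", "myosin"),
    protrusion_pct = mk("protrusion_pct", "protrusion_pct"),
    basal_area = mk("basal_area", "basal_area"),
    dv_length = mk("dv_length", "dv_length"),
    ap_length = mk("ap_length", "ap_length"),
    truth = NULL, preset_name = NA_character_
  ), class = "trace_bundle")
}
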