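# Oscillation analysis: background subtraction and Gaussian smoothing,
# alternating peak/trough detection with a prominence criterion, period
# estimation from adjacent-peak intervals and from the power spectrum of
# the autocorrelation, max-minus-min amplitudes, and myosin/geometry
# coupling statistics.

#' Preprocess an intensity trace
#'
#' Subtracts the background value, clips at zero, and smooths with a
#' Gaussian kernel of `sigma` samples (truncated at 3 sigma, reflect
#' padding). The operation is linear and shift-invariant once the
#' background is zero.
#'
#' @param trace an `intensity_trace`.
#' @param background_value background (a.u.), >= 0, e.g. from a cell-free
#'   region.
#' @param sigma kernel SD in samples (default 3).
#' @return A preprocessed `intensity_trace`.
#' @export
preprocess_trace <- function(trace, background_value = 0, sigma = 3) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (background_value < 0)
    stop("background must be non-negative", call. = FALSE)
  x <- pmax(trace$values - background_value, 0)
  r <- ceiling(3 * sigma)
  if (length(x) <= r)
    stop("trace shorter than the smoothing kernel support", call. = FALSE)
  intensity_trace(smooth1d(x, sigma), trace$dt_s, trace$label)
}

# Topographic prominence of extremum candidates (peaks of x; pass -x for
# troughs): height above the higher of the two valley floors separating
# the candidate from the nearest higher ground on each side.
prominences <- function(x, idx) {
  vapply(idx, function(i) {
    lf <- x[i]; j <- i
    while (j > 1L && x[j - 1L] <= x[i]) { j <- j - 1L; lf <- min(lf, x[j]) }
    if (j == 1L) lf <- min(x[1:i])
    rf <- x[i]; j <- i
    n <- length(x)
    while (j < n && x[j + 1L] <= x[i]) { j <- j + 1L; rf <- min(rf, x[j]) }
    if (j == n) rf <- min(x[i:n])
    x[i] - max(lf, rf)
  }, numeric(1))
}

#' Detect oscillation cycles
#'
#' Finds alternating peaks and troughs whose prominence reaches
#' `prominence_frac` of the signal range. Per-cycle amplitudes are the
#' difference between each peak and its preceding trough. When `refine` is
#' supplied (typically the raw background-subtracted trace whose smoothed
#' version was searched), extremum positions are refined to the local
#' extremum of `refine` within `refine_window` samples and amplitudes are
#' evaluated on it, so smoothing does not attenuate the max-minus-min
#' amplitude statistic.
#'
#' @param trace a (preprocessed) `intensity_trace`.
#' @param prominence_frac prominence threshold as a fraction of the global
#'   range.
#' @param refine optional `intensity_trace` for amplitude evaluation.
#' @param refine_window half-window (samples) for extremum refinement.
#' @return A `cycle_set`: `peak_indices`, `trough_indices`, `amplitudes`,
#'   `flagged` (TRUE when fewer than 2 peaks were found).
#' @export
detect_cycles <- function(trace, prominence_frac = 0.2, refine = NULL,
                          refine_window = 2L) {
  x <- trace$values
  rng <- max(x) - min(x)
  if (rng <= 0)
    return(structure(list(peak_indices = integer(0),
                          trough_indices = integer(0),
                          amplitudes = numeric(0), flagged = TRUE),
                     class = "cycle_set"))
  thr <- prominence_frac * rng
  pk <- local_maxima(x); pk <- pk[prominences(x, pk) >= thr]
  tr <- local_maxima(-x); tr <- tr[prominences(-x, tr) >= thr]
  # enforce alternation: among consecutive same-type extrema keep the most
  # extreme one
  ext <- data.frame(i = c(pk, tr),
                    type = c(rep(1L, length(pk)), rep(-1L, length(tr))))
  ext <- ext[order(ext$i), , drop = FALSE]
  keep <- logical(nrow(ext))
  last_type <- 0L; last_row <- 0L
  for (r in seq_len(nrow(ext))) {
    if (ext$type[r] != last_type) {
      keep[r] <- TRUE; last_type <- ext$type[r]; last_row <- r
    } else {
      better <- if (ext$type[r] == 1L) x[ext$i[r]] > x[ext$i[last_row]]
                else x[ext$i[r]] < x[ext$i[last_row]]
      if (better) { keep[last_row] <- FALSE; keep[r] <- TRUE; last_row <- r }
    }
  }
  ext <- ext[keep, , drop = FALSE]
  pk <- ext$i[ext$type == 1L]; tr <- ext$i[ext$type == -1L]
  amp_src <- if (!is.null(refine)) refine$values else x
  refine_idx <- function(i, want_max) {
    if (is.null(refine)) return(i)
    w <- max(1L, i - refine_window):min(length(amp_src), i + refine_window)
    w[if (want_max) which.max(amp_src[w]) else which.min(amp_src[w])]
  }
  pk <- vapply(pk, refine_idx, integer(1), want_max = TRUE)
  tr <- vapply(tr, refine_idx, integer(1), want_max = FALSE)
  amps <- numeric(0)
  for (p in pk) {
    prev <- tr[tr < p]
    if (length(prev)) amps <- c(amps, amp_src[p] - amp_src[max(prev)])
  }
  structure(list(peak_indices = pk, trough_indices = tr,
                 amplitudes = pmax(amps, 0), flagged = length(pk) < 2L),
            class = "cycle_set")
}

#' Period from adjacent-peak intervals
#'
#' @param cycles a `cycle_set` with >= 2 peaks.
#' @param dt_s frame interval (s).
#' @return List: `mean_s`, `intervals_s`.
#' @export
period_from_intervals <- function(cycles, dt_s) {
  if (length(cycles$peak_indices) < 2L)
    stop("period undefined: fewer than 2 peaks", call. = FALSE)
  iv <- diff(cycles$peak_indices) * dt_s
  list(mean_s = mean(iv), intervals_s = iv)
}

#' Mean oscillation amplitude
#'
#' Mean of the per-cycle peak-minus-preceding-trough differences.
#' @param cycles a `cycle_set` with >= 1 complete cycle.
#' @return Mean amplitude (a.u.).
#' @export
cycle_amplitude <- function(cycles) {
  if (length(cycles$amplitudes) < 1L)
    stop("no complete cycle", call. = FALSE)
  mean(cycles$amplitudes)
}

#' Dominant period from the power spectrum of the autocorrelation
#'
#' The mean-subtracted signal's biased autocorrelation (normalised to 1 at
#' lag zero) is Fourier-transformed; the PSD is its FFT magnitude. The
#' dominant period is the reciprocal of the frequency of maximum power,
#' searched above the DC bin (frequencies below 1/duration are excluded to
#' avoid trend leakage). No window function is applied.
#'
#' @param trace an `intensity_trace` with >= 32 samples.
#' @return A `psd_result`: `frequencies` (1/s, up to Nyquist), `power`,
#'   `dominant_period_s`, `autocorrelation`, `flagged` (TRUE for a
#'   constant trace).
#' @export
psd_dominant_period <- function(trace) {
  x <- trace$values
  n <- length(x)
  if (n < 32L) stop("need at least 32 samples", call. = FALSE)
  x <- x - mean(x)
  c0 <- sum(x^2) / n
  if (c0 <= 0)
    return(structure(list(frequencies = numeric(0), power = numeric(0),
                          dominant_period_s = NA_real_,
                          autocorrelation = NULL, flagged = TRUE),
                     class = "psd_result"))
  ac <- vapply(0:(n - 1L), function(k)
    sum(x[seq_len(n - k)] * x[(k + 1L):n]) / n, numeric(1)) / c0
  P <- Mod(stats::fft(ac))
  half <- floor(n / 2)
  freqs <- (0:half) / (n * trace$dt_s)
  ks <- seq(2L, half + 1L)            # k >= 1: exclude DC / sub-duration
  kmax <- ks[which.max(P[ks])]
  structure(list(frequencies = freqs, power = P[seq_len(half + 1L)],
                 dominant_period_s = 1 / freqs[kmax],
                 autocorrelation = ac, flagged = FALSE),
            class = "psd_result")
}

#' Myosin / geometry coupling statistics
#'
#' Zero-lag Pearson correlation of myosin with protrusion area and with
#' basal area, the lag of maximum cross-correlation, and the period
#' coefficient of variation of each trace (the stochasticity summary).
#'
#' @param bundle a `trace_bundle`.
#' @param smooth_sigma smoothing (samples) applied before cycle detection
#'   for the period CVs.
#' @return List: `r_myosin_protrusion`, `r_myosin_area`,
#'   `lag_myosin_protrusion_s`, `lag_myosin_area_s`, `period_cv` (named),
#'   `flagged`.
#' @export
coupling_stats <- function(bundle, smooth_sigma = 3) {
  chans <- c("myosin", "protrusion_pct", "basal_area")
  vals <- lapply(chans, function(ch) bundle[[ch]]$values)
  names(vals) <- chans
  flagged <- any(vapply(vals, function(v) stats::var(v) == 0, logical(1)))
  r <- function(a, b)
    if (stats::var(a) == 0 || stats::var(b) == 0) NA_real_
    else stats::cor(a, b)
  best_lag <- function(a, b) {
    if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
    cc <- stats::ccf(a, b, lag.max = floor(length(a) / 3), plot = FALSE)
    cc$lag[which.max(cc$acf)] * bundle$myosin$dt_s
  }
  period_cv <- vapply(chans, function(ch) {
    tr <- bundle[[ch]]
    if (stats::var(tr$values) == 0) return(NA_real_)
    cyc <- detect_cycles(preprocess_trace(tr, 0, smooth_sigma))
    if (length(cyc$peak_indices) < 3L) return(NA_real_)
    iv <- diff(cyc$peak_indices) * tr$dt_s
    stats::sd(iv) / mean(iv)
  }, numeric(1))
  list(
    r_myosin_protrusion = r(vals$myosin, vals$protrusion_pct),
    r_myosin_area = r(vals$myosin, vals$basal_area),
    lag_myosin_protrusion_s = best_lag(vals$myosin, vals$protrusion_pct),
    lag_myosin_area_s = best_lag(vals$myosin, vals$basal_area),
    period_cv = period_cv,
    flagged = flagged
  )
}
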