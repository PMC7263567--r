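# Time-series pipeline: smoothing, cycle detection, interval and spectral
# period estimates, amplitudes, coupling.

sin_trace <- function(period_s, n, dt = 30, amp = 1, mean_ = 0,
                      phase = 0, noise = 0) {
  t <- (seq_len(n) - 1) * dt
  v <- mean_ + amp * sin(2 * pi * t / period_s + phase)
  if (noise > 0) v <- v + rnorm(n, 0, noise)
  intensity_trace(v, dt)
}

test_that("preprocessing preserves constants, mass and linearity", {
  const <- intensity_trace(rep(12, 64), 30)
  out <- preprocess_trace(const, background_value = 2)
  expect_equal(out$values, rep(10, 64), tolerance = 1e-9)
  # impulse: kernel comes out, sum preserved
  imp <- intensity_trace(c(rep(0, 31), 100, rep(0, 32)), 30)
  sm <- preprocess_trace(imp)
  expect_equal(sum(sm$values), 100, tolerance = 1e-9)
  expect_equal(which.max(sm$values), 32)
  # variance reduction factor for white noise: sum of squared weights
  w <- basalact:::gaussian_kernel(3)
  set.seed(9)
  x <- rnorm(4096)
  sm2 <- basalact:::smooth1d(x, 3)
  expect_lt(var(sm2), var(x))
  expect_equal(var(sm2) / var(x), sum(w^2), tolerance = 0.1)
  # linearity after zero background
  a <- intensity_trace(runif(64, 1, 2), 30)
  b <- intensity_trace(runif(64, 1, 2), 30)
  lhs <- preprocess_trace(intensity_trace(2 * a$values + 3 * b$values, 30))
  rhs <- 2 * preprocess_trace(a)$values + 3 * preprocess_trace(b)$values
  expect_equal(lhs$values, rhs, tolerance = 1e-9)
  expect_error(preprocess_trace(intensity_trace(1:8, 30)), "kernel")
  expect_error(preprocess_trace(const, background_value = -1),
               "non-negative")
})

test_that("cycle detection finds sinusoid extrema and flags ramps", {
  tr <- sin_trace(480, 4 * 16, dt = 30)     # exactly 4 periods
  cyc <- detect_cycles(tr)
  expect_false(cyc$flagged)
  expect_equal(length(cyc$peak_indices), 4)
  expect_equal(length(cyc$trough_indices), 4)
  expect_true(all(diff(sort(c(cyc$peak_indices, cyc$trough_indices))) > 0))
  ramp <- intensity_trace(seq_len(64), 30)
  expect_true(detect_cycles(ramp)$flagged)
  # 1% noise leaves the peak count unchanged (smoothed first)
  set.seed(4)
  noisy <- sin_trace(480, 128, noise = 0.01)
  cyc_n <- detect_cycles(preprocess_trace(noisy))
  cyc_0 <- detect_cycles(preprocess_trace(sin_trace(480, 128)))
  expect_equal(length(cyc_n$peak_indices), length(cyc_0$peak_indices))
})

test_that("interval periods and amplitudes follow their definitions", {
  cyc <- structure(list(peak_indices = c(5, 21, 37),
                        trough_indices = c(13, 29),
                        amplitudes = c(4, 4), flagged = FALSE),
                   class = "cycle_set")
  p <- period_from_intervals(cyc, 30)
  expect_equal(p$intervals_s, c(480, 480))
  expect_equal(p$mean_s, 480)
  cyc2 <- structure(list(peak_indices = c(1, 11, 31),
                         trough_indices = c(5, 21),
                         amplitudes = c(1, 2), flagged = FALSE),
                    class = "cycle_set")
  expect_equal(period_from_intervals(cyc2, 1)$intervals_s, c(10, 20))
  expect_equal(period_from_intervals(cyc2, 1)$mean_s, 15)
  one <- structure(list(peak_indices = 3L, trough_indices = integer(0),
                        amplitudes = numeric(0), flagged = TRUE),
                   class = "cycle_set")
  expect_error(period_from_intervals(one, 30), "fewer than 2")
  expect_error(cycle_amplitude(one), "no complete cycle")
  # sinusoid of amplitude A has max - min = 2A
  tr <- sin_trace(480, 128, amp = 50, mean_ = 100)
  expect_equal(cycle_amplitude(detect_cycles(tr, refine = tr)), 100,
               tolerance = 1e-9)
  # constant trace has no cycles
  expect_true(detect_cycles(intensity_trace(rep(3, 64), 30))$flagged)
})

test_that("PSD dominant period is exact on on-bin sinusoids", {
  tr <- sin_trace(480, 128, dt = 30)
  ps <- psd_dominant_period(tr)
  expect_equal(ps$dominant_period_s, 480)
  expect_equal(ps$autocorrelation[1], 1)
  # the stronger of two sinusoids wins (amplitudes 3 vs 1)
  t <- (0:127) * 30
  two <- intensity_trace(3 * sin(2 * pi * t / 480) +
                           1 * sin(2 * pi * t / 240), 30)
  expect_equal(psd_dominant_period(two)$dominant_period_s, 480)
  # lag-0 autocorrelation is 1 for any non-constant trace
  set.seed(2)
  rnd <- intensity_trace(rnorm(64), 30)
  expect_equal(psd_dominant_period(rnd)$autocorrelation[1], 1)
  expect_true(psd_dominant_period(intensity_trace(rep(1, 64), 30))$flagged)
  expect_error(psd_dominant_period(intensity_trace(rnorm(16), 30)),
               "32 samples")
})

test_that("interval and spectral estimators agree on on-bin sinusoids", {
  for (Tp in c(320, 480, 640)) {           # on-bin for n = 128, dt = 30
    n <- 128
    tr <- sin_trace(Tp, n, dt = 30)
    cyc <- detect_cycles(tr)
    p_int <- period_from_intervals(cyc, 30)$mean_s
    p_psd <- psd_dominant_period(tr)$dominant_period_s
    bin <- 1 / (n * 30)
    expect_lte(abs(1 / p_int - 1 / p_psd), bin + 1e-12)
  }
})

test_that("coupling statistics report phase relations and period CV", {
  tb <- simulate_traces(cfg0, "mutant", seed = 6, noise_frac = 0,
                        period_jitter = 0)
  cs <- coupling_stats(tb)
  expect_equal(cs$r_myosin_protrusion, 1, tolerance = 1e-9)
  expect_equal(cs$r_myosin_area, -1, tolerance = 1e-9)
  expect_equal(cs$lag_myosin_protrusion_s, 0)
  expect_false(cs$flagged)
  # constant channel flags and yields NA correlation
  tb$basal_area <- intensity_trace(rep(60, length(tb$myosin$values)), 30)
  cs2 <- coupling_stats(tb)
  expect_true(cs2$flagged)
  expect_true(is.na(cs2$r_myosin_area))
  # jittered mutant periods vary more than control ones
  cvm <- mean(replicate(5, {
    s <- sample.int(1e6, 1)
    coupling_stats(simulate_traces(cfg0, "mutant", seed = s,
                                   noise_frac = 0))$period_cv[["myosin"]]
  }), na.rm = TRUE)
  cvc <- mean(replicate(5, {
    s <- sample.int(1e6, 1)
    coupling_stats(simulate_traces(cfg0, "control", seed = s,
                                   noise_frac = 0))$period_cv[["myosin"]]
  }), na.rm = TRUE)
  expect_gt(cvm, cvc)
})

test_that("period recovery works under jitter and noise", {
  set.seed(11)
  errs <- replicate(20, {
    s <- sample.int(1e6, 1)
    tb <- simulate_traces(cfg0, "control", seed = s, noise_frac = 0.05)
    cyc <- detect_cycles(preprocess_trace(tb$myosin))
    abs(period_from_intervals(cyc, 30)$mean_s - 480) / 480
  })
  expect_lt(mean(errs), 0.05)
})
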