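# Stress-fiber scoring: reference statistics, SD-threshold peak calling
# against a brute-force oracle, densities, and intensity ratios.

test_that("control reference pools raw peak heights", {
  mk_prof <- function(heights, base = 0) {
    v <- base
    for (h in heights) v <- c(v, h, base)
    structure(list(positions_um = seq_along(v) - 1, intensity = v,
                   cell_id = 1L, length_um = length(v) - 1),
              class = "line_profile")
  }
  ref <- build_control_reference(list(mk_prof(100), mk_prof(100)))
  expect_equal(ref$mean_peak_intensity, 100)
  expect_equal(ref$sd_peak_intensity, 0)
  ref2 <- build_control_reference(list(mk_prof(80), mk_prof(120)))
  expect_equal(ref2$mean_peak_intensity, 100)
  expect_equal(ref2$sd_peak_intensity, sd(c(80, 120)), tolerance = 1e-6)
  expect_equal(round(ref2$sd_peak_intensity, 3), 28.284)
  expect_error(build_control_reference(list()), "at least 2")
  flat <- structure(list(positions_um = 0:9, intensity = rep(1, 10),
                         cell_id = 1L, length_um = 9),
                    class = "line_profile")
  expect_error(build_control_reference(list(flat, flat)), "no local maxima")
})

test_that("detect_peaks matches the hand-computed bump examples", {
  # 5 bumps of height 100 on baseline 10, 2 um apart
  v <- rep(10, 55)
  pos <- (seq_along(v) - 1) * 0.2
  bump_at <- c(5, 15, 25, 35, 45)
  v[bump_at] <- 100
  prof <- structure(list(positions_um = pos, intensity = v, cell_id = 1L,
                         length_um = max(pos)), class = "line_profile")
  ref_lo <- structure(list(mean_peak_intensity = 80, sd_peak_intensity = 20,
                           n_peaks = 10), class = "control_reference")
  pk <- detect_peaks(prof, ref_lo)           # threshold 60
  expect_equal(length(pk$peak_heights), 5)
  expect_equal(pk$threshold_used, 60)
  ref_hi <- structure(list(mean_peak_intensity = 150,
                           sd_peak_intensity = 20, n_peaks = 10),
                      class = "control_reference")
  expect_equal(length(detect_peaks(prof, ref_hi)$peak_heights), 0)
  flat <- structure(list(positions_um = pos, intensity = rep(5, 55),
                         cell_id = 1L, length_um = max(pos)),
                    class = "line_profile")
  expect_equal(length(detect_peaks(flat, ref_lo)$peak_heights), 0)
})

test_that("detect_peaks equals the exhaustive brute-force scan", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(10:200, 1)
    x <- cumsum(rnorm(n))
    x <- x - min(x) + runif(1, 0, 5)
    pos <- (seq_len(n) - 1) * 0.2
    thr <- quantile(x, runif(1, 0.2, 0.9))
    prof <- structure(list(positions_um = pos, intensity = x, cell_id = 1L,
                           length_um = max(pos)), class = "line_profile")
    ref <- structure(list(mean_peak_intensity = thr, sd_peak_intensity = 0,
                          n_peaks = 5), class = "control_reference")
    got <- detect_peaks(prof, ref, min_sep_um = 0.5)
    want <- oracle_peaks(x, pos, thr, 0.5)
    expect_equal(got$peak_positions_um, pos[want])
    expect_equal(got$peak_heights, x[want])
  }
})

test_that("plateaus resolve to their leftmost sample", {
  x <- c(0, 1, 5, 5, 5, 1, 0)
  idx <- basalact:::local_maxima(x)
  expect_identical(idx, 3L)
})

test_that("peak density divides count by profile length", {
  prof <- structure(list(positions_um = seq(0, 10, by = 0.5),
                         intensity = rep(1, 21), cell_id = 1L,
                         length_um = 10), class = "line_profile")
  pk <- structure(list(peak_positions_um = 1:6, peak_heights = rep(9, 6),
                       threshold_used = 0), class = "peak_set")
  expect_equal(peak_density(pk, prof), 0.6)
  pk0 <- structure(list(peak_positions_um = numeric(0),
                        peak_heights = numeric(0), threshold_used = 0),
                   class = "peak_set")
  expect_equal(peak_density(pk0, prof), 0)
  prof$length_um <- 0
  expect_error(peak_density(pk, prof), "zero-length")
})

test_that("peak density is invariant to joint intensity rescaling", {
  gs <- generate_scene(cfg0, "control", n_cells = 9, seed = 5, noise_sd = 0)
  prof <- extract_profile(gs$scene, 1L)
  ref <- build_control_reference(list(prof, extract_profile(gs$scene, 2L)))
  d1 <- peak_density(detect_peaks(prof, ref), prof)
  prof2 <- prof; prof2$intensity <- prof$intensity * 3.7
  ref2 <- ref
  ref2$mean_peak_intensity <- ref$mean_peak_intensity * 3.7
  ref2$sd_peak_intensity <- ref$sd_peak_intensity * 3.7
  d2 <- peak_density(detect_peaks(prof2, ref2), prof2)
  expect_equal(d1, d2)
})

test_that("profiles cross the cell and match chord geometry", {
  gs <- generate_scene(cfg0, "control", n_cells = 9, seed = 6, noise_sd = 0)
  sc <- gs$scene
  prof <- extract_profile(sc, 4L)
  # length agrees with the chord computed from the label mask
  chord_px <- sqrt(sum((prof$chord_end - prof$chord_start)^2))
  expect_equal(prof$length_um, chord_px * sc$calibration,
               tolerance = sc$calibration + 1e-9)
  # uniform cell: profile is constant
  flat <- two_cell_scene(value = 4)
  pf <- extract_profile(flat, 1L, cortical_margin_um = 0.5)
  expect_true(all(pf$intensity == 4))
  # degenerate cell errors out
  lab <- matrix(0L, 30, 30); lab[10:12, 10:12] <- 1L
  tiny <- make_scene(matrix(1, 30, 30), lab, px_um = 0.5)
  expect_error(extract_profile(tiny, 1L), "degenerate|narrow")
})

test_that("detected peaks equal truth fibers crossing the chord", {
  for (sd_ in c(5, 9, 11)) {
    gs <- generate_scene(cfg0, "control", n_cells = 9, seed = sd_,
                         noise_sd = 0)
    sc <- gs$scene; tru <- gs$truth
    ids <- as.integer(names(sc$genotype))
    profs <- lapply(ids, function(id) extract_profile(sc, id))
    ref <- build_control_reference(profs)
    for (i in seq_along(ids)) {
      prof <- profs[[i]]
      fb <- tru$fibers[tru$fibers$cell_id == ids[i], , drop = FALSE]
      xr <- range(prof$chord_start[1], prof$chord_end[1])
      yrow <- prof$chord_start[2]
      crossing <- sum(fb$x_px >= xr[1] & fb$x_px <= xr[2] &
                        fb$y0_px <= yrow & fb$y1_px >= yrow)
      expect_equal(length(detect_peaks(prof, ref)$peak_heights), crossing)
    }
  }
})

test_that("relative intensity recovers the preset reductions", {
  gs <- generate_scene(cfg0, "mutant", seed = 3, noise_sd = 0)
  sc <- gs$scene
  ids <- as.integer(names(sc$genotype))
  mut <- ids[sc$genotype[as.character(ids)] == "mutant"]
  ctl <- setdiff(ids, mut)
  # identical groups -> exactly 1
  expect_equal(relative_intensity(sc, ctl, ctl), 1)
  # F-actin in fibers: mutant at 40% of control (the 60% reduction)
  expect_equal(relative_intensity(sc, mut, ctl, "fiber-region", gs$truth),
               0.40, tolerance = 1e-6)
  gm <- generate_scene(cfg0, "mutant", seed = 3, channel = "myosin",
                       noise_sd = 0)
  idsm <- as.integer(names(gm$scene$genotype))
  mutm <- idsm[gm$scene$genotype[as.character(idsm)] == "mutant"]
  expect_equal(relative_intensity(gm$scene, mutm, setdiff(idsm, mutm),
                                  "fiber-region", gm$truth),
               0.60, tolerance = 1e-6)
  expect_error(relative_intensity(sc, integer(0), ctl), "non-empty")
})

test_that("mutant peak density falls below control on noiseless scenes", {
  gs <- generate_scene(cfg0, "mutant", seed = 8, noise_sd = 0)
  ft <- fiber_table(gs$scene)
  dens <- tapply(ft$density_per_um, ft$genotype, mean)
  expect_lt(dens[["mutant"]], dens[["control"]])
})
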