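# Synthetic-data generators: determinism, ground-truth bookkeeping, and
# the closed forms the traces must satisfy.

test_that("configuration validates physical parameters and preset names", {
  expect_s3_class(cfg0, "synth_config")
  bad <- cfg0
  bad$presets$control$fiber_intensity <- -1
  expect_error(basalact:::validate_synth_config(bad), "positive")
  bad2 <- cfg0
  bad2$recoil[["mut-mut"]]$tau_s <- 0
  expect_error(basalact:::validate_synth_config(bad2), "tau")
  expect_error(generate_scene(cfg0, "nonexistent"), "unknown preset")
  expect_error(generate_scene(cfg0, "control", n_cells = 3L),
               "tricellular")
})

test_that("configuration survives a YAML round trip", {
  path <- tempfile(fileext = ".yaml")
  write_synth_config(cfg0, path)
  cfg2 <- read_synth_config(path)
  expect_equal(cfg2$presets, cfg0$presets)
  expect_equal(cfg2$recoil, cfg0$recoil)
  expect_equal(cfg2$morpho$control$basal_area_by_stage,
               cfg0$morpho$control$basal_area_by_stage)
})

test_that("fixed seed gives bit-identical scenes, traces and tables", {
  a <- generate_scene(cfg0, "mutant", n_cells = 9, seed = 7)
  b <- generate_scene(cfg0, "mutant", n_cells = 9, seed = 7)
  expect_identical(a$scene$image, b$scene$image)
  expect_identical(a$scene$labels, b$scene$labels)
  expect_identical(a$truth$fibers, b$truth$fibers)
  expect_identical(simulate_traces(cfg0, "control", seed = 3)$myosin$values,
                   simulate_traces(cfg0, "control", seed = 3)$myosin$values)
  expect_identical(simulate_recoil(cfg0, "mut-mut", seed = 5)$distance_um,
                   simulate_recoil(cfg0, "mut-mut", seed = 5)$distance_um)
  expect_identical(simulate_morphometry(cfg0, 10, seed = 2),
                   simulate_morphometry(cfg0, 10, seed = 2))
})

test_that("scene truth records the configured structures", {
  gs <- generate_scene(cfg0, "control", n_cells = 9, seed = 5, noise_sd = 0)
  # large cells: every cell carries its full preset fiber complement
  counts <- table(gs$truth$fibers$cell_id)
  expect_true(all(counts <= 6))
  expect_gte(mean(counts), 5)
  # whip truth: two per control cell, anchored at junctions
  wc <- count_whips(gs$scene, gs$truth$whips)
  expect_equal(mean(wc$whip_count), 2)
  # labels and image agree in shape; genotype keys all occur in labels
  expect_identical(dim(gs$scene$image), dim(gs$scene$labels))
  expect_true(all(as.integer(names(gs$scene$genotype)) %in%
                    gs$scene$labels))
})

test_that("tricellular points touch >= 3 labels within one pixel", {
  gs <- generate_scene(cfg0, "mutant", n_cells = 12, seed = 2)
  lab <- gs$scene$labels
  jx <- gs$scene$tricellular
  expect_gt(nrow(jx), 0)
  for (i in seq_len(nrow(jx))) {
    xs <- max(1, floor(jx$x[i] - 1)):min(ncol(lab), ceiling(jx$x[i] + 1))
    ys <- max(1, floor(jx$y[i] - 1)):min(nrow(lab), ceiling(jx$y[i] + 1))
    v <- lab[ys, xs]
    expect_gte(length(unique(v[v > 0])), 3)
  }
})

test_that("noiseless traces satisfy their closed forms", {
  tb <- simulate_traces(cfg0, "control", seed = 1, noise_frac = 0,
                        period_jitter = 0)
  n <- length(tb$myosin$values)
  t <- (seq_len(n) - 1) * 30
  expect_equal(tb$myosin$values, 200 + 100 * sin(2 * pi * t / 480),
               tolerance = 1e-9)
  # myosin maxima spaced exactly one period apart
  pk <- basalact:::local_maxima(tb$myosin$values)
  expect_true(all(diff(pk) * 30 == 480))
  # protrusion is phase-locked (coupling phase 0 -> r = 1)
  expect_equal(cor(tb$myosin$values, tb$protrusion_pct$values), 1,
               tolerance = 1e-12)
  # basal area is anti-phase
  expect_equal(cor(tb$myosin$values, tb$basal_area$values), -1,
               tolerance = 1e-12)
  expect_true(all(tb$protrusion_pct$values >= 0 &
                    tb$protrusion_pct$values <= 100))
  expect_error(simulate_traces(cfg0, "control", duration_s = 600),
               "3 oscillation periods")
})

test_that("recoil traces follow the saturating exponential", {
  tr <- simulate_recoil(cfg0, "mut-mut", seed = 1, noise_frac = 0)
  expect_equal(diff(tr$times_s), rep(0.8, length(tr$times_s) - 1),
               tolerance = 1e-12)
  expect_gte(tr$times_s[tr$cut_index] - tr$times_s[1], 10)
  r <- cfg0$recoil[["mut-mut"]]
  post <- tr$times_s[-(1:tr$cut_index)] - tr$times_s[tr$cut_index]
  expect_equal(tr$distance_um[-(1:tr$cut_index)],
               r$L0_um + r$dLmax_um * (1 - exp(-post / r$tau_s)),
               tolerance = 1e-9)
  expect_equal(tr$truth_v0_um_per_s, 1.26, tolerance = 1e-9)
  # closed form evaluated independently: dLmax 2, tau 2
  tr2 <- exp_recoil_trace(dLmax = 2, tau = 2)
  expect_equal(tr2$truth_v0_um_per_s, 2 * (1 - exp(-0.4)) / 0.8,
               tolerance = 1e-12)
  # no recoil
  cfgz <- cfg0
  cfgz$recoil[["mut-mut"]]$dLmax_um <- 0
  trz <- simulate_recoil(cfgz, "mut-mut", seed = 1, noise_frac = 0)
  expect_true(all(trz$distance_um == cfgz$recoil[["mut-mut"]]$L0_um))
  expect_equal(trz$truth_v0_um_per_s, 0)
})

test_that("morphometry table honours stage means and handles n = 0", {
  empty <- simulate_morphometry(cfg0, 0)
  expect_s3_class(empty, "cell_table")
  expect_equal(nrow(empty), 0)
  mt <- simulate_morphometry(cfg0, 20, seed = 4, area_cv = 0)
  m <- aggregate(basal_area_um2 ~ stage + genotype, mt, mean)
  ctrl <- cfg0$morpho$control$basal_area_by_stage
  for (st in names(ctrl))
    expect_equal(m$basal_area_um2[m$stage == st & m$genotype == "control"],
                 unname(ctrl[[st]]))
  # nuclear size identical between genotypes by preset (the null result)
  nuc <- aggregate(nuclear_area_um2 ~ genotype, mt, mean)
  expect_equal(nuc$nuclear_area_um2[1], nuc$nuclear_area_um2[2])
  cfgbad <- cfg0
  cfgbad$morpho$mutant$basal_area_by_stage <-
    cfgbad$morpho$mutant$basal_area_by_stage[-1]
  expect_error(simulate_morphometry(cfgbad, 5), "stage presets")
})

test_that("scene and trace I/O round-trip through TIFF and CSV", {
  gs <- generate_scene(cfg0, "mutant", n_cells = 9, seed = 3, noise_sd = 0)
  stem <- file.path(tempdir(), "scene_rt")
  write_scene(gs$scene, stem)
  sc2 <- read_scene(stem)
  expect_identical(sc2$labels, gs$scene$labels)
  expect_equal(sc2$image, round(gs$scene$image), tolerance = 1e-6)
  expect_identical(sc2$genotype, gs$scene$genotype)
  tb <- simulate_traces(cfg0, "control", seed = 1)
  pth <- tempfile(fileext = ".csv")
  write_trace_bundle(tb, pth)
  tb2 <- read_trace_bundle(pth)
  expect_equal(tb2$myosin$values, tb$myosin$values, tolerance = 1e-6)
  tr <- simulate_recoil(cfg0, "ctrl-ctrl", seed = 2)
  pth2 <- tempfile(fileext = ".csv")
  write_ablation_trace(tr, pth2)
  tr2 <- read_ablation_trace(pth2)
  expect_equal(tr2$cut_index, tr$cut_index)
  expect_equal(tr2$distance_um, tr$distance_um, tolerance = 1e-6)
})
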