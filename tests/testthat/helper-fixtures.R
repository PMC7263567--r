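# Shared fixtures: a default configuration and hand-built scenes used by
# the unit tests. Everything is generated in code; nothing is read from
# disk.

cfg0 <- synth_config()

# Wrap bare matrices into an image_scene (calibration in um/pixel).
make_scene <- function(image, labels, genotype = NULL, px_um = 0.5,
                       channel = "factin", surface = "basal") {
  if (is.null(genotype)) {
    ids <- sort(unique(labels[labels > 0L]))
    genotype <- stats::setNames(rep("control", length(ids)),
                                as.character(ids))
  }
  structure(list(
    image = image, labels = labels, genotype = genotype,
    tricellular = basalact:::find_tricellular(labels),
    calibration = px_um, channel = channel, surface = surface,
    leading_edge = "west", preset_name = NA_character_
  ), class = "image_scene")
}

# Two cells split by a vertical line, uniform intensity.
two_cell_scene <- function(n = 40L, value = 7, px_um = 0.5) {
  labels <- matrix(0L, n, n)
  labels[3:(n - 2), 3:(n / 2)] <- 1L
  labels[3:(n - 2), (n / 2 + 1):(n - 2)] <- 2L
  make_scene(matrix(value, n, n), labels, px_um = px_um)
}

# Noiseless synthetic ablation trace built directly from the closed form.
exp_recoil_trace <- function(L0 = 5, dLmax = 2, tau = 2, dt = 0.8,
                             pre_s = 10.4, post_s = 15.2) {
  pre_t <- seq(0, pre_s, by = dt)
  post_t <- seq(dt, post_s, by = dt)
  structure(list(
    times_s = c(pre_t, pre_t[length(pre_t)] + post_t),
    distance_um = c(rep(L0, length(pre_t)),
                    L0 + dLmax * (1 - exp(-post_t / tau))),
    cut_index = length(pre_t),
    truth_v0_um_per_s = dLmax * (1 - exp(-dt / tau)) / dt,
    group = "synthetic"
  ), class = "ablation_trace")
}

# Brute-force peak-detection oracle: scan all strict-left / non-strict-
# right maxima, apply the height threshold, then greedy separation by
# descending height. Independent of the package's vectorised path.
oracle_peaks <- function(x, pos, threshold, min_sep) {
  cand <- integer(0)
  for (i in 2:(length(x) - 1L))
    if (x[i] > x[i - 1L] && x[i] >= x[i + 1L] && x[i] >= threshold)
      cand <- c(cand, i)
  kept <- integer(0)
  for (j in cand[order(-x[cand], pos[cand])]) {
    ok <- TRUE
    for (k in kept) if (abs(pos[j] - pos[k]) < min_sep) ok <- FALSE
    if (ok) kept <- c(kept, j)
  }
  sort(kept)
}
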