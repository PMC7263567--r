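# Vertex-distance traces around a laser cut: a >= 10 s pre-cut baseline
# sampled every 0.8 s, then saturating-exponential recoil
# L(t) = L0 + dLmax * (1 - exp(-t / tau)).

#' Simulate a laser-ablation vertex-distance trace
#'
#' The pre-cut window covers 10.4 s (14 frames at 0.8 s) of baseline; the
#' post-cut recoil is monitored for 15.2 s. The closed-form initial
#' velocity at the first post-cut frame,
#' `dLmax * (1 - exp(-0.8 / tau)) / 0.8`, is recorded as ground truth.
#' Gaussian noise with SD `noise_frac * dLmax` is added to every sample.
#'
#' @param config a [synth_config()].
#' @param preset_name boundary class: one of the names of `config$recoil`
#'   (`"ctrl-ctrl"`, `"ctrl-mut"`, `"mut-mut"`, `"rescue"`).
#' @param seed integer seed.
#' @param noise_frac noise SD as a fraction of `dLmax`; defaults to the
#'   preset.
#' @return An `ablation_trace`: `times_s`, `distance_um`, `cut_index`
#'   (last pre-cut frame), `truth_v0_um_per_s`, `group`.
#' @export
simulate_recoil <- function(config, preset_name, seed = config$seed,
                            noise_frac = NULL) {
  r <- config$recoil[[preset_name]]
  if (is.null(r))
    stop("unknown recoil preset '", preset_name, "'", call. = FALSE)
  if (r$tau_s <= 0) stop("tau must be positive", call. = FALSE)
  noise_frac <- noise_frac %||% r$noise_frac
  dt <- 0.8
  pre_t <- seq(0, 10.4, by = dt)
  post_t <- seq(dt, 15.2, by = dt)
  with_seed(seed, {
    d_pre <- rep(r$L0_um, length(pre_t))
    d_post <- r$L0_um + r$dLmax_um * (1 - exp(-post_t / r$tau_s))
    d <- c(d_pre, d_post)
    sdn <- noise_frac * r$dLmax_um
    if (sdn > 0) d <- d + stats::rnorm(length(d), 0, sdn)
    structure(list(
      times_s = c(pre_t, pre_t[length(pre_t)] + post_t),
      distance_um = d,
      cut_index = length(pre_t),
      truth_v0_um_per_s = r$dLmax_um * (1 - exp(-dt / r$tau_s)) / dt,
      group = preset_name
    ), class = "ablation_trace")
  })
}

#' Write / read an ablation trace as CSV
#'
#' Columns: `time_s`, `distance_um`, `post_cut` (0/1).
#' @param trace an `ablation_trace`.
#' @param path CSV path.
#' @return the path / an `ablation_trace`.
#' @export
write_ablation_trace <- function(trace, path) {
  utils::write.csv(data.frame(
    time_s = trace$times_s, distance_um = trace$distance_um,
    post_cut = as.integer(seq_along(trace$times_s) > trace$cut_index)),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ablation_trace
#' @export
read_ablation_trace <- function(path) {
  df <- utils::read.csv(path)
  structure(list(
    times_s = df$time_s, distance_um = df$distance_um,
    cut_index = max(which(df$post_cut == 0L)),
    truth_v0_um_per_s = NA_real_, group = NA_character_
  ), class = "ablation_trace")
}
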