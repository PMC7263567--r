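#' Build a synthetic-data configuration
#'
#' Central parameter object for the synthetic generators. The condition
#' presets transcribe the effect sizes measured in mosaic follicular
#' epithelia: a mutant (integrin-null) follicle cell carries ~3x more
#' whip-like protrusions than the two found at control leading edges,
#' stress-fiber F-actin reduced to 40% and fiber myosin to 60% of control,
#' a two-fold cortical F-actin increase restricted to mutant-mutant
#' boundaries, a shorter and more jittery basal oscillation period, and a
#' near-symmetric (~1.2) D-V/A-P contraction anisotropy against ~5 in
#' controls. Recoil presets hold the baseline vertex distance, maximal
#' displacement and viscoelastic time constant per boundary class; the
#' maximal displacement is chosen so that the closed-form initial velocity
#' dLmax * (1 - exp(-0.8/tau)) / 0.8 equals the measured group velocity
#' (1.26, 0.58, 0.61 and 0.38 um/s for mut-mut, ctrl-ctrl, ctrl-mut and the
#' protrusion-suppressed rescue).
#'
#' @param seed default integer seed for the generators.
#' @param pixel_size_um physical pixel size of synthetic scenes (um/pixel).
#' @param frame_interval_s sampling interval of oscillation traces (s).
#' @param field_px side length of the square synthetic field, in pixels.
#' @param background_offset constant detector offset added to every pixel
#'   (a.u.); the value recovered by background subtraction.
#' @param presets named list of condition presets; see
#'   [default_presets()].
#' @param recoil named list of ablation presets per boundary class; see
#'   [default_recoil_presets()].
#' @param morpho per-genotype stage means for the morphometry generator; see
#'   [default_morpho_presets()].
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         pixel_size_um = 0.2,
                         frame_interval_s = 30,
                         field_px = 256L,
                         background_offset = 20,
                         presets = default_presets(),
                         recoil = default_recoil_presets(),
                         morpho = default_morpho_presets()) {
  cfg <- structure(list(
    seed = as.integer(seed),
    pixel_size_um = pixel_size_um,
    frame_interval_s = frame_interval_s,
    field_px = as.integer(field_px),
    background_offset = background_offset,
    presets = presets,
    recoil = recoil,
    morpho = morpho
  ), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

#' Default condition presets
#'
#' One parameter set per condition. Image parameters are in arbitrary
#' fluorescence units, times in seconds, lengths in micrometres.
#' `fiber_jitter_frac` is the half-width of the uniform per-fiber intensity
#' jitter (bounded, so the control reference threshold mean - 1 SD lies below
#' every control peak).
#' @return Named list with elements `control`, `mutant`, `mutant_rescue`.
#' @export
default_presets <- function() {
  control <- list(
    fiber_count_per_cell = 6L,
    fiber_intensity = 200,         # F-actin channel, peak height a.u.
    myosin_intensity = 150,        # myosin channel, peak height a.u.
    fiber_jitter_frac = 0,
    cortical_intensity = 100,
    whip_count_leading_edge = 2L,
    whip_intensity = 150,
    protrusion_area_pct = 2,
    oscillation_period_s = 480,
    oscillation_amplitude = 100,
    period_jitter = 0.05,
    coupling_phase = 0,
    dv_frac_change = 0.10,         # per-cycle fractional D-V length change
    ap_frac_change = 0.02,         # anisotropy 5
    trace_noise_frac = 0.10,
    noise_sd = 10                  # image Gaussian read noise, a.u.
  )
  mutant <- utils::modifyList(control, list(
    fiber_count_per_cell = 3L,
    fiber_intensity = 80,          # 40% of control: the 60% reduction
    myosin_intensity = 90,         # 60% of control: the 40% reduction
    cortical_intensity = 200,      # two-fold cortical F-actin
    whip_count_leading_edge = 6L,  # "more than 5"
    protrusion_area_pct = 20,
    oscillation_period_s = 300,
    oscillation_amplitude = 60,
    period_jitter = 0.20,          # "more stochastic" oscillations
    dv_frac_change = 0.06,
    ap_frac_change = 0.05          # anisotropy 1.2
  ))
  rescue <- utils::modifyList(mutant, list(
    whip_count_leading_edge = 0L,  # protrusion formation blocked
    protrusion_area_pct = 0,
    cortical_intensity = 100
  ))
  list(control = control, mutant = mutant, mutant_rescue = rescue)
}

#' Default laser-ablation presets per boundary class
#'
#' `dLmax_um` is derived from the target initial velocity `v0_um_per_s`
#' through the exponential-recoil closed form at the 0.8-s frame interval.
#' @param tau_s viscoelastic relaxation time (s), shared across classes.
#' @return Named list keyed by boundary class.
#' @export
default_recoil_presets <- function(tau_s = 2) {
  v0 <- c("ctrl-ctrl" = 0.58, "ctrl-mut" = 0.61,
          "mut-mut" = 1.26, "rescue" = 0.38)
  lapply(as.list(v0), function(v) {
    list(L0_um = 5,
         dLmax_um = v * 0.8 / (1 - exp(-0.8 / tau_s)),
         tau_s = tau_s,
         noise_frac = 0.05)
  })
}

#' Default morphometry stage presets
#'
#' Mean basal areas per stage encode the measured growth: control cells grow
#' their basal surface 1.7x from S8 to S9 and 1.8x from S9 to S10; mutant
#' cells only 1.5x and 1.3x. Apical area, height and nuclear size are shared
#' between genotypes (the null results).
#' @return Named list with elements `control`, `mutant`, `area_cv`.
#' @export
default_morpho_presets <- function() {
  stages <- c("S6", "S7", "S8", "S9", "S10")
  basal_ctrl <- c(30, 40, 50, 50 * 1.7, 50 * 1.7 * 1.8)
  basal_mut  <- c(30, 40, 50, 50 * 1.5, 50 * 1.5 * 1.3)
  apical     <- c(30, 35, 40, 48, 55)
  names(basal_ctrl) <- names(basal_mut) <- names(apical) <- stages
  list(
    control = list(basal_area_by_stage = basal_ctrl,
                   apical_area_by_stage = apical,
                   height_um = 12, nuclear_area_um2 = 25),
    mutant  = list(basal_area_by_stage = basal_mut,
                   apical_area_by_stage = apical,
                   height_um = 12, nuclear_area_um2 = 25),
    area_cv = 0.2
  )
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$pixel_size_um <= 0 || cfg$frame_interval_s <= 0 ||
      cfg$field_px < 32)
    stop("calibration parameters must be strictly positive", call. = FALSE)
  if (anyDuplicated(names(cfg$presets)))
    stop("preset names must be unique", call. = FALSE)
  for (nm in names(cfg$presets)) {
    p <- cfg$presets[[nm]]
    num <- unlist(p[c("fiber_intensity", "myosin_intensity",
                      "cortical_intensity", "whip_intensity",
                      "oscillation_period_s", "oscillation_amplitude")])
    if (any(!is.finite(num)) || any(num <= 0))
      stop("preset '", nm, "': physical parameters must be positive",
           call. = FALSE)
  }
  for (nm in names(cfg$recoil)) {
    r <- cfg$recoil[[nm]]
    if (r$tau_s <= 0)
      stop("recoil preset '", nm, "': tau must be positive", call. = FALSE)
    if (r$L0_um <= 0 || r$dLmax_um < 0)
      stop("recoil preset '", nm, "': invalid geometry", call. = FALSE)
  }
  invisible(cfg)
}

get_preset <- function(cfg, preset_name) {
  p <- cfg$presets[[preset_name]]
  if (is.null(p))
    stop("unknown preset '", preset_name, "'", call. = FALSE)
  p
}

#' Read / write a configuration as YAML
#' @param path file path.
#' @param cfg a `synth_config`.
#' @return `read_synth_config` returns a `synth_config`;
#'   `write_synth_config` returns `path` invisibly.
#' @export
read_synth_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML drops the named-numeric structure of stage means; restore it.
  fix_stages <- function(g) {
    g$basal_area_by_stage <- unlist(g$basal_area_by_stage)
    g$apical_area_by_stage <- unlist(g$apical_area_by_stage)
    g
  }
  raw$morpho$control <- fix_stages(raw$morpho$control)
  raw$morpho$mutant <- fix_stages(raw$morpho$mutant)
  do.call(synth_config, raw)
}

#' @rdname read_synth_config
#' @export
write_synth_config <- function(cfg, path) {
  validate_synth_config(cfg)
  out <- unclass(cfg)
  # named numeric vectors serialise as YAML maps only as lists
  for (g in c("control", "mutant")) {
    out$morpho[[g]]$basal_area_by_stage <-
      as.list(out$morpho[[g]]$basal_area_by_stage)
    out$morpho[[g]]$apical_area_by_stage <-
      as.list(out$morpho[[g]]$apical_area_by_stage)
  }
  yaml::write_yaml(out, path, precision = 12L)
  invisible(path)
}
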