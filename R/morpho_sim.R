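# Synthetic per-cell morphometry table across oogenesis stages.

#' Simulate a morphometric cell table
#'
#' Draws per-cell basal area, apical area, height and nuclear area for both
#' genotypes at stages S6-S10 from the configured stage means with
#' multiplicative Gaussian noise of coefficient of variation `area_cv`.
#' With zero noise the group means equal the presets exactly, so
#' stage-to-stage fold changes reproduce the configured growth ratios.
#'
#' @param config a [synth_config()].
#' @param n_cells_per_group cells per (stage, genotype) combination; `0`
#'   yields an empty table.
#' @param seed integer seed.
#' @param area_cv coefficient of variation; defaults to the config.
#' @return A `cell_table` data frame with columns `cell_id`, `stage`,
#'   `genotype`, `basal_area_um2`, `apical_area_um2`, `height_um`,
#'   `nuclear_area_um2`.
#' @export
simulate_morphometry <- function(config, n_cells_per_group = 46L,
                                 seed = config$seed, area_cv = NULL) {
  m <- config$morpho
  area_cv <- area_cv %||% m$area_cv
  stages <- names(m$control$basal_area_by_stage)
  for (g in c("control", "mutant")) {
    if (is.null(m[[g]]) || length(m[[g]]$basal_area_by_stage) == 0L)
      stop("missing stage presets for genotype '", g, "'", call. = FALSE)
    if (!setequal(names(m[[g]]$basal_area_by_stage), stages))
      stop("stage presets differ between genotypes", call. = FALSE)
  }
  empty <- data.frame(cell_id = integer(0), stage = character(0),
                      genotype = character(0), basal_area_um2 = numeric(0),
                      apical_area_um2 = numeric(0), height_um = numeric(0),
                      nuclear_area_um2 = numeric(0))
  if (n_cells_per_group < 1L) return(structure(empty, class = c("cell_table",
                                                                "data.frame")))
  with_seed(seed, {
    rows <- list()
    cid <- 0L
    draw <- function(mean, n) {
      if (area_cv <= 0) return(rep(mean, n))
      pmax(mean * (1 + area_cv * stats::rnorm(n)), 0.05 * mean)
    }
    for (g in c("control", "mutant")) {
      gp <- m[[g]]
      for (st in stages) {
        n <- n_cells_per_group
        rows[[length(rows) + 1L]] <- data.frame(
          cell_id = cid + seq_len(n), stage = st, genotype = g,
          basal_area_um2 = draw(gp$basal_area_by_stage[[st]], n),
          apical_area_um2 = draw(gp$apical_area_by_stage[[st]], n),
          height_um = draw(gp$height_um, n),
          nuclear_area_um2 = draw(gp$nuclear_area_um2, n))
        cid <- cid + n
      }
    }
    structure(do.call(rbind, rows), class = c("cell_table", "data.frame"))
  })
}
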