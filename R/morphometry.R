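# Per-cell geometry and the consolidated report: label-map areas, stage
# growth ratios, protrusion fractions, whip counts at leading-edge
# junctions, contraction anisotropy, and group statistics.

#' Measure basal areas from a label image
#'
#' Basal area is the label pixel count times the squared calibration.
#' Cells present in the genotype map but absent from the labels are
#' skipped with a warning.
#'
#' @param scene an `image_scene`.
#' @return Data frame: `cell_id`, `genotype`, `basal_area_um2`.
#' @export
measure_areas <- function(scene) {
  ids <- as.integer(names(scene$genotype))
  counts <- table(factor(scene$labels[scene$labels > 0L], levels = ids))
  missing <- ids[counts == 0L]
  if (length(missing))
    warning("cells absent from labels skipped: ",
            paste(missing, collapse = ", "), call. = FALSE)
  keep <- counts > 0L
  data.frame(cell_id = ids[keep],
             genotype = unname(scene$genotype[as.character(ids[keep])]),
             basal_area_um2 = as.numeric(counts[keep]) *
               scene$calibration^2,
             row.names = NULL)
}

#' Stage-to-stage basal-area growth ratios
#'
#' Mean basal area at each stage divided by the mean at the preceding
#' stage, per genotype, with a percentile bootstrap confidence interval.
#' Missing stages are omitted and flagged.
#'
#' @param table a `cell_table` (from [simulate_morphometry()] or
#'   equivalent).
#' @param n_boot bootstrap replicates for the CI.
#' @param conf confidence level.
#' @param seed seed for the bootstrap.
#' @return Data frame: `genotype`, `from`, `to`, `fold`, `ci_lo`, `ci_hi`,
#'   `flagged`.
#' @export
growth_ratios <- function(table, n_boot = 200L, conf = 0.95, seed = 1L) {
  stage_order <- c("S6", "S7", "S8", "S9", "S10", "S10A", "S10B")
  stages <- intersect(stage_order, unique(table$stage))
  out <- list()
  with_seed(seed, {
    for (g in unique(table$genotype)) {
      for (k in seq_len(length(stages) - 1L)) {
        a <- table$basal_area_um2[table$stage == stages[k] &
                                    table$genotype == g]
        b <- table$basal_area_um2[table$stage == stages[k + 1L] &
                                    table$genotype == g]
        if (length(a) == 0L || length(b) == 0L) {
          out[[length(out) + 1L]] <- data.frame(
            genotype = g, from = stages[k], to = stages[k + 1L],
            fold = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
            flagged = TRUE)
          next
        }
        fold <- mean(b) / mean(a)
        bs <- vapply(seq_len(n_boot), function(r)
          mean(sample(b, replace = TRUE)) / mean(sample(a, replace = TRUE)),
          numeric(1))
        qs <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                              names = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          genotype = g, from = stages[k], to = stages[k + 1L],
          fold = fold, ci_lo = qs[1], ci_hi = qs[2], flagged = FALSE)
      }
    }
  })
  do.call(rbind, out)
}

#' Protrusion area as a percentage of the basal surface
#'
#' Union of the protrusion masks clipped to the cell, over the cell's
#' basal area, times 100. Overlapping masks count once.
#'
#' @param cell_pixels linear pixel indices of the cell.
#' @param protrusion_pixels list of linear-index vectors, one per
#'   protrusion (or a single vector).
#' @return Percentage in `[0, 100]`.
#' @export
protrusion_fraction <- function(cell_pixels, protrusion_pixels) {
  if (length(cell_pixels) == 0L)
    stop("zero basal area", call. = FALSE)
  pr <- unique(unlist(protrusion_pixels))
  100 * length(intersect(pr, cell_pixels)) / length(cell_pixels)
}

#' Per-cell protrusion statistics of a scene
#'
#' @param scene an `image_scene`.
#' @param truth the matching `scene_truth`.
#' @return Data frame: `cell_id`, `genotype`, `protrusion_area_pct`.
#' @export
protrusion_table <- function(scene, truth) {
  ids <- as.integer(names(scene$genotype))
  do.call(rbind, lapply(ids, function(id) {
    data.frame(cell_id = id, genotype = scene$genotype[as.character(id)],
               protrusion_area_pct = protrusion_fraction(
                 which(scene$labels == id),
                 truth$protrusions[[as.character(id)]]),
               row.names = NULL)
  }))
}

#' Count whip-like structures at leading-edge junctions
#'
#' Counts, per cell, the whip objects anchored within `anchor_radius_um`
#' of one of the cell's leading-edge tricellular junctions (the junctions
#' on the side the scene declares as leading edge), assigned to the cell
#' owning the anchor.
#'
#' @param scene an `image_scene` (supplies junctions and the leading-edge
#'   side).
#' @param whips data frame of whip objects with `cell_id`, `anchor_x`,
#'   `anchor_y` (e.g. `truth$whips`).
#' @param anchor_radius_um assignment radius around a junction.
#' @return Data frame: `cell_id`, `genotype`, `whip_count`.
#' @export
count_whips <- function(scene, whips, anchor_radius_um = 1.0) {
  if (nrow(scene$tricellular) == 0L)
    stop("scene has no tricellular junctions", call. = FALSE)
  cent <- cell_centroids(scene$labels)
  r2 <- (anchor_radius_um / scene$calibration)^2
  ids <- as.integer(names(scene$genotype))
  do.call(rbind, lapply(ids, function(id) {
    js <- leading_junctions_for(scene$tricellular, cent, id)
    n <- 0L
    w <- whips[whips$cell_id == id, , drop = FALSE]
    if (nrow(js) > 0L && nrow(w) > 0L) {
      for (i in seq_len(nrow(w))) {
        d2 <- (js$x - w$anchor_x[i])^2 + (js$y - w$anchor_y[i])^2
        if (any(d2 <= r2)) n <- n + 1L
      }
    }
    data.frame(cell_id = id, genotype = scene$genotype[as.character(id)],
               whip_count = n, row.names = NULL)
  }))
}

#' D-V / A-P contraction anisotropy
#'
#' Ratio of the mean per-cycle fractional change of the D-V basal length
#' to that of the A-P length. The fractional change of a cycle is
#' (max - min) / mean over the cycle, with cycles delimited by the peaks
#' detected on the lightly smoothed trace.
#'
#' @param bundle a `trace_bundle` with `dv_length` and `ap_length`.
#' @param smooth_sigma smoothing (samples) before cycle detection.
#' @return Anisotropy ratio; `Inf` (flagged by a warning) when the A-P
#'   change is zero.
#' @export
dv_ap_anisotropy <- function(bundle, smooth_sigma = 1) {
  frac_change <- function(tr) {
    cyc <- detect_cycles(preprocess_trace(tr, 0, smooth_sigma),
                         refine = tr)
    pk <- sort(cyc$peak_indices)
    if (length(pk) < 2L) return(NA_real_)
    fc <- vapply(seq_len(length(pk) - 1L), function(i) {
      seg <- tr$values[pk[i]:pk[i + 1L]]
      (max(seg) - min(seg)) / mean(seg)
    }, numeric(1))
    mean(fc)
  }
  if (stats::var(bundle$ap_length$values) == 0) {
    warning("zero A-P change: infinite anisotropy", call. = FALSE)
    return(Inf)
  }
  dv <- frac_change(bundle$dv_length)
  ap <- frac_change(bundle$ap_length)
  if (is.na(dv) || is.na(ap)) return(NA_real_)
  if (ap == 0) {
    warning("zero A-P change: infinite anisotropy", call. = FALSE)
    return(Inf)
  }
  dv / ap
}

#' Consolidated analysis report
#'
#' Bundles group means, standard errors and pairwise Welch tests for any
#' combination of module outputs, with provenance (seed and configuration).
#'
#' @param fibers optional [fiber_table()] output.
#' @param cortical optional [cortical_table()] output.
#' @param recoil optional [recoil_summary()] output.
#' @param morpho optional `cell_table`.
#' @param seed seed recorded as provenance.
#' @param config optional `synth_config` recorded as provenance.
#' @return A `report_bundle` list; empty inputs give an empty report.
#' @export
summarize_report <- function(fibers = NULL, cortical = NULL, recoil = NULL,
                             morpho = NULL, seed = NA_integer_,
                             config = NULL) {
  group_stats <- function(df, value, group) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    sp <- split(df[[value]], df[[group]])
    st <- data.frame(
      group = names(sp),
      n = vapply(sp, length, integer(1)),
      mean = vapply(sp, mean, numeric(1)),
      se = vapply(sp, function(v) sd0(v) / sqrt(length(v)), numeric(1)),
      row.names = NULL)
    tests <- NULL
    ok <- names(sp)[vapply(sp, length, integer(1)) >= 2L]
    if (length(ok) >= 2L) {
      sub <- df[df[[group]] %in% ok, , drop = FALSE]
      fake <- data.frame(group = sub[[group]], v0_um_per_s = sub[[value]])
      tests <- compare_groups(fake)
    }
    list(stats = st, tests = tests)
  }
  rep_ <- list(
    fibers = group_stats(fibers, "density_per_um", "genotype"),
    cortical = group_stats(cortical, "mean_per_sample", "class"),
    recoil = group_stats(recoil, "v0_um_per_s", "group"),
    morpho = group_stats(morpho, "basal_area_um2", "genotype"),
    provenance = list(seed = seed,
                      config = if (!is.null(config))
                        yaml::as.yaml(unclass(config)) else NULL)
  )
  structure(rep_, class = "report_bundle")
}

#' Write a report bundle to disk
#'
#' One CSV per analysis plus a JSON summary.
#' @param report a `report_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  js <- list()
  for (nm in c("fibers", "cortical", "recoil", "morpho")) {
    part <- report[[nm]]
    if (is.null(part)) next
    utils::write.csv(part$stats, file.path(dir, paste0(nm, "_groups.csv")),
                     row.names = FALSE)
    if (!is.null(part$tests))
      utils::write.csv(part$tests, file.path(dir, paste0(nm, "_tests.csv")),
                       row.names = FALSE)
    js[[nm]] <- part$stats
  }
  js$provenance <- report$provenance["seed"]
  jsonlite::write_json(js, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
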