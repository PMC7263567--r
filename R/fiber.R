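# Stress-fiber scoring: an intensity profile is taken along the longest
# interior chord perpendicular to the cell's dominant fiber orientation
# (cortical rim excluded), peaks are counted against a control-derived
# threshold (control mean peak height minus one SD), and density is
# reported as peaks per micrometre of profile.

# Local maxima with a deterministic plateau rule: strict rise on the left,
# non-strict fall on the right, so a plateau yields its leftmost sample.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2L:(n - 1L)
  i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
}

# Greedy minimum-separation filter: candidates are taken in order of
# decreasing height (ties: leftmost first); a candidate is kept only if it
# lies at least `min_sep` from every already-kept peak.
greedy_separate <- function(idx, heights, positions, min_sep) {
  if (length(idx) <= 1L) return(idx)
  ord <- order(-heights, positions[idx])
  kept <- integer(0)
  for (j in ord) {
    if (all(abs(positions[idx[j]] - positions[kept]) >= min_sep) ||
        length(kept) == 0L)
      kept <- c(kept, idx[j])
  }
  sort(kept)
}

# Dominant fiber orientation from the image structure tensor inside a mask:
# returns unit vectors along the fibers (minor eigenvector) and across them
# (major eigenvector). NULL when the cell is isotropic (flat field).
structure_orientation <- function(img, mask) {
  sm <- smooth2d(img, sigma = 1)
  nr <- nrow(img); nc <- ncol(img)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (sm[, 3:nc] - sm[, 1:(nc - 2)]) / 2
  gy[2:(nr - 1), ] <- (sm[3:nr, ] - sm[1:(nr - 2), ]) / 2
  idx <- which(mask)
  J <- matrix(c(sum(gx[idx]^2), sum(gx[idx] * gy[idx]),
                sum(gx[idx] * gy[idx]), sum(gy[idx]^2)), 2, 2)
  ev <- eigen(J, symmetric = TRUE)
  if (ev$values[1] < 1e-9 || ev$values[2] / ev$values[1] > 0.98)
    return(NULL)
  list(across = ev$vectors[, 1], along = ev$vectors[, 2])
}

#' Extract a fiber-crossing intensity profile from a cell
#'
#' Erodes the cortical rim off the cell mask, estimates the dominant fiber
#' orientation from the structure tensor, and samples the image at pixel
#' pitch along the longest interior chord perpendicular to the fibers.
#' For an isotropic (e.g. uniform) cell the chord defaults to horizontal.
#'
#' @param scene an `image_scene`.
#' @param cell_id cell label.
#' @param cortical_margin_um rim excluded before profiling (um).
#' @return A `line_profile`: `positions_um`, `intensity`, `cell_id`,
#'   `length_um`.
#' @export
extract_profile <- function(scene, cell_id, cortical_margin_um = 1.0) {
  labels <- scene$labels
  if (!any(labels == cell_id))
    stop("cell ", cell_id, " not present in labels", call. = FALSE)
  px_um <- scene$calibration
  emask <- erode_mask(labels == cell_id,
                      round(cortical_margin_um / px_um))
  min_len_px <- ceiling(2 / px_um)
  if (sum(emask) < min_len_px)
    stop("cell ", cell_id, " degenerate after cortical erosion",
         call. = FALSE)
  ori <- structure_orientation(scene$image, emask)
  if (is.null(ori)) ori <- list(across = c(1, 0), along = c(0, 1))
  d <- ori$across / sqrt(sum(ori$across^2))   # profile direction (x, y)
  f <- ori$along / sqrt(sum(ori$along^2))

  nr <- nrow(labels)
  idx <- which(emask)
  cy <- mean(((idx - 1L) %% nr) + 1L)
  cx <- mean(((idx - 1L) %/% nr) + 1L)
  inside <- function(x, y) {
    xi <- round(x); yi <- round(y)
    xi >= 1 & xi <= ncol(labels) & yi >= 1 & yi <= nr &
      emask[cbind(pmax(pmin(yi, nr), 1), pmax(pmin(xi, ncol(labels)), 1))]
  }
  half_span <- max(nr, ncol(labels))
  chord_at <- function(ax, ay) {
    if (!inside(ax, ay)) return(NULL)
    lo <- 0
    while (lo > -half_span && inside(ax + (lo - 1) * d[1],
                                     ay + (lo - 1) * d[2])) lo <- lo - 1
    hi <- 0
    while (hi < half_span && inside(ax + (hi + 1) * d[1],
                                    ay + (hi + 1) * d[2])) hi <- hi + 1
    c(lo, hi)
  }
  # anchors slide along the fiber axis through the centroid, snapped to
  # the pixel grid so axis-aligned chords sample exact pixel values
  best <- NULL; best_len <- -1
  for (s in seq(-half_span / 2, half_span / 2, by = 1)) {
    ax <- round(cx + s * f[1]); ay <- round(cy + s * f[2])
    ch <- chord_at(ax, ay)
    if (is.null(ch)) next
    if (ch[2] - ch[1] > best_len) {
      best_len <- ch[2] - ch[1]
      best <- c(ax, ay, ch)
    }
  }
  if (is.null(best) || best_len + 1 < min_len_px)
    stop("cell ", cell_id, " too narrow for a 2 um profile", call. = FALSE)
  ss <- seq(best[3], best[4])
  xs <- best[1] + ss * d[1]
  ys <- best[2] + ss * d[2]
  # nearest-pixel sampling keeps peak heights on the pixel grid exact,
  # so the SD-based reference threshold is not eroded by interpolation
  xi <- pmax(pmin(round(xs), ncol(labels)), 1L)
  yi <- pmax(pmin(round(ys), nr), 1L)
  vals <- scene$image[cbind(yi, xi)]
  keep <- !is.na(vals)
  pos <- (ss[keep] - ss[keep][1]) * px_um
  structure(list(positions_um = pos, intensity = vals[keep],
                 cell_id = cell_id, length_um = pos[length(pos)] - pos[1],
                 chord_start = c(xs[keep][1], ys[keep][1]),
                 chord_end = c(xs[keep][sum(keep)], ys[keep][sum(keep)]),
                 direction = d),
            class = "line_profile")
}

#' Build the control peak-intensity reference
#'
#' Detects raw local maxima (plateau rule, 0.5-um minimum separation, no
#' height threshold) on each control profile, pools their heights, and
#' returns the pooled mean and sample SD. The scoring threshold used by
#' [detect_peaks()] is `mean - sd`.
#'
#' @param profiles list of `line_profile`s from control cells (>= 2).
#' @param min_sep_um minimum peak separation.
#' @return A `control_reference`: `mean_peak_intensity`,
#'   `sd_peak_intensity`, `n_peaks`.
#' @export
build_control_reference <- function(profiles, min_sep_um = 0.5) {
  if (length(profiles) < 2L)
    stop("need at least 2 control profiles", call. = FALSE)
  heights <- unlist(lapply(profiles, function(p) {
    idx <- local_maxima(p$intensity)
    idx <- greedy_separate(idx, p$intensity[idx], p$positions_um, min_sep_um)
    p$intensity[idx]
  }))
  if (length(heights) == 0L)
    stop("no local maxima found in control profiles", call. = FALSE)
  structure(list(mean_peak_intensity = mean(heights),
                 sd_peak_intensity = sd0(heights),
                 n_peaks = length(heights)),
            class = "control_reference")
}

#' Detect stress-fiber peaks against the control reference
#'
#' Local maxima whose height reaches at least one SD below the control mean
#' peak intensity, with a greedy minimum-separation rule merging
#' sub-resolution doublets. An empty peak set is a valid result.
#'
#' @param profile a `line_profile`.
#' @param ref a `control_reference`.
#' @param min_sep_um minimum peak separation (um).
#' @return A `peak_set`: `peak_positions_um`, `peak_heights`,
#'   `threshold_used`.
#' @export
detect_peaks <- function(profile, ref, min_sep_um = 0.5) {
  stopifnot(inherits(ref, "control_reference"))
  thr <- ref$mean_peak_intensity - ref$sd_peak_intensity
  idx <- local_maxima(profile$intensity)
  idx <- idx[profile$intensity[idx] >= thr]
  idx <- greedy_separate(idx, profile$intensity[idx], profile$positions_um,
                         min_sep_um)
  structure(list(peak_positions_um = profile$positions_um[idx],
                 peak_heights = profile$intensity[idx],
                 threshold_used = thr),
            class = "peak_set")
}

#' Peak density along a profile
#'
#' Number of detected peaks divided by the profile length, in peaks/um.
#' @param peaks a `peak_set`.
#' @param profile the `line_profile` the peaks came from.
#' @return Peaks per micrometre.
#' @export
peak_density <- function(peaks, profile) {
  if (profile$length_um <= 0)
    stop("zero-length profile", call. = FALSE)
  length(peaks$peak_heights) / profile$length_um
}

# Linear pixel indices of the fiber-region mask of a set of cells: the
# rendered fiber cross-sections, minus any pixels overlaid by whips.
fiber_region_idx <- function(scene, truth, cell_ids) {
  nr <- nrow(scene$image)
  fb <- truth$fibers[truth$fibers$cell_id %in% cell_ids, , drop = FALSE]
  if (nrow(fb) == 0L) return(integer(0))
  idx <- unlist(lapply(seq_len(nrow(fb)), function(i) {
    rows <- fb$y0_px[i]:fb$y1_px[i]
    cols <- (fb$x_px[i] - 2L):(fb$x_px[i] + 2L)
    as.vector(outer(rows, (cols - 1L) * nr, `+`))
  }))
  idx <- unique(idx)
  setdiff(idx, unique(unlist(truth$whip_pixels)))
}

#' Mutant-to-control relative intensity
#'
#' Background (mean over label-0 pixels) is subtracted, then the ratio of
#' mean per-area intensity over the mutant cells to the same over the
#' control cells is returned. `mask_source = "whole-cell"` uses each
#' group's full label masks; `"fiber-region"` restricts to the rendered
#' stress-fiber cross-sections recorded in the scene truth (whip-overlaid
#' pixels excluded), which is the measure behind the printed percentage
#' reductions.
#'
#' @param scene an `image_scene`.
#' @param cell_ids_mutant,cell_ids_control non-empty cell-id vectors.
#' @param mask_source `"whole-cell"` or `"fiber-region"`.
#' @param truth a `scene_truth`, required for `"fiber-region"`.
#' @return Ratio (mutant / control) of background-subtracted mean
#'   intensities.
#' @export
relative_intensity <- function(scene, cell_ids_mutant, cell_ids_control,
                               mask_source = c("whole-cell", "fiber-region"),
                               truth = NULL) {
  mask_source <- match.arg(mask_source)
  if (length(cell_ids_mutant) == 0L || length(cell_ids_control) == 0L)
    stop("both cell groups must be non-empty", call. = FALSE)
  bg <- mean(scene$image[scene$labels == 0L])
  grp_mean <- function(ids) {
    idx <- if (mask_source == "whole-cell")
      which(scene$labels %in% ids)
    else {
      if (is.null(truth))
        stop("fiber-region masks require scene truth", call. = FALSE)
      fiber_region_idx(scene, truth, ids)
    }
    if (length(idx) == 0L) stop("empty group mask", call. = FALSE)
    mean(scene$image[idx]) - bg
  }
  grp_mean(cell_ids_mutant) / grp_mean(cell_ids_control)
}

#' Per-cell fiber scoring table
#'
#' Convenience wrapper running [extract_profile()], the control reference
#' and [detect_peaks()] over every cell of a scene.
#'
#' @param scene an `image_scene`.
#' @param cortical_margin_um rim excluded before profiling.
#' @return Data frame with `cell_id`, `genotype`, `n_peaks`,
#'   `density_per_um`, `mean_intensity`.
#' @export
fiber_table <- function(scene, cortical_margin_um = 1.0) {
  ids <- as.integer(names(scene$genotype))
  profs <- list()
  for (id in ids) {
    p <- tryCatch(extract_profile(scene, id, cortical_margin_um),
                  error = function(e) NULL)
    if (!is.null(p)) profs[[as.character(id)]] <- p
  }
  ctrl_ids <- as.character(ids[scene$genotype[as.character(ids)] ==
                                 "control"])
  ref <- build_control_reference(profs[names(profs) %in% ctrl_ids])
  bg <- mean(scene$image[scene$labels == 0L])
  do.call(rbind, lapply(names(profs), function(idc) {
    id <- as.integer(idc)
    pk <- detect_peaks(profs[[idc]], ref)
    data.frame(cell_id = id, genotype = scene$genotype[idc],
               n_peaks = length(pk$peak_heights),
               density_per_um = peak_density(pk, profs[[idc]]),
               mean_intensity = mean(scene$image[scene$labels == id]) - bg,
               row.names = NULL)
  }))
}
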