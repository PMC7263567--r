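# Junctional F-actin: every cell-cell boundary is profiled with a 2-um bar
# centred on the boundary and perpendicular to it; boundary classes
# (ctrl-ctrl, ctrl-mut, mut-mut) are compared as ratios to the control
# baseline.

#' Enumerate cell-cell boundary segments
#'
#' Every 4-adjacent pixel pair with two different nonzero labels
#' contributes its midpoint to exactly one segment keyed by the unordered
#' cell-id pair; the class follows from the genotype map.
#'
#' @param scene an `image_scene`.
#' @return A list of `boundary_segment`s, each with `cell_a`, `cell_b`
#'   (`cell_a < cell_b`), `class`, and `pixels` (n x 2 matrix of x, y
#'   midpoint coordinates). Empty list for a single-cell scene.
#' @export
enumerate_boundaries <- function(scene) {
  labels <- scene$labels
  nr <- nrow(labels); nc <- ncol(labels)
  out <- list()
  collect <- function(a, b, xa, ya, xb, yb) {
    keep <- a != b & a > 0L & b > 0L
    data.frame(la = a[keep], lb = b[keep],
               x = (xa[keep] + xb[keep]) / 2, y = (ya[keep] + yb[keep]) / 2)
  }
  # horizontal neighbours
  a <- labels[, -nc]; b <- labels[, -1]
  iy <- rep(seq_len(nr), nc - 1L); ix <- rep(seq_len(nc - 1L), each = nr)
  h <- collect(as.vector(a), as.vector(b), ix, iy, ix + 1L, iy)
  # vertical neighbours
  a <- labels[-nr, ]; b <- labels[-1, ]
  iy <- rep(seq_len(nr - 1L), nc); ix <- rep(seq_len(nc), each = nr - 1L)
  v <- collect(as.vector(a), as.vector(b), ix, iy, ix, iy + 1L)
  df <- rbind(h, v)
  if (nrow(df) == 0L) return(list())
  ka <- pmin(df$la, df$lb); kb <- pmax(df$la, df$lb)
  key <- paste(ka, kb)
  for (k in unique(key)) {
    sel <- key == k
    a_id <- ka[sel][1]; b_id <- kb[sel][1]
    out[[length(out) + 1L]] <- structure(list(
      cell_a = a_id, cell_b = b_id,
      class = boundary_class(scene$genotype[as.character(a_id)],
                             scene$genotype[as.character(b_id)]),
      pixels = cbind(x = df$x[sel], y = df$y[sel])
    ), class = "boundary_segment")
  }
  out
}

#' Total bar intensity across a boundary
#'
#' At each boundary pixel the image is sampled along the local boundary
#' normal over +/- half the bar length; all background-subtracted samples
#' are summed. The normal is the gradient of a Gaussian-smoothed indicator
#' of the first cell's mask, which is stable on pixelated boundaries.
#' Boundary pixels within `junction_exclusion_um` of a tricellular point
#' are skipped so the bar neither mixes boundary classes at vertices nor
#' picks up the whip-like protrusions anchored there; pixels within
#' `rim_exclusion_um` of the tissue rim are skipped because the bar would
#' leave the tissue. Samples falling outside the field are clipped with a
#' warning.
#'
#' @param scene an `image_scene`.
#' @param boundary a `boundary_segment` with >= 3 pixels.
#' @param bar_length_um bar length (default the standard 2 um).
#' @param step_um sampling pitch along the normal.
#' @param junction_exclusion_um radius around tricellular points excluded.
#' @param rim_exclusion_um distance to the tissue rim (background pixels)
#'   below which boundary pixels are excluded.
#' @return List: `total` (a.u., background-subtracted), `n_samples`,
#'   `mean_per_sample`, `clipped` (logical).
#' @export
bar_intensity <- function(scene, boundary, bar_length_um = 2.0,
                          step_um = scene$calibration / 4,
                          junction_exclusion_um = 2.0,
                          rim_exclusion_um = 1.5) {
  stopifnot(inherits(boundary, "boundary_segment"))
  px <- boundary$pixels
  if (nrow(px) < 3L)
    stop("boundary needs at least 3 pixels", call. = FALSE)
  px_um <- scene$calibration
  bg <- mean(scene$image[scene$labels == 0L])
  if (nrow(scene$tricellular) > 0L && junction_exclusion_um > 0) {
    r2 <- (junction_exclusion_um / px_um)^2
    far <- vapply(seq_len(nrow(px)), function(i) {
      all((scene$tricellular$x - px[i, 1])^2 +
            (scene$tricellular$y - px[i, 2])^2 > r2)
    }, logical(1))
    px <- px[far, , drop = FALSE]
  }
  if (rim_exclusion_um > 0 && nrow(px) > 0L) {
    rr <- ceiling(rim_exclusion_um / px_um)
    nr0 <- nrow(scene$labels); nc0 <- ncol(scene$labels)
    far <- vapply(seq_len(nrow(px)), function(i) {
      xs <- max(1L, round(px[i, 1]) - rr):min(nc0, round(px[i, 1]) + rr)
      ys <- max(1L, round(px[i, 2]) - rr):min(nr0, round(px[i, 2]) + rr)
      all(scene$labels[ys, xs] > 0L)
    }, logical(1))
    px <- px[far, , drop = FALSE]
  }
  if (nrow(px) == 0L)
    return(list(total = 0, n_samples = 0L, mean_per_sample = NA_real_,
                clipped = FALSE))
  # smoothed indicator of cell_a over the local crop
  nr <- nrow(scene$labels); nc <- ncol(scene$labels)
  pad <- ceiling(bar_length_um / px_um) + 6L
  x0 <- max(1L, floor(min(px[, 1])) - pad)
  x1 <- min(nc, ceiling(max(px[, 1])) + pad)
  y0 <- max(1L, floor(min(px[, 2])) - pad)
  y1 <- min(nr, ceiling(max(px[, 2])) + pad)
  ind <- smooth2d((scene$labels[y0:y1, x0:x1, drop = FALSE] ==
                     boundary$cell_a) * 1, sigma = 1.5)
  half_px <- (bar_length_um / 2) / px_um
  ts <- seq(-half_px, half_px, by = step_um / px_um)
  total <- 0; n_used <- 0L; clipped <- FALSE
  for (i in seq_len(nrow(px))) {
    lx <- px[i, 1] - x0 + 1; ly <- px[i, 2] - y0 + 1
    gx <- bilinear(ind, lx + 0.5, ly) - bilinear(ind, lx - 0.5, ly)
    gy <- bilinear(ind, lx, ly + 0.5) - bilinear(ind, lx, ly - 0.5)
    nrm <- sqrt(gx^2 + gy^2)
    if (!is.finite(nrm) || nrm < 1e-9) next
    nx <- gx / nrm; ny <- gy / nrm
    vals <- bilinear(scene$image, px[i, 1] + ts * nx, px[i, 2] + ts * ny)
    if (anyNA(vals)) clipped <- TRUE
    vals <- vals[!is.na(vals)]
    total <- total + sum(vals - bg)
    n_used <- n_used + length(vals)
  }
  if (clipped)
    warning("bar exited the field; samples clipped", call. = FALSE)
  list(total = total, n_samples = n_used,
       mean_per_sample = if (n_used > 0L) total / n_used else NA_real_,
       clipped = clipped)
}

#' Per-boundary cortical intensity table
#'
#' Runs [bar_intensity()] over every boundary of a scene.
#' @param scene an `image_scene`.
#' @param bar_length_um bar length in um.
#' @return Data frame: `boundary_id`, `cell_a`, `cell_b`, `class`,
#'   `total_intensity`, `n_samples`, `mean_per_sample`.
#' @export
cortical_table <- function(scene, bar_length_um = 2.0) {
  segs <- enumerate_boundaries(scene)
  segs <- Filter(function(s) nrow(s$pixels) >= 3L, segs)
  df <- do.call(rbind, lapply(seq_along(segs), function(i) {
    b <- bar_intensity(scene, segs[[i]], bar_length_um)
    data.frame(boundary_id = i, cell_a = segs[[i]]$cell_a,
               cell_b = segs[[i]]$cell_b, class = segs[[i]]$class,
               total_intensity = b$total, n_samples = b$n_samples,
               mean_per_sample = b$mean_per_sample)
  }))
  df[df$n_samples > 0L, , drop = FALSE]
}

#' Boundary-class cortical ratios
#'
#' Class means normalised to the ctrl-ctrl baseline. Per-boundary values
#' are the mean bar intensity per sample, so long and short boundaries
#' weigh equally; for class ratios the sum-vs-average distinction cancels.
#' The class mean is trimmed (default 15% each side) because a single
#' whip-like protrusion running along a boundary can inflate that
#' boundary's bar severalfold.
#'
#' @param stats data frame from [cortical_table()] (or with columns
#'   `class` and `mean_per_sample`).
#' @param trim trimming fraction for the class means.
#' @return A `cortical_stats`: per-class `mean`, `n`, and
#'   `ratio_to_ctrl_ctrl`.
#' @export
cortical_ratios <- function(stats, trim = 0.15) {
  if (!any(stats$class == "ctrl-ctrl"))
    stop("no ctrl-ctrl boundary to normalise against", call. = FALSE)
  cls <- sort(unique(stats$class))
  means <- vapply(cls, function(cl)
    mean(stats$mean_per_sample[stats$class == cl], trim = trim),
    numeric(1))
  base <- means[["ctrl-ctrl"]]
  structure(list(
    class_means = means,
    n = vapply(cls, function(cl) sum(stats$class == cl), integer(1)),
    ratio_to_ctrl_ctrl = means / base
  ), class = "cortical_stats")
}
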