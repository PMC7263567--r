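# Synthetic basal-surface scene generator: a jittered hexagonal Voronoi
# mosaic of follicle cells with per-cell stress-fiber bundles, a cortical
# ring on every cell-cell boundary, and whip-like protrusions anchored at
# tricellular junctions. Ground truth is recorded before noise.

# --- tessellation -----------------------------------------------------------

hex_lattice_seeds <- function(n_cells, field_px, margin) {
  lo <- margin; hi <- field_px - margin
  spacing <- sqrt((hi - lo)^2 / (n_cells * sqrt(3) / 2))
  repeat {
    dy <- spacing * sqrt(3) / 2
    ys <- seq(lo, hi, by = dy)
    pts <- do.call(rbind, lapply(seq_along(ys), function(i) {
      off <- if (i %% 2L == 0L) spacing / 2 else 0
      xs <- seq(lo + off, hi, by = spacing)
      cbind(x = xs, y = ys[i])
    }))
    if (nrow(pts) >= n_cells) break
    spacing <- spacing * 0.95
  }
  ctr <- (lo + hi) / 2
  ord <- order((pts[, 1] - ctr)^2 + (pts[, 2] - ctr)^2)
  pts <- pts[ord[seq_len(n_cells)], , drop = FALSE]
  jit <- spacing * 0.15
  pts[, 1] <- pts[, 1] + stats::runif(n_cells, -jit, jit)
  pts[, 2] <- pts[, 2] + stats::runif(n_cells, -jit, jit)
  list(seeds = pts, spacing = spacing)
}

# Nearest-seed (Voronoi) labelling; pixels farther than `cutoff` from every
# seed become background (label 0), carving a cell-free rim for background
# estimation.
voronoi_labels <- function(seeds, field_px, cutoff) {
  cx <- matrix(seq_len(field_px), field_px, field_px, byrow = TRUE)
  cy <- matrix(seq_len(field_px), field_px, field_px)
  best <- matrix(Inf, field_px, field_px)
  best2 <- matrix(Inf, field_px, field_px)
  lab <- matrix(0L, field_px, field_px)
  lab2 <- matrix(0L, field_px, field_px)
  for (i in seq_len(nrow(seeds))) {
    d2 <- (cx - seeds[i, 1])^2 + (cy - seeds[i, 2])^2
    upd <- d2 < best
    best2[upd] <- best[upd]; lab2[upd] <- lab[upd]
    best[upd] <- d2[upd]; lab[upd] <- i
    upd2 <- !upd & d2 < best2
    best2[upd2] <- d2[upd2]; lab2[upd2] <- i
  }
  lab[best > cutoff^2] <- 0L
  list(labels = lab, second = lab2)
}

# Tricellular junctions: centers of 2x2 pixel blocks touching >=3 distinct
# nonzero labels, clustered so each physical vertex yields one point.
find_tricellular <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  a <- labels[-nr, -nc]; b <- labels[-nr, -1]
  c_ <- labels[-1, -nc]; d <- labels[-1, -1]
  cand <- which(!(a == b & a == c_ & a == d))
  if (length(cand) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0)))
  blocks <- cbind(a[cand], b[cand], c_[cand], d[cand])
  ndist <- apply(blocks, 1L, function(v) length(unique(v[v > 0L])))
  keep <- cand[ndist >= 3L]
  if (length(keep) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0)))
  ky <- ((keep - 1L) %% (nr - 1L)) + 1L
  kx <- ((keep - 1L) %/% (nr - 1L)) + 1L
  pts <- data.frame(x = kx + 0.5, y = ky + 0.5)
  cells <- lapply(which(cand %in% keep), function(i) {
    v <- blocks[i, ]; sort(unique(v[v > 0L]))
  })
  # greedy clustering within 2 px
  ordp <- order(pts$y, pts$x)
  taken <- rep(FALSE, nrow(pts))
  out <- list()
  for (i in ordp) {
    if (taken[i]) next
    close_ <- which(!taken & abs(pts$x - pts$x[i]) <= 2 &
                      abs(pts$y - pts$y[i]) <= 2)
    taken[close_] <- TRUE
    out[[length(out) + 1L]] <- list(
      x = mean(pts$x[close_]), y = mean(pts$y[close_]),
      cells = sort(unique(unlist(cells[close_]))))
  }
  data.frame(
    x = vapply(out, `[[`, numeric(1), "x"),
    y = vapply(out, `[[`, numeric(1), "y"),
    cells = I(lapply(out, `[[`, "cells"))
  )
}

# --- per-cell helpers -------------------------------------------------------

erode_mask <- function(mask, radius_px) {
  if (radius_px < 1) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
  EBImage::erode(mask * 1, brush) > 0.5
}

cell_centroids <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  nr <- nrow(labels)
  idx <- which(labels > 0L)
  yy <- ((idx - 1L) %% nr) + 1L
  xx <- ((idx - 1L) %/% nr) + 1L
  lb <- labels[idx]
  data.frame(cell_id = ids,
             x = as.numeric(tapply(xx, lb, mean)[as.character(ids)]),
             y = as.numeric(tapply(yy, lb, mean)[as.character(ids)]))
}

longest_true_run <- function(v) {
  r <- rle(v)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)[which.max(r$lengths[r$values])]
  c(starts[i], ends[i])
}

# Choose fiber x-positions (integer image columns) inside the eroded cell:
# evenly spaced across the usable width with +/-1 px jitter and a minimum
# gap that keeps the rendered cross-sections disjoint.
place_fiber_columns <- function(emask, k, min_run_px, min_gap_px = 5L,
                                inset_px = 2L) {
  ok_cols <- which(vapply(seq_len(ncol(emask)), function(cc) {
    r <- longest_true_run(emask[, cc])
    !is.null(r) && (r[2] - r[1] + 1L) >= min_run_px
  }, logical(1)))
  if (length(ok_cols) == 0L || k < 1L) return(integer(0))
  lo <- min(ok_cols) + inset_px
  hi <- max(ok_cols) - inset_px
  if (hi < lo) return(integer(0))
  ideal <- lo + (seq_len(k) - 0.5) / k * (hi - lo)
  chosen <- integer(0)
  for (p in ideal) {
    x <- round(p) + sample(-1:1, 1L)
    x <- ok_cols[which.min(abs(ok_cols - x))]
    if (all(abs(x - chosen) >= min_gap_px)) chosen <- c(chosen, x)
  }
  sort(chosen)
}

# --- whips ------------------------------------------------------------------

# Grow a whip polyline from a junction anchor, beating over the basal
# surface of an adjacent cell (heading toward `target`, a neighbour
# centroid). Growth stops at the edge of any cell's fiber-placement
# interior or at the field edge; when the tip reaches `reach_um` from the
# anchor it curls back (flagella-like), so the whole whip stays within the
# junctional neighbourhood while keeping its 2-4 um contour length.
grow_whip <- function(anchor, target, length_um, px_um, interior_mask,
                      n_seg = 3L, reach_um = 1.8) {
  nr <- nrow(interior_mask); nc <- ncol(interior_mask)
  reach_px <- reach_um / px_um
  dir0 <- c(target[1] - anchor[1], target[2] - anchor[2])
  nrm <- sqrt(sum(dir0^2))
  if (nrm < 1e-9) dir0 <- c(-1, 0) else dir0 <- dir0 / nrm
  ang <- atan2(dir0[2], dir0[1]) + stats::runif(1, -pi / 12, pi / 12)
  step <- 0.4
  seg_px <- length_um / px_um / n_seg
  pos <- anchor
  pts <- matrix(pos, ncol = 2)
  curl <- sample(c(-0.5, 0.5), 1L)
  for (s in seq_len(n_seg)) {
    if (s > 1L) ang <- ang + stats::runif(1, -pi / 7, pi / 7)
    nstep <- max(1L, round(seg_px / step))
    for (i in seq_len(nstep)) {
      nxt <- pos + step * c(cos(ang), sin(ang))
      turns <- 0L
      while (sqrt(sum((nxt - anchor)^2)) > reach_px && turns < 12L) {
        ang <- ang + curl
        nxt <- pos + step * c(cos(ang), sin(ang))
        turns <- turns + 1L
      }
      xi <- round(nxt[1]); yi <- round(nxt[2])
      if (xi < 1 || xi > nc || yi < 1 || yi > nr) return(pts)
      if (interior_mask[yi, xi]) return(pts)
      pos <- nxt
      pts <- rbind(pts, pos)
    }
  }
  pts
}

polyline_pixels <- function(pts, nr) {
  xi <- round(pts[, 1]); yi <- round(pts[, 2])
  unique((xi - 1L) * nr + yi)
}

# --- main generator ---------------------------------------------------------

#' Generate a synthetic basal-surface scene
#'
#' Renders a mosaic epithelium as seen in a basal confocal section: a
#' Voronoi tessellation of a jittered hexagonal lattice, per-cell parallel
#' stress fibers with Gaussian cross-section, a piecewise-constant cortical
#' ring whose intensity depends on the boundary class (mutant-mutant
#' boundaries carry the mutant preset's cortical value, all others the
#' control value; on the apical surface all boundaries take the control
#' value), and whip-like protrusions anchored at leading-edge tricellular
#' junctions (F-actin channel only; whips carry no myosin). Poisson shot
#' noise plus Gaussian read noise is added last unless `noise_sd = 0`, in
#' which case the render is returned noiselessly. Ground truth (fiber
#' segments, boundary intensities, whip polylines, protrusion masks) is
#' recorded before noise.
#'
#' @param config a [synth_config()].
#' @param preset_name condition preset supplying the mutant cells'
#'   parameters (`"mutant"`, `"mutant_rescue"`); `"control"` yields an
#'   all-control scene.
#' @param n_cells number of cells (>= 4).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param channel `"factin"` (fibers + cortex + whips) or `"myosin"`
#'   (fibers only, at the myosin preset intensity).
#' @param mutant_fraction fraction of cells in the mutant clone (ignored for
#'   the control preset).
#' @param surface `"basal"` or `"apical"`; apically the cortical intensity
#'   is genotype-independent (the apical null result).
#' @param field_px field side length in pixels; defaults to the config.
#' @param noise_sd Gaussian read-noise SD in a.u.; defaults to the preset.
#'   `0` disables both noise components.
#' @return A list with elements `scene` (class `image_scene`) and `truth`
#'   (class `scene_truth`).
#' @export
generate_scene <- function(config, preset_name, n_cells = 16L,
                           seed = config$seed,
                           channel = c("factin", "myosin"),
                           mutant_fraction = 0.5,
                           surface = c("basal", "apical"),
                           field_px = config$field_px,
                           noise_sd = NULL) {
  channel <- match.arg(channel)
  surface <- match.arg(surface)
  preset <- get_preset(config, preset_name)
  ctrl <- get_preset(config, "control")
  if (n_cells < 4L)
    stop("n_cells must be >= 4 to form tricellular junctions", call. = FALSE)
  noise_sd <- noise_sd %||% preset$noise_sd
  px_um <- config$pixel_size_um

  with_seed(seed, {
    # lattice margin sized so that every cell (max extent ~0.66 spacing
    # from its seed) keeps a >= 2 um cell-free rim inside the field
    rim <- max(10L, round(2 / px_um))
    margin <- 20
    for (it in 1:3) {
      spacing_est <- sqrt((field_px - 2 * margin)^2 /
                            (n_cells * sqrt(3) / 2))
      margin <- ceiling(0.66 * spacing_est + rim)
    }
    hx <- hex_lattice_seeds(n_cells, field_px, margin)
    vl <- voronoi_labels(hx$seeds, field_px, cutoff = 0.66 * hx$spacing)
    labels <- vl$labels
    ids <- sort(unique(labels[labels > 0L]))
    cent <- cell_centroids(labels)

    # clone assignment: mutant cells cluster around a random clone center
    genotype <- stats::setNames(rep("control", length(ids)),
                                as.character(ids))
    if (preset_name != "control" && mutant_fraction > 0) {
      n_mut <- max(1L, round(mutant_fraction * length(ids)))
      center_id <- sample(ids, 1L)
      cc <- cent[cent$cell_id == center_id, ]
      d2 <- (cent$x - cc$x)^2 + (cent$y - cc$y)^2
      genotype[as.character(cent$cell_id[order(d2)[seq_len(n_mut)]])] <-
        "mutant"
    }

    junctions <- find_tricellular(labels)
    if (nrow(junctions) == 0L)
      stop("n_cells too small to form tricellular junctions", call. = FALSE)

    nr <- field_px
    img <- matrix(config$background_offset, nr, field_px)

    # cortical ring: frontier pixels of each boundary interface
    shifts <- list(c(0L, 1L), c(1L, 0L))
    pairs <- list()
    for (sh in shifts) {
      a <- labels[seq_len(nr - sh[1]), seq_len(field_px - sh[2]),
                  drop = FALSE]
      b <- labels[(1L + sh[1]):nr, (1L + sh[2]):field_px, drop = FALSE]
      d <- which(a != b)
      if (length(d) == 0L) next
      ya <- ((d - 1L) %% nrow(a)) + 1L
      xa <- ((d - 1L) %/% nrow(a)) + 1L
      pairs[[length(pairs) + 1L]] <- data.frame(
        la = a[d], lb = b[d],
        ia = (xa - 1L) * nr + ya,
        ib = (xa + sh[2] - 1L) * nr + (ya + sh[1]))
    }
    pairs <- do.call(rbind, pairs)

    cort_val_of <- function(la, lb) {
      if (la == 0L || lb == 0L) {          # tissue rim: own genotype
        g <- genotype[as.character(max(la, lb))]
        v <- if (surface == "basal" && g == "mutant")
          preset$cortical_intensity else ctrl$cortical_intensity
        return(v)
      }
      both_mut <- genotype[as.character(la)] == "mutant" &&
        genotype[as.character(lb)] == "mutant"
      if (surface == "basal" && both_mut) preset$cortical_intensity
      else ctrl$cortical_intensity
    }

    boundary_truth <- NULL
    cort <- matrix(0, nr, field_px)
    if (channel == "factin" && !is.null(pairs)) {
      key <- paste(pmin(pairs$la, pairs$lb), pmax(pairs$la, pairs$lb))
      cell_idx <- split(seq_along(labels), as.vector(labels))
      h_px <- 0.2 / px_um              # band half-width, ~0.4 um total
      for (k in unique(key)) {
        rows <- pairs[key == k, ]
        v <- cort_val_of(rows$la[1], rows$lb[1])
        if (rows$la[1] > 0L && rows$lb[1] > 0L) {
          a <- min(rows$la[1], rows$lb[1]); b <- max(rows$la[1], rows$lb[1])
          # Voronoi interfaces are seed bisectors: render the ring as the
          # pixels within a fixed Euclidean distance of the bisector, so
          # the band width does not depend on boundary orientation
          u <- c(hx$seeds[b, 1] - hx$seeds[a, 1],
                 hx$seeds[b, 2] - hx$seeds[a, 2])
          u <- u / sqrt(sum(u^2))
          m <- c((hx$seeds[a, 1] + hx$seeds[b, 1]) / 2,
                 (hx$seeds[a, 2] + hx$seeds[b, 2]) / 2)
          cand <- c(cell_idx[[as.character(a)]], cell_idx[[as.character(b)]])
          # confine the band to the shared edge: nearest two seeds must be
          # exactly this pair (the bisector plane itself is unbounded)
          cand <- cand[(labels[cand] == a & vl$second[cand] == b) |
                         (labels[cand] == b & vl$second[cand] == a)]
          yy <- ((cand - 1L) %% nr) + 1L
          xx <- ((cand - 1L) %/% nr) + 1L
          d <- abs((xx - m[1]) * u[1] + (yy - m[2]) * u[2])
          pix <- cand[d <= h_px]
          boundary_truth <- rbind(boundary_truth, data.frame(
            cell_a = a, cell_b = b,
            class = boundary_class(genotype[as.character(a)],
                                   genotype[as.character(b)]),
            intensity = v))
        } else {
          pix <- unique(c(rows$ia[rows$la > 0L], rows$ib[rows$lb > 0L]))
        }
        cort[pix] <- pmax(cort[pix], v)
      }
      img <- img + cort
    }

    # fibers: vertical bundles in the eroded interior
    place_r <- round(1.5 / px_um)
    fiber_sigma <- 1           # px; cross-section sigma = pixel pitch
    fiber_dx <- -2:2
    fiber_w <- exp(-fiber_dx^2 / (2 * fiber_sigma^2))
    min_run <- round(2 / px_um)
    interior_mask <- matrix(FALSE, nr, field_px)
    fibers <- list()
    for (id in ids) {
      g <- genotype[as.character(id)]
      p <- if (g == "mutant") preset else ctrl
      emask <- erode_mask(labels == id, place_r)
      # whips must stay clear of the rendered fiber support, which reaches
      # 2 px beyond the placement interior
      interior_mask <- interior_mask | erode_mask(labels == id, place_r - 2L)
      inten <- if (channel == "factin") p$fiber_intensity
               else p$myosin_intensity
      cols <- place_fiber_columns(emask, p$fiber_count_per_cell, min_run)
      for (xf in cols) {
        run <- longest_true_run(emask[, xf])
        u <- if (p$fiber_jitter_frac > 0)
          stats::runif(1, 1 - p$fiber_jitter_frac, 1 + p$fiber_jitter_frac)
        else 1
        for (j in seq_along(fiber_dx))
          img[run[1]:run[2], xf + fiber_dx[j]] <-
            img[run[1]:run[2], xf + fiber_dx[j]] + inten * u * fiber_w[j]
        fibers[[length(fibers) + 1L]] <- data.frame(
          cell_id = id, x_px = xf, y0_px = run[1], y1_px = run[2],
          peak_intensity = inten * u)
      }
    }
    fibers <- if (length(fibers)) do.call(rbind, fibers) else
      data.frame(cell_id = integer(0), x_px = integer(0), y0_px = integer(0),
                 y1_px = integer(0), peak_intensity = numeric(0))

    # whips at leading-edge tricellular junctions (F-actin only)
    whips <- list(); whip_pixels <- list()
    if (channel == "factin") {
      for (id in ids) {
        g <- genotype[as.character(id)]
        p <- if (g == "mutant") preset else ctrl
        w <- as.integer(round(p$whip_count_leading_edge))
        if (w < 1L) next
        js <- leading_junctions_for(junctions, cent, id)
        if (nrow(js) == 0L) next
        for (wi in seq_len(w)) {
          j <- js[((wi - 1L) %% nrow(js)) + 1L, ]
          others <- setdiff(j$cells[[1]], id)
          tgt_id <- if (length(others)) others[sample.int(length(others),
                                                          1L)] else id
          tc <- cent[cent$cell_id == tgt_id, ]
          pl <- grow_whip(c(j$x, j$y), c(tc$x, tc$y),
                          stats::runif(1, 2, 4), px_um, interior_mask)
          pix <- polyline_pixels(pl, nr)
          img[pix] <- img[pix] + preset_whip(p)
          whips[[length(whips) + 1L]] <- data.frame(
            cell_id = id, anchor_x = j$x, anchor_y = j$y,
            n_px = length(pix))
          whip_pixels[[length(whip_pixels) + 1L]] <- pix
        }
      }
    }
    whips <- if (length(whips)) do.call(rbind, whips) else
      data.frame(cell_id = integer(0), anchor_x = numeric(0),
                 anchor_y = numeric(0), n_px = integer(0))

    # protrusion ground-truth masks (membrane channel; not rendered here)
    protrusions <- list()
    for (id in ids) {
      g <- genotype[as.character(id)]
      p <- if (g == "mutant") preset else ctrl
      protrusions[[as.character(id)]] <-
        draw_protrusion_mask(labels, id, p$protrusion_area_pct, px_um)
    }

    truth <- structure(list(
      fibers = fibers, boundaries = boundary_truth, whips = whips,
      whip_pixels = whip_pixels, protrusions = protrusions,
      preset_name = preset_name, channel = channel
    ), class = "scene_truth")

    if (noise_sd > 0) {
      n <- length(img)
      img <- matrix(stats::rpois(n, pmax(img, 0)) +
                      stats::rnorm(n, 0, noise_sd), nr, field_px)
      img[img < 0] <- 0
    }

    scene <- structure(list(
      image = img, labels = labels, genotype = genotype,
      tricellular = junctions, calibration = px_um,
      channel = channel, surface = surface, leading_edge = "west",
      preset_name = preset_name
    ), class = "image_scene")
    list(scene = scene, truth = truth)
  })
}

preset_whip <- function(p) p$whip_intensity

boundary_class <- function(ga, gb) {
  n_mut <- (ga == "mutant") + (gb == "mutant")
  c("ctrl-ctrl", "ctrl-mut", "mut-mut")[n_mut + 1L]
}

# Junctions on a cell's leading-edge side (x below the cell centroid when
# the leading edge faces west); falls back to the westernmost junction.
leading_junctions_for <- function(junctions, centroids, cell_id) {
  touch <- vapply(junctions$cells, function(cs) cell_id %in% cs, logical(1))
  js <- junctions[touch, , drop = FALSE]
  if (nrow(js) == 0L) return(js)
  cx <- centroids$x[centroids$cell_id == cell_id]
  lead <- js[js$x <= cx, , drop = FALSE]
  if (nrow(lead) == 0L) lead <- js[which.min(js$x), , drop = FALSE]
  lead
}

# Random non-overlapping discs inside the cell covering roughly
# `target_pct` percent of its area; returned as linear pixel indices.
draw_protrusion_mask <- function(labels, cell_id, target_pct, px_um) {
  if (target_pct <= 0) return(integer(0))
  nr <- nrow(labels)
  idx <- which(labels == cell_id)
  area <- length(idx)
  r_px <- max(2L, round(1 / px_um))
  per_disc <- pi * r_px^2
  n_disc <- max(1L, round(target_pct / 100 * area / per_disc))
  yy <- ((idx - 1L) %% nr) + 1L
  xx <- ((idx - 1L) %/% nr) + 1L
  centers <- sample(length(idx), min(n_disc, length(idx)))
  pix <- integer(0)
  for (ci in centers) {
    dx <- xx - xx[ci]; dy <- yy - yy[ci]
    pix <- c(pix, idx[dx^2 + dy^2 <= r_px^2])
  }
  unique(pix)
}

# --- I/O --------------------------------------------------------------------

#' Write / read a scene as TIFF + CSV
#'
#' The image and label map are written as two single-page 16-bit grayscale
#' TIFFs (`<stem>_image.tif`, `<stem>_labels.tif`; intensities stored at
#' 1 a.u. resolution), the genotype map and junctions as CSV, and the
#' calibration as YAML.
#'
#' @param scene an `image_scene`.
#' @param stem path stem (directory + basename without extension).
#' @return `write_scene` returns `stem` invisibly; `read_scene` an
#'   `image_scene`.
#' @export
write_scene <- function(scene, stem) {
  tiff::writeTIFF(round(pmax(scene$image, 0)) / 65535,
                  paste0(stem, "_image.tif"), bits.per.sample = 16L)
  tiff::writeTIFF(scene$labels / 65535, paste0(stem, "_labels.tif"),
                  bits.per.sample = 16L)
  utils::write.csv(data.frame(cell_id = as.integer(names(scene$genotype)),
                              genotype = unname(scene$genotype)),
                   paste0(stem, "_genotypes.csv"), row.names = FALSE)
  utils::write.csv(data.frame(x = scene$tricellular$x,
                              y = scene$tricellular$y),
                   paste0(stem, "_junctions.csv"), row.names = FALSE)
  yaml::write_yaml(list(pixel_size_um = scene$calibration,
                        channel = scene$channel, surface = scene$surface,
                        leading_edge = scene$leading_edge),
                   paste0(stem, "_meta.yaml"))
  invisible(stem)
}

#' @rdname write_scene
#' @export
read_scene <- function(stem) {
  img <- tiff::readTIFF(paste0(stem, "_image.tif")) * 65535
  lab <- round(tiff::readTIFF(paste0(stem, "_labels.tif")) * 65535)
  gdf <- utils::read.csv(paste0(stem, "_genotypes.csv"))
  meta <- yaml::read_yaml(paste0(stem, "_meta.yaml"))
  jdf <- utils::read.csv(paste0(stem, "_junctions.csv"))
  labels <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  junctions <- find_tricellular(labels)
  if (nrow(jdf) > 0L && nrow(junctions) == 0L)
    junctions <- data.frame(x = jdf$x, y = jdf$y, cells = I(vector("list",
                                                                  nrow(jdf))))
  structure(list(
    image = img, labels = labels,
    genotype = stats::setNames(as.character(gdf$genotype),
                               as.character(gdf$cell_id)),
    tricellular = junctions, calibration = meta$pixel_size_um,
    channel = meta$channel, surface = meta$surface,
    leading_edge = meta$leading_edge, preset_name = NA_character_
  ), class = "image_scene")
}

#' @export
print.image_scene <- function(x, ...) {
  cat("image_scene:", nrow(x$image), "x", ncol(x$image), "px,",
      length(x$genotype), "cells (",
      sum(x$genotype == "mutant"), "mutant ),",
      x$channel, "channel,", x$surface, "surface,",
      nrow(x$tricellular), "tricellular junctions\n")
  invisible(x)
}
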