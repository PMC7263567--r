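# Recoil analysis of laser-ablated cell bonds: pre-cut baseline L0,
# displacement curves dL(t), the initial velocity at the first post-cut
# frame (the relative tension proxy), and Welch group comparisons.

#' Pre-cut baseline vertex distance
#'
#' Mean vertex distance over the 10-s window immediately preceding the
#' cut, inclusive of the last pre-cut frame.
#'
#' @param trace an `ablation_trace`.
#' @return L0 in micrometres.
#' @export
baseline_L0 <- function(trace) {
  t_cut <- trace$times_s[trace$cut_index]
  if (t_cut - trace$times_s[1] < 10 - 0.8 - 1e-9)
    stop("insufficient pre-cut window (need 10 s)", call. = FALSE)
  sel <- seq_len(trace$cut_index)
  sel <- sel[trace$times_s[sel] > t_cut - 10 - 1e-9]
  mean(trace$distance_um[sel])
}

#' Initial recoil velocity
#'
#' Velocity at the first post-cut frame:
#' `(L(cut + 0.8 s) - L0) / 0.8`, in um/s. Invariant to adding a constant
#' to the whole trace.
#'
#' @param trace an `ablation_trace`.
#' @param L0 pre-cut baseline; computed with [baseline_L0()] by default.
#' @return v0 in um/s.
#' @export
initial_velocity <- function(trace, L0 = baseline_L0(trace)) {
  i1 <- trace$cut_index + 1L
  if (i1 > length(trace$times_s))
    stop("missing first post-cut frame", call. = FALSE)
  dt1 <- trace$times_s[i1] - trace$times_s[trace$cut_index]
  (trace$distance_um[i1] - L0) / dt1
}

#' Averaged displacement curve
#'
#' Per-time-point mean and standard error of the vertex-distance increase
#' dL(t) = L(t) - L0 across ablation experiments sharing one sampling
#' grid.
#'
#' @param traces list of `ablation_trace`s.
#' @return A `recoil_curve` data frame: `time_s` (from the cut),
#'   `delta_L_um`, `se_um`, `n`.
#' @export
displacement_curve <- function(traces) {
  stopifnot(length(traces) >= 1L)
  post <- lapply(traces, function(tr) {
    tt <- tr$times_s - tr$times_s[tr$cut_index]
    idx <- (tr$cut_index + 1L):length(tr$times_s)
    list(t = tt[idx], dL = tr$distance_um[idx] - baseline_L0(tr))
  })
  t0 <- post[[1]]$t
  for (p in post)
    if (length(p$t) != length(t0) || max(abs(p$t - t0)) > 1e-6)
      stop("traces do not share a sampling grid", call. = FALSE)
  m <- do.call(rbind, lapply(post, `[[`, "dL"))
  n <- nrow(m)
  structure(data.frame(
    time_s = t0,
    delta_L_um = colMeans(m),
    se_um = if (n > 1L) apply(m, 2L, stats::sd) / sqrt(n) else rep(0,
                                                                   ncol(m)),
    n = n
  ), class = c("recoil_curve", "data.frame"))
}

#' Per-trace recoil summary
#'
#' @param traces list of `ablation_trace`s.
#' @param group group label; defaults to each trace's own.
#' @return A `recoil_summary` data frame: `trace_id`, `group`, `L0_um`,
#'   `v0_um_per_s`.
#' @export
recoil_summary <- function(traces, group = NULL) {
  structure(do.call(rbind, lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    L0 <- baseline_L0(tr)
    data.frame(trace_id = i,
               group = group %||% tr$group,
               L0_um = L0,
               v0_um_per_s = initial_velocity(tr, L0))
  })), class = c("recoil_summary", "data.frame"))
}

#' Pairwise Welch comparison of recoil groups
#'
#' Welch (unequal-variance) two-sample t-tests on initial velocities for
#' every pair of groups, with group means and standard errors. Two
#' zero-variance groups with equal means are reported as t = 0, p = 1;
#' with unequal means the t statistic is infinite and the pair is flagged
#' as a zero-variance case.
#'
#' @param summaries a `recoil_summary` data frame (or any data frame with
#'   `group` and `v0_um_per_s`), >= 2 groups with n >= 2 each.
#' @return A comparison data frame: one row per group pair with means,
#'   SEs, `t`, `df`, `p_value`, `note`.
#' @export
compare_groups <- function(summaries) {
  gs <- split(summaries$v0_um_per_s, summaries$group)
  if (length(gs) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(gs, length, integer(1)) < 2L))
    stop("every group needs n >= 2", call. = FALSE)
  nms <- names(gs)
  rows <- list()
  for (i in seq_along(gs)) for (j in seq_along(gs)) {
    if (j <= i) next
    a <- gs[[i]]; b <- gs[[j]]
    va <- stats::var(a); vb <- stats::var(b)
    if (va == 0 && vb == 0) {
      eq <- isTRUE(all.equal(mean(a), mean(b)))
      tt <- list(statistic = if (eq) 0 else Inf,
                 parameter = NA_real_, p.value = if (eq) 1 else 0)
      note <- "zero-variance"
    } else {
      ht <- stats::t.test(a, b, var.equal = FALSE)
      tt <- list(statistic = unname(ht$statistic),
                 parameter = unname(ht$parameter), p.value = ht$p.value)
      note <- "welch"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = nms[i], group2 = nms[j],
      mean1 = mean(a), se1 = sd0(a) / sqrt(length(a)),
      mean2 = mean(b), se2 = sd0(b) / sqrt(length(b)),
      t = tt$statistic, df = tt$parameter, p_value = tt$p.value,
      note = note)
  }
  do.call(rbind, rows)
}
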