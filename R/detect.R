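#' @title PCWA detector internals: local maxima, macro and micro clusters
#' @name pcwa-clustering
#' @description
#' The PCWA detector proceeds in three stages. (1) Per-scale local maxima of
#' the CWT map above a threshold are collected. (2) Maxima are grouped into
#' macro clusters by splitting the time-sorted list wherever consecutive
#' maxima are separated by more than `gap` seconds. (3) Each macro cluster
#' is resolved into star-graph micro clusters: the largest-coefficient
#' maximum (centroid) links every maximum whose directional ellipse overlaps
#' it; a sufficiently large linked set is emitted as one event, and the
#' unlinked remainder forms a new, smaller cluster, until no maxima remain.
NULL

# Leftmost-of-plateau local maxima of one scale row, vectorized via run
# length encoding: a run is a maximum if its value exceeds both neighboring
# runs' values (plateau tie-break: leftmost sample wins).
row_local_maxima <- function(v, threshold) {
  r <- rle(v)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  idx <- which(r$values[-c(1, 2)] < r$values[-c(1, k)] &
                 r$values[-c(k - 1, k)] < r$values[-c(1, k)]) + 1L
  if (length(idx) == 0) return(integer(0))
  starts <- cumsum(c(1L, r$lengths))[idx]
  starts[v[starts] >= threshold]
}

# Sub-bin refinement of maxima positions: parabola through the maximum and
# its neighbors; removes the half-bin quantization of the argmax. Plateau
# maxima (flat neighbors) keep a zero offset.
subbin_offset <- function(v, idx) {
  n <- length(v)
  ok <- idx > 1L & idx < n
  delta <- numeric(length(idx))
  a <- v[pmax(idx - 1L, 1L)]; b <- v[idx]; c <- v[pmin(idx + 1L, n)]
  den <- a - 2 * b + c
  good <- ok & is.finite(den) & den < 0
  delta[good] <- 0.5 * (a[good] - c[good]) / den[good]
  pmin(pmax(delta, -0.5), 0.5)
}

#' Per-scale local maxima of a CWT map
#'
#' Finds, independently in each scale row, every sample strictly greater
#' than its time neighbors (leftmost sample of a plateau wins) with a
#' coefficient at or above the threshold.
#'
#' @param map A `cwt_map` from [compute_cwt()].
#' @param threshold Minimum coefficient. With `threshold_mode = "mad"` the
#'   per-row threshold is `threshold` times the row's median absolute
#'   deviation (consistent estimator for the noise sd of the row).
#' @param threshold_mode `"absolute"` (default) or `"mad"`.
#' @param exclude_boundary Drop maxima within one wavelet support of either
#'   trace end (where the convolution sees the zero padding).
#' @return data.frame with columns `t_index`, `scale_index`, `t`, `scale`,
#'   `C`, sorted by `t`.
#' @export
find_local_maxima <- function(map, threshold,
                              threshold_mode = c("absolute", "mad"),
                              exclude_boundary = TRUE) {
  stopifnot(inherits(map, "cwt_map"))
  threshold_mode <- match.arg(threshold_mode)
  out <- vector("list", length(map$scales))
  for (i in seq_along(map$scales)) {
    v <- map$coeffs[i, ]
    thr <- if (threshold_mode == "mad") threshold * stats::mad(v) else threshold
    idx <- row_local_maxima(v, thr)
    if (exclude_boundary && length(idx) > 0) {
      m <- map$margin[i]
      idx <- idx[idx > m & idx <= map$n - m]
    }
    if (length(idx) > 0)
      out[[i]] <- data.frame(t_index = idx, scale_index = i,
                             t = map$t0 +
                               (idx - 1 + subbin_offset(v, idx)) * map$dt,
                             scale = map$scales[i], C = v[idx])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(t_index = integer(0), scale_index = integer(0),
                      t = numeric(0), scale = numeric(0), C = numeric(0))
  res[order(res$t, res$scale), , drop = FALSE]
}

#' Group local maxima into macro clusters
#'
#' Sorts maxima by time and splits wherever successive times differ by more
#' than `gap`. Every maximum lands in exactly one cluster.
#'
#' @param maxima data.frame with at least columns `t`, `scale`, `C`.
#' @param gap Split gap in seconds, > 0.
#' @return List of data.frames, each one macro cluster, ordered by time.
#' @export
form_macro_clusters <- function(maxima, gap) {
  stopifnot(gap > 0)
  if (nrow(maxima) == 0) return(list())
  maxima <- maxima[order(maxima$t), , drop = FALSE]
  id <- cumsum(c(1, diff(maxima$t) > gap))
  unname(split(maxima, id))
}

#' Ellipse-overlap link test between cluster maxima and the centroid
#'
#' Implements the overlap rule that defines links in a micro cluster. For a
#' candidate maximum i and the cluster centroid 0 (largest coefficient):
#' \deqn{d^2 = (t_i - t_0)^2 + (\Delta t_i - \Delta t_0)^2}
#' \deqn{r_i = w h N \Delta t_i \sqrt{C'_i} / \sqrt{w^2 N^2 \sin^2\theta_i
#'   + h^2 \cos^2\theta_i}}
#' with \eqn{C'_i} the cluster-normalized coefficient and \eqn{r_0} the
#' analogous centroid radius without the coefficient weight. The candidate
#' is linked iff \eqn{(r_i + r_0)^2 \ge d^2}. \eqn{\theta_i} is the angle of
#' the segment from centroid to candidate, so \eqn{r} is the ellipse's
#' directional radius toward the candidate. The coefficient weight shrinks
#' the reach of weak maxima, which helps keep weak events near strong ones
#' as separate clusters.
#'
#' @param points data.frame of candidate maxima (columns `t`, `scale`, `C`).
#' @param centroid Single-row data.frame or list with `t`, `scale`, `C`.
#' @param w,h Spreading parameters (> 0) controlling refinement sensitivity
#'   in time and scale respectively.
#' @param N Peak count of the wavelet in use.
#' @param c_range Numeric length-2: min and max coefficient over the
#'   cluster, the normalization context for `C'`. When degenerate
#'   (max == min), `C'` is defined as 1 for all members.
#' @param symmetric_r0 If `TRUE`, the centroid radius uses its own peak
#'   count in the denominator instead of the candidate's (identical when a
#'   single wavelet is used, as here).
#' @return Logical vector, one entry per row of `points`.
#' @export
overlap_link <- function(points, centroid, w, h, N, c_range,
                         symmetric_r0 = FALSE) {
  stopifnot(w > 0, h > 0, N >= 1)
  dtv <- points$t - centroid$t
  dsv <- points$scale - centroid$scale
  d2 <- dtv^2 + dsv^2
  if (diff(c_range) > 0) {
    cp <- (points$C - c_range[1]) / (c_range[2] - c_range[1])
    cp <- pmin(pmax(cp, 0), 1)
  } else cp <- rep(1, nrow(points))
  theta <- atan2(dsv, dtv)
  den <- sqrt(w^2 * N^2 * sin(theta)^2 + h^2 * cos(theta)^2)
  ri <- w * h * N * points$scale * sqrt(cp) / den
  # r0 shares the candidate's denominator as printed; the symmetric
  # reading swaps in the centroid's own peak count, which coincides with
  # the printed form whenever one wavelet (one N) is used for detection
  r0 <- w * h * N * centroid$scale / den
  (ri + r0)^2 >= d2
}

#' Resolve a macro cluster into micro-cluster events
#'
#' Iterative star-graph extraction: pick the largest-coefficient maximum as
#' centroid (ties: smallest time), link members via [overlap_link()], emit
#' an event when the linked set (centroid included) reaches
#' `min_cluster_size`, then recurse on the unlinked remainder, which forms
#' a new, smaller cluster with a freshly picked centroid and normalization
#' context. Terminates because every iteration removes at least the
#' centroid.
#'
#' @param cluster data.frame of maxima (columns `t`, `scale`, `C`).
#' @inheritParams overlap_link
#' @param min_cluster_size Minimum number of maxima per event, >= 1.
#' @return data.frame of events with columns `t`, `scale`, `C`,
#'   `n_members`, sorted by `t`.
#' @export
resolve_micro_clusters <- function(cluster, w, h, N, min_cluster_size = 3,
                                   symmetric_r0 = FALSE) {
  events <- list()
  while (nrow(cluster) > 0) {
    ci <- order(-cluster$C, cluster$t)[1]
    cen <- cluster[ci, ]
    rest <- cluster[-ci, , drop = FALSE]
    linked <- if (nrow(rest) > 0)
      overlap_link(rest, cen, w, h, N, range(cluster$C), symmetric_r0)
    else logical(0)
    size <- sum(linked) + 1L
    if (size >= min_cluster_size)
      events[[length(events) + 1L]] <-
        data.frame(t = cen$t, scale = cen$scale, C = cen$C,
                   n_members = size)
    cluster <- rest[!linked, , drop = FALSE]
  }
  res <- do.call(rbind, events)
  if (is.null(res))
    res <- data.frame(t = numeric(0), scale = numeric(0), C = numeric(0),
                      n_members = integer(0))
  res[order(res$t), , drop = FALSE]
}

# Streaming per-scale maxima: computes each CWT row from the shared trace
# FFT and extracts its maxima without materializing the full map, keeping
# memory at one row regardless of trace length.
pcwa_maxima <- function(trace, wavelet, scales, threshold,
                        threshold_mode = "absolute",
                        exclude_boundary = TRUE) {
  check_scales(scales, trace$dt)
  kernels <- lapply(scales, function(s) wavelet_samples(wavelet, s, trace$dt))
  halves <- vapply(kernels, function(k) (length(k$values) - 1L) %/% 2L,
                   integer(1))
  plan <- cwt_plan(trace$counts, trace$dt, max(halves))
  n <- length(trace$counts)
  out <- vector("list", length(scales))
  for (i in seq_along(scales)) {
    kv <- kernels[[i]]$values
    v <- if (length(kv) <= 64L) cwt_row_direct(trace$counts, trace$dt, kv)
    else cwt_row(plan, kv)
    thr <- if (threshold_mode == "mad") threshold * stats::mad(v) else threshold
    idx <- row_local_maxima(v, thr)
    if (exclude_boundary && length(idx) > 0)
      idx <- idx[idx > halves[i] & idx <= n - halves[i]]
    if (length(idx) > 0)
      out[[i]] <- data.frame(t_index = idx, scale_index = i,
                             t = trace$t0 +
                               (idx - 1 + subbin_offset(v, idx)) * trace$dt,
                             scale = scales[i], C = v[idx])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(t_index = integer(0), scale_index = integer(0),
                      t = numeric(0), scale = numeric(0), C = numeric(0))
  res[order(res$t, res$scale), , drop = FALSE]
}

# Clustering stages shared by pcwa() and the threshold-scan harness.
cluster_maxima <- function(maxima, w, h, N, gap, min_cluster_size,
                           symmetric_r0 = FALSE) {
  clusters <- form_macro_clusters(maxima, gap)
  events <- lapply(clusters, resolve_micro_clusters, w = w, h = h, N = N,
                   min_cluster_size = min_cluster_size,
                   symmetric_r0 = symmetric_r0)
  res <- do.call(rbind, events)
  if (is.null(res))
    res <- data.frame(t = numeric(0), scale = numeric(0), C = numeric(0),
                      n_members = integer(0))
  res[order(res$t), , drop = FALSE]
}

#' Parallel Cluster Wavelet Analysis event detection
#'
#' The main entry point: computes the CWT of the trace over the scale grid,
#' extracts per-scale local maxima above the threshold, groups them into
#' macro clusters along the time axis and resolves star-graph micro
#' clusters via the ellipse-overlap rule, emitting one event per micro
#' cluster. Macro clusters are independent, so the result does not depend
#' on their processing order.
#'
#' @param trace A [pcwa_trace()].
#' @param wavelet A `pcwa_wavelet`; [ricker_wavelet()] for single-peak
#'   events, [msg_wavelet()] for N-spot multi-peak events.
#' @param scales Increasing scale vector in seconds, see [log_scales()].
#' @param threshold Coefficient threshold for local maxima (absolute, or in
#'   row-MAD units with `threshold_mode = "mad"`).
#' @param threshold_mode `"absolute"` or `"mad"`.
#' @param w,h Ellipse spreading parameters (time and scale sensitivity).
#' @param gap Macro-cluster split gap in seconds; default twice the largest
#'   scale (events farther apart than the widest wavelet cannot share
#'   maxima).
#' @param min_cluster_size Minimum maxima per event; default 3 (a genuine
#'   event produces maxima across several adjacent scales, single-scale
#'   noise spikes do not).
#' @param exclude_boundary Drop maxima within one wavelet support of the
#'   trace ends.
#' @param symmetric_r0 See [overlap_link()].
#' @param keep_maxima Keep the full local-maxima table in the result.
#' @return Object of class `pcwa`: list with `events` (data.frame `t`,
#'   `scale`, `C`, `n_members`, `t_adjusted`, `N`), `n_maxima`,
#'   `n_macro_clusters`, the configuration, and trace metadata. The event
#'   time `t` is the micro-cluster centroid; `t_adjusted` is the raw-trace
#'   local maximum within half a scale of it.
#' @examples
#' tr <- simulate_trace(sim_config(duration = 0.5, event_rate = 20,
#'                                 n_spots = 1, seed = 1))
#' fit <- pcwa(tr$trace, ricker_wavelet(), log_scales(5e-5, 1e-3, 30),
#'             threshold = 4, threshold_mode = "mad")
#' fit
#' @export
pcwa <- function(trace, wavelet, scales, threshold,
                 threshold_mode = c("absolute", "mad"),
                 w = 0.5, h = 3, gap = 2 * max(scales),
                 min_cluster_size = 3, exclude_boundary = TRUE,
                 symmetric_r0 = FALSE, keep_maxima = FALSE) {
  stopifnot(inherits(trace, "pcwa_trace"), inherits(wavelet, "pcwa_wavelet"))
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(is.finite(threshold), gap > 0, min_cluster_size >= 1)
  maxima <- pcwa_maxima(trace, wavelet, scales, threshold, threshold_mode,
                        exclude_boundary)
  clusters <- form_macro_clusters(maxima, gap)
  events <- cluster_maxima(maxima, w = w, h = h, N = wavelet$N, gap = gap,
                           min_cluster_size = min_cluster_size,
                           symmetric_r0 = symmetric_r0)
  events$t_adjusted <- adjust_event_times(trace, events)
  events$N <- rep(wavelet$N, nrow(events))
  structure(list(
    events = events, n_maxima = nrow(maxima),
    n_macro_clusters = length(clusters),
    maxima = if (keep_maxima) maxima else NULL,
    wavelet = wavelet, scales = scales,
    config = list(threshold = threshold, threshold_mode = threshold_mode,
                  w = w, h = h, gap = gap,
                  min_cluster_size = min_cluster_size,
                  exclude_boundary = exclude_boundary,
                  symmetric_r0 = symmetric_r0),
    trace_meta = list(n = length(trace$counts), dt = trace$dt,
                      t0 = trace$t0)), class = "pcwa")
}

# Refined peak time: the raw-trace maximum within +/- scale/2 of the
# micro-cluster centroid (the CWT centroid of an asymmetric peak can sit
# between samples).
adjust_event_times <- function(trace, events) {
  if (nrow(events) == 0) return(numeric(0))
  vapply(seq_len(nrow(events)), function(i) {
    half <- max(1L, as.integer(round(events$scale[i] / 2 / trace$dt)))
    c0 <- time_to_bin(trace, events$t[i])
    i0 <- max(1L, c0 - half); i1 <- min(length(trace$counts), c0 + half)
    win <- trace$counts[i0:i1]
    bin_to_time(trace, i0 + which.max(win) - 1L)
  }, numeric(1))
}

#' @export
print.pcwa <- function(x, ...) {
  cat(sprintf(
    "PCWA detection (%s wavelet, %d scales [%.3g, %.3g] s)\n",
    x$wavelet$family, length(x$scales), min(x$scales), max(x$scales)))
  cat(sprintf("  trace: %d bins, dt %.3g s\n", x$trace_meta$n,
              x$trace_meta$dt))
  cat(sprintf(
    "  %d local maxima -> %d macro clusters -> %d events (threshold %.4g%s)\n",
    x$n_maxima, x$n_macro_clusters, nrow(x$events), x$config$threshold,
    if (x$config$threshold_mode == "mad") " x row MAD" else ""))
  invisible(x)
}

#' @export
summary.pcwa <- function(object, ...) {
  ev <- object$events
  cat(sprintf("PCWA: %d events over %.4g s (%.3g events/s)\n", nrow(ev),
              object$trace_meta$n * object$trace_meta$dt,
              nrow(ev) / (object$trace_meta$n * object$trace_meta$dt)))
  if (nrow(ev) > 0) {
    cat("  scale (s):   "); print(summary(ev$scale))
    cat("  coefficient: "); print(summary(ev$C))
    cat("  cluster size:"); print(summary(ev$n_members))
  }
  invisible(object)
}

#' Extract the event table from a detection result
#' @param x A `pcwa` object (or any detector result with `$events`).
#' @return data.frame of events.
#' @export
events <- function(x) {
  if (is.data.frame(x)) x else x$events
}

#' Plot detected events over the raw trace
#' @param x A `pcwa` object.
#' @param trace The `pcwa_trace` that was analyzed.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.pcwa <- function(x, trace, ...) {
  stopifnot(inherits(trace, "pcwa_trace"))
  tt <- bin_to_time(trace, seq_along(trace$counts))
  graphics::plot(tt, trace$counts, type = "l", xlab = "time (s)",
                 ylab = "counts/bin", ...)
  if (nrow(x$events) > 0) {
    yy <- trace$counts[pmin(pmax(time_to_bin(trace, x$events$t_adjusted), 1),
                            length(trace$counts))]
    graphics::points(x$events$t_adjusted, yy, col = 2, pch = 1, cex = 1.5)
  }
  invisible(x)
}
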