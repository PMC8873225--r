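#' Amplitude-threshold event counting
#'
#' The simplest reference detector: one event per contiguous run of samples
#' above the threshold, located at the run's maximum sample.
#'
#' @param trace A [pcwa_trace()].
#' @param threshold Counts threshold; should exceed the background level.
#' @return data.frame of events with columns `t` (time of the run maximum),
#'   `C` (the maximum value) and `width` (run length in seconds).
#' @export
amplitude_threshold_detect <- function(trace, threshold) {
  stopifnot(inherits(trace, "pcwa_trace"))
  above <- trace$counts > threshold
  if (!any(above))
    return(data.frame(t = numeric(0), C = numeric(0), width = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  t <- numeric(length(runs)); C <- numeric(length(runs))
  for (j in seq_along(runs)) {
    i0 <- starts[runs[j]]; i1 <- ends[runs[j]]
    k <- i0 + which.max(trace$counts[i0:i1]) - 1L
    t[j] <- bin_to_time(trace, k); C[j] <- trace$counts[k]
  }
  data.frame(t = t, C = C,
             width = r$lengths[runs] * trace$dt)
}

#' Shift-multiply detection of N-peak trains
#'
#' Baseline for periodic multi-peak signals: the trace is shifted N-1 times
#' by a candidate spacing and all shifted copies are multiplied together.
#' The product is large where N correctly spaced peaks line up and
#' collapses for wrong peak counts or spacings. The spacing is scanned over
#' a linear grid and each sample keeps the best product over the scan.
#'
#' @param trace A [pcwa_trace()].
#' @param N Peak count to test, >= 2.
#' @param dt_range Length-2 spacing scan range in seconds.
#' @param dt_steps Number of scan points (shifts are rounded to whole bins
#'   and deduplicated).
#' @param threshold Product threshold for event emission.
#' @param smooth Moving-average half-width in bins applied to the trace
#'   before multiplying (0 = none). With sparse photon counts the raw
#'   product is degenerate (any empty bin annihilates it), so the trace is
#'   smoothed over roughly one peak width first, as in practical
#'   implementations of the method.
#' @return data.frame of events: `t` (center of the matched train), `scale`
#'   (best spacing, s), `N`, `product` (the product value).
#' @export
shift_multiply_detect <- function(trace, N, dt_range, dt_steps = 25,
                                  threshold = 1, smooth = 0) {
  pm <- shift_multiply_map(trace, N, dt_range, dt_steps, smooth)
  idx <- row_local_maxima(pm$best, threshold)
  if (length(idx) == 0)
    return(data.frame(t = numeric(0), scale = numeric(0), N = integer(0),
                      product = numeric(0)))
  k <- pm$shifts[pm$arg[idx]]
  data.frame(
    t = bin_to_time(trace, idx) + (N - 1) * k * trace$dt / 2,
    scale = k * trace$dt, N = N, product = pm$best[idx])
}

# Product map over the spacing scan: best[i] = max over spacings of
# prod_{n=0}^{N-1} f[i + n*k]; arg tracks the winning spacing index.
shift_multiply_map <- function(trace, N, dt_range, dt_steps = 25,
                               smooth = 0) {
  stopifnot(inherits(trace, "pcwa_trace"), N >= 2,
            dt_range[1] < dt_range[2])
  f <- trace$counts
  if (smooth > 0) {
    k <- 2L * as.integer(smooth) + 1L
    f <- as.numeric(stats::filter(f, rep(1 / k, k), sides = 2))
    f[is.na(f)] <- 0
  }
  n <- length(f)
  shifts <- unique(pmax(1L, as.integer(round(
    seq(dt_range[1], dt_range[2], length.out = dt_steps) / trace$dt))))
  if ((N - 1) * max(shifts) >= n)
    stop("trace shorter than (N-1) * max spacing")
  best <- rep(-Inf, n); arg <- integer(n)
  for (j in seq_along(shifts)) {
    k <- shifts[j]
    m <- n - (N - 1L) * k
    p <- f[seq_len(m)]
    for (s in 1:(N - 1L)) p <- p * f[seq_len(m) + s * k]
    upd <- which(p > best[seq_len(m)])
    best[upd] <- p[upd]; arg[upd] <- j
  }
  best[!is.finite(best)] <- 0
  list(best = best, arg = arg, shifts = shifts)
}

#' Ridge-line CWT event detection
#'
#' Minimal re-implementation of the classic serial ridge-following CWT peak
#' finder used as a runtime and accuracy reference: starting from the
#' largest scale, per-scale local maxima are linked into ridges by
#' searching the adjacent smaller-scale row for a maximum within
#' `ridge_gap` bins (each active ridge scans the row's maxima in turn; a
#' ridge closes when no continuation is found). Ridges are filtered by
#' length and by SNR (ridge maximum over the consistency-scaled median
#' absolute deviation of its scale row) and each surviving ridge emits one
#' event at its maximum-coefficient point.
#'
#' @param map A `cwt_map` from [compute_cwt()].
#' @param ridge_gap Maximum time distance (bins) to continue a ridge into
#'   the next row.
#' @param min_ridge_length Minimum rows a ridge must span.
#' @param snr_threshold Minimum ridge SNR.
#' @param threshold Minimum coefficient for the per-row maxima.
#' @return data.frame of events: `t`, `scale` (at the ridge maximum), `C`,
#'   `ridge_length`, `snr`.
#' @export
ridge_line_detect <- function(map, ridge_gap = 4, min_ridge_length = 3,
                              snr_threshold = 2, threshold = 0) {
  stopifnot(inherits(map, "cwt_map"))
  ns <- length(map$scales)
  row_mads <- apply(map$coeffs, 1, stats::mad)
  rows <- lapply(seq_len(ns), function(i)
    row_local_maxima(map$coeffs[i, ], threshold))
  ridges <- list()    # each: list(t_idx, scale_idx, C) vectors
  active <- list()
  for (i in rev(seq_len(ns))) {       # largest scale first
    cand <- rows[[i]]
    used <- rep(FALSE, length(cand))
    next_active <- list()
    for (rd in active) {
      # serial linear scan over the row's maxima for the nearest
      # continuation (deliberately unindexed, as in the original method)
      best <- 0L; bestd <- Inf
      last_t <- rd$t_idx[length(rd$t_idx)]
      for (jj in seq_along(cand)) {
        if (used[jj]) next
        dd <- abs(cand[jj] - last_t)
        if (dd < bestd) { bestd <- dd; best <- jj }
      }
      if (best > 0L && bestd <= ridge_gap) {
        used[best] <- TRUE
        rd$t_idx <- c(rd$t_idx, cand[best])
        rd$scale_idx <- c(rd$scale_idx, i)
        rd$C <- c(rd$C, map$coeffs[i, cand[best]])
        next_active[[length(next_active) + 1L]] <- rd
      } else ridges[[length(ridges) + 1L]] <- rd
    }
    for (jj in which(!used))
      next_active[[length(next_active) + 1L]] <-
        list(t_idx = cand[jj], scale_idx = i,
             C = map$coeffs[i, cand[jj]])
    active <- next_active
  }
  ridges <- c(ridges, active)
  out <- list()
  for (rd in ridges) {
    len <- length(rd$t_idx)
    if (len < min_ridge_length) next
    k <- which.max(rd$C)
    snr <- rd$C[k] / row_mads[rd$scale_idx[k]]
    if (!is.finite(snr) || snr < snr_threshold) next
    out[[length(out) + 1L]] <- data.frame(
      t = map$t0 + (rd$t_idx[k] - 1) * map$dt,
      scale = map$scales[rd$scale_idx[k]], C = rd$C[k],
      ridge_length = len, snr = snr)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(t = numeric(0), scale = numeric(0), C = numeric(0),
                      ridge_length = integer(0), snr = numeric(0))
  res[order(res$t), , drop = FALSE]
}
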