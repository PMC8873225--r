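#' Convert an event scale (peak spacing) to particle velocity
#'
#' The excitation spots have a lithographically defined pitch, so the
#' temporal peak spacing of a detected event maps directly to the
#' particle's flow velocity: `v = pitch / spacing`.
#'
#' @param scale Peak spacing in seconds (> 0).
#' @param spot_pitch Spot pitch in micrometers (> 0).
#' @return Velocity in micrometers per millisecond.
#' @examples
#' velocity_from_scale(1e-3, 5)  # 5 um/ms
#' @export
velocity_from_scale <- function(scale, spot_pitch) {
  if (any(scale <= 0)) stop("scale must be > 0")
  if (!(spot_pitch > 0)) stop("spot_pitch must be > 0")
  spot_pitch / (scale * 1e3)
}

#' Peak spacing corresponding to a velocity
#' @inheritParams velocity_from_scale
#' @param velocity Velocity in micrometers per millisecond.
#' @return Peak spacing in seconds.
#' @export
scale_from_velocity <- function(velocity, spot_pitch) {
  if (any(velocity <= 0)) stop("velocity must be > 0")
  spot_pitch / (velocity * 1e3)
}

#' Classify the peak number of one event by competing MSG wavelets
#'
#' Computes, in a window around the event, the maximum CWT coefficient for
#' an MSG wavelet at each candidate peak count (scales refined locally
#' around the event scale) and assigns the count with the highest
#' coefficient. Ties break to the smallest count.
#'
#' @param trace A [pcwa_trace()].
#' @param event One event (single-row data.frame or list with `t`,
#'   `scale`).
#' @param candidate_Ns Integer vector of candidate peak counts.
#' @param msg_base An [msg_wavelet()] supplying the shape parameters
#'   (`sigma_plus`, `alpha`, ...) reused at every candidate `N`; or a
#'   [morlet_wavelet()], in which case the candidate wavelets are Morlets
#'   whose envelope spans `N` cycles (the single-band reference
#'   classifier).
#' @param refine Length-2 multiplicative scale-refinement range around the
#'   event scale.
#' @param refine_n Number of refinement scales.
#' @param search_half_time Half-width, in units of the event scale, of the
#'   time interval around the event center over which the coefficient is
#'   maximized. Kept narrow so a wrong-count wavelet cannot improve its
#'   coefficient by sliding to a shifted alignment.
#' @return List with `N_best`, `coeffs_by_N` (named numeric), and
#'   `scale_best` (the coefficient-maximizing spacing at `N_best`).
#' @export
classify_event <- function(trace, event, candidate_Ns, msg_base,
                           refine = c(0.92, 1.08), refine_n = 5,
                           search_half_time = 0.25) {
  stopifnot(inherits(trace, "pcwa_trace"))
  candidate_Ns <- sort(as.integer(candidate_Ns))
  sc <- event$scale
  n <- length(trace$counts)
  wavelets <- lapply(candidate_Ns, function(Nj)
    candidate_wavelet(msg_base, Nj))
  # window must contain the full wavelet support around every searched
  # position so central coefficients are boundary-free
  supp <- max(vapply(wavelets, wavelet_half_support, numeric(1)))
  span <- (supp + search_half_time) * sc * max(refine) + sc
  i0 <- time_to_bin(trace, event$t - span)
  i1 <- time_to_bin(trace, event$t + span)
  if (i0 < 1 || i1 > n)
    stop("classification window clipped by trace boundary")
  win <- pcwa_trace(trace$counts[i0:i1], dt = trace$dt,
                    t0 = bin_to_time(trace, i0))
  scales <- sc * exp(seq(log(refine[1]), log(refine[2]),
                         length.out = refine_n))
  c0 <- time_to_bin(win, event$t)
  half <- max(1L, as.integer(round(search_half_time * sc / trace$dt)))
  cols <- max(1L, c0 - half):min(length(win$counts), c0 + half)
  coeffs <- numeric(length(candidate_Ns))
  scale_at <- numeric(length(candidate_Ns))
  for (j in seq_along(candidate_Ns)) {
    m <- suppressWarnings(compute_cwt(win, wavelets[[j]], scales))
    sub <- m$coeffs[, cols, drop = FALSE]
    k <- arrayInd(which.max(sub), dim(sub))
    coeffs[j] <- sub[k]
    scale_at[j] <- scales[k[1]]
  }
  names(coeffs) <- as.character(candidate_Ns)
  best <- which(coeffs == max(coeffs))[1]  # tie -> smallest N (sorted)
  list(N_best = candidate_Ns[best], coeffs_by_N = coeffs,
       scale_best = scale_at[best])
}

# Half support of a wavelet in units of the scale.
wavelet_half_support <- function(w) {
  if (inherits(w, "morlet_wavelet")) w$support_radius * w$cycles / 6
  else w$support_radius
}

candidate_wavelet <- function(base, N) {
  if (inherits(base, "msg_wavelet")) {
    p <- base$params
    msg_wavelet(N, sigma_plus = p$sigma_plus, alpha = p$alpha,
                lobe_gap = p$lobe_gap)
  } else if (inherits(base, "morlet_wavelet")) {
    morlet_wavelet(cycles = N, support_radius = base$support_radius)
  } else stop("unsupported base wavelet for classification")
}

#' Summed background-subtracted event intensity
#'
#' Sum of (counts - local background median) over the event window
#' `[t - N*scale/2, t + N*scale/2]`, floored at zero. The background is the
#' median of the counts in a surrounding window of 50 scales, excluding the
#' event window itself (robust to sparse events).
#'
#' @param trace A [pcwa_trace()].
#' @param event Single event (list/row with `t`, `scale`).
#' @param N Peak count of the event.
#' @return Intensity in photon counts.
#' @export
event_intensity <- function(trace, event, N = 1) {
  n <- length(trace$counts)
  half <- max(1L, as.integer(round(N * event$scale / 2 / trace$dt)))
  c0 <- time_to_bin(trace, event$t)
  i0 <- max(1L, c0 - half); i1 <- min(n, c0 + half)
  bg_half <- as.integer(round(25 * N * event$scale / trace$dt))
  b0 <- max(1L, c0 - bg_half); b1 <- min(n, c0 + bg_half)
  bg_idx <- setdiff(b0:b1, i0:i1)
  bg <- if (length(bg_idx) > 0) stats::median(trace$counts[bg_idx])
  else stats::median(trace$counts)
  max(sum(trace$counts[i0:i1] - bg), 0)
}

#' Classify, and extract velocity and intensity for, a set of events
#'
#' Applies [classify_event()] to every event, converts the refined peak
#' spacing to velocity when a spot pitch is given, and extracts the summed
#' background-subtracted intensity.
#'
#' @param trace A [pcwa_trace()].
#' @param events Event data.frame (from [pcwa()]).
#' @param candidate_Ns Candidate peak counts, e.g. `c(6, 7, 8)`.
#' @param msg_base Base wavelet for the candidates (see [classify_event()]).
#' @param spot_pitch Spot pitch in micrometers, or `NULL` to skip velocity.
#' @return The events data.frame with added columns `N_best`,
#'   `coeff_best`, one `coeff_N<k>` column per candidate,
#'   `velocity_um_per_ms` (NA without pitch) and `intensity`. Events whose
#'   window is clipped by the trace boundary get NA classification.
#' @export
classify_events <- function(trace, events, candidate_Ns, msg_base,
                            spot_pitch = NULL) {
  ev <- as.data.frame(events)
  nev <- nrow(ev)
  candidate_Ns <- sort(as.integer(candidate_Ns))
  ev$N_best <- rep(NA_integer_, nev)
  ev$coeff_best <- rep(NA_real_, nev)
  for (Nj in candidate_Ns) ev[[paste0("coeff_N", Nj)]] <- rep(NA_real_, nev)
  ev$velocity_um_per_ms <- rep(NA_real_, nev)
  ev$intensity <- rep(NA_real_, nev)
  for (i in seq_len(nev)) {
    cl <- tryCatch(
      classify_event(trace, ev[i, ], candidate_Ns, msg_base),
      error = function(e) NULL)
    if (is.null(cl)) next
    ev$N_best[i] <- cl$N_best
    ev$coeff_best[i] <- max(cl$coeffs_by_N)
    for (Nj in candidate_Ns)
      ev[[paste0("coeff_N", Nj)]][i] <- cl$coeffs_by_N[[as.character(Nj)]]
    if (!is.null(spot_pitch))
      ev$velocity_um_per_ms[i] <- velocity_from_scale(cl$scale_best,
                                                      spot_pitch)
    ev$intensity[i] <- event_intensity(trace, ev[i, ], cl$N_best)
  }
  ev
}

#' Joint intensity-velocity histogram with elliptical confidence gate
#'
#' Bins classified events in the (intensity, velocity) plane and marks
#' events inside a robust elliptical confidence region (center and
#' covariance from a robust fit, gate at a configurable Mahalanobis
#' radius). Misidentified noise peaks fall outside the gate and can be
#' rejected on the joint information.
#'
#' @param events Classified event data.frame with `intensity` and
#'   `velocity_um_per_ms` columns.
#' @param n_bins Bins per axis.
#' @param gate_radius Mahalanobis radius of the gate (default 3).
#' @return List with `counts` (matrix), `intensity_breaks`,
#'   `velocity_breaks`, `center`, `cov`, and `in_gate` (logical per event).
#' @export
joint_histogram <- function(events, n_bins = 30, gate_radius = 3) {
  ok <- is.finite(events$intensity) & is.finite(events$velocity_um_per_ms)
  if (!any(ok)) stop("no events with finite intensity and velocity")
  x <- events$intensity[ok]; y <- events$velocity_um_per_ms[ok]
  xb <- seq(min(x), max(x), length.out = n_bins + 1)
  yb <- seq(min(y), max(y), length.out = n_bins + 1)
  xi <- pmin(findInterval(x, xb, rightmost.closed = TRUE), n_bins)
  yi <- pmin(findInterval(y, yb, rightmost.closed = TRUE), n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  for (i in seq_along(xi)) counts[xi[i], yi[i]] <- counts[xi[i], yi[i]] + 1L
  m <- cbind(x, y)
  rc <- if (nrow(m) >= 5 && all(apply(m, 2, stats::sd) > 0))
    tryCatch(MASS::cov.rob(m), error = function(e) NULL) else NULL
  if (is.null(rc)) rc <- list(center = colMeans(m), cov = stats::cov(m))
  d2 <- tryCatch(stats::mahalanobis(m, rc$center, rc$cov),
                 error = function(e) rep(0, nrow(m)))
  in_gate <- rep(NA, nrow(events))
  in_gate[ok] <- d2 <= gate_radius^2
  list(counts = counts, intensity_breaks = xb, velocity_breaks = yb,
       center = rc$center, cov = rc$cov, in_gate = in_gate)
}

#' Time-resolved event statistics
#'
#' Bins events along the measurement time and reports, per bin, the event
#' count and the mean and standard deviation of intensity and velocity
#' (for dynamic monitoring of flow conditions). Empty bins report count 0
#' with NA means; single-event bins report NA standard deviations.
#'
#' @param events Classified event data.frame (`t`, `intensity`,
#'   `velocity_um_per_ms`).
#' @param bin_width Bin width in seconds, > 0.
#' @param duration Total measurement span in seconds (default: last event
#'   time).
#' @return data.frame with `t_mid`, `count`, `mean_intensity`,
#'   `sd_intensity`, `mean_velocity`, `sd_velocity`.
#' @export
time_resolved_stats <- function(events, bin_width, duration = NULL) {
  stopifnot(bin_width > 0)
  if (is.null(duration))
    duration <- if (nrow(events) > 0) max(events$t) else bin_width
  nb <- max(1L, as.integer(ceiling(duration / bin_width)))
  bins <- pmin(pmax(floor(events$t / bin_width) + 1L, 1L), nb)
  out <- data.frame(t_mid = (seq_len(nb) - 0.5) * bin_width,
                    count = 0L, mean_intensity = NA_real_,
                    sd_intensity = NA_real_, mean_velocity = NA_real_,
                    sd_velocity = NA_real_)
  for (b in unique(bins)) {
    sel <- bins == b
    out$count[b] <- sum(sel)
    if ("intensity" %in% names(events)) {
      out$mean_intensity[b] <- mean(events$intensity[sel])
      out$sd_intensity[b] <- stats::sd(events$intensity[sel])
    }
    if ("velocity_um_per_ms" %in% names(events)) {
      out$mean_velocity[b] <- mean(events$velocity_um_per_ms[sel])
      out$sd_velocity[b] <- stats::sd(events$velocity_um_per_ms[sel])
    }
  }
  out
}
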