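#' Mother wavelets for cluster-based CWT event detection
#'
#' Constructors for the three mother-wavelet families used by the PCWA
#' detector: the Ricker (Mexican hat) wavelet for single-peak events, the
#' real Morlet wavelet as a single-band reference, and the Multi-Spot
#' Gaussian (MSG) wavelet matched to multi-peak signals produced by a
#' particle crossing an N-spot excitation pattern.
#'
#' All families share two calibration conditions, enforced on every sampled
#' realization: zero mean (admissibility) and unit square norm
#' (`sum(psi^2) * dt == 1`), so that CWT coefficients are comparable across
#' scales.
#'
#' @param support_radius Dimensionless truncation half-width. The sampled
#'   wavelet is set to zero for `|t| >= support_radius * scale` (Ricker,
#'   Morlet) or `|t| >= support_radius * scale` with `support_radius` in
#'   units of the peak spacing (MSG). Defaults keep the truncation error
#'   below 1e-8 of the norm.
#' @return An object of class `pcwa_wavelet` (subclass per family) holding
#'   the family parameters. Sample it at a given scale with
#'   [wavelet_samples()].
#' @seealso [msg_wavelet()], [wavelet_samples()], [wavelet_spectrum()]
#' @examples
#' w <- ricker_wavelet()
#' sw <- wavelet_samples(w, scale = 1e-3, dt = 1e-5)
#' sum(sw$values^2) * sw$dt  # ~1
#' @export
ricker_wavelet <- function(support_radius = 5) {
  stopifnot(support_radius > 0)
  structure(
    list(family = "ricker", support_radius = support_radius, N = 1L),
    class = c("ricker_wavelet", "pcwa_wavelet")
  )
}

#' Real Morlet wavelet
#'
#' A cosine carrier under a Gaussian (Gabor) window. The carrier frequency
#' at scale `s` is `1/s`, so the dominant frequency of the sampled wavelet
#' aligns with the first harmonic of a periodic peak train of spacing `s`.
#'
#' @param cycles Number of oscillation cycles contained in the +/-3 sigma
#'   extent of the Gaussian window. Larger values narrow the frequency band.
#'   When used to interrogate an N-peak train, `cycles = N` makes the
#'   envelope span the whole train.
#' @param support_radius Truncation half-width in units of the envelope
#'   standard deviation.
#' @inherit ricker_wavelet return
#' @export
morlet_wavelet <- function(cycles = 6, support_radius = 6) {
  stopifnot(cycles > 0, support_radius > 0)
  structure(
    list(family = "morlet", cycles = cycles, support_radius = support_radius,
         N = 1L),
    class = c("morlet_wavelet", "pcwa_wavelet")
  )
}

#' Multi-Spot Gaussian (MSG) wavelet
#'
#' Mother wavelet matched to the signal of a particle crossing an N-spot
#' excitation pattern: the sum of `N` Gaussians spaced by the scale
#' (peak spacing) `dt`, flanked by two negative skew-Gaussian side lobes.
#' The side lobes restore the zero-mean (admissibility) condition and make
#' the wavelet sensitive to the exact peak count: an (N+1)-peak signal has
#' its extra peak fall onto a negative lobe, suppressing the coefficient.
#'
#' The side-lobe amplitude `a` is solved numerically so the integral of the
#' wavelet is exactly zero; the skew-normal mode offset `m0` is computed
#' numerically from the shape parameter `alpha`; the lobe centers are placed
#' so the lobe maxima sit `lobe_gap` peak spacings outside the first and
#' last positive peaks.
#'
#' @param N Number of positive peaks (excitation spots), integer >= 1.
#' @param sigma_plus Positive-peak standard deviation, in units of the peak
#'   spacing. Default 0.18 (peak FWHM ~ 0.42 spacings, visually separated
#'   spots). Fit it from data with [fit_sigma_plus()].
#' @param alpha Skewness shape of the side lobes; positive values point the
#'   tails away from the peak train.
#' @param sigma_minus Side-lobe width in peak-spacing units; default
#'   `sigma_plus * sqrt(N)` so one lobe spans the scale of the whole train.
#' @param a Side-lobe amplitude. `NULL` (default) solves it numerically for
#'   an exactly zero-mean continuous form.
#' @param lobe_gap Distance, in peak spacings, of each side-lobe maximum
#'   beyond the outermost positive peak. Default 1.
#' @param support_radius Truncation half-width in peak-spacing units;
#'   default covers the train plus the full side-lobe tails.
#' @return Object of classes `msg_wavelet`, `pcwa_wavelet` with the solved
#'   parameter set in `$params` (fields `N`, `sigma_plus`, `sigma_minus`,
#'   `a`, `alpha`, `m0`).
#' @examples
#' w <- msg_wavelet(7)
#' w$params$a            # solved zero-mean side-lobe amplitude
#' sw <- wavelet_samples(w, scale = 2e-4, dt = 1e-5)
#' @export
msg_wavelet <- function(N, sigma_plus = 0.18, alpha = 3,
                        sigma_minus = sigma_plus * sqrt(N), a = NULL,
                        lobe_gap = 1, support_radius = NULL) {
  if (!(is.numeric(N) && length(N) == 1 && N >= 1 && N == round(N)))
    stop("N must be a single integer >= 1")
  if (!(sigma_plus > 0)) stop("sigma_plus must be > 0")
  if (!(sigma_minus > 0)) stop("sigma_minus must be > 0")
  N <- as.integer(N)
  m0 <- skew_normal_mode(alpha)
  if (is.null(support_radius))
    support_radius <- (N + 1) / 2 + 6 * sigma_minus + 4 * sigma_plus
  if (is.null(a)) {
    a <- solve_msg_zero_mean(N, sigma_plus, sigma_minus, alpha, m0, lobe_gap,
                             support_radius)
  }
  if (!(a > 0)) stop("side-lobe amplitude a must be > 0")
  structure(
    list(family = "msg",
         params = list(N = N, sigma_plus = sigma_plus,
                       sigma_minus = sigma_minus, a = a, alpha = alpha,
                       m0 = m0, lobe_gap = lobe_gap),
         support_radius = support_radius, N = N),
    class = c("msg_wavelet", "pcwa_wavelet")
  )
}

#' @export
print.pcwa_wavelet <- function(x, ...) {
  cat(sprintf("<%s wavelet>", x$family))
  if (x$family == "msg") {
    p <- x$params
    cat(sprintf(" N=%d sigma+=%.3g sigma-=%.3g a=%.4g alpha=%.3g m0=%.4g",
                p$N, p$sigma_plus, p$sigma_minus, p$a, p$alpha, p$m0))
  }
  if (x$family == "morlet") cat(sprintf(" cycles=%.3g", x$cycles))
  cat(sprintf("  support_radius=%.3g\n", x$support_radius))
  invisible(x)
}

# Mode of the standard skew-normal density 2*phi(z)*Phi(alpha*z),
# located numerically (no closed form).
skew_normal_mode <- function(alpha) {
  if (alpha == 0) return(0)
  f <- function(z) -2 * stats::dnorm(z) * stats::pnorm(alpha * z)
  sgn <- sign(alpha)
  opt <- stats::optimize(f, interval = sort(c(0, sgn * 2)), tol = 1e-12)
  opt$minimum
}

# Continuous MSG waveform on the normalized axis tau = t / scale
# (peak-spacing units), split so the side-lobe amplitude can be solved
# linearly: psi = pos - a * neg_unit. Lobe centers are chosen so the
# skew-normal mode lands lobe_gap spacings outside the outermost peaks.
msg_shape_parts <- function(tau, N, sigma_plus, sigma_minus, alpha, m0,
                            lobe_gap) {
  pos <- 0
  centers <- (0:(N - 1)) - (N - 1) / 2
  for (c0 in centers) pos <- pos + exp(-(tau - c0)^2 / (2 * sigma_plus^2))
  L <- (N - 1) / 2 + lobe_gap
  neg <- 0
  for (k in c(1, -1)) {
    z <- (tau + k * (sigma_minus * m0 - L)) / sigma_minus
    neg <- neg + (2 / sigma_minus) * stats::dnorm(z) *
      stats::pnorm(k * alpha * z)
  }
  list(pos = pos, neg_unit = neg)
}

# Solve the side-lobe amplitude for a zero-mean wavelet on a dense grid over
# the truncated support. The integral is linear in a, so the root is the
# ratio of the positive and unit-lobe integrals. Closed form (untruncated):
# a = N * sigma_plus * sqrt(2*pi) / 2.
solve_msg_zero_mean <- function(N, sigma_plus, sigma_minus, alpha, m0,
                                lobe_gap, support_radius) {
  h <- min(sigma_plus, sigma_minus) / 50
  tau <- seq(-support_radius, support_radius, by = h)
  parts <- msg_shape_parts(tau, N, sigma_plus, sigma_minus, alpha, m0,
                           lobe_gap)
  denom <- sum(parts$neg_unit) * h
  if (!is.finite(denom) || denom <= 0)
    stop("MSG zero-mean calibration failed: degenerate side-lobe integral")
  a <- sum(parts$pos) * h / denom
  resid <- sum(parts$pos - a * parts$neg_unit) * h
  if (abs(resid) > 1e-8 * max(parts$pos))
    stop(sprintf("MSG zero-mean calibration failed: residual %.3g", resid))
  a
}

#' Sample a mother wavelet at a given scale
#'
#' Evaluates the wavelet on a uniform, symmetric time grid at the requested
#' scale, truncates it at the family's support radius, and calibrates the
#' samples to zero mean and unit square norm (`sum(psi^2) * dt == 1`,
#' absorbing the 1/sqrt(scale) energy normalization of the transform).
#'
#' @param wavelet A `pcwa_wavelet` object.
#' @param scale Scale (temporal peak spacing for MSG) in seconds; must be
#'   positive and larger than `dt`.
#' @param dt Sampling interval in seconds.
#' @return A list of class `sampled_wavelet`: `values`, `t_grid` (seconds,
#'   symmetric about 0), `scale`, `dt`.
#' @export
wavelet_samples <- function(wavelet, scale, dt) {
  if (!inherits(wavelet, "pcwa_wavelet")) stop("not a pcwa_wavelet")
  if (!(is.numeric(scale) && length(scale) == 1 && scale > 0))
    stop("scale must be a single positive number")
  if (!(is.numeric(dt) && length(dt) == 1 && dt > 0)) stop("dt must be > 0")
  if (dt >= scale) stop("dt must be smaller than scale")
  UseMethod("wavelet_samples")
}

#' @export
wavelet_samples.ricker_wavelet <- function(wavelet, scale, dt) {
  half <- floor(wavelet$support_radius * scale / dt)
  t <- (-half:half) * dt
  x <- t / scale
  v <- (1 - x^2) * exp(-x^2 / 2)
  calibrate_samples(v, t, scale, dt)
}

#' @export
wavelet_samples.morlet_wavelet <- function(wavelet, scale, dt) {
  # Envelope sd chosen so +/-3 sd holds `cycles` carrier periods.
  sd_env <- wavelet$cycles * scale / 6
  half <- floor(wavelet$support_radius * sd_env / dt)
  t <- (-half:half) * dt
  # Subtracting the carrier's Gaussian-window mean keeps the continuous
  # form zero-mean before discrete calibration.
  omega <- 2 * pi * sd_env / scale
  v <- (cos(2 * pi * t / scale) - exp(-omega^2 / 2)) *
    exp(-t^2 / (2 * sd_env^2))
  calibrate_samples(v, t, scale, dt)
}

#' @export
wavelet_samples.msg_wavelet <- function(wavelet, scale, dt) {
  p <- wavelet$params
  if (p$sigma_plus * scale < 2 * dt)
    warning(sprintf(paste0(
      "scale %.3g under-resolved: fewer than ~4 samples per positive peak ",
      "(sigma_plus * scale = %.3g, dt = %.3g)"), scale,
      p$sigma_plus * scale, dt))
  half <- floor(wavelet$support_radius * scale / dt)
  t <- (-half:half) * dt
  parts <- msg_shape_parts(t / scale, p$N, p$sigma_plus, p$sigma_minus,
                           p$alpha, p$m0, p$lobe_gap)
  v <- parts$pos - p$a * parts$neg_unit
  calibrate_samples(v, t, scale, dt)
}

# Discrete calibration shared by all families: exact zero mean, then unit
# square norm with the dt quadrature weight.
calibrate_samples <- function(v, t, scale, dt) {
  v <- v - mean(v)
  nrm2 <- sum(v^2) * dt
  if (nrm2 <= 0) stop("degenerate wavelet: zero norm after calibration")
  v <- v / sqrt(nrm2)
  structure(list(values = v, t_grid = t, scale = scale, dt = dt),
            class = "sampled_wavelet")
}

#' @export
print.sampled_wavelet <- function(x, ...) {
  cat(sprintf("<sampled wavelet> %d samples, scale %.4g s, dt %.4g s\n",
              length(x$values), x$scale, x$dt))
  invisible(x)
}

#' Magnitude spectrum of a sampled wavelet
#'
#' Matched-design diagnostic: the discrete Fourier magnitude spectrum of the
#' sampled wavelet on a frequency grid up to Nyquist. A well-matched
#' multi-peak wavelet shows energy at the peak-spacing harmonics
#' (1/scale, 2/scale, ...) like the signal it targets; a zero-mean wavelet
#' has zero DC magnitude.
#'
#' @param sw A `sampled_wavelet` from [wavelet_samples()].
#' @return data.frame with columns `freq` (Hz) and `magnitude`.
#' @export
wavelet_spectrum <- function(sw) {
  stopifnot(inherits(sw, "sampled_wavelet"))
  n <- length(sw$values)
  mag <- Mod(stats::fft(sw$values)) * sw$dt
  nk <- floor(n / 2) + 1
  data.frame(freq = (0:(nk - 1)) / (n * sw$dt), magnitude = mag[seq_len(nk)])
}

#' Convenience samplers matching the module surface
#'
#' Thin wrappers that build the wavelet object and sample it in one call.
#' @inheritParams wavelet_samples
#' @param ... Passed to the corresponding constructor.
#' @return A `sampled_wavelet`.
#' @rdname samplers
#' @export
sample_ricker <- function(scale, dt, ...)
  wavelet_samples(ricker_wavelet(...), scale, dt)

#' @rdname samplers
#' @param center_cycles Cycles in the Gabor window (see [morlet_wavelet()]).
#' @export
sample_morlet <- function(scale, dt, center_cycles = 6)
  wavelet_samples(morlet_wavelet(cycles = center_cycles), scale, dt)

#' @rdname samplers
#' @param params An `msg_wavelet` object (or its `$params` list is not
#'   accepted; pass the object).
#' @export
sample_msg <- function(params, scale, dt) wavelet_samples(params, scale, dt)

#' Estimate the positive-peak width of multi-peak events from data
#'
#' Fits the `sigma_plus` parameter of the MSG wavelet from a set of detected
#' events: for each event, the peak spacing is taken from the event scale
#' and a Gaussian width is estimated from the second moment of the
#' background-subtracted signal around each positive peak.
#'
#' @param trace A `pcwa_trace`.
#' @param events Event data.frame (from [pcwa()]) with columns `t`, `scale`.
#' @param N Peak count of the events.
#' @return Estimated `sigma_plus` (peak sd in units of the peak spacing),
#'   the median over events and peaks.
#' @export
fit_sigma_plus <- function(trace, events, N) {
  stopifnot(inherits(trace, "pcwa_trace"), N >= 1)
  if (nrow(events) == 0) stop("no events to fit")
  ests <- numeric(0)
  for (i in seq_len(nrow(events))) {
    sc <- events$scale[i]; tc <- events$t[i]
    centers <- tc + ((0:(N - 1)) - (N - 1) / 2) * sc
    bg <- stats::median(trace$counts)
    for (c0 in centers) {
      i0 <- max(1L, time_to_bin(trace, c0 - sc / 2))
      i1 <- min(length(trace$counts), time_to_bin(trace, c0 + sc / 2))
      if (i1 - i0 < 3) next
      w <- pmax(trace$counts[i0:i1] - bg, 0)
      if (sum(w) <= 0) next
      tt <- bin_to_time(trace, i0:i1)
      mu <- sum(w * tt) / sum(w)
      s2 <- sum(w * (tt - mu)^2) / sum(w)
      if (s2 > 0) ests <- c(ests, sqrt(s2) / sc)
    }
  }
  if (length(ests) == 0) stop("sigma_plus fit failed: no usable peaks")
  stats::median(ests)
}
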