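#' Logarithmic scale grid
#'
#' Geometrically spaced scale values between `min_scale` and `max_scale`
#' inclusive, the grid on which the CWT map is evaluated. 100 scales is the
#' standard working resolution for event detection.
#'
#' @param min_scale,max_scale Scale range in seconds, `0 < min < max`.
#' @param n Number of scales, >= 2.
#' @return Strictly increasing numeric vector of length `n` with constant
#'   ratio between neighbors.
#' @examples
#' log_scales(1e-4, 1e-2, 3)  # 1e-4, 1e-3, 1e-2
#' @export
log_scales <- function(min_scale, max_scale, n = 100) {
  if (!(min_scale > 0 && max_scale > min_scale)) stop("need 0 < min_scale < max_scale")
  if (n < 2) stop("n must be >= 2")
  s <- exp(seq(log(min_scale), log(max_scale), length.out = n))
  s[1] <- min_scale; s[n] <- max_scale
  s
}

# FFT convolution plan: the trace spectrum is computed once and reused for
# every scale row. P is a mixed-radix-friendly padded length large enough
# to make circular convolution equal the zero-padded linear one.
cwt_plan <- function(counts, dt, max_half) {
  n <- length(counts)
  P <- stats::nextn(n + 2L * max_half + 1L, c(2, 3, 5))
  Ff <- stats::fft(c(counts, numeric(P - n)))
  list(F = Ff, P = P, n = n, dt = dt)
}

# One CWT row: discrete correlation of the trace with the sampled wavelet,
# evaluated at every trace sample (Riemann sum with weight dt).
cwt_row <- function(plan, kernel) {
  K <- (length(kernel) - 1L) %/% 2L
  kp <- numeric(plan$P)
  kp[1:(K + 1L)] <- kernel[(K + 1L):(2L * K + 1L)]
  if (K > 0) kp[(plan$P - K + 1L):plan$P] <- kernel[1:K]
  conv <- Re(stats::fft(plan$F * stats::fft(kp), inverse = TRUE)) / plan$P
  conv[seq_len(plan$n)] * plan$dt
}

# Direct-summation row used for short kernels and as a simple reference.
cwt_row_direct <- function(counts, dt, kernel) {
  n <- length(counts)
  K <- (length(kernel) - 1L) %/% 2L
  out <- numeric(n)
  for (off in -K:K) {
    kv <- kernel[off + K + 1L]
    if (kv == 0) next
    # C[i] = sum_j f[j] * psi[i - j]; j = i - off
    src <- seq_len(n) - off
    ok <- src >= 1L & src <= n
    out[ok] <- out[ok] + counts[src[ok]] * kv
  }
  out * dt
}

#' Continuous wavelet transform of a trace
#'
#' Computes the 2D coefficient map C(t, scale): at each scale the trace is
#' correlated with the sampled, zero-mean, unit-square-norm wavelet at that
#' scale, evaluated at every trace sample. Rows are computed independently
#' (one FFT of the trace is shared; each row adds one kernel FFT and one
#' inverse FFT, or a direct sum for short kernels).
#'
#' @param trace A [pcwa_trace()].
#' @param wavelet A `pcwa_wavelet`.
#' @param scales Increasing vector of scales in seconds (see
#'   [log_scales()]). Each scale must be at least `4 * dt` (and, for the
#'   MSG family, resolve the positive peak width).
#' @return Object of class `cwt_map`: list with `coeffs` (matrix, one row
#'   per scale), `scales`, `dt`, `t0`, `n`, and `margin` (per-scale
#'   boundary half-width, in bins, inside which coefficients are affected
#'   by the trace ends).
#' @export
compute_cwt <- function(trace, wavelet, scales) {
  stopifnot(inherits(trace, "pcwa_trace"), inherits(wavelet, "pcwa_wavelet"))
  check_scales(scales, trace$dt)
  kernels <- lapply(scales, function(s) wavelet_samples(wavelet, s, trace$dt))
  max_half <- max(vapply(kernels, function(k) (length(k$values) - 1L) %/% 2L,
                         integer(1)))
  plan <- cwt_plan(trace$counts, trace$dt, max_half)
  coeffs <- matrix(0, nrow = length(scales), ncol = length(trace$counts))
  margin <- integer(length(scales))
  for (i in seq_along(scales)) {
    kv <- kernels[[i]]$values
    margin[i] <- (length(kv) - 1L) %/% 2L
    coeffs[i, ] <- if (length(kv) <= 64L)
      cwt_row_direct(trace$counts, trace$dt, kv)
    else cwt_row(plan, kv)
  }
  structure(list(coeffs = coeffs, scales = scales, dt = trace$dt,
                 t0 = trace$t0, n = length(trace$counts), margin = margin),
            class = "cwt_map")
}

check_scales <- function(scales, dt) {
  if (length(scales) < 1 || any(!is.finite(scales)))
    stop("invalid scale grid")
  if (is.unsorted(scales, strictly = TRUE)) stop("scales must be strictly increasing")
  bad <- scales < 4 * dt * (1 - 1e-9)   # tolerate the exact 4*dt boundary
  if (any(bad))
    stop("unresolvable scales (< 4*dt): ",
         paste(signif(scales[bad], 4), collapse = ", "))
  invisible(TRUE)
}

#' @export
print.cwt_map <- function(x, ...) {
  cat(sprintf("<cwt_map> %d scales x %d samples, scale range [%.4g, %.4g] s\n",
              length(x$scales), x$n, min(x$scales), max(x$scales)))
  invisible(x)
}

#' Plot a CWT map as a scalogram
#' @param x A `cwt_map`.
#' @param events Optional event data.frame to mark (columns `t`, `scale`).
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.cwt_map <- function(x, events = NULL, ...) {
  tt <- x$t0 + (seq_len(x$n) - 1) * x$dt
  graphics::image(tt, log10(x$scales), t(x$coeffs), xlab = "time (s)",
                  ylab = "log10 scale (s)", col = grDevices::hcl.colors(64),
                  ...)
  if (!is.null(events) && nrow(events) > 0)
    graphics::points(events$t, log10(events$scale), pch = 0, col = "white")
  invisible(x)
}
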