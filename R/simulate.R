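#' Configuration for synthetic single-/multi-peak sensor traces
#'
#' Defines the generative model for ground-truthed synthetic fluorescence
#' traces: a homogeneous Poisson background, events arriving as a Poisson
#' process in time, and per-event signal profiles produced by a particle of
#' velocity v crossing an `n_spots`-spot excitation pattern of pitch
#' `spot_pitch` (temporal peak spacing `spot_pitch / v`, peak width
#' `spot_sigma / v`). Per-bin counts are Poisson draws around background
#' plus signal (shot noise).
#'
#' @param duration Trace duration in seconds.
#' @param dt Bin width in seconds (default 1e-5, i.e. 10 microsecond bins).
#' @param bg_rate Mean background counts per bin.
#' @param event_rate Event rate in events per second.
#' @param n_spots Number of excitation spots (1 = single-peak events).
#' @param spot_pitch Center-to-center spot spacing in micrometers.
#' @param spot_sigma Spot 1-sigma half-width in micrometers.
#' @param velocity_mean Mean particle velocity in micrometers per
#'   millisecond.
#' @param velocity_shape `"parabolic"`: velocities from a pressure-driven
#'   laminar profile, v = vmax (1 - r^2) with r uniform on [0, r_max)
#'   (vmax set so the mean matches `velocity_mean`); or `"lognormal"` with
#'   `velocity_spread` as sdlog.
#' @param velocity_spread For `"parabolic"`, the truncation radius r_max
#'   (default 0.9, keeping velocities above ~20% of vmax); for
#'   `"lognormal"`, the sdlog.
#' @param amplitude_median Median peak amplitude in counts per bin (at a
#'   spot center).
#' @param amplitude_sdlog Lognormal spread of the amplitude (brightness
#'   varies with particle position in the channel).
#' @param seed Integer seed; a fixed seed gives bit-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration = 10, dt = 1e-5, bg_rate = 0.5,
                       event_rate = 3, n_spots = 7, spot_pitch = 2.2,
                       spot_sigma = 0.18 * spot_pitch,
                       velocity_mean = 10,
                       velocity_shape = c("parabolic", "lognormal"),
                       velocity_spread = NULL,
                       amplitude_median = 1.5, amplitude_sdlog = 0.75,
                       seed = NULL) {
  velocity_shape <- match.arg(velocity_shape)
  if (is.null(velocity_spread))
    velocity_spread <- if (velocity_shape == "parabolic") 0.9 else 0.4
  stopifnot(duration > 0, dt > 0, bg_rate >= 0, event_rate >= 0,
            n_spots >= 1, spot_pitch > 0, spot_sigma > 0,
            velocity_mean > 0, amplitude_median > 0)
  structure(list(duration = duration, dt = dt, bg_rate = bg_rate,
                 event_rate = event_rate, n_spots = as.integer(n_spots),
                 spot_pitch = spot_pitch, spot_sigma = spot_sigma,
                 velocity_mean = velocity_mean,
                 velocity_shape = velocity_shape,
                 velocity_spread = velocity_spread,
                 amplitude_median = amplitude_median,
                 amplitude_sdlog = amplitude_sdlog, seed = seed),
            class = "sim_config")
}

#' Preset emulating the multi-spot single-molecule (KPC-like) experiment
#'
#' 60 s trace in 10 microsecond bins, 7-spot events over a 30 kcps Poisson
#' background, 2.2 micrometer spot pitch with a truncated-parabolic velocity
#' profile around 10 micrometers/ms (so a typical event's first harmonic
#' sits near 4.5 kHz), and a lognormal amplitude distribution (median peak
#' 0.9 counts/bin) emulating the dim single-molecule regime in which
#' matched-filter detection pays off. All values are package choices
#' standing in for restricted raw data; see the methods vignette.
#'
#' @param seed Integer seed.
#' @param duration Trace duration in seconds.
#' @return A `sim_config`.
#' @export
kpc_config <- function(seed = NULL, duration = 60) {
  sim_config(duration = duration, dt = 1e-5, bg_rate = 0.3, event_rate = 3,
             n_spots = 7, spot_pitch = 2.2, spot_sigma = 0.18 * 2.2,
             velocity_mean = 10, velocity_shape = "parabolic",
             amplitude_median = 0.9, amplitude_sdlog = 0.3, seed = seed)
}

#' Preset emulating single-peak fluorescent-bead traces
#'
#' Bright, sparse single-peak events (single-spot excitation) over a
#' moderate Poisson background.
#'
#' @param seed Integer seed.
#' @param duration Trace duration in seconds.
#' @param amplitude_median Median peak amplitude (counts/bin).
#' @return A `sim_config`.
#' @export
beads_config <- function(seed = NULL, duration = 20, amplitude_median = 6) {
  sim_config(duration = duration, dt = 1e-5, bg_rate = 1, event_rate = 5,
             n_spots = 1, spot_pitch = 2.2, spot_sigma = 0.3,
             velocity_mean = 10, velocity_shape = "parabolic",
             amplitude_median = amplitude_median, amplitude_sdlog = 0.3,
             seed = seed)
}

draw_velocities <- function(n, cfg) {
  if (cfg$velocity_shape == "parabolic") {
    rmax <- cfg$velocity_spread
    vmax <- cfg$velocity_mean / (1 - rmax^2 / 3)
    r <- stats::runif(n, 0, rmax)
    vmax * (1 - r^2)
  } else {
    stats::rlnorm(n, meanlog = log(cfg$velocity_mean) -
                    cfg$velocity_spread^2 / 2, sdlog = cfg$velocity_spread)
  }
}

#' Simulate a ground-truthed sensor trace
#'
#' Event times follow a Poisson process at `event_rate` (restricted so each
#' event's full footprint lies inside the trace); each event contributes
#' `amplitude * sum_n exp(-(t - t_n)^2 / (2 sigma_t^2))` with spot centers
#' `t_n` spaced by `spot_pitch / v` and `sigma_t = spot_sigma / v`; per-bin
#' counts are `Poisson(bg_rate + signal)`.
#'
#' @param cfg A [sim_config()].
#' @return List with `trace` (a [pcwa_trace()]) and `truth`, a data.frame
#'   with one row per event: `t_true` (event center, s), `velocity_true`
#'   (um/ms), `dt_true` (peak spacing, s), `width_true` (peak sigma, s),
#'   `N_true`, `amplitude_true` (counts/bin at a spot center) and
#'   `photon_sum_true` (expected signal photons).
#' @export
simulate_trace <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_bins <- as.integer(round(cfg$duration / cfg$dt))
  lambda <- rep(cfg$bg_rate, n_bins)
  n_ev <- stats::rpois(1, cfg$event_rate * cfg$duration)
  truth <- data.frame(t_true = numeric(0), velocity_true = numeric(0),
                      dt_true = numeric(0), width_true = numeric(0),
                      N_true = integer(0), amplitude_true = numeric(0),
                      photon_sum_true = numeric(0))
  if (n_ev > 0) {
    v <- draw_velocities(n_ev, cfg)                   # um/ms
    dt_true <- cfg$spot_pitch / v / 1000              # s
    width <- cfg$spot_sigma / v / 1000                # s
    amp <- stats::rlnorm(n_ev, meanlog = log(cfg$amplitude_median),
                         sdlog = cfg$amplitude_sdlog)
    footprint <- (cfg$n_spots - 1) * dt_true / 2 + 5 * width
    t_ev <- stats::runif(n_ev, footprint, cfg$duration - footprint)
    ord <- order(t_ev)
    v <- v[ord]; dt_true <- dt_true[ord]; width <- width[ord]
    amp <- amp[ord]; t_ev <- t_ev[ord]; footprint <- footprint[ord]
    photon_sum <- numeric(n_ev)
    offsets <- function(N) ((0:(N - 1)) - (N - 1) / 2)
    for (i in seq_len(n_ev)) {
      i0 <- max(1L, as.integer(floor((t_ev[i] - footprint[i]) / cfg$dt)))
      i1 <- min(n_bins, as.integer(ceiling((t_ev[i] + footprint[i]) / cfg$dt)))
      tt <- (i0:i1 - 1) * cfg$dt
      sig <- 0
      for (o in offsets(cfg$n_spots))
        sig <- sig + exp(-(tt - (t_ev[i] + o * dt_true[i]))^2 /
                           (2 * width[i]^2))
      sig <- amp[i] * sig
      lambda[i0:i1] <- lambda[i0:i1] + sig
      photon_sum[i] <- sum(sig)
    }
    truth <- data.frame(t_true = t_ev, velocity_true = v, dt_true = dt_true,
                        width_true = width, N_true = cfg$n_spots,
                        amplitude_true = amp, photon_sum_true = photon_sum)
  }
  if (max(lambda) > 1e9) stop("expected per-bin signal overflows count range")
  counts <- stats::rpois(n_bins, lambda)
  list(trace = pcwa_trace(counts, dt = cfg$dt), truth = truth)
}

#' Simulate a static peak spectrum with ground truth
#'
#' Generic 1D spectrum (mass-spectrometry-like) for ROC studies: Gaussian
#' peaks of random widths and heights on a smooth drifting baseline plus
#' white Gaussian noise of unit sd, so peak height equals SNR.
#'
#' @param n_points Number of samples.
#' @param n_peaks Number of peaks.
#' @param peak_width_range Length-2 range of peak sigmas, in samples.
#' @param snr_range Length-2 range of peak heights in noise-sd units.
#' @param baseline_drift Amplitude of the smooth baseline component.
#' @param seed Integer seed.
#' @return List with `trace` (a `pcwa_trace` with `dt = 1`; arbitrary
#'   units) and `truth` (`t_true` = peak centers in sample units,
#'   `width_true`, `snr_true`).
#' @export
simulate_spectrum <- function(n_points = 2000, n_peaks = 8,
                              peak_width_range = c(3, 12),
                              snr_range = c(3, 30), baseline_drift = 2,
                              seed = NULL) {
  stopifnot(n_points >= 10, n_peaks >= 0)
  if (!is.null(seed)) set.seed(seed)
  x <- seq_len(n_points)
  base <- baseline_drift * (sin(2 * pi * x / n_points + stats::runif(1, 0, 2 * pi)) +
                              0.5 * sin(4 * pi * x / n_points + stats::runif(1, 0, 2 * pi)))
  signal <- base - min(base)
  truth <- data.frame(t_true = numeric(0), width_true = numeric(0),
                      snr_true = numeric(0))
  if (n_peaks > 0) {
    wmax <- max(peak_width_range)
    pos <- sort(stats::runif(n_peaks, 6 * wmax, n_points - 6 * wmax))
    wid <- stats::runif(n_peaks, peak_width_range[1], peak_width_range[2])
    snr <- exp(stats::runif(n_peaks, log(snr_range[1]), log(snr_range[2])))
    for (i in seq_len(n_peaks))
      signal <- signal + snr[i] * exp(-(x - pos[i])^2 / (2 * wid[i]^2))
    truth <- data.frame(t_true = pos, width_true = wid, snr_true = snr)
  }
  counts <- signal + stats::rnorm(n_points)
  list(trace = pcwa_trace(counts, dt = 1, warn_negative = FALSE),
       truth = truth)
}
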