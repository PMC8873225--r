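test_that("all wavelet families are zero-mean and unit-norm at random scales", {
  set.seed(101)
  fams <- list(ricker_wavelet(), morlet_wavelet(),
               msg_wavelet(1), msg_wavelet(6), msg_wavelet(7), msg_wavelet(8))
  for (w in fams) {
    scales <- exp(stats::runif(20, log(1e-4), log(1e-2)))
    for (s in scales) {
      sw <- suppressWarnings(wavelet_samples(w, s, s / 40))
      expect_lte(abs(sum(sw$values) * sw$dt), 1e-10 * max(abs(sw$values)))
      expect_lt(abs(sum(sw$values^2) * sw$dt - 1), 1e-6)
    }
  }
})

test_that("Ricker has the Mexican-hat shape with zeros at one scale", {
  sw <- sample_ricker(scale = 1, dt = 1e-3)
  expect_equal(which.max(sw$values), which(sw$t_grid == 0))
  # zeros of (1 - x^2) survive calibration up to the tiny demeaning shift
  at1 <- sw$values[abs(abs(sw$t_grid) - 1) < 1e-9]
  expect_true(all(abs(at1) < 1e-5 * max(sw$values)))
})

test_that("dilation covariance: doubling the scale stretches time and scales amplitude by 1/sqrt(2)", {
  for (w in list(ricker_wavelet(), msg_wavelet(7))) {
    a <- wavelet_samples(w, 1e-3, 1e-5)
    b <- wavelet_samples(w, 2e-3, 2e-5)   # same grid in x = t/scale
    expect_equal(length(a$values), length(b$values))
    expect_equal(b$values, a$values / sqrt(2), tolerance = 1e-10)
    expect_equal(b$t_grid, 2 * a$t_grid, tolerance = 1e-12)
  }
})

test_that("Morlet spectrum peaks at 1/scale, independent of sampling", {
  sw <- sample_morlet(scale = 1 / 4500, dt = 1e-5)
  sp <- wavelet_spectrum(sw)
  f_peak <- sp$freq[which.max(sp$magnitude)]
  expect_lt(abs(f_peak - 4500) / 4500, 0.02)
  sw2 <- sample_morlet(scale = 1 / 4500, dt = 5e-6)
  sp2 <- wavelet_spectrum(sw2)
  f_peak2 <- sp2$freq[which.max(sp2$magnitude)]
  expect_lt(abs(f_peak2 - f_peak) / f_peak, 0.02)
})

test_that("MSG wavelet has N positive peaks spaced by the scale and lobes one spacing outside", {
  sw <- sample_msg(msg_wavelet(7), scale = 2e-4, dt = 1e-5)
  v <- sw$values
  imax <- which(diff(sign(diff(v))) == -2) + 1L
  pos <- imax[v[imax] > 0.05 * max(v)]
  expect_length(pos, 7)
  spacing <- diff(sw$t_grid[pos])
  expect_true(all(abs(spacing - sw$scale) <= sw$dt))
  # the two most negative samples are the side-lobe modes, one spacing
  # beyond the outermost positive peaks: at +/- (N+1)/2 * scale
  lobes <- sort(sw$t_grid[order(v)[1:2]])
  expect_lt(abs(lobes[1] + 4 * sw$scale), sw$dt)
  expect_lt(abs(lobes[2] - 4 * sw$scale), sw$dt)
})

test_that("solved MSG side-lobe amplitude matches the analytic zero-mean value", {
  for (N in c(1, 6, 7, 8)) {
    w <- msg_wavelet(N)
    expect_equal(w$params$a, N * w$params$sigma_plus * sqrt(2 * pi) / 2,
                 tolerance = 1e-4)
  }
})

test_that("m0 is the mode of the standard skew-normal with shape alpha", {
  for (alpha in c(0, 1, 3, 8)) {
    w <- msg_wavelet(3, alpha = alpha)
    z <- seq(-1, 1.5, by = 1e-4)
    dens <- 2 * dnorm(z) * pnorm(alpha * z)
    expect_lt(abs(w$params$m0 - z[which.max(dens)]), 2e-4)
  }
})

test_that("degenerate MSG (N = 1, alpha -> 0) is a zero-mean single-peak band-pass", {
  w <- msg_wavelet(1, alpha = 1e-8)
  sw <- wavelet_samples(w, 1e-3, 1e-5)
  expect_lte(abs(sum(sw$values) * sw$dt), 1e-10 * max(abs(sw$values)))
  v <- sw$values
  imax <- which(diff(sign(diff(v))) == -2) + 1L
  pos <- imax[v[imax] > 0.05 * max(v)]
  expect_length(pos, 1)
  expect_equal(sw$t_grid[pos], 0)
})

test_that("MSG spectrum is comb-like with first and second harmonics; Morlet is single-band", {
  sw <- sample_msg(msg_wavelet(7), scale = 2e-4, dt = 1e-5)
  sp <- wavelet_spectrum(sw)
  band <- function(sp, f1, f2) mean(sp$magnitude[sp$freq >= f1 & sp$freq <= f2])
  f1 <- 1 / sw$scale
  expect_lt(sp$magnitude[1], 1e-12)                        # zero DC
  expect_gt(band(sp, 0.9 * f1, 1.1 * f1), 3 * band(sp, 1.3 * f1, 1.7 * f1))
  expect_gt(band(sp, 1.9 * f1, 2.1 * f1), 5 * band(sp, 2.3 * f1, 2.9 * f1))
  expect_gt(band(sp, 0.05 * f1, 0.3 * f1), band(sp, 1.3 * f1, 1.7 * f1))
  m <- wavelet_spectrum(sample_morlet(2e-4, 1e-5, center_cycles = 7))
  expect_lt(m$magnitude[1], 1e-12)
  expect_gt(band(m, 0.9 * f1, 1.1 * f1), 1e5 * band(m, 1.9 * f1, 2.1 * f1))
  expect_gt(band(m, 0.9 * f1, 1.1 * f1), 1e5 * band(m, 0.05 * f1, 0.3 * f1))
  r <- wavelet_spectrum(sample_ricker(1e-3, 1e-5))
  expect_lt(r$magnitude[1], 1e-12)                         # band-pass
})

test_that("invalid wavelet parameters are rejected and coarse sampling warns", {
  expect_error(ricker_wavelet(support_radius = -1))
  expect_error(msg_wavelet(0))
  expect_error(msg_wavelet(7, sigma_plus = -0.1))
  expect_error(wavelet_samples(ricker_wavelet(), scale = -1, dt = 1e-3))
  expect_error(wavelet_samples(ricker_wavelet(), scale = 1e-3, dt = 1e-2))
  expect_warning(wavelet_samples(msg_wavelet(7), scale = 8e-5, dt = 1e-5),
                 "under-resolved")
})

test_that("sigma_plus fit helper recovers the injected peak width", {
  tr <- make_train_trace(30000, 1e-5, tc = 0.15, dtv = 3e-4, N = 7,
                         amp = 50, sigma_rel = 0.18)
  ev <- data.frame(t = 0.15, scale = 3e-4)
  est <- fit_sigma_plus(tr, ev, N = 7)
  expect_lt(abs(est - 0.18) / 0.18, 0.15)
})
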