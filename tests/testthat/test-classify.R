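test_that("scale-velocity conversion is the pitch ratio and inverts exactly", {
  expect_equal(velocity_from_scale(1e-3, 5), 5)      # 5 um/ms
  expect_equal(velocity_from_scale(2e-3, 5), 2.5)    # doubling dt halves v
  expect_equal(scale_from_velocity(velocity_from_scale(3.3e-4, 2.2), 2.2),
               3.3e-4)
  expect_error(velocity_from_scale(0, 5))
  expect_error(velocity_from_scale(1e-3, -1))
})

test_that("noise-free trains are assigned their true peak number", {
  for (Ntrue in c(6, 7, 8)) {
    tr <- make_train_trace(30000, 1e-5, tc = 0.15, dtv = 2.5e-4, N = Ntrue,
                           amp = 10)
    cl <- classify_event(tr, list(t = 0.15, scale = 2.5e-4), c(6, 7, 8),
                         msg_wavelet(7))
    expect_equal(cl$N_best, Ntrue)
    expect_equal(unname(which.max(cl$coeffs_by_N)), Ntrue - 5L)
  }
})

test_that("classification is invariant to candidate order and breaks ties to the smallest N", {
  tr <- make_train_trace(30000, 1e-5, tc = 0.15, dtv = 2.5e-4, N = 7,
                         amp = 10)
  a <- classify_event(tr, list(t = 0.15, scale = 2.5e-4), c(8, 6, 7),
                      msg_wavelet(7))
  b <- classify_event(tr, list(t = 0.15, scale = 2.5e-4), c(6, 7, 8),
                      msg_wavelet(7))
  expect_equal(a$N_best, b$N_best)
  expect_equal(a$coeffs_by_N[order(names(a$coeffs_by_N))],
               b$coeffs_by_N[order(names(b$coeffs_by_N))])
})

test_that("a window clipped by the trace boundary raises an error", {
  tr <- make_train_trace(4000, 1e-5, tc = 0.002, dtv = 2.5e-4, N = 7,
                         amp = 10)
  expect_error(classify_event(tr, list(t = 0.002, scale = 2.5e-4),
                              c(6, 7, 8), msg_wavelet(7)),
               "boundary")
})

test_that("event intensity recovers the injected photon sum and is monotone in amplitude", {
  flat <- pcwa_trace(rep(2, 5000), dt = 1e-5)
  expect_lt(event_intensity(flat, list(t = 0.025, scale = 2e-4), N = 7), 1e-9)
  set.seed(51)
  sums <- vapply(c(2, 5, 10), function(amp) {
    tr <- make_train_trace(40000, 1e-5, tc = 0.2, dtv = 2.5e-4, N = 7,
                           amp = amp, bg = 0.5, poisson = TRUE, seed = amp)
    event_intensity(tr, list(t = 0.2, scale = 2.5e-4), N = 7)
  }, numeric(1))
  expect_true(all(diff(sums) > 0))
  # injected expected photon sum for amp = 10: amp * N * sqrt(2*pi) * sigma_bins
  expected <- 10 * 7 * sqrt(2 * pi) * 0.18 * 25
  expect_lt(abs(sums[3] - expected) / expected, 0.15)
})

test_that("joint histogram conserves events and gates injected outliers", {
  set.seed(52)
  n <- 200
  ev <- data.frame(t = runif(n), intensity = rnorm(n, 100, 10),
                   velocity_um_per_ms = rnorm(n, 10, 1))
  out_idx <- sample(n, 10)
  ev$intensity[out_idx] <- runif(10, 300, 600)
  ev$velocity_um_per_ms[out_idx] <- runif(10, 25, 40)
  jh <- joint_histogram(ev, n_bins = 25, gate_radius = 3)
  expect_equal(sum(jh$counts), n)
  expect_gte(sum(!jh$in_gate[out_idx]), 9)   # >= 90% of outliers rejected
  expect_gt(mean(jh$in_gate[-out_idx]), 0.9)
  one <- data.frame(intensity = rep(5, 4), velocity_um_per_ms = rep(2, 4))
  jh1 <- joint_histogram(one, n_bins = 10)
  expect_equal(sum(jh1$counts > 0), 1)
  expect_true(all(jh1$in_gate))
})

test_that("time-resolved statistics conserve counts and flag degenerate bins", {
  ev <- data.frame(t = c(0.5, 1.2, 1.3, 4.7), intensity = c(10, 20, 30, 40),
                   velocity_um_per_ms = c(5, 6, 7, 8))
  st <- time_resolved_stats(ev, bin_width = 1, duration = 5)
  expect_equal(sum(st$count), 4)
  expect_equal(st$count, c(1L, 2L, 0L, 0L, 1L))
  expect_true(is.na(st$sd_intensity[1]))        # single event: sd undefined
  expect_true(is.na(st$mean_intensity[3]))      # empty bin
  expect_equal(st$mean_intensity[2], 25)
  set.seed(53)
  evp <- data.frame(t = runif(400, 0, 20))
  stp <- time_resolved_stats(evp, bin_width = 1, duration = 20)
  expect_equal(sum(stp$count), 400)
  # uniform rate: per-bin counts consistent with Poisson(20)
  chi <- sum((stp$count - 20)^2 / 20)
  expect_lt(chi, qchisq(0.999, df = 19))
})

test_that("end-to-end multi-peak extraction recovers velocities within grid resolution", {
  sim <- simulate_trace(sim_config(duration = 8, event_rate = 2.5,
                                   amplitude_median = 6,
                                   amplitude_sdlog = 0.2, seed = 54))
  scales <- log_scales(1.2e-4, 1e-3, 32)
  fit <- pcwa(sim$trace, msg_wavelet(7), scales, threshold = 5,
              threshold_mode = "mad")
  tol <- pmax(7 * sim$truth$dt_true / 2, 4e-5)
  m <- match_events(fit$events, sim$truth, tol)
  expect_gt(m$TP / nrow(sim$truth), 0.9)
  cl <- classify_events(sim$trace, fit$events[m$pairs$detected_index, ],
                        c(6, 7, 8), msg_wavelet(7), spot_pitch = 2.2)
  ok <- !is.na(cl$velocity_um_per_ms)
  v_true <- sim$truth$velocity_true[m$pairs$truth_index][ok]
  step <- exp(log(max(scales) / min(scales)) / (length(scales) - 1)) - 1
  expect_true(all(abs(cl$velocity_um_per_ms[ok] / v_true - 1) < 2.5 * step))
})
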