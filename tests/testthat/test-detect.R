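test_that("per-row local maxima follow the strict/plateau rule", {
  m <- structure(list(coeffs = rbind(c(0, 1, 0, 0), c(0, 1, 1, 0)),
                      scales = c(1e-3, 2e-3), dt = 1e-3, t0 = 0, n = 4L,
                      margin = c(0L, 0L)), class = "cwt_map")
  mx <- find_local_maxima(m, threshold = 0.5, exclude_boundary = FALSE)
  expect_equal(nrow(mx), 2L)
  expect_equal(mx$t_index, c(2L, 2L))   # plateau: leftmost sample wins
  mx2 <- find_local_maxima(m, threshold = 1.5, exclude_boundary = FALSE)
  expect_equal(nrow(mx2), 0L)
})

test_that("a single Gaussian event produces a connected streak of per-scale maxima", {
  tr <- make_gauss_trace(centers = 0.5, widths = 8e-3, amps = 5, n = 1000,
                         dt = 1e-3)
  scales <- log_scales(4e-3, 6e-2, 15)
  m <- compute_cwt(tr, ricker_wavelet(), scales)
  mx <- find_local_maxima(m, threshold = 1e-4)
  # brute-force scan per row agrees
  for (i in seq_along(scales)) {
    v <- m$coeffs[i, ]
    ref <- which(v >= 1e-4 & v > c(-Inf, v[-1000]) & v > c(v[-1], -Inf))
    mg <- m$margin[i]
    ref <- ref[ref > mg & ref <= 1000 - mg]
    expect_equal(mx$t_index[mx$scale_index == i], ref)
  }
  # the streak spans many adjacent scales around the event center
  expect_gte(length(unique(mx$scale_index[abs(mx$t - 0.5) < 0.02])), 8)
})

test_that("macro clustering splits on time gaps exactly like the pairwise-chain oracle", {
  cl <- form_macro_clusters(
    data.frame(t = c(1.0, 1.001, 5.0), scale = 1, C = 1), gap = 0.1)
  expect_length(cl, 2)
  expect_equal(nrow(cl[[1]]), 2)
  expect_length(form_macro_clusters(data.frame(t = numeric(0), scale = numeric(0),
                                               C = numeric(0)), 0.1), 0)
  set.seed(21)
  for (rep in 1:20) {
    t <- sort(runif(sample(2:40, 1), 0, 1))
    gap <- runif(1, 0.01, 0.2)
    cl <- form_macro_clusters(data.frame(t = t, scale = 1, C = 1), gap)
    ids <- rep(seq_along(cl), vapply(cl, nrow, integer(1)))
    expect_equal(ids, oracle_macro_partition(t, gap))
  }
})

test_that("three synthetic events far apart give exactly three macro clusters", {
  tr <- make_gauss_trace(centers = c(0.2, 0.5, 0.8), widths = rep(5e-3, 3),
                         amps = rep(5, 3), n = 1000, dt = 1e-3)
  scales <- log_scales(4e-3, 2e-2, 10)
  mx <- find_local_maxima(compute_cwt(tr, ricker_wavelet(), scales), 1e-3)
  expect_length(form_macro_clusters(mx, gap = 2 * max(scales)), 3)
})

test_that("overlap rule: coincident points link, distant points do not", {
  cen <- list(t = 1, scale = 1e-3, C = 5)
  pts <- data.frame(t = c(1, 50), scale = c(1e-3, 1e-3), C = c(3, 3))
  linked <- overlap_link(pts, cen, w = 0.5, h = 3, N = 7, c_range = c(1, 5))
  expect_true(linked[1])
  expect_false(linked[2])
  # degenerate single-value context: C' defined as 1
  linked2 <- overlap_link(pts, cen, w = 0.5, h = 3, N = 7, c_range = c(5, 5))
  expect_true(linked2[1])
})

test_that("micro-cluster resolution equals the literal scalar transcription on random clusters", {
  set.seed(22)
  for (rep in 1:60) {
    n <- sample(1:30, 1)
    cl <- data.frame(t = runif(n, 0, 5e-3),
                     scale = exp(runif(n, log(1e-4), log(1e-3))),
                     C = runif(n, 0.1, 2))
    w <- runif(1, 0.2, 1.5); h <- runif(1, 0.5, 4)
    N <- sample(c(1, 7), 1); ms <- sample(1:4, 1)
    got <- resolve_micro_clusters(cl, w = w, h = h, N = N,
                                  min_cluster_size = ms)
    ref <- oracle_micro_clusters(cl, w = w, h = h, N = N,
                                 min_cluster_size = ms)
    expect_equal(got$t, ref$t)
    expect_equal(got$n_members, ref$n_members)
  }
})

test_that("a single maximum yields one event when min_cluster_size is 1", {
  cl <- data.frame(t = 0.5, scale = 1e-3, C = 2)
  ev <- resolve_micro_clusters(cl, w = 0.5, h = 3, N = 1,
                               min_cluster_size = 1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_members, 1L)
  ev2 <- resolve_micro_clusters(cl, w = 0.5, h = 3, N = 1,
                                min_cluster_size = 2)
  expect_equal(nrow(ev2), 0)
})

test_that("noise-free multi-event trace is recovered exactly, and zero traces give no events", {
  set.seed(23)
  centers <- seq(0.3, 4.8, by = 0.5)
  widths <- runif(10, 3e-3, 1.5e-2)
  tr <- make_gauss_trace(centers, widths, amps = runif(10, 3, 8),
                         n = 5000, dt = 1e-3)
  scales <- log_scales(4e-3, 6e-2, 30)
  fit <- pcwa(tr, ricker_wavelet(), scales, threshold = 1e-3)
  expect_equal(nrow(fit$events), 10)
  expect_true(all(abs(fit$events$t - centers) <= 1e-3))
  # scales track the response-maximizing sqrt(5) * width within a grid step
  step <- log(scales[2] / scales[1])
  expect_true(all(abs(log(fit$events$scale / (sqrt(5) * widths))) <= 1.5 * step))
  z <- pcwa(pcwa_trace(rep(0, 2000), 1e-3), ricker_wavelet(), scales,
            threshold = 1e-3)
  expect_equal(nrow(z$events), 0)
})

test_that("event list is invariant to macro-cluster processing order", {
  set.seed(24)
  tr <- make_train_trace(60000, 1e-5, tc = 0.3, dtv = 2.5e-4, N = 7,
                         amp = 3, bg = 0.5, poisson = TRUE, seed = 24)
  scales <- log_scales(1.2e-4, 8e-4, 20)
  fit <- pcwa(tr, msg_wavelet(7), scales, threshold = 4.5,
              threshold_mode = "mad", keep_maxima = TRUE)
  # process clusters serially in reversed / shuffled order
  mx <- fit$maxima
  clusters <- form_macro_clusters(mx, fit$config$gap)
  for (ord in list(rev(seq_along(clusters)),
                   sample(seq_along(clusters)))) {
    ev <- do.call(rbind, lapply(clusters[ord], resolve_micro_clusters,
                                w = fit$config$w, h = fit$config$h, N = 7,
                                min_cluster_size = fit$config$min_cluster_size))
    ev <- ev[order(ev$t), ]
    expect_equal(ev$t, fit$events$t)
    expect_equal(ev$C, fit$events$C)
  }
})

test_that("the coefficient weighting keeps a weak event next to strong ones", {
  # three nearby events, the middle one much weaker
  tr <- make_gauss_trace(centers = c(0.44, 0.5, 0.56),
                         widths = c(5e-3, 5e-3, 5e-3),
                         amps = c(8, 1.2, 8), n = 1000, dt = 1e-3)
  scales <- log_scales(4e-3, 3e-2, 25)
  fit <- pcwa(tr, ricker_wavelet(), scales, threshold = 1e-3)
  expect_equal(nrow(fit$events), 3)
  expect_true(any(abs(fit$events$t - 0.5) < 5e-3))
})

test_that("raising the threshold never increases the number of events", {
  set.seed(25)
  sim <- simulate_trace(sim_config(duration = 2, event_rate = 8, n_spots = 1,
                                   amplitude_median = 4, bg_rate = 1,
                                   seed = 25))
  scales <- log_scales(4e-5, 6e-4, 20)
  counts <- vapply(c(3, 4, 5, 6, 8), function(th)
    nrow(pcwa(sim$trace, ricker_wavelet(), scales, threshold = th,
              threshold_mode = "mad")$events), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("t_adjusted lands on the raw-trace peak near the centroid", {
  tr <- make_gauss_trace(centers = 0.25, widths = 6e-3, amps = 6, n = 500,
                         dt = 1e-3)
  fit <- pcwa(tr, ricker_wavelet(), log_scales(4e-3, 3e-2, 15),
              threshold = 1e-3)
  expect_equal(nrow(fit$events), 1)
  expect_lt(abs(fit$events$t_adjusted - 0.25), 1.5e-3)
})
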