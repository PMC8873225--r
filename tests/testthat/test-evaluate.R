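test_that("exact detections match one-to-one; empty detections are all misses", {
  tt <- c(1, 2, 3.5)
  m <- match_events(tt, tt, tolerance = 0.1)
  expect_equal(m$TP, 3); expect_equal(m$FP, 0); expect_equal(m$FN, 0)
  m2 <- match_events(numeric(0), tt, tolerance = 0.1)
  expect_equal(m2$TP, 0); expect_equal(m2$FN, 3)
  m3 <- match_events(tt, numeric(0), tolerance = 0.1)
  expect_equal(m3$FP, 3)
})

test_that("greedy nearest-first matching equals exhaustive optimal matching on jittered detections", {
  set.seed(61)
  for (rep in 1:40) {
    nt <- sample(2:7, 1)
    tt <- sort(runif(nt, 0, 10 * nt))   # truth sparse relative to tolerance
    tol <- runif(1, 0.2, 1)
    td <- tt + rnorm(nt, 0, tol / 3)    # jittered detections
    td <- td[runif(nt) > 0.2]           # some missed
    td <- c(td, runif(sample(0:2, 1), 0, 10 * nt))  # some spurious
    got <- match_events(td, tt, tol)
    ref <- oracle_match_optimal(td, tt, tol)
    expect_equal(got$TP, ref$TP)
  }
})

test_that("matching is invariant under shifting both lists", {
  set.seed(62)
  tt <- sort(runif(15, 0, 30)); td <- tt + rnorm(15, 0, 0.05)
  m1 <- match_events(td, tt, 0.2)
  m2 <- match_events(td + 123.4, tt + 123.4, 0.2)
  expect_equal(m1$TP, m2$TP)
  expect_equal(m1$pairs$time_error, m2$pairs$time_error, tolerance = 1e-9)
})

test_that("ROC of a perfect detector has area 1 and extreme thresholds behave", {
  set.seed(63)
  dataset <- lapply(1:3, function(i) {
    truth <- data.frame(t_true = sort(runif(5, 1, 9)))
    list(trace = pcwa_trace(rep(0, 1000 + i), 1e-2), truth = truth)
  })
  perfect <- function(trace, thr) {
    d <- dataset[[length(trace$counts) - 1000L]]
    data.frame(t = d$truth$t_true)
  }
  r <- roc_curve(perfect, dataset, thresholds = c(0.1, 1), tolerance = 0.1,
                 footprint = 0.5)
  expect_equal(r$auc, 1)
  expect_true(all(r$curve$TPR == 1 & r$curve$FPR == 0))
  none <- function(trace, thr) data.frame(t = numeric(0))
  r0 <- roc_curve(none, dataset, thresholds = 1, tolerance = 0.1,
                  footprint = 0.5)
  expect_equal(r0$curve$TPR, 0)
  expect_equal(r0$curve$FPR, 0)
  expect_error(roc_curve(none, list(list(trace = pcwa_trace(rep(0, 10), 1),
                                         truth = data.frame(t_true = numeric(0)))),
                         1, 0.1, 0.5), "no ground-truth")
})

test_that("TPR and FPR are non-increasing in the detection threshold", {
  set.seed(64)
  dataset <- lapply(1:4, function(i)
    simulate_spectrum(n_points = 1500, n_peaks = 6, snr_range = c(2, 12),
                      seed = 640 + i))
  detect_fun <- function(trace, thr)
    pcwa(trace, ricker_wavelet(), log_scales(4, 30, 15), threshold = thr,
         threshold_mode = "mad")$events
  r <- roc_curve(detect_fun, dataset, thresholds = c(2.5, 3.5, 5, 7, 10),
                 tolerance = function(truth) 3 * truth$width_true,
                 footprint = 40)
  expect_true(all(diff(r$curve$TPR) <= 1e-12))
  expect_true(all(diff(r$curve$FPR) <= 1e-12))
  expect_gte(r$auc, 0)
  expect_lte(r$auc, 1)
})

test_that("comparison table reports all methods with accuracy in range on an easy benchmark", {
  sim <- simulate_trace(sim_config(duration = 6, event_rate = 2,
                                   amplitude_median = 8,
                                   amplitude_sdlog = 0.15, seed = 65))
  scales <- log_scales(1.2e-4, 1e-3, 24)
  tab <- comparison_table(sim$trace, sim$truth, c(6, 7, 8), scales,
                          n_thresholds = 8)
  expect_setequal(tab$method, c("shift_multiply", "pcwa_morlet", "pcwa_msg"))
  expect_true(all(tab$accuracy_pct >= 0 & tab$accuracy_pct <= 100,
                  na.rm = TRUE))
  expect_equal(tab$error_rate_pct, 100 - tab$accuracy_pct)
  # bright events: the matched wavelet detects essentially all of them
  msg <- tab[tab$method == "pcwa_msg", ]
  expect_gt(msg$detected_true / nrow(sim$truth), 0.85)
  expect_gt(msg$accuracy_pct,
            tab$accuracy_pct[tab$method == "pcwa_morlet"])
})

test_that("scaling benchmark fits a positive slope near 1 for a linear-cost detector", {
  lens <- c(3e3, 1e4, 3e4, 1e5)
  sim_fun <- function(n) pcwa_trace(rpois(n, 1), dt = 1e-5)
  res <- scaling_benchmark(function(tr)
    pcwa(tr, ricker_wavelet(), log_scales(5e-5, 5e-4, 8), threshold = 6,
         threshold_mode = "mad"),
    lengths = lens, reps = 2, sim_fun = sim_fun)
  expect_s3_class(res, "scaling_result")
  expect_true(all(res$table$median_s >= 0))
  expect_true(is.finite(res$slope))
})
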