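#' Match detected events to ground truth
#'
#' Greedy nearest-first one-to-one matching in time: candidate
#' (detected, truth) pairs within the tolerance are processed in order of
#' increasing time distance; each side is matched at most once. Unmatched
#' detections are false positives, unmatched truth events false negatives.
#'
#' @param detected Numeric vector of detected event times, or a data.frame
#'   with column `t`.
#' @param truth Numeric vector of true event times, or a data.frame with
#'   column `t_true`.
#' @param tolerance Matching tolerance in seconds: a scalar, or a vector
#'   with one entry per truth event (e.g. half the event footprint).
#' @return List of class `match_result`: `TP`, `FP`, `FN`, `pairs`
#'   (data.frame `detected_index`, `truth_index`, `time_error`),
#'   `tolerance`.
#' @export
match_events <- function(detected, truth, tolerance) {
  td <- if (is.data.frame(detected)) detected$t else detected
  tt <- if (is.data.frame(truth)) truth$t_true else truth
  stopifnot(all(tolerance > 0))
  tol <- rep_len(tolerance, length(tt))
  nd <- length(td); nt <- length(tt)
  pairs <- data.frame(detected_index = integer(0), truth_index = integer(0),
                      time_error = numeric(0))
  if (nd > 0 && nt > 0) {
    # candidate pairs within tolerance (truth events are sparse relative to
    # their tolerance windows, so each detection has few candidates)
    ord <- order(tt)
    tts <- tt[ord]
    tmax <- max(tol)
    cand_d <- integer(0); cand_t <- integer(0); cand_e <- numeric(0)
    for (i in seq_len(nd)) {
      j0 <- findInterval(td[i] - tmax, tts) + 1L
      j1 <- findInterval(td[i] + tmax, tts)
      if (j1 < j0) next
      for (jj in j0:j1) {
        err <- td[i] - tts[jj]
        if (abs(err) <= tol[ord[jj]]) {
          cand_d <- c(cand_d, i); cand_t <- c(cand_t, ord[jj])
          cand_e <- c(cand_e, err)
        }
      }
    }
    if (length(cand_d) > 0) {
      o <- order(abs(cand_e), cand_d, cand_t)
      used_d <- rep(FALSE, nd); used_t <- rep(FALSE, nt)
      keep <- integer(0)
      for (k in o) {
        if (used_d[cand_d[k]] || used_t[cand_t[k]]) next
        used_d[cand_d[k]] <- TRUE; used_t[cand_t[k]] <- TRUE
        keep <- c(keep, k)
      }
      pairs <- data.frame(detected_index = cand_d[keep],
                          truth_index = cand_t[keep],
                          time_error = cand_e[keep])
    }
  }
  structure(list(TP = nrow(pairs), FP = nd - nrow(pairs),
                 FN = nt - nrow(pairs), pairs = pairs,
                 tolerance = tolerance), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d, FP %d, FN %d\n", x$TP, x$FP, x$FN))
  invisible(x)
}

#' ROC curve of a detector over a threshold sweep
#'
#' For each threshold, detections on every trace of the dataset are matched
#' to ground truth and aggregated: TPR = TP / (TP + FN); the false-positive
#' rate is normalized per decision window (trace duration divided by the
#' median event footprint), since a 1D detector has no fixed number of
#' negative instances.
#'
#' @param detect_fun Function `(trace, threshold) -> events data.frame`.
#' @param dataset List of `list(trace, truth)` entries.
#' @param thresholds Numeric threshold sweep.
#' @param tolerance Matching tolerance in seconds (scalar or function of a
#'   truth data.frame returning per-event tolerances).
#' @param footprint Median event footprint in seconds (the decision
#'   resolution for the FPR denominator).
#' @return List of class `roc_result`: `curve` (data.frame `threshold`,
#'   `TP`, `FP`, `FN`, `TPR`, `FPR`), `auc`.
#' @export
roc_curve <- function(detect_fun, dataset, thresholds, tolerance,
                      footprint) {
  stopifnot(length(dataset) >= 1, footprint > 0)
  n_truth <- sum(vapply(dataset, function(d) nrow(d$truth), numeric(1)))
  if (n_truth == 0) stop("dataset has no ground-truth events")
  n_windows <- sum(vapply(dataset, function(d)
    length(d$trace$counts) * d$trace$dt, numeric(1))) / footprint
  rows <- lapply(thresholds, function(thr) {
    tp <- fp <- fn <- 0
    for (d in dataset) {
      ev <- detect_fun(d$trace, thr)
      tol <- if (is.function(tolerance)) tolerance(d$truth) else tolerance
      m <- match_events(ev, d$truth, tol)
      tp <- tp + m$TP; fp <- fp + m$FP; fn <- fn + m$FN
    }
    data.frame(threshold = thr, TP = tp, FP = fp, FN = fn,
               TPR = tp / (tp + fn), FPR = min(fp / n_windows, 1))
  })
  curve <- do.call(rbind, rows)
  structure(list(curve = curve, auc = roc_auc(curve)), class = "roc_result")
}

# Trapezoidal area under the (FPR, TPR) points, anchored at (0, 0) and
# extended horizontally to FPR = 1 at the largest observed TPR.
roc_auc <- function(curve) {
  pts <- curve[order(curve$FPR, curve$TPR), c("FPR", "TPR")]
  pts <- rbind(data.frame(FPR = 0, TPR = 0), pts,
               data.frame(FPR = 1, TPR = max(curve$TPR)))
  sum(diff(pts$FPR) * (utils::head(pts$TPR, -1) + utils::tail(pts$TPR, -1)) / 2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d thresholds, AUC %.4f\n", nrow(x$curve),
              x$auc))
  invisible(x)
}

#' Method comparison on a multi-peak benchmark (threshold-scan protocol)
#'
#' Runs shift-multiply, PCWA with a Morlet wavelet, and PCWA with the MSG
#' wavelet on one ground-truthed multi-peak trace. Each method detects
#' events and assigns each event a peak number from `candidate_Ns`
#' (competing wavelets for PCWA, competing shift counts for
#' shift-multiply). A series of thresholds is scanned and, per method, the
#' threshold maximizing the accuracy x detected-true-events compromise is
#' reported. Accuracy is the percentage of detected true events assigned
#' the correct peak number.
#'
#' @param trace A [pcwa_trace()].
#' @param truth Ground-truth data.frame from [simulate_trace()].
#' @param candidate_Ns Candidate peak counts (default 6, 7, 8).
#' @param scales Scale grid covering the expected peak spacings.
#' @param msg_base MSG wavelet carrying the shape parameters (default
#'   `msg_wavelet(median candidate)`).
#' @param morlet_cycles Envelope cycles of the detection Morlet.
#' @param base_threshold Detection floor, in row-MAD units, below which
#'   maxima are not collected (the scan starts here).
#' @param n_thresholds Number of scanned thresholds per method.
#' @param sm_smooth Moving-average half-width (bins) applied to the trace
#'   for the shift-multiply arm (0 = raw counts, the method's standard
#'   form on binned photon data).
#' @param w,h,min_cluster_size PCWA clustering parameters.
#' @param methods Subset of `c("shift_multiply", "pcwa_morlet",
#'   "pcwa_msg")`.
#' @return data.frame of class `comparison_table`, one row per method:
#'   `method`, `threshold`, `detected_true`, `false_positives`,
#'   `accuracy_pct`, `error_rate_pct`, `detection_rate_per_s`. The full
#'   scans are attached as `attr(, "scan")`.
#' @export
comparison_table <- function(trace, truth, candidate_Ns = c(6, 7, 8),
                             scales, msg_base = NULL, morlet_cycles = NULL,
                             base_threshold = 4.5, n_thresholds = 15,
                             sm_smooth = 0,
                             w = 0.5, h = 3, min_cluster_size = 3,
                             methods = c("shift_multiply", "pcwa_morlet",
                                         "pcwa_msg")) {
  stopifnot(inherits(trace, "pcwa_trace"), nrow(truth) > 0)
  methods <- match.arg(methods, several.ok = TRUE)
  N_ref <- sort(candidate_Ns)[ceiling(length(candidate_Ns) / 2)]
  if (is.null(msg_base)) msg_base <- msg_wavelet(N_ref)
  if (is.null(morlet_cycles)) morlet_cycles <- N_ref
  tol <- pmax(truth$N_true * truth$dt_true / 2, 4 * trace$dt)
  duration <- length(trace$counts) * trace$dt
  scan_all <- list()
  rows <- list()

  scan_row <- function(th, ev_t, ev_N) {
    m <- match_events(ev_t, truth$t_true, tol)
    acc <- if (m$TP > 0) {
      nb <- ev_N[m$pairs$detected_index]
      100 * sum(nb == truth$N_true[m$pairs$truth_index], na.rm = TRUE) / m$TP
    } else NA_real_
    fdr <- if (m$TP + m$FP > 0) m$FP / (m$TP + m$FP) else 0
    data.frame(threshold = th, detected_true = m$TP,
               false_positives = m$FP, accuracy_pct = acc, fdr = fdr,
               objective = ifelse(is.na(acc), 0, acc / 100 * m$TP))
  }
  scan_events <- function(ev, value) {
    # log-spaced threshold scan over the emitted events' own detection
    # statistic, from the noise floor to the strongest event
    lo <- max(stats::quantile(value, 0.05, names = FALSE),
              min(value[value > 0]))
    thr <- exp(seq(log(lo), log(max(value)), length.out = n_thresholds))
    do.call(rbind, lapply(thr, function(th) {
      sel <- which(value >= th)
      scan_row(th, ev$t[sel], ev$N_best[sel])
    }))
  }
  # The compromise: among operating points whose false-discovery rate is
  # at most 1/3 (a point where most detections are noise is unusable --
  # on real data it would inflate the measured concentration severalfold
  # and dilute the species identification), maximize the
  # accuracy x detected-events product. If no point qualifies, take the
  # least-contaminated one.
  pick <- function(scan, method) {
    ok <- which(scan$fdr <= 1 / 3 & scan$detected_true > 0)
    k <- if (length(ok) > 0) ok[which.max(scan$objective[ok])]
    else order(scan$fdr, -scan$objective)[1]
    data.frame(method = method, threshold = scan$threshold[k],
               detected_true = scan$detected_true[k],
               false_positives = scan$false_positives[k],
               accuracy_pct = scan$accuracy_pct[k],
               error_rate_pct = 100 - scan$accuracy_pct[k],
               detection_rate_per_s = scan$detected_true[k] / duration)
  }

  if ("shift_multiply" %in% methods) {
    # The scanned threshold for this arm is the candidate-selection
    # amplitude (counts/bin): events are first selected as threshold
    # crossings and the product scan then classifies each selected event
    # and scores it. The scan covers integer thresholds from the lowest
    # workable selection level upward.
    maps <- lapply(sort(as.integer(candidate_Ns)), function(N)
      shift_multiply_map(trace, N, range(scales), length(scales),
                         sm_smooth))
    theta_max <- max(trace$counts)
    theta_min <- stats::qpois(1 - 2000 / length(trace$counts),
                              mean(trace$counts)) + 1L
    thetas <- seq(max(2L, theta_min), max(theta_max - 1L, theta_min + 1L))
    scan <- do.call(rbind, lapply(thetas, function(th) {
      ev <- selected_shift_multiply_events(trace, maps, candidate_Ns,
                                           range(scales), th)
      scan_row(th, ev$t, ev$N_best)
    }))
    scan_all$shift_multiply <- scan
    rows$shift_multiply <- pick(scan, "shift_multiply")
  }
  for (meth in intersect(methods, c("pcwa_morlet", "pcwa_msg"))) {
    wl <- if (meth == "pcwa_msg") {
      p <- msg_base$params
      msg_wavelet(N_ref, sigma_plus = p$sigma_plus, alpha = p$alpha,
                  lobe_gap = p$lobe_gap)
    } else morlet_wavelet(cycles = morlet_cycles)
    base_cls <- if (meth == "pcwa_msg") wl else morlet_wavelet(cycles = morlet_cycles)
    fit <- pcwa(trace, wl, scales, threshold = base_threshold,
                threshold_mode = "mad", w = w, h = h,
                min_cluster_size = min_cluster_size)
    ev <- classify_events(trace, fit$events, candidate_Ns, base_cls)
    scan <- if (nrow(ev) > 0) scan_events(ev, ev$C) else
      data.frame(threshold = base_threshold, detected_true = 0L,
                 false_positives = 0L, accuracy_pct = NA_real_,
                 objective = 0)
    scan_all[[meth]] <- scan
    rows[[meth]] <- pick(scan, meth)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "scan") <- scan_all
  class(res) <- c("comparison_table", class(res))
  res
}

# Selection-based shift-multiply: candidate events are contiguous runs of
# counts at or above the selection threshold theta (runs closer than one
# train footprint are merged); within each candidate window the
# precomputed per-N product maps are scanned for the best (N, spacing)
# product, which classifies and scores the event. This is the procedure's
# published form: the product is applied to selected multi-peak events,
# not slid blindly over the whole trace.
selected_shift_multiply_events <- function(trace, maps, candidate_Ns,
                                           dt_range, theta) {
  candidate_Ns <- sort(as.integer(candidate_Ns))
  n <- length(trace$counts)
  above <- trace$counts >= theta
  if (!any(above))
    return(data.frame(t = numeric(0), scale = numeric(0),
                      N_best = integer(0), product = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  a <- starts[r$values]; b <- ends[r$values]
  span <- as.integer(ceiling((max(candidate_Ns) - 1) * dt_range[2] /
                               trace$dt))
  # merge runs within one footprint
  keep_a <- a[1]; keep_b <- b[1]
  if (length(a) > 1) for (i in 2:length(a)) {
    last <- length(keep_b)
    if (a[i] - keep_b[last] <= span) keep_b[last] <- b[i]
    else { keep_a <- c(keep_a, a[i]); keep_b <- c(keep_b, b[i]) }
  }
  out <- vector("list", length(keep_a))
  for (i in seq_along(keep_a)) {
    lo <- max(1L, keep_a[i] - span); hi <- min(n, keep_b[i])
    best <- -Inf; bestN <- NA_integer_; bestk <- NA_integer_; besti <- lo
    for (j in seq_along(candidate_Ns)) {
      seg <- maps[[j]]$best[lo:hi]
      k <- which.max(seg)
      if (seg[k] > best) {
        best <- seg[k]; bestN <- candidate_Ns[j]
        besti <- lo + k - 1L
        bestk <- maps[[j]]$shifts[maps[[j]]$arg[besti]]
      }
    }
    out[[i]] <- data.frame(
      t = bin_to_time(trace, besti) + (bestN - 1) * bestk * trace$dt / 2,
      scale = bestk * trace$dt, N_best = bestN, product = best)
  }
  res <- do.call(rbind, out)
  res[order(res$t), , drop = FALSE]
}

# Shift-multiply detection with multi-N classification: per candidate N the
# product map over the spacing scan is computed; events are local maxima of
# the best product over all N, classified by the argmax N at the event.
# Nearby product maxima within half a train footprint of a stronger one are
# suppressed (one event per matched train).
shift_multiply_events <- function(trace, candidate_Ns, dt_range,
                                  dt_steps = 25, smooth = 0) {
  candidate_Ns <- sort(as.integer(candidate_Ns))
  maps <- lapply(candidate_Ns, function(N)
    shift_multiply_map(trace, N, dt_range, dt_steps, smooth))
  n <- length(trace$counts)
  best <- maps[[1]]$best; bestN <- rep(1L, n)
  if (length(maps) > 1) for (j in 2:length(maps)) {
    upd <- which(maps[[j]]$best > best)
    best[upd] <- maps[[j]]$best[upd]; bestN[upd] <- j
  }
  idx <- row_local_maxima(best, .Machine$double.xmin)
  if (length(idx) == 0)
    return(data.frame(t = numeric(0), scale = numeric(0),
                      N_best = integer(0), product = numeric(0)))
  Nj <- bestN[idx]
  N <- candidate_Ns[Nj]
  k <- vapply(seq_along(idx), function(ii)
    maps[[Nj[ii]]]$shifts[maps[[Nj[ii]]]$arg[idx[ii]]], numeric(1))
  ev <- data.frame(t = bin_to_time(trace, idx) + (N - 1) * k * trace$dt / 2,
                   scale = k * trace$dt, N_best = N, product = best[idx])
  # non-maximum suppression within half a footprint: strongest first, a
  # weaker maximum is dropped if a kept one lies within either's radius
  # (sorted kept-time vector + window lookup keeps this near-linear)
  ord <- order(-ev$product)
  r_all <- (ev$N_best - 1) * ev$scale / 2
  maxr <- max(r_all)
  keep <- logical(nrow(ev))
  kt <- numeric(0)
  kr <- numeric(0)
  for (i in ord) {
    lo <- findInterval(ev$t[i] - 2 * maxr, kt) + 1L
    hi <- findInterval(ev$t[i] + 2 * maxr, kt)
    ok <- TRUE
    if (hi >= lo) {
      sl <- lo:hi
      ok <- all(abs(ev$t[i] - kt[sl]) > pmax(r_all[i], kr[sl]))
    }
    if (ok) {
      keep[i] <- TRUE
      at <- findInterval(ev$t[i], kt)
      kt <- append(kt, ev$t[i], after = at)
      kr <- append(kr, r_all[i], after = at)
    }
  }
  ev <- ev[keep, , drop = FALSE]
  ev[order(ev$t), , drop = FALSE]
}

#' Empirical runtime scaling of a detector
#'
#' Measures median wall-clock runtime of a detector over a range of trace
#' lengths and fits the log-log slope (1.0 = linear scaling in the trace
#' length).
#'
#' @param detector_fun Function `(trace) -> anything`, the timed unit.
#' @param lengths Integer vector of trace lengths (should span at least two
#'   decades).
#' @param reps Repetitions per length (median taken); a scalar or one
#'   value per length (long runs need fewer repetitions).
#' @param sim_fun Function `(n) -> pcwa_trace` generating the input of
#'   length `n`.
#' @return List of class `scaling_result`: `table` (data.frame `n`,
#'   `median_s`), `slope`.
#' @export
scaling_benchmark <- function(detector_fun, lengths, reps = 2, sim_fun) {
  stopifnot(length(lengths) >= 2)
  reps <- rep_len(reps, length(lengths))
  med <- vapply(seq_along(lengths), function(k) {
    tr <- sim_fun(lengths[k])
    times <- vapply(seq_len(reps[k]), function(r) {
      t0 <- proc.time()[["elapsed"]]
      detector_fun(tr)
      proc.time()[["elapsed"]] - t0
    }, numeric(1))
    stats::median(times)
  }, numeric(1))
  slope <- unname(stats::coef(stats::lm(log(med) ~ log(lengths)))[2])
  structure(list(table = data.frame(n = lengths, median_s = med),
                 slope = slope), class = "scaling_result")
}

#' @export
print.scaling_result <- function(x, ...) {
  cat(sprintf("<scaling_result> log-log slope %.3f over n = [%g, %g]\n",
              x$slope, min(x$table$n), max(x$table$n)))
  invisible(x)
}
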