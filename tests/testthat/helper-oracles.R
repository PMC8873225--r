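# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive transcriptions (scalar loops, direct sums) kept
# separate from the package's vectorized implementations.

# Direct-sum CWT: C[i] = sum_j f[j] * psi((t_i - t_j)/s) * dt with the
# package's sampled (calibrated) wavelet, computed sample by sample.
oracle_cwt_direct <- function(counts, dt, wavelet, scale) {
  sw <- wavelet_samples(wavelet, scale, dt)
  K <- (length(sw$values) - 1L) %/% 2L
  n <- length(counts)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (off in -K:K) {
      j <- i - off
      if (j >= 1 && j <= n) acc <- acc + counts[j] * sw$values[off + K + 1L]
    }
    out[i] <- acc * dt
  }
  out
}

# Literal scalar transcription of the ellipse-overlap rule for one
# candidate i against the centroid, on given normalization context.
oracle_link_scalar <- function(ti, si, Ci, t0, s0, w, h, N, cmin, cmax) {
  d2 <- (ti - t0)^2 + (si - s0)^2
  cp <- if (cmax > cmin) (Ci - cmin) / (cmax - cmin) else 1
  cp <- min(max(cp, 0), 1)
  theta <- atan2(si - s0, ti - t0)
  den <- sqrt(w^2 * N^2 * sin(theta)^2 + h^2 * cos(theta)^2)
  ri <- w * h * N * si * sqrt(cp) / den
  r0 <- w * h * N * s0 / den
  (ri + r0)^2 >= d2
}

# Literal transcription of the star-graph micro-cluster recursion:
# largest-coefficient centroid (ties -> smallest t), scalar link tests,
# emit when linked set is large enough, recurse on the remainder with a
# fresh normalization context.
oracle_micro_clusters <- function(cluster, w, h, N, min_cluster_size) {
  events <- list()
  cl <- cluster
  while (nrow(cl) > 0) {
    best <- 1L
    for (i in seq_len(nrow(cl))) {
      if (cl$C[i] > cl$C[best] ||
          (cl$C[i] == cl$C[best] && cl$t[i] < cl$t[best])) best <- i
    }
    cmin <- min(cl$C); cmax <- max(cl$C)
    linked <- logical(nrow(cl))
    for (i in seq_len(nrow(cl))) {
      if (i == best) next
      linked[i] <- oracle_link_scalar(cl$t[i], cl$scale[i], cl$C[i],
                                      cl$t[best], cl$scale[best],
                                      w, h, N, cmin, cmax)
    }
    size <- sum(linked) + 1L
    if (size >= min_cluster_size)
      events[[length(events) + 1L]] <- data.frame(
        t = cl$t[best], scale = cl$scale[best], C = cl$C[best],
        n_members = size)
    cl <- cl[!linked & seq_len(nrow(cl)) != best, , drop = FALSE]
  }
  res <- do.call(rbind, events)
  if (is.null(res))
    res <- data.frame(t = numeric(0), scale = numeric(0), C = numeric(0),
                      n_members = integer(0))
  res[order(res$t), , drop = FALSE]
}

# Brute-force macro-cluster partition: two maxima share a cluster iff they
# are connected by a chain of pairwise gaps <= gap.
oracle_macro_partition <- function(t, gap) {
  n <- length(t)
  id <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(t[i] - t[j]) <= gap && id[i] != id[j]) {
        id[id == id[j]] <- id[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(id, unique(id[order(t)]))
}

# Exhaustive optimal one-to-one matching (max matches, then min total
# |error|) for small instances, by enumerating truth permutations.
oracle_match_optimal <- function(td, tt, tol) {
  tol <- rep_len(tol, length(tt))
  nd <- length(td); nt <- length(tt)
  if (nd == 0 || nt == 0) return(list(TP = 0))
  best_tp <- 0; best_err <- Inf
  assign_rec <- function(i, used, tp, err) {
    if (i > nd) {
      if (tp > best_tp || (tp == best_tp && err < best_err)) {
        best_tp <<- tp; best_err <<- err
      }
      return(invisible())
    }
    assign_rec(i + 1L, used, tp, err)   # leave detection i unmatched
    for (j in seq_len(nt)) {
      if (!used[j] && abs(td[i] - tt[j]) <= tol[j]) {
        used[j] <- TRUE
        assign_rec(i + 1L, used, tp + 1L, err + abs(td[i] - tt[j]))
        used[j] <- FALSE
      }
    }
  }
  assign_rec(1L, logical(nt), 0L, 0)
  list(TP = best_tp, total_err = best_err)
}

# Noise-free trace with injected Gaussian peaks (single-peak events).
make_gauss_trace <- function(centers, widths, amps, n, dt, bg = 0) {
  tt <- (seq_len(n) - 1) * dt
  lam <- rep(bg, n)
  for (i in seq_along(centers))
    lam <- lam + amps[i] * exp(-(tt - centers[i])^2 / (2 * widths[i]^2))
  pcwa_trace(lam, dt)
}

# Noise-free N-peak train centered at tc with spacing dtv.
make_train_trace <- function(n, dt, tc, dtv, N = 7, amp = 10,
                             sigma_rel = 0.18, bg = 0, poisson = FALSE,
                             seed = NULL) {
  tt <- (seq_len(n) - 1) * dt
  lam <- rep(bg, n)
  for (o in (0:(N - 1)) - (N - 1) / 2)
    lam <- lam + amp * exp(-(tt - (tc + o * dtv))^2 /
                             (2 * (sigma_rel * dtv)^2))
  if (poisson) {
    if (!is.null(seed)) set.seed(seed)
    lam <- stats::rpois(n, lam)
  }
  pcwa_trace(lam, dt)
}
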