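#' Uniformly sampled sensor trace
#'
#' Container for a binned photon-count time trace (or any uniformly sampled
#' 1D signal): a numeric vector of per-bin values, the bin width `dt` and
#' the start time `t0`. Bin `i` is centered at `t0 + (i - 1) * dt`
#' (0-based bin indexing in time).
#'
#' @param counts Numeric vector of per-bin values, length >= 2. Photon
#'   counts are non-negative; negative values trigger a warning (generic
#'   signals may legitimately contain them).
#' @param dt Bin width in seconds, > 0.
#' @param t0 Start time (center of the first bin) in seconds.
#' @param warn_negative Warn when values are negative (photon counts);
#'   generic signals (e.g. noisy spectra) may switch this off.
#' @return Object of class `pcwa_trace`.
#' @examples
#' tr <- pcwa_trace(rpois(1000, 2), dt = 1e-5)
#' tr
#' @export
pcwa_trace <- function(counts, dt, t0 = 0, warn_negative = TRUE) {
  if (!is.numeric(counts) || length(counts) < 2)
    stop("counts must be a numeric vector of length >= 2")
  if (!(is.numeric(dt) && length(dt) == 1 && is.finite(dt) && dt > 0))
    stop("dt must be a single positive number")
  if (anyNA(counts)) stop("counts contain NA")
  if (warn_negative && any(counts < 0))
    warning("trace contains negative values")
  structure(list(counts = as.numeric(counts), dt = dt, t0 = t0),
            class = "pcwa_trace")
}

#' @export
print.pcwa_trace <- function(x, ...) {
  n <- length(x$counts)
  cat(sprintf(
    "<pcwa_trace> %d bins, dt %.4g s, span %.4g s, mean %.3g counts/bin\n",
    n, x$dt, n * x$dt, mean(x$counts)))
  invisible(x)
}

#' @export
length.pcwa_trace <- function(x) length(x$counts)

# time <-> bin conversions (bin 1 is centered at t0)
time_to_bin <- function(trace, t) as.integer(round((t - trace$t0) / trace$dt)) + 1L
bin_to_time <- function(trace, i) trace$t0 + (i - 1) * trace$dt

#' Read a trace from delimited text
#'
#' Supports two layouts: two columns (time, value) with automatic header
#' detection and `dt` inferred from the median time step (sampling must be
#' uniform to 1e-6 relative), or a single value column with `dt` supplied.
#'
#' @param path Path to a delimited text file (whitespace, comma or tab).
#' @param dt Bin width in seconds; required for single-column files,
#'   ignored (inferred) for two-column files.
#' @return A [pcwa_trace()].
#' @export
read_trace <- function(path, dt = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("format error: empty file: ", path)
  sep <- if (grepl(",", first)) "," else ""
  header <- {
    fields <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]]
    any(is.na(suppressWarnings(as.numeric(fields))))
  }
  df <- utils::read.table(path, header = header, sep = sep)
  if (nrow(df) < 2) stop("format error: fewer than 2 samples in ", path)
  if (ncol(df) >= 2) {
    tcol <- as.numeric(df[[1]]); vcol <- as.numeric(df[[2]])
    steps <- diff(tcol)
    step <- stats::median(steps)
    if (step <= 0) stop("format error: non-increasing time column")
    bad <- which(abs(steps - step) > 1e-6 * step)
    if (length(bad) > 0)
      stop(sprintf("format error: non-uniform sampling at row %d (step %.6g, expected %.6g)",
                   bad[1] + 1L, steps[bad[1]], step))
    pcwa_trace(vcol, dt = step, t0 = tcol[1])
  } else {
    if (is.null(dt)) stop("single-column trace requires dt")
    pcwa_trace(as.numeric(df[[1]]), dt = dt)
  }
}

#' Write a trace to two-column delimited text
#'
#' @param trace A `pcwa_trace`.
#' @param path Output path.
#' @param digits Significant digits for the time column.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path, digits = 12) {
  stopifnot(inherits(trace, "pcwa_trace"))
  tt <- bin_to_time(trace, seq_along(trace$counts))
  df <- data.frame(time = signif(tt, digits), counts = trace$counts)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Stable column order for event tables (blank-friendly optional columns).
event_columns <- c("t", "scale", "C", "n_members", "t_adjusted", "N",
                   "N_best", "velocity_um_per_ms", "intensity", "in_gate")

#' Write an event table to delimited text
#'
#' Header plus one row per event, sorted by time, in a stable column order
#' with deterministic fixed formatting, so that saved tables are
#' byte-reproducible for a given detection run.
#'
#' @param events Event data.frame (from [pcwa()], a baseline detector, or
#'   [classify_events()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_events <- function(events, path) {
  keep <- intersect(event_columns, names(events))
  extra <- setdiff(names(events), keep)
  df <- events[, c(keep, extra), drop = FALSE]
  if (nrow(df) > 0 && "t" %in% names(df)) df <- df[order(df$t), , drop = FALSE]
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
      df[[nm]] <- sprintf("%.9g", df[[nm]])
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event table written by [write_events()]
#' @param path Path to the table.
#' @return data.frame of events.
#' @export
read_events <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
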