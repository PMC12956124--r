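#' @useDynLib pshkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom e1071 svm
#' @importFrom jsonlite write_json
#' @importFrom stats median sd var qt rnorm runif rpois rlnorm predict
#' @importFrom utils head
#' @import data.table
NULL

SIGNAL_KINDS <- c("HR", "RR", "SBP")

#' Construct a vital-sign trend series
#'
#' A `vital_series` holds one patient's trend for one signal: timestamps in
#' seconds from the start of the recording ("time zero") and the measured
#' values (bpm for HR, breaths/min for RR, mmHg for SBP). Timestamps must be
#' strictly increasing and non-negative; values must be finite.
#'
#' @param patient_id Patient identifier (length-1 character).
#' @param signal One of `"HR"`, `"RR"`, `"SBP"`.
#' @param timestamps Numeric vector, seconds from record start, strictly
#'   increasing, all `>= 0`.
#' @param values Numeric vector of measurements, same length as `timestamps`,
#'   all finite.
#' @param rate_hz Nominal sampling rate in Hz (default 0.5, one sample every
#'   2 s, the usual bedside-monitor trend rate).
#' @return An object of class `vital_series`.
#' @export
#' @examples
#' vs <- vital_series("p1", "HR", seq(0, 58, by = 2), rep(80, 30))
#' vs
vital_series <- function(patient_id, signal, timestamps, values, rate_hz = 0.5) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  signal <- match.arg(signal, SIGNAL_KINDS)
  timestamps <- as.numeric(timestamps)
  values <- as.numeric(values)
  if (length(timestamps) != length(values))
    stop("timestamps and values must have equal length", call. = FALSE)
  if (length(timestamps)) {
    if (anyNA(timestamps) || any(timestamps < 0))
      stop("timestamps must be non-negative and non-missing", call. = FALSE)
    if (is.unsorted(timestamps, strictly = TRUE))
      stop("timestamps must be strictly increasing", call. = FALSE)
    if (!all(is.finite(values)))
      stop("values must all be finite", call. = FALSE)
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("rate_hz must be a positive scalar", call. = FALSE)
  structure(
    list(patient_id = patient_id, signal = signal,
         timestamps = timestamps, values = values, rate_hz = rate_hz),
    class = "vital_series"
  )
}

#' @export
print.vital_series <- function(x, ...) {
  n <- length(x$timestamps)
  span <- if (n) sprintf("[%.0f, %.0f] s", x$timestamps[1L], x$timestamps[n]) else "(empty)"
  cat(sprintf("<vital_series> patient %s, %s, %d samples %s @ %g Hz\n",
              x$patient_id, x$signal, n, span, x$rate_hz))
  invisible(x)
}

#' @export
length.vital_series <- function(x) length(x$timestamps)

record_end <- function(series) {
  n <- length(series$timestamps)
  if (n == 0L) return(0)
  # half-open extent: one sampling period past the last sample
  series$timestamps[n] + 1 / series$rate_hz
}

#' Read vital-sign trend CSV
#'
#' Reads the shared vital-sign dialect (`patient_id,signal,timestamp_s,value`)
#' into a list of [vital_series()], one per `(patient_id, signal)` pair, named
#' `"<patient_id>.<signal>"`. Rows whose timestamp or value does not parse as
#' a finite number are dropped with a warning counting them; exact duplicate
#' timestamps within a series collapse to the last-read value (warned).
#'
#' @param path Path to a CSV file with header
#'   `patient_id,signal,timestamp_s,value`.
#' @param rate_hz Nominal sampling rate recorded on each returned series.
#' @return Named list of `vital_series` (empty list for an empty file).
#' @export
read_vitals_csv <- function(path, rate_hz = 0.5) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, showProgress = FALSE)
  req <- c("patient_id", "signal", "timestamp_s", "value")
  missing_col <- setdiff(req, names(dt))
  if (length(missing_col))
    stop("vital-sign CSV is missing required column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  if (nrow(dt) == 0L) return(list())
  dt[, `:=`(patient_id = as.character(patient_id), signal = as.character(signal))]
  ts <- suppressWarnings(as.numeric(dt$timestamp_s))
  val <- suppressWarnings(as.numeric(dt$value))
  ok <- is.finite(ts) & is.finite(val) & dt$signal %chin% SIGNAL_KINDS
  n_bad <- sum(!ok)
  if (n_bad > 0L)
    warning(sprintf("dropped %d row(s) with unparseable numerics or unknown signal", n_bad),
            call. = FALSE)
  dt <- dt[ok]
  dt[, `:=`(timestamp_s = ts[ok], value = val[ok])]
  out <- list()
  n_dup_total <- 0L
  for (grp in split(seq_len(nrow(dt)), list(dt$patient_id, dt$signal), drop = TRUE)) {
    t_g <- dt$timestamp_s[grp]
    v_g <- dt$value[grp]
    o <- order(t_g)          # stable: ties keep file order, so "last read" is last
    t_g <- t_g[o]; v_g <- v_g[o]
    dup <- duplicated(t_g, fromLast = TRUE)
    n_dup_total <- n_dup_total + sum(dup)
    vs <- vital_series(dt$patient_id[grp[1L]], dt$signal[grp[1L]],
                       t_g[!dup], v_g[!dup], rate_hz = rate_hz)
    out[[paste(vs$patient_id, vs$signal, sep = ".")]] <- vs
  }
  if (n_dup_total > 0L)
    warning(sprintf("collapsed %d duplicate timestamp(s) to the last-read value", n_dup_total),
            call. = FALSE)
  out[order(names(out))]
}

#' Write vital-sign trend CSV
#'
#' Writer counterpart of [read_vitals_csv()]: emits the same dialect
#' (`patient_id,signal,timestamp_s,value`, UTF-8, LF line endings).
#'
#' @param series A `vital_series` or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_vitals_csv <- function(series, path) {
  if (inherits(series, "vital_series")) series <- list(series)
  dt <- data.table::rbindlist(lapply(series, function(s)
    data.table::data.table(patient_id = s$patient_id, signal = s$signal,
                           timestamp_s = s$timestamps, value = s$values)))
  if (nrow(dt) == 0L)
    dt <- data.table::data.table(patient_id = character(), signal = character(),
                                 timestamp_s = numeric(), value = numeric())
  data.table::fwrite(dt, path, eol = "\n")
  invisible(path)
}

#' Default artifact-filter range for a signal
#'
#' Physiologically plausible bounds used by extreme-value artifact filtering.
#' The HR range of 30-250 bpm is the adult normal reference range; the RR
#' (4-80 breaths/min) and SBP (40-300 mmHg) bounds are configurable package
#' defaults chosen on the same plausibility principle.
#'
#' @param signal One of `"HR"`, `"RR"`, `"SBP"`.
#' @return Numeric `c(lo, hi)`, both bounds inclusive.
#' @export
default_filter_range <- function(signal) {
  switch(match.arg(signal, SIGNAL_KINDS),
         HR = c(30, 250), RR = c(4, 80), SBP = c(40, 300))
}

#' Remove extreme (artifact) values from a series
#'
#' Keeps exactly the samples with `lo <= value <= hi` (closed interval; a
#' value equal to a bound is retained). Order is preserved and the input is
#' not modified. Idempotent.
#'
#' @param series A [vital_series()].
#' @param range Numeric `c(lo, hi)` with `lo < hi`; defaults to
#'   [default_filter_range()] for the series' signal.
#' @return The filtered `vital_series` (possibly empty).
#' @export
filter_extreme_values <- function(series, range = default_filter_range(series$signal)) {
  stopifnot(inherits(series, "vital_series"),
            is.numeric(range), length(range) == 2L, range[1L] < range[2L])
  keep <- series$values >= range[1L] & series$values <= range[2L]
  vital_series(series$patient_id, series$signal,
               series$timestamps[keep], series$values[keep], series$rate_hz)
}

#' Summary statistics over a half-open time window
#'
#' Statistics of the samples with `start_s <= t < end_s`. Variance is the
#' population variance (divide by `n`, so a single sample has variance 0);
#' the median is the midpoint average for even `n`.
#'
#' @param series A [vital_series()].
#' @param start_s,end_s Window bounds in seconds, `start_s < end_s`.
#' @return A list with `start_s`, `end_s`, `n`, `mean`, `sd`, `variance`,
#'   `min`, `max`, `median`, or `NULL` if no sample falls in the window.
#' @export
window_stats <- function(series, start_s, end_s) {
  if (!(is.numeric(start_s) && is.numeric(end_s) && start_s < end_s))
    stop("start_s must be < end_s", call. = FALSE)
  i <- which(series$timestamps >= start_s & series$timestamps < end_s)
  if (length(i) == 0L) return(NULL)
  x <- series$values[i]
  n <- length(x)
  v <- sum((x - mean(x))^2) / n
  list(start_s = start_s, end_s = end_s, n = n,
       mean = mean(x), sd = sqrt(v), variance = v,
       min = min(x), max = max(x), median = stats::median(x))
}

#' Slice a series to a half-open time window
#'
#' Returns the samples with `start_s <= t < end_s`. Timestamps are NOT
#' re-based: they stay relative to the original time zero.
#'
#' @inheritParams window_stats
#' @return A `vital_series`, possibly empty.
#' @export
slice_series <- function(series, start_s, end_s) {
  if (!(is.numeric(start_s) && is.numeric(end_s) && start_s < end_s))
    stop("start_s must be < end_s", call. = FALSE)
  keep <- series$timestamps >= start_s & series$timestamps < end_s
  vital_series(series$patient_id, series$signal,
               series$timestamps[keep], series$values[keep], series$rate_hz)
}

# Exact stats for a batch of equal-width half-open windows [starts, starts+width),
# via the Fenwick-tree sliding implementation in src/. Returns a data.frame with
# one row per window (n = 0 rows carry NAs).
sliding_stats <- function(series, starts, width_s) {
  stopifnot(width_s > 0, !is.unsorted(starts))
  m <- sliding_window_stats_cpp(series$timestamps, series$values,
                                as.numeric(starts), as.numeric(width_s))
  out <- as.data.frame(m)
  names(out) <- c("n", "mean", "variance", "sd", "min", "max", "median")
  out$start_s <- as.numeric(starts)
  out$end_s <- as.numeric(starts) + width_s
  out
}
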