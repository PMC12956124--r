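#' Clinical Feature Scale thresholds
#'
#' Three ascending cut-points per signal mapping an hourly summary value to a
#' 0-3 subscore. Defaults follow the PSH-AM Clinical Feature Scale rows for
#' heart rate (<100 / 100-119 / 120-139 / >=140 bpm), respiratory rate
#' (<18 / 18-23 / 24-29 / >=30 breaths/min) and systolic blood pressure
#' (<140 / 140-159 / 160-179 / >=180 mmHg).
#'
#' @param HR,RR,SBP Numeric length-3 strictly ascending cut-points.
#' @return A named list of class `cfs_thresholds`.
#' @export
cfs_thresholds <- function(HR = c(100, 120, 140),
                           RR = c(18, 24, 30),
                           SBP = c(140, 160, 180)) {
  th <- list(HR = as.numeric(HR), RR = as.numeric(RR), SBP = as.numeric(SBP))
  for (k in names(th)) {
    if (length(th[[k]]) != 3L || is.unsorted(th[[k]], strictly = TRUE))
      stop(k, " cut-points must be 3 strictly ascending values", call. = FALSE)
  }
  structure(th, class = "cfs_thresholds")
}

#' Score a single vital-sign value on the 0-3 scale
#'
#' The subscore is the number of cut-points at or below the value:
#' `value < c1` scores 0, `c1 <= value < c2` scores 1, `c2 <= value < c3`
#' scores 2 and `value >= c3` scores 3.
#'
#' @param signal One of `"HR"`, `"RR"`, `"SBP"`.
#' @param value Finite numeric value (vectorized).
#' @param thresholds A [cfs_thresholds()] object.
#' @return Integer subscore(s) in 0..3.
#' @export
#' @examples
#' score_vital("HR", c(99, 100, 119, 120, 140)) # 0 1 1 2 3
score_vital <- function(signal, value, thresholds = cfs_thresholds()) {
  signal <- match.arg(signal, SIGNAL_KINDS)
  stopifnot(all(is.finite(value)))
  cuts <- thresholds[[signal]]
  findInterval(value, cuts)
}

hour_window_starts <- function() seq(0, 3450, by = 150)  # 24 offsets, 2.5-min step

#' Per-window maxima within one hour
#'
#' The hour `[3600*h, 3600*(h+1))` is scanned by 24 rolling 5-minute windows
#' with 50% overlap (start offsets 0, 150, ..., 3450 s within the hour); the
#' 24th window would overrun the hour so it is truncated to `[3450, 3600)`.
#' Returns the maximum observed value in each window (`NA` for windows with
#' no samples).
#'
#' @param series A filtered [vital_series()].
#' @param hour_index Non-negative integer hour since time zero.
#' @return A data.frame with 24 rows: `start_s`, `end_s`, `max`.
#' @export
hourly_window_maxima <- function(series, hour_index) {
  if (!(is.numeric(hour_index) && length(hour_index) == 1L && hour_index >= 0))
    stop("hour_index must be a non-negative integer", call. = FALSE)
  h0 <- 3600 * hour_index
  ts <- series$timestamps
  starts <- h0 + hour_window_starts()
  ends <- pmin(starts + 300, h0 + 3600)   # truncate the final window at the hour
  # index range per window on the sorted timestamp grid
  i_lo <- findInterval(starts, ts, left.open = TRUE) + 1L
  i_hi <- findInterval(ends, ts, left.open = TRUE)
  wmax <- rep(NA_real_, length(starts))
  for (k in seq_along(starts)) {
    if (i_lo[k] <= i_hi[k]) wmax[k] <- max(series$values[i_lo[k]:i_hi[k]])
  }
  data.frame(start_s = starts, end_s = ends, max = wmax)
}

#' Hourly vital-sign summary via rolling-window maxima
#'
#' The maximum over the hour's 24 per-window maxima
#' ([hourly_window_maxima()]); equal to the plain hourly maximum when the
#' hour is fully covered. Returns `NA` if every window is empty.
#'
#' @inheritParams hourly_window_maxima
#' @return Numeric hourly summary value, or `NA_real_`.
#' @export
hourly_vital_max <- function(series, hour_index) {
  wmax <- hourly_window_maxima(series, hour_index)$max
  if (all(is.na(wmax))) NA_real_ else max(wmax, na.rm = TRUE)
}

#' Compute the hourly high-resolution Clinical Feature Scale
#'
#' For each hour from time zero to the last hour containing any sample of any
#' signal, each signal's hourly rolling-window maximum ([hourly_vital_max()])
#' is scored 0-3 ([score_vital()]); the composite hrCFS is the sum of the
#' three subscores (range 0-9). A signal's subscore is missing for hours where
#' its coverage (observed samples / expected samples at the nominal rate)
#' falls below `min_coverage`; the composite is missing unless all three
#' subscores are present.
#'
#' @param hr,rr,sbp [vital_series()] for one patient, already passed through
#'   [filter_extreme_values()].
#' @param thresholds A [cfs_thresholds()] object.
#' @param min_coverage Minimum per-signal hourly coverage fraction (default
#'   0.5) for a subscore to be emitted.
#' @return A data.frame with columns `patient_id`, `hour_index`, `hr_score`,
#'   `rr_score`, `sbp_score`, `composite`, `coverage` (mean coverage across
#'   the three signals).
#' @export
compute_hrcfs <- function(hr, rr, sbp, thresholds = cfs_thresholds(),
                          min_coverage = 0.5) {
  stopifnot(inherits(hr, "vital_series"), inherits(rr, "vital_series"),
            inherits(sbp, "vital_series"))
  if (length(unique(c(hr$patient_id, rr$patient_id, sbp$patient_id))) != 1L)
    stop("hr, rr, sbp must belong to the same patient", call. = FALSE)
  series <- list(HR = hr, RR = rr, SBP = sbp)
  last_t <- max(0, unlist(lapply(series, function(s)
    if (length(s)) max(s$timestamps) else 0)))
  n_hours <- floor(last_t / 3600) + 1L
  hours <- seq_len(n_hours) - 1L

  sub <- cov <- matrix(NA_real_, nrow = n_hours, ncol = 3L,
                       dimnames = list(NULL, SIGNAL_KINDS))
  for (k in SIGNAL_KINDS) {
    s <- series[[k]]
    expected <- 3600 * s$rate_hz
    counts <- if (length(s)) tabulate(floor(s$timestamps / 3600) + 1L, nbins = n_hours)
              else integer(n_hours)
    cov[, k] <- pmin(1, counts / expected)
    for (h in hours) {
      if (cov[h + 1L, k] >= min_coverage) {
        m <- hourly_vital_max(s, h)
        if (!is.na(m)) sub[h + 1L, k] <- score_vital(k, m, thresholds)
      }
    }
  }
  composite <- rowSums(sub)   # NA unless all three subscores present
  data.frame(patient_id = hr$patient_id, hour_index = hours,
             hr_score = sub[, "HR"], rr_score = sub[, "RR"],
             sbp_score = sub[, "SBP"], composite = composite,
             coverage = rowMeans(cov))
}

#' Write hourly hrCFS scores to CSV
#'
#' Emits `patient_id,hour_index,hr_score,rr_score,sbp_score,composite,coverage`
#' with missing scores as empty fields.
#'
#' @param hrcfs Data frame from [compute_hrcfs()] (rows for several patients
#'   may be bound together).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_hrcfs_csv <- function(hrcfs, path) {
  data.table::fwrite(hrcfs, path, eol = "\n", na = "")
  invisible(path)
}
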