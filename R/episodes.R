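EPISODE_SOURCES <- c("annotation", "es", "svm", "truth")

#' Construct an episode set
#'
#' An `episode_set` is a sorted collection of non-overlapping half-open time
#' intervals `[start_s, end_s)`, in seconds from time zero, representing PSH
#' episodes for one patient. Intervals passed in any order are sorted;
#' overlap is an error.
#'
#' @param patient_id Patient identifier.
#' @param start_s,end_s Numeric vectors of interval bounds, `end_s > start_s`
#'   elementwise.
#' @param source One of `"annotation"`, `"es"`, `"svm"`, `"truth"`.
#' @return An object of class `episode_set`.
#' @export
episode_set <- function(patient_id, start_s = numeric(), end_s = numeric(),
                        source = "annotation") {
  source <- match.arg(source, EPISODE_SOURCES)
  start_s <- as.numeric(start_s); end_s <- as.numeric(end_s)
  stopifnot(length(start_s) == length(end_s))
  if (length(start_s)) {
    if (any(end_s <= start_s)) stop("every interval needs end_s > start_s", call. = FALSE)
    o <- order(start_s)
    start_s <- start_s[o]; end_s <- end_s[o]
    if (any(start_s[-1L] < end_s[-length(end_s)]))
      stop("episode intervals must not overlap", call. = FALSE)
  }
  structure(list(patient_id = patient_id, start_s = start_s, end_s = end_s,
                 source = source),
            class = "episode_set")
}

#' @export
print.episode_set <- function(x, ...) {
  cat(sprintf("<episode_set> patient %s, source %s, %d episode(s), total %.1f min\n",
              x$patient_id, x$source, length(x$start_s),
              sum(x$end_s - x$start_s) / 60))
  invisible(x)
}

#' @export
length.episode_set <- function(x) length(x$start_s)

#' Read / write episode CSV
#'
#' Shared episode dialect: `patient_id,start_s,end_s,source` with source in
#' `{annotation, es, svm, truth}`. `read_episodes_csv()` returns a named list
#' of [episode_set()] keyed `"<patient_id>.<source>"`.
#'
#' @param path CSV path.
#' @return For the reader, a named list of `episode_set`.
#' @export
read_episodes_csv <- function(path) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, showProgress = FALSE)
  req <- c("patient_id", "start_s", "end_s", "source")
  missing_col <- setdiff(req, names(dt))
  if (length(missing_col))
    stop("episode CSV is missing required column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  out <- list()
  if (nrow(dt) == 0L) return(out)
  dt[, `:=`(patient_id = as.character(patient_id), source = as.character(source))]
  for (grp in split(seq_len(nrow(dt)), list(dt$patient_id, dt$source), drop = TRUE)) {
    es <- episode_set(dt$patient_id[grp[1L]], dt$start_s[grp], dt$end_s[grp],
                      dt$source[grp[1L]])
    out[[paste(es$patient_id, es$source, sep = ".")]] <- es
  }
  out[order(names(out))]
}

#' @rdname read_episodes_csv
#' @param episodes An `episode_set` or list of them.
#' @export
write_episodes_csv <- function(episodes, path) {
  if (inherits(episodes, "episode_set")) episodes <- list(episodes)
  dt <- data.table::rbindlist(lapply(episodes, function(e)
    data.table::data.table(patient_id = e$patient_id, start_s = e$start_s,
                           end_s = e$end_s, source = e$source)))
  if (nrow(dt) == 0L)
    dt <- data.table::data.table(patient_id = character(), start_s = numeric(),
                                 end_s = numeric(), source = character())
  data.table::fwrite(dt, path, eol = "\n")
  invisible(path)
}

#' Assemble point labels into episode intervals
#'
#' Maximal runs of consecutive positive samples become intervals
#' `[t_first, t_last + 1/rate)` — the interval extends one sampling period
#' past the last positive sample, keeping episodes half-open on the sampling
#' grid. A sampling gap larger than `max_sample_gap_s` between consecutive
#' positive samples splits the run, so monitoring dropouts do not silently
#' bridge an episode.
#'
#' @param labels A point-label series as returned by [label_points_es()] or
#'   [label_points_svm()]: list with `patient_id`, `timestamps`, `labels`
#'   (0/1), `rate_hz`.
#' @param max_sample_gap_s Maximum within-episode sampling gap in seconds
#'   (default 60, aligned with the episode merge threshold).
#' @param source Source tag for the resulting [episode_set()].
#' @return An `episode_set`.
#' @export
assemble_episodes <- function(labels, max_sample_gap_s = 60, source = "es") {
  idx <- which(labels$labels == 1L)
  if (length(idx) == 0L)
    return(episode_set(labels$patient_id, source = source))
  pos <- labels$timestamps[idx]
  period <- 1 / labels$rate_hz
  # a run breaks on an intervening negative sample or an over-long sampling gap
  brk <- which(diff(idx) > 1L | diff(pos) > max_sample_gap_s)
  first <- pos[c(1L, brk + 1L)]
  last <- pos[c(brk, length(pos))]
  episode_set(labels$patient_id, first, last + period, source = source)
}

#' Merge episodes separated by short breaks
#'
#' Consecutive intervals whose gap is strictly less than `min_gap_s` are
#' merged into one spanning interval, transitively: after merging every
#' remaining inter-episode gap is `>= min_gap_s`. A gap of exactly
#' `min_gap_s` is not merged.
#'
#' @param eps An [episode_set()].
#' @param min_gap_s Merge threshold in seconds (default 60, i.e. breaks of
#'   less than one minute are merged).
#' @return An `episode_set`.
#' @export
merge_episodes <- function(eps, min_gap_s = 60) {
  stopifnot(inherits(eps, "episode_set"))
  n <- length(eps$start_s)
  if (n <= 1L) return(eps)
  gap <- eps$start_s[-1L] - eps$end_s[-n]
  new_run <- c(TRUE, gap >= min_gap_s)
  grp <- cumsum(new_run)
  episode_set(eps$patient_id,
              eps$start_s[new_run],
              vapply(split(eps$end_s, grp), max, numeric(1L), USE.NAMES = FALSE),
              source = eps$source)
}

clip_total <- function(eps, frame_start_s, frame_end_s) {
  lo <- pmax(eps$start_s, frame_start_s)
  hi <- pmin(eps$end_s, frame_end_s)
  sum(pmax(0, hi - lo))
}

#' Episode burden score over a time frame
#'
#' The burden is the temporal density of episodes within the frame:
#' `B = (1/T) * sum(duration(episode_n))` with episodes clipped to the frame
#' `[frame_start_s, frame_end_s)` of length `T`. A patient with a cumulative
#' 2 h of episodes over a 4-h frame has burden 0.5; the same score can come
#' from many short episodes or a single long one.
#'
#' @param eps An [episode_set()].
#' @param frame_start_s,frame_end_s Frame bounds in seconds,
#'   `frame_end_s > frame_start_s`.
#' @return Burden fraction in `[0, 1]`.
#' @export
burden_score <- function(eps, frame_start_s, frame_end_s) {
  stopifnot(inherits(eps, "episode_set"))
  if (!(frame_end_s > frame_start_s))
    stop("frame must have positive length", call. = FALSE)
  clip_total(eps, frame_start_s, frame_end_s) / (frame_end_s - frame_start_s)
}

#' Burden trend over consecutive windows from time zero
#'
#' [burden_score()] evaluated on consecutive non-overlapping windows of
#' `window_s` seconds anchored at time zero; a trailing partial window is
#' scored over its actual length. A 14-day record with the default 12-h
#' window yields exactly 28 scores.
#'
#' @param eps An [episode_set()].
#' @param record_span_s Record length in seconds.
#' @param window_s Trend window in seconds (default 43200 = 12 h).
#' @return A data.frame with `patient_id`, `window_index` (0-based),
#'   `window_start_s`, `window_end_s`, `burden`.
#' @export
burden_trend <- function(eps, record_span_s, window_s = 43200) {
  stopifnot(record_span_s > 0, window_s > 0)
  n_win <- ceiling(record_span_s / window_s)
  starts <- (seq_len(n_win) - 1L) * window_s
  ends <- pmin(starts + window_s, record_span_s)
  data.frame(patient_id = eps$patient_id,
             window_index = seq_len(n_win) - 1L,
             window_start_s = starts, window_end_s = ends,
             burden = vapply(seq_len(n_win), function(i)
               burden_score(eps, starts[i], ends[i]), numeric(1L)))
}

#' Summarize episodes over the first 14 days
#'
#' Episodes are clipped to `[0, 14 * 86400)` seconds; reports the episode
#' count, mean clipped duration in minutes (`NA` when there are none) and the
#' burden over the 14-day frame.
#'
#' @param eps An [episode_set()].
#' @return A data.frame row: `patient_id`, `n_episodes`, `mean_duration_min`,
#'   `burden_14d`.
#' @export
summarize_first14 <- function(eps) {
  stopifnot(inherits(eps, "episode_set"))
  span <- 14 * 86400
  lo <- pmax(eps$start_s, 0)
  hi <- pmin(eps$end_s, span)
  dur <- (hi - lo)[hi > lo]
  data.frame(patient_id = eps$patient_id,
             n_episodes = length(dur),
             mean_duration_min = if (length(dur)) mean(dur) / 60 else NA_real_,
             burden_14d = sum(dur) / span)
}

#' Cohen's d between two groups
#'
#' Standardized mean difference `d = (mean_a - mean_b) / pooled_sd` with the
#' pooled standard deviation from the two sample variances,
#' `pooled_sd = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`.
#'
#' @param group_a,group_b Numeric vectors, each of length `>= 2`.
#' @return Cohen's d, or `NA` when the pooled sd is zero.
#' @export
cohort_effect_size <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  na <- length(group_a); nb <- length(group_b)
  sp <- sqrt(((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
               (na + nb - 2))
  if (sp == 0) return(NA_real_)
  (mean(group_a) - mean(group_b)) / sp
}

#' Cross-patient trend mean with t-based confidence interval
#'
#' For each window index, the cross-patient mean of the trend values and a
#' t-distribution confidence interval `mean +/- t * sd / sqrt(n)`. Windows
#' with fewer than 2 contributing patients report the mean only (`NA` CI).
#'
#' @param trends Data frame with columns `patient_id`, `window_index` and a
#'   value column (default `burden`), e.g. several [burden_trend()] outputs
#'   bound together.
#' @param value_col Name of the value column to aggregate.
#' @param confidence Confidence level (default 0.95).
#' @return A data.frame with `window_index`, `n`, `mean`, `lo`, `hi`.
#' @export
trend_ci <- function(trends, value_col = "burden", confidence = 0.95) {
  stopifnot(value_col %in% names(trends), confidence > 0, confidence < 1)
  idx <- sort(unique(trends$window_index))
  res <- lapply(idx, function(w) {
    x <- trends[[value_col]][trends$window_index == w]
    x <- x[!is.na(x)]
    n <- length(x)
    m <- if (n) mean(x) else NA_real_
    if (n >= 2L) {
      half <- stats::qt(1 - (1 - confidence) / 2, df = n - 1) * stats::sd(x) / sqrt(n)
      c(n, m, m - half, m + half)
    } else c(n, m, NA_real_, NA_real_)
  })
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c("n", "mean", "lo", "hi")
  cbind(window_index = idx, out)
}
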