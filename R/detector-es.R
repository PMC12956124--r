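#' Expert-system rule set
#'
#' Parameterized heart-rate rules and sliding-window geometry for the
#' expert-system episode detector. Defaults are the rules derived from
#' single-patient clinician-annotated training data: HR minimum > 95 bpm,
#' HR median > 104 bpm and HR variance > 37 bpm^2, evaluated on 10-minute
#' windows sliding by 2 s, with a window voting positive when at least 2 of
#' the 3 rules hold (strict inequalities).
#'
#' @param min_thr HR minimum threshold `a` in bpm.
#' @param median_thr HR median threshold `b` in bpm.
#' @param var_thr HR variance threshold `c` in bpm^2.
#' @param window_s Sliding-window width in seconds.
#' @param step_s Window step in seconds, `0 < step_s <= window_s`.
#' @param votes_required Number of rules (of 3) that must hold.
#' @return A list of class `psh_rules`.
#' @export
rule_set <- function(min_thr = 95, median_thr = 104, var_thr = 37,
                     window_s = 600, step_s = 2, votes_required = 2L) {
  stopifnot(window_s > 0, step_s > 0, step_s <= window_s,
            votes_required >= 1L, votes_required <= 3L)
  structure(list(min_thr = min_thr, median_thr = median_thr, var_thr = var_thr,
                 window_s = window_s, step_s = step_s,
                 votes_required = as.integer(votes_required)),
            class = "psh_rules")
}

#' @export
print.psh_rules <- function(x, ...) {
  cat(sprintf(paste0("<psh_rules> min > %g, median > %g, variance > %g ",
                     "(%d of 3); %gs windows, %gs step\n"),
              x$min_thr, x$median_thr, x$var_thr, x$votes_required,
              x$window_s, x$step_s))
  invisible(x)
}

#' Evaluate the expert-system rules on one window
#'
#' A window votes positive when at least `votes_required` of the three strict
#' rules hold: `min > a`, `median > b`, `variance > c`.
#'
#' @param stats Non-empty window statistics from [window_stats()] (any list
#'   with `min`, `median`, `variance`).
#' @param rules A [rule_set()].
#' @return `TRUE` (positive) or `FALSE`.
#' @export
evaluate_rules <- function(stats, rules = rule_set()) {
  if (is.null(stats)) stop("stats must describe a non-empty window", call. = FALSE)
  votes <- (stats$min > rules$min_thr) + (stats$median > rules$median_thr) +
    (stats$variance > rules$var_thr)
  votes >= rules$votes_required
}

point_label_series <- function(patient_id, timestamps, labels, rate_hz) {
  structure(list(patient_id = patient_id, timestamps = timestamps,
                 labels = as.integer(labels), rate_hz = rate_hz),
            class = "point_labels")
}

#' @export
print.point_labels <- function(x, ...) {
  cat(sprintf("<point_labels> patient %s, %d samples, %d positive (%.1f%%)\n",
              x$patient_id, length(x$labels), sum(x$labels),
              if (length(x$labels)) 100 * mean(x$labels) else 0))
  invisible(x)
}

# Per-sample max-fusion of per-window votes shared by both detectors: a sample
# is positive iff at least one covering positive window exists. Implemented by
# unioning the positive windows' spans and marking samples inside the union.
fuse_window_votes <- function(series, starts, width_s, votes) {
  labels <- integer(length(series$timestamps))
  pos <- which(votes)
  if (length(pos)) {
    s <- starts[pos]; e <- starts[pos] + width_s
    # union of sorted, equal-width intervals
    brk <- which(s[-1L] > e[-length(e)])
    u_lo <- s[c(1L, brk + 1L)]
    u_hi <- e[c(brk, length(e))]
    for (i in seq_along(u_lo)) {
      labels[series$timestamps >= u_lo[i] & series$timestamps < u_hi[i]] <- 1L
    }
  }
  point_label_series(series$patient_id, series$timestamps, labels, series$rate_hz)
}

#' Label heart-rate samples with the expert-system detector
#'
#' Dense sliding windows `[k*step_s, k*step_s + window_s)` are enumerated for
#' `k = 0, 1, ...` while the window start lies before the record end; each
#' non-empty window votes via [evaluate_rules()] (empty windows vote
#' negative). Every sample's final label is the maximum over the votes of all
#' windows containing it, i.e. a sample is positive iff at least one covering
#' window is positive.
#'
#' @param hr A pre-filtered heart-rate [vital_series()].
#' @param rules A [rule_set()].
#' @return A `point_labels` object (`timestamps`, binary `labels`) on the
#'   series' sampling grid; empty for an empty series.
#' @export
label_points_es <- function(hr, rules = rule_set()) {
  stopifnot(inherits(hr, "vital_series"))
  if (length(hr) == 0L)
    return(point_label_series(hr$patient_id, numeric(), integer(), hr$rate_hz))
  starts <- seq(0, record_end(hr) - 1e-9, by = rules$step_s)
  st <- sliding_stats(hr, starts, rules$window_s)
  votes <- !is.na(st$n) & st$n > 0 &
    ((st$min > rules$min_thr) + (st$median > rules$median_thr) +
       (st$variance > rules$var_thr)) >= rules$votes_required
  fuse_window_votes(hr, starts, rules$window_s, votes)
}

#' Grid search for expert-system rule thresholds
#'
#' Evaluates every `(a, b, c)` triple in the Cartesian grid: labels the
#' record with [label_points_es()], assembles and merges episodes, and scores
#' range-based precision and recall against the ground-truth annotation. The
#' triple maximizing F1 = 2PR/(P+R) (taken as 0 when both are 0 or undefined)
#' is returned; ties prefer the more conservative rules (larger `a`, then
#' `b`, then `c`).
#'
#' @param hr A pre-filtered heart-rate [vital_series()].
#' @param truth Ground-truth [episode_set()] within the record span.
#' @param grid_a,grid_b,grid_c Candidate values for the minimum, median and
#'   variance thresholds.
#' @param base_rules Window geometry and voting carried into each candidate.
#' @param merge_gap_s Episode merge threshold passed to [merge_episodes()].
#' @param max_sample_gap_s Passed to [assemble_episodes()].
#' @return The winning [rule_set()], with attributes `f1`, `precision`,
#'   `recall`.
#' @export
grid_search_rules <- function(hr, truth, grid_a, grid_b, grid_c,
                              base_rules = rule_set(), merge_gap_s = 60,
                              max_sample_gap_s = 60) {
  if (!length(grid_a) || !length(grid_b) || !length(grid_c))
    stop("threshold grids must be non-empty", call. = FALSE)
  cand <- expand.grid(a = grid_a, b = grid_b, c = grid_c)
  # conservative-first order so the first max encountered is the tie-break
  cand <- cand[order(-cand$a, -cand$b, -cand$c), ]
  best <- NULL; best_f1 <- -1
  for (i in seq_len(nrow(cand))) {
    rules <- rule_set(cand$a[i], cand$b[i], cand$c[i],
                      base_rules$window_s, base_rules$step_s,
                      base_rules$votes_required)
    eps <- merge_episodes(
      assemble_episodes(label_points_es(hr, rules), max_sample_gap_s, source = "es"),
      merge_gap_s)
    p <- suppressWarnings(range_precision(truth, eps))  # empty detections -> F1 0
    r <- suppressWarnings(range_recall(truth, eps))
    f1 <- if (is.na(p) || is.na(r) || (p + r) == 0) 0 else 2 * p * r / (p + r)
    if (f1 > best_f1) {
      best_f1 <- f1
      best <- rules
      attr(best, "f1") <- f1
      attr(best, "precision") <- p
      attr(best, "recall") <- r
    }
  }
  if (best_f1 == 0)
    warning("no candidate rule set detected any episode overlap (F1 = 0); ",
            "returning the most conservative triple", call. = FALSE)
  best
}
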