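#' Overlap length of two half-open intervals
#'
#' @param a,b Numeric `c(start, end)` half-open intervals in seconds.
#' @return Length of the intersection in seconds (`>= 0`; abutting intervals
#'   overlap by 0).
#' @export
interval_overlap <- function(a, b) {
  max(0, min(a[2L], b[2L]) - max(a[1L], b[1L]))
}

# total overlap of one interval [lo, hi) with a union of sorted disjoint
# intervals (starts, ends)
overlap_with_union <- function(lo, hi, starts, ends) {
  if (!length(starts)) return(0)
  sum(pmax(0, pmin(hi, ends) - pmax(lo, starts)))
}

range_scores <- function(ref, other) {
  vapply(seq_along(ref$start_s), function(i)
    overlap_with_union(ref$start_s[i], ref$end_s[i], other$start_s, other$end_s) /
      (ref$end_s[i] - ref$start_s[i]),
    numeric(1L))
}

#' Range-based precision of detected episodes
#'
#' Interval (range-based) precision in the Tatbul style with flat positional
#' bias and no existence bonus: each detected episode `P_i` scores the
#' fraction of its duration covered by the union of annotated episodes,
#' `|P_i intersect union(R)| / |P_i|`, and the overall precision is the mean
#' of these per-episode scores over the `N_p` detected episodes.
#'
#' @param R Annotated (ground-truth) [episode_set()].
#' @param P Detected [episode_set()].
#' @return Precision in `[0, 1]`; `NA` (undefined, with a warning) when `P`
#'   is empty.
#' @export
range_precision <- function(R, P) {
  stopifnot(inherits(R, "episode_set"), inherits(P, "episode_set"))
  if (length(P) == 0L) {
    warning("precision undefined: no detected episodes", call. = FALSE)
    return(NA_real_)
  }
  mean(range_scores(P, R))
}

#' Range-based recall of annotated episodes
#'
#' Each annotated episode `R_i` scores the fraction of its duration covered
#' by the union of detected episodes, `|R_i intersect union(P)| / |R_i|`; the
#' overall recall is the mean over the `N_r` annotated episodes.
#'
#' @inheritParams range_precision
#' @return Recall in `[0, 1]`; `NA` (undefined, with a warning) when `R` is
#'   empty.
#' @export
range_recall <- function(R, P) {
  stopifnot(inherits(R, "episode_set"), inherits(P, "episode_set"))
  if (length(R) == 0L) {
    warning("recall undefined: no annotated episodes", call. = FALSE)
    return(NA_real_)
  }
  mean(range_scores(R, P))
}

#' Evaluate a detected episode set against annotations
#'
#' Combines [range_precision()] and [range_recall()] with the per-episode
#' score lists and counts into one report.
#'
#' @inheritParams range_precision
#' @return A list of class `range_eval`: `precision`, `recall`,
#'   `n_annotated`, `n_detected`, `precision_per_episode` (length
#'   `n_detected`), `recall_per_episode` (length `n_annotated`).
#' @export
evaluate_detection <- function(R, P) {
  stopifnot(inherits(R, "episode_set"), inherits(P, "episode_set"))
  pp <- range_scores(P, R)
  rp <- range_scores(R, P)
  structure(list(
    precision = if (length(P)) mean(pp) else NA_real_,
    recall = if (length(R)) mean(rp) else NA_real_,
    n_annotated = length(R), n_detected = length(P),
    precision_per_episode = pp, recall_per_episode = rp),
    class = "range_eval")
}

#' @export
print.range_eval <- function(x, ...) {
  cat(sprintf("<range_eval> precision %.3f (n_detected %d), recall %.3f (n_annotated %d)\n",
              x$precision, x$n_detected, x$recall, x$n_annotated))
  invisible(x)
}
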