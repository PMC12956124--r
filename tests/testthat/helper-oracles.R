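# Independent brute-force oracles and small random-instance generators used by
# the property-style tests. These deliberately avoid the package's optimized
# code paths: statistics are recomputed from plain vector slices, fusion by
# per-sample enumeration of covering windows, and interval overlap by fine
# time discretization.

rand_series <- function(n = NULL, patient = "pX", signal = "HR",
                        irregular = FALSE) {
  if (is.null(n)) n <- sample(1:60, 1L)
  ts <- if (irregular) sort(sample(seq(0, 4 * n, by = 0.5), n))
        else seq(0, by = 2, length.out = n)
  vital_series(patient, signal, ts, round(runif(n, 40, 160), 1))
}

# plain-R window statistics from a vector slice
brute_window_stats <- function(series, start_s, end_s) {
  x <- series$values[series$timestamps >= start_s & series$timestamps < end_s]
  if (!length(x)) return(NULL)
  v <- mean((x - mean(x))^2)
  list(n = length(x), mean = mean(x), variance = v, sd = sqrt(v),
       min = min(x), max = max(x), median = median(x))
}

# per-sample ES labels: enumerate every covering window, recompute its stats,
# vote, take the max
brute_labels_es <- function(series, rules) {
  end <- max(series$timestamps) + 1 / series$rate_hz
  starts <- seq(0, end - 1e-9, by = rules$step_s)
  votes <- vapply(starts, function(s) {
    st <- brute_window_stats(series, s, s + rules$window_s)
    if (is.null(st)) return(FALSE)
    ((st$min > rules$min_thr) + (st$median > rules$median_thr) +
       (st$variance > rules$var_thr)) >= rules$votes_required
  }, logical(1L))
  vapply(series$timestamps, function(t) {
    covering <- which(starts <= t & t < starts + rules$window_s)
    as.integer(length(covering) && any(votes[covering]))
  }, integer(1L))
}

# run assembly by explicit run enumeration over the label vector
brute_assemble <- function(timestamps, labels, rate_hz, max_gap) {
  starts <- ends <- numeric()
  open <- FALSE
  period <- 1 / rate_hz
  for (i in seq_along(labels)) {
    if (labels[i] == 1L) {
      if (!open) {
        starts <- c(starts, timestamps[i]); open <- TRUE
      } else if (timestamps[i] - last_t > max_gap) {
        ends <- c(ends, last_t + period)
        starts <- c(starts, timestamps[i])
      }
      last_t <- timestamps[i]
    } else if (open) {
      ends <- c(ends, last_t + period); open <- FALSE
    }
  }
  if (open) ends <- c(ends, last_t + period)
  cbind(start = starts, end = ends)
}

# merge by pairwise passes until a fixed point
brute_merge <- function(starts, ends, min_gap) {
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(starts)) {
      if (starts[i + 1L] - ends[i] < min_gap) {
        ends[i] <- max(ends[i], ends[i + 1L])
        starts <- starts[-(i + 1L)]; ends <- ends[-(i + 1L)]
        merged <- TRUE
      } else i <- i + 1L
    }
    if (!merged) break
  }
  cbind(start = starts, end = ends)
}

# range precision/recall by discretizing time on a fine grid
brute_range_scores <- function(ref, other, dt = 0.125) {
  vapply(seq_along(ref$start_s), function(i) {
    g <- seq(ref$start_s[i], ref$end_s[i] - dt / 2, by = dt)
    inside <- vapply(g, function(t)
      any(t >= other$start_s & t < other$end_s), logical(1L))
    mean(inside)
  }, numeric(1L))
}

rand_episode_set <- function(patient = "pX", source = "annotation",
                             span = 200, max_n = 5L) {
  n <- sample(0:max_n, 1L)
  if (n == 0L) return(episode_set(patient, source = source))
  # draw disjoint intervals on a 0.25-step grid so discretized overlap is exact
  edges <- sort(sample(seq(0, span, by = 0.25), 2L * n))
  keep <- seq(1L, 2L * n, by = 2L)
  ok <- edges[keep + 1L] > edges[keep]
  episode_set(patient, edges[keep][ok], edges[keep + 1L][ok], source = source)
}

make_labels <- function(timestamps, labels, patient = "pX", rate_hz = 0.5) {
  structure(list(patient_id = patient, timestamps = as.numeric(timestamps),
                 labels = as.integer(labels), rate_hz = rate_hz),
            class = "point_labels")
}
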