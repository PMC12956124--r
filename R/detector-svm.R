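SVM_FEATURES <- c("mean", "sd", "min", "max", "median")

#' Extract rolling-window summary features
#'
#' Rolling windows `[k*step_s, k*step_s + window_s)` are enumerated while the
#' window start lies before the record end; each non-empty window yields the
#' five summary features (mean, standard deviation, minimum, maximum,
#' median). The defaults — 10-minute windows sliding by 2.5 minutes (75%
#' overlap) — are the detector's training geometry; the coarser step limits
#' redundancy between neighbouring training windows. Empty windows are
#' skipped.
#'
#' @param hr A pre-filtered heart-rate [vital_series()].
#' @param window_s Window width in seconds (default 600).
#' @param step_s Window step in seconds (default 150).
#' @return A data.frame with `start_s`, `end_s`, `n` and the five feature
#'   columns.
#' @export
extract_features <- function(hr, window_s = 600, step_s = 150) {
  stopifnot(inherits(hr, "vital_series"))
  if (!(is.numeric(step_s) && step_s > 0)) stop("step_s must be > 0", call. = FALSE)
  if (length(hr) == 0L) {
    out <- data.frame(start_s = numeric(), end_s = numeric(), n = numeric(),
                      mean = numeric(), sd = numeric(), min = numeric(),
                      max = numeric(), median = numeric())
    return(out)
  }
  starts <- seq(0, record_end(hr) - 1e-9, by = step_s)
  st <- sliding_stats(hr, starts, window_s)
  st <- st[!is.na(st$n) & st$n > 0, , drop = FALSE]
  rownames(st) <- NULL
  st[, c("start_s", "end_s", "n", SVM_FEATURES)]
}

#' Build a labeled training set from annotated episodes
#'
#' Windows fully contained in an annotated episode are labeled positive;
#' windows disjoint from every episode (inter-episode baseline) are labeled
#' negative; windows partially overlapping an episode boundary are excluded
#' from training, since their mixed statistics belong to neither class.
#'
#' @param hr A pre-filtered heart-rate [vital_series()].
#' @param annotations Clinician-annotated [episode_set()].
#' @param window_s,step_s Rolling-window geometry (see [extract_features()]).
#' @return A list: `features` (data.frame), `labels` (factor `"neg"`/`"pos"`),
#'   `n_pos`, `n_neg`, `window_s`, `step_s`.
#' @export
build_training_set <- function(hr, annotations, window_s = 600, step_s = 150) {
  stopifnot(inherits(annotations, "episode_set"))
  feats <- extract_features(hr, window_s, step_s)
  ov <- vapply(seq_len(nrow(feats)), function(i)
    overlap_with_union(feats$start_s[i], feats$end_s[i],
                       annotations$start_s, annotations$end_s),
    numeric(1L))
  width <- feats$end_s - feats$start_s
  pos <- ov >= width - 1e-9        # fully inside an episode
  neg <- ov <= 1e-9                # disjoint from all episodes
  keep <- pos | neg
  if (!any(pos))
    stop("training data has no positive windows (no window fully inside an episode)",
         call. = FALSE)
  if (!any(neg))
    stop("training data has no negative windows (no window disjoint from episodes)",
         call. = FALSE)
  list(features = feats[keep, , drop = FALSE],
       labels = factor(ifelse(pos[keep], "pos", "neg"), levels = c("neg", "pos")),
       n_pos = sum(pos), n_neg = sum(neg),
       window_s = window_s, step_s = step_s)
}

#' Train the SVM episode detector
#'
#' Standardizes the five summary features to zero mean and unit variance on
#' the training set (a zero-variance feature gets scale 1 with a warning),
#' then fits a support-vector classifier with radial-basis-function kernel.
#' Defaults: regularization cost 1 and kernel width
#' `gamma = 1 / (n_features * mean feature variance)` of the standardized
#' features (i.e. 1/5 for non-degenerate training data). Training is
#' deterministic given the seed and data order.
#'
#' @param training A training set from [build_training_set()].
#' @param cost SVM regularization parameter.
#' @param gamma RBF kernel width; `NULL` (default) uses the rule above.
#' @param class_weights Optional named vector of per-class weights
#'   (`c(neg = , pos = )`); `NULL` fits unweighted.
#' @param seed Integer seed fixed around the fit.
#' @return A list of class `psh_svm` holding the fitted classifier, the
#'   per-feature standardization offsets and scales, the window geometry, the
#'   hyperparameters and the seed.
#' @export
train_detector <- function(training, cost = 1, gamma = NULL,
                           class_weights = NULL, seed = 1L) {
  x <- as.matrix(training$features[, SVM_FEATURES])
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  if (any(scale == 0)) {
    warning("zero-variance feature(s): ",
            paste(SVM_FEATURES[scale == 0], collapse = ", "),
            "; using scale 1", call. = FALSE)
    scale[scale == 0] <- 1
  }
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  if (is.null(gamma)) {
    v <- mean(apply(xs, 2L, stats::var))
    gamma <- 1 / (ncol(xs) * if (v > 0) v else 1)
  }
  set.seed(as.integer(seed))
  fit <- e1071::svm(xs, training$labels, type = "C-classification",
                    kernel = "radial", cost = cost, gamma = gamma,
                    class.weights = class_weights, scale = FALSE)
  structure(list(fit = fit, center = center, scale = scale,
                 cost = cost, gamma = gamma, class_weights = class_weights,
                 window_s = training$window_s, step_s = training$step_s,
                 seed = as.integer(seed), version = 1L),
            class = "psh_svm")
}

#' @export
print.psh_svm <- function(x, ...) {
  cat(sprintf(paste0("<psh_svm> RBF SVM (cost %g, gamma %.4g), %d support vectors; ",
                     "%gs windows, %gs step\n"),
              x$cost, x$gamma, x$fit$tot.nSV, x$window_s, x$step_s))
  invisible(x)
}

#' Window-level predictions of a trained detector
#'
#' Applies the model's standardization and classifier to a feature table from
#' [extract_features()], returning the per-window binary vote before
#' max-fusion.
#'
#' @param model A [train_detector()] model.
#' @param feats Feature data.frame with columns `mean`, `sd`, `min`, `max`,
#'   `median`.
#' @return Logical vector, `TRUE` for windows predicted as episode.
#' @export
predict_windows <- function(model, feats) {
  stopifnot(inherits(model, "psh_svm"))
  xs <- sweep(sweep(as.matrix(feats[, SVM_FEATURES]), 2L, model$center),
              2L, model$scale, "/")
  as.character(stats::predict(model$fit, xs)) == "pos"
}

#' Label heart-rate samples with the SVM detector
#'
#' Features are extracted with the model's training window geometry, each
#' window receives a binary prediction, and every sample's final label is the
#' maximum over the predictions of all windows containing it — the same
#' max-fusion contract as [label_points_es()].
#'
#' @param hr A pre-filtered heart-rate [vital_series()].
#' @param model A trained [train_detector()] model.
#' @return A `point_labels` object; empty for an empty series.
#' @export
label_points_svm <- function(hr, model) {
  stopifnot(inherits(model, "psh_svm"))
  if (length(hr) == 0L)
    return(point_label_series(hr$patient_id, numeric(), integer(), hr$rate_hz))
  feats <- extract_features(hr, model$window_s, model$step_s)
  votes <- predict_windows(model, feats)
  fuse_window_votes(hr, feats$start_s, model$window_s, votes)
}

#' Save / load a trained detector model
#'
#' The model file is a version-tagged RDS archive holding the fitted
#' classifier (support vectors and coefficients), the feature
#' standardization, the window geometry and the hyperparameters; a reloaded
#' model produces identical predictions.
#'
#' @param model A [train_detector()] model.
#' @param path Model file path.
#' @return `save_detector()` returns `path` invisibly; `load_detector()`
#'   returns the `psh_svm` model.
#' @export
save_detector <- function(model, path) {
  stopifnot(inherits(model, "psh_svm"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "psh_svm") || is.null(model$version))
    stop("not a pshkit detector model file", call. = FALSE)
  model
}
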