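#' Simulation configuration
#'
#' Parameters of the synthetic vital-sign generator. The defaults emulate the
#' PSH phenomenology the detectors target: a stable autocorrelated baseline
#' (AR(1), lag-1 correlation `phi` at the 0.5 Hz grid) punctuated by
#' abrupt-onset, recurrent, simultaneous HR/RR/SBP elevations arriving as a
#' Poisson process (default 4/day), with log-normal durations
#' moment-matched to mean 42 min / sd 16 min and truncated to 2 min-2 h.
#' During an episode the per-signal mean is shifted by `delta` with short
#' linear onset/offset ramps and the noise sd is inflated by `sd_mult`.
#'
#' @param duration_days Record length in days.
#' @param sampling_hz Sampling rate (default 0.5).
#' @param baseline_mean,baseline_sd Named per-signal baseline mean and
#'   marginal sd (HR bpm, RR breaths/min, SBP mmHg).
#' @param phi AR(1) lag-1 autocorrelation in `[0, 1)`.
#' @param episode_rate_per_day Episode arrival rate (0 disables episodes).
#' @param duration_mean_min,duration_sd_min Log-normal duration moments
#'   (minutes) before truncation.
#' @param duration_range_min Truncation bounds in minutes (default
#'   `c(2, 120)`).
#' @param delta Named per-signal within-episode mean elevation.
#' @param sd_mult Within-episode noise sd multiplier.
#' @param ramp_s Linear onset/offset ramp duration in seconds.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration_days = 14,
                       sampling_hz = 0.5,
                       baseline_mean = c(HR = 80, RR = 14, SBP = 120),
                       baseline_sd = c(HR = 5, RR = 2, SBP = 8),
                       phi = 0.95,
                       episode_rate_per_day = 4,
                       duration_mean_min = 42,
                       duration_sd_min = 16,
                       duration_range_min = c(2, 120),
                       delta = c(HR = 35, RR = 12, SBP = 45),
                       sd_mult = 2,
                       ramp_s = 30) {
  stopifnot(duration_days > 0, sampling_hz > 0,
            phi >= 0, phi < 1,
            episode_rate_per_day >= 0,
            duration_range_min[1L] < duration_range_min[2L],
            all(delta >= 0), sd_mult > 0, ramp_s >= 0,
            all(SIGNAL_KINDS %in% names(baseline_mean)),
            all(SIGNAL_KINDS %in% names(baseline_sd)),
            all(SIGNAL_KINDS %in% names(delta)))
  structure(as.list(environment()), class = "sim_config")
}

#' Control-group configuration
#'
#' Convenience wrapper: a [sim_config()] with the episode process disabled,
#' so simulated controls carry baseline physiology only and an empty truth
#' set.
#'
#' @param ... Overrides passed to [sim_config()].
#' @export
control_config <- function(...) {
  cfg <- sim_config(...)
  cfg$episode_rate_per_day <- 0
  cfg
}

# log-normal (mu, sigma) matching mean m and sd s on the natural scale
lnorm_moments <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# AR(1) noise with unit marginal variance
ar1_noise <- function(n, phi) {
  innov <- stats::rnorm(n, sd = sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive",
                           init = stats::rnorm(1)))
}

# draw episode core intervals: Poisson arrivals thinned to keep cores
# non-overlapping with inter-core gaps >= 120 s, ramps included in the record
draw_episodes <- function(cfg, span_s) {
  lambda <- cfg$episode_rate_per_day * cfg$duration_days
  if (lambda == 0) return(cbind(start = numeric(), end = numeric()))
  dmin <- cfg$duration_range_min[1L] * 60
  dmax <- cfg$duration_range_min[2L] * 60
  if (dmin + 2 * cfg$ramp_s >= span_s)
    stop("record too short to place any episode at the configured duration bounds",
         call. = FALSE)
  lm <- lnorm_moments(cfg$duration_mean_min * 60, cfg$duration_sd_min * 60)
  n_cand <- stats::rpois(1L, lambda)
  if (n_cand == 0L) return(cbind(start = numeric(), end = numeric()))
  starts <- sort(stats::runif(n_cand, cfg$ramp_s, span_s - cfg$ramp_s))
  durs <- stats::rlnorm(n_cand, lm["meanlog"], lm["sdlog"])
  durs <- pmin(pmax(durs, dmin), dmax)
  keep_s <- keep_e <- numeric()
  prev_end <- -Inf
  for (i in seq_len(n_cand)) {
    s <- starts[i]; e <- s + durs[i]
    if (s < prev_end + 120) next          # enforce >= 2 min inter-episode gap
    if (e + cfg$ramp_s > span_s) next     # episode (plus ramp) must fit
    keep_s <- c(keep_s, s); keep_e <- c(keep_e, e)
    prev_end <- e
  }
  cbind(start = keep_s, end = keep_e)
}

# piecewise-linear episode weight at times t: 0 outside, ramping to 1 over
# ramp_s before each core start and after each core end
episode_weight <- function(t, cores, ramp_s) {
  w <- numeric(length(t))
  for (i in seq_len(nrow(cores))) {
    s <- cores[i, "start"]; e <- cores[i, "end"]
    if (ramp_s > 0) {
      up <- t >= s - ramp_s & t < s
      w[up] <- pmax(w[up], (t[up] - (s - ramp_s)) / ramp_s)
      dn <- t >= e & t < e + ramp_s
      w[dn] <- pmax(w[dn], 1 - (t[dn] - e) / ramp_s)
    }
    w[t >= s & t < e] <- 1
  }
  w
}

#' Simulate one patient's vital-sign record with ground truth
#'
#' Generates HR, RR and SBP series on a shared 0.5 Hz grid: per-signal AR(1)
#' Gaussian baseline, plus episode mean shifts with linear onset/offset ramps
#' and inflated within-episode noise. Episode start times come from a Poisson
#' process at the configured rate; candidates overlapping a previous episode
#' or leaving an inter-episode gap under 2 minutes are rejected. The returned
#' truth [episode_set()] records the un-ramped core intervals. Fully
#' reproducible from the seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param patient_id Patient identifier.
#' @return A list of class `sim_patient`: `HR`, `RR`, `SBP`
#'   ([vital_series()]), `truth` ([episode_set()]), `config`, `seed`.
#' @export
simulate_patient <- function(config = sim_config(), seed = 1L, patient_id = "sim01") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  span_s <- config$duration_days * 86400
  period <- 1 / config$sampling_hz
  t <- seq(0, span_s - period, by = period)
  cores <- draw_episodes(config, span_s)
  w <- episode_weight(t, cores, config$ramp_s)
  series <- list()
  for (k in SIGNAL_KINDS) {
    z <- ar1_noise(length(t), config$phi)
    sd_t <- config$baseline_sd[[k]] * (1 + (config$sd_mult - 1) * w)
    x <- config$baseline_mean[[k]] + config$delta[[k]] * w + sd_t * z
    series[[k]] <- vital_series(patient_id, k, t, x, config$sampling_hz)
  }
  structure(list(HR = series$HR, RR = series$RR, SBP = series$SBP,
                 truth = episode_set(patient_id, cores[, "start"], cores[, "end"],
                                     source = "truth"),
                 config = config, seed = as.integer(seed)),
            class = "sim_patient")
}

#' @export
print.sim_patient <- function(x, ...) {
  cat(sprintf("<sim_patient> %s: %g days at %g Hz, %d truth episode(s)\n",
              x$HR$patient_id, x$config$duration_days, x$config$sampling_hz,
              length(x$truth)))
  invisible(x)
}

#' Simulate a case-control cohort
#'
#' Simulates `n_cases` patients under `case_config` and `n_controls` under
#' `control_config` (episode process disabled), with independent per-patient
#' seeds derived from the master seed. Optionally writes the shared-dialect
#' CSVs (`vitals.csv`, `truth_episodes.csv`, `groups.csv`) to `out_dir`.
#'
#' @param n_cases,n_controls Group sizes.
#' @param case_config,control_config [sim_config()] for each group; the
#'   control configuration must have a zero episode rate or all-zero deltas.
#' @param seed Master seed.
#' @param out_dir Optional directory for CSV output.
#' @return A list of class `sim_cohort`: `patients` (list of `sim_patient`),
#'   `groups` (data.frame `patient_id`, `label` in `{PSH+, PSH-}`), `seed`.
#' @export
simulate_cohort <- function(n_cases, n_controls,
                            case_config = sim_config(),
                            control_config = pshkit::control_config(),
                            seed = 1L, out_dir = NULL) {
  stopifnot(n_cases >= 0, n_controls >= 0)
  if (control_config$episode_rate_per_day > 0 && any(control_config$delta > 0))
    stop("control_config must have episode rate 0 or all-zero deltas", call. = FALSE)
  set.seed(as.integer(seed))
  n <- n_cases + n_controls
  seeds <- sample.int(.Machine$integer.max, n)
  ids <- c(sprintf("case%02d", seq_len(n_cases)),
           sprintf("ctrl%02d", seq_len(n_controls)))
  labels <- rep(c("PSH+", "PSH-"), c(n_cases, n_controls))
  patients <- lapply(seq_len(n), function(i)
    simulate_patient(if (labels[i] == "PSH+") case_config else control_config,
                     seed = seeds[i], patient_id = ids[i]))
  names(patients) <- ids
  groups <- data.frame(patient_id = ids, label = labels)
  cohort <- structure(list(patients = patients, groups = groups,
                           seed = as.integer(seed)),
                      class = "sim_cohort")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_vitals_csv(unlist(lapply(patients, function(p) p[SIGNAL_KINDS]),
                            recursive = FALSE),
                     file.path(out_dir, "vitals.csv"))
    write_episodes_csv(lapply(patients, function(p) p$truth),
                       file.path(out_dir, "truth_episodes.csv"))
    data.table::fwrite(groups, file.path(out_dir, "groups.csv"), eol = "\n")
  }
  cohort
}
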