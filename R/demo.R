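detect_patient <- function(hr, labeller, source, merge_gap_s = 60,
                           max_sample_gap_s = 60) {
  merge_episodes(assemble_episodes(labeller(hr), max_sample_gap_s, source = source),
                 merge_gap_s)
}

#' Run the end-to-end synthetic demo pipeline
#'
#' Simulates a small case-control cohort, filters the signals, computes the
#' hourly hrCFS, detects episodes with the expert-system rules and with an
#' SVM trained on a single simulated annotated case (mirroring a
#' single-patient training regime) applied cohort-wide, computes 12-hour
#' burden trends and 14-day summaries, and evaluates both detectors against
#' the simulated ground truth of the training case. All artifacts are written
#' to `out_dir`:
#' `vitals.csv`, `truth_episodes.csv`, `groups.csv`, `hrcfs.csv`,
#' `episodes_es.csv`, `episodes_svm.csv`, `burden.csv`, `summary.csv`,
#' `report.json`.
#'
#' @param out_dir Writable output directory (created if needed).
#' @param seed Master seed; identical seeds reproduce identical artifacts.
#' @param n_cases,n_controls Cohort sizes (default 2 + 2).
#' @param duration_days Record length per patient (default 14).
#' @param rules Expert-system [rule_set()].
#' @param merge_gap_s Episode merge threshold in seconds.
#' @return Invisibly, a list with the cohort, detected episode sets, burden
#'   trends, summary table and the evaluation report.
#' @export
run_demo <- function(out_dir, seed = 17L, n_cases = 2L, n_controls = 2L,
                     duration_days = 14, rules = rule_set(), merge_gap_s = 60) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2L) != 0L)
    stop("output directory is not writable: ", out_dir, call. = FALSE)

  cohort <- simulate_cohort(n_cases, n_controls,
                            case_config = sim_config(duration_days = duration_days),
                            control_config = control_config(duration_days = duration_days),
                            seed = seed, out_dir = out_dir)
  filtered <- lapply(cohort$patients, function(p) {
    p$HR <- filter_extreme_values(p$HR)
    p$RR <- filter_extreme_values(p$RR)
    p$SBP <- filter_extreme_values(p$SBP)
    p
  })

  hrcfs <- do.call(rbind, lapply(filtered, function(p)
    compute_hrcfs(p$HR, p$RR, p$SBP)))
  write_hrcfs_csv(hrcfs, file.path(out_dir, "hrcfs.csv"))

  es_eps <- lapply(filtered, function(p)
    detect_patient(p$HR, function(hr) label_points_es(hr, rules), "es",
                   merge_gap_s))

  # SVM trained on one simulated "annotated" case, then applied cohort-wide
  train_id <- cohort$groups$patient_id[cohort$groups$label == "PSH+"][1L]
  if (is.na(train_id)) stop("demo needs at least one case patient", call. = FALSE)
  training <- build_training_set(filtered[[train_id]]$HR,
                                 cohort$patients[[train_id]]$truth)
  model <- train_detector(training, seed = seed)
  svm_eps <- lapply(filtered, function(p)
    detect_patient(p$HR, function(hr) label_points_svm(hr, model), "svm",
                   merge_gap_s))

  write_episodes_csv(es_eps, file.path(out_dir, "episodes_es.csv"))
  write_episodes_csv(svm_eps, file.path(out_dir, "episodes_svm.csv"))

  span_s <- duration_days * 86400
  burden <- rbind(
    cbind(method = "es", do.call(rbind, lapply(es_eps, burden_trend, record_span_s = span_s))),
    cbind(method = "svm", do.call(rbind, lapply(svm_eps, burden_trend, record_span_s = span_s))))
  data.table::fwrite(burden, file.path(out_dir, "burden.csv"), eol = "\n")

  summarize_method <- function(eps_list, method) {
    s <- do.call(rbind, lapply(eps_list, summarize_first14))
    cbind(method = method, s,
          label = cohort$groups$label[match(s$patient_id, cohort$groups$patient_id)])
  }
  summary_tab <- rbind(summarize_method(es_eps, "es"), summarize_method(svm_eps, "svm"))
  data.table::fwrite(summary_tab, file.path(out_dir, "summary.csv"), eol = "\n")

  group_mean_burden <- function(method, label)
    mean(summary_tab$burden_14d[summary_tab$method == method & summary_tab$label == label])
  truth_train <- cohort$patients[[train_id]]$truth
  report <- list(
    seed = as.integer(seed),
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    duration_days = duration_days,
    training_patient = train_id,
    es = list(
      evaluation = unclass(evaluate_detection(truth_train, es_eps[[train_id]])),
      mean_burden_cases = group_mean_burden("es", "PSH+"),
      mean_burden_controls = group_mean_burden("es", "PSH-")),
    svm = list(
      evaluation = unclass(evaluate_detection(truth_train, svm_eps[[train_id]])),
      mean_burden_cases = group_mean_burden("svm", "PSH+"),
      mean_burden_controls = group_mean_burden("svm", "PSH-")))
  report$es$burden_diff <- report$es$mean_burden_cases - report$es$mean_burden_controls
  report$svm$burden_diff <- report$svm$mean_burden_cases - report$svm$mean_burden_controls
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(list(cohort = cohort, es_episodes = es_eps, svm_episodes = svm_eps,
                 burden = burden, summary = summary_tab, report = report))
}
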