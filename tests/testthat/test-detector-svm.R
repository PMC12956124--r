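# small synthetic patient shared across the SVM tests: 8 h at 0.5 Hz with
# well-separated episode physiology (baseline 80 bpm sd 5, episodes +40 bpm)
svm_fixture <- function(seed = 7, hours = 8) {
  cfg <- sim_config(duration_days = hours / 24,
                    delta = c(HR = 40, RR = 12, SBP = 45))
  p <- simulate_patient(cfg, seed = seed)
  p$HR <- filter_extreme_values(p$HR)
  p
}

test_that("rolling feature windows enumerate starts before the record end", {
  hr <- vital_series("p", "HR", seq(0, 3598, by = 2), rep(100, 1800))
  f <- extract_features(hr)
  expect_equal(nrow(f), 24L)
  expect_equal(f$start_s, seq(0, 3450, by = 150))
  expect_equal(f$mean, rep(100, 24))
  expect_equal(f$sd, rep(0, 24))
  expect_equal(f$min, rep(100, 24))
  expect_equal(f$max, rep(100, 24))
  expect_equal(f$median, rep(100, 24))
  expect_error(extract_features(hr, step_s = 0), "step_s")
})

test_that("features agree with window_stats on every window", {
  withr::local_seed(131)
  hr <- rand_series(n = 400)
  f <- extract_features(hr, window_s = 100, step_s = 40)
  for (i in seq_len(nrow(f))) {
    st <- window_stats(hr, f$start_s[i], f$end_s[i])
    expect_equal(f$mean[i], st$mean)
    expect_equal(f$sd[i], st$sd)
    expect_equal(f$min[i], st$min)
    expect_equal(f$max[i], st$max)
    expect_equal(f$median[i], st$median)
  }
})

test_that("training windows are labeled by full containment, boundaries excluded", {
  hr <- vital_series("p", "HR", seq(0, 7198, by = 2), rep(100, 3600))
  ann <- episode_set("p", 0, 1800, source = "annotation")
  tr <- build_training_set(hr, ann)
  # containment: starts <= 1200 positive; >= 1800 negative; 1350..1650 excluded
  expect_true(all(tr$features$start_s[tr$labels == "pos"] <= 1200))
  expect_true(all(tr$features$start_s[tr$labels == "neg"] >= 1800))
  expect_false(any(tr$features$start_s %in% c(1350, 1500, 1650)))
  expect_true(1200 %in% tr$features$start_s[tr$labels == "pos"])
  expect_equal(tr$n_pos + tr$n_neg, nrow(tr$features))

  expect_error(build_training_set(hr, episode_set("p", source = "annotation")),
               "no positive")
  expect_error(build_training_set(hr, episode_set("p", 0, 7200, "annotation")),
               "no negative")
})

test_that("separable classes train to perfect window classification", {
  p <- svm_fixture()
  tr <- build_training_set(p$HR, p$truth)
  model <- train_detector(tr, seed = 1)
  expect_equal(unname(predict_windows(model, tr$features)),
               tr$labels == "pos")
})

test_that("training is deterministic and the model round-trips through disk", {
  p <- svm_fixture()
  tr <- build_training_set(p$HR, p$truth)
  probe <- svm_fixture(seed = 8)

  m1 <- train_detector(tr, seed = 17)
  m2 <- train_detector(tr, seed = 17)
  expect_identical(label_points_svm(probe$HR, m1)$labels,
                   label_points_svm(probe$HR, m2)$labels)

  path <- withr::local_tempfile(fileext = ".rds")
  save_detector(m1, path)
  m3 <- load_detector(path)
  expect_identical(label_points_svm(probe$HR, m1)$labels,
                   label_points_svm(probe$HR, m3)$labels)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(), bad)
  expect_error(load_detector(bad), "model file")
})

test_that("zero-variance features fall back to unit scale with a warning", {
  hr <- vital_series("p", "HR", seq(0, 7198, by = 2),
                     rep(c(120, 80), c(1200, 2400)))
  ann <- episode_set("p", 0, 2400, source = "annotation")
  tr <- build_training_set(hr, ann)
  expect_warning(m <- train_detector(tr), "zero-variance")
  expect_true(all(m$scale > 0))
})

test_that("sample labels equal the brute-force max over covering windows", {
  p <- svm_fixture()
  tr <- build_training_set(p$HR, p$truth)
  model <- train_detector(tr, seed = 3)
  probe <- svm_fixture(seed = 9, hours = 3)
  lab <- label_points_svm(probe$HR, model)
  feats <- extract_features(probe$HR, model$window_s, model$step_s)
  votes <- predict_windows(model, feats)
  idx <- sample(length(probe$HR$timestamps), 400)
  for (i in idx) {
    t <- probe$HR$timestamps[i]
    covering <- which(feats$start_s <= t & t < feats$end_s)
    expect_identical(lab$labels[i],
                     as.integer(length(covering) && any(votes[covering])))
  }
})

test_that("all-baseline records stay negative; sustained episodes label positive", {
  p <- svm_fixture()
  tr <- build_training_set(p$HR, p$truth)
  model <- train_detector(tr, seed = 5)

  ctrl <- simulate_patient(control_config(duration_days = 1/6), seed = 11)
  expect_equal(sum(label_points_svm(filter_extreme_values(ctrl$HR), model)$labels), 0L)

  # one long sustained episode at the training episode regime
  ts <- seq(0, 7198, by = 2)
  withr::local_seed(141)
  episodic <- vital_series("sim01", "HR", ts, rnorm(length(ts), 120, 5))
  expect_true(all(label_points_svm(episodic, model)$labels == 1L))
})

test_that("detected episodes recover ground truth with high range recall", {
  p <- svm_fixture()
  tr <- build_training_set(p$HR, p$truth)
  model <- train_detector(tr, seed = 13)
  probe <- svm_fixture(seed = 10)
  eps <- merge_episodes(assemble_episodes(label_points_svm(probe$HR, model),
                                          source = "svm"))
  expect_gte(range_recall(probe$truth, eps), 0.8)
})
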