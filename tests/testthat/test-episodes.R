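test_that("episode_set validates and sorts its intervals", {
  e <- episode_set("p", c(300, 0), c(400, 100), source = "truth")
  expect_equal(e$start_s, c(0, 300))
  expect_error(episode_set("p", 0, 0), "end_s > start_s")
  expect_error(episode_set("p", c(0, 50), c(100, 150)), "overlap")
  expect_length(episode_set("p"), 0L)
})

test_that("episode CSV round-trips through the shared dialect", {
  eps <- list(episode_set("p1", c(0, 600), c(300, 1200), source = "es"),
              episode_set("p2", 100, 400, source = "truth"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_episodes_csv(eps, path)
  back <- read_episodes_csv(path)
  expect_length(back, 2L)
  expect_equal(back$p1.es$start_s, c(0, 600))
  expect_equal(back$p2.truth$end_s, 400)
  writeLines("patient_id,start_s,end_s", path)
  expect_error(read_episodes_csv(path), "source")
})

test_that("runs of positive labels become half-open episodes", {
  lab <- make_labels(seq(0, 8, by = 2), c(0, 1, 1, 1, 0))
  eps <- assemble_episodes(lab)
  expect_equal(eps$start_s, 2)
  expect_equal(eps$end_s, 8)      # one sample period past the last positive

  expect_length(assemble_episodes(make_labels(seq(0, 8, by = 2), rep(0, 5))), 0L)

  two <- assemble_episodes(make_labels(seq(0, 8, by = 2), c(1, 1, 0, 1, 1)))
  expect_equal(two$start_s, c(0, 6))
  expect_equal(two$end_s, c(4, 10))

  # a sampling gap beyond max_sample_gap_s splits a run
  gap <- assemble_episodes(make_labels(c(0, 2, 200, 202), rep(1, 4)))
  expect_equal(gap$start_s, c(0, 200))
  expect_equal(gap$end_s, c(4, 204))
})

test_that("episode assembly matches brute-force run enumeration", {
  withr::local_seed(81)
  for (i in 1:40) {
    n <- sample(5:40, 1L)
    ts <- sort(sample(seq(0, 10 * n, by = 2), n))
    labels <- sample(0:1, n, replace = TRUE)
    gap <- sample(c(10, 60, 100), 1L)
    got <- assemble_episodes(make_labels(ts, labels), gap)
    want <- brute_assemble(ts, labels, 0.5, gap)
    expect_equal(got$start_s, unname(want[, "start"]))
    expect_equal(got$end_s, unname(want[, "end"]))
  }
})

test_that("episodes merge across breaks strictly shorter than the gap", {
  m <- merge_episodes(episode_set("p", c(0, 630), c(600, 1200), source = "es"))
  expect_equal(m$start_s, 0)
  expect_equal(m$end_s, 1200)     # 30 s break < 1 min -> merged

  u <- merge_episodes(episode_set("p", c(0, 720), c(600, 1200), source = "es"))
  expect_length(u, 2L)            # 120 s break -> kept apart

  x <- merge_episodes(episode_set("p", c(0, 660), c(600, 1200), source = "es"))
  expect_length(x, 2L)            # break of exactly 60 s is NOT merged

  chain <- merge_episodes(episode_set("p", c(0, 130, 260), c(100, 230, 400),
                                      source = "es"))
  expect_equal(chain$start_s, 0)  # transitive merging collapses the chain
  expect_equal(chain$end_s, 400)
})

test_that("merging matches the fixed-point oracle and is idempotent", {
  withr::local_seed(91)
  for (i in 1:40) {
    eps <- rand_episode_set("p", source = "es", span = 400, max_n = 8L)
    gap <- sample(c(5, 20, 60), 1L)
    got <- merge_episodes(eps, gap)
    want <- brute_merge(eps$start_s, eps$end_s, gap)
    expect_equal(got$start_s, unname(want[, "start"]))
    expect_equal(got$end_s, unname(want[, "end"]))
    expect_identical(merge_episodes(got, gap), got)   # idempotent
    expect_lte(sum(eps$end_s - eps$start_s), sum(got$end_s - got$start_s) + 1e-9)
    if (length(got) > 1L)
      expect_true(all(got$start_s[-1L] - got$end_s[-length(got)] >= gap))
  }
})

test_that("burden is the clipped episode time over the frame length", {
  eps <- episode_set("p", c(0, 7200), c(3600, 10800), source = "es")  # 2 h total
  expect_equal(burden_score(eps, 0, 14400), 0.5)                      # 4-h frame
  expect_equal(burden_score(episode_set("p"), 0, 14400), 0)
  full <- episode_set("p", 0, 14400, source = "es")
  expect_equal(burden_score(full, 0, 14400), 1)
  expect_equal(burden_score(full, 7200, 14400), 1)                    # clipping
  expect_error(burden_score(full, 100, 100), "positive length")
})

test_that("burden is additive over a partition of the frame", {
  withr::local_seed(101)
  for (i in 1:20) {
    eps <- rand_episode_set("p", source = "es", span = 300)
    cut <- runif(1, 10, 290)
    whole <- burden_score(eps, 0, 300)
    parts <- (burden_score(eps, 0, cut) * cut +
                burden_score(eps, cut, 300) * (300 - cut)) / 300
    expect_equal(whole, parts)
    expect_gte(whole, 0); expect_lte(whole, 1)
  }
})

test_that("12-hour burden trend partitions a 14-day record into 28 windows", {
  eps <- episode_set("p", 3 * 43200, 4 * 43200, source = "es")  # fills window 3
  tr <- burden_trend(eps, 14 * 86400)
  expect_equal(nrow(tr), 28L)
  expect_equal(tr$window_index, 0:27)
  expect_equal(tr$burden[4L], 1)
  expect_equal(tr$burden[-4L], rep(0, 27))
  expect_true(all(diff(tr$window_start_s) == 43200))

  none <- burden_trend(episode_set("p"), 14 * 86400)
  expect_equal(none$burden, rep(0, 28))

  # trailing partial window is scored over its actual length
  part <- burden_trend(episode_set("p", 43200, 64800, source = "es"), 64800)
  expect_equal(nrow(part), 2L)
  expect_equal(part$window_end_s[2L], 64800)
  expect_equal(part$burden[2L], 1)
})

test_that("14-day summaries clip, count and average episode durations", {
  s0 <- summarize_first14(episode_set("p"))
  expect_equal(s0$n_episodes, 0L)
  expect_true(is.na(s0$mean_duration_min))
  expect_equal(s0$burden_14d, 0)

  day2 <- episode_set("p", 2 * 86400, 2 * 86400 + 42 * 60, source = "es")
  s1 <- summarize_first14(day2)
  expect_equal(s1$n_episodes, 1L)
  expect_equal(s1$mean_duration_min, 42)
  expect_equal(s1$burden_14d, 42 / (14 * 24 * 60))

  straddle <- episode_set("p", 14 * 86400 - 600, 14 * 86400 + 600, source = "es")
  s2 <- summarize_first14(straddle)
  expect_equal(s2$n_episodes, 1L)
  expect_equal(s2$mean_duration_min, 10)   # clipped at the day-14 boundary
})

test_that("Cohen's d uses the pooled sample standard deviation", {
  expect_equal(cohort_effect_size(c(2, 4, 6), c(1, 3, 5)), 0.5)
  expect_equal(cohort_effect_size(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohort_effect_size(c(1, 3, 5), c(2, 4, 6)), -0.5)  # antisymmetry
  expect_true(is.na(cohort_effect_size(c(2, 2), c(2, 2))))        # zero pooled sd
  expect_error(cohort_effect_size(1, c(1, 2)))
})

test_that("trend confidence intervals follow the t distribution", {
  tr <- data.frame(patient_id = rep(c("a", "b", "c"), each = 2),
                   window_index = rep(0:1, 3), burden = rep(0.25, 6))
  ci <- trend_ci(tr)
  expect_equal(ci$mean, c(0.25, 0.25))
  expect_equal(ci$lo, ci$hi)                 # zero-width at identical values

  two <- data.frame(patient_id = c("a", "b"), window_index = 0, burden = c(0, 1))
  ci2 <- trend_ci(two)
  half <- qt(0.975, df = 1) * sd(c(0, 1)) / sqrt(2)
  expect_equal(ci2$mean, 0.5)
  expect_equal(ci2$lo, 0.5 - half)
  expect_equal(ci2$hi, 0.5 + half)
  expect_true(ci2$lo <= ci2$mean && ci2$mean <= ci2$hi)

  one <- data.frame(patient_id = "a", window_index = 0, burden = 0.3)
  ci1 <- trend_ci(one)
  expect_equal(ci1$mean, 0.3)
  expect_true(is.na(ci1$lo))                 # <2 patients: mean only
})
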