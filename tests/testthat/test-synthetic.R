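test_that("generation is reproducible under a seed", {
  s1 <- generate_tracks(small_track_spec(5))
  s2 <- generate_tracks(small_track_spec(5))
  expect_identical(s1$fixes, s2$fixes)
  s3 <- generate_tracks(small_track_spec(6))
  expect_false(identical(s1$fixes$x, s3$fixes$x))
})

test_that("truth counts equal the schedule ticks inside each bout", {
  spec <- track_spec(
    animal_ids = "A1",
    period_start = "2020-05-01 00:00:00", period_end = "2020-05-03 23:59:59",
    fix_interval_minutes = 60,
    bouts = data.frame(animal_id = "A1", center_x = 500000, center_y = 6800000,
                       start = "2020-05-02 03:00:00", end = "2020-05-02 08:00:00",
                       scatter_sd_m = 5),
    travel_step_m = 400, seed = 9)
  gen <- generate_tracks(spec)
  expect_equal(gen$truth$expected_n, 6L)  # 03:00..08:00 inclusive
  # the planted fixes really are near the center
  at <- gen$fixes$timestamp >= gen$truth$start & gen$fixes$timestamp <= gen$truth$end
  expect_equal(sum(at), 6L)
  d <- sqrt((gen$fixes$x[at] - 500000)^2 + (gen$fixes$y[at] - 6800000)^2)
  expect_true(all(d < 30))
})

test_that("a single planted bout is recovered with an accurate mean center", {
  spec <- track_spec(
    animal_ids = "A1",
    period_start = "2020-05-01 00:00:00", period_end = "2020-05-02 23:59:59",
    fix_interval_minutes = 60,
    bouts = data.frame(animal_id = "A1", center_x = 500000, center_y = 6800000,
                       start = "2020-05-01 10:00:00", end = "2020-05-01 14:00:00",
                       scatter_sd_m = 5),
    travel_step_m = 500, seed = 17)
  gen <- generate_tracks(spec)
  expect_equal(gen$truth$expected_n, 5L)
  res <- run_analysis(gen$fixes, test_config(buffer_m = 30, min_locations = 2))
  expect_equal(nrow(res$clusters), 1L)
  expect_equal(res$clusters$n_inside, 5L)
  err <- sqrt((res$clusters$mean_x - 500000)^2 + (res$clusters$mean_y - 6800000)^2)
  expect_lt(err, 3 * 5 / sqrt(5))  # 3 sigma of the mean of 5 scattered fixes
})

test_that("zero scatter gives coincident fixes and a single-disc polygon", {
  spec <- track_spec(
    animal_ids = "A1",
    period_start = "2020-05-01 00:00:00", period_end = "2020-05-01 23:59:59",
    fix_interval_minutes = 60,
    bouts = data.frame(animal_id = "A1", center_x = 500000, center_y = 6800000,
                       start = "2020-05-01 05:00:00", end = "2020-05-01 09:00:00",
                       scatter_sd_m = 0),
    travel_step_m = 400, seed = 2)
  gen <- generate_tracks(spec)
  at <- gen$fixes$timestamp >= gen$truth$start & gen$fixes$timestamp <= gen$truth$end
  expect_equal(length(unique(gen$fixes$x[at])), 1L)
  res <- run_analysis(gen$fixes, test_config(buffer_m = 30, min_locations = 2))
  expect_equal(attr(res$clusters$polygon[[1]], "area"), pi * 900,
               tolerance = 0.01)
})

test_that("overlapping bouts are rejected", {
  expect_error(track_spec(
    animal_ids = "A1",
    period_start = "2020-05-01", period_end = "2020-05-10 23:59:59",
    bouts = data.frame(animal_id = "A1", center_x = c(0, 100), center_y = 0,
                       start = c("2020-05-02 00:00:00", "2020-05-02 12:00:00"),
                       end = c("2020-05-03 00:00:00", "2020-05-03 12:00:00"),
                       scatter_sd_m = 5)), "overlapping")
})

test_that("the case-study scenario recovers all planted bouts", {
  sc <- scenario_case_study(seed = 104)
  expect_equal(length(unique(sc$fixes$animal_id)), 3L)
  expect_true(all(sc$truth$expected_n >= 2))
  res <- run_analysis(sc$fixes, sc$config)
  got <- table(res$clusters$animal_id)
  want <- table(sc$truth$animal_id)
  expect_equal(as.vector(got[names(want)]), as.vector(want))
  # each recovered cluster sits on a planted center
  for (i in seq_len(nrow(res$clusters))) {
    cl <- res$clusters[i, ]
    tr <- sc$truth[sc$truth$animal_id == cl$animal_id, ]
    d <- sqrt((tr$center_x - cl$mean_x)^2 + (tr$center_y - cl$mean_y)^2)
    expect_lt(min(d), 30)
  }
})

test_that("burst fixes sit between ticks and vanish under the z filter", {
  sc <- scenario_case_study(seed = 104)
  mins <- as.integer(format(sc$fixes$timestamp, "%M"))
  expect_gt(sum(mins != 0), 0)  # the burst added off-schedule fixes
  sub <- subsample_fixes(sc$fixes, 60)
  expect_equal(sum(as.integer(format(sub$timestamp, "%M")) != 0), 0L)
  # and preprocessing therefore analyses the nominal schedule only
  pp <- preprocess_fixes(sc$fixes, sc$config)
  expect_equal(nrow(pp), nrow(sc$fixes) - sum(mins != 0))
})

test_that("the packaged scenario excerpt loads through read_fixes", {
  path <- system.file("extdata", "synthetic_fixes_excerpt.csv",
                      package = "fixclust")
  expect_true(nzchar(path))
  cfg <- test_config(label = "demo_bears", subsample_minutes = 60,
                     period_start = "2014-05-01 00:00:00",
                     period_end = "2014-05-31 23:59:59")
  got <- expect_silent(read_fixes(path, list(animal = "animal_id",
                                             timestamp = "timestamp",
                                             x = "x", y = "y"), cfg))
  expect_gt(nrow(got), 100)
  expect_equal(attr(got, "report")$n_dropped_nonfinite, 0L)
})

test_that("a travelling animal with no bouts produces no clusters", {
  for (seed in 1:5) {
    spec <- track_spec(animal_ids = "A1",
                       period_start = "2020-05-01 00:00:00",
                       period_end = "2020-05-31 23:59:59",
                       fix_interval_minutes = 60,
                       travel_step_m = 300, seed = seed)
    gen <- generate_tracks(spec)
    res <- run_analysis(gen$fixes, test_config(buffer_m = 30, min_locations = 2))
    expect_equal(nrow(res$clusters), 0L, info = sprintf("seed %d", seed))
  }
})
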