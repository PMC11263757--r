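test_that("study period filtering uses a closed interval", {
  cfg <- test_config(period_start = "2020-05-01 00:00:00",
                     period_end = "2020-05-31 23:59:59")
  f <- rbind(
    fx(0, 0, base = as.POSIXct("2020-05-01 00:00:00", tz = "UTC")),
    fx(0, 10, base = as.POSIXct("2020-05-16 12:00:00", tz = "UTC")),
    fx(0, 20, base = as.POSIXct("2020-05-31 23:59:59", tz = "UTC")))
  expect_equal(nrow(filter_period(f, cfg)), 3L)
  late <- fx(0, 0, base = as.POSIXct("2020-04-30 23:59:00", tz = "UTC"))
  expect_equal(nrow(filter_period(late, cfg)), 0L)
  expect_equal(nrow(filter_period(f[0, ], cfg)), 0L)
})

test_that("greedy subsampling keeps the hand-traced fixes", {
  f <- fx(c(0, 10, 20, 30, 40, 60), seq(0, 500, 100))
  out <- subsample_fixes(f, 30)
  expect_equal(as.numeric(out$timestamp - out$timestamp[1], units = "mins"),
               c(0, 30, 60))
  # a schedule already at z passes through untouched
  reg <- fx(seq(0, 600, 60), seq(0, 1000, 100))
  expect_equal(subsample_fixes(reg, 60)[, 1:4], reg)
  # z = 0 means all data
  expect_equal(subsample_fixes(f, 0)[, 1:4], f)
})

test_that("a burst collapses to at most one fix per window", {
  sched <- seq(0, 600, 60)
  burst <- seq(181, 239, 1)  # 1-min proximity burst between two ticks
  f <- fx(sort(c(sched, burst)), seq_along(c(sched, burst)) * 100)
  out <- subsample_fixes(f, 60)
  expect_lt(nrow(out), nrow(f))
  gaps <- diff(as.numeric(out$timestamp)) / 60
  expect_true(all(gaps >= 60))
})

test_that("subsampling is idempotent and respects the z-minute floor", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(10:80, 1)
    mins <- sort(sample(0:2000, n))
    z <- sample(c(5, 15, 30, 60), 1)
    f <- fx(mins, seq_len(n))
    once <- subsample_fixes(f, z)
    twice <- subsample_fixes(once, z)
    expect_equal(twice, once)
    if (nrow(once) > 1)
      expect_true(all(diff(as.numeric(once$timestamp)) / 60 >= z))
  }
})

test_that("subsampling is applied per animal independently", {
  f <- rbind(fx(c(0, 20, 40, 60), 1:4, animal = "A"),
             fx(c(10, 30, 50, 70), 1:4, animal = "B"))
  f <- f[order(f$animal_id, f$timestamp), ]
  out <- subsample_fixes(f, 40)
  expect_equal(sum(out$animal_id == "A"), 2L)  # 0, 40
  expect_equal(sum(out$animal_id == "B"), 2L)  # 10, 50
})

test_that("validation sorts, deduplicates and drops bad coordinates", {
  f <- fx(c(30, 0, 60, 30), c(1, 2, 3, 1))
  f$x[3] <- NaN
  out <- validate_fixes(f)
  rep <- attr(out, "report")
  expect_equal(nrow(out), 2L)
  expect_false(is.unsorted(out$timestamp))
  expect_equal(rep$n_dropped_nonfinite, 1L)
  expect_equal(rep$n_dropped_duplicate, 1L)
  allbad <- fx(c(0, 10), c(NA, NaN))
  expect_error(validate_fixes(allbad), "no usable fixes")
})
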