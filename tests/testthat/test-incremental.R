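cfg_inc <- test_config(buffer_m = 30, min_locations = 2)

test_that("new sites get fresh IDs while previous IDs are kept", {
  old <- rbind(fx(c(0, 60), c(0, 10)), fx(c(120, 180), c(2000, 2010)))
  r1 <- run_analysis(old, cfg_inc)
  expect_equal(r1$clusters$cluster_id, c("W1_1", "W1_2"))
  new <- rbind(old, fx(c(240, 300), c(7000, 7005)))
  rec <- reconcile(run_analysis(new, cfg_inc), as_previous(r1), cfg_inc)
  expect_setequal(rec$report$kept_ids, c("W1_1", "W1_2"))
  expect_equal(rec$report$new_ids, "W1_3")
  expect_equal(nrow(rec$report$merged), 0L)
  expect_equal(rec$result$clusters$state, c("New", "New", "New"))
})

test_that("a bridging fix merges clusters under the lowest surviving ID", {
  old <- rbind(fx(c(0, 60), c(0, 10)), fx(c(120, 180), c(110, 120)))
  r1 <- run_analysis(old, cfg_inc)
  r1$clusters$event <- c("bed site", "carcass")
  r1$clusters$technician <- c("", "AT")
  bridged <- rbind(old, fx(300, 60))
  rec <- reconcile(run_analysis(bridged, cfg_inc), as_previous(r1), cfg_inc)
  expect_equal(rec$result$clusters$cluster_id, "W1_1")
  expect_equal(rec$result$clusters$state, "Grown")
  expect_equal(rec$report$merged$absorbed_id, "W1_2")
  expect_equal(rec$report$merged$surviving_id, "W1_1")
  # editable columns conserved: survivor keeps its own, absorbed folded into notes
  expect_equal(rec$result$clusters$event, "bed site")
  expect_match(rec$result$clusters$notes, "carcass")
  expect_match(rec$result$clusters$notes, "AT")
  # an absorbed seq number is never reissued
  more <- rbind(bridged, fx(c(360, 420), c(5000, 5010)))
  rec2 <- reconcile(run_analysis(more, cfg_inc), as_previous(rec$result), cfg_inc)
  expect_equal(rec2$report$new_ids, "W1_3")
})

test_that("re-running with no new fixes reproduces the previous analysis", {
  old <- rbind(fx(c(0, 60), c(0, 10)), fx(c(120, 180), c(2000, 2010)))
  r1 <- run_analysis(old, cfg_inc)
  r1$clusters$event <- c("scat", "")
  r1$clusters$state <- c("Done", "New")
  rec <- reconcile(run_analysis(old, cfg_inc), as_previous(r1), cfg_inc)
  expect_setequal(rec$report$kept_ids, c("W1_1", "W1_2"))
  expect_length(rec$report$grown_ids, 0)
  expect_length(rec$report$new_ids, 0)
  got <- rec$result$clusters[order(rec$result$clusters$seq_number), ]
  expect_equal(got$state, c("Done", "New"))
  expect_equal(got$event, c("scat", ""))
})

test_that("growth keeps the ID and flips state to Grown", {
  old <- fx(c(0, 60), c(0, 10))
  r1 <- run_analysis(old, cfg_inc)
  grown <- rbind(old, fx(120, 20))
  rec <- reconcile(run_analysis(grown, cfg_inc), as_previous(r1), cfg_inc)
  expect_equal(rec$result$clusters$cluster_id, "W1_1")
  expect_equal(rec$result$clusters$state, "Grown")
  expect_equal(rec$report$grown_ids, "W1_1")
})

test_that("mark_done_on_import marks imported clusters Done", {
  cfg_done <- test_config(buffer_m = 30, min_locations = 2,
                          mark_done_on_import = TRUE)
  old <- rbind(fx(c(0, 60), c(0, 10)), fx(c(120, 180), c(2000, 2010)))
  r1 <- run_analysis(old, cfg_done)
  rec <- reconcile(run_analysis(old, cfg_done), as_previous(r1), cfg_done)
  expect_equal(rec$result$clusters$state, c("Done", "Done"))
})

test_that("parameter changes between runs are refused, naming the fields", {
  old <- fx(c(0, 60), c(0, 10))
  r1 <- run_analysis(old, cfg_inc)
  cfg_big <- test_config(buffer_m = 50, min_locations = 3)
  err <- tryCatch(reconcile(run_analysis(old, cfg_big), as_previous(r1), cfg_big),
                  error = conditionMessage)
  expect_match(err, "buffer_m")
  expect_match(err, "min_locations")
})

test_that("a truncated fix file is detected", {
  old <- rbind(fx(c(0, 60), c(0, 10)), fx(c(120, 180), c(2000, 2010)))
  r1 <- run_analysis(old, cfg_inc)
  cut <- old[-1, ]  # first member of W1_1 missing
  expect_error(reconcile(run_analysis(cut, cfg_inc), as_previous(r1), cfg_inc),
               "absent")
})

test_that("incremental analysis equals batch analysis across random splits", {
  set.seed(61)
  for (ds in 1:3) {
    gen <- generate_tracks(small_track_spec(ds))
    cfg <- test_config(buffer_m = 30, min_locations = 2,
                       period_end = "2020-05-05 23:59:59")
    ts <- sort(unique(gen$fixes$timestamp))
    splits <- sample(ts, 5)
    for (sp in splits) {
      expect_true(batch_equivalence_check(gen$fixes, sp, cfg),
                  info = sprintf("dataset %d split %s", ds,
                                 format(as.POSIXct(sp, tz = "UTC", origin = "1970-01-01"))))
    }
    # degenerate splits
    expect_true(batch_equivalence_check(gen$fixes, min(ts) - 1, cfg))
    expect_true(batch_equivalence_check(gen$fixes, max(ts) + 1, cfg))
  }
})

test_that("reconciliation reports partition all previous IDs", {
  set.seed(62)
  gen <- generate_tracks(small_track_spec(9))
  cfg <- test_config(buffer_m = 30, min_locations = 2,
                     period_end = "2020-05-05 23:59:59")
  ts <- sort(unique(gen$fixes$timestamp))
  sp <- ts[round(length(ts) / 2)]
  first <- run_analysis(gen$fixes[gen$fixes$timestamp <= sp, ], cfg)
  rec <- reconcile(run_analysis(gen$fixes, cfg), as_previous(first), cfg)
  rep <- rec$report
  accounted <- c(rep$kept_ids, rep$grown_ids, rep$merged$absorbed_id)
  # surviving ids of merges were previous ids too
  accounted <- union(accounted, intersect(rep$merged$surviving_id,
                                          first$clusters$cluster_id))
  expect_setequal(accounted, first$clusters$cluster_id)
  expect_length(intersect(rep$new_ids, first$clusters$cluster_id), 0)
})

test_that("reconciliation report serialises to CSV", {
  old <- rbind(fx(c(0, 60), c(0, 10)), fx(c(120, 180), c(2000, 2010)))
  r1 <- run_analysis(old, cfg_inc)
  new <- rbind(old, fx(c(240, 300), c(7000, 7005)))
  rec <- reconcile(run_analysis(new, cfg_inc), as_previous(r1), cfg_inc)
  path <- withr::local_tempfile(fileext = ".csv")
  write_reconciliation(rec$report, path)
  tab <- read.csv(path)
  expect_setequal(tab$action, c("kept", "new"))
  expect_equal(sum(tab$action == "kept"), 2L)
})
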