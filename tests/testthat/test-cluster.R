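test_that("buffer overlap at most 2x forms a cluster; beyond it does not", {
  cfg <- test_config(buffer_m = 30, min_locations = 2)
  near <- fx(c(0, 60), c(0, 50))   # 50 m <= 60 m
  p <- find_clusters(near, cfg)
  expect_equal(p$clusters, list(c(1L, 2L)))
  expect_equal(p$singles, integer(0))
  far <- fx(c(0, 60), c(0, 70))    # 70 m > 60 m
  p2 <- find_clusters(far, cfg)
  expect_equal(p2$clusters, list())
  expect_equal(p2$singles, c(1L, 2L))
  # tangent buffers (exactly 2x apart) count as overlapping
  tangent <- fx(c(0, 60), c(0, 60))
  expect_equal(find_clusters(tangent, cfg)$clusters, list(c(1L, 2L)))
})

test_that("transitive overlap chains into one cluster", {
  cfg <- test_config(buffer_m = 30, min_locations = 3)
  chain <- fx(c(0, 60, 120), c(0, 55, 110))
  p <- find_clusters(chain, cfg)
  expect_equal(canon_partition(p),
               canon_partition(oracle_partition(chain$x, chain$y, 30, 3)))
  expect_equal(p$clusters, list(1:3))
})

test_that("degenerate inputs produce no clusters", {
  cfg <- test_config()
  expect_equal(find_clusters(fx(numeric(0), numeric(0)), cfg),
               list(clusters = list(), singles = integer(0)))
  expect_equal(find_clusters(fx(0, 0), cfg),
               list(clusters = list(), singles = 1L))
})

test_that("consecutive mode ignores non-sequential overlap", {
  cfg_c <- test_config(buffer_m = 30, min_locations = 2, consecutive_only = TRUE)
  cfg_d <- test_config(buffer_m = 30, min_locations = 2)
  # A at origin, B 500 m away, C back next to A: A and C overlap but are
  # not sequential in time
  abc <- fx(c(0, 60, 120), c(0, 500, 10))
  pc <- find_clusters_consecutive(abc, cfg_c)
  expect_equal(pc$clusters, list())
  expect_equal(pc$singles, 1:3)
  pd <- find_clusters(abc, cfg_d)
  expect_equal(pd$clusters, list(c(1L, 3L)))
  expect_equal(pd$singles, 2L)
})

test_that("consecutive runs form and break as hand-traced", {
  cfg4 <- test_config(buffer_m = 30, min_locations = 4, consecutive_only = TRUE)
  walk <- fx(c(0, 60, 120, 180), c(0, 40, 80, 120))  # each step 40 <= 60
  expect_equal(find_clusters_consecutive(walk, cfg4)$clusters, list(1:4))
  cfg3 <- test_config(buffer_m = 30, min_locations = 3, consecutive_only = TRUE)
  jump <- fx(c(0, 60, 120, 180, 240, 300),
             c(0, 10, 20, 520, 530, 540))  # 500 m jump splits two runs of 3
  p <- find_clusters_consecutive(jump, cfg3)
  expect_equal(p$clusters, list(1:3, 4:6))
})

test_that("grid-binned clustering matches the brute-force oracle", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(20:200, 1)
    spread <- sample(c(300, 800, 2000), 1)
    buffer <- sample(c(15, 30, 50), 1)
    minloc <- sample(2:4, 1)
    inst <- random_instance(n, spread)
    cfg <- test_config(buffer_m = buffer, min_locations = minloc)
    got <- find_clusters(inst, cfg)
    want <- oracle_partition(inst$x, inst$y, buffer, minloc)
    expect_equal(canon_partition(got), canon_partition(want),
                 info = sprintf("instance %d (n=%d buffer=%g min=%d)",
                                i, n, buffer, minloc))
  }
})

test_that("multi-animal tables are rejected by the per-animal API", {
  cfg <- test_config()
  two <- rbind(fx(0, 0, animal = "A"), fx(0, 1, animal = "B"))
  expect_error(find_clusters(two, cfg), "one animal")
})
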