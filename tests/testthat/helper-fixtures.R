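# Shared fixture builders and independent oracles.

# a config with sensible defaults for tests
test_config <- function(buffer_m = 30, min_locations = 2,
                        consecutive_only = FALSE, subsample_minutes = 0,
                        label = "teststudy",
                        period_start = "2020-05-01 00:00:00",
                        period_end = "2020-05-31 23:59:59",
                        crs_epsg = 32633, ...) {
  study_config(label = label, buffer_m = buffer_m,
               min_locations = min_locations,
               consecutive_only = consecutive_only,
               subsample_minutes = subsample_minutes,
               period_start = period_start, period_end = period_end,
               crs_epsg = crs_epsg, ...)
}

# fixes at minute offsets from a base time, coordinates offset from a UTM
# point well inside zone 33
fx <- function(mins, x, y = 0, animal = "W1",
               base = as.POSIXct("2020-05-02 00:00:00", tz = "UTC")) {
  tibble::tibble(animal_id = animal, timestamp = base + mins * 60,
                 x = 500000 + x, y = 6800000 + y)
}

# independent clustering oracle: full O(n^2) distance matrix + igraph
# connected components (different route from the package's grid-binned
# union-find)
oracle_partition <- function(x, y, buffer_m, min_locations) {
  n <- length(x)
  if (n == 0) return(list(clusters = list(), singles = integer(0)))
  adj <- as.matrix(stats::dist(cbind(x, y))) <= 2 * buffer_m
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  groups <- split(seq_len(n), memb)
  big <- groups[lengths(groups) >= min_locations]
  big <- lapply(big, sort)
  big <- big[order(vapply(big, `[`, integer(1), 1L))]
  names(big) <- NULL
  singles <- sort(unlist(groups[lengths(groups) < min_locations],
                         use.names = FALSE))
  if (is.null(singles)) singles <- integer(0)
  list(clusters = big, singles = singles)
}

# canonical form of a partition for comparison
canon_partition <- function(p) {
  list(clusters = lapply(p$clusters, as.integer), singles = as.integer(p$singles))
}

# random fix table whose density produces a mix of clusters and singles
random_instance <- function(n, spread_m, animal = "A1",
                            base = as.POSIXct("2020-05-05 00:00:00", tz = "UTC")) {
  tibble::tibble(animal_id = animal,
                 timestamp = base + seq_len(n) * 3600,
                 x = 500000 + stats::runif(n, 0, spread_m),
                 y = 6800000 + stats::runif(n, 0, spread_m))
}

# small synthetic dataset with a handful of planted bouts, cheap enough for
# property loops
small_track_spec <- function(seed, n_animals = 2, days = 5) {
  start <- "2020-05-01 00:00:00"
  end <- sprintf("2020-05-%02d 23:59:59", days)
  animals <- paste0("A", seq_len(n_animals))
  rows <- list()
  set.seed(seed * 7919)
  for (ai in seq_along(animals)) {
    n_bouts <- sample(2:3, 1)
    day_starts <- sort(sample(seq_len(days) - 1, n_bouts))
    ang <- stats::runif(1, 0, 2 * pi)
    cx <- 400000 + ai * 30000; cy <- 6700000
    prev_end <- NULL
    for (b in seq_len(n_bouts)) {
      s <- as.POSIXct(start, tz = "UTC") + day_starts[b] * 86400 +
        sample(0:5, 1) * 3600
      e <- s + sample(3:9, 1) * 3600
      if (b > 1) {
        gap_ticks <- max(1, round(as.numeric(s - prev_end, units = "hours")))
        d <- 130 * (gap_ticks + 1)
        cx <- cx + d * cos(ang); cy <- cy + d * sin(ang)
      }
      prev_end <- e
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = animals[ai], center_x = cx, center_y = cy,
        start = s, end = e, scatter_sd_m = 7)
    }
  }
  track_spec(animal_ids = animals, period_start = start, period_end = end,
             fix_interval_minutes = 60, bouts = do.call(rbind, rows),
             travel_step_m = 400, crs_epsg = 32633, seed = seed)
}

# membership of every point inside the polygon (independent point-in-polygon
# oracle via mgcv::in.out, even-odd rule with ring breaks)
points_in_polygon <- function(poly, px, py) {
  bnd <- do.call(rbind, lapply(poly, function(r) rbind(r, c(NA, NA))))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  mgcv::in.out(bnd, cbind(px, py))
}
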