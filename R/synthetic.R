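# Synthetic GPS tracks with planted activity clusters. The movement model
# contrasts two regimes, which is all a clustering validation needs:
#
# * stationary bouts — fixes scatter isotropically (Gaussian) around a
#   planted center for the bout's duration;
# * directed travel — between bouts the animal transits in a straight line
#   at constant per-fix displacement with small cross-track jitter; before
#   the first and after the last bout (and for bout-free animals) it walks
#   with a persistent per-animal drift heading and turning noise capped at
#   +/- 45 degrees.
#
# Capped-turn directional travel makes progress along the drift axis exceed
# half the step length every fix, so a travelling animal never re-approaches
# its old positions: spurious clusters cannot arise from travel itself.
# Real animal movement is messier (revisits, tortuous foraging); what this
# generator validates is recovery of true stationary bouts against a moving
# background, not behaviour on arbitrary real data.
#
# Optional burst episodes insert extra fixes between the schedule ticks at a
# faster interval, mimicking proximity-sensor collars; truth counts are
# defined by schedule ticks only, so a z-minute subsample equal to the
# schedule interval restores the planted truth exactly.

#' Specify a synthetic track
#'
#' @param animal_ids character vector of animal labels.
#' @param period_start,period_end study period (UTC).
#' @param fix_interval_minutes nominal fix schedule, minutes (default 60).
#' @param bouts data.frame with columns `animal_id`, `center_x`, `center_y`
#'   (meters, projected), `start`, `end` (timestamps), `scatter_sd_m`
#'   (isotropic Gaussian scatter during the bout). Bouts of one animal must
#'   not overlap in time and must lie inside the period.
#' @param travel_step_m mean displacement per fix while travelling (meters).
#' @param burst optional list with `animal_id`, `window_start`,
#'   `window_end`, `burst_interval_minutes`: extra fixes inserted at that
#'   interval inside the window (off the nominal schedule).
#' @param crs_epsg projected CRS the coordinates live in (default 32633,
#'   UTM 33N).
#' @param seed integer seed; generation is bit-for-bit reproducible.
#' @return An object of class `fixclust_trackspec`.
#' @export
track_spec <- function(animal_ids,
                       period_start, period_end,
                       fix_interval_minutes = 60,
                       bouts = NULL,
                       travel_step_m = 400,
                       burst = NULL,
                       crs_epsg = 32633,
                       seed = 1L) {
  period_start <- .as_utc(period_start)
  period_end <- .as_utc(period_end)
  stopifnot(period_start < period_end, fix_interval_minutes > 0,
            travel_step_m > 0)
  if (is.null(bouts)) {
    bouts <- data.frame(animal_id = character(0), center_x = numeric(0),
                        center_y = numeric(0), start = .as_utc(character(0)),
                        end = .as_utc(character(0)), scatter_sd_m = numeric(0))
  } else {
    bouts <- as.data.frame(bouts)
    bouts$start <- .as_utc(bouts$start)
    bouts$end <- .as_utc(bouts$end)
    stopifnot(all(c("animal_id", "center_x", "center_y", "start", "end",
                    "scatter_sd_m") %in% names(bouts)),
              all(bouts$scatter_sd_m >= 0),
              all(bouts$start < bouts$end))
    if (any(bouts$start < period_start) || any(bouts$end > period_end))
      stop("bout intervals must lie within the study period")
    bouts <- bouts[order(bouts$animal_id, bouts$start), , drop = FALSE]
    for (a in unique(bouts$animal_id)) {
      b <- bouts[bouts$animal_id == a, , drop = FALSE]
      if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
        stop("overlapping bouts for animal ", a)
    }
  }
  if (!is.null(burst)) {
    stopifnot(all(c("animal_id", "window_start", "window_end",
                    "burst_interval_minutes") %in% names(burst)))
    burst$window_start <- .as_utc(burst$window_start)
    burst$window_end <- .as_utc(burst$window_end)
  }
  structure(list(animal_ids = as.character(animal_ids),
                 period_start = period_start, period_end = period_end,
                 fix_interval_minutes = fix_interval_minutes,
                 bouts = bouts, travel_step_m = travel_step_m,
                 burst = burst, crs_epsg = crs_epsg,
                 seed = as.integer(seed)),
            class = "fixclust_trackspec")
}

#' Generate synthetic GPS fixes with planted truth
#'
#' @param spec a [track_spec()].
#' @return A list with `fixes` (fix tibble, all animals interleaved in
#'   time-sorted order per animal) and `truth` (tibble, one row per planted
#'   bout: `animal_id`, `center_x`, `center_y`, `start`, `end`,
#'   `expected_n` = number of schedule ticks inside the bout interval).
#' @export
generate_tracks <- function(spec) {
  stopifnot(inherits(spec, "fixclust_trackspec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  dt <- spec$fix_interval_minutes * 60
  ticks <- seq(as.numeric(spec$period_start), as.numeric(spec$period_end), by = dt)
  all_rows <- list()
  truth_rows <- list()
  for (ai in seq_along(spec$animal_ids)) {
    animal <- spec$animal_ids[ai]
    b <- spec$bouts[spec$bouts$animal_id == animal, , drop = FALSE]
    # the travel axis: with planted bouts it follows the bout transect, so
    # approach, transits and departure all progress the same way and the
    # track stays globally self-avoiding; bout-free animals draw a random
    # heading
    drift <- stats::runif(1, 0, 2 * pi)
    if (nrow(b) >= 2) {
      dxy <- c(b$center_x[nrow(b)] - b$center_x[1],
               b$center_y[nrow(b)] - b$center_y[1])
      if (any(dxy != 0)) drift <- atan2(dxy[2], dxy[1])
    }
    # phase of each tick: bout index or 0 = travel
    phase <- integer(length(ticks))
    for (bi in seq_len(nrow(b))) {
      inb <- ticks >= as.numeric(b$start[bi]) & ticks <= as.numeric(b$end[bi])
      phase[inb] <- bi
      truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
        animal_id = animal, center_x = b$center_x[bi], center_y = b$center_y[bi],
        start = b$start[bi], end = b$end[bi], expected_n = sum(inb))
    }
    pos <- matrix(NA_real_, length(ticks), 2)
    # bout fixes: center + isotropic scatter
    for (bi in seq_len(nrow(b))) {
      at <- which(phase == bi)
      pos[at, 1] <- b$center_x[bi] + stats::rnorm(length(at), 0, b$scatter_sd_m[bi])
      pos[at, 2] <- b$center_y[bi] + stats::rnorm(length(at), 0, b$scatter_sd_m[bi])
    }
    if (nrow(b) == 0) {
      # bout-free: pure directional walk from a per-animal origin
      origin <- c(ai * 50000, 0)
      pos <- .drift_walk(origin, drift, length(ticks), spec$travel_step_m)
    } else {
      # before the first bout: approach along the drift axis (built backward
      # from the first bout center so arrival coincides with bout start)
      pre <- which(ticks < as.numeric(b$start[1]))
      if (length(pre) > 0) {
        back <- .drift_walk(c(b$center_x[1], b$center_y[1]), drift + pi,
                            length(pre) + 1L, spec$travel_step_m)
        pos[rev(pre), ] <- back[-1, , drop = FALSE]
      }
      # between bouts: straight-line transit at constant per-fix displacement
      for (bi in seq_len(nrow(b) - 1L)) {
        gap <- which(ticks > as.numeric(b$end[bi]) &
                       ticks < as.numeric(b$start[bi + 1L]))
        if (length(gap) == 0) next
        a0 <- c(b$center_x[bi], b$center_y[bi])
        a1 <- c(b$center_x[bi + 1L], b$center_y[bi + 1L])
        fr <- seq_along(gap) / (length(gap) + 1L)
        pos[gap, 1] <- a0[1] + fr * (a1[1] - a0[1]) + stats::rnorm(length(gap), 0, 5)
        pos[gap, 2] <- a0[2] + fr * (a1[2] - a0[2]) + stats::rnorm(length(gap), 0, 5)
      }
      # after the last bout: depart along the drift axis
      post <- which(ticks > as.numeric(b$end[nrow(b)]))
      if (length(post) > 0) {
        fwd <- .drift_walk(c(b$center_x[nrow(b)], b$center_y[nrow(b)]), drift,
                           length(post) + 1L, spec$travel_step_m)
        pos[post, ] <- fwd[-1, , drop = FALSE]
      }
    }
    t_all <- ticks
    # burst episode: extra off-schedule fixes
    bu <- spec$burst
    if (!is.null(bu) && identical(as.character(bu$animal_id), animal)) {
      bt <- seq(as.numeric(bu$window_start), as.numeric(bu$window_end),
                by = bu$burst_interval_minutes * 60)
      bt <- setdiff(bt, ticks)
      if (length(bt) > 0) {
        bpos <- .interp_positions(bt, ticks, pos, b)
        t_all <- c(t_all, bt)
        pos <- rbind(pos, bpos)
      }
    }
    ord <- order(t_all)
    all_rows[[ai]] <- tibble::tibble(
      animal_id = animal,
      timestamp = as.POSIXct(t_all[ord], tz = "UTC", origin = "1970-01-01"),
      x = pos[ord, 1], y = pos[ord, 2])
  }
  fixes <- do.call(rbind, all_rows)
  truth <- if (length(truth_rows) > 0) do.call(rbind, truth_rows) else
    tibble::tibble(animal_id = character(0), center_x = numeric(0),
                   center_y = numeric(0), start = .as_utc(character(0)),
                   end = .as_utc(character(0)), expected_n = integer(0))
  list(fixes = .as_fix_tibble(fixes), truth = truth)
}

# directional walk: heading = drift + uniform(-45, +45) degrees, step length
# uniform in [0.9, 1.1] * step. Progress along the drift axis is at least
# 0.9 * cos(45 deg) ~ 0.64 of a step every fix, so the path never loops back.
.drift_walk <- function(origin, drift, n, step) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  head_ <- drift + stats::runif(n - 1, -pi / 4, pi / 4)
  len <- step * stats::runif(n - 1, 0.9, 1.1)
  dx <- c(0, cumsum(len * cos(head_)))
  dy <- c(0, cumsum(len * sin(head_)))
  cbind(origin[1] + dx, origin[2] + dy)
}

# positions for off-schedule burst fixes: inside a bout, scatter around its
# center; otherwise linear interpolation between the bracketing tick
# positions
.interp_positions <- function(bt, ticks, pos, bouts) {
  out <- matrix(NA_real_, length(bt), 2)
  for (i in seq_along(bt)) {
    t <- bt[i]
    bi <- which(t >= as.numeric(bouts$start) & t <= as.numeric(bouts$end))
    if (length(bi) == 1) {
      out[i, ] <- c(bouts$center_x[bi] + stats::rnorm(1, 0, bouts$scatter_sd_m[bi]),
                    bouts$center_y[bi] + stats::rnorm(1, 0, bouts$scatter_sd_m[bi]))
    } else {
      lo <- findInterval(t, ticks)
      lo <- min(max(lo, 1L), length(ticks) - 1L)
      f <- (t - ticks[lo]) / (ticks[lo + 1L] - ticks[lo])
      out[i, ] <- (1 - f) * pos[lo, ] + f * pos[lo + 1L, ]
    }
  }
  out
}

#' Packaged case-study-shaped scenario
#'
#' A ready-made fixture shaped like a spring bear predation study: three
#' animals tracked May 1-31 on a 60-minute fix schedule, several planted
#' stationary bouts per animal along each animal's seasonal travel axis, and
#' one proximity-burst episode (extra fixes every 10 minutes for six hours)
#' during one animal's transit. The matching analysis parameters are a 30 m
#' buffer with a minimum of two locations; the 60-minute subsample filter
#' neutralises the burst fixes.
#'
#' Bout centers are spaced proportionally to the travel time between them
#' (120 m per schedule tick) so transit fixes stay well beyond the overlap
#' distance.
#'
#' @param seed integer seed (default 104).
#' @return A list with `fixes`, `truth` (from [generate_tracks()]),
#'   `config` (the matching [study_config()]) and `spec`.
#' @export
scenario_case_study <- function(seed = 104L) {
  period_start <- "2014-05-01 00:00:00"
  period_end <- "2014-05-31 23:59:59"
  animals <- c("B1", "B2", "B3")
  # per-animal bout intervals (day, start hour, duration hours)
  plan <- list(
    B1 = list(c(3, 6, 8), c(10, 20, 14), c(18, 2, 5), c(27, 12, 10)),
    B2 = list(c(2, 14, 6), c(9, 3, 20), c(16, 8, 4), c(24, 22, 12)),
    B3 = list(c(5, 1, 9), c(13, 11, 7), c(22, 15, 16)))
  base_xy <- list(B1 = c(480000, 6780000), B2 = c(520000, 6820000),
                  B3 = c(455000, 6755000))
  angles <- c(B1 = 0.4, B2 = 2.2, B3 = 5.1)
  bout_rows <- list()
  for (a in animals) {
    t0 <- .as_utc(period_start)
    starts <- ends <- .as_utc(character(0))
    for (p in plan[[a]]) {
      s <- t0 + (p[1] - 1) * 86400 + p[2] * 3600
      starts <- c(starts, s); ends <- c(ends, s + p[3] * 3600)
    }
    # centers along the travel axis, spaced 120 m per tick of travel time
    u <- c(cos(angles[[a]]), sin(angles[[a]]))
    cx <- base_xy[[a]][1]; cy <- base_xy[[a]][2]
    for (i in seq_along(starts)) {
      if (i > 1) {
        gap_ticks <- max(1, round(as.numeric(starts[i] - ends[i - 1], units = "hours")))
        d <- 120 * (gap_ticks + 1)
        cx <- cx + d * u[1]; cy <- cy + d * u[2]
      }
      bout_rows[[length(bout_rows) + 1L]] <- data.frame(
        animal_id = a, center_x = cx, center_y = cy,
        start = starts[i], end = ends[i], scatter_sd_m = 8)
    }
  }
  bouts <- do.call(rbind, bout_rows)
  spec <- track_spec(
    animal_ids = animals,
    period_start = period_start, period_end = period_end,
    fix_interval_minutes = 60,
    bouts = bouts,
    travel_step_m = 400,
    burst = list(animal_id = "B2",
                 window_start = "2014-05-12 09:00:00",
                 window_end = "2014-05-12 15:00:00",
                 burst_interval_minutes = 10),
    crs_epsg = 32633,
    seed = seed)
  gen <- generate_tracks(spec)
  config <- study_config(label = "demo_bears", buffer_m = 30,
                         min_locations = 2, consecutive_only = FALSE,
                         subsample_minutes = 60,
                         period_start = period_start, period_end = period_end,
                         crs_epsg = 32633, add_summary_columns = TRUE)
  list(fixes = gen$fixes, truth = gen$truth, config = config, spec = spec)
}
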