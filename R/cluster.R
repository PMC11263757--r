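# Cluster formation. Two fixes are "connected" when their buffers overlap,
# i.e. planar distance <= 2 * buffer_m (tangent buffers count: the rule is a
# maximum distance of twice the buffer, read as inclusive). Default mode
# takes connected components of that graph; consecutive mode restricts the
# graph to edges between fixes adjacent in time.

#' Find activity clusters for one animal (default spatial mode)
#'
#' Builds the overlap graph on the animal's fixes — an edge whenever two
#' fixes are at most `2 * config$buffer_m` apart in the projected plane —
#' and returns its connected components. Components with at least
#' `config$min_locations` members become clusters; every other fix is a
#' single point. Connectivity is transitive: a chain of pairwise-overlapping
#' buffers forms one cluster even when its endpoints are far apart.
#'
#' The neighbour search bins fixes into a grid of cell size `2 * buffer_m`
#' and only compares fixes in adjacent cells, so typical telemetry tables
#' cluster in near-linear time.
#'
#' @param fixes fix tibble of a single animal, preprocessed and time-sorted.
#' @param config a [study_config()].
#' @return A list with `clusters` (list of integer index vectors into
#'   `fixes`, each time-sorted; ordered by time of first member) and
#'   `singles` (integer vector of unclustered fix indices).
#' @export
find_clusters <- function(fixes, config) {
  stopifnot(inherits(config, "fixclust_config"))
  fixes <- .as_fix_tibble(fixes)
  n <- nrow(fixes)
  if (length(unique(fixes$animal_id)) > 1L)
    stop("find_clusters() operates on one animal at a time")
  if (n < 2L) return(list(clusters = list(), singles = seq_len(n)))
  comp <- .overlap_components(fixes$x, fixes$y, 2 * config$buffer_m)
  .partition_from_components(comp, config$min_locations)
}

#' Find activity clusters for one animal (consecutive-only mode)
#'
#' Clusters are maximal runs of fixes consecutive in time in which every
#' adjacent pair is within `2 * config$buffer_m`. Fixes whose buffers overlap
#' but that are not sequential in time do not join: an animal that leaves a
#' site and later returns starts a new run.
#'
#' @inheritParams find_clusters
#' @return Same structure as [find_clusters()].
#' @export
find_clusters_consecutive <- function(fixes, config) {
  stopifnot(inherits(config, "fixclust_config"))
  fixes <- .as_fix_tibble(fixes)
  n <- nrow(fixes)
  if (length(unique(fixes$animal_id)) > 1L)
    stop("find_clusters_consecutive() operates on one animal at a time")
  if (n < 2L) return(list(clusters = list(), singles = seq_len(n)))
  if (is.unsorted(fixes$timestamp)) stop("fixes must be sorted in time")
  d2max <- (2 * config$buffer_m)^2
  gap <- (diff(fixes$x)^2 + diff(fixes$y)^2) > d2max
  run_id <- cumsum(c(0L, as.integer(gap)))
  comp <- run_id + 1L
  .partition_from_components(comp, config$min_locations)
}

# Component labels -> {clusters, singles}; clusters ordered by first member
# index (fixes are time-sorted, so this is first_time order).
.partition_from_components <- function(comp, min_locations) {
  groups <- split(seq_along(comp), comp)
  sizes <- lengths(groups)
  big <- groups[sizes >= min_locations]
  if (length(big) > 0) {
    big <- lapply(big, sort)
    big <- big[order(vapply(big, `[`, integer(1), 1L))]
    names(big) <- NULL
  } else {
    big <- list()
  }
  singles <- sort(unlist(groups[sizes < min_locations], use.names = FALSE))
  if (is.null(singles)) singles <- integer(0)
  list(clusters = big, singles = singles)
}

# Connected components of the "distance <= d" graph via grid binning plus
# union-find (path halving). Returns an integer component label per point.
.overlap_components <- function(x, y, d) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[[parent[i]]]
      i <- parent[i]
    }
    i
  }
  cx <- floor(x / d)
  cy <- floor(y / d)
  key <- paste(cx, cy)
  cells <- split(seq_len(n), key)
  cell_of <- match(key, names(cells))
  # coordinates of each occupied cell
  first_idx <- vapply(cells, `[`, integer(1), 1L)
  ccx <- cx[first_idx]
  ccy <- cy[first_idx]
  cell_lookup <- stats::setNames(seq_along(cells), names(cells))
  d2 <- d^2
  # forward half-neighbourhood avoids visiting a cell pair twice
  offsets <- list(c(0, 0), c(1, 0), c(-1, 1), c(0, 1), c(1, 1))
  for (ci in seq_along(cells)) {
    a <- cells[[ci]]
    for (off in offsets) {
      if (off[1] == 0 && off[2] == 0) {
        b <- a
        same <- TRUE
      } else {
        nb <- cell_lookup[paste(ccx[ci] + off[1], ccy[ci] + off[2])]
        if (is.na(nb)) next
        b <- cells[[nb]]
        same <- FALSE
      }
      # all pairs between a and b within distance d
      dx <- outer(x[a], x[b], "-")
      dy <- outer(y[a], y[b], "-")
      hit <- which(dx * dx + dy * dy <= d2, arr.ind = TRUE)
      if (same) hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
      if (nrow(hit) == 0) next
      for (k in seq_len(nrow(hit))) {
        ra <- find(a[hit[k, 1]])
        rb <- find(b[hit[k, 2]])
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
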