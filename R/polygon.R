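# Union of equal-radius circular buffers, computed analytically: the union
# boundary consists of the arcs of each circle not interior to any other
# circle. Arcs are stitched into closed rings at circle-circle intersection
# points, then discretised. Circles are approximated by regular polygons at
# >= 64 segments of angular resolution (vector polygon formats cannot store
# true circles).

#' Build the buffer-union polygon of a cluster
#'
#' Geometric union of discs of radius `buffer_m` centered on the member
#' fixes. For a valid cluster the members are pairwise connected through
#' overlapping buffers, so the union is a single connected polygon (two
#' buffers tangent at exactly `2 * buffer_m` meet in one point and yield a
#' single pinched ring). Interior holes, when a ring of buffers encloses
#' uncovered ground, are returned as additional rings.
#'
#' @param members fix tibble (or data.frame with `x`, `y`) of the member
#'   fixes; at least one row.
#' @param buffer_m disc radius, meters.
#' @param n_segments angular resolution of the circle approximation
#'   (segments per full circle, >= 32; default 64, area error below 0.2%).
#' @return An object of class `fixclust_polygon`: a list of rings, each a
#'   two-column matrix of closed coordinates (first point repeated last).
#'   Ring 1 is the outer boundary (counter-clockwise); any further rings are
#'   holes (clockwise). Attribute `"area"` holds the signed-area total, m^2.
#' @export
build_polygon <- function(members, buffer_m, n_segments = 64L) {
  stopifnot(is.numeric(buffer_m), buffer_m > 0, n_segments >= 32L)
  x <- as.numeric(members$x)
  y <- as.numeric(members$y)
  stopifnot(length(x) >= 1L, all(is.finite(x)), all(is.finite(y)))
  # collapse coincident centers (union is idempotent)
  key <- paste(signif(x, 12), signif(y, 12))
  keep <- !duplicated(key)
  x <- x[keep]; y <- y[keep]
  r <- buffer_m
  k <- length(x)
  step <- 2 * pi / n_segments
  if (k == 1L) {
    ring <- .arc_points(x, y, r, 0, 2 * pi, step, close = TRUE)
    return(.polygon_object(list(ring)))
  }
  # for each circle: angular intervals of its boundary lying inside another
  arcs <- list()   # each: list(ci, a0, a1) boundary arc of circle ci
  for (i in seq_len(k)) {
    dx <- x - x[i]; dy <- y - y[i]
    dd <- sqrt(dx^2 + dy^2)
    ov <- which(dd <= 2 * r & seq_len(k) != i)
    if (length(ov) == 0) {
      arcs[[length(arcs) + 1L]] <- list(ci = i, a0 = 0, a1 = 2 * pi)
      next
    }
    ints <- matrix(numeric(0), ncol = 2)
    split_pts <- numeric(0)
    for (j in ov) {
      half <- acos(min(1, dd[j] / (2 * r)))
      mid <- atan2(dy[j], dx[j])
      if (half > 0) {
        ints <- rbind(ints, c(mid - half, mid + half))
      } else {
        split_pts <- c(split_pts, mid)  # tangency: zero-width contact point
      }
    }
    free <- .circular_complement(ints)
    if (is.null(free)) next  # fully covered
    # split free arcs at tangency points so tangent circles share a vertex
    free <- .split_arcs(free, split_pts)
    for (rix in seq_len(nrow(free)))
      arcs[[length(arcs) + 1L]] <- list(ci = i, a0 = free[rix, 1], a1 = free[rix, 2])
  }
  rings <- .stitch_arcs(arcs, x, y, r, step)
  .polygon_object(rings)
}

#' @export
print.fixclust_polygon <- function(x, ...) {
  cat("<fixclust_polygon> ", length(x), " ring(s), area ",
      format(attr(x, "area"), digits = 6), " m^2\n", sep = "")
  invisible(x)
}

#' Signed area of a closed ring (shoelace)
#' @param ring two-column coordinate matrix, closed.
#' @return Signed area; positive for counter-clockwise rings.
#' @export
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

.polygon_object <- function(rings) {
  areas <- vapply(rings, ring_area, numeric(1))
  ord <- order(-abs(areas))
  rings <- rings[ord]; areas <- areas[ord]
  # a ring nested inside an odd number of other rings is a hole (CW);
  # outer boundaries are counter-clockwise
  depth <- integer(length(rings))
  if (length(rings) > 1) {
    for (i in seq_along(rings)) {
      probe <- rings[[i]][1, ]
      for (j in seq_along(rings)) {
        if (i != j && abs(areas[j]) > abs(areas[i]) &&
            .point_in_ring(probe[1], probe[2], rings[[j]]))
          depth[i] <- depth[i] + 1L
      }
    }
  }
  for (i in seq_along(rings)) {
    want_ccw <- depth[i] %% 2L == 0L
    if ((areas[i] > 0) != want_ccw) {
      rings[[i]] <- rings[[i]][rev(seq_len(nrow(rings[[i]]))), , drop = FALSE]
      areas[i] <- -areas[i]
    }
  }
  structure(rings, class = "fixclust_polygon", area = sum(areas))
}

# even-odd ray casting; boundary points may land either way (tolerable here:
# probes are ring vertices of *other* rings)
.point_in_ring <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring) - 1L
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((y[i] > py) != (y[j] > py)) {
      xint <- x[i] + (py - y[i]) / (y[j] - y[i]) * (x[j] - x[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# points along an arc of circle (cx,cy,r), from a0 to a1 (a1 > a0), at
# angular resolution <= step; includes both endpoints
.arc_points <- function(cx, cy, r, a0, a1, step, close = FALSE) {
  span <- a1 - a0
  m <- max(1L, ceiling(span / step))
  th <- a0 + span * seq(0, m) / m
  if (close) th <- th[-length(th)]
  pts <- cbind(cx + r * cos(th), cy + r * sin(th))
  if (close) pts <- rbind(pts, pts[1, , drop = FALSE])
  pts
}

# complement of a union of angular intervals on the circle; intervals given
# as rows (a0, a1) with a1 > a0 (may straddle the 2*pi wrap). Returns a
# matrix of free arcs (a0, a1), a1 > a0, or NULL when fully covered.
.circular_complement <- function(ints) {
  if (nrow(ints) == 0) return(matrix(c(0, 2 * pi), ncol = 2))
  w <- ints[, 2] - ints[, 1]
  ints[, 1] <- ints[, 1] %% (2 * pi)
  ints[, 2] <- ints[, 1] + w  # widths preserved after wrapping the start
  # unwrap intervals crossing 2*pi into two pieces
  pieces <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(ints))) {
    a <- ints[i, 1]; b <- ints[i, 2]
    if (b <= 2 * pi) pieces <- rbind(pieces, c(a, b))
    else pieces <- rbind(pieces, c(a, 2 * pi), c(0, b - 2 * pi))
  }
  pieces <- pieces[order(pieces[, 1]), , drop = FALSE]
  # merge
  merged <- pieces[1, , drop = FALSE]
  for (i in seq_len(nrow(pieces))[-1]) {
    last <- nrow(merged)
    if (pieces[i, 1] <= merged[last, 2] + 1e-12)
      merged[last, 2] <- max(merged[last, 2], pieces[i, 2])
    else merged <- rbind(merged, pieces[i, ])
  }
  free <- matrix(numeric(0), ncol = 2)
  if (merged[1, 1] > 1e-12) free <- rbind(free, c(0, merged[1, 1]))
  for (i in seq_len(nrow(merged))[-1])
    free <- rbind(free, c(merged[i - 1, 2], merged[i, 1]))
  tail_start <- merged[nrow(merged), 2]
  if (tail_start < 2 * pi - 1e-12) free <- rbind(free, c(tail_start, 2 * pi))
  # join the wrap-around free arc (… 2*pi) + (0 …) into one
  if (nrow(free) >= 2 && free[1, 1] <= 1e-12 && free[nrow(free), 2] >= 2 * pi - 1e-12) {
    free[nrow(free), 2] <- free[nrow(free), 2] + (free[1, 2] - free[1, 1])
    free <- free[-1, , drop = FALSE]
  }
  if (nrow(free) == 0) NULL else free
}

# split arcs at given angles (tangency contact points) when strictly inside
.split_arcs <- function(free, split_pts) {
  if (length(split_pts) == 0) return(free)
  for (sp in split_pts %% (2 * pi)) {
    out <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(nrow(free))) {
      a <- free[i, 1]; b <- free[i, 2]
      hit <- NA_real_
      for (cand in c(sp, sp + 2 * pi)) {
        if (cand > a + 1e-9 && cand < b - 1e-9) hit <- cand
      }
      if (is.na(hit)) {
        # full-circle arc with endpoint elsewhere: rotate so it starts at sp
        da <- (a - sp) %% (2 * pi)
        starts_at_sp <- da < 1e-9 || da > 2 * pi - 1e-9
        if (abs((b - a) - 2 * pi) < 1e-12 && !starts_at_sp) {
          out <- rbind(out, c(sp, sp + 2 * pi))
        } else {
          out <- rbind(out, c(a, b))
        }
      } else {
        out <- rbind(out, c(a, hit), c(hit, b))
      }
    }
    free <- out
  }
  free
}

# stitch boundary arcs into closed rings by matching endpoints
.stitch_arcs <- function(arcs, x, y, r, step) {
  if (length(arcs) == 0) stop("degenerate buffer union: no boundary arcs")
  ends <- t(vapply(arcs, function(a) c(
    x[a$ci] + r * cos(a$a0), y[a$ci] + r * sin(a$a0),
    x[a$ci] + r * cos(a$a1), y[a$ci] + r * sin(a$a1)), numeric(4)))
  tol <- max(1e-9, r * 1e-9)
  used <- logical(length(arcs))
  rings <- list()
  for (start in seq_along(arcs)) {
    if (used[start]) next
    chain <- integer(0)
    cur <- start
    repeat {
      used[cur] <- TRUE
      chain <- c(chain, cur)
      endpt <- ends[cur, 3:4]
      cand <- which(!used &
                      (ends[, 1] - endpt[1])^2 + (ends[, 2] - endpt[2])^2 <= tol^2)
      at_start <- sum((endpt - ends[chain[1], 1:2])^2) <= tol^2
      # close only when nothing continues from here: tangency junctions
      # (two discs meeting in a point) must traverse both discs and yield a
      # single pinched ring
      if (length(cand) == 0) break
      if (at_start && length(cand) == 0) break
      # prefer switching to a different circle at a junction
      circs <- vapply(cand, function(ai) arcs[[ai]]$ci, integer(1))
      pick <- cand[circs != arcs[[cur]]$ci][1]
      if (is.na(pick)) pick <- cand[1]
      cur <- pick
    }
    pts <- do.call(rbind, lapply(chain, function(ai) {
      a <- arcs[[ai]]
      p <- .arc_points(x[a$ci], y[a$ci], r, a$a0, a$a1, step)
      p[-nrow(p), , drop = FALSE]  # next arc re-adds the shared endpoint
    }))
    rings[[length(rings) + 1L]] <- rbind(pts, pts[1, , drop = FALSE])
  }
  rings
}
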