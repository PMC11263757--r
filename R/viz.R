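# Static HTML map of an analysis result: a self-contained page with an
# inline SVG rendering of the cluster polygons and, optionally, fixes,
# per-animal tracks, cluster labels and last-position markers. The map is a
# pure read of the analysis outputs; it never mutates them.

# fixed State palette; Event colours are assigned stably by sorted event name
.state_palette <- c(New = "#d7191c", Grown = "#fdae61", Done = "#1a9641")
.event_palette_pool <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a",
                         "#66a61e", "#e6ab02", "#a6761d", "#666666")
.track_palette <- c("#1f78b4", "#33a02c", "#6a3d9a", "#ff7f00", "#b15928",
                    "#a6cee3", "#b2df8a", "#cab2d6")

#' Export an analysis result as a static HTML map
#'
#' Layers: cluster polygons coloured by the `State` column (New = red,
#' Grown = orange, Done = green) or filled by `Event`; optional fix points
#' whose marker radius grows strictly with recency within each animal;
#' optional per-animal track polylines; optional cluster-ID labels. The
#' most recent position of each animal is always marked with a pin.
#'
#' @param result a `fixclust_result`, or a path to a `.geojson` cluster
#'   layer written by [write_cluster_file()] (fix-dependent layers then
#'   require the fixes via `fixes`).
#' @param path output `.html` path.
#' @param show_fixes draw the fix points.
#' @param show_tracks draw per-animal track lines.
#' @param show_labels draw cluster-ID labels at the mean centers.
#' @param color_by `"state"` or `"event"`.
#' @param fixes optional fix tibble when `result` is a layer path.
#' @param rows optional cluster row filter: only these clusters are drawn.
#' @return The path, invisibly.
#' @export
write_map <- function(result, path, show_fixes = FALSE, show_tracks = FALSE,
                      show_labels = FALSE, color_by = c("state", "event"),
                      fixes = NULL, rows = NULL) {
  color_by <- match.arg(color_by)
  if (inherits(result, "fixclust_result")) {
    clusters <- result$clusters
    if (is.null(fixes)) fixes <- result$fixes
    label <- result$config$label
  } else if (is.character(result) && length(result) == 1L) {
    clusters <- read_cluster_file(result)
    label <- sub("_clusters_.*$", "", basename(result))
  } else {
    stop("'result' must be a fixclust_result or a cluster layer path")
  }
  if ((show_fixes || show_tracks) && (is.null(fixes) || nrow(fixes) == 0))
    stop("show_fixes/show_tracks need a fixes table")
  if (!is.null(rows)) clusters <- clusters[rows, , drop = FALSE]

  # bounding box over everything drawn
  xs <- ys <- numeric(0)
  for (p in clusters$polygon) for (ring in p) { xs <- c(xs, ring[, 1]); ys <- c(ys, ring[, 2]) }
  if (!is.null(fixes) && nrow(fixes) > 0) { xs <- c(xs, fixes$x); ys <- c(ys, fixes$y) }
  if (length(xs) == 0) { xs <- c(0, 1); ys <- c(0, 1) }
  pad <- 0.03 * max(diff(range(xs)), diff(range(ys)), 1)
  x0 <- min(xs) - pad; x1 <- max(xs) + pad
  y0 <- min(ys) - pad; y1 <- max(ys) + pad
  W <- 960
  H <- max(320, round(W * (y1 - y0) / (x1 - x0)))
  if (H > 4000) H <- 4000
  sx <- function(x) (x - x0) / (x1 - x0) * W
  sy <- function(y) H - (y - y0) / (y1 - y0) * H
  fmt <- function(v) formatC(v, format = "f", digits = 2)

  cluster_fill <- function(i) {
    if (color_by == "state") {
      col <- .state_palette[clusters$state[i]]
      if (is.na(col)) col <- "#999999"
      col
    } else {
      evs <- sort(unique(clusters$event[nzchar(clusters$event)]))
      if (!nzchar(clusters$event[i])) return("#cccccc")
      .event_palette_pool[(match(clusters$event[i], evs) - 1L) %%
                            length(.event_palette_pool) + 1L]
    }
  }

  svg <- character(0)
  add <- function(...) svg <<- c(svg, paste0(...))
  add(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">', W, H, W, H))
  add('<rect width="100%" height="100%" fill="#f4f1ea"/>')

  if (show_tracks) {
    animals <- unique(fixes$animal_id)
    for (k in seq_along(animals)) {
      fx <- fixes[fixes$animal_id == animals[k], , drop = FALSE]
      fx <- fx[order(fx$timestamp), , drop = FALSE]
      pts <- paste(fmt(sx(fx$x)), fmt(sy(fx$y)), sep = ",", collapse = " ")
      add(sprintf('<polyline class="track" data-animal="%s" points="%s" fill="none" stroke="%s" stroke-width="1"/>',
                  animals[k], pts,
                  .track_palette[(k - 1L) %% length(.track_palette) + 1L]))
    }
  }
  for (i in seq_len(nrow(clusters))) {
    d <- paste(vapply(clusters$polygon[[i]], function(ring) {
      paste0("M", paste(fmt(sx(ring[, 1])), fmt(sy(ring[, 2])), sep = ",",
                        collapse = " L"), " Z")
    }, character(1)), collapse = " ")
    add(sprintf('<path class="cluster" data-cluster="%s" d="%s" fill="%s" fill-opacity="0.55" fill-rule="evenodd" stroke="#333" stroke-width="0.7"/>',
                clusters$cluster_id[i], d, cluster_fill(i)))
  }
  if (show_fixes) {
    for (a in unique(fixes$animal_id)) {
      fx <- fixes[fixes$animal_id == a, , drop = FALSE]
      fx <- fx[order(fx$timestamp), , drop = FALSE]
      n <- nrow(fx)
      # radius strictly monotone in recency within the animal
      r <- if (n == 1) 3 else 1.5 + 3.5 * (seq_len(n) - 1) / (n - 1)
      for (j in seq_len(n)) {
        add(sprintf('<circle class="fix" data-animal="%s" cx="%s" cy="%s" r="%s" fill="#2b2b2b" fill-opacity="0.6"/>',
                    a, fmt(sx(fx$x[j])), fmt(sy(fx$y[j])), fmt(r[j])))
      }
    }
  }
  # last position per animal: a pin marker
  if (!is.null(fixes) && nrow(fixes) > 0) {
    for (a in unique(fixes$animal_id)) {
      fx <- fixes[fixes$animal_id == a, , drop = FALSE]
      last <- fx[which.max(fx$timestamp), , drop = FALSE]
      cx <- sx(last$x); cy <- sy(last$y)
      add(sprintf('<path class="last-pos" data-animal="%s" d="M%s,%s l-5,-12 a6,6 0 1,1 10,0 Z" fill="#2166ac" stroke="#fff" stroke-width="1"/>',
                  a, fmt(cx), fmt(cy)))
    }
  }
  if (show_labels) {
    for (i in seq_len(nrow(clusters))) {
      add(sprintf('<text class="label" x="%s" y="%s" font-size="11" font-family="sans-serif" fill="#111">%s</text>',
                  fmt(sx(clusters$mean_x[i])), fmt(sy(clusters$mean_y[i]) - 6),
                  clusters$cluster_id[i]))
    }
  }
  add("</svg>")

  legend <- if (color_by == "state") {
    paste(sprintf('<span class="key"><i style="background:%s"></i>%s</span>',
                  .state_palette, names(.state_palette)), collapse = " ")
  } else {
    evs <- sort(unique(clusters$event[nzchar(clusters$event)]))
    paste(sprintf('<span class="key"><i style="background:%s"></i>%s</span>',
                  .event_palette_pool[seq_along(evs)], evs), collapse = " ")
  }
  html <- c("<!DOCTYPE html>",
            "<html><head><meta charset=\"utf-8\"/>",
            sprintf("<title>%s - cluster map</title>", label),
            "<style>body{font-family:sans-serif;margin:16px;}",
            ".key i{display:inline-block;width:12px;height:12px;margin:0 4px 0 10px;}",
            "</style></head><body>",
            sprintf("<h2>%s</h2>", label),
            sprintf("<p>%d cluster(s)%s. %s</p>", nrow(clusters),
                    if (!is.null(fixes)) sprintf(", %d fixes", nrow(fixes)) else "",
                    legend),
            svg,
            "</body></html>")
  writeLines(html, path)
  invisible(path)
}
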