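# The cluster layer: a GeoJSON FeatureCollection, one polygon feature per
# cluster, carrying the full attribute table (IDs, summaries, the editable
# State/Event/DateDone/Technician/Notes columns) plus the member point IDs
# and member timestamps needed to keep IDs stable in subsequent analyses.
# Coordinates are written in the study's projected CRS (declared in a "crs"
# member) at full double precision so that a write -> read round trip
# reproduces vertices exactly.

#' Write the cluster layer, sidecar and attribute table
#'
#' Writes three files into `directory`, named
#' `<label>_clusters_<YYYYMMDDHHMMSS>` after the study label and the
#' analysis time: the GeoJSON polygon layer (`.geojson`), the plain-text
#' settings sidecar (`_settings.txt`), and the full cluster attribute table
#' as CSV (`.csv`). Saving the layer is what makes field edits and issued
#' cluster IDs available to subsequent analyses via [discover_previous()].
#'
#' @param result a [run_analysis()] / [reconcile()] result.
#' @param directory output directory (created if missing).
#' @param format layer format; only `"geojson"` is supported.
#' @param source_fix_file optional name of the fix file, recorded in the
#'   sidecar.
#' @return Character vector of written paths (layer, sidecar, csv),
#'   invisibly.
#' @export
write_cluster_file <- function(result, directory, format = "geojson",
                               source_fix_file = "") {
  stopifnot(inherits(result, "fixclust_result"))
  format <- match.arg(format, "geojson")
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory)
  }
  stamp <- format(result$analysis_time, "%Y%m%d%H%M%S", tz = "UTC")
  stem <- file.path(directory, paste0(result$config$label, "_clusters_", stamp))
  layer_path <- paste0(stem, ".geojson")
  sidecar_path <- paste0(stem, "_settings.txt")
  csv_path <- paste0(stem, ".csv")

  cl <- result$clusters
  features <- lapply(seq_len(nrow(cl)), function(i) {
    poly <- cl$polygon[[i]]
    coords <- lapply(poly, function(ring) unname(ring))
    list(type = "Feature",
         properties = list(
           animal_id = cl$animal_id[i],
           seq_number = cl$seq_number[i],
           cluster_id = cl$cluster_id[i],
           n_inside = cl$n_inside[i],
           n_outside = cl$n_outside[i],
           percent_time = cl$percent_time[i],
           first_time = .fmt_time(cl$first_time[i]),
           last_time = .fmt_time(cl$last_time[i]),
           mean_x = cl$mean_x[i],
           mean_y = cl$mean_y[i],
           mean_lon = cl$mean_lon[i],
           mean_lat = cl$mean_lat[i],
           state = cl$state[i],
           event = cl$event[i],
           date_done = if (is.na(cl$date_done[i])) NA else format(cl$date_done[i]),
           technician = cl$technician[i],
           notes = cl$notes[i],
           members = as.list(cl$members[[i]]),
           member_times = as.list(.fmt_time(.member_times(result, i)))),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  issued <- result$issued_seq
  if (is.null(issued)) issued <- .seq_high_water(cl)
  fc <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(
                          name = paste0("urn:ogc:def:crs:EPSG::",
                                        result$config$crs_epsg))),
             issued_seq = as.list(issued),  # ID high-water marks per animal
             features = features)
  json <- jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA, null = "null",
                           na = "null")
  writeLines(json, layer_path)
  write_settings(result$config, sidecar_path,
                 analysis_time = result$analysis_time,
                 source_fix_file = source_fix_file)
  utils::write.csv(cluster_table(result), csv_path, row.names = FALSE)
  invisible(c(layer = layer_path, sidecar = sidecar_path, table = csv_path))
}

# timestamps of the member fixes of cluster i, in member order
.member_times <- function(result, i) {
  cl <- result$clusters
  sel <- result$fixes$animal_id == cl$animal_id[i] &
    !is.na(result$fixes$cluster_seq) &
    result$fixes$cluster_seq == cl$seq_number[i]
  result$fixes$timestamp[sel]
}

#' Read a cluster layer written by [write_cluster_file()]
#'
#' @param path path to the `.geojson` layer.
#' @return A cluster tibble (same columns as `result$clusters`, plus a
#'   `member_times` list-column), with attribute `"crs_epsg"`.
#' @export
read_cluster_file <- function(path) {
  if (!file.exists(path)) stop("cluster layer not found: ", path)
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path)
  crs_epsg <- NA_integer_
  crs_name <- tryCatch(fc$crs$properties$name, error = function(e) NULL)
  if (is.character(crs_name))
    crs_epsg <- as.integer(sub(".*EPSG::?", "", crs_name))
  rows <- lapply(fc$features, function(f) {
    p <- f$properties
    chr <- function(v) if (is.null(v) || is.na(v)) "" else as.character(v)
    tibble::tibble(
      animal_id = as.character(p$animal_id),
      seq_number = as.integer(p$seq_number),
      cluster_id = as.character(p$cluster_id),
      n_inside = as.integer(p$n_inside),
      n_outside = as.integer(p$n_outside),
      percent_time = as.numeric(p$percent_time),
      first_time = .as_utc(p$first_time),
      last_time = .as_utc(p$last_time),
      mean_x = as.numeric(p$mean_x),
      mean_y = as.numeric(p$mean_y),
      mean_lon = if (is.null(p$mean_lon) || is.na(p$mean_lon)) NA_real_ else as.numeric(p$mean_lon),
      mean_lat = if (is.null(p$mean_lat) || is.na(p$mean_lat)) NA_real_ else as.numeric(p$mean_lat),
      state = chr(p$state),
      event = chr(p$event),
      date_done = if (is.null(p$date_done) || is.na(p$date_done)) as.Date(NA) else as.Date(p$date_done),
      technician = chr(p$technician),
      notes = chr(p$notes),
      members = list(vapply(p$members, as.character, character(1))),
      member_times = list(.as_utc(vapply(p$member_times, as.character, character(1)))),
      polygon = list(.rings_from_geojson(f$geometry)))
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    tb <- .empty_cluster_tibble()
    tb$mean_lon <- numeric(0); tb$mean_lat <- numeric(0)
    tb$member_times <- list()
    tb
  }
  attr(out, "crs_epsg") <- crs_epsg
  issued <- integer(0)
  if (!is.null(fc$issued_seq) && length(fc$issued_seq) > 0)
    issued <- stats::setNames(vapply(fc$issued_seq, as.integer, integer(1)),
                              names(fc$issued_seq))
  attr(out, "issued_seq") <- issued
  out
}

.rings_from_geojson <- function(geom) {
  stopifnot(identical(geom$type, "Polygon"))
  rings <- lapply(geom$coordinates, function(ring) {
    do.call(rbind, lapply(ring, function(pt) c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
  })
  areas <- vapply(rings, ring_area, numeric(1))
  structure(rings, class = "fixclust_polygon", area = sum(areas))
}

#' Locate the most recent previous analysis of a study
#'
#' Searches `directory` for cluster layers of the given study label (files
#' named `<label>_clusters_<timestamp>.geojson`) and returns the one whose
#' settings sidecar records the most recent analysis time. The sidecar, not
#' the filesystem timestamp, decides recency, so layers copied between field
#' laptops keep their history.
#'
#' @param directory directory to search.
#' @param label study label (must match the label used in the previous runs).
#' @return `NULL` when no previous run exists (an initial analysis; callers
#'   log `"No latest cluster file"`), otherwise a list of class
#'   `fixclust_previous` with `clusters`, `sidecar` (see [parse_settings()])
#'   and `path`.
#' @export
discover_previous <- function(directory, label) {
  if (!dir.exists(directory)) stop("directory not found: ", directory)
  pat <- paste0("^", .regex_escape(label), "_clusters_[0-9]{14}\\.geojson$")
  layers <- list.files(directory, pattern = pat, full.names = TRUE)
  if (length(layers) == 0) return(NULL)
  sidecars <- sub("\\.geojson$", "_settings.txt", layers)
  missing <- !file.exists(sidecars)
  if (any(missing))
    stop("cluster layer found without its settings sidecar: ",
         paste(basename(layers[missing]), collapse = ", "),
         " (settings cannot be restored; supply them explicitly)")
  parsed <- lapply(sidecars, parse_settings)
  times <- vapply(parsed, function(p) as.numeric(p$analysis_time), numeric(1))
  best <- which.max(times)
  clusters <- read_cluster_file(layers[best])
  structure(list(clusters = clusters,
                 sidecar = parsed[[best]],
                 issued_seq = attr(clusters, "issued_seq"),
                 path = layers[best]),
            class = "fixclust_previous")
}

#' @export
print.fixclust_previous <- function(x, ...) {
  cat("<fixclust_previous> ", basename(x$path), ": ", nrow(x$clusters),
      " cluster(s), analysis time ", .fmt_time(x$sidecar$analysis_time),
      "\n", sep = "")
  invisible(x)
}

.regex_escape <- function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)
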