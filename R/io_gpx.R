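# GPX 1.1 waypoint export, for loading cluster centers (or individual
# fixes) onto hand-held GPS units used to navigate to sites in the field.

#' Write GPX 1.1 waypoints
#'
#' Writes one waypoint per cluster (placed at the cluster's mean center,
#' named by its cluster ID) or one per fix (named by point ID). Coordinates
#' are geographic WGS84; projected mean centers are inverse-projected, which
#' requires a UTM `crs_epsg`.
#'
#' @param items a `fixclust_result`, a cluster tibble, or a fix tibble.
#' @param path output `.gpx` path.
#' @param which for a `fixclust_result`: export `"clusters"` or `"fixes"`.
#' @param rows optional row filter (logical or integer index into the
#'   exported table), e.g. to export only the clusters left after table
#'   filtering.
#' @return The path, invisibly.
#' @export
write_gpx <- function(items, path, which = c("clusters", "fixes"), rows = NULL) {
  which <- match.arg(which)
  tab <- .gpx_waypoints(items, which)
  if (!is.null(rows)) tab <- tab[rows, , drop = FALSE]
  if (nrow(tab) > 0 && any(!is.finite(tab$lat) | !is.finite(tab$lon)))
    stop("waypoints lack geographic coordinates; a UTM crs_epsg (326xx/327xx) ",
         "is needed to derive lon/lat")
  doc <- xml2::xml_new_root("gpx",
                            version = "1.1",
                            creator = paste0("fixclust ",
                                             utils::packageVersion("fixclust")),
                            xmlns = "http://www.topografix.com/GPX/1/1")
  for (i in seq_len(nrow(tab))) {
    wpt <- xml2::xml_add_child(doc, "wpt",
                               lat = format(tab$lat[i], digits = 10),
                               lon = format(tab$lon[i], digits = 10))
    if (!is.na(tab$time[i]))
      xml2::xml_add_child(wpt, "time", .fmt_time(tab$time[i]))
    xml2::xml_add_child(wpt, "name", tab$name[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

.gpx_waypoints <- function(items, which) {
  if (inherits(items, "fixclust_result")) {
    items <- if (which == "clusters") items$clusters else items$fixes
  }
  items <- tibble::as_tibble(items)
  if ("cluster_id" %in% names(items)) {
    tibble::tibble(name = items$cluster_id,
                   lon = items$mean_lon, lat = items$mean_lat,
                   time = items$first_time)
  } else if ("point_id" %in% names(items)) {
    tibble::tibble(name = items$point_id,
                   lon = items$lon, lat = items$lat,
                   time = items$timestamp)
  } else {
    stop("cannot derive waypoints: expected a cluster or fix table")
  }
}

#' Structurally validate a GPX 1.1 file
#'
#' Checks the constraints of the GPX 1.1 schema that apply to the documents
#' this package writes: root element `gpx` in the GPX 1.1 namespace with
#' `version` and `creator`, waypoints carrying numeric `lat` in [-90, 90]
#' and `lon` in [-180, 180], and `time` (if present) preceding `name` in
#' each waypoint, per the schema's fixed child order.
#'
#' @param path path to a `.gpx` file.
#' @return `TRUE` if valid, otherwise a character vector of problems.
#' @export
validate_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  problems <- character(0)
  if (xml2::xml_name(doc) != "gpx")
    problems <- c(problems, "root element is not <gpx>")
  ns <- xml2::xml_ns(doc)
  if (!"http://www.topografix.com/GPX/1/1" %in% unlist(ns))
    problems <- c(problems, "GPX 1.1 namespace missing")
  if (!identical(xml2::xml_attr(doc, "version"), "1.1"))
    problems <- c(problems, "version attribute is not '1.1'")
  if (is.na(xml2::xml_attr(doc, "creator")))
    problems <- c(problems, "creator attribute missing")
  wpts <- xml2::xml_find_all(doc, ".//d1:wpt", ns)
  for (w in wpts) {
    lat <- suppressWarnings(as.numeric(xml2::xml_attr(w, "lat")))
    lon <- suppressWarnings(as.numeric(xml2::xml_attr(w, "lon")))
    if (is.na(lat) || abs(lat) > 90)
      problems <- c(problems, "wpt lat missing or out of [-90, 90]")
    if (is.na(lon) || abs(lon) > 180)
      problems <- c(problems, "wpt lon missing or out of [-180, 180]")
    kids <- xml2::xml_name(xml2::xml_children(w))
    ti <- match("time", kids)
    ni <- match("name", kids)
    if (!is.na(ti) && !is.na(ni) && ti > ni)
      problems <- c(problems, "wpt children out of schema order (time after name)")
  }
  if (length(problems) == 0) TRUE else unique(problems)
}
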