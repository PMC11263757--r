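# Reading GPS fixes. CSV (delimiter auto-detected among comma, semicolon,
# tab) and GeoJSON point layers are supported. Coordinates in a CSV are
# assumed to already be in the study's projected CRS unless the column map
# points at lon/lat columns, in which case they are projected. Timestamps
# are treated as UTC throughout.

#' Read GPS fixes from a delimited file or point layer
#'
#' @param path path to a `.csv` (any of comma/semicolon/tab delimited) or a
#'   GeoJSON point layer. Shapefiles are not supported; convert to CSV or
#'   GeoJSON first.
#' @param column_map named list mapping the roles `animal`, `timestamp`, and
#'   either `x`,`y` (projected meters, already in `config$crs_epsg`) or
#'   `lon`,`lat` (degrees WGS84, reprojected on read) to source column
#'   names. Ignored for GeoJSON input (geometry supplies coordinates; the
#'   `animal` and `timestamp` roles still name the properties to use).
#' @param config a [study_config()]; supplies the target CRS.
#' @return A fix tibble sorted by animal and timestamp, duplicates collapsed
#'   (validation report in attribute `"report"`). Geographic lon/lat are
#'   retained or derived (for UTM CRS) for later GPX export.
#' @export
read_fixes <- function(path, column_map, config) {
  stopifnot(inherits(config, "fixclust_config"))
  if (!file.exists(path)) stop("input file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "shp")
    stop("shapefile input is not supported by this build; ",
         "export the layer as CSV or GeoJSON and try again")
  if (ext %in% c("geojson", "json")) {
    raw <- .read_point_layer(path)
  } else {
    raw <- .read_delim_auto(path)
  }
  .fixes_from_table(raw, column_map, config)
}

.read_delim_auto <- function(path) {
  head1 <- readLines(path, n = 1L, warn = FALSE)
  if (length(head1) == 0) stop("empty input file: ", path)
  counts <- c(`,` = lengths(regmatches(head1, gregexpr(",", head1, fixed = TRUE))),
              `;` = lengths(regmatches(head1, gregexpr(";", head1, fixed = TRUE))),
              `\t` = lengths(regmatches(head1, gregexpr("\t", head1, fixed = TRUE))))
  sep <- names(counts)[which.max(counts)]
  if (max(counts) == 0) sep <- ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

.read_point_layer <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path)
  rows <- lapply(fc$features, function(f) {
    if (!identical(f$geometry$type, "Point"))
      stop("expected Point geometries in ", path)
    p <- f$properties
    p$`.geom_x` <- as.numeric(f$geometry$coordinates[[1]])
    p$`.geom_y` <- as.numeric(f$geometry$coordinates[[2]])
    as.data.frame(p, stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "geojson") <- TRUE
  out
}

.fixes_from_table <- function(raw, column_map, config) {
  column_map <- as.list(column_map)
  is_geojson <- isTRUE(attr(raw, "geojson"))
  need <- c("animal", "timestamp")
  geographic <- FALSE
  if (is_geojson) {
    # GeoJSON is geographic (WGS84) by convention
    geographic <- TRUE
    column_map$lon <- ".geom_x"
    column_map$lat <- ".geom_y"
  } else if (all(c("lon", "lat") %in% names(column_map))) {
    geographic <- TRUE
  } else if (all(c("x", "y") %in% names(column_map))) {
    need <- c(need, "x", "y")
  } else {
    stop("column_map must map either x/y (projected) or lon/lat (geographic) columns")
  }
  if (geographic) need <- c(need, "lon", "lat")
  for (role in need) {
    col <- column_map[[role]]
    if (is.null(col))
      stop("column_map is missing the '", role, "' role")
    if (!col %in% names(raw))
      stop("mapped column '", col, "' (role '", role, "') not found in input")
  }
  ts <- .as_utc(raw[[column_map$timestamp]])
  bad <- which(is.na(ts))
  if (length(bad) > 0)
    stop("unparseable timestamp in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  if (geographic) {
    lon <- as.numeric(raw[[column_map$lon]])
    lat <- as.numeric(raw[[column_map$lat]])
    if (any(abs(lat) > 90, na.rm = TRUE) || any(abs(lon) > 180, na.rm = TRUE))
      stop("lon/lat outside valid ranges; check the column mapping")
    if (is.null(utm_epsg_info(config$crs_epsg)))
      stop("geographic input needs a WGS84 UTM crs_epsg (326xx/327xx) ",
           "to project into; set crs_epsg accordingly")
    xy <- utm_project(lon, lat, config$crs_epsg)
    fixes <- tibble::tibble(animal_id = as.character(raw[[column_map$animal]]),
                            timestamp = ts, x = xy$x, y = xy$y,
                            lon = lon, lat = lat)
  } else {
    fixes <- tibble::tibble(animal_id = as.character(raw[[column_map$animal]]),
                            timestamp = ts,
                            x = as.numeric(raw[[column_map$x]]),
                            y = as.numeric(raw[[column_map$y]]))
  }
  out <- validate_fixes(fixes)
  .derive_lonlat(out, config)
}
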