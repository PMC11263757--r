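# Tabular views and exports: the "GPS location clusters" table and the
# "GPS data" (fixes) table, with fixed, documented column orders and ISO
# 8601 timestamps.

#' Cluster attribute table
#'
#' One row per cluster. Fixed column order: `animal_id`, `cluster_id`,
#' `seq_number`, `state`, `event`, `date_done`, `technician`, `notes`,
#' `first_time`, `last_time`, `mean_x`, `mean_y`, `mean_lon`, `mean_lat`,
#' then — when the config enables summary columns — `n_inside`,
#' `n_outside`, `percent_time`.
#'
#' @param result a `fixclust_result`.
#' @return A tibble.
#' @export
cluster_table <- function(result) {
  stopifnot(inherits(result, "fixclust_result"))
  cl <- result$clusters
  base <- cl[, c("animal_id", "cluster_id", "seq_number", "state", "event",
                 "date_done", "technician", "notes", "first_time",
                 "last_time", "mean_x", "mean_y", "mean_lon", "mean_lat")]
  if (isTRUE(result$config$add_summary_columns)) {
    base$n_inside <- cl$n_inside
    base$n_outside <- cl$n_outside
    base$percent_time <- cl$percent_time
  }
  base
}

#' Fix ("GPS data") table
#'
#' One row per fix used in the analysis. Fixed column order: `animal_id`,
#' `point_id`, `cluster_id` (empty for single points), `timestamp`, `x`,
#' `y`, `lon`, `lat`.
#'
#' @param result a `fixclust_result`.
#' @return A tibble.
#' @export
fix_table <- function(result) {
  stopifnot(inherits(result, "fixclust_result"))
  fx <- result$fixes
  tibble::tibble(
    animal_id = fx$animal_id,
    point_id = fx$point_id,
    cluster_id = ifelse(is.na(fx$cluster_seq), "",
                        paste0(fx$animal_id, "_", fx$cluster_seq)),
    timestamp = fx$timestamp,
    x = fx$x, y = fx$y, lon = fx$lon, lat = fx$lat)
}

#' Export the cluster or fix table
#'
#' Writes the table with its documented column order; timestamps are
#' formatted as ISO 8601 UTC. A row filter, when provided, restricts the
#' export (the filtered table is what is written).
#'
#' @param result a `fixclust_result`.
#' @param path output file path.
#' @param which `"clusters"` or `"fixes"`.
#' @param format `"csv"`. (`"xlsx"` is recognised but unavailable in this
#'   build — no xlsx writer is bundled — and raises an error suggesting
#'   csv.)
#' @param rows optional row filter (logical or integer indices).
#' @param animal optional animal ID (or vector); keeps only that animal's
#'   rows.
#' @return The path, invisibly.
#' @export
write_tables <- function(result, path, which = c("clusters", "fixes"),
                         format = c("csv", "xlsx"), rows = NULL,
                         animal = NULL) {
  stopifnot(inherits(result, "fixclust_result"))
  which <- match.arg(which)
  if (length(format) == 1 && !format %in% c("csv", "xlsx"))
    stop("unknown format: ", format)
  format <- match.arg(format)
  if (format == "xlsx")
    stop("xlsx export is not available in this build (no xlsx writer); ",
         "use format = \"csv\"")
  tab <- if (which == "clusters") cluster_table(result) else fix_table(result)
  if (!is.null(animal)) tab <- tab[tab$animal_id %in% animal, , drop = FALSE]
  if (!is.null(rows)) tab <- tab[rows, , drop = FALSE]
  for (col in names(tab)) {
    if (inherits(tab[[col]], "POSIXct")) tab[[col]] <- .fmt_time(tab[[col]])
  }
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}
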