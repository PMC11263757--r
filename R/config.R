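#' Analysis configuration for a cluster study
#'
#' Bundles every parameter of a cluster analysis run. These parameters must
#' stay constant through a study period: subsequent analyses check them
#' against the stored settings of the previous run and refuse to proceed on a
#' mismatch, so that clusters remain comparable across the season.
#'
#' @param label short study label used in output filenames and to locate
#'   previous runs; must not contain path separators.
#' @param buffer_m buffer radius around each fix, meters (> 0). Two fixes are
#'   connected when they are at most `2 * buffer_m` apart.
#' @param min_locations minimum number of fixes required to form a cluster
#'   (integer >= 2).
#' @param consecutive_only if `TRUE`, only runs of fixes that are sequential
#'   in time can form a cluster; spatially overlapping but non-sequential
#'   fixes stay single points.
#' @param subsample_minutes keep at most one fix per this many minutes
#'   (greedy, anchored at each animal's first fix); `0` uses all fixes.
#'   Use this to neutralise burst/proximity oversampling.
#' @param period_start,period_end study period bounds (closed interval);
#'   anything coercible by [as.POSIXct()]; interpreted as UTC.
#' @param crs_epsg EPSG code of the projected, meter-unit CRS in which `x`/`y`
#'   coordinates live (e.g. 32633 for UTM 33N).
#' @param add_summary_columns include the overview columns (fixes inside /
#'   outside, percent time) in exported cluster tables.
#' @param mark_done_on_import when loading a previous run, mark all its
#'   clusters as state `"Done"`.
#' @return An object of class `fixclust_config` (a validated list).
#' @export
#' @examples
#' cfg <- study_config("bears", buffer_m = 30, min_locations = 2,
#'                     period_start = "2014-05-01", period_end = "2014-05-31 23:59:59",
#'                     crs_epsg = 32633)
#' cfg
study_config <- function(label,
                         buffer_m,
                         min_locations,
                         consecutive_only = FALSE,
                         subsample_minutes = 0,
                         period_start,
                         period_end,
                         crs_epsg,
                         add_summary_columns = TRUE,
                         mark_done_on_import = FALSE) {
  label <- as.character(label)
  if (length(label) != 1L || is.na(label) || !nzchar(label))
    stop("'label' must be a non-empty string")
  if (grepl("[/\\\\]", label))
    stop("'label' must not contain path separators: ", label)
  buffer_m <- as.numeric(buffer_m)
  if (!is.finite(buffer_m) || buffer_m <= 0)
    stop("'buffer_m' must be > 0")
  min_locations <- as.integer(min_locations)
  if (is.na(min_locations) || min_locations < 2L)
    stop("'min_locations' must be an integer >= 2")
  subsample_minutes <- as.numeric(subsample_minutes)
  if (!is.finite(subsample_minutes) || subsample_minutes < 0)
    stop("'subsample_minutes' must be >= 0")
  period_start <- .as_utc(period_start)
  period_end <- .as_utc(period_end)
  if (is.na(period_start) || is.na(period_end))
    stop("'period_start'/'period_end' must be parseable timestamps")
  if (!(period_start < period_end))
    stop("'period_start' must be earlier than 'period_end'")
  crs_epsg <- as.integer(crs_epsg)
  if (is.na(crs_epsg) || crs_epsg <= 0)
    stop("'crs_epsg' must be a positive integer EPSG code")
  structure(list(
    label = label,
    buffer_m = buffer_m,
    min_locations = min_locations,
    consecutive_only = isTRUE(consecutive_only),
    subsample_minutes = subsample_minutes,
    period_start = period_start,
    period_end = period_end,
    crs_epsg = crs_epsg,
    add_summary_columns = isTRUE(add_summary_columns),
    mark_done_on_import = isTRUE(mark_done_on_import)
  ), class = "fixclust_config")
}

#' @export
print.fixclust_config <- function(x, ...) {
  cat("<fixclust_config> study '", x$label, "'\n", sep = "")
  cat("  buffer: ", x$buffer_m, " m (overlap at <= ", 2 * x$buffer_m,
      " m), min locations: ", x$min_locations,
      if (x$consecutive_only) ", consecutive-only" else "", "\n", sep = "")
  cat("  period: ", format(x$period_start, "%Y-%m-%d %H:%M:%S"), " .. ",
      format(x$period_end, "%Y-%m-%d %H:%M:%S"), " UTC\n", sep = "")
  cat("  subsample: ",
      if (x$subsample_minutes > 0) paste0("every ", x$subsample_minutes, " min")
      else "off (all fixes)",
      ", CRS: EPSG:", x$crs_epsg, "\n", sep = "")
  invisible(x)
}

# Fields that define the clustering and must match between runs of one study.
.config_match_fields <- c("label", "buffer_m", "min_locations",
                          "consecutive_only", "subsample_minutes",
                          "period_start", "period_end", "crs_epsg")

# Parse a timestamp as UTC. Accepts POSIXct, Date, and the string forms
# "YYYY-MM-DD HH:MM:SS", ISO 8601 "YYYY-MM-DDTHH:MM:SS[Z]", and "YYYY-MM-DD".
.as_utc <- function(t) {
  if (inherits(t, "POSIXct") || is.numeric(t))
    return(as.POSIXct(as.numeric(t), tz = "UTC", origin = "1970-01-01"))
  if (inherits(t, "Date")) return(as.POSIXct(format(t), tz = "UTC"))
  s <- trimws(as.character(t))
  s <- sub("Z$", "", s)
  s <- sub("T", " ", s, fixed = TRUE)
  out <- as.POSIXct(rep(NA_real_, length(s)), tz = "UTC", origin = "1970-01-01")
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(out) & !is.na(s)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(s[todo], tz = "UTC", format = fmt)
  }
  out
}
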