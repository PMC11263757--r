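# Settings sidecar: a plain-text `key = value` file written next to every
# cluster layer, recording all analysis parameters so that methods can be
# retraced across field seasons, and so that subsequent analyses restore the
# parameters automatically. The key set is fixed and the round trip through
# write_settings()/parse_settings() is lossless.

.settings_keys <- c("label", "buffer_m", "min_locations", "consecutive_only",
                    "subsample_minutes", "period_start", "period_end",
                    "crs_epsg", "add_summary_columns", "mark_done_on_import",
                    "analysis_time", "app_version", "source_fix_file")

.fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Write a settings sidecar file
#'
#' @param config a [study_config()].
#' @param path output file path (conventionally `<layer stem>_settings.txt`).
#' @param analysis_time timestamp of the analysis the sidecar belongs to.
#' @param source_fix_file name of the fix file the analysis consumed.
#' @return The path, invisibly.
#' @export
write_settings <- function(config, path, analysis_time = Sys.time(),
                           source_fix_file = "") {
  stopifnot(inherits(config, "fixclust_config"))
  analysis_time <- .as_utc(analysis_time)
  vals <- c(label = config$label,
            buffer_m = format(config$buffer_m, digits = 15),
            min_locations = as.character(config$min_locations),
            consecutive_only = as.character(config$consecutive_only),
            subsample_minutes = format(config$subsample_minutes, digits = 15),
            period_start = .fmt_time(config$period_start),
            period_end = .fmt_time(config$period_end),
            crs_epsg = as.character(config$crs_epsg),
            add_summary_columns = as.character(config$add_summary_columns),
            mark_done_on_import = as.character(config$mark_done_on_import),
            analysis_time = .fmt_time(analysis_time),
            app_version = as.character(utils::packageVersion("fixclust")),
            source_fix_file = as.character(source_fix_file))
  writeLines(paste(names(vals), "=", vals), path)
  invisible(path)
}

#' Parse a settings sidecar file
#'
#' @param path path to a file written by [write_settings()].
#' @return A list with `config` (a [study_config()]), `analysis_time`,
#'   `app_version` and `source_fix_file`.
#' @export
parse_settings <- function(path) {
  if (!file.exists(path)) stop("settings file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("corrupt settings file (unparseable line): ", path)
  kv <- stats::setNames(vapply(m, `[`, character(1), 3L),
                        vapply(m, `[`, character(1), 2L))
  miss <- setdiff(.settings_keys, names(kv))
  if (length(miss) > 0)
    stop("corrupt settings file, missing key(s): ", paste(miss, collapse = ", "))
  config <- study_config(
    label = kv[["label"]],
    buffer_m = as.numeric(kv[["buffer_m"]]),
    min_locations = as.integer(kv[["min_locations"]]),
    consecutive_only = as.logical(kv[["consecutive_only"]]),
    subsample_minutes = as.numeric(kv[["subsample_minutes"]]),
    period_start = kv[["period_start"]],
    period_end = kv[["period_end"]],
    crs_epsg = as.integer(kv[["crs_epsg"]]),
    add_summary_columns = as.logical(kv[["add_summary_columns"]]),
    mark_done_on_import = as.logical(kv[["mark_done_on_import"]]))
  list(config = config,
       analysis_time = .as_utc(kv[["analysis_time"]]),
       app_version = kv[["app_version"]],
       source_fix_file = kv[["source_fix_file"]])
}
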