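# Preprocessing pipeline. Order is fixed: validate -> filter_period ->
# subsample. Subsampling after the period filter anchors the greedy rule at
# each animal's first in-period fix.

#' Validate and tidy a fix table
#'
#' Sorts fixes by animal and timestamp, collapses exact duplicate
#' (animal, timestamp) rows keeping the first, and drops rows with non-finite
#' coordinates. The attached report counts each action.
#'
#' @param fixes a fix tibble (see [read_fixes()]).
#' @return The cleaned tibble, with attribute `"report"`: a list with
#'   `n_in`, `n_dropped_nonfinite`, `n_dropped_duplicate`, `n_out`.
#' @export
validate_fixes <- function(fixes) {
  fixes <- .as_fix_tibble(fixes)
  n_in <- nrow(fixes)
  finite <- is.finite(fixes$x) & is.finite(fixes$y)
  n_bad <- sum(!finite)
  fixes <- fixes[finite, , drop = FALSE]
  ord <- order(fixes$animal_id, fixes$timestamp)
  fixes <- fixes[ord, , drop = FALSE]
  dup <- duplicated(fixes[, c("animal_id", "timestamp")])
  n_dup <- sum(dup)
  fixes <- fixes[!dup, , drop = FALSE]
  if (n_in > 0 && nrow(fixes) == 0)
    stop("no usable fixes (all rows dropped during validation)")
  attr(fixes, "report") <- list(n_in = n_in,
                                n_dropped_nonfinite = n_bad,
                                n_dropped_duplicate = n_dup,
                                n_out = nrow(fixes))
  fixes
}

#' Restrict fixes to the study period
#'
#' Keeps fixes with `period_start <= timestamp <= period_end` (closed
#' interval on both ends, so a fix at exactly midnight on the last day is
#' inside).
#'
#' @param fixes a fix tibble, sorted per animal.
#' @param config a [study_config()].
#' @return The filtered tibble (possibly empty).
#' @export
filter_period <- function(fixes, config) {
  stopifnot(inherits(config, "fixclust_config"))
  fixes <- .as_fix_tibble(fixes)
  keep <- fixes$timestamp >= config$period_start &
    fixes$timestamp <= config$period_end
  fixes[keep, , drop = FALSE]
}

#' Regularise fix rate by greedy subsampling
#'
#' Per animal: keep the first fix, then keep each next fix whose timestamp is
#' at least `z_minutes` after the last kept fix. `z_minutes = 0` returns the
#' input unchanged. This neutralises burst/proximity oversampling: extra
#' fixes squeezed between the nominal schedule ticks are discarded, while a
#' schedule already at `z_minutes` passes through untouched.
#'
#' The operation is idempotent, and all inter-fix gaps in the output are
#' `>= z_minutes`.
#'
#' @param fixes a fix tibble, sorted ascending in time per animal.
#' @param z_minutes minimum minutes between kept fixes (>= 0).
#' @return The subsampled tibble.
#' @export
subsample_fixes <- function(fixes, z_minutes) {
  stopifnot(is.numeric(z_minutes), length(z_minutes) == 1L, z_minutes >= 0)
  fixes <- .as_fix_tibble(fixes)
  if (z_minutes == 0 || nrow(fixes) == 0) return(fixes)
  zs <- z_minutes * 60
  keep <- logical(nrow(fixes))
  for (idx in split(seq_len(nrow(fixes)), fixes$animal_id)) {
    t <- as.numeric(fixes$timestamp[idx])
    last <- -Inf
    for (j in seq_along(idx)) {
      if (t[j] - last >= zs || !is.finite(last)) {
        keep[idx[j]] <- TRUE
        last <- t[j]
      }
    }
  }
  fixes[keep, , drop = FALSE]
}

#' Run the full preprocessing pipeline
#'
#' `validate_fixes()`, then [filter_period()], then [subsample_fixes()] with
#' the configured interval.
#'
#' @inheritParams filter_period
#' @return The preprocessed tibble; attribute `"report"` carries the
#'   validation counts plus `n_outside_period` and `n_subsampled_out`.
#' @export
preprocess_fixes <- function(fixes, config) {
  fixes <- validate_fixes(fixes)
  report <- attr(fixes, "report")
  in_period <- filter_period(fixes, config)
  report$n_outside_period <- nrow(fixes) - nrow(in_period)
  out <- subsample_fixes(in_period, config$subsample_minutes)
  report$n_subsampled_out <- nrow(in_period) - nrow(out)
  report$n_used <- nrow(out)
  attr(out, "report") <- report
  out
}

# Canonical fix tibble: ensure required columns exist with the right types.
.fix_columns <- c("animal_id", "timestamp", "x", "y", "lon", "lat",
                  "point_id", "cluster_seq")

.as_fix_tibble <- function(fixes) {
  if (is.null(fixes)) fixes <- list()
  fixes <- tibble::as_tibble(fixes)
  need <- c("animal_id", "timestamp", "x", "y")
  miss <- setdiff(need, names(fixes))
  if (length(miss) > 0 && nrow(fixes) > 0)
    stop("fix table lacks required column(s): ", paste(miss, collapse = ", "))
  n <- nrow(fixes)
  if (!"animal_id" %in% names(fixes)) fixes$animal_id <- character(n)
  if (!"timestamp" %in% names(fixes)) fixes$timestamp <- .as_utc(character(n))
  if (!"x" %in% names(fixes)) fixes$x <- numeric(n)
  if (!"y" %in% names(fixes)) fixes$y <- numeric(n)
  if (!"lon" %in% names(fixes)) fixes$lon <- rep(NA_real_, n)
  if (!"lat" %in% names(fixes)) fixes$lat <- rep(NA_real_, n)
  if (!"point_id" %in% names(fixes)) fixes$point_id <- rep(NA_character_, n)
  if (!"cluster_seq" %in% names(fixes)) fixes$cluster_seq <- rep(NA_integer_, n)
  fixes$animal_id <- as.character(fixes$animal_id)
  fixes$timestamp <- .as_utc(fixes$timestamp)
  fixes$cluster_seq <- as.integer(fixes$cluster_seq)
  fixes[, .fix_columns]
}
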