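# Subsequent analyses. Clustering itself is always recomputed on the full
# fix set (old + new) — with unchanged parameters this is deterministic and
# components can only grow or merge as fixes accumulate — and reconciliation
# then relabels the fresh clusters so that every previously issued cluster
# ID keeps naming the same site. IDs are never reused: a cluster absorbed in
# a merge retires its ID permanently, and new clusters continue numbering
# above the highest seq ever issued for that animal.

#' Convert an analysis result to a previous-analysis object
#'
#' In-memory equivalent of [write_cluster_file()] followed by
#' [discover_previous()]; useful for pipelines that keep everything in R.
#'
#' @param result a `fixclust_result`.
#' @param source_fix_file recorded in the synthetic sidecar.
#' @return A `fixclust_previous` object.
#' @export
as_previous <- function(result, source_fix_file = "") {
  stopifnot(inherits(result, "fixclust_result"))
  cl <- result$clusters
  cl$member_times <- lapply(seq_len(nrow(cl)), function(i) .member_times(result, i))
  structure(list(clusters = cl,
                 sidecar = list(config = result$config,
                                analysis_time = result$analysis_time,
                                app_version = as.character(utils::packageVersion("fixclust")),
                                source_fix_file = source_fix_file),
                 issued_seq = result$issued_seq,
                 path = NA_character_),
            class = "fixclust_previous")
}

#' Reconcile a fresh analysis with the previous run
#'
#' Matches every cluster of `current` (computed on the complete fix set)
#' against the clusters of the previous analysis via their member fixes:
#'
#' * identical member set: the previous ID and editable columns carry over
#'   (state `"Done"` stays `"Done"`);
#' * previous members plus new ones: same ID, state becomes `"Grown"`;
#' * members of two or more previous clusters: the lowest previous seq
#'   number survives as the ID, the others are recorded as absorbed and
#'   their editable columns are folded into the survivor's notes;
#' * no previous members: a new ID, numbered from one above the highest seq
#'   ever issued for that animal.
#'
#' With `mark_done_on_import` in the config, all previous clusters enter as
#' state `"Done"` before matching.
#'
#' @param current a `fixclust_result` computed with [run_analysis()] on the
#'   full (old + new) fix set.
#' @param previous a `fixclust_previous` from [discover_previous()] or
#'   [as_previous()].
#' @param config the run's [study_config()]; must agree with the previous
#'   sidecar on every clustering-relevant field (label, buffer, minimum
#'   locations, consecutive flag, subsampling, period, CRS) — parameters
#'   must stay constant through a study period.
#' @return A list with `result` (the relabelled `fixclust_result`) and
#'   `report` (a `fixclust_reconciliation`: `kept_ids`, `grown_ids`,
#'   `merged` data.frame of absorbed/surviving pairs, `new_ids`).
#' @export
reconcile <- function(current, previous, config) {
  stopifnot(inherits(current, "fixclust_result"),
            inherits(previous, "fixclust_previous"),
            inherits(config, "fixclust_config"))
  .check_config_match(config, previous$sidecar$config)
  prev <- previous$clusters
  if (isTRUE(config$mark_done_on_import) && nrow(prev) > 0)
    prev$state <- rep("Done", nrow(prev))

  fix_key <- paste(current$fixes$animal_id, as.numeric(current$fixes$timestamp))
  cur <- current$clusters
  # current cluster index for every fix key
  fix_cluster <- rep(NA_integer_, nrow(current$fixes))
  if (nrow(cur) > 0) {
    cur_key <- paste(cur$animal_id, cur$seq_number)
    this_key <- paste(current$fixes$animal_id, current$fixes$cluster_seq)
    fix_cluster <- match(this_key, cur_key)
  }

  # locate each previous cluster inside the current partition
  prev_target <- rep(NA_integer_, nrow(prev))
  for (i in seq_len(nrow(prev))) {
    keys <- paste(prev$animal_id[i], as.numeric(prev$member_times[[i]]))
    at <- match(keys, fix_key)
    if (anyNA(at))
      stop("previous cluster ", prev$cluster_id[i], " has member fixes absent ",
           "from the current fix set (fix file truncated or subsampling ",
           "anchor shifted); supply the complete fix history")
    targets <- unique(fix_cluster[at])
    if (length(targets) != 1L || is.na(targets))
      stop("previous cluster ", prev$cluster_id[i], " no longer maps into a ",
           "single current cluster; the fix set is inconsistent with the ",
           "previous analysis")
    prev_target[i] <- targets
  }

  kept <- character(0); grown <- character(0); new_ids <- character(0)
  merged <- data.frame(absorbed_id = character(0), surviving_id = character(0),
                       stringsAsFactors = FALSE)
  new_seq <- integer(nrow(cur))
  state <- cur$state; event <- cur$event; date_done <- cur$date_done
  technician <- cur$technician; notes <- cur$notes

  # next fresh seq per animal: one above anything previously issued,
  # including seq numbers retired by earlier merges (high-water mark)
  prev_max <- tapply(prev$seq_number, prev$animal_id, max)
  high_water <- previous$issued_seq
  if (is.null(high_water)) high_water <- integer(0)
  next_seq <- function(animal) {
    base <- if (animal %in% names(prev_max)) prev_max[[animal]] else 0L
    if (animal %in% names(high_water))
      base <- max(base, high_water[[animal]])
    as.integer(base)
  }

  counters <- integer(0)  # per-animal running counter for fresh IDs
  order_new <- order(cur$first_time)  # new clusters numbered by first visit
  for (ci in seq_len(nrow(cur))) new_seq[ci] <- NA_integer_
  for (ci in seq_len(nrow(cur))) {
    matched <- which(prev_target == ci)
    if (length(matched) == 0) next
    surv <- matched[which.min(prev$seq_number[matched])]
    new_seq[ci] <- prev$seq_number[surv]
    event[ci] <- prev$event[surv]
    date_done[ci] <- prev$date_done[surv]
    technician[ci] <- prev$technician[surv]
    notes[ci] <- prev$notes[surv]
    surv_id <- paste0(cur$animal_id[ci], "_", prev$seq_number[surv])
    if (length(matched) > 1) {
      state[ci] <- "Grown"
      for (ab in setdiff(matched, surv)) {
        merged <- rbind(merged, data.frame(absorbed_id = prev$cluster_id[ab],
                                           surviving_id = surv_id,
                                           stringsAsFactors = FALSE))
        extras <- c(event = prev$event[ab],
                    date_done = if (is.na(prev$date_done[ab])) "" else format(prev$date_done[ab]),
                    technician = prev$technician[ab],
                    notes = prev$notes[ab])
        extras <- extras[nzchar(extras)]
        tagline <- paste0("[absorbed ", prev$cluster_id[ab],
                          if (length(extras) > 0)
                            paste0(": ", paste(names(extras), extras,
                                               sep = "=", collapse = "; "))
                          else "",
                          "]")
        notes[ci] <- trimws(paste(notes[ci], tagline))
      }
    } else {
      prev_n <- length(prev$members[[surv]])
      if (cur$n_inside[ci] > prev_n) {
        state[ci] <- "Grown"
        grown <- c(grown, surv_id)
      } else {
        state[ci] <- prev$state[surv]
        kept <- c(kept, surv_id)
      }
    }
  }
  # fresh IDs for unmatched clusters, in order of first visit
  for (ci in order_new) {
    if (!is.na(new_seq[ci])) next
    animal <- cur$animal_id[ci]
    nxt <- if (animal %in% names(counters)) counters[[animal]] + 1L
           else next_seq(animal) + 1L
    counters[[animal]] <- nxt
    new_seq[ci] <- nxt
    state[ci] <- "New"
    new_ids <- c(new_ids, paste0(animal, "_", nxt))
  }

  # relabel the result
  seq_map_key <- paste(cur$animal_id, cur$seq_number)
  cur$seq_number <- new_seq
  cur$cluster_id <- paste0(cur$animal_id, "_", new_seq)
  cur$state <- state; cur$event <- event; cur$date_done <- date_done
  cur$technician <- technician; cur$notes <- notes
  fixes <- current$fixes
  remap <- match(paste(fixes$animal_id, fixes$cluster_seq), seq_map_key)
  fixes$cluster_seq <- ifelse(is.na(remap), NA_integer_, new_seq[remap])
  fixes <- assign_point_ids(fixes)
  if (nrow(cur) > 0) {
    cur$members <- lapply(seq_len(nrow(cur)), function(i) {
      fixes$point_id[fixes$animal_id == cur$animal_id[i] &
                       !is.na(fixes$cluster_seq) &
                       fixes$cluster_seq == cur$seq_number[i]]
    })
    cur <- cur[order(cur$animal_id, cur$seq_number), , drop = FALSE]
  }
  hw_new <- .seq_high_water(cur)
  animals <- union(names(hw_new), names(high_water))
  issued <- stats::setNames(vapply(animals, function(a) {
    max(if (a %in% names(hw_new)) hw_new[[a]] else 0L,
        if (a %in% names(high_water)) high_water[[a]] else 0L,
        if (a %in% names(prev_max)) as.integer(prev_max[[a]]) else 0L)
  }, integer(1)), animals)
  result <- structure(list(config = config, clusters = cur, fixes = fixes,
                           analysis_time = current$analysis_time,
                           report = current$report,
                           issued_seq = issued,
                           previous_analysis_time = previous$sidecar$analysis_time),
                      class = "fixclust_result")
  report <- structure(list(kept_ids = sort(kept), grown_ids = sort(grown),
                           merged = merged, new_ids = sort(new_ids)),
                      class = "fixclust_reconciliation")
  list(result = result, report = report)
}

#' @export
print.fixclust_reconciliation <- function(x, ...) {
  cat("<fixclust_reconciliation> kept:", length(x$kept_ids),
      " grown:", length(x$grown_ids),
      " merged:", nrow(x$merged),
      " new:", length(x$new_ids), "\n")
  if (nrow(x$merged) > 0)
    cat("  merges:", paste(x$merged$absorbed_id, "->", x$merged$surviving_id,
                           collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a reconciliation report to CSV
#'
#' @param report a `fixclust_reconciliation`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_reconciliation <- function(report, path) {
  stopifnot(inherits(report, "fixclust_reconciliation"))
  block <- function(ids, action, detail = "") {
    if (length(ids) == 0) return(NULL)
    data.frame(cluster_id = ids, action = action, detail = detail,
               stringsAsFactors = FALSE)
  }
  rows <- rbind(block(report$kept_ids, "kept"),
                block(report$grown_ids, "grown"),
                block(report$merged$absorbed_id, "absorbed",
                      report$merged$surviving_id),
                block(report$new_ids, "new"))
  if (is.null(rows))
    rows <- data.frame(cluster_id = character(0), action = character(0),
                       detail = character(0), stringsAsFactors = FALSE)
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

.check_config_match <- function(config, prev_config) {
  bad <- character(0)
  for (f in .config_match_fields) {
    a <- config[[f]]; b <- prev_config[[f]]
    same <- if (inherits(a, "POSIXct")) {
      isTRUE(all.equal(as.numeric(a), as.numeric(b)))
    } else if (is.numeric(a)) {
      isTRUE(all.equal(a, b))
    } else {
      identical(a, b)
    }
    if (!same) bad <- c(bad, f)
  }
  if (length(bad) > 0)
    stop("analysis parameters differ from the previous run (parameters must ",
         "stay constant through the study period): ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Check batch/incremental equivalence on a fix set
#'
#' Test utility: runs the analysis once on all fixes, and once as a
#' two-stage pipeline (fixes up to `split_time`, then reconciliation with
#' the full set), and compares the resulting member partitions. IDs may
#' differ only where merges occurred; the partition itself must be
#' identical.
#'
#' @param fixes fix tibble.
#' @param split_time instant separating "old" from "new" fixes.
#' @param config a [study_config()].
#' @return `TRUE` when the partitions coincide.
#' @export
batch_equivalence_check <- function(fixes, split_time, config) {
  fixes <- .as_fix_tibble(fixes)
  split_time <- .as_utc(split_time)
  full <- run_analysis(fixes, config)
  first <- run_analysis(fixes[fixes$timestamp <= split_time, , drop = FALSE],
                        config)
  two <- reconcile(run_analysis(fixes, config), as_previous(first), config)
  identical(.partition_sets(full), .partition_sets(two$result))
}

# canonical member partition: sorted list of sorted member-key vectors
.partition_sets <- function(result) {
  keys <- paste(result$fixes$animal_id, as.numeric(result$fixes$timestamp))
  grp <- paste(result$fixes$animal_id, result$fixes$cluster_seq)
  grp[is.na(result$fixes$cluster_seq)] <- NA
  parts <- split(keys, grp)
  parts <- lapply(parts, sort)
  unname(parts[order(vapply(parts, `[`, character(1), 1L))])
}
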