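# Full analysis pipeline: preprocessing, per-animal clustering, cluster
# numbering, polygons, summaries and point IDs, assembled into an
# `fixclust_result`.

#' Summarise a cluster
#'
#' Computes the overview attributes of one cluster from its member fixes and
#' the animal's full (preprocessed) fix table: first/last member timestamp,
#' fixes inside, fixes of the same animal outside the cluster during the
#' first-to-last-visit window, percent time (fix-count based:
#' `100 * n_inside / (n_inside + n_outside)`), and the arithmetic mean
#' center of the member coordinates.
#'
#' @param cluster_members fix tibble of the member fixes.
#' @param all_animal_fixes fix tibble of all the animal's fixes (members
#'   included).
#' @return A one-row data.frame with `first_time`, `last_time`, `n_inside`,
#'   `n_outside`, `percent_time`, `mean_x`, `mean_y`.
#' @export
summarize_cluster <- function(cluster_members, all_animal_fixes) {
  stopifnot(nrow(cluster_members) >= 1)
  first_time <- min(cluster_members$timestamp)
  last_time <- max(cluster_members$timestamp)
  n_inside <- nrow(cluster_members)
  member_key <- paste(cluster_members$animal_id, as.numeric(cluster_members$timestamp))
  all_key <- paste(all_animal_fixes$animal_id, as.numeric(all_animal_fixes$timestamp))
  in_window <- all_animal_fixes$timestamp >= first_time &
    all_animal_fixes$timestamp <= last_time
  n_outside <- sum(in_window & !(all_key %in% member_key))
  data.frame(first_time = first_time, last_time = last_time,
             n_inside = n_inside, n_outside = n_outside,
             percent_time = 100 * n_inside / (n_inside + n_outside),
             mean_x = mean(cluster_members$x), mean_y = mean(cluster_members$y))
}

#' Assign point IDs to a fix table
#'
#' The point ID is `<animal>_<C{seq}|SP>_<MMDDHH>`: the animal, the cluster
#' number the fix belongs to (or `SP` for a single point), and zero-padded
#' month, day and hour of the fix. When two fixes of one animal would share
#' an ID within the same hour, the minute is appended to each of them; any
#' remaining ties get a running letter. All resulting IDs are unique.
#'
#' @param fixes fix tibble with `cluster_seq` filled (NA = single point).
#' @return The tibble with `point_id` assigned.
#' @export
assign_point_ids <- function(fixes) {
  fixes <- .as_fix_tibble(fixes)
  if (nrow(fixes) == 0) return(fixes)
  tag <- ifelse(is.na(fixes$cluster_seq), "SP",
                paste0("C", fixes$cluster_seq))
  base <- paste(fixes$animal_id, tag, format(fixes$timestamp, "%m%d%H"), sep = "_")
  id <- base
  dup_groups <- unique(base[duplicated(base)])
  if (length(dup_groups) > 0) {
    for (g in dup_groups) {
      at <- which(base == g)
      id[at] <- paste0(base[at], format(fixes$timestamp[at], "%M"))
    }
    still <- unique(id[duplicated(id)])
    for (g in still) {
      at <- which(id == g)
      id[at] <- paste0(id[at], letters[seq_along(at)])
    }
  }
  fixes$point_id <- id
  fixes
}

#' Run a complete cluster analysis
#'
#' The full pipeline on one or more animals: validation, study-period
#' filtering, optional z-minute subsampling, per-animal clustering (default
#' or consecutive-only mode per the config), cluster numbering by time of
#' first visit (earliest cluster = 1, per animal), buffer-union polygons,
#' summary attributes and point IDs. Every cluster starts in state `"New"`.
#' Animals are never pooled: clusters belong to a single animal and cluster
#' IDs are `<animal>_<seq>`.
#'
#' @param fixes fix tibble for all animals (see [read_fixes()] or
#'   [generate_tracks()]).
#' @param config a [study_config()].
#' @return An object of class `fixclust_result`: a list with `config`,
#'   `clusters` (tibble, one row per cluster), `fixes` (the preprocessed fix
#'   tibble with `point_id` and `cluster_seq` filled), `analysis_time`, and
#'   `report` (preprocessing counts).
#' @export
run_analysis <- function(fixes, config) {
  stopifnot(inherits(config, "fixclust_config"))
  fixes <- .as_fix_tibble(fixes)
  if (nrow(fixes) > 0) {
    fixes <- preprocess_fixes(fixes, config)
  }
  report <- attr(fixes, "report")
  fixes$cluster_seq <- rep(NA_integer_, nrow(fixes))
  cluster_rows <- list()
  for (animal in unique(fixes$animal_id)) {
    sel <- which(fixes$animal_id == animal)
    sub <- fixes[sel, , drop = FALSE]
    part <- if (config$consecutive_only) {
      find_clusters_consecutive(sub, config)
    } else {
      find_clusters(sub, config)
    }
    if (length(part$clusters) == 0) next
    # number clusters by first member time, earliest = 1
    first_times <- vapply(part$clusters,
                          function(ix) min(as.numeric(sub$timestamp[ix])),
                          numeric(1))
    ord <- order(first_times)
    for (s in seq_along(ord)) {
      ix <- part$clusters[[ord[s]]]
      fixes$cluster_seq[sel[ix]] <- s
      members <- sub[ix, , drop = FALSE]
      summ <- summarize_cluster(members, sub)
      poly <- build_polygon(members, config$buffer_m)
      cluster_rows[[length(cluster_rows) + 1L]] <- tibble::tibble(
        animal_id = animal,
        seq_number = s,
        cluster_id = paste0(animal, "_", s),
        n_inside = summ$n_inside,
        n_outside = summ$n_outside,
        percent_time = summ$percent_time,
        first_time = summ$first_time,
        last_time = summ$last_time,
        mean_x = summ$mean_x,
        mean_y = summ$mean_y,
        state = "New",
        event = "",
        date_done = as.Date(NA),
        technician = "",
        notes = "",
        members = list(integer(0)),  # filled below with point ids
        polygon = list(poly))
    }
  }
  fixes <- assign_point_ids(fixes)
  clusters <- if (length(cluster_rows) > 0) {
    do.call(rbind, cluster_rows)
  } else {
    .empty_cluster_tibble()
  }
  # member point ids, in time order
  if (nrow(clusters) > 0) {
    clusters$members <- lapply(seq_len(nrow(clusters)), function(i) {
      fixes$point_id[fixes$animal_id == clusters$animal_id[i] &
                       !is.na(fixes$cluster_seq) &
                       fixes$cluster_seq == clusters$seq_number[i]]
    })
  }
  clusters <- .add_geo_centers(clusters, config)
  structure(list(config = config,
                 clusters = clusters,
                 fixes = .derive_lonlat(fixes, config),
                 analysis_time = .as_utc(Sys.time()),
                 report = report,
                 issued_seq = .seq_high_water(clusters)),
            class = "fixclust_result")
}

#' @export
print.fixclust_result <- function(x, ...) {
  cat("<fixclust_result> study '", x$config$label, "': ",
      nrow(x$clusters), " cluster(s) from ", nrow(x$fixes), " fixes, ",
      length(unique(x$fixes$animal_id)), " animal(s)\n", sep = "")
  if (nrow(x$clusters) > 0) {
    tab <- table(x$clusters$animal_id)
    cat("  clusters per animal: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# highest seq number per animal; the high-water mark below which IDs are
# never (re)issued
.seq_high_water <- function(clusters) {
  if (nrow(clusters) == 0) return(stats::setNames(integer(0), character(0)))
  hw <- tapply(clusters$seq_number, clusters$animal_id, max)
  stats::setNames(as.integer(hw), names(hw))
}

.empty_cluster_tibble <- function() {
  tibble::tibble(animal_id = character(0), seq_number = integer(0),
                 cluster_id = character(0), n_inside = integer(0),
                 n_outside = integer(0), percent_time = numeric(0),
                 first_time = .as_utc(character(0)),
                 last_time = .as_utc(character(0)),
                 mean_x = numeric(0), mean_y = numeric(0),
                 state = character(0), event = character(0),
                 date_done = as.Date(character(0)),
                 technician = character(0), notes = character(0),
                 members = list(), polygon = list())
}

.add_geo_centers <- function(clusters, config) {
  if (nrow(clusters) > 0 && !is.null(utm_epsg_info(config$crs_epsg))) {
    ll <- utm_inverse(clusters$mean_x, clusters$mean_y, config$crs_epsg)
    clusters$mean_lon <- ll$lon
    clusters$mean_lat <- ll$lat
  } else {
    clusters$mean_lon <- rep(NA_real_, nrow(clusters))
    clusters$mean_lat <- rep(NA_real_, nrow(clusters))
  }
  clusters
}

# fill lon/lat from x/y where missing and the CRS allows it
.derive_lonlat <- function(fixes, config) {
  if (nrow(fixes) == 0 || is.null(utm_epsg_info(config$crs_epsg))) return(fixes)
  miss <- is.na(fixes$lon) | is.na(fixes$lat)
  if (any(miss)) {
    ll <- utm_inverse(fixes$x[miss], fixes$y[miss], config$crs_epsg)
    fixes$lon[miss] <- ll$lon
    fixes$lat[miss] <- ll$lat
  }
  fixes
}
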