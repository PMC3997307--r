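#' Capture effort per location
#'
#' Effort at a location (an exact coordinate pair) is the number of distinct
#' calendar dates with at least one capture there over the whole study
#' window. Note this is species-filtered effort: days on which a station
#' operated but caught nothing of the focal species are invisible in a
#' species-filtered record file.
#'
#' @param records capture records ([read_records()]).
#' @return data.frame with columns `lat`, `lon`, `effort_days`, sorted by
#'   descending effort then coordinates.
#' @export
compute_effort <- function(records) {
  if (nrow(records) == 0) stop("no records supplied")
  key <- paste(format(records$lat, digits = 12),
               format(records$lon, digits = 12), sep = "|")
  eff <- tapply(as.character(records$date), key,
                function(d) length(unique(d)))
  first_idx <- !duplicated(key)
  tab <- data.frame(lat = records$lat[first_idx], lon = records$lon[first_idx],
                    key = key[first_idx], stringsAsFactors = FALSE)
  tab$effort_days <- as.integer(eff[tab$key])
  tab$key <- NULL
  tab[order(-tab$effort_days, tab$lat, tab$lon), , drop = FALSE] ->
    tab
  rownames(tab) <- NULL
  tab
}

#' Filter locations by minimum capture effort
#'
#' @param effort_table output of [compute_effort()].
#' @param min_days minimum distinct capture days (default study rule: 24).
#' @return the retained rows, ordered by descending effort then coordinates.
#'   An empty result raises a warning; downstream modelling should not
#'   proceed without high-effort locations.
#' @export
filter_high_effort <- function(effort_table, min_days = 24L) {
  stopifnot(min_days >= 1)
  keep <- effort_table[effort_table$effort_days >= min_days, , drop = FALSE]
  keep <- keep[order(-keep$effort_days, keep$lat, keep$lon), , drop = FALSE]
  rownames(keep) <- NULL
  if (nrow(keep) == 0)
    warning("no locations meet the effort threshold; pipeline cannot proceed")
  cmr_log(sprintf("%d of %d locations at >= %d capture days",
                  nrow(keep), nrow(effort_table), min_days))
  keep
}

#' Pool captures onto high-effort sites
#'
#' Assigns every record lying within `radius` of at least one high-effort
#' location to its nearest one (ties broken towards the lower site id), then
#' maps locations to sites through `site_merge_map`, which groups locations
#' that are mutually within the radius and share a vegetation unit. Records
#' outside all radii are dropped with a logged count. The default distance
#' is Chebyshev (max of |dlat|, |dlon|): a radius quoted in minutes "South
#' and East" describes a box, not a disc; Euclidean is available via
#' `metric`.
#'
#' @param records capture records.
#' @param high_locations data.frame with `lat`, `lon` of retained locations
#'   ([filter_high_effort()]).
#' @param radius pooling radius in decimal degrees (default 0.17).
#' @param site_merge_map integer vector, one site id per row of
#'   `high_locations`; defaults to one site per location.
#' @param metric "chebyshev" or "euclidean".
#' @return the assigned records with a `site_id` column appended; attribute
#'   `n_dropped` counts records outside all radii.
#' @export
pool_captures <- function(records, high_locations, radius = 0.17,
                          site_merge_map = NULL, metric = "chebyshev") {
  stopifnot(radius > 0, nrow(high_locations) >= 1)
  metric <- match.arg(metric, c("chebyshev", "euclidean"))
  if (is.null(site_merge_map)) site_merge_map <- seq_len(nrow(high_locations))
  stopifnot(length(site_merge_map) == nrow(high_locations))

  dlat <- abs(outer(records$lat, high_locations$lat, "-"))
  dlon <- abs(outer(records$lon, high_locations$lon, "-"))
  d <- if (metric == "chebyshev") pmax(dlat, dlon) else sqrt(dlat^2 + dlon^2)

  site_id <- rep(NA_integer_, nrow(records))
  for (i in seq_len(nrow(records))) {
    within <- which(d[i, ] <= radius)
    if (length(within) == 0) next
    dmin <- min(d[i, within])
    cand <- within[d[i, within] == dmin]
    site_id[i] <- min(site_merge_map[cand])
  }
  dropped <- is.na(site_id)
  if (any(dropped))
    cmr_log(sprintf("dropped %d record(s) outside the %.3g-degree radius",
                    sum(dropped), radius))
  out <- records[!dropped, , drop = FALSE]
  out$site_id <- site_id[!dropped]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(dropped)
  out
}

#' Classify a site as migratory or sedentary by latitude
#'
#' Populations strictly south of the threshold latitude (default 26 deg S,
#' i.e. -26) are classed migratory; a site exactly on the threshold is
#' sedentary.
#'
#' @param site_lat latitude(s), decimal degrees (southern negative).
#' @param threshold_lat split latitude (default -26).
#' @return logical vector: TRUE = migratory.
#' @export
classify_migratory <- function(site_lat, threshold_lat = -26) {
  stopifnot(all(site_lat >= -90 & site_lat <= 90))
  site_lat < threshold_lat
}

#' Build encounter histories from site-assigned records
#'
#' Each record is mapped to its annual occasion (the Aug-Jul year containing
#' its date, for the default August boundary); multiple captures of one bird
#' within an occasion collapse to a single detection. An individual's site
#' is that of its first capture. Individuals first captured at the final
#' occasion are excluded (after conditioning on first capture they carry no
#' likelihood information); their count is logged.
#'
#' @param site_records records with a `site_id` column ([pool_captures()]).
#' @param config [run_config()] defining the study window and occasion
#'   boundary month.
#' @return object of class `encounter_histories`: list with `detections`
#'   (individuals x T 0/1 matrix, rownames = ring ids), `site_index`
#'   (per-individual site id), `first_capture` (occasion of first
#'   detection), `occasion_labels`, `site_levels`.
#' @export
build_histories <- function(site_records, config = run_config()) {
  stopifnot("site_id" %in% names(site_records))
  start_year <- as.integer(format(config$study_start, "%Y"))
  bm <- config$occasion_month

  out_of_window <- site_records$date < config$study_start |
    site_records$date > config$study_end
  if (any(out_of_window)) {
    i <- which(out_of_window)[1]
    stop(sprintf("record outside study window: ring %s on %s",
                 site_records$ring_id[i],
                 format(site_records$date[i])))
  }

  yr <- as.integer(format(site_records$date, "%Y"))
  mo <- as.integer(format(site_records$date, "%m"))
  occ_year <- ifelse(mo >= bm, yr, yr - 1L)
  occ <- occ_year - start_year + 1L

  end_year <- as.integer(format(config$study_end, "%Y"))
  end_month <- as.integer(format(config$study_end, "%m"))
  T_occ <- (if (end_month >= bm) end_year else end_year - 1L) - start_year + 1L

  ids <- unique(site_records$ring_id)
  det <- matrix(0L, nrow = length(ids), ncol = T_occ,
                dimnames = list(ids, NULL))
  det[cbind(match(site_records$ring_id, ids), occ)] <- 1L

  ord <- order(match(site_records$ring_id, ids), site_records$date)
  first_rec <- ord[!duplicated(site_records$ring_id[ord])]
  site_index <- site_records$site_id[first_rec][
    match(ids, site_records$ring_id[first_rec])]
  first_capture <- apply(det, 1, function(r) which(r == 1L)[1])

  last_only <- first_capture == T_occ
  if (any(last_only))
    cmr_log(sprintf("excluded %d individual(s) first captured at the final occasion",
                    sum(last_only)))
  det <- det[!last_only, , drop = FALSE]
  site_index <- site_index[!last_only]
  first_capture <- first_capture[!last_only]

  labels <- sprintf("Aug %d-Jul %d", start_year + seq_len(T_occ) - 1L,
                    start_year + seq_len(T_occ))
  structure(list(detections = det, site_index = as.integer(site_index),
                 first_capture = as.integer(unname(first_capture)),
                 occasion_labels = labels,
                 site_levels = sort(unique(as.integer(site_index)))),
            class = "encounter_histories")
}

#' Construct an encounter-histories object directly
#'
#' Used by the synthetic generator and tests; applies the same validity
#' rules as [build_histories()].
#'
#' @param detections individuals x occasions 0/1 matrix.
#' @param site_index per-individual site id.
#' @param occasion_labels optional labels.
#' @return `encounter_histories` object.
#' @export
encounter_histories <- function(detections, site_index,
                                occasion_labels = NULL) {
  detections <- as.matrix(detections)
  storage.mode(detections) <- "integer"
  stopifnot(all(detections %in% c(0L, 1L)),
            length(site_index) == nrow(detections),
            all(rowSums(detections) >= 1))
  first_capture <- if (nrow(detections) == 0) integer() else
    apply(detections, 1, function(r) which(r == 1L)[1])
  stopifnot(all(first_capture < ncol(detections)))
  structure(list(detections = detections,
                 site_index = as.integer(site_index),
                 first_capture = as.integer(unname(first_capture)),
                 occasion_labels = occasion_labels %||%
                   paste0("occ_", seq_len(ncol(detections))),
                 site_levels = sort(unique(as.integer(site_index)))),
            class = "encounter_histories")
}

#' @export
print.encounter_histories <- function(x, ...) {
  cat(sprintf("Encounter histories: %d individuals x %d occasions, %d site(s)\n",
              nrow(x$detections), ncol(x$detections), length(x$site_levels)))
  cat(sprintf("  recaptured at least once: %d\n",
              sum(rowSums(x$detections) > 1)))
  invisible(x)
}

#' Subset encounter histories by site
#'
#' @param histories `encounter_histories` object.
#' @param sites site ids to keep.
#' @return `encounter_histories` restricted to those individuals.
#' @export
subset_histories <- function(histories, sites) {
  keep <- histories$site_index %in% sites
  structure(list(detections = histories$detections[keep, , drop = FALSE],
                 site_index = histories$site_index[keep],
                 first_capture = histories$first_capture[keep],
                 occasion_labels = histories$occasion_labels,
                 site_levels = sort(unique(histories$site_index[keep]))),
            class = "encounter_histories")
}

#' Build the reduced m-array
#'
#' Standard reduced m-array: every detection at occasion i < T is a release
#' (re-releases included; no losses on capture); `m[i, j]` counts first
#' reencounters at occasion j > i, and `never[i]` the releases at i never
#' seen again.
#'
#' @param histories `encounter_histories` object (typically one site, or
#'   pooled).
#' @return object of class `marray`: list with `R` (releases, length T-1),
#'   `m` (T-1 x T matrix, entries only for j > i), `never` (length T-1).
#' @export
build_marray <- function(histories) {
  det <- histories$detections
  T_occ <- ncol(det)
  R <- integer(T_occ - 1)
  m <- matrix(0L, nrow = T_occ - 1, ncol = T_occ)
  never <- integer(T_occ - 1)
  for (ind in seq_len(nrow(det))) {
    seen <- which(det[ind, ] == 1L)
    for (k in seq_along(seen)) {
      i <- seen[k]
      if (i == T_occ) next
      R[i] <- R[i] + 1L
      if (k < length(seen)) m[i, seen[k + 1]] <- m[i, seen[k + 1]] + 1L
      else never[i] <- never[i] + 1L
    }
  }
  structure(list(R = R, m = m, never = never), class = "marray")
}

#' @export
print.marray <- function(x, ...) {
  cat("Reduced m-array:", length(x$R), "release occasions\n")
  tab <- cbind(R = x$R, x$m[, -1, drop = FALSE], never = x$never)
  colnames(tab) <- c("R", paste0("j", 2:ncol(x$m)), "never")
  print(tab)
  invisible(x)
}

#' Write / read encounter histories as delimited text
#'
#' Columns: `ring_id`, `site_id`, then one 0/1 column per occasion.
#'
#' @param histories `encounter_histories` object.
#' @param path output path.
#' @return `path` (write) or an `encounter_histories` object (read).
#' @export
write_histories <- function(histories, path) {
  df <- data.frame(ring_id = rownames(histories$detections) %||%
                     paste0("ind_", seq_len(nrow(histories$detections))),
                   site_id = histories$site_index,
                   stringsAsFactors = FALSE)
  occ <- as.data.frame(histories$detections)
  names(occ) <- paste0("occ_", seq_len(ncol(occ)))
  utils::write.csv(cbind(df, occ), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_histories
#' @export
read_histories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  occ_cols <- grep("^occ_", names(df))
  det <- as.matrix(df[, occ_cols, drop = FALSE])
  rownames(det) <- df$ring_id
  colnames(det) <- NULL
  encounter_histories(det, df$site_id)
}
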