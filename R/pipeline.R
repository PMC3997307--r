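#' Run the preprocessing pipeline end to end
#'
#' Convenience wrapper chaining [compute_effort()], [filter_high_effort()],
#' [pool_captures()] and [build_histories()]. High-effort locations are
#' mapped to the sites of `site_table` by nearest center (within the
#' pooling radius); locations matching no listed site keep their own fresh
#' site id, with a warning, so an incomplete site table is visible rather
#' than silently absorbed.
#'
#' @param records capture records ([read_records()] dialect).
#' @param site_table site metadata with `site_id`, `center_lat`,
#'   `center_lon` (used for the location-to-site merge map).
#' @param config [run_config()].
#' @return list: `effort`, `high_locations`, `pooled` (site-assigned
#'   records), `histories` (`encounter_histories`), `n_dropped`.
#' @export
preprocess_records <- function(records, site_table, config = run_config()) {
  effort <- compute_effort(records)
  high <- filter_high_effort(effort, config$min_effort_days)
  if (nrow(high) == 0) stop("no high-effort locations; cannot proceed")

  dlat <- abs(outer(high$lat, site_table$center_lat, "-"))
  dlon <- abs(outer(high$lon, site_table$center_lon, "-"))
  d <- if (config$distance_metric == "chebyshev") pmax(dlat, dlon) else
    sqrt(dlat^2 + dlon^2)
  merge_map <- integer(nrow(high))
  next_id <- max(site_table$site_id) + 1L
  for (i in seq_len(nrow(high))) {
    j <- which.min(d[i, ])
    if (d[i, j] <= config$pooling_radius) {
      merge_map[i] <- site_table$site_id[j]
    } else {
      warning(sprintf("high-effort location (%.4f, %.4f) matches no site; given id %d",
                      high$lat[i], high$lon[i], next_id))
      merge_map[i] <- next_id
      next_id <- next_id + 1L
    }
  }

  pooled <- pool_captures(records, high, config$pooling_radius, merge_map,
                          config$distance_metric)
  histories <- build_histories(pooled, config)
  list(effort = effort, high_locations = high, pooled = pooled,
       histories = histories, n_dropped = attr(pooled, "n_dropped"))
}
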