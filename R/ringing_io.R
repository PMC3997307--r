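#' Read ringing capture records
#'
#' Reads a comma-delimited file of capture events, one row per capture, with
#' header columns `ring_id`, `date` (ISO 8601), `lat`, `lon`, `age`
#' (adult/juvenile/unknown). Coordinates are decimal degrees with southern
#' latitudes negative. Rows failing validation are collected and reported
#' with their line numbers; any invalid row aborts the read. Non-adult
#' records are dropped with a logged count, since the survival analysis is
#' restricted to adults.
#'
#' @param path path to the records file.
#' @param config optional [run_config()]; when supplied, capture dates are
#'   additionally required to fall inside the study window.
#' @param drop_non_adult drop juvenile/unknown age rows (default TRUE).
#' @return data.frame with columns `ring_id` (character), `date` (Date),
#'   `lat`, `lon` (numeric), `age` (character), one row per retained capture.
#' @export
read_records <- function(path, config = NULL, drop_non_adult = TRUE) {
  if (!file.exists(path)) stop("records file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("ring_id", "date", "lat", "lon", "age")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("records file missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0) {
    cmr_log("records file has no data rows", "WARN")
    return(data.frame(ring_id = character(), date = as.Date(character()),
                      lat = numeric(), lon = numeric(), age = character(),
                      stringsAsFactors = FALSE))
  }

  errors <- character()
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  lat <- suppressWarnings(as.numeric(raw$lat))
  lon <- suppressWarnings(as.numeric(raw$lon))
  for (i in seq_len(nrow(raw))) {
    row_errs <- character()
    if (is.na(dates[i])) row_errs <- c(row_errs, "unparseable date")
    if (is.na(lat[i]) || lat[i] < -90 || lat[i] > 90)
      row_errs <- c(row_errs, "latitude outside [-90, 90]")
    if (is.na(lon[i]) || lon[i] < -180 || lon[i] > 180)
      row_errs <- c(row_errs, "longitude outside [-180, 180]")
    if (!is.na(dates[i]) && !is.null(config) &&
        (dates[i] < config$study_start || dates[i] > config$study_end))
      row_errs <- c(row_errs, "date outside study window")
    if (length(row_errs) > 0)
      errors <- c(errors, sprintf("row %d: %s", i + 1L,
                                  paste(row_errs, collapse = "; ")))
  }
  if (length(errors) > 0)
    stop("invalid records:\n", paste(errors, collapse = "\n"))

  rec <- data.frame(ring_id = raw$ring_id, date = dates, lat = lat,
                    lon = lon, age = tolower(raw$age),
                    stringsAsFactors = FALSE)
  if (drop_non_adult) {
    non_adult <- rec$age != "adult"
    if (any(non_adult))
      cmr_log(sprintf("dropped %d non-adult capture(s)", sum(non_adult)))
    rec <- rec[!non_adult, , drop = FALSE]
    rownames(rec) <- NULL
  }
  rec
}

#' Write ringing capture records
#'
#' Inverse of [read_records()]: writes the comma-delimited dialect with
#' ISO 8601 dates. `read_records(write_records(x, p))` round-trips exactly.
#'
#' @param records data.frame as returned by [read_records()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- records
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out[, c("ring_id", "date", "lat", "lon", "age")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the site configuration table
#'
#' Reads per-site metadata: `site_id`, `center_lat`, `center_lon`,
#' `vegetation_unit`, `rainfall_regime` (summer/winter/irregular),
#' `migratory` (TRUE/FALSE), and the climate covariates `apcv` (annual
#' precipitation CV, percent), `mat` (mean annual temperature, deg C),
#' `mafd` (mean annual frost days). Climate values of `?` or empty are
#' parsed as missing (`NA`), never as zero.
#'
#' @param path path to the site table file.
#' @return data.frame, one row per site. Duplicate `site_id`s are fatal;
#'   an empty file yields an empty table with a warning.
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop("site table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = c("?", "NA", ""))
  if (nrow(raw) == 0) {
    cmr_log("site table is empty", "WARN")
    warning("site table is empty")
    return(data.frame(site_id = integer(), center_lat = numeric(),
                      center_lon = numeric(), vegetation_unit = character(),
                      rainfall_regime = character(), migratory = logical(),
                      apcv = numeric(), mat = numeric(), mafd = numeric(),
                      stringsAsFactors = FALSE))
  }
  required <- c("site_id", "center_lat", "center_lon", "vegetation_unit",
                "rainfall_regime", "migratory")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("site table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  sites <- data.frame(
    site_id = as.integer(raw$site_id),
    center_lat = as.numeric(raw$center_lat),
    center_lon = as.numeric(raw$center_lon),
    vegetation_unit = raw$vegetation_unit,
    rainfall_regime = raw$rainfall_regime,
    migratory = as.logical(raw$migratory),
    apcv = if ("apcv" %in% names(raw)) suppressWarnings(as.numeric(raw$apcv)) else NA_real_,
    mat = if ("mat" %in% names(raw)) suppressWarnings(as.numeric(raw$mat)) else NA_real_,
    mafd = if ("mafd" %in% names(raw)) suppressWarnings(as.numeric(raw$mafd)) else NA_real_,
    stringsAsFactors = FALSE)
  if ("reported_bin" %in% names(raw)) sites$reported_bin <- raw$reported_bin
  if (anyDuplicated(sites$site_id))
    stop("duplicate site_id in site table: ",
         paste(unique(sites$site_id[duplicated(sites$site_id)]), collapse = ", "))
  bad_regime <- !sites$rainfall_regime %in% c("summer", "winter", "irregular") &
    !is.na(sites$rainfall_regime)
  if (any(bad_regime))
    stop("unknown rainfall_regime: ",
         paste(unique(sites$rainfall_regime[bad_regime]), collapse = ", "))
  sites
}

#' @rdname read_site_table
#' @param sites data.frame of sites.
#' @export
write_site_table <- function(sites, path) {
  out <- sites
  for (cc in c("apcv", "mat", "mafd"))
    if (cc %in% names(out)) out[[cc]] <- ifelse(is.na(out[[cc]]), "?", out[[cc]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Holds every tunable of the pipeline with the study defaults: a 12-year
#' study window of annual August-July occasions (Aug 1998 - Jul 2010), a
#' 24-day minimum capture effort for a location to be retained, a pooling
#' radius of 0.17 decimal degrees, a migratory/sedentary split at 26 deg S,
#' and the MCMC protocol.
#'
#' @param study_start,study_end study window (Dates or ISO strings).
#' @param occasion_month first month of each annual occasion (8 = August).
#' @param min_effort_days minimum distinct capture days for a location.
#' @param pooling_radius pooling radius, decimal degrees.
#' @param distance_metric "chebyshev" (a radius in degrees South and East,
#'   i.e. a box) or "euclidean".
#' @param migratory_latitude sites strictly south of this latitude are
#'   classed migratory.
#' @param chains,iterations,burn_in,thinning,seed MCMC settings. The
#'   defaults (3 chains of 20,000, burn-in 10,000, thinning 10) are a
#'   scaled-down protocol suitable for simulation studies; set
#'   `iterations = 1e5, burn_in = 5e4, thinning = 20` for a full run.
#' @param logit_bound half-width of the uniform prior for the mean logit
#'   survival and recapture.
#' @param sd_upper upper bound of the uniform priors on the random-effect
#'   standard deviations.
#' @return object of class `run_config` (a named list).
#' @export
run_config <- function(study_start = "1998-08-01", study_end = "2010-07-31",
                       occasion_month = 8L, min_effort_days = 24L,
                       pooling_radius = 0.17, distance_metric = "chebyshev",
                       migratory_latitude = -26, chains = 3L,
                       iterations = 20000L, burn_in = 10000L, thinning = 10L,
                       seed = 1L, logit_bound = 5, sd_upper = 5) {
  cfg <- list(study_start = as.Date(study_start),
              study_end = as.Date(study_end),
              occasion_month = as.integer(occasion_month),
              min_effort_days = as.integer(min_effort_days),
              pooling_radius = as.numeric(pooling_radius),
              distance_metric = match.arg(distance_metric,
                                          c("chebyshev", "euclidean")),
              migratory_latitude = as.numeric(migratory_latitude),
              chains = as.integer(chains), iterations = as.integer(iterations),
              burn_in = as.integer(burn_in), thinning = as.integer(thinning),
              seed = as.integer(seed), logit_bound = as.numeric(logit_bound),
              sd_upper = as.numeric(sd_upper))
  stopifnot(cfg$study_start < cfg$study_end,
            cfg$burn_in < cfg$iterations, cfg$thinning >= 1,
            cfg$pooling_radius > 0, cfg$min_effort_days >= 1,
            cfg$chains >= 1, cfg$logit_bound > 0, cfg$sd_upper > 0)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path path of a `key: value` config file; unknown keys are fatal.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  vals <- stats::setNames(vapply(kv, `[`, "", 3L), vapply(kv, `[`, "", 2L))
  allowed <- names(formals(run_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, as.list(vals))
}

#' @rdname run_config
#' @param config a `run_config` object.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s: %s", k, as.character(v))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, as.character(x[[k]])))
  invisible(x)
}

#' Write pipeline outputs under a run directory
#'
#' Writes the resolved configuration, any supplied tables (as delimited
#' text) and a manifest listing every file, so a run can be reproduced
#' from its output directory alone.
#'
#' @param dir run directory (created if needed).
#' @param config the [run_config()] used.
#' @param tables named list of data.frames to write as `<name>.csv`.
#' @return character vector of files written, invisibly.
#' @export
write_run_outputs <- function(dir, config, tables = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  cfg_path <- file.path(dir, "config.txt")
  write_run_config(config, cfg_path)
  files <- c(files, cfg_path)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE, quote = FALSE)
    files <- c(files, p)
  }
  manifest <- file.path(dir, "MANIFEST.txt")
  writeLines(basename(files), manifest)
  cmr_log(sprintf("wrote %d file(s) under %s", length(files) + 1L, dir))
  invisible(c(files, manifest))
}
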