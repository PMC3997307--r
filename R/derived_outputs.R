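#' Per-draw site mean survival
#'
#' For each retained draw, the mean over intervals t of
#' invlogit(mu + eta_s + eps_t): the period-average survival of site s.
#' Averaging over the year effects per draw (rather than reporting
#' invlogit(mu + eta_s)) makes the quantity a period average on the
#' probability scale, and transforming per draw (not transforming the
#' posterior mean) respects the Jensen gap.
#'
#' @param fit `cmr_draws` object.
#' @param site site id (an element of `fit$site_levels`).
#' @return numeric vector, one value per retained draw (chains pooled).
#' @export
site_mean_survival <- function(fit, site) {
  s <- match(site, fit$site_levels)
  if (is.na(s)) stop("unknown site: ", site)
  mu <- get_draws(fit, "mu")
  eta <- get_draws(fit, sprintf("eta[%d]", s))
  eps <- matrix(vapply(seq_len(fit$K),
                       function(k) get_draws(fit, sprintf("eps[%d]", k)),
                       numeric(length(mu))),
                nrow = length(mu))
  rowMeans(invlogit(mu + eta + eps))
}

#' Site survival summary table
#'
#' Posterior mean and 95% CRI of the per-site mean survival for every site.
#'
#' @param fit `cmr_draws` object.
#' @return data.frame: `site_id`, `mean`, `lower`, `upper`.
#' @export
site_survival_summary <- function(fit) {
  rows <- lapply(fit$site_levels, function(s) {
    sm <- summarize_vector(site_mean_survival(fit, s))
    data.frame(site_id = s, mean = sm$mean, lower = sm$lower,
               upper = sm$upper)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group mean survival
#'
#' Per draw, the unweighted arithmetic mean of [site_mean_survival()] over
#' the member sites (e.g. a rainfall regime or the migratory/sedentary
#' split); a single-site group reduces to that site's summary.
#'
#' @param fit `cmr_draws` object.
#' @param sites site ids forming the group (non-empty).
#' @return one-row data.frame: `mean`, `lower`, `upper`, `n`.
#' @export
group_mean_survival <- function(fit, sites) {
  stopifnot(length(sites) >= 1)
  unknown <- setdiff(sites, fit$site_levels)
  if (length(unknown) > 0)
    stop("unknown site(s) in group: ", paste(unknown, collapse = ", "))
  per_site <- vapply(sites, function(s) site_mean_survival(fit, s),
                     numeric(dim(fit$draws)[1] * dim(fit$draws)[2]))
  summarize_vector(rowMeans(matrix(per_site, ncol = length(sites))))
}

#' Per-draw group survival draws
#'
#' The unsummarized counterpart of [group_mean_survival()], useful for
#' comparing groups draw by draw.
#'
#' @inheritParams group_mean_survival
#' @return numeric vector of per-draw group means.
#' @export
group_survival_draws <- function(fit, sites) {
  stopifnot(length(sites) >= 1)
  unknown <- setdiff(sites, fit$site_levels)
  if (length(unknown) > 0)
    stop("unknown site(s) in group: ", paste(unknown, collapse = ", "))
  per_site <- vapply(sites, function(s) site_mean_survival(fit, s),
                     numeric(dim(fit$draws)[1] * dim(fit$draws)[2]))
  rowMeans(matrix(per_site, ncol = length(sites)))
}

#' Climate seasonality score and bin
#'
#' The seasonality of a vegetation unit is scored by summing three climate
#' covariates: annual precipitation coefficient of variation (APCV,
#' percent), mean annual temperature (MAT, deg C) and mean annual frost
#' days (MAFD). Scores are binned at the configured breakpoints
#' (default 50, 80): below 50 low, 50 to below 80 intermediate, 80 and
#' above high. A missing covariate makes the score undefined (the site is
#' reported, not silently dropped).
#'
#' @param apcv,mat,mafd climate covariates (vectors; `NA` = missing).
#' @param breakpoints two increasing cut points (default `c(50, 80)`).
#' @return data.frame: `score` (NA when undefined) and `bin` ("low",
#'   "intermediate", "high" or "undefined").
#' @export
seasonality_score <- function(apcv, mat, mafd, breakpoints = c(50, 80)) {
  stopifnot(length(breakpoints) == 2, breakpoints[1] < breakpoints[2])
  score <- apcv + mat + mafd
  bin <- ifelse(is.na(score), "undefined",
         ifelse(score < breakpoints[1], "low",
         ifelse(score < breakpoints[2], "intermediate", "high")))
  data.frame(score = score, bin = bin, stringsAsFactors = FALSE)
}

#' Score seasonality for a whole site table
#'
#' Applies [seasonality_score()] to each site; when the table carries a
#' `reported_bin` column (+ = high, +- = intermediate, - = low), the
#' computed bins are compared against it and disagreements are flagged, so
#' discrepancies between a published labelling and the stated scoring rule
#' are surfaced rather than hidden.
#'
#' @param sites site table ([read_site_table()]).
#' @param breakpoints passed to [seasonality_score()].
#' @return the site table with `score`, `bin`, and (when reported labels
#'   exist) `reported` and `concordant` columns.
#' @export
score_sites <- function(sites, breakpoints = c(50, 80)) {
  sc <- seasonality_score(sites$apcv, sites$mat, sites$mafd, breakpoints)
  out <- cbind(sites, sc)
  if ("reported_bin" %in% names(sites)) {
    map <- c("+" = "high", "+-" = "intermediate", "-" = "low",
             "?" = "undefined")
    out$reported <- unname(map[as.character(sites$reported_bin)])
    out$reported[is.na(out$reported)] <- "undefined"
    out$concordant <- out$bin == out$reported
    n_bad <- sum(!out$concordant & out$bin != "undefined")
    if (n_bad > 0)
      cmr_log(sprintf(
        "%d site(s) where the computed seasonality bin disagrees with the reported label",
        n_bad), "WARN")
  }
  out
}

#' Posterior association between site survival and latitude
#'
#' Exploratory summary (not part of the core model): per draw, the Pearson
#' correlation between logit site mean survival and site latitude, giving
#' a posterior distribution of the cross-site correlation. Draws in which
#' the site survivals are constant (zero variance) have no defined
#' correlation and are excluded with a count.
#'
#' @param fit `cmr_draws` object (>= 3 sites).
#' @param site_latitudes numeric latitudes, one per `fit$site_levels`.
#' @return list: `summary` (mean/CRI data.frame), `n_excluded` (degenerate
#'   draws), `draws` (the per-draw correlations).
#' @export
latitude_association <- function(fit, site_latitudes) {
  stopifnot(length(site_latitudes) == length(fit$site_levels),
            length(fit$site_levels) >= 3)
  if (var(site_latitudes) == 0) stop("latitudes have zero variance")
  per_site <- vapply(fit$site_levels, function(s) site_mean_survival(fit, s),
                     numeric(dim(fit$draws)[1] * dim(fit$draws)[2]))
  lg <- logit(matrix(per_site, ncol = length(fit$site_levels)))
  sds <- apply(lg, 1, stats::sd)
  ok <- sds > 0
  draws <- rep(NA_real_, nrow(lg))
  draws[ok] <- apply(lg[ok, , drop = FALSE], 1,
                     function(r) cor(r, site_latitudes))
  list(summary = summarize_vector(draws[ok]),
       n_excluded = sum(!ok), draws = draws)
}

#' Site/group survival table as delimited text
#'
#' Writes the per-site posterior survival summaries joined with the site
#' table's seasonality columns.
#'
#' @param fit `cmr_draws` object.
#' @param sites site table (optional; adds seasonality columns).
#' @param path output path.
#' @return the table written, invisibly.
#' @export
write_survival_table <- function(fit, sites = NULL, path) {
  tab <- site_survival_summary(fit)
  if (!is.null(sites)) {
    sc <- score_sites(sites)
    tab <- merge(tab, sc[, c("site_id", "score", "bin")], by = "site_id",
                 all.x = TRUE)
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(tab)
}
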