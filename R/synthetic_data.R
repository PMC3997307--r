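#' Simulation scenario
#'
#' Defines a complete synthetic study: site layout, occasions, cohort
#' sizes, and the true parameters of the generating model. The defaults
#' emulate the regime of a subcontinental public ringing scheme for a
#' wetland passerine: 16 sites spanning 21-34 deg S over 12 annual Aug-Jul
#' occasions, overall mean survival 0.67 and low mean recapture 0.12 on
#' the probability scale, logit-scale spatial SD 0.70, temporal SD 1.08,
#' recapture SD 1.21, and residence probabilities spanning 0.25-0.86
#' across sites (substantial transience). First captures are assigned
#' uniformly over occasions 1..T-1.
#'
#' @param seed RNG seed (mandatory).
#' @param S number of sites.
#' @param T_occ number of annual occasions.
#' @param n_per_site new individuals per site over the study.
#' @param mu true overall mean survival, logit scale.
#' @param sigma_space,sigma_time,sigma_gamma true random-effect SDs.
#' @param beta true overall mean recapture, logit scale.
#' @param psi true per-site residence probabilities (recycled to length S).
#' @param site_lat,site_lon site center coordinates (defaults: a diagonal
#'   transect with > 0.8 degree spacing, so pooling radii never overlap).
#' @param jitter_prob fraction of generated capture records placed at a
#'   jittered coordinate (within 90% of the pooling radius of the site
#'   center) instead of exactly at the center.
#' @param n_decoys number of low-effort decoy locations added by
#'   [simulate_records()] to exercise the effort filter.
#' @param decoy_days distinct capture dates per decoy location (default 23,
#'   one below the 24-day effort threshold).
#' @return object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(seed, S = 16L, T_occ = 12L,
                                n_per_site = 435L,
                                mu = logit(0.67), sigma_space = 0.70,
                                sigma_time = 1.08, beta = logit(0.12),
                                sigma_gamma = 1.21,
                                psi = seq(0.25, 0.86, length.out = S),
                                site_lat = seq(-21, -34, length.out = S),
                                site_lon = seq(18, 30, length.out = S),
                                jitter_prob = 0.3, n_decoys = 2L,
                                decoy_days = 23L) {
  stopifnot(!missing(seed), S >= 1, T_occ >= 2, n_per_site >= 0,
            sigma_space >= 0, sigma_time >= 0, sigma_gamma >= 0,
            length(site_lat) == S, length(site_lon) == S,
            jitter_prob >= 0, jitter_prob <= 1)
  psi <- rep(psi, length.out = S)
  stopifnot(all(psi >= 0 & psi <= 1))
  structure(list(seed = as.integer(seed), S = as.integer(S),
                 T_occ = as.integer(T_occ),
                 n_per_site = as.integer(n_per_site), mu = mu,
                 sigma_space = sigma_space, sigma_time = sigma_time,
                 beta = beta, sigma_gamma = sigma_gamma, psi = psi,
                 site_lat = site_lat, site_lon = site_lon,
                 jitter_prob = jitter_prob, n_decoys = as.integer(n_decoys),
                 decoy_days = as.integer(decoy_days)),
            class = "simulation_scenario")
}

#' Draw the random effects and implied rates of a scenario
#'
#' eta_s ~ N(0, sigma_space^2), eps_t ~ N(0, sigma_time^2), gamma_{s,t} ~
#' N(0, sigma_gamma^2); survival and recapture by inverse logit of the
#' linear predictors. Resets the RNG to the scenario seed, so the whole
#' generation pathway is reproducible.
#'
#' @param scenario [simulation_scenario()].
#' @return list: `eta`, `eps`, `gamma`, `phi` (S x T-1), `p` (S x T-1),
#'   and `params` (the full true [model_parameters()]).
#' @export
draw_effects <- function(scenario) {
  set.seed(scenario$seed)
  S <- scenario$S; K <- scenario$T_occ - 1L
  eta <- rnorm(S, 0, scenario$sigma_space)
  eps <- rnorm(K, 0, scenario$sigma_time)
  gamma <- matrix(rnorm(S * K, 0, scenario$sigma_gamma), S, K)
  params <- model_parameters(mu = scenario$mu, eta = eta, eps = eps,
                             sigma_space = scenario$sigma_space,
                             sigma_time = scenario$sigma_time,
                             beta = scenario$beta, gamma = gamma,
                             sigma_gamma = scenario$sigma_gamma,
                             psi = scenario$psi)
  rates <- implied_rates(params)
  list(eta = eta, eps = eps, gamma = gamma, phi = rates$phi, p = rates$p,
       params = params)
}

#' Simulate encounter histories under the three-state model
#'
#' Each new individual enters in state Initial at its first-capture
#' occasion (detected there by construction), then evolves by the state
#' transition matrix -- settling as a Resident with probability phi * psi
#' over the first interval, surviving with phi thereafter -- and Residents
#' are detected with the site-by-occasion recapture probability.
#' Individuals never detected again remain in the matrix with a single 1.
#' The generating truth (latent states, effects, parameters) is attached
#' as attribute `"truth"`.
#'
#' @param scenario [simulation_scenario()].
#' @param effects output of [draw_effects()]; drawn afresh (resetting the
#'   RNG to the scenario seed) when omitted.
#' @return `encounter_histories` with attribute `truth` (list: `states`
#'   matrix coded 1 Initial / 2 Resident / 3 Dead, `effects`, `params`).
#' @export
simulate_histories <- function(scenario, effects = NULL) {
  if (is.null(effects)) effects <- draw_effects(scenario)
  S <- scenario$S; T_occ <- scenario$T_occ
  n <- scenario$n_per_site * S
  det <- matrix(0L, n, T_occ)
  states <- matrix(NA_integer_, n, T_occ)
  site_index <- rep(seq_len(S), each = scenario$n_per_site)
  fc <- sample.int(T_occ - 1L, n, replace = TRUE)
  for (i in seq_len(n)) {
    s <- site_index[i]; f <- fc[i]
    det[i, f] <- 1L
    states[i, f] <- 1L
    st <- 1L
    for (t in seq.int(f + 1L, T_occ)) {
      ph <- effects$phi[s, t - 1L]
      st <- if (st == 1L) {
        if (runif(1) < ph * scenario$psi[s]) 2L else 3L
      } else if (st == 2L) {
        if (runif(1) < ph) 2L else 3L
      } else 3L
      states[i, t] <- st
      if (st == 2L && runif(1) < effects$p[s, t - 1L]) det[i, t] <- 1L
    }
  }
  rownames(det) <- sprintf("SIM%06d", seq_len(n))
  h <- encounter_histories(det, site_index)
  attr(h, "truth") <- list(states = states, effects = effects,
                           params = effects$params, scenario = scenario)
  h
}

#' Expand encounter histories into dated capture records
#'
#' Each detection becomes 1-3 dated capture records within its Aug-Jul
#' occasion. Records are placed exactly at the site center with
#' probability 1 - `jitter_prob`, otherwise at a coordinate jittered
#' within 90% of the pooling radius, so the center accumulates capture
#' effort while satellite captures exercise the pooling rule. Low-effort
#' decoy locations (each with `decoy_days` distinct capture dates, default
#' one below the 24-day threshold, and placed far outside all pooling
#' radii) are appended to exercise the effort filter. Running the
#' preprocessing pipeline on the result reproduces the input histories.
#'
#' @param histories `encounter_histories` from [simulate_histories()].
#' @param scenario the generating [simulation_scenario()].
#' @param config [run_config()] fixing the study window and radius.
#' @return list: `records` (capture-record data.frame in the
#'   [read_records()] dialect), `site_table` (site metadata data.frame),
#'   `n_decoy_records`.
#' @export
simulate_records <- function(histories, scenario, config = run_config()) {
  det <- histories$detections
  T_occ <- ncol(det)
  start_year <- as.integer(format(config$study_start, "%Y"))
  radius <- config$pooling_radius
  occ_start <- as.Date(sprintf("%d-08-01", start_year + seq_len(T_occ) - 1L))

  ids <- rownames(det)
  recs <- list()
  nrec <- 0L
  add <- function(df) {
    nrec <<- nrec + 1L
    recs[[nrec]] <<- df
  }
  for (i in seq_len(nrow(det))) {
    s <- histories$site_index[i]
    for (k in which(det[i, ] == 1L)) {
      n_rec <- sample.int(3L, 1L)
      offs <- sample.int(364L, n_rec) - 1L
      jit <- runif(n_rec) < scenario$jitter_prob
      dlat <- ifelse(jit, runif(n_rec, -0.9, 0.9) * radius, 0)
      dlon <- ifelse(jit, runif(n_rec, -0.9, 0.9) * radius, 0)
      add(data.frame(ring_id = ids[i], date = occ_start[k] + offs,
                     lat = scenario$site_lat[s] + dlat,
                     lon = scenario$site_lon[s] + dlon,
                     age = "adult", stringsAsFactors = FALSE))
    }
  }
  records <- do.call(rbind, recs[seq_len(nrec)])

  # decoy locations: sub-threshold effort, far outside every pooling radius
  n_decoy_records <- 0L
  if (scenario$n_decoys > 0) {
    all_days <- seq(config$study_start, config$study_end, by = "day")
    for (d in seq_len(scenario$n_decoys)) {
      dlat <- max(scenario$site_lat) + 2 + d
      dlon <- min(scenario$site_lon) - 2 - d
      days <- sort(sample(all_days, scenario$decoy_days))
      decoy <- data.frame(
        ring_id = sprintf("DEC%02d_%03d", d,
                          (seq_along(days) - 1L) %% 5L + 1L),
        date = days, lat = dlat, lon = dlon, age = "adult",
        stringsAsFactors = FALSE)
      records <- rbind(records, decoy)
      n_decoy_records <- n_decoy_records + nrow(decoy)
    }
  }
  rownames(records) <- NULL

  site_table <- data.frame(
    site_id = seq_len(scenario$S),
    center_lat = scenario$site_lat, center_lon = scenario$site_lon,
    vegetation_unit = sprintf("synthetic_unit_%02d", seq_len(scenario$S)),
    rainfall_regime = ifelse(scenario$site_lat <= -32, "winter",
                             ifelse(scenario$site_lat >= -22, "irregular",
                                    "summer")),
    migratory = classify_migratory(scenario$site_lat,
                                   config$migratory_latitude),
    apcv = NA_real_, mat = NA_real_, mafd = NA_real_,
    stringsAsFactors = FALSE)

  list(records = records, site_table = site_table,
       n_decoy_records = n_decoy_records)
}

#' Write the generating truth to a sidecar file
#'
#' The truth never travels in the record file itself, so the pipeline
#' under test cannot read it.
#'
#' @param histories output of [simulate_histories()] (carries the truth
#'   attribute).
#' @param path output path (plain text, `key: value` plus tables).
#' @return `path`, invisibly.
#' @export
write_truth <- function(histories, path) {
  truth <- attr(histories, "truth")
  if (is.null(truth)) stop("histories carry no truth attribute")
  p <- truth$params
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("mu: %.10g", p$mu), sprintf("beta: %.10g", p$beta),
               sprintf("sigma_space: %.10g", p$sigma_space),
               sprintf("sigma_time: %.10g", p$sigma_time),
               sprintf("sigma_gamma: %.10g", p$sigma_gamma),
               sprintf("psi: %s", paste(format(p$psi), collapse = ",")),
               sprintf("eta: %s", paste(format(p$eta), collapse = ",")),
               sprintf("eps: %s", paste(format(p$eps), collapse = ","))),
             con)
  invisible(path)
}
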