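param_names <- function(S, K) {
  c("mu", "beta", paste0("eta[", seq_len(S), "]"),
    paste0("eps[", seq_len(K), "]"),
    as.vector(t(outer(seq_len(S), seq_len(K),
                      function(s, k) paste0("gamma[", s, ",", k, "]")))),
    "sigma_space", "sigma_time", "sigma_gamma",
    paste0("psi[", seq_len(S), "]"))
}

params_to_vector <- function(params) {
  c(params$mu, params$beta, params$eta, params$eps,
    as.vector(t(params$gamma)),
    params$sigma_space, params$sigma_time, params$sigma_gamma, params$psi)
}

vector_to_params <- function(v, S, K) {
  i <- 2
  eta <- v[i + seq_len(S)]; i <- i + S
  eps <- v[i + seq_len(K)]; i <- i + K
  gamma <- matrix(v[i + seq_len(S * K)], nrow = S, ncol = K, byrow = TRUE)
  i <- i + S * K
  model_parameters(mu = v[1], eta = eta, eps = eps, sigma_space = v[i + 1],
                   sigma_time = v[i + 2], beta = v[2], gamma = gamma,
                   sigma_gamma = v[i + 3], psi = v[i + 3 + seq_len(S)])
}

#' Joint log prior density
#'
#' Uniform(-logit_bound, logit_bound) for the mean logit survival and
#' recapture, Uniform(0, 1) for each residence probability, Uniform(0,
#' sd_upper) for the three random-effect SDs, and Normal(0, sigma^2) for
#' the site, year and site-by-year effects given their SDs. Returns -Inf
#' outside the support (including the degenerate sigma = 0 case).
#'
#' @param params `model_parameters`.
#' @param config [run_config()] supplying the prior bounds.
#' @return log density (scalar, possibly -Inf).
#' @export
log_prior <- function(params, config = run_config()) {
  b <- config$logit_bound; up <- config$sd_upper
  if (abs(params$mu) >= b || abs(params$beta) >= b) return(-Inf)
  sds <- c(params$sigma_space, params$sigma_time, params$sigma_gamma)
  if (any(sds <= 0 | sds >= up)) return(-Inf)
  if (any(params$psi < 0 | params$psi > 1)) return(-Inf)
  sum(dnorm(params$eta, 0, params$sigma_space, log = TRUE)) +
    sum(dnorm(params$eps, 0, params$sigma_time, log = TRUE)) +
    sum(dnorm(params$gamma, 0, params$sigma_gamma, log = TRUE)) +
    2 * (-log(2 * b)) + 3 * (-log(up))
}

draw_initial <- function(S, K, config) {
  sigma_space <- runif(1, 0, config$sd_upper)
  sigma_time <- runif(1, 0, config$sd_upper)
  sigma_gamma <- runif(1, 0, config$sd_upper)
  c(runif(1, -config$logit_bound, config$logit_bound),   # mu
    runif(1, -config$logit_bound, config$logit_bound),   # beta
    rnorm(S, 0, sigma_space), rnorm(K, 0, sigma_time),
    rnorm(S * K, 0, sigma_gamma),
    sigma_space, sigma_time, sigma_gamma,
    runif(S, 0, 1))
}

resolve_fixed <- function(fixed, S, K, nm) {
  update <- rep(TRUE, length(nm))
  values <- rep(NA_real_, length(nm))
  block <- function(name) switch(name,
    mu = 1L, beta = 2L,
    eta = 2L + seq_len(S),
    eps = 2L + S + seq_len(K),
    gamma = 2L + S + K + seq_len(S * K),
    sigma_space = 2L + S + K + S * K + 1L,
    sigma_time = 2L + S + K + S * K + 2L,
    sigma_gamma = 2L + S + K + S * K + 3L,
    psi = 2L + S + K + S * K + 3L + seq_len(S),
    stop("unknown parameter block in `fixed`: ", name))
  for (name in names(fixed)) {
    idx <- block(name)
    v <- fixed[[name]]
    if (length(v) == 1) v <- rep(v, length(idx))
    stopifnot(length(v) == length(idx))
    update[idx] <- FALSE
    values[idx] <- v
  }
  list(update = update, values = values)
}

#' Fit the hierarchical multistate model by MCMC
#'
#' Runs `config$chains` independent chains of an adaptive random-walk
#' Metropolis-within-Gibbs sampler over all model parameters, on the exact
#' marginalized likelihood of the encounter histories. Each scalar is
#' updated on an unconstrained scale (log for SDs, logit for psi), with
#' proposal scales adapted towards an acceptance rate of about 0.44 during
#' burn-in only, so retained draws come from a fixed kernel. Chains are
#' initialized from the priors (retrying a bounded number of times if the
#' likelihood is non-finite) and are reproducible given `config$seed`.
#'
#' @param histories `encounter_histories` (may contain zero individuals,
#'   in which case the posterior is the prior).
#' @param config [run_config()]; uses the MCMC and prior settings.
#' @param fixed named list of parameter blocks to hold constant, e.g.
#'   `list(psi = 1, eta = 0, eps = 0, gamma = 0, sigma_space = 0.5)`.
#'   Fixed blocks are never updated.
#' @param init optional full initial parameter vector (natural scale),
#'   recycled across chains; defaults to independent prior draws per chain.
#' @param site_levels optional site ids (required if `histories` has no
#'   individuals); defaults to `histories$site_levels`.
#' @return object of class `cmr_draws`: `draws` is a (retained iterations)
#'   x chains x parameters array on the natural scale, plus parameter
#'   names, acceptance rates, proposal scales and sampler metadata.
#' @export
run_mcmc <- function(histories, config = run_config(), fixed = list(),
                     init = NULL, site_levels = NULL) {
  site_levels <- site_levels %||% histories$site_levels
  if (length(site_levels) == 0)
    stop("no sites: supply `site_levels` for a prior-only run")
  S <- length(site_levels)
  T_occ <- ncol(histories$detections)
  K <- T_occ - 1
  nm <- param_names(S, K)
  site_data <- collapse_site_data(histories, site_levels)
  fx <- resolve_fixed(fixed, S, K, nm)
  settings <- list(iterations = config$iterations, burn_in = config$burn_in,
                   thinning = config$thinning, target_accept = 0.44,
                   adapt_window = 50L, logit_bound = config$logit_bound,
                   sd_upper = config$sd_upper)

  n_ret <- length(seq.int(config$burn_in + config$thinning,
                          config$iterations, by = config$thinning))
  draws <- array(NA_real_, dim = c(n_ret, config$chains, length(nm)),
                 dimnames = list(NULL, paste0("chain", seq_len(config$chains)),
                                 nm))
  accept <- matrix(NA_real_, length(nm), config$chains, dimnames = list(nm, NULL))
  prop_sd <- matrix(NA_real_, length(nm), config$chains, dimnames = list(nm, NULL))

  chain_ll <- function(v) {
    pr <- vector_to_params(pmin(pmax(v, -1e10), 1e10), S, K)
    rates <- implied_rates(pr)
    total_loglik_cpp(site_data, rates$phi, rates$p, pr$psi)
  }

  for (chain in seq_len(config$chains)) {
    set.seed((config$seed + 1000L * (chain - 1L)) %% .Machine$integer.max)
    v <- NULL
    for (try in seq_len(20)) {
      v0 <- if (is.null(init)) draw_initial(S, K, config) else as.numeric(init)
      v0[!fx$update] <- fx$values[!fx$update]
      if (is.finite(chain_ll(v0))) { v <- v0; break }
      if (!is.null(init)) stop("supplied init has non-finite likelihood")
    }
    if (is.null(v)) stop("could not find a finite-likelihood initialization")
    res <- run_chain_cpp(site_data, T_occ, v, fx$update, settings)
    draws[, chain, ] <- res$draws
    accept[, chain] <- res$accept_rate
    prop_sd[, chain] <- res$proposal_sd
  }
  structure(list(draws = draws, params = nm, S = S, K = K,
                 site_levels = site_levels, accept = accept,
                 proposal_sd = prop_sd, settings = settings,
                 chains = config$chains, seed = config$seed,
                 updated = fx$update),
            class = "cmr_draws")
}

#' @export
print.cmr_draws <- function(x, ...) {
  cat(sprintf("Posterior draws: %d retained x %d chain(s) x %d parameter(s)\n",
              dim(x$draws)[1], dim(x$draws)[2], dim(x$draws)[3]))
  cat(sprintf("  sites: %d, intervals: %d, seed: %d\n", x$S, x$K, x$seed))
  invisible(x)
}

#' Extract draws of one parameter
#'
#' @param fit `cmr_draws` object.
#' @param param parameter name, e.g. `"mu"` or `"eta[2]"`.
#' @param pool pool chains into one vector (default) or keep an
#'   iterations x chains matrix.
#' @return numeric vector or matrix.
#' @export
get_draws <- function(fit, param, pool = TRUE) {
  if (!param %in% fit$params) stop("unknown parameter: ", param)
  m <- fit$draws[, , param, drop = TRUE]
  m <- matrix(m, nrow = dim(fit$draws)[1])
  if (pool) as.vector(m) else m
}

#' Brooks-Gelman-Rubin potential scale reduction factor
#'
#' Classic (univariate) PSRF: with m chains of n draws, W the mean
#' within-chain variance and B the between-chain variance of chain means
#' times n, Rhat = sqrt(((n-1)/n * W + B/n) / W). Values near 1 indicate
#' convergence. Zero within-chain variance is flagged degenerate (NA with
#' a warning).
#'
#' @param chains n x m matrix: one column of draws per chain (m >= 2,
#'   n >= 4).
#' @return scalar Rhat.
#' @export
rhat <- function(chains) {
  chains <- as.matrix(chains)
  n <- nrow(chains); m <- ncol(chains)
  stopifnot(m >= 2, n >= 4)
  W <- mean(apply(chains, 2, var))
  if (W == 0) {
    warning("degenerate chains: zero within-chain variance")
    return(NA_real_)
  }
  B <- n * var(colMeans(chains))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Rhat for every (updated) parameter of a fit
#'
#' @param fit `cmr_draws` object with >= 2 chains.
#' @return named numeric vector of Rhat values.
#' @export
rhat_all <- function(fit) {
  stopifnot(dim(fit$draws)[2] >= 2)
  vapply(seq_along(fit$params), function(j) {
    if (!fit$updated[j]) return(NA_real_)
    suppressWarnings(rhat(fit$draws[, , j]))
  }, numeric(1)) -> out
  stats::setNames(out, fit$params)
}

#' Posterior summaries
#'
#' Posterior mean and central 95% (equal-tailed) credible interval per
#' parameter, pooling chains, plus the retained draw count and Rhat (when
#' >= 2 chains). Summaries are on the parameter's natural scale: logit for
#' `mu`/`beta`/effects, the SD scale for sigmas, probability for psi.
#' Probability-scale survival summaries belong to the derived layer
#' ([site_mean_survival()]), which transforms per draw rather than
#' transforming the summary (the two differ by the Jensen gap).
#'
#' @param fit `cmr_draws` object.
#' @param probs interval probabilities (default `c(0.025, 0.975)`).
#' @return data.frame: `parameter`, `mean`, `lower`, `upper`, `n`, `rhat`.
#' @export
summarize_draws <- function(fit, probs = c(0.025, 0.975)) {
  nit <- dim(fit$draws)[1] * dim(fit$draws)[2]
  rh <- if (dim(fit$draws)[2] >= 2) rhat_all(fit) else
    rep(NA_real_, length(fit$params))
  rows <- lapply(seq_along(fit$params), function(j) {
    d <- as.vector(fit$draws[, , j])
    qs <- unname(quantile(d, probs))
    data.frame(parameter = fit$params[j], mean = mean(d), lower = qs[1],
               upper = qs[2], n = nit, rhat = unname(rh[j]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize an arbitrary draw vector
#'
#' Same convention as [summarize_draws()] but for a plain numeric vector of
#' posterior draws of a derived quantity.
#'
#' @param x numeric vector of draws.
#' @param probs interval probabilities.
#' @return one-row data.frame with `mean`, `lower`, `upper`, `n`.
#' @export
summarize_vector <- function(x, probs = c(0.025, 0.975)) {
  x <- x[is.finite(x)]
  qs <- unname(quantile(x, probs))
  data.frame(mean = mean(x), lower = qs[1], upper = qs[2], n = length(x))
}

#' Persist posterior draws as delimited text
#'
#' One row per retained iteration per chain: `chain`, `iteration`, then one
#' column per parameter.
#'
#' @param fit `cmr_draws` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  tabs <- lapply(seq_len(dim(fit$draws)[2]), function(ch) {
    d <- as.data.frame(matrix(fit$draws[, ch, ], nrow = dim(fit$draws)[1]))
    names(d) <- fit$params
    cbind(data.frame(chain = ch, iteration = seq_len(nrow(d))), d)
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
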