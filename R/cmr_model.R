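#' Model parameter container
#'
#' All unknowns of the three-state hierarchical model for S sites and T
#' occasions: logit survival is mu + eta_s + eps_t (eta_s site effects with
#' SD sigma_space; eps_t year effects, one per interval t -> t+1, with SD
#' sigma_time); logit recapture is beta + gamma_{s,t} (gamma a site-by-
#' occasion effect for recapture occasions 2..T, SD sigma_gamma); and a
#' time-constant, site-specific residence probability psi_s.
#'
#' @param mu overall mean survival, logit scale.
#' @param eta site survival effects, length S.
#' @param eps year (interval) survival effects, length T-1.
#' @param sigma_space,sigma_time,sigma_gamma random-effect SDs (>= 0).
#' @param beta overall mean recapture, logit scale.
#' @param gamma S x (T-1) matrix of recapture effects (column k is
#'   recapture occasion k+1).
#' @param psi per-site residence probabilities in \[0, 1\], length S.
#' @return object of class `model_parameters`.
#' @export
model_parameters <- function(mu, eta, eps, sigma_space, sigma_time,
                             beta, gamma, sigma_gamma, psi) {
  gamma <- as.matrix(gamma)
  S <- length(eta); K <- length(eps)
  stopifnot(length(mu) == 1, length(beta) == 1,
            nrow(gamma) == S, ncol(gamma) == K,
            length(psi) == S,
            sigma_space >= 0, sigma_time >= 0, sigma_gamma >= 0,
            all(psi >= 0 & psi <= 1))
  structure(list(mu = mu, eta = as.numeric(eta), eps = as.numeric(eps),
                 sigma_space = sigma_space, sigma_time = sigma_time,
                 beta = beta, gamma = gamma, sigma_gamma = sigma_gamma,
                 psi = as.numeric(psi)),
            class = "model_parameters")
}

#' Survival / recapture probabilities implied by the parameters
#'
#' @param params `model_parameters`.
#' @return list with `phi` (S x T-1 matrix of survival over interval
#'   t -> t+1) and `p` (S x T-1 matrix of recapture at occasions 2..T).
#' @export
implied_rates <- function(params) {
  phi <- invlogit(outer(params$mu + params$eta, params$eps, "+"))
  p <- invlogit(params$beta + params$gamma)
  list(phi = phi, p = p)
}

#' State transition matrix of the three-state model
#'
#' Rows and columns ordered Initial, Resident, Dead. A newly captured bird
#' (Initial) survives and settles as a Resident with probability phi * psi;
#' a Resident survives with phi; Dead is absorbing and Initial is never
#' re-entered.
#'
#' @param phi survival probability in \[0, 1\].
#' @param psi residence probability in \[0, 1\].
#' @return 3 x 3 row-stochastic matrix.
#' @export
transition_matrix <- function(phi, psi) {
  if (!is.finite(phi) || phi < 0 || phi > 1)
    stop("phi must be in [0, 1]")
  if (!is.finite(psi) || psi < 0 || psi > 1)
    stop("psi must be in [0, 1]")
  matrix(c(0, phi * psi, 1 - phi * psi,
           0, phi,       1 - phi,
           0, 0,         1),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("initial", "resident", "dead"),
                         c("initial", "resident", "dead")))
}

#' Observation probabilities by true state
#'
#' Only Residents can be detected: (p, 1-p) over (seen as Resident, not
#' seen); Initial and Dead are never observed.
#'
#' @param p recapture probability in \[0, 1\].
#' @param state "initial", "resident" or "dead" (or index 1:3).
#' @return length-2 vector (seen, not seen).
#' @export
observation_row <- function(p, state) {
  stopifnot(p >= 0, p <= 1)
  if (is.numeric(state)) state <- c("initial", "resident", "dead")[state]
  state <- match.arg(state, c("initial", "resident", "dead"))
  if (state == "resident") c(seen = p, not_seen = 1 - p)
  else c(seen = 0, not_seen = 1)
}

#' Marginal log-likelihood of one encounter history
#'
#' Exact marginal probability of the detections after first capture,
#' computed by a scaled forward recursion over the latent states: the bird
#' starts in state Initial at its first capture with probability 1,
#' transitions by [transition_matrix()] each interval, and emits via
#' [observation_row()]. Impossible histories under boundary parameters
#' return -Inf rather than raising an error.
#'
#' @param history 0/1 detection vector over the T occasions.
#' @param first_capture occasion index of first detection.
#' @param phi_t per-interval survival, length T-1.
#' @param p_t per-occasion recapture, length T (entry 1 is unused: the
#'   model conditions on first capture and defines recapture only for
#'   occasions 2..T).
#' @param psi residence probability.
#' @return natural-log probability.
#' @export
history_loglik <- function(history, first_capture, phi_t, p_t, psi) {
  T_occ <- length(history)
  stopifnot(length(phi_t) == T_occ - 1, length(p_t) == T_occ,
            history[first_capture] == 1,
            all(phi_t >= 0 & phi_t <= 1),
            all(p_t >= 0 & p_t <= 1, na.rm = TRUE),
            psi >= 0, psi <= 1)
  hist_loglik_cpp(as.integer(history), as.integer(first_capture),
                  as.numeric(phi_t), as.numeric(p_t[-1]), psi)
}

# Collapse an encounter-history matrix into per-site unique
# (first-capture, pattern) groups with counts, the sufficient structure
# for the likelihood. site_levels fixes the site order.
collapse_site_data <- function(histories, site_levels = NULL) {
  site_levels <- site_levels %||% histories$site_levels
  det <- histories$detections
  T_occ <- ncol(det)
  lapply(site_levels, function(s) {
    rows <- which(histories$site_index == s)
    if (length(rows) == 0)
      return(list(patterns = matrix(integer(), 0, T_occ),
                  counts = integer(), first = integer()))
    sub <- det[rows, , drop = FALSE]
    fc <- histories$first_capture[rows]
    key <- paste(fc, apply(sub, 1, paste, collapse = ""))
    idx <- which(!duplicated(key))
    counts <- as.integer(table(key)[key[idx]])
    list(patterns = sub[idx, , drop = FALSE], counts = counts,
         first = as.integer(fc[idx]))
  })
}

#' Total log-likelihood of all encounter histories
#'
#' Sum over individuals of [history_loglik()] with site- and time-specific
#' rates: phi_{s,t} = invlogit(mu + eta_s + eps_t), p_{s,t} =
#' invlogit(beta + gamma_{s,t}). Deterministic given its inputs.
#'
#' @param histories `encounter_histories` object.
#' @param params `model_parameters`; `eta`, `gamma` rows and `psi` follow
#'   the order of `histories$site_levels`.
#' @return log-likelihood (scalar).
#' @export
total_loglik <- function(histories, params) {
  S <- length(histories$site_levels)
  K <- ncol(histories$detections) - 1
  if (length(params$eta) != S)
    stop(sprintf("eta has length %d but there are %d sites",
                 length(params$eta), S))
  if (length(params$eps) != K)
    stop(sprintf("eps has length %d but there are %d intervals",
                 length(params$eps), K))
  if (length(params$psi) != S)
    stop(sprintf("psi has length %d but there are %d sites",
                 length(params$psi), S))
  rates <- implied_rates(params)
  site_data <- collapse_site_data(histories)
  total_loglik_cpp(site_data, rates$phi, rates$p, params$psi)
}

#' Cormack-Jolly-Seber log-likelihood from an m-array
#'
#' The standard product-multinomial CJS likelihood (up to an additive
#' data-dependent constant), used as an independent oracle: with psi = 1
#' the three-state model reduces exactly to CJS, so likelihood differences
#' between parameter settings must agree with this factorization.
#'
#' @param marray `marray` object ([build_marray()]).
#' @param phi_t per-interval survival, length T-1.
#' @param p_t per-occasion recapture, length T (entry 1 unused).
#' @return log-likelihood (scalar; -Inf if a positive count has zero cell
#'   probability).
#' @export
cjs_loglik_marray <- function(marray, phi_t, p_t) {
  T_occ <- length(p_t)
  stopifnot(length(phi_t) == T_occ - 1, length(marray$R) == T_occ - 1)
  ll <- 0
  for (i in seq_len(T_occ - 1)) {
    if (marray$R[i] == 0) next
    q <- numeric(T_occ)
    for (j in (i + 1):T_occ) {
      surv <- prod(phi_t[i:(j - 1)])
      miss <- if (j - 1 >= i + 1) prod(1 - p_t[(i + 1):(j - 1)]) else 1
      q[j] <- surv * miss * p_t[j]
    }
    chi <- 1 - sum(q)
    for (j in (i + 1):T_occ) {
      if (marray$m[i, j] > 0) {
        if (q[j] <= 0) return(-Inf)
        ll <- ll + marray$m[i, j] * log(q[j])
      }
    }
    if (marray$never[i] > 0) {
      if (chi <= 0) return(-Inf)
      ll <- ll + marray$never[i] * log(chi)
    }
  }
  ll
}
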