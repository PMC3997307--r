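# Independent oracles and small builders used across the suite. The
# enumeration oracle deliberately re-derives the model from its transition
# and observation tables, without touching the package's forward recursion.

# Probability of the post-release detections of one history by exhaustive
# enumeration of every latent state sequence (1 Initial, 2 Resident, 3 Dead).
enum_history_prob <- function(history, f, phi_t, p_t, psi) {
  T_occ <- length(history)
  if (f == T_occ) return(1)
  steps <- T_occ - f
  trans <- lapply(phi_t, function(phi)
    matrix(c(0, phi * psi, 1 - phi * psi,
             0, phi, 1 - phi,
             0, 0, 1), 3, 3, byrow = TRUE))
  # emission probability by state (rows) and seen/not (cols) per occasion
  emis <- lapply(seq_len(T_occ), function(t)
    cbind(c(0, p_t[t], 0), c(1, 1 - p_t[t], 1)))
  paths <- as.matrix(expand.grid(rep(list(1:3), steps)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    pr <- 1
    prev <- 1L
    for (k in seq_len(steps)) {
      t <- f + k
      st <- paths[r, k]
      pr <- pr * trans[[t - 1]][prev, st] *
        emis[[t]][st, if (history[t] == 1) 1L else 2L]
      if (pr == 0) break
      prev <- st
    }
    total <- total + pr
  }
  total
}

# Probability that a bird released in state Initial at occasion f is never
# detected again, by the backward "chi" recursion (independent derivation).
never_seen_prob <- function(f, T_occ, phi, p, psi) {
  chiR <- 1
  for (t in seq(T_occ - 1, f + 1)) chiR <- (1 - phi) + phi * (1 - p) * chiR
  (1 - phi * psi) + phi * psi * (1 - p) * chiR
}

make_histories <- function(rows, site_index = rep(1L, length(rows))) {
  det <- do.call(rbind, rows)
  rownames(det) <- sprintf("B%03d", seq_len(nrow(det)))
  encounter_histories(det, site_index)
}

random_phi_p <- function(T_occ) {
  list(phi = runif(T_occ - 1, 0.05, 0.95),
       p = c(NA, runif(T_occ - 1, 0.05, 0.95)),
       psi = runif(1, 0.05, 0.95))
}

# batch-means Monte Carlo standard error for a (possibly autocorrelated)
# draw sequence
mcse_batch <- function(x, n_batch = 40) {
  bs <- floor(length(x) / n_batch)
  means <- vapply(seq_len(n_batch),
                  function(b) mean(x[((b - 1) * bs + 1):(b * bs)]),
                  numeric(1))
  stats::sd(means) / sqrt(n_batch)
}

# a hand-built posterior-draws object with given per-parameter draw vectors
fake_fit <- function(mu, beta = NULL, eta = NULL, eps = NULL, S = 1, K = 1,
                     psi = NULL) {
  n <- length(mu)
  nm <- c("mu", "beta", paste0("eta[", seq_len(S), "]"),
          paste0("eps[", seq_len(K), "]"),
          as.vector(t(outer(seq_len(S), seq_len(K),
                            function(s, k) paste0("gamma[", s, ",", k, "]")))),
          "sigma_space", "sigma_time", "sigma_gamma",
          paste0("psi[", seq_len(S), "]"))
  draws <- array(0, dim = c(n, 1, length(nm)),
                 dimnames = list(NULL, "chain1", nm))
  draws[, 1, "mu"] <- mu
  if (!is.null(beta)) draws[, 1, "beta"] <- beta
  if (!is.null(eta)) for (s in seq_len(S))
    draws[, 1, paste0("eta[", s, "]")] <- eta[, s]
  if (!is.null(eps)) for (k in seq_len(K))
    draws[, 1, paste0("eps[", k, "]")] <- eps[, k]
  if (!is.null(psi)) for (s in seq_len(S))
    draws[, 1, paste0("psi[", s, "]")] <- psi[, s]
  structure(list(draws = draws, params = nm, S = S, K = K,
                 site_levels = seq_len(S),
                 updated = rep(TRUE, length(nm)), chains = 1L, seed = 0L),
            class = "cmr_draws")
}
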