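test_that("transition matrix has the three-state structure", {
  m <- transition_matrix(0.5, 0.5)
  expect_equal(unname(m), matrix(c(0, 0.25, 0.75, 0, 0.5, 0.5, 0, 0, 1),
                                 3, byrow = TRUE))
  expect_equal(rowSums(m), c(initial = 1, resident = 1, dead = 1))
  # limits: certain settlement; certain death
  expect_equal(unname(transition_matrix(1, 1)[1, ]), c(0, 1, 0))
  m0 <- transition_matrix(0, 0.8)
  expect_equal(unname(m0[1:2, 3]), c(1, 1))
  # the Initial state is never re-entered; Dead is absorbing
  expect_true(all(m[, 1] == 0))
  expect_equal(unname(m[3, ]), c(0, 0, 1))
  expect_error(transition_matrix(1.2, 0.5), "phi")
  expect_error(transition_matrix(0.5, -0.1), "psi")
})

test_that("only residents are observable", {
  expect_equal(unname(observation_row(0.12, "resident")), c(0.12, 0.88))
  expect_equal(unname(observation_row(0.9, "dead")), c(0, 1))
  expect_equal(unname(observation_row(0.9, "initial")), c(0, 1))
  expect_equal(unname(observation_row(1, "resident")), c(1, 0))
  expect_equal(observation_row(0.3, 2), observation_row(0.3, "resident"))
})

test_that("history likelihood matches closed forms and handles -Inf", {
  expect_equal(exp(history_loglik(c(1, 1), 1, 0.8, c(NA, 0.3), 0.7)),
               0.8 * 0.7 * 0.3)
  expect_equal(exp(history_loglik(c(1, 0, 1), 1, c(0.5, 0.5),
                                  c(NA, 0.5, 0.5), 0.5)), 0.03125)
  expect_equal(exp(history_loglik(c(1, 0, 0), 1, c(0.5, 0.5),
                                  c(NA, 0.5, 0.5), 0.5)), 0.84375)
  # detection after an interval with zero survival is impossible, not an error
  expect_identical(history_loglik(c(1, 0, 1), 1, c(0, 0.5),
                                  c(NA, 0.5, 0.5), 0.5), -Inf)
  expect_identical(history_loglik(c(1, 1), 1, 0.5, c(NA, 1), 0), -Inf)
})

test_that("forward recursion equals latent-path enumeration", {
  set.seed(123)
  for (rep in 1:60) {
    T_occ <- sample(3:6, 1)
    f <- sample(seq_len(T_occ - 1), 1)
    pars <- random_phi_p(T_occ)
    hist <- integer(T_occ)
    hist[f] <- 1L
    if (f < T_occ)
      hist[(f + 1):T_occ] <- rbinom(T_occ - f, 1, 0.5)
    ll <- history_loglik(hist, f, pars$phi, pars$p, pars$psi)
    oracle <- enum_history_prob(hist, f, pars$phi, pars$p, pars$psi)
    if (oracle == 0) expect_identical(ll, -Inf)
    else expect_equal(ll, log(oracle), tolerance = 1e-12)
  }
})

test_that("post-release detection patterns conserve probability", {
  set.seed(77)
  for (rep in 1:20) {
    T_occ <- sample(3:6, 1)
    f <- 1L
    pars <- random_phi_p(T_occ)
    pats <- as.matrix(expand.grid(rep(list(0:1), T_occ - 1)))
    total <- sum(apply(pats, 1, function(tail) {
      exp(history_loglik(c(1L, tail), f, pars$phi, pars$p, pars$psi))
    }))
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("likelihood is monotone in final-occasion p when it ends detected", {
  hist <- c(1, 0, 1, 1)
  phi <- c(0.7, 0.6, 0.8)
  lls <- vapply(seq(0.05, 0.95, by = 0.1), function(p)
    history_loglik(hist, 1, phi, c(NA, 0.4, 0.4, p), 0.6), numeric(1))
  expect_true(all(diff(lls) >= 0))
})

test_that("total likelihood sums per-individual terms with site/year rates", {
  set.seed(5)
  S <- 3; T_occ <- 5
  params <- model_parameters(
    mu = 0.4, eta = rnorm(S, 0, 0.5), eps = rnorm(T_occ - 1, 0, 0.5),
    sigma_space = 0.5, sigma_time = 0.5, beta = -1.5,
    gamma = matrix(rnorm(S * (T_occ - 1), 0, 0.5), S), sigma_gamma = 0.5,
    psi = c(0.3, 0.6, 0.9))
  rates <- implied_rates(params)

  one <- make_histories(list(c(0, 1, 0, 1, 0)), site_index = 2L)
  ll_one <- total_loglik(one, model_parameters(
    mu = params$mu, eta = params$eta[2], eps = params$eps,
    sigma_space = 0.5, sigma_time = 0.5, beta = params$beta,
    gamma = params$gamma[2, , drop = FALSE], sigma_gamma = 0.5,
    psi = params$psi[2]))
  expect_equal(ll_one, history_loglik(c(0, 1, 0, 1, 0), 2, rates$phi[2, ],
                                      c(NA, rates$p[2, ]), params$psi[2]))

  rows <- lapply(1:30, function(i) {
    repeat {
      v <- rbinom(T_occ, 1, 0.4)
      if (sum(v) > 0 && which(v == 1)[1] < T_occ) return(v)
    }
  })
  sites <- sample(1:S, 30, replace = TRUE)
  sites[1:3] <- 1:3  # every site represented
  h <- make_histories(rows, sites)
  ll <- total_loglik(h, params)
  # doubling every history doubles the log likelihood
  h2 <- make_histories(c(rows, rows), c(sites, sites))
  expect_equal(total_loglik(h2, params), 2 * ll, tolerance = 1e-10)
  # against the enumeration oracle summed per individual
  ll_oracle <- sum(vapply(seq_along(rows), function(i) {
    s <- sites[i]
    f <- which(rows[[i]] == 1)[1]
    log(enum_history_prob(rows[[i]], f, rates$phi[s, ],
                          c(NA, rates$p[s, ]), params$psi[s]))
  }, numeric(1)))
  expect_equal(ll, ll_oracle, tolerance = 1e-10)
  # dimension mismatches name the offending piece
  bad <- model_parameters(mu = 0.4, eta = rnorm(2), eps = rnorm(4),
                          sigma_space = 0.5, sigma_time = 0.5, beta = -1.5,
                          gamma = matrix(0, 2, 4), sigma_gamma = 0.5,
                          psi = c(0.5, 0.5))
  expect_error(total_loglik(h, bad), "eta.*3 sites")
})

test_that("CJS m-array oracle: single-cell and perfect-detection limits", {
  h <- make_histories(list(c(1, 1)))
  ma <- build_marray(h)
  expect_equal(cjs_loglik_marray(ma, 0.8, c(NA, 0.3)), log(0.8 * 0.3))
  # perfect detection: never-seen mass is exactly 1 - phi per release
  h2 <- make_histories(list(c(1, 0, 0)))
  ma2 <- build_marray(h2)
  expect_equal(cjs_loglik_marray(ma2, c(0.7, 0.6), c(NA, 1, 1)), log(1 - 0.7))
})

test_that("with psi = 1 the three-state model reduces to CJS", {
  set.seed(9)
  sc <- simulation_scenario(seed = 9, S = 1, T_occ = 6, n_per_site = 120,
                            psi = 1, sigma_space = 0, sigma_time = 0.6,
                            sigma_gamma = 0.6, beta = logit(0.35))
  h <- simulate_histories(sc)
  ma <- build_marray(h)
  make_par <- function(shift) {
    tr <- attr(h, "truth")$params
    model_parameters(mu = tr$mu + shift, eta = 0, eps = tr$eps,
                     sigma_space = 1, sigma_time = 1, beta = tr$beta,
                     gamma = tr$gamma, sigma_gamma = 1, psi = 1)
  }
  for (shift in c(-0.5, 0, 0.4)) {
    par <- make_par(shift)
    rates <- implied_rates(par)
    d_ms <- total_loglik(h, par) - total_loglik(h, make_par(0))
    rates0 <- implied_rates(make_par(0))
    d_cjs <- cjs_loglik_marray(ma, rates$phi[1, ], c(NA, rates$p[1, ])) -
      cjs_loglik_marray(ma, rates0$phi[1, ], c(NA, rates0$p[1, ]))
    expect_equal(d_ms, d_cjs, tolerance = 1e-8)
  }
})
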