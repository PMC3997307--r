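test_that("effects reduce to the means when the SDs vanish", {
  sc <- simulation_scenario(seed = 1, S = 4, T_occ = 6, n_per_site = 10,
                            sigma_space = 0, sigma_time = 0,
                            sigma_gamma = 0)
  eff <- draw_effects(sc)
  expect_true(all(eff$phi == invlogit(sc$mu)))
  expect_true(all(eff$p == invlogit(sc$beta)))
  expect_equal(unique(as.vector(eff$phi)), 0.67, tolerance = 1e-12)
})

test_that("drawn site effects have the requested spread", {
  sc <- simulation_scenario(seed = 2, S = 10000, T_occ = 3, n_per_site = 0,
                            sigma_space = 0.7)
  eff <- draw_effects(sc)
  expect_equal(sd(eff$eta), 0.7, tolerance = 0.02)
  expect_equal(mean(eff$eta), 0, tolerance = 0.03)
})

test_that("boundary scenarios behave deterministically", {
  # psi = 0: all transients, never a reencounter
  sc0 <- simulation_scenario(seed = 3, S = 2, T_occ = 8, n_per_site = 100,
                             psi = 0)
  h0 <- simulate_histories(sc0)
  expect_true(all(rowSums(h0$detections) == 1))
  # certain survival, settlement and detection: detected ever after
  sc1 <- simulation_scenario(seed = 4, S = 1, T_occ = 6, n_per_site = 50,
                             psi = 1, mu = 20, beta = 20, sigma_space = 0,
                             sigma_time = 0, sigma_gamma = 0)
  h1 <- simulate_histories(sc1)
  for (i in seq_len(nrow(h1$detections)))
    expect_true(all(h1$detections[i, h1$first_capture[i]:6] == 1L))
})

test_that("the reencounter fraction matches the chi recursion", {
  phi <- 0.67; p <- 0.12; psi <- 0.6; T_occ <- 12
  sc <- simulation_scenario(seed = 5, S = 1, T_occ = T_occ,
                            n_per_site = 5000, mu = logit(phi),
                            beta = logit(p), psi = psi, sigma_space = 0,
                            sigma_time = 0, sigma_gamma = 0)
  h <- simulate_histories(sc)
  fc <- h$first_capture
  p_reenc <- vapply(seq_len(T_occ - 1), function(f)
    1 - never_seen_prob(f, T_occ, phi, p, psi), numeric(1))
  expected <- mean(p_reenc[fc])
  se <- sqrt(sum(p_reenc[fc] * (1 - p_reenc[fc]))) / length(fc)
  observed <- mean(rowSums(h$detections) > 1)
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("generation is reproducible and the truth rides a sidecar", {
  sc <- simulation_scenario(seed = 6, S = 3, T_occ = 6, n_per_site = 40)
  h1 <- simulate_histories(sc)
  r1 <- simulate_records(h1, sc)
  h2 <- simulate_histories(sc)
  r2 <- simulate_records(h2, sc)
  expect_identical(h1$detections, h2$detections)
  expect_identical(r1$records, r2$records)
  tr <- attr(h1, "truth")
  expect_equal(tr$params$mu, sc$mu)
  path <- withr::local_tempfile(fileext = ".txt")
  write_truth(h1, path)
  expect_true(any(grepl("^mu:", readLines(path))))
  # truth never travels in the record file
  expect_false(any(grepl("mu", names(r1$records))))
})

test_that("the likelihood prefers the truth over a shifted model", {
  wins <- 0L
  for (r in 1:10) {
    sc <- simulation_scenario(seed = 100 + r, S = 4, T_occ = 8,
                              n_per_site = 120)
    h <- simulate_histories(sc)
    tr <- attr(h, "truth")$params
    shifted <- model_parameters(mu = tr$mu + 1, eta = tr$eta, eps = tr$eps,
                                sigma_space = tr$sigma_space,
                                sigma_time = tr$sigma_time, beta = tr$beta,
                                gamma = tr$gamma,
                                sigma_gamma = tr$sigma_gamma, psi = tr$psi)
    if (total_loglik(h, tr) > total_loglik(h, shifted)) wins <- wins + 1L
  }
  expect_gte(wins, 9)
})

test_that("records expand detections inside their occasion and jitter box", {
  cfg <- run_config()
  sc <- simulation_scenario(seed = 7, S = 2, T_occ = 5, n_per_site = 30,
                            beta = logit(0.3), n_decoys = 1)
  h <- simulate_histories(sc)
  out <- simulate_records(h, sc, cfg)
  recs <- out$records
  core <- recs[!grepl("^DEC", recs$ring_id), ]
  # every record within the pooling radius (chebyshev) of its bird's site
  site_of <- h$site_index[match(core$ring_id, rownames(h$detections))]
  dlat <- abs(core$lat - sc$site_lat[site_of])
  dlon <- abs(core$lon - sc$site_lon[site_of])
  expect_true(all(pmax(dlat, dlon) <= cfg$pooling_radius))
  # occasion of every record matches a detection of that bird
  yr <- as.integer(format(core$date, "%Y"))
  mo <- as.integer(format(core$date, "%m"))
  occ <- ifelse(mo >= 8, yr, yr - 1) - 1998 + 1
  expect_true(all(h$detections[cbind(match(core$ring_id,
                                           rownames(h$detections)), occ)] == 1L))
  # decoy locations carry exactly the sub-threshold number of dates
  dec <- recs[grepl("^DEC", recs$ring_id), ]
  expect_equal(length(unique(dec$date)), sc$decoy_days)
  # no-jitter scenarios put everything exactly on the centers
  sc0 <- simulation_scenario(seed = 8, S = 2, T_occ = 5, n_per_site = 20,
                             jitter_prob = 0, n_decoys = 0)
  h0 <- simulate_histories(sc0)
  r0 <- simulate_records(h0, sc0, cfg)$records
  expect_true(all(r0$lat %in% sc0$site_lat & r0$lon %in% sc0$site_lon))
})

test_that("preprocessing the generated records reproduces the histories", {
  cfg <- run_config(study_end = "2006-07-31")  # 8 occasions
  sc <- simulation_scenario(seed = 9, S = 3, T_occ = 8, n_per_site = 60,
                            beta = logit(0.25), n_decoys = 2)
  h <- simulate_histories(sc)
  out <- simulate_records(h, sc, cfg)
  pp <- suppressMessages(suppressWarnings(
    preprocess_records(out$records, out$site_table, cfg)))
  rebuilt <- pp$histories
  ord <- match(rownames(h$detections), rownames(rebuilt$detections))
  expect_false(any(is.na(ord)))
  expect_equal(unname(rebuilt$detections[ord, ]), unname(h$detections))
  expect_equal(rebuilt$site_index[ord], h$site_index)
  # all decoy records were dropped by the radius rule
  expect_equal(pp$n_dropped, out$n_decoy_records)
  expect_false(any(grepl("^DEC", rownames(rebuilt$detections))))
})
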