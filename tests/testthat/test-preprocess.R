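rec_df <- function(ring, date, lat, lon) {
  data.frame(ring_id = ring, date = as.Date(date), lat = lat, lon = lon,
             age = "adult", stringsAsFactors = FALSE)
}

test_that("effort counts distinct calendar dates per exact coordinate", {
  r <- rec_df(c("A", "B", "C"), rep("2000-09-01", 3), rep(-29.5, 3),
              rep(26.1, 3))
  eff <- compute_effort(r)
  expect_equal(nrow(eff), 1)
  expect_equal(eff$effort_days, 1)

  dates <- format(seq(as.Date("1999-01-01"), by = "day", length.out = 24))
  r24 <- rec_df(paste0("A", 1:24), dates, rep(-29.5, 24), rep(26.1, 24))
  expect_equal(compute_effort(r24)$effort_days, 24)

  # brute force: random date sets at three coordinates
  set.seed(1)
  base <- as.Date("2000-08-01")
  r3 <- do.call(rbind, lapply(1:3, function(k) {
    d <- base + sample(0:400, 30, replace = TRUE)
    rec_df(paste0("X", k, seq_along(d)), format(d), rep(-20 - k, 30),
           rep(25, 30))
  }))
  eff3 <- compute_effort(r3)
  expected <- sapply(split(r3$date, r3$lat), function(d) length(unique(d)))
  expect_equal(eff3$effort_days[order(eff3$lat)],
               unname(expected[order(as.numeric(names(expected)))]))
})

test_that("effort filter keeps locations at or above the threshold", {
  eff <- data.frame(lat = c(-29, -30), lon = c(26, 27),
                    effort_days = c(24L, 23L))
  suppressMessages({
    keep <- filter_high_effort(eff, 24)
    expect_equal(nrow(keep), 1)
    expect_equal(keep$lat, -29)
    expect_equal(nrow(filter_high_effort(eff, 1)), 2)
    expect_warning(filter_high_effort(eff, 100), "no locations")
  })
})

test_that("pooling assigns within the radius, drops outside, breaks ties low", {
  high <- data.frame(lat = c(-29.0, -30.0), lon = c(26.0, 26.0))
  r <- rec_df(c("in", "out", "tie"), rep("2000-09-01", 3),
              c(-29.10, -29.40, -29.50), c(26.0, 26.2, 26.0))
  pooled <- suppressMessages(pool_captures(r, high, radius = 0.17,
                                           site_merge_map = c(1L, 2L)))
  expect_equal(pooled$ring_id, "in")
  expect_equal(pooled$site_id, 1L)
  expect_equal(attr(pooled, "n_dropped"), 2L)

  # equidistant record with a wide radius goes to the lower site id
  pooled2 <- suppressMessages(pool_captures(r, high, radius = 0.6,
                                            site_merge_map = c(2L, 1L)))
  expect_equal(pooled2$site_id[pooled2$ring_id == "tie"], 1L)
  # conservation: assigned + dropped = input
  expect_equal(nrow(pooled2) + attr(pooled2, "n_dropped"), nrow(r))
})

test_that("chebyshev and euclidean radii differ on the box corners", {
  high <- data.frame(lat = 0, lon = 0)
  r <- rec_df("c", "2000-09-01", 0.15, 0.15)  # chebyshev 0.15, euclid 0.212
  expect_equal(nrow(suppressMessages(
    pool_captures(r, high, 0.17, metric = "chebyshev"))), 1)
  expect_equal(nrow(suppressMessages(
    pool_captures(r, high, 0.17, metric = "euclidean"))), 0)
})

test_that("migratory classification is strict at the threshold", {
  expect_true(classify_migratory(-33.9))
  expect_false(classify_migratory(-21.0))
  expect_false(classify_migratory(-26.0))
  expect_equal(classify_migratory(c(-30, -20)), c(TRUE, FALSE))
})

test_that("occasions are Aug-Jul years and within-occasion captures collapse", {
  cfg <- run_config()
  r <- rec_df(c("A", "A", "B", "B"),
              c("2000-09-01", "2001-03-01", "2000-07-15", "2000-08-15"),
              rep(-29, 4), rep(26, 4))
  r$site_id <- 1L
  h <- build_histories(r, cfg)
  # A: both dates inside Aug 2000-Jul 2001 (occasion 3) -> one detection
  expect_equal(sum(h$detections["A", ]), 1)
  expect_equal(h$first_capture[rownames(h$detections) == "A"], 3L)
  # B: Jul then Aug 2000 -> adjacent occasions 2 and 3
  expect_equal(which(h$detections["B", ] == 1L), c(2L, 3L))
})

test_that("a ten-bird fixture reproduces the hand-computed matrix", {
  cfg <- run_config()
  dates <- list(
    c("1998-08-05"), c("1999-09-01", "2000-09-01"),
    c("2000-01-10", "2000-02-10"), c("2001-08-01", "2003-07-31"),
    c("2004-12-25"), c("2005-06-30", "2005-07-01", "2005-08-01"),
    c("2006-10-10"), c("2007-02-01", "2008-02-01", "2009-02-01"),
    c("2008-08-20"), c("1998-08-01", "2009-08-01"))
  r <- do.call(rbind, lapply(seq_along(dates), function(i)
    rec_df(rep(sprintf("R%02d", i), length(dates[[i]])), dates[[i]],
           rep(-29, length(dates[[i]])), rep(26, length(dates[[i]])))))
  r$site_id <- 1L
  h <- build_histories(r, cfg)
  occ_of <- function(d) {
    d <- as.Date(d); y <- as.integer(format(d, "%Y"))
    ifelse(as.integer(format(d, "%m")) >= 8, y, y - 1) - 1998 + 1
  }
  expected <- matrix(0L, 10, 12)
  for (i in seq_along(dates)) expected[i, occ_of(dates[[i]])] <- 1L
  rownames(expected) <- sprintf("R%02d", seq_along(dates))
  expect_equal(h$detections, expected)
  expect_equal(ncol(h$detections), 12)
})

test_that("records outside the window and last-occasion entrants are handled", {
  cfg <- run_config()
  r <- rec_df("A", "1990-01-01", -29, 26)
  r$site_id <- 1L
  expect_error(build_histories(r, cfg), "study window.*A|A.*study window")

  r2 <- rec_df(c("A", "B"), c("2009-09-01", "2000-09-01"), c(-29, -29),
               c(26, 26))
  r2$site_id <- 1L
  h <- suppressMessages(build_histories(r2, cfg))
  expect_equal(rownames(h$detections), "B")  # A entered at occasion 12 of 12
})

test_that("the m-array matches the two-history walk-through and brute force", {
  h <- make_histories(list(c(1, 1, 0), c(1, 0, 1)))
  ma <- build_marray(h)
  expect_equal(ma$R, c(2L, 1L))
  expect_equal(ma$m[1, 2:3], c(1L, 1L))
  expect_equal(ma$m[2, 3], 0L)
  expect_equal(ma$never, c(0L, 1L))

  singles <- make_histories(list(c(1, 0, 0), c(0, 1, 0), c(0, 1, 0)))
  ma1 <- build_marray(singles)
  expect_true(all(ma1$m == 0L))
  expect_equal(ma1$never, ma1$R)

  # random fixture against a direct first-reencounter scan
  set.seed(42)
  rows <- lapply(1:40, function(i) {
    repeat {
      v <- rbinom(6, 1, 0.4)
      if (sum(v) > 0 && which(v == 1)[1] < 6) return(v)
    }
  })
  hr <- make_histories(rows)
  ma2 <- build_marray(hr)
  m_direct <- matrix(0L, 5, 6)
  for (v in rows) {
    seen <- which(v == 1)
    if (length(seen) > 1)
      for (k in seq_len(length(seen) - 1))
        m_direct[seen[k], seen[k + 1]] <- m_direct[seen[k], seen[k + 1]] + 1L
  }
  expect_equal(ma2$m[, 2:6], m_direct[, 2:6])
  # marginals: releases = reencounters + never
  expect_equal(ma2$R, rowSums(ma2$m) + ma2$never)
  # total first reencounters equal recapture events counted from histories
  expect_equal(sum(ma2$m), sum(vapply(rows, function(v) sum(v) - 1L, 1L)))
})
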