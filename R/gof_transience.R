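#' Per-occasion transience contingency tables
#'
#' For each occasion i = 1..T-1, the individuals detected at i are
#' cross-classified as newly versus previously marked (rows) against
#' reencountered at any later occasion versus never (columns). Transients
#' -- birds with effectively zero survival after initial capture -- inflate
#' the newly-marked/never-reencountered cell, which is what the directional
#' 3.SR test detects. Tables with a zero row or column margin carry no
#' information about that contrast and are flagged uninformative.
#'
#' @param histories `encounter_histories` object; by default all sites are
#'   pooled (pass a [subset_histories()] result for a per-site test).
#' @return data.frame, one row per occasion, with counts `new_seen`,
#'   `new_never`, `old_seen`, `old_never` and a logical `informative`.
#' @export
transience_tables <- function(histories) {
  det <- histories$detections
  T_occ <- ncol(det)
  fc <- histories$first_capture
  out <- data.frame(occasion = seq_len(T_occ - 1), new_seen = 0L,
                    new_never = 0L, old_seen = 0L, old_never = 0L)
  for (i in seq_len(T_occ - 1)) {
    at_i <- det[, i] == 1L
    if (!any(at_i)) next
    later <- if (i + 1 <= T_occ)
      rowSums(det[, (i + 1):T_occ, drop = FALSE]) > 0 else
      rep(FALSE, nrow(det))
    new <- fc == i
    out$new_seen[i] <- sum(at_i & new & later)
    out$new_never[i] <- sum(at_i & new & !later)
    out$old_seen[i] <- sum(at_i & !new & later)
    out$old_never[i] <- sum(at_i & !new & !later)
  }
  r1 <- out$new_seen + out$new_never
  r2 <- out$old_seen + out$old_never
  c1 <- out$new_seen + out$old_seen
  c2 <- out$new_never + out$old_never
  out$informative <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
  out
}

#' Directional z-test for transience (3.SR)
#'
#' Per informative table, the Pearson chi-square statistic (no continuity
#' correction) is signed: positive when newly marked birds are reencountered
#' less than expected under homogeneity (the transience direction). The
#' components z_i = sign * sqrt(chi2_i) are combined with equal weights,
#' Z = sum(z_i) / sqrt(M) over the M informative tables, and referred to a
#' standard normal for a one-sided p-value, p = 1 - Phi(Z).
#'
#' @param tables output of [transience_tables()] (or any data.frame with
#'   the same count columns).
#' @return object of class `gof_3sr`: list with per-table `z` and `chisq`,
#'   pooled `Z`, one-sided `p_value`, number of informative tables `M`, and
#'   a `status` flag ("ok", or "no informative tables" with `p_value` NA).
#' @export
test_3sr <- function(tables) {
  inf <- tables$informative
  M <- sum(inf)
  z <- rep(NA_real_, nrow(tables))
  chisq <- rep(NA_real_, nrow(tables))
  for (i in which(inf)) {
    a <- tables$new_seen[i]; b <- tables$new_never[i]
    c <- tables$old_seen[i]; d <- tables$old_never[i]
    n <- a + b + c + d
    r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
    chisq[i] <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
    expected_a <- r1 * c1 / n
    s <- if (a < expected_a) 1 else if (a > expected_a) -1 else 0
    z[i] <- s * sqrt(chisq[i])
  }
  if (M == 0) {
    res <- list(tables = tables, z = z, chisq = chisq, Z = NA_real_,
                p_value = NA_real_, M = 0L,
                status = "no informative tables")
  } else {
    Z <- sum(z[inf]) / sqrt(M)
    res <- list(tables = tables, z = z, chisq = chisq, Z = Z,
                p_value = 1 - stats::pnorm(Z), M = as.integer(M),
                status = "ok")
  }
  class(res) <- "gof_3sr"
  res
}

#' @export
print.gof_3sr <- function(x, ...) {
  cat("Directional z-test for transience (3.SR)\n")
  if (x$status != "ok") {
    cat("  status:", x$status, "\n")
    return(invisible(x))
  }
  cat(sprintf("  informative tables: %d\n", x$M))
  cat(sprintf("  Z = %.3f, one-sided p = %.4g\n", x$Z, x$p_value))
  invisible(x)
}

#' Write a 3.SR report as structured text
#'
#' @param result `gof_3sr` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gof_report <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("3.SR transience goodness-of-fit report", con)
  writeLines(sprintf("status: %s", result$status), con)
  if (result$status == "ok") {
    writeLines(sprintf("informative_tables: %d", result$M), con)
    writeLines(sprintf("Z: %.6f", result$Z), con)
    writeLines(sprintf("p_one_sided: %.6g", result$p_value), con)
  }
  writeLines("", con)
  writeLines("occasion,new_seen,new_never,old_seen,old_never,informative,chisq,z",
             con)
  t <- result$tables
  for (i in seq_len(nrow(t)))
    writeLines(sprintf("%d,%d,%d,%d,%d,%s,%s,%s", t$occasion[i],
                       t$new_seen[i], t$new_never[i], t$old_seen[i],
                       t$old_never[i], t$informative[i],
                       format(result$chisq[i]), format(result$z[i])), con)
  invisible(path)
}
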