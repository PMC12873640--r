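test_that("activation CCG finds the planted lag and is antisymmetric", {
  set.seed(61)
  n <- 6000; mask <- rep(TRUE, n)
  a <- ar_trace(n)
  b <- c(rep(0, 2), a[1:(n - 2)]) + rnorm(n, sd = 0.1)  # b lags a by 2 bins
  cc <- activation_ccg(a, b, mask)
  expect_equal(cc$peak_lag, 0.04)
  cc_rev <- activation_ccg(b, a, mask)
  expect_equal(cc_rev$peak_lag, -cc$peak_lag)
  expect_equal(rev(cc_rev$ccg), cc$ccg, tolerance = 1e-12)
  expect_error(activation_ccg(a, b, rep(FALSE, n)), "NREM")
})

test_that("CCG never multiplies bins across NREM segment boundaries", {
  # two segments whose junction would create a spurious correlation at lag 1:
  # a ends each segment high, b starts each segment high
  n <- 4000
  mask <- rep(FALSE, n); mask[1:1000] <- TRUE; mask[3001:4000] <- TRUE
  set.seed(62)
  a <- rnorm(n); b <- rnorm(n)
  a[1000] <- 50; b[3001] <- 50   # adjacent in concatenated order, not in time
  cc <- activation_ccg(a, b, mask)
  # brute force within segments only
  za <- a; zb <- b
  mu_a <- mean(a[mask]); s_a <- sd(a[mask]); mu_b <- mean(b[mask]); s_b <- sd(b[mask])
  segs <- rbind(c(1, 1000), c(3001, 4000))
  for (k in seq_along(cc$lags_s)) {
    L <- round(cc$lags_s[k] / 0.02)
    tot <- 0; cnt <- 0
    for (r in 1:2) {
      t0 <- max(segs[r, 1], segs[r, 1] - L)
      t1 <- min(segs[r, 2], segs[r, 2] - L)
      if (t1 < t0) next
      tt <- t0:t1
      tot <- tot + sum((a[tt] - mu_a) / s_a * (b[tt + L] - mu_b) / s_b)
      cnt <- cnt + length(tt)
    }
    expect_equal(cc$ccg[k], tot / cnt, tolerance = 1e-10)
  }
})

test_that("chunk-shuffle null matches a brute-force shuffle oracle", {
  set.seed(63)
  n <- 1300
  mask <- rep(FALSE, n); mask[51:550] <- TRUE; mask[701:1200] <- TRUE
  a <- ar_trace(n); b <- ar_trace(n)
  res <- chunk_shuffle_null(a, b, mask, n_shuffles = 30, seed = 9)
  expect_identical(res, chunk_shuffle_null(a, b, mask, n_shuffles = 30, seed = 9))

  chunk_bins <- 100L
  segs <- rbind(c(51L, 550L), c(701L, 1200L))
  idx <- integer(0); seg_of <- integer(0)
  for (r in 1:2) {
    nck <- (segs[r, 2] - segs[r, 1] + 1L) %/% chunk_bins
    idx <- c(idx, segs[r, 1] + seq_len(nck * chunk_bins) - 1L)
    seg_of <- c(seg_of, rep(r, nck))
  }
  K <- length(seg_of)
  za <- (a[idx] - mean(a[idx])) / sd(a[idx])
  zb <- (b[idx] - mean(b[idx])) / sd(b[idx])
  set.seed(9)
  perms <- t(vapply(1:30, function(i) sample.int(K), integer(K)))
  brute_ccg <- function(bperm) {
    barr <- as.vector(matrix(zb, nrow = chunk_bins)[, bperm])
    vapply(-5:5, function(L) {
      tot <- 0; cnt <- 0
      for (t in seq_len(K * chunk_bins)) {
        u <- t + L
        if (u < 1 || u > K * chunk_bins) next
        if (seg_of[ceiling(t / chunk_bins)] != seg_of[ceiling(u / chunk_bins)]) next
        tot <- tot + za[t] * barr[u]; cnt <- cnt + 1
      }
      tot / cnt
    }, 0)
  }
  expect_equal(res$observed_ccg, brute_ccg(seq_len(K)), tolerance = 1e-12)
  peaks <- vapply(1:30, function(s) max(brute_ccg(perms[s, ])), 0)
  expect_equal(res$null_peaks, peaks, tolerance = 1e-12)
  short_mask <- rep(FALSE, n); short_mask[1:300] <- TRUE   # only 3 chunks
  expect_error(chunk_shuffle_null(a, b, short_mask, n_shuffles = 10), "chunk")
})

test_that("planted coupled pairs are significant; coupling power is high", {
  set.seed(64)
  n <- 30000; mask <- rep(TRUE, n)
  hits <- 0L
  for (i in 1:10) {
    shared <- rbinom(n, 1, 0.004) * 8
    a <- ar_trace(n, 0.3) + shared
    b <- ar_trace(n, 0.3) + c(rep(0, 1), shared[1:(n - 1)])
    res <- chunk_shuffle_null(a, b, mask, n_shuffles = 200, seed = i)
    if (res$observed_peak > res$percentiles[["p995"]]) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("coactivation events require the 25 z^2 product threshold", {
  n <- 200
  a <- rep(0, n); b <- rep(0, n)
  a[50] <- 6; b[50] <- 6       # product 36 -> event
  a[100] <- 10; b[100] <- 2    # product 20 -> no event
  ev <- coactivation_events(a, b, lag_s = 0, nrem_mask = rep(TRUE, n))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$time_s, (50 - 0.5) * 0.02)
  # lag alignment: b leads by 2 bins
  b2 <- rep(0, n); b2[52] <- 6
  ev2 <- coactivation_events(a, b2, lag_s = 0.04, nrem_mask = rep(TRUE, n))
  expect_equal(ev2$time_s, (50 - 0.5) * 0.02)
  # outside NREM -> dropped
  m <- rep(TRUE, n); m[50] <- FALSE
  ev3 <- coactivation_events(a, b, lag_s = 0, nrem_mask = m)
  expect_equal(nrow(ev3), 0L)
})

test_that("pair turnover splits post-epoch pairs into unchanged and reorganized", {
  mk <- function(sig) data.frame(region_a = "PL5", ens_a = 1:4,
                                 region_b = "BLA", ens_b = 1L,
                                 significant = sig)
  same <- pair_turnover(mk(c(TRUE, TRUE, FALSE, FALSE)),
                        mk(c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(unname(attr(same, "fractions")["unchanged"]), 1)
  flip <- pair_turnover(mk(c(TRUE, TRUE, FALSE, FALSE)),
                        mk(c(FALSE, FALSE, TRUE, TRUE)))
  expect_equal(unname(attr(flip, "fractions")["reorganized"]), 1)
  expect_equal(nrow(flip), 2L)
})

test_that("fraction statistics give Wilson CIs and flat heterogeneity on equal rats", {
  st <- coactivation_fraction_stats(rep(c(TRUE, rep(FALSE, 9)), 4),
                                    rat = rep(letters[1:4], each = 10))
  expect_equal(st$fraction, 0.1)
  expect_equal(unname(st$ci["upper"]), unname(wilson_ci(4, 40)["upper"]))
  expect_true(all(st$heterogeneity$p_adj == 1))
  st0 <- coactivation_fraction_stats(rep(FALSE, 10))
  expect_equal(unname(st0$ci["lower"]), 0)
  expect_equal(unname(st0$ci["upper"]), 0.2775, tolerance = 1e-3)
})
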