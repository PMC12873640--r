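test_that("band power matches a brute-force windowed RMS oracle", {
  fs <- 1250
  set.seed(2)
  x <- rnorm(4 * fs) * 30
  nrem <- rep(TRUE, length(x))
  pz <- band_power_z(x, fs, c(90, 180), 0.020, nrem)
  bf <- signal::butter(4, c(90, 180) / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, x)
  w <- round(0.020 * fs)
  rms <- vapply(seq_along(x), function(i) {
    lo <- max(1, i - w %/% 2); hi <- min(length(x), i + w %/% 2)
    if (i - w %/% 2 < 1 || i + (w - w %/% 2 - 1) > length(x)) {
      sqrt(mean(filt[lo:hi]^2))
    } else {
      sqrt(mean(filt[(i - w %/% 2):(i + (w - w %/% 2 - 1))]^2))
    }
  }, 0)
  oracle <- (rms - mean(rms)) / sd(rms)
  expect_gt(cor(pz, oracle), 0.999)
  # in-band sinusoid: windowed RMS of the filtered signal ~ A / sqrt(2)
  a_amp <- 100
  xs <- a_amp * sin(2 * pi * 130 * seq_along(x) / fs)
  fs_rms <- sqrt(mean(signal::filtfilt(bf, xs)[w:(length(x) - w)]^2))
  expect_equal(fs_rms, a_amp / sqrt(2), tolerance = 0.02)
  expect_error(band_power_z(x, fs, c(90, 700), 0.02, nrem), "Nyquist")
})

test_that("cRipple rules: entry/peak/duration thresholds, merging, NREM only", {
  # measured durations exceed planted burst length by roughly the RMS window,
  # so rule-violating plants sit clearly below the thresholds
  bursts <- data.frame(
    t0 = c(20, 40, 60, 60.09, 80, 5),
    freq = 130,
    amp = c(400, 400, 400, 400, 400, 400),
    dur = c(0.08, 0.025, 0.10, 0.10, 1.3, 0.08))
  lfp <- lfp_scene(bursts = bursts, seed = 3)
  ep <- nrem_epochs()
  ev <- detect_cripples(lfp, ep)
  hit <- function(t0) any(ev$peak_s > t0 - 0.1 & ev$peak_s < t0 + 0.1)
  expect_true(hit(20))          # compliant
  expect_false(hit(40))         # measured span < 50 ms minimum duration
  expect_false(any(ev$peak_s > 79 & ev$peak_s < 81))  # >= 750 ms cap
  expect_false(hit(5))          # WAKE: not reported
  # two 100 ms bursts whose above-threshold spans end < 30 ms apart merge
  n_at_60 <- sum(ev$peak_s > 59.5 & ev$peak_s < 60.7)
  expect_equal(n_at_60, 1L)
  expect_true(all(ev$end_s - ev$start_s < 0.75))

  # weak burst: peak below 5 z is rejected even if entry threshold is crossed
  weak <- lfp_scene(bursts = data.frame(t0 = 30, freq = 130, amp = 95,
                                        dur = 0.1), seed = 4)
  pk <- detect_cripples(weak, ep)
  strong <- lfp_scene(bursts = data.frame(t0 = 30, freq = 130, amp = 400,
                                          dur = 0.1), seed = 4)
  pk2 <- detect_cripples(strong, ep)
  expect_true(any(pk2$peak_s > 29.9 & pk2$peak_s < 30.1))
  expect_gt(max(pk2$peak_z), ifelse(nrow(pk), max(pk$peak_z), 0))
})

test_that("HFO detection uses per-shank median, NREM restriction and its thresholds", {
  bursts <- data.frame(t0 = c(30, 5), freq = 120, amp = 400, dur = 0.1)
  lfp <- lfp_scene(region = "BLA", bursts = bursts, seed = 5)
  ep <- nrem_epochs()
  ev <- detect_hfo(lfp, ep)
  expect_true(any(abs(ev$peak_s - 30) < 0.05))
  expect_false(any(abs(ev$peak_s - 5) < 0.05))   # WAKE burst not reported
  expect_true(all(ev$end_s - ev$start_s < 0.75))
  # two bursts separated by < 20 ms merge into one event
  close_b <- data.frame(t0 = c(50, 50.062), freq = 120, amp = 400, dur = 0.05)
  lfp2 <- lfp_scene(region = "BLA", bursts = close_b, seed = 6)
  ev2 <- detect_hfo(lfp2, ep)
  expect_equal(sum(ev2$peak_s > 49.8 & ev2$peak_s < 50.3), 1L)
})

test_that("SWR requires ripple and sharp-wave co-occurrence on the same shank", {
  ep <- nrem_epochs()
  # ripple burst with a co-occurring deep positive deflection -> SWR
  with_sw <- lfp_scene(region = "vCA1", seed = 7,
                       bursts = data.frame(t0 = 40, freq = 150, amp = 400,
                                           dur = 0.08),
                       sw = data.frame(t0 = 40, amp = 700, dur = 0.1))
  ev <- detect_swr(with_sw, ep)
  expect_true(any(abs(ev$peak_s - 40) < 0.025))
  # the same ripple without the sharp wave is not an SWR
  no_sw <- lfp_scene(region = "vCA1", seed = 7,
                     bursts = data.frame(t0 = 40, freq = 150, amp = 400,
                                         dur = 0.08))
  expect_false(any(abs(detect_swr(no_sw, ep)$peak_s - 40) < 0.05))
  # a ripple whose measured span stays under 30 ms is rejected
  short <- lfp_scene(region = "vCA1", seed = 8,
                     bursts = data.frame(t0 = 60, freq = 150, amp = 400,
                                         dur = 0.006),
                     sw = data.frame(t0 = 60, amp = 700, dur = 0.1))
  expect_false(any(abs(detect_swr(short, ep)$peak_s - 60) < 0.05))
  # detection is invariant to a global gain change
  g <- with_sw; g$samples <- g$samples * 3
  ev3 <- detect_swr(g, ep)
  expect_equal(ev3$peak_s, ev$peak_s, tolerance = 1e-6)
})

test_that("oscillation-locked gain matches closed forms", {
  ep <- epoch_set("s", "NREM", 0, 1000)
  osc <- structure(data.frame(start_s = seq(10, 990, by = 10),
                              end_s = seq(10, 990, by = 10) + 0.1,
                              peak_s = seq(10, 990, by = 10) + 0.05,
                              peak_z = 6, source = 1L),
                   class = c("oscillation_events", "data.frame"))
  # uniform events -> gain ~ 1
  set.seed(9)
  ev_unif <- runif(2000, 0, 1000)
  mod <- oscillation_modulation(ev_unif, osc, ep)
  expect_equal(mod$gain, 1, tolerance = 0.25)
  # all events inside oscillations occupying ~0.98% of NREM -> gain ~ 1/frac
  ev_in <- osc$peak_s
  frac <- sum(osc$end_s - osc$start_s) / 1000
  mod2 <- oscillation_modulation(ev_in, osc, ep)
  expect_equal(mod2$gain, 1 / frac, tolerance = 1e-6)
  # PETH concentrates at zero lag for locked events
  expect_equal(mod2$lags_s[which.max(mod2$peth)], 0, tolerance = 0.011)
})
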