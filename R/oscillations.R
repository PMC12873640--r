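#' @name oscillations
#' @title Fast network oscillation detection (SWR, HFO, cRipple)
#'
#' @description
#' Three band-power detectors with the standard parameterization. Band power is
#' the RMS of zero-phase band-pass filtered LFP in a sliding window, z-scored
#' by its NREM mean and SD. Hippocampal SWRs are the co-occurrence of ripples
#' (100-250 Hz power > 1.5 z in 13.3 ms windows; candidates with peak < 4 z or
#' duration < 30 ms excluded; gaps < 10 ms merged; merged within shank) and
#' sharp waves (superficial-minus-deep LFP, 2-40 Hz, z < -2.5 for 20-400 ms):
#' a ripple must contain a sharp-wave trough on its shank. Amygdalar HFOs use
#' the per-shank median LFP (90-180 Hz, 20 ms windows, > 2 z for >= 30 ms,
#' peak > 4 z, gaps < 20 ms merged). Prelimbic cRipples are per-channel
#' (90-180 Hz, 20 ms windows, > 3 z; peak < 5 z or duration < 50 ms excluded;
#' gaps < 30 ms merged). All events must be shorter than 750 ms; SWRs are
#' reported during NREM and wakefulness, HFOs and cRipples during NREM only.
NULL

#' Band-limited RMS power, z-scored by NREM
#'
#' Zero-phase 4th-order Butterworth band-pass, then centered sliding-window
#' RMS at sample step, z-scored using NREM samples.
#'
#' @param x numeric signal (one channel).
#' @param sample_rate Hz.
#' @param band numeric c(low, high), Hz; must lie inside Nyquist.
#' @param window RMS window length, seconds.
#' @param nrem_samples logical mask of NREM samples (z-basis).
#' @param order Butterworth order.
#' @return numeric z-scored power trace, same length as `x`.
#' @export
band_power_z <- function(x, sample_rate, band, window, nrem_samples,
                         order = 4L) {
  if (band[2L] >= sample_rate / 2) stop("band must lie below Nyquist")
  bf <- signal::butter(order, band / (sample_rate / 2), type = "pass")
  filt <- signal::filtfilt(bf, x)
  w <- max(1L, round(window * sample_rate))
  ms <- as.numeric(stats::filter(filt^2, rep(1 / w, w), sides = 2))
  # shrink the window at the edges rather than returning NA
  na <- which(is.na(ms))
  for (i in na) {
    lo <- max(1L, i - w %/% 2L); hi <- min(length(filt), i + w %/% 2L)
    ms[i] <- mean(filt[lo:hi]^2)
  }
  pw <- sqrt(ms)
  (pw - mean(pw[nrem_samples])) / sd(pw[nrem_samples])
}

# Candidate intervals from a z-power trace: runs above enter_z, filtered by
# minimum duration / peak, then gap-merged (in that order).
.band_candidates <- function(pz, fs, enter_z, min_dur, min_peak, merge_gap) {
  runs <- .true_runs(pz > enter_z)
  if (nrow(runs) == 0L) return(runs)
  keep <- logical(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    dur <- (runs[i, 2L] - runs[i, 1L] + 1L) / fs
    keep[i] <- dur >= min_dur && max(pz[runs[i, 1L]:runs[i, 2L]]) > min_peak
  }
  runs <- runs[keep, , drop = FALSE]
  if (nrow(runs) > 1L) runs <- .merge_gaps(runs, gap = merge_gap * fs)
  runs
}

# Assemble an oscillation_events data.frame from sample-index intervals,
# deriving peak time/power/source from the pointwise-max z-power trace.
.events_from_intervals <- function(iv, fs, pz_max, src_of_max, kind,
                                   allowed_iv) {
  if (nrow(iv) == 0L) {
    ev <- data.frame(start_s = numeric(0), end_s = numeric(0),
                     peak_s = numeric(0), peak_z = numeric(0),
                     source = integer(0))
  } else {
    iv <- iv[(iv[, 2L] - iv[, 1L] + 1L) / fs < 0.750, , drop = FALSE]
    ev <- do.call(rbind, lapply(seq_len(nrow(iv)), function(i) {
      span <- iv[i, 1L]:iv[i, 2L]
      pk <- span[which.max(pz_max[span])]
      data.frame(start_s = (iv[i, 1L] - 1L) / fs, end_s = iv[i, 2L] / fs,
                 peak_s = (pk - 0.5) / fs, peak_z = pz_max[pk],
                 source = src_of_max[pk])
    }))
    if (is.null(ev)) ev <- data.frame(start_s = numeric(0), end_s = numeric(0),
                                      peak_s = numeric(0), peak_z = numeric(0),
                                      source = integer(0))
    ev <- ev[.in_intervals(ev$peak_s, allowed_iv), , drop = FALSE]
    rownames(ev) <- NULL
  }
  attr(ev, "kind") <- kind
  class(ev) <- c("oscillation_events", "data.frame")
  ev
}

# Pointwise max across rows of a matrix plus the row achieving it.
.pointwise_max <- function(m, row_ids) {
  if (nrow(m) == 1L) return(list(mx = m[1L, ], src = rep(row_ids[1L], ncol(m))))
  which_r <- max.col(t(m), ties.method = "first")
  list(mx = m[cbind(which_r, seq_len(ncol(m)))], src = row_ids[which_r])
}

.nrem_sample_mask <- function(epochs, states, fs, n) {
  iv <- .state_intervals(epochs, states)
  .in_intervals((seq_len(n) - 0.5) / fs, iv)
}

#' Detect hippocampal sharp-wave ripples
#'
#' @param lfp an `lfp_set`.
#' @param epochs an [epoch_set()].
#' @param region hippocampal region label in the channel metadata.
#' @return An `oscillation_events` data.frame (start_s, end_s, peak_s, peak_z,
#'   source channel), during NREM and wakefulness.
#' @export
detect_swr <- function(lfp, epochs, region = "vCA1") {
  meta <- lfp$channel_meta
  ch <- which(meta$region == region)
  if (length(ch) == 0L) stop("no channels for region ", region)
  fs <- lfp$sample_rate
  n <- ncol(lfp$samples)
  nrem <- .nrem_sample_mask(epochs, "NREM", fs, n)
  pz_region <- t(vapply(ch, function(cc) {
    band_power_z(lfp$samples[cc, ], fs, c(100, 250), 0.0133, nrem)
  }, numeric(n)))
  shanks <- unique(meta$shank[ch])
  all_iv <- matrix(numeric(0), 0L, 2L)
  for (sh in shanks) {
    in_sh <- meta$shank[ch] == sh
    sh_ch <- ch[in_sh]
    if (length(sh_ch) < 2L) stop("shank ", sh, " needs >= 2 channels (depth metadata)")
    if (anyNA(meta$depth_order[sh_ch])) stop("missing depth metadata on shank ", sh)
    pz <- pz_region[in_sh, , drop = FALSE]
    ripple_iv <- matrix(numeric(0), 0L, 2L)
    for (r in seq_len(nrow(pz))) {
      cand <- .band_candidates(pz[r, ], fs, enter_z = 1.5, min_dur = 0.030,
                               min_peak = 4, merge_gap = 0.010)
      ripple_iv <- rbind(ripple_iv, cand)
    }
    ripple_iv <- .interval_union(ripple_iv)        # merge within shank
    # sharp waves on superficial-minus-deep difference
    sup <- sh_ch[which.min(meta$depth_order[sh_ch])]
    deep <- sh_ch[which.max(meta$depth_order[sh_ch])]
    bf <- signal::butter(4, c(2, 40) / (fs / 2), type = "pass")
    dz <- signal::filtfilt(bf, lfp$samples[sup, ] - lfp$samples[deep, ])
    dz <- (dz - mean(dz[nrem])) / sd(dz[nrem])
    sw <- .true_runs(dz < -2.5)
    if (nrow(sw)) {
      dur <- (sw[, 2L] - sw[, 1L] + 1L) / fs
      sw <- sw[dur >= 0.020 & dur <= 0.400, , drop = FALSE]
    }
    troughs <- vapply(seq_len(nrow(sw)), function(i) {
      span <- sw[i, 1L]:sw[i, 2L]; span[which.min(dz[span])]
    }, 0L)
    # ripple candidates containing >= 1 sharp-wave trough on this shank
    if (nrow(ripple_iv) && length(troughs)) {
      has_sw <- vapply(seq_len(nrow(ripple_iv)), function(i) {
        any(troughs >= ripple_iv[i, 1L] & troughs <= ripple_iv[i, 2L])
      }, TRUE)
      all_iv <- rbind(all_iv, ripple_iv[has_sw, , drop = FALSE])
    }
  }
  pmx <- .pointwise_max(pz_region, ch)
  all_iv <- .interval_union(all_iv)                # merge across shanks
  allowed <- .state_intervals(epochs, c("NREM", "WAKE"))
  .events_from_intervals(all_iv, fs, pmx$mx, pmx$src, "SWR", allowed)
}

#' Detect amygdalar high-frequency oscillations
#'
#' @param lfp an `lfp_set`.
#' @param epochs an [epoch_set()].
#' @param region amygdalar region label.
#' @return An `oscillation_events` data.frame, NREM only.
#' @export
detect_hfo <- function(lfp, epochs, region = "BLA") {
  meta <- lfp$channel_meta
  ch <- which(meta$region == region)
  if (length(ch) == 0L) stop("no channels for region ", region)
  fs <- lfp$sample_rate; n <- ncol(lfp$samples)
  nrem <- .nrem_sample_mask(epochs, "NREM", fs, n)
  shanks <- unique(meta$shank[ch])
  iv <- matrix(numeric(0), 0L, 2L)
  pz_sh <- matrix(0, 0L, n)
  for (sh in shanks) {
    sh_ch <- ch[meta$shank[ch] == sh]
    med <- apply(lfp$samples[sh_ch, , drop = FALSE], 2L, median)
    pz <- band_power_z(med, fs, c(90, 180), 0.020, nrem)
    iv <- rbind(iv, .band_candidates(pz, fs, enter_z = 2, min_dur = 0.030,
                                     min_peak = 4, merge_gap = 0.020))
    pz_sh <- rbind(pz_sh, pz)
  }
  iv <- .interval_union(iv)                        # merge across shanks
  pm <- .pointwise_max(pz_sh, shanks)
  allowed <- .state_intervals(epochs, "NREM")
  .events_from_intervals(iv, fs, pm$mx, pm$src, "HFO", allowed)
}

#' Detect prelimbic cortical ripples
#'
#' @param lfp an `lfp_set`.
#' @param epochs an [epoch_set()].
#' @param region prelimbic region label.
#' @return An `oscillation_events` data.frame, NREM only.
#' @export
detect_cripples <- function(lfp, epochs, region = "PL5") {
  meta <- lfp$channel_meta
  ch <- which(meta$region == region)
  if (length(ch) == 0L) stop("no channels for region ", region)
  fs <- lfp$sample_rate; n <- ncol(lfp$samples)
  nrem <- .nrem_sample_mask(epochs, "NREM", fs, n)
  pz <- t(vapply(ch, function(cc) {
    band_power_z(lfp$samples[cc, ], fs, c(90, 180), 0.020, nrem)
  }, numeric(n)))
  iv <- matrix(numeric(0), 0L, 2L)
  for (r in seq_len(nrow(pz))) {
    iv <- rbind(iv, .band_candidates(pz[r, ], fs, enter_z = 3, min_dur = 0.050,
                                     min_peak = 5, merge_gap = 0.030))
  }
  iv <- .interval_union(iv)                        # merge across channels
  pm <- .pointwise_max(pz, ch)
  allowed <- .state_intervals(epochs, "NREM")
  .events_from_intervals(iv, fs, pm$mx, pm$src, "cRipple", allowed)
}

#' Oscillation-locked modulation of activation events
#'
#' Peri-event time histogram of activation events around oscillation peaks
#' (+/-0.5 s, 20 ms lag bins) and the rate gain: the event rate inside
#' oscillation intervals divided by the event rate over all NREM time.
#'
#' @param event_times activation event times, seconds.
#' @param osc an `oscillation_events` data.frame.
#' @param epochs an [epoch_set()].
#' @param window PETH half-width, seconds.
#' @param bin_size PETH lag bin, seconds.
#' @return list of class `modulation_result`: `peth` (counts), `lags_s`,
#'   `gain`, `n_events`, `n_osc`.
#' @export
oscillation_modulation <- function(event_times, osc, epochs, window = 0.5,
                                   bin_size = 0.02) {
  nrem_iv <- .state_intervals(epochs, "NREM")
  nrem_time <- sum(nrem_iv[, 2L] - nrem_iv[, 1L])
  if (nrem_time <= 0) stop("zero NREM time")
  edges <- seq(-window, window, by = bin_size)
  peth <- integer(length(edges) - 1L)
  for (pk in osc$peak_s) {
    rel <- event_times - pk
    rel <- rel[rel >= -window & rel < window]
    peth <- peth + tabulate(findInterval(rel, edges), nbins = length(peth))
  }
  osc_iv <- cbind(osc$start_s, osc$end_s)
  osc_time <- if (nrow(osc)) sum(osc_iv[, 2L] - osc_iv[, 1L]) else 0
  ev_nrem <- sum(.in_intervals(event_times, nrem_iv))
  ev_osc <- if (nrow(osc)) sum(.in_intervals(event_times, osc_iv)) else 0
  gain <- if (osc_time > 0 && ev_nrem > 0) {
    (ev_osc / osc_time) / (ev_nrem / nrem_time)
  } else NA_real_
  structure(list(peth = peth, lags_s = head(edges, -1L) + bin_size / 2,
                 gain = gain, n_events = length(event_times), n_osc = nrow(osc)),
            class = "modulation_result")
}
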