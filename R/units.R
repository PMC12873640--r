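#' @name units
#' @title Putative excitatory / inhibitory classification
#'
#' @description
#' Units are classified by detecting monosynaptic interactions between
#' simultaneously recorded pairs from the same region. For each pair, a spike
#' timing cross-correlogram (CCG) in 0.1 ms bins over +/-5 ms is smoothed with
#' a Gaussian kernel (sigma = 0.5 ms) and compared against 99% global bands
#' built from uniformly jittered (+/-5 ms) surrogate trains: a smoothed-CCG
#' peak above the upper band within the +1 to +4 ms lag range marks an
#' excitatory output of the reference unit, a trough below the lower band an
#' inhibitory one. Units that send at least one excitatory and no inhibitory
#' output are putative excitatory cells (and symmetrically for inhibitory);
#' units unresolved by CCG fall back to waveform width (FWHM > 0.6 ms
#' excitatory, < 0.5 ms inhibitory), and the rest stay non-classified.
NULL

.CCG_BIN <- 1e-4          # 0.1 ms
.CCG_HALF <- 50L          # +/- 5 ms -> 101 bins
.CCG_SIGMA_BINS <- 5      # 0.5 ms kernel in 0.1 ms bins

.gauss_kernel <- function(sigma_bins, half_width = 4L * ceiling(sigma_bins)) {
  x <- (-half_width):half_width
  k <- exp(-x^2 / (2 * sigma_bins^2))
  k / sum(k)
}

# Truncated "same"-length Gaussian smoothing (kernel renormalized at edges so
# flat inputs stay flat).
.smooth_same <- function(x, kernel) {
  hw <- (length(kernel) - 1L) / 2L
  padded <- c(rep(0, hw), x, rep(0, hw))
  num <- as.numeric(stats::filter(padded, kernel, sides = 2))[(hw + 1L):(hw + length(x))]
  ones <- c(rep(0, hw), rep(1, length(x)), rep(0, hw))
  den <- as.numeric(stats::filter(ones, kernel, sides = 2))[(hw + 1L):(hw + length(x))]
  num / den
}

# Raw lag histogram of (ref, tgt) spike pairs in 0.1 ms bins over +/-5 ms.
.ccg_counts <- function(ref, tgt) {
  half_range <- (.CCG_HALF + 0.5) * .CCG_BIN
  lo <- findInterval(ref - half_range, tgt)
  hi <- findInterval(ref + half_range, tgt)
  n_pairs <- hi - lo
  counts <- integer(2L * .CCG_HALF + 1L)
  has <- which(n_pairs > 0L)
  if (length(has)) {
    lags <- unlist(lapply(has, function(i) tgt[(lo[i] + 1L):hi[i]] - ref[i]),
                   use.names = FALSE)
    bins <- floor(lags / .CCG_BIN + 0.5) + .CCG_HALF + 1L
    keep <- bins >= 1L & bins <= length(counts)
    counts <- tabulate(bins[keep], nbins = length(counts))
  }
  counts
}

#' Spike-timing cross-correlogram of a unit pair
#'
#' Lag = target spike time minus reference spike time, histogrammed in 0.1 ms
#' bins over +/-5 ms, plus a Gaussian-smoothed (sigma = 0.5 ms) version.
#'
#' @param ref,tgt [spike_train()] objects, or bare numeric time vectors.
#' @return list of class `pair_ccg` with `counts`, `smoothed`, `lags_ms`, and
#'   `n_reference_spikes`.
#' @export
pair_ccg <- function(ref, tgt) {
  rt <- if (inherits(ref, "spike_train")) ref$times else as.numeric(ref)
  tt <- if (inherits(tgt, "spike_train")) tgt$times else as.numeric(tgt)
  if (length(rt) == 0L || length(tt) == 0L) stop("empty spike train")
  counts <- .ccg_counts(rt, tt)
  structure(list(counts = counts,
                 smoothed = .smooth_same(counts, .gauss_kernel(.CCG_SIGMA_BINS)),
                 lags_ms = ((-.CCG_HALF):.CCG_HALF) * 0.1,
                 n_reference_spikes = length(rt)),
            class = "pair_ccg")
}

#' Jittered-surrogate global bands for a pair CCG
#'
#' For each replicate the target train's spikes are displaced by i.i.d.
#' Uniform(-5, +5) ms, the smoothed CCG recomputed, and its maximum and
#' minimum over the +/-5 ms range recorded. The bands are the 99.5th
#' percentile of the maxima and the 0.5th percentile of the minima (together a
#' 99% global band).
#'
#' @param ref,tgt spike trains (see [pair_ccg()]).
#' @param n_jitters number of surrogate replicates (>= 100; the field
#'   convention is 1000).
#' @param seed integer RNG seed.
#' @return list of class `global_bands` with `upper`, `lower`, `n_jitters`.
#' @export
jitter_bands <- function(ref, tgt, n_jitters = 1000L, seed = 1L) {
  if (n_jitters < 100L) stop("n_jitters must be >= 100")
  rt <- if (inherits(ref, "spike_train")) ref$times else as.numeric(ref)
  tt <- if (inherits(tgt, "spike_train")) tgt$times else as.numeric(tgt)
  if (length(rt) == 0L || length(tt) == 0L) stop("empty spike train")
  kernel <- .gauss_kernel(.CCG_SIGMA_BINS)
  set.seed(seed)
  mx <- numeric(n_jitters); mn <- numeric(n_jitters)
  for (j in seq_len(n_jitters)) {
    jt <- sort(tt + runif(length(tt), -0.005, 0.005))
    sm <- .smooth_same(.ccg_counts(rt, jt), kernel)
    mx[j] <- max(sm); mn[j] <- min(sm)
  }
  structure(list(upper = .pctile(mx, 0.995), lower = .pctile(mn, 0.005),
                 n_jitters = n_jitters),
            class = "global_bands")
}

# Monosynaptic call for one ordered pair: "+", "-", or NA (no interaction).
.pair_call <- function(ref, tgt, n_jitters, seed) {
  cc <- pair_ccg(ref, tgt)
  bands <- jitter_bands(ref, tgt, n_jitters, seed)
  win <- cc$lags_ms >= 1 & cc$lags_ms <= 4
  exc <- max(cc$smoothed[win]) > bands$upper
  inh <- min(cc$smoothed[win]) < bands$lower
  if (exc && !inh) "+" else if (inh && !exc) "-" else NA_character_
}

#' Classify units as putative excitatory / inhibitory
#'
#' Applies the CCG-jitter monosynaptic test to every ordered pair of units
#' within each region, aggregates outputs per the at-least-one-and-none rule,
#' and falls back to waveform FWHM (> 0.6 ms excitatory, < 0.5 ms inhibitory)
#' for units unresolved by CCG. FWHM in the 0.5-0.6 ms gap, or absent, leaves
#' the unit non-classified.
#'
#' @param dataset an `ensemble_dataset`.
#' @param n_jitters surrogate replicates per pair.
#' @param seed integer RNG seed.
#' @param min_spikes pairs where either train has fewer spikes are skipped
#'   (no CCG evidence).
#' @return data.frame (unit_id, class, basis) of class `unit_classification`,
#'   basis one of "ccg", "fwhm", "none".
#' @export
classify_units <- function(dataset, n_jitters = 1000L, seed = 1L,
                           min_spikes = 50L) {
  units <- dataset$spikes
  n <- length(units)
  n_exc_out <- integer(n); n_inh_out <- integer(n)
  regs <- vapply(units, `[[`, "", "region")
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || regs[i] != regs[j]) next
      if (length(units[[i]]$times) < min_spikes ||
          length(units[[j]]$times) < min_spikes) next
      call <- .pair_call(units[[i]], units[[j]], n_jitters,
                         .substream_seed(seed, paste0("pair", i, "_", j)))
      if (is.na(call)) next
      if (call == "+") n_exc_out[i] <- n_exc_out[i] + 1L
      else n_inh_out[i] <- n_inh_out[i] + 1L
    }
  }
  cls <- rep("non_classified", n); basis <- rep("none", n)
  ccg_exc <- n_exc_out > 0L & n_inh_out == 0L
  ccg_inh <- n_inh_out > 0L & n_exc_out == 0L
  ccg_conflict <- n_exc_out > 0L & n_inh_out > 0L
  cls[ccg_exc] <- "excitatory"; cls[ccg_inh] <- "inhibitory"
  basis[ccg_exc | ccg_inh | ccg_conflict] <- "ccg"
  fwhm <- vapply(units, `[[`, 1, "waveform_fwhm")
  open <- !(ccg_exc | ccg_inh | ccg_conflict)
  fe <- open & !is.na(fwhm) & fwhm > 0.6
  fi <- open & !is.na(fwhm) & fwhm < 0.5
  cls[fe] <- "excitatory"; cls[fi] <- "inhibitory"
  basis[fe | fi] <- "fwhm"
  out <- data.frame(unit_id = vapply(units, `[[`, 1L, "unit_id"),
                    class = cls, basis = basis, stringsAsFactors = FALSE)
  class(out) <- c("unit_classification", "data.frame")
  out
}
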