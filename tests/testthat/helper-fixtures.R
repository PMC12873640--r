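# Shared in-code fixtures for the suite.

# Minimal hand-built dataset: 3 units, one WAKE and one NREM epoch.
tiny_dataset <- function() {
  new_dataset(
    "tiny",
    list(spike_train(1L, "PL5", 1L, c(0.1, 0.5, 1.2), waveform_fwhm = 0.8),
         spike_train(2L, "PL5", 1L, c(0.3, 0.9), waveform_fwhm = 0.4),
         spike_train(3L, "vCA1", 2L, c(0.2, 1.5, 1.9))),
    epoch_set(c("task", "sleep"), c("WAKE", "NREM"), c(0, 2), c(2, 4)))
}

# AR(1) trace (autocorrelated noise standing in for an activation trace).
ar_trace <- function(n, phi = 0.5, sd = 1) {
  as.numeric(stats::filter(rnorm(n, sd = sd), phi, method = "recursive"))
}

# Random unit-norm vectors as columns.
random_unit_vectors <- function(d, k) {
  m <- matrix(rnorm(d * k), d, k)
  sweep(m, 2L, sqrt(colSums(m^2)), "/")
}

# Wrap a bare weight matrix as an ensemble_set for similarity tests.
as_ensemble_set <- function(w, region = "PL5", template = "extinction",
                            unit_ids = seq_len(nrow(w))) {
  structure(list(projections = w,
                 contributors = matrix(FALSE, nrow(w), ncol(w)),
                 n_significant = ncol(w), unit_ids = as.integer(unit_ids),
                 region = region, template_label = template),
            class = "ensemble_set")
}

# Homogeneous Poisson spike train on [0, total).
poisson_train <- function(rate, total) sort(runif(rpois(1L, rate * total), 0, total))

# Single-region session plan with one NREM block framed by wake.
simple_plan <- function(nrem_s = 480, wake_s = 60) {
  data.frame(label = c("wake1", "sleep", "wake2"),
             state = c("WAKE", "NREM", "WAKE"),
             duration = c(wake_s, nrem_s, wake_s), stringsAsFactors = FALSE)
}

# A compact LFP scene builder: pink noise on 2 channels of one region at
# 1250 Hz, with injected Hann-windowed bursts and optional sharp-wave bumps.
lfp_scene <- function(total = 120, region = "PL5", fs = 1250, seed = 1,
                      bursts = NULL, sw = NULL, n_ch = 2L) {
  set.seed(seed)
  n <- total * fs
  samples <- t(vapply(seq_len(n_ch), function(i) {
    ensembledyn:::.pink_noise(n, 40)
  }, numeric(n)))
  add_burst <- function(ch, t0, freq, amp, dur) {
    half <- round(dur * fs / 2)
    win <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = 2 * half + 1)))
    rel <- (-half):half
    idx <- round(t0 * fs) + rel
    samples[ch, idx] <<- samples[ch, idx] +
      amp * win * sin(2 * pi * freq * rel / fs)
  }
  if (!is.null(bursts)) {
    for (r in seq_len(nrow(bursts))) {
      for (ch in seq_len(n_ch)) {
        add_burst(ch, bursts$t0[r], bursts$freq[r], bursts$amp[r], bursts$dur[r])
      }
    }
  }
  if (!is.null(sw)) {
    for (r in seq_len(nrow(sw))) {
      half <- round(sw$dur[r] * fs / 2)
      win <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = 2 * half + 1)))
      idx <- round(sw$t0[r] * fs) + (-half):half
      samples[n_ch, idx] <- samples[n_ch, idx] + sw$amp[r] * win
    }
  }
  lfp_set(round(samples), fs,
          data.frame(region = region, shank = 1L, depth_order = 0:(n_ch - 1L)))
}

nrem_epochs <- function(total = 120) {
  epoch_set(c("w", "s"), c("WAKE", "NREM"), c(0, 10), c(10, total))
}

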