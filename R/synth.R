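#' @name synth
#' @title Synthetic datasets with planted ground truth
#'
#' @description
#' The generator emulates the statistical structure of a multi-region fear
#' conditioning / extinction recording at desk scale: three regions of tens of
#' units firing as inhomogeneous Poisson processes, a five-session behavioral
#' schedule with interleaved NREM-containing home-cage periods, low-dimensional
#' ensemble structure planted as 20 ms windows of elevated member firing,
#' cross-region coactivation at controlled lags, monosynaptically coupled unit
#' pairs (1-4 ms spike transmission), and LFP channels carrying pink noise plus
#' band-limited transients under a flat-topped (Tukey) envelope (ripples,
#' HFOs, cortical ripples, with sharp-wave deflections for SWRs). Every draw
#' is reproducible from the config seed.
NULL

#' Describe a planted ensemble
#'
#' @param region region the ensemble lives in.
#' @param members integer unit ids (global) elevated during ensemble events.
#' @param event_rate events per second within each active session.
#' @param active_sessions character labels of sessions during which the
#'   ensemble emits events.
#' @param rate_boost firing-rate increment (Hz) added to members inside each
#'   20 ms event window.
#' @param partner index (into the config's ensemble list) of an ensemble in
#'   another region that fires a coupled event at `partner_lag` after each of
#'   this ensemble's events, or NA.
#' @param partner_lag lag of coupled partner events, seconds.
#' @return A `planted_ensemble` list.
#' @export
planted_ensemble <- function(region, members, event_rate = 0.5,
                             active_sessions, rate_boost = 50,
                             partner = NA_integer_, partner_lag = 0.02) {
  stopifnot(event_rate > 0, rate_boost >= 0)
  structure(list(region = region, members = as.integer(members),
                 event_rate = event_rate, active_sessions = active_sessions,
                 rate_boost = rate_boost, partner = as.integer(partner),
                 partner_lag = partner_lag),
            class = "planted_ensemble")
}

#' Describe a planted fast oscillation train
#'
#' @param kind "SWR", "HFO" or "cRipple".
#' @param region target region (its channels receive the transient).
#' @param center_freq oscillation frequency, Hz.
#' @param amplitude transient amplitude in raw LFP units.
#' @param duration event duration, seconds.
#' @param rate event rate (per second of eligible state time) used to draw
#'   event centers when `times` is NULL.
#' @param times explicit event centers (seconds), or NULL to draw them.
#' @param couples_ensemble_events when TRUE, every planted ensemble of the same
#'   region fires one extra event at each oscillation center.
#' @return A `planted_oscillation` list.
#' @export
planted_oscillation <- function(kind, region, center_freq, amplitude,
                                duration, rate = 0.1, times = NULL,
                                couples_ensemble_events = FALSE) {
  kind <- match.arg(kind, c("SWR", "HFO", "cRipple"))
  structure(list(kind = kind, region = region, center_freq = center_freq,
                 amplitude = amplitude, duration = duration, rate = rate,
                 times = times,
                 couples_ensemble_events = couples_ensemble_events),
            class = "planted_oscillation")
}

#' Default desk-scale session plan
#'
#' Five behavioral sessions (baseline, conditioning, context retrieval,
#' cue retrieval/extinction, retention) separated by home-cage periods whose
#' bulk is NREM sleep, compressed to a total of about 1 h.
#'
#' @return data.frame with columns label, state, duration (seconds).
#' @export
default_session_plan <- function() {
  data.frame(
    label = c("baseline",
              "homecage_pre_conditioning", "homecage_pre_conditioning",
              "conditioning",
              "homecage_pre_extinction", "homecage_pre_extinction",
              "context_retrieval", "cue_retrieval", "extinction",
              "homecage_post_extinction", "homecage_post_extinction",
              "retention",
              "homecage_post_retention", "homecage_post_retention"),
    state = c("WAKE",
              "WAKE", "NREM",
              "WAKE",
              "WAKE", "NREM",
              "WAKE", "WAKE", "WAKE",
              "WAKE", "NREM",
              "WAKE",
              "WAKE", "NREM"),
    duration = c(240,
                 60, 540,
                 300,
                 60, 540,
                 60, 120, 300,
                 60, 540,
                 300,
                 60, 540),
    stringsAsFactors = FALSE)
}

#' Build a synthetic-data configuration
#'
#' Defaults emulate one subject of a fear-conditioning extinction experiment at desk scale: three regions
#' (vCA1, PL5, BLA) with 12-40 units each, 2 Hz background firing, planted
#' ensembles spanning the maintained / initiated / terminated / transient
#' dynamics, one cross-region coactivated pair, and the five-session schedule
#' of [default_session_plan()].
#'
#' @param seed integer RNG seed; all generator randomness derives from it.
#' @param regions named integer vector, units per region.
#' @param session_plan data.frame (label, state, duration) as in
#'   [default_session_plan()].
#' @param ensembles list of [planted_ensemble()], or NULL for the default set.
#' @param oscillations list of [planted_oscillation()] (may be empty).
#' @param monosynapses data.frame (pre_unit, post_unit, sign, transmission_prob,
#'   lag_ms) of planted monosynaptic couplings, or NULL.
#' @param base_rate background Poisson rate per unit, Hz.
#' @param lfp list of LFP geometry options: sample_rate (Hz),
#'   channels_per_shank, noise_sd (raw units).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         regions = c(vCA1 = 12L, PL5 = 40L, BLA = 24L),
                         session_plan = default_session_plan(),
                         ensembles = NULL,
                         oscillations = list(),
                         monosynapses = NULL,
                         base_rate = 2,
                         lfp = list(sample_rate = 1250, channels_per_shank = 4,
                                    noise_sd = 50)) {
  if (nrow(session_plan) == 0L) stop("session_plan must be non-empty")
  unit_region <- rep(names(regions), regions)
  first_unit <- c(1L, 1L + cumsum(regions))[seq_along(regions)]
  names(first_unit) <- names(regions)
  homecages <- grep("^homecage", unique(session_plan$label), value = TRUE)
  if (is.null(ensembles) &&
      !(all(c("vCA1", "PL5", "BLA") %in% names(regions)) &&
        all(c("conditioning", "extinction", "retention") %in% session_plan$label))) {
    ensembles <- list()   # defaults only fit the standard suite layout
  }
  if (is.null(ensembles)) {
    u <- function(region, k, m = 6L) {
      first_unit[[region]] + ((k - 1L) * m):((k * m) - 1L)
    }
    post_sleep <- intersect(c("homecage_post_extinction",
                              "homecage_post_retention"), homecages)
    all_sleep <- homecages
    ensembles <- list(
      # PL5: maintained (also the coactivated one), initiated, terminated
      planted_ensemble("PL5", u("PL5", 1),
                       active_sessions = c("conditioning", "extinction",
                                           "retention", all_sleep),
                       partner = 4L, partner_lag = 0.02),
      planted_ensemble("PL5", u("PL5", 2),
                       active_sessions = c("extinction", "retention", post_sleep)),
      planted_ensemble("PL5", u("PL5", 3),
                       active_sessions = c("conditioning", "extinction",
                                           "homecage_pre_extinction")),
      # BLA: maintained, transient
      planted_ensemble("BLA", u("BLA", 1),
                       active_sessions = c("conditioning", "extinction",
                                           "retention", all_sleep)),
      planted_ensemble("BLA", u("BLA", 2),
                       active_sessions = c("extinction", post_sleep)),
      # vCA1: initiated, transient
      planted_ensemble("vCA1", u("vCA1", 1),
                       active_sessions = c("extinction", "retention", post_sleep)),
      planted_ensemble("vCA1", u("vCA1", 2), members = u("vCA1", 1) + 6L,
                       active_sessions = "extinction"))
  }
  for (e in ensembles) {
    if (!e$region %in% names(regions)) stop("ensemble region not configured: ", e$region)
    if (!all(unit_region[e$members] == e$region)) {
      stop("ensemble member unit(s) outside region ", e$region)
    }
  }
  if (!is.null(monosynapses)) {
    stopifnot(all(c("pre_unit", "post_unit", "sign", "transmission_prob",
                    "lag_ms") %in% names(monosynapses)))
    if (any(monosynapses$transmission_prob <= 0 | monosynapses$transmission_prob > 1)) {
      stop("transmission_prob must be in (0, 1]")
    }
    if (any(monosynapses$lag_ms < 1 | monosynapses$lag_ms > 4)) {
      stop("monosynaptic lag must be within [1, 4] ms")
    }
  }
  structure(list(seed = as.integer(seed), regions = regions,
                 session_plan = session_plan, ensembles = ensembles,
                 oscillations = oscillations, monosynapses = monosynapses,
                 base_rate = base_rate, lfp = lfp,
                 unit_region = unit_region),
            class = "synth_config")
}

# Epoch table from the sequential session plan.
.plan_epochs <- function(plan) {
  ends <- cumsum(plan$duration)
  epoch_set(plan$label, plan$state, c(0, head(ends, -1L)), ends)
}

# Session-plan rows (with absolute bounds) matching a label set.
.plan_rows <- function(plan, labels) {
  ends <- cumsum(plan$duration)
  data.frame(label = plan$label, state = plan$state,
             start = c(0, head(ends, -1L)), end = ends)[plan$label %in% labels, ,
                                                        drop = FALSE]
}

# Resolve oscillation event centers deterministically from the config seed.
# Events are drawn within the eligible state (NREM for HFO/cRipple, NREM+WAKE
# for SWR; SWRs are planted in NREM home cages only, the sleep focus of the
# analyses), kept clear of epoch boundaries by duration/2 plus a margin, and
# separated from each other by >= 1 s.
.resolve_oscillation_times <- function(config) {
  plan <- config$session_plan
  ends <- cumsum(plan$duration)
  starts <- c(0, head(ends, -1L))
  out <- vector("list", length(config$oscillations))
  for (i in seq_along(config$oscillations)) {
    osc <- config$oscillations[[i]]
    if (!is.null(osc$times)) { out[[i]] <- sort(osc$times); next }
    set.seed(.substream_seed(config$seed, paste0("osc", i)))
    rows <- which(plan$state == "NREM")
    tt <- numeric(0)
    for (r in rows) {
      margin <- osc$duration / 2 + 0.25
      lo <- starts[r] + margin; hi <- ends[r] - margin
      if (hi <= lo) next
      n <- rpois(1L, osc$rate * (hi - lo))
      tt <- c(tt, sort(runif(n, lo, hi)))
    }
    if (length(tt) > 1L) tt <- tt[c(TRUE, diff(tt) >= 1)]
    out[[i]] <- tt
  }
  out
}

#' Generate spike trains with planted ensemble structure
#'
#' Background spikes are homogeneous Poisson at `base_rate`. Each planted
#' ensemble emits Poisson events within its active sessions; at each event the
#' member units receive `rate_boost` extra rate for one 20 ms window aligned to
#' the analysis bin grid. Partner ensembles fire coupled events at
#' `partner_lag`; oscillation-coupled ensembles fire one event per oscillation
#' center. Monosynaptic couplings inject (sign "+") or thin (sign "-") target
#' spikes 1-4 ms after source spikes.
#'
#' @param config a [synth_config()].
#' @return list with elements `dataset` (an `ensemble_dataset`) and `truth`
#'   (planted weight vectors, event times, oscillation times, cell classes,
#'   monosynapse plan).
#' @export
generate_spikes <- function(config) {
  plan <- config$session_plan
  epochs <- .plan_epochs(plan)
  total <- sum(plan$duration)
  n_units <- sum(config$regions)
  unit_region <- config$unit_region

  set.seed(.substream_seed(config$seed, "cells"))
  # ~15% narrow-waveform (putative inhibitory) units per region
  is_inh <- runif(n_units) < 0.15
  fwhm <- ifelse(is_inh, pmax(0.25, rnorm(n_units, 0.40, 0.03)),
                 rnorm(n_units, 0.80, 0.06))

  set.seed(.substream_seed(config$seed, "spikes"))
  spikes <- lapply(seq_len(n_units), function(i) {
    n <- rpois(1L, config$base_rate * total)
    sort(runif(n, 0, total))
  })

  # planted ensemble events (20 ms grid-aligned, clear of session bounds)
  ev_list <- vector("list", length(config$ensembles))
  for (k in seq_along(config$ensembles)) {
    e <- config$ensembles[[k]]
    rows <- .plan_rows(plan, e$active_sessions)
    tt <- numeric(0)
    for (r in seq_len(nrow(rows))) {
      lo <- rows$start[r] + 0.02; hi <- rows$end[r] - 0.04
      if (hi <= lo) next
      n <- rpois(1L, e$event_rate * (rows$end[r] - rows$start[r]))
      tt <- c(tt, runif(n, lo, hi))
    }
    ev_list[[k]] <- sort(unique(floor(tt / 0.02) * 0.02))
  }
  # partner-coupled events
  for (k in seq_along(config$ensembles)) {
    e <- config$ensembles[[k]]
    if (!is.na(e$partner)) {
      coupled <- floor((ev_list[[k]] + e$partner_lag) / 0.02) * 0.02
      ev_list[[e$partner]] <- sort(unique(c(ev_list[[e$partner]], coupled)))
    }
  }
  # oscillation-coupled events
  osc_times <- .resolve_oscillation_times(config)
  for (i in seq_along(config$oscillations)) {
    osc <- config$oscillations[[i]]
    if (!isTRUE(osc$couples_ensemble_events) || length(osc_times[[i]]) == 0L) next
    for (k in seq_along(config$ensembles)) {
      if (config$ensembles[[k]]$region != osc$region) next
      coupled <- floor(osc_times[[i]] / 0.02) * 0.02
      ev_list[[k]] <- sort(unique(c(ev_list[[k]], coupled)))
    }
  }
  # member spikes inside event windows
  for (k in seq_along(config$ensembles)) {
    e <- config$ensembles[[k]]
    for (u in e$members) {
      n_extra <- rpois(length(ev_list[[k]]), e$rate_boost * 0.02)
      if (sum(n_extra) == 0L) next
      extra <- rep(ev_list[[k]], n_extra) + runif(sum(n_extra), 0, 0.02)
      spikes[[u]] <- sort(c(spikes[[u]], extra))
    }
  }
  # monosynaptic couplings
  if (!is.null(config$monosynapses)) {
    ms <- config$monosynapses
    for (r in seq_len(nrow(ms))) {
      pre <- spikes[[ms$pre_unit[r]]]
      lag <- ms$lag_ms[r] / 1000
      if (ms$sign[r] == "+") {
        hit <- runif(length(pre)) < ms$transmission_prob[r]
        add <- pre[hit] + lag + runif(sum(hit), -4e-4, 4e-4)
        add <- add[add >= 0 & add < total]
        spikes[[ms$post_unit[r]]] <- sort(c(spikes[[ms$post_unit[r]]], add))
      } else {
        post <- spikes[[ms$post_unit[r]]]
        in_win <- .in_intervals(post, cbind(pre + lag - 7.5e-4, pre + lag + 7.5e-4))
        drop <- in_win & runif(length(post)) < ms$transmission_prob[r]
        spikes[[ms$post_unit[r]]] <- post[!drop]
      }
    }
  }

  # shank assignment: consecutive blocks of up to 8 units per region
  shank <- integer(n_units); sh <- 0L
  for (rg in names(config$regions)) {
    idx <- which(unit_region == rg)
    blocks <- ceiling(seq_along(idx) / 8)
    shank[idx] <- sh + blocks
    sh <- sh + max(blocks)
  }
  trains <- lapply(seq_len(n_units), function(i) {
    spike_train(i, unit_region[i], shank[i], spikes[[i]],
                waveform_fwhm = fwhm[i])
  })
  dataset <- new_dataset(paste0("synth-", config$seed), trains, epochs,
                         regions = names(config$regions))

  weights <- lapply(config$ensembles, function(e) {
    idx <- which(unit_region == e$region)
    w <- numeric(length(idx)); names(w) <- idx
    w[as.character(e$members)] <- 1
    w / sqrt(sum(w^2))
  })
  truth <- list(
    ensembles = config$ensembles,
    weights = weights,
    events = ev_list,
    oscillation_times = osc_times,
    cell_class = ifelse(is_inh, "inhibitory", "excitatory"),
    monosynapses = config$monosynapses)
  list(dataset = dataset, truth = truth)
}

# Tapered-cosine window: flat top, cosine ramps over alpha/2 of each side.
.tukey_window <- function(n, alpha = 0.2) {
  u <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- u < alpha / 2
  hi <- u > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * u[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - u[hi]) / alpha - 1)))
  w
}

# Pink (1/f amplitude) noise of length n with SD ~= sd, via spectral shaping.
.pink_noise <- function(n, sd) {
  white <- rnorm(n)
  sp <- fft(white)
  f <- c(1, seq_len(n - 1L))            # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)               # fold to two-sided frequency index
  sp <- sp / sqrt(f)
  x <- Re(fft(sp, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}

#' Generate LFP with planted fast-oscillation transients
#'
#' Each channel carries independent pink noise. Each planted oscillation adds
#' a sinusoid at its center frequency, under a flat-topped Tukey envelope, to
#' every channel of the target region; SWR events additionally add a
#' low-frequency (sharp-wave)
#' deflection to the deepest channel of the shank so that the superficial-
#' minus-deep difference swings negative, as the SWR detector requires.
#'
#' @param config a [synth_config()].
#' @return list with `lfp` (an `lfp_set`) and `truth` (per-oscillation event
#'   centers).
#' @export
generate_lfp <- function(config) {
  fs <- config$lfp$sample_rate
  if (fs < 1000) stop("sample_rate must be >= 1000 Hz")
  cps <- config$lfp$channels_per_shank
  if (cps < 2L) stop("need >= 2 channels per shank for sharp-wave differences")
  total <- sum(config$session_plan$duration)
  n_samp <- round(total * fs)
  regions <- names(config$regions)
  meta <- do.call(rbind, lapply(seq_along(regions), function(i) {
    data.frame(region = regions[i], shank = i, depth_order = 0:(cps - 1L))
  }))
  set.seed(.substream_seed(config$seed, "lfp"))
  samples <- t(vapply(seq_len(nrow(meta)),
                      function(i) .pink_noise(n_samp, config$lfp$noise_sd),
                      numeric(n_samp)))
  osc_times <- .resolve_oscillation_times(config)
  tvec_cache <- NULL
  for (i in seq_along(config$oscillations)) {
    osc <- config$oscillations[[i]]
    ch <- which(meta$region == osc$region)
    if (length(ch) == 0L) stop("no LFP channels for region ", osc$region)
    half <- round(osc$duration * fs / 2)
    if (half < 1L) next
    # Tukey (tapered-cosine) envelope: the flat top keeps the band power above
    # the detectors' entry thresholds for nearly the whole planted duration,
    # so planted durations correspond to measured event durations.
    win <- .tukey_window(2L * half + 1L, alpha = 0.2)
    rel <- (-half):half
    carrier <- osc$amplitude * win * sin(2 * pi * osc$center_freq * rel / fs)
    deep <- ch[which.max(meta$depth_order[ch])]
    sw_half <- round(max(0.08, osc$duration) * fs / 2)
    sw_win <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = 2L * sw_half + 1L)))
    for (t0 in osc_times[[i]]) {
      c0 <- round(t0 * fs)
      idx <- c0 + rel
      ok <- idx >= 1L & idx <= n_samp
      for (cc in ch) samples[cc, idx[ok]] <- samples[cc, idx[ok]] + carrier[ok]
      if (osc$kind == "SWR") {
        idx2 <- c0 + ((-sw_half):sw_half)
        ok2 <- idx2 >= 1L & idx2 <= n_samp
        # positive bump on the deepest channel -> (superficial - deep) < 0
        samples[deep, idx2[ok2]] <- samples[deep, idx2[ok2]] +
          2 * osc$amplitude * sw_win[ok2]
      }
    }
  }
  samples <- round(pmin(pmax(samples, -32767), 32767))
  list(lfp = lfp_set(samples, fs, meta, scale = 0.195),
       truth = osc_times)
}

#' Generate a complete synthetic session suite
#'
#' Runs [generate_spikes()] and, when the config plants oscillations,
#' [generate_lfp()], returning a single Dataset whose planted ensembles can
#' differ by session so that downstream tracking sees maintained / initiated /
#' terminated / transient dynamics.
#'
#' @param config a [synth_config()].
#' @param with_lfp force LFP generation on/off; default generates LFP only
#'   when oscillations are planted.
#' @return list with `dataset` and `truth`.
#' @export
generate_session_suite <- function(config, with_lfp = length(config$oscillations) > 0) {
  out <- generate_spikes(config)
  if (with_lfp) {
    l <- generate_lfp(config)
    out$dataset$lfp <- l$lfp
  }
  out
}
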