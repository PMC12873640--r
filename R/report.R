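#' @name report
#' @title End-to-end pipeline orchestration
#'
#' @description
#' [run_pipeline()] composes the full analysis on one Dataset: per-region
#' ensemble extraction for the conditioning / extinction / retention
#' templates, cross-session similarity and dynamic categories, activation
#' events and their rates per home-cage NREM epoch, inter-regional
#' coactivation in the pre- and post-extinction home cages with pair turnover,
#' the preserved-by-coactivated contingency, and (when LFP is present)
#' oscillation detection with activation-rate gains. All thresholds are echoed
#' into the report for provenance and the run is deterministic under the
#' config seed.
NULL

#' Pipeline configuration
#'
#' @param seed master seed for ICA, similarity nulls, and shuffles.
#' @param templates named list of epoch labels for the conditioning,
#'   extinction, and retention template sessions.
#' @param pre_label,post_label home-cage epoch labels flanking extinction.
#' @param homecage_labels labels of home-cage sessions for activation-rate
#'   tables; defaults to all labels containing NREM epochs.
#' @param n_shuffles chunk shuffles per coactivation pair.
#' @param n_null_pairs null draws for the similarity threshold.
#' @param activation_threshold activation-event threshold, z.
#' @param coactivation_threshold coactivation-event threshold, z^2.
#' @param region_roles named character: which region hosts each oscillation
#'   detector.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            templates = list(conditioning = "conditioning",
                                             extinction = "extinction",
                                             retention = "retention"),
                            pre_label = "homecage_pre_extinction",
                            post_label = "homecage_post_extinction",
                            homecage_labels = NULL,
                            n_shuffles = 500L,
                            n_null_pairs = 5000L,
                            activation_threshold = 5,
                            coactivation_threshold = 25,
                            region_roles = c(SWR = "vCA1", HFO = "BLA",
                                             cRipple = "PL5")) {
  structure(list(seed = as.integer(seed), templates = templates,
                 pre_label = pre_label, post_label = post_label,
                 homecage_labels = homecage_labels,
                 n_shuffles = as.integer(n_shuffles),
                 n_null_pairs = as.integer(n_null_pairs),
                 activation_threshold = activation_threshold,
                 coactivation_threshold = coactivation_threshold,
                 region_roles = region_roles),
            class = "pipeline_config")
}

#' Run the full ensemble-dynamics pipeline
#'
#' @param dataset an `ensemble_dataset`.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory: writes `report.json`, `dynamics.csv`,
#'   `coactivation_pre.csv`, `coactivation_post.csv`,
#'   `activation_events.csv`, and per-kind oscillation event CSVs.
#' @return list of class `pipeline_report`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config(), out_dir = NULL) {
  regs <- vapply(dataset$spikes, `[[`, "", "region")
  regions <- dataset$regions[table(regs)[dataset$regions] >= 2L]
  tlabs <- config$templates
  seed <- config$seed

  # --- ensembles per region x template --------------------------------------
  sets <- list()
  for (rg in regions) {
    sets[[rg]] <- lapply(tlabs, function(lb) {
      z <- bin_and_zscore(dataset, rg, lb)
      suppressWarnings(extract_ensembles(z, seed = .substream_seed(seed, paste0("ica-", rg, lb))))
    })
  }
  ensemble_counts <- do.call(rbind, lapply(regions, function(rg) {
    data.frame(region = rg,
               conditioning = sets[[rg]]$conditioning$n_significant,
               extinction = sets[[rg]]$extinction$n_significant,
               retention = sets[[rg]]$retention$n_significant)
  }))

  # --- similarity thresholds and dynamic categories -------------------------
  dynamics <- list(); thresholds <- c()
  for (rg in regions) {
    s <- sets[[rg]]
    if (s$extinction$n_significant == 0L) next
    if (sum(vapply(s, `[[`, 0L, "n_significant")) < 2L) next  # no usable null pool
    thr <- similarity_threshold(s, n_pairs = config$n_null_pairs,
                                seed = .substream_seed(seed, paste0("sim-", rg)))
    thresholds[rg] <- thr
    dyn <- classify_dynamics(s$extinction, s$conditioning, s$retention, thr)
    dyn$region <- rg
    dynamics[[rg]] <- dyn
  }
  dynamics <- do.call(rbind, dynamics)
  cat_levels <- c("maintained", "initiated", "terminated", "transient")
  category_fractions <- do.call(rbind, lapply(regions, function(rg) {
    d <- dynamics[dynamics$region == rg, , drop = FALSE]
    if (is.null(d) || nrow(d) == 0L) return(NULL)
    data.frame(region = rg, category = cat_levels,
               count = as.integer(table(factor(d$category, cat_levels))),
               n = nrow(d))
  }))

  # --- activation traces, events, per-epoch rates ---------------------------
  traces <- list(); events <- list()
  for (rg in regions) {
    if (sets[[rg]]$extinction$n_significant == 0L) next
    tr <- activation_strength(sets[[rg]]$extinction, dataset)
    traces[[rg]] <- tr
    ev <- detect_activation_events(tr, config$activation_threshold)
    if (!is.null(ev) && nrow(ev)) ev$region <- rg
    events[[rg]] <- ev
  }
  hc_labels <- config$homecage_labels
  if (is.null(hc_labels)) {
    hc_labels <- unique(dataset$epochs$label[dataset$epochs$state == "NREM"])
  }
  activation_rates <- do.call(rbind, lapply(names(events), function(rg) {
    ev <- events[[rg]]
    if (is.null(ev) || nrow(ev) == 0L) return(NULL)
    do.call(rbind, lapply(hc_labels, function(lb) {
      iv <- .state_intervals(dataset$epochs, "NREM", labels = lb)
      dur <- sum(iv[, 2L] - iv[, 1L])
      if (dur <= 0) return(NULL)
      cnt <- vapply(split(ev$time_s, ev$ensemble),
                    function(tt) sum(.in_intervals(tt, iv)), 0)
      data.frame(region = rg, epoch = lb,
                 ensemble = as.integer(names(cnt)),
                 rate_hz = unname(cnt) / dur)
    }))
  }))

  # --- inter-regional coactivation, pre vs post -----------------------------
  coact_pre <- coact_post <- NULL
  turnover <- NULL
  coact_fraction <- list()
  if (length(traces) >= 2L) {
    coact_pre <- detect_coactivated_pairs(
      traces, dataset, nrem_labels = config$pre_label,
      n_shuffles = config$n_shuffles, seed = .substream_seed(seed, "pre"))
    coact_post <- detect_coactivated_pairs(
      traces, dataset, nrem_labels = config$post_label,
      n_shuffles = config$n_shuffles, seed = .substream_seed(seed, "post"))
    coact_fraction <- list(
      pre = coactivation_fraction_stats(coact_pre$significant),
      post = coactivation_fraction_stats(coact_post$significant))
    turnover <- pair_turnover(coact_pre, coact_post)
  }

  # --- preserved x coactivated contingency (post-extinction) ----------------
  preserved_by_coactivation <- NULL
  if (!is.null(coact_post) && !is.null(dynamics) && nrow(dynamics)) {
    coact_ens <- unique(c(
      paste(coact_post$region_a, coact_post$ens_a)[coact_post$significant],
      paste(coact_post$region_b, coact_post$ens_b)[coact_post$significant]))
    dynamics$coactivated <- paste(dynamics$region, dynamics$ensemble) %in% coact_ens
    tab <- rbind(
      c(sum(dynamics$coactivated & dynamics$preserved),
        sum(dynamics$coactivated & !dynamics$preserved)),
      c(sum(!dynamics$coactivated & dynamics$preserved),
        sum(!dynamics$coactivated & !dynamics$preserved)))
    fish <- fisher_exact_2x2(tab)
    preserved_by_coactivation <- list(table = tab, odds_ratio = fish$odds_ratio,
                                      p = fish$p)
  }

  # --- oscillations and gains ----------------------------------------------
  oscillations <- NULL; gains <- NULL; gain_tests <- NULL
  if (!is.null(dataset$lfp)) {
    roles <- config$region_roles
    detect <- list(SWR = detect_swr, HFO = detect_hfo, cRipple = detect_cripples)
    oscillations <- list()
    for (kind in names(roles)) {
      if (!roles[[kind]] %in% dataset$lfp$channel_meta$region) next
      oscillations[[kind]] <- detect[[kind]](dataset$lfp, dataset$epochs,
                                             region = roles[[kind]])
    }
    gains <- do.call(rbind, lapply(names(events), function(rg) {
      ev <- events[[rg]]
      if (is.null(ev) || nrow(ev) == 0L) return(NULL)
      do.call(rbind, lapply(names(oscillations), function(kind) {
        osc <- oscillations[[kind]]
        if (nrow(osc) == 0L) return(NULL)
        do.call(rbind, lapply(sort(unique(ev$ensemble)), function(en) {
          mod <- oscillation_modulation(ev$time_s[ev$ensemble == en], osc,
                                        dataset$epochs)
          data.frame(region = rg, ensemble = en, kind = kind, gain = mod$gain)
        }))
      }))
    }))
    if (!is.null(gains) && !is.null(dynamics) && nrow(dynamics) &&
        "coactivated" %in% names(dynamics)) {
      # coactivated-preserved vs the rest, per oscillation kind
      grp_of <- function(rg_ens) {
        i <- match(rg_ens, paste(dynamics$region, dynamics$ensemble))
        ifelse(dynamics$coactivated[i] & dynamics$preserved[i],
               "coactivated_preserved", "other")
      }
      gains$group <- grp_of(paste(gains$region, gains$ensemble))
      gain_tests <- do.call(rbind, lapply(unique(gains$kind), function(kind) {
        g <- gains[gains$kind == kind & is.finite(gains$gain), , drop = FALSE]
        a <- g$gain[g$group == "coactivated_preserved"]
        b <- g$gain[g$group == "other"]
        if (length(a) < 2L || length(b) < 2L) return(NULL)
        mw <- mann_whitney_u(a, b)
        data.frame(kind = kind, U = mw$statistic, p = mw$p,
                   n_a = length(a), n_b = length(b))
      }))
      if (!is.null(gain_tests) && nrow(gain_tests)) {
        gain_tests$p_adj <- adjust_bonferroni(gain_tests$p, nrow(gain_tests))
      }
    }
  }

  report <- structure(list(
    schema_version = "1.0",
    subject_id = dataset$subject_id,
    params = unclass(config),
    ensemble_counts = ensemble_counts,
    similarity_thresholds = as.list(thresholds),
    dynamics = dynamics,
    category_fractions = category_fractions,
    activation_rates = activation_rates,
    coactivation = list(pre = coact_pre, post = coact_post,
                        fraction = coact_fraction),
    turnover = if (!is.null(turnover)) {
      list(pairs = turnover, fractions = as.list(attr(turnover, "fractions")))
    },
    preserved_by_coactivation = preserved_by_coactivation,
    oscillation_counts = if (!is.null(oscillations)) {
      lapply(oscillations, nrow)
    },
    gains = gains,
    gain_tests = gain_tests),
    class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(.report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(dynamics)) {
      write.csv(dynamics, file.path(out_dir, "dynamics.csv"), row.names = FALSE)
    }
    if (!is.null(coact_pre)) {
      write.csv(coact_pre, file.path(out_dir, "coactivation_pre.csv"),
                row.names = FALSE)
      write.csv(coact_post, file.path(out_dir, "coactivation_post.csv"),
                row.names = FALSE)
    }
    all_ev <- do.call(rbind, events)
    if (!is.null(all_ev)) {
      write.csv(all_ev, file.path(out_dir, "activation_events.csv"),
                row.names = FALSE)
    }
    if (!is.null(oscillations)) {
      for (kind in names(oscillations)) {
        write.csv(as.data.frame(oscillations[[kind]]),
                  file.path(out_dir, paste0("events_", tolower(kind), ".csv")),
                  row.names = FALSE)
      }
    }
  }
  report
}

# Strip S3 classes so jsonlite serializes plainly and reproducibly.
.report_to_json <- function(report) {
  strip <- function(x) {
    if (is.data.frame(x)) return(as.data.frame(lapply(unclass(x), strip)))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  strip(unclass(report))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report for", x$subject_id, "\n")
  print(x$ensemble_counts)
  if (!is.null(x$category_fractions)) {
    cat("dynamic categories:\n"); print(x$category_fractions)
  }
  if (length(x$coactivation$fraction)) {
    cat(sprintf("coactivated pair fraction: pre %.3f, post %.3f\n",
                x$coactivation$fraction$pre$fraction,
                x$coactivation$fraction$post$fraction))
  }
  invisible(x)
}
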