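#' @name ensembles
#' @title ICA ensemble extraction and activation
#'
#' @description
#' Ensembles are detected per region and per template session. Unit firing is
#' binned at 20 ms over the template epoch and z-scored within unit; the
#' number of significant co-activity components is the number of eigenvalues
#' of the unit correlation matrix above the Marchenko-Pastur upper edge
#' `(1 + sqrt(n_units / n_bins))^2`; ICA (deflation fixed-point, log-cosh
#' contrast) rotates the principal subspace into that many projection vectors,
#' each normalized to unit length with its largest-magnitude element positive.
#' Significantly contributing units have within-vector z-scored weights > 2.
#' The instantaneous activation strength of an ensemble in any 20 ms bin with
#' z-scored population rate vector M is the quadratic form `M' P M` with
#' `P = w w'` and zeroed diagonal (so a single active unit contributes
#' nothing); it is expressed in z units relative to its NREM mean and SD, and
#' activation events are strict local maxima above 5 z.
NULL

.BIN <- 0.02

#' Bin and z-score unit firing over a template epoch
#'
#' @param dataset an `ensemble_dataset`.
#' @param region region label.
#' @param template_label epoch label(s) defining the template session.
#' @param bin_size bin width in seconds.
#' @return list of class `binned_rate_matrix`: `z` (units x bins), `unit_ids`,
#'   `bin_centers` (absolute time), `region`, `template_label`, `bin_size`.
#'   Units with zero template variance get an all-zero row.
#' @export
bin_and_zscore <- function(dataset, region, template_label, bin_size = .BIN) {
  regs <- vapply(dataset$spikes, `[[`, "", "region")
  units <- dataset$spikes[regs == region]
  if (length(units) < 2L) stop("need >= 2 units in region ", region)
  rows <- dataset$epochs[dataset$epochs$label %in% template_label, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no epochs labeled ", paste(template_label, collapse = "/"))
  counts_edges <- lapply(seq_len(nrow(rows)), function(i) {
    n <- floor((rows$end[i] - rows$start[i]) / bin_size)
    rows$start[i] + (0:n) * bin_size
  })
  centers <- unlist(lapply(counts_edges, function(e) head(e, -1L) + bin_size / 2))
  counts <- t(vapply(units, function(u) {
    unlist(lapply(counts_edges, function(e) {
      if (length(e) < 2L) return(numeric(0))
      idx <- findInterval(u$times, e)
      tabulate(idx[idx >= 1L & idx < length(e)], nbins = length(e) - 1L)
    }))
  }, numeric(length(centers))))
  z <- .zscore_rows(counts)
  structure(list(z = z, unit_ids = vapply(units, `[[`, 1L, "unit_id"),
                 bin_centers = centers, region = region,
                 template_label = template_label, bin_size = bin_size),
            class = "binned_rate_matrix")
}

# Row-wise z-score; zero-variance rows become all zero.
.zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' Number of significant co-activity components
#'
#' Counts eigenvalues of the unit-by-unit correlation matrix above the
#' Marchenko-Pastur upper edge `(1 + sqrt(n_units / n_bins))^2`, the expected
#' largest eigenvalue for an uncorrelated population.
#'
#' @param z a `binned_rate_matrix` (or bare units x bins z-scored matrix).
#' @return integer count.
#' @export
count_significant_components <- function(z) {
  zm <- if (inherits(z, "binned_rate_matrix")) z$z else z
  n_units <- nrow(zm); n_bins <- ncol(zm)
  live <- apply(zm, 1L, function(r) any(r != 0))
  if (!any(live)) stop("all units have zero template variance")
  if (n_bins <= n_units) {
    warning("fewer template bins than units; Marchenko-Pastur edge unreliable")
  }
  cm <- tcrossprod(zm) / (n_bins - 1L)
  ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  lambda_max <- (1 + sqrt(n_units / n_bins))^2
  sum(ev > lambda_max)
}

# Deflation fixed-point ICA with log-cosh contrast on whitened data.
# x_white: k x B with identity covariance. Returns k x k orthogonal unmixing
# matrix (rows are components).
.fixed_point_ica <- function(x_white, tol = 1e-6, max_iter = 1000L, seed = 1L) {
  k <- nrow(x_white); B <- ncol(x_white)
  set.seed(seed)
  W <- matrix(0, k, k)
  for (comp in seq_len(k)) {
    w <- rnorm(k); w <- w / sqrt(sum(w^2))
    for (it in seq_len(max_iter)) {
      wx <- drop(crossprod(w, x_white))          # 1 x B
      g <- tanh(wx)
      gp <- 1 - g^2
      w_new <- (x_white %*% g) / B - mean(gp) * w
      if (comp > 1L) {
        proj <- W[seq_len(comp - 1L), , drop = FALSE]
        w_new <- w_new - t(proj) %*% (proj %*% w_new)
      }
      w_new <- w_new / sqrt(sum(w_new^2))
      conv <- abs(abs(sum(w_new * w)) - 1) < tol
      w <- drop(w_new)
      if (conv) break
    }
    W[comp, ] <- w
  }
  W
}

#' Extract ensembles by ICA over the significant subspace
#'
#' @param z a `binned_rate_matrix`.
#' @param n_components number of components; defaults to
#'   [count_significant_components()].
#' @param seed ICA initialization seed.
#' @return list of class `ensemble_set`: `projections` (units x k matrix of
#'   unit-norm columns, largest-|.| element positive), `contributors` (units x
#'   k logical, within-vector z-scored weight > 2), `n_significant`,
#'   `unit_ids`, `region`, `template_label`. Zero components give empty
#'   matrices with a warning.
#' @export
extract_ensembles <- function(z, n_components = NULL, seed = 1L) {
  stopifnot(inherits(z, "binned_rate_matrix"))
  if (is.null(n_components)) n_components <- count_significant_components(z)
  n_units <- nrow(z$z); n_bins <- ncol(z$z)
  if (n_components == 0L) {
    warning("no significant components; returning empty ensemble set")
    return(structure(list(projections = matrix(0, n_units, 0L),
                          contributors = matrix(FALSE, n_units, 0L),
                          n_significant = 0L, unit_ids = z$unit_ids,
                          region = z$region, template_label = z$template_label),
                     class = "ensemble_set"))
  }
  cm <- tcrossprod(z$z) / (n_bins - 1L)
  eg <- eigen(cm, symmetric = TRUE)
  E <- eg$vectors[, seq_len(n_components), drop = FALSE]
  lam <- eg$values[seq_len(n_components)]
  x_white <- diag(1 / sqrt(lam), n_components) %*% t(E) %*% z$z
  W <- .fixed_point_ica(x_white, seed = seed)
  # back-project: mixing columns in unit space are E diag(sqrt(lam)) W'
  proj <- E %*% diag(sqrt(lam), n_components) %*% t(W)
  proj <- apply(proj, 2L, function(w) {
    w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) -w else w
  })
  proj <- matrix(proj, nrow = n_units)
  contrib <- apply(proj, 2L, function(w) (w - mean(w)) / sd(w) > 2.0)
  contrib <- matrix(contrib, nrow = n_units)
  structure(list(projections = proj, contributors = contrib,
                 n_significant = as.integer(n_components),
                 unit_ids = z$unit_ids, region = z$region,
                 template_label = z$template_label),
            class = "ensemble_set")
}

# Bin the whole recording for one region; z-score per unit over all bins.
.whole_recording_z <- function(dataset, region, bin_size = .BIN) {
  regs <- vapply(dataset$spikes, `[[`, "", "region")
  units <- dataset$spikes[regs == region]
  total <- max(dataset$epochs$end)
  n_bins <- floor(total / bin_size)
  edges <- (0:n_bins) * bin_size
  counts <- t(vapply(units, function(u) {
    idx <- findInterval(u$times, edges)
    tabulate(idx[idx >= 1L & idx <= n_bins], nbins = n_bins)
  }, numeric(n_bins)))
  list(z = .zscore_rows(counts),
       unit_ids = vapply(units, `[[`, 1L, "unit_id"),
       bin_size = bin_size, n_bins = n_bins)
}

#' Instantaneous activation strength of ensembles over the whole recording
#'
#' Computes `M' P M` per 20 ms bin for each projection vector (P = w w' with
#' zero diagonal, M the z-scored population rate vector), then z-scores each
#' ensemble's trace by its NREM mean and SD. Per-unit z-scoring of the matched
#' bins uses whole-recording statistics so strengths are comparable across
#' sessions; set `zscore_with = "template"` to reuse template statistics
#' instead.
#'
#' @param ensembles an `ensemble_set`.
#' @param dataset the `ensemble_dataset` it came from.
#' @param zscore_with "recording" (default) or "template".
#' @param nrem_labels optional epoch-label subset defining the NREM z-basis;
#'   default all NREM epochs.
#' @return list of class `activation_trace`: `strength_z` (ensembles x bins),
#'   `raw` (same shape), `bin_size`, `nrem_mask`, `zscore_basis` (mean, sd per
#'   ensemble), `region`, `template_label`.
#' @export
activation_strength <- function(ensembles, dataset,
                                zscore_with = c("recording", "template"),
                                nrem_labels = NULL) {
  zscore_with <- match.arg(zscore_with)
  wr <- .whole_recording_z(dataset, ensembles$region)
  stopifnot(identical(wr$unit_ids, ensembles$unit_ids))
  Z <- wr$z
  if (zscore_with == "template") {
    # whole-recording counts, z-scored with template-bin mean/sd per unit
    regs <- vapply(dataset$spikes, `[[`, "", "region")
    units <- dataset$spikes[regs == ensembles$region]
    edges <- (0:wr$n_bins) * wr$bin_size
    counts <- t(vapply(units, function(u) {
      idx <- findInterval(u$times, edges)
      tabulate(idx[idx >= 1L & idx <= wr$n_bins], nbins = wr$n_bins)
    }, numeric(wr$n_bins)))
    trows <- dataset$epochs[dataset$epochs$label %in% ensembles$template_label, ]
    tmask <- rep(FALSE, wr$n_bins)
    centers <- (seq_len(wr$n_bins) - 0.5) * wr$bin_size
    for (i in seq_len(nrow(trows))) {
      tmask <- tmask | (centers >= trows$start[i] & centers < trows$end[i])
    }
    mu <- rowMeans(counts[, tmask, drop = FALSE])
    s <- apply(counts[, tmask, drop = FALSE], 1L, sd)
    Z <- (counts - mu) / ifelse(s > 0, s, 1)
    Z[s == 0, ] <- 0
  }
  nrem_rows <- dataset$epochs$state == "NREM"
  if (!is.null(nrem_labels)) {
    nrem_rows <- nrem_rows & dataset$epochs$label %in% nrem_labels
  }
  nrem_eps <- dataset$epochs[nrem_rows, , drop = FALSE]
  if (nrow(nrem_eps) == 0L) stop("no NREM epochs: activation z-basis undefined")
  nrem_mask <- epoch_mask(epoch_set(nrem_eps$label, nrem_eps$state,
                                    nrem_eps$start, nrem_eps$end),
                          "NREM", wr$bin_size, wr$n_bins)
  k <- ncol(ensembles$projections)
  raw <- matrix(0, k, wr$n_bins)
  for (j in seq_len(k)) {
    w <- ensembles$projections[, j]
    p <- drop(crossprod(w, Z))
    raw[j, ] <- p^2 - colSums((w^2) * Z^2)
  }
  mu <- rowMeans(raw[, nrem_mask, drop = FALSE])
  s <- apply(raw[, nrem_mask, drop = FALSE], 1L, sd)
  strength_z <- (raw - mu) / ifelse(s > 0, s, 1)
  structure(list(strength_z = strength_z, raw = raw, bin_size = wr$bin_size,
                 nrem_mask = nrem_mask, zscore_basis = cbind(mean = mu, sd = s),
                 region = ensembles$region,
                 template_label = ensembles$template_label),
            class = "activation_trace")
}

#' Detect ensemble activation events
#'
#' Events are strict local maxima of the z-scored activation strength above
#' the threshold; a plateau counts once, at its first bin.
#'
#' @param trace an `activation_trace`.
#' @param threshold event threshold in z units (field convention 5).
#' @return data.frame (ensemble, time_s, height_z), time at the bin center.
#' @export
detect_activation_events <- function(trace, threshold = 5) {
  stopifnot(threshold > 0)
  out <- lapply(seq_len(nrow(trace$strength_z)), function(j) {
    x <- trace$strength_z[j, ]
    idx <- .peak_indices(x, threshold)
    data.frame(ensemble = rep(j, length(idx)),
               time_s = (idx - 0.5) * trace$bin_size,
               height_z = x[idx])
  })
  do.call(rbind, out)
}

#' Coefficient of variation of inter-event intervals within a state
#'
#' Successive intervals between events are computed within epochs of the
#' requested state; intervals spanning an epoch gap are excluded.
#'
#' @param events numeric event times (seconds).
#' @param epochs an [epoch_set()].
#' @param state state label restricting the events.
#' @return CV (SD / mean of intervals), or NA when fewer than 3 events fall in
#'   the state.
#' @export
interevent_cv <- function(events, epochs, state = "NREM") {
  iv <- .state_intervals(epochs, state)
  events <- sort(events[.in_intervals(events, iv)])
  if (length(events) < 3L) return(NA_real_)
  ep_of <- findInterval(events, as.vector(t(iv)))  # odd index -> epoch number
  same <- diff(ep_of) == 0
  intervals <- diff(events)[same]
  if (length(intervals) < 2L) return(NA_real_)
  sd(intervals) / mean(intervals)
}
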