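#' @name io
#' @title On-disk formats and the Dataset container
#'
#' @description
#' A `Dataset` bundles everything one subject contributes to the analysis:
#' spike trains per unit (with region and shank provenance), labeled behavioral
#' / sleep-state epochs, and optionally multi-channel LFP. On disk the formats
#' are deliberately plain: `spikes.csv` (unit_id, region, shank, time_s, and
#' optional waveform_fwhm_ms / cell_class columns), `epochs.csv`
#' (label, state, start_s, end_s), and `lfp.dat` (little-endian int16,
#' channel-interleaved frames) with a JSON sidecar `lfp.json` declaring
#' sample_rate, n_channels, dtype, scale and per-channel metadata.
#'
#' Conventions: all times are seconds; epochs are half-open `[start, end)`;
#' a time bin belongs to a state when its center falls inside an epoch of that
#' state; duplicate spike times within a unit are collapsed.
NULL

.STATES <- c("NREM", "WAKE", "REM", "NA")

#' Construct a spike train for one unit
#'
#' Times are sorted and exact duplicates dropped.
#'
#' @param unit_id integer unit label, unique within a dataset.
#' @param region character region label (e.g. "vCA1", "PL5", "BLA").
#' @param shank integer shank index the unit was recorded on.
#' @param times numeric spike times in seconds.
#' @param waveform_fwhm spike waveform full-width at half-maximum in ms, or NA.
#' @param cell_class "excitatory", "inhibitory", "non_classified", or NA.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(unit_id, region, shank, times,
                        waveform_fwhm = NA_real_, cell_class = NA_character_) {
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times))) stop("spike times must be finite")
  if (any(times < 0)) stop("spike times must be non-negative")
  times <- sort(unique(times))
  if (!is.na(waveform_fwhm) && waveform_fwhm <= 0) {
    stop("waveform_fwhm must be positive when present")
  }
  if (!is.na(cell_class) &&
      !cell_class %in% c("excitatory", "inhibitory", "non_classified")) {
    stop("unknown cell_class: ", cell_class)
  }
  structure(
    list(unit_id = as.integer(unit_id), region = as.character(region),
         shank = as.integer(shank), times = times,
         waveform_fwhm = as.numeric(waveform_fwhm),
         cell_class = as.character(cell_class)),
    class = "spike_train")
}

#' Construct a validated epoch table
#'
#' @param label character epoch labels (session names).
#' @param state one of "NREM", "WAKE", "REM", "NA" per row.
#' @param start,end epoch bounds in seconds, half-open `[start, end)`.
#' @return A `data.frame` of class `epoch_set`.
#' @export
epoch_set <- function(label, state, start, end) {
  state <- as.character(state)
  state[is.na(state)] <- "NA"
  if (!all(state %in% .STATES)) {
    stop("unknown state label(s): ", paste(setdiff(state, .STATES), collapse = ", "))
  }
  start <- as.numeric(start); end <- as.numeric(end)
  if (anyNA(start) || anyNA(end) || any(!is.finite(c(start, end)))) {
    stop("epoch bounds must be finite")
  }
  if (any(start >= end)) stop("every epoch must satisfy start < end")
  ep <- data.frame(label = as.character(label), state = state,
                   start = start, end = end, stringsAsFactors = FALSE)
  for (s in unique(state)) {
    rows <- ep[ep$state == s, , drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    if (nrow(rows) > 1L && any(rows$start[-1L] < rows$end[-nrow(rows)])) {
      stop("overlapping epochs with the same state: ", s)
    }
  }
  class(ep) <- c("epoch_set", "data.frame")
  ep
}

#' Construct a multi-channel LFP container
#'
#' @param samples numeric or integer matrix, channels x time.
#' @param sample_rate sampling rate in Hz (>= 1000).
#' @param channel_meta data.frame with one row per channel: `region`, `shank`,
#'   `depth_order` (integer, 0 = most superficial, unique within a shank).
#' @param scale multiplicative factor from stored int16 units to microvolts;
#'   carried for provenance only, detection is scale-invariant.
#' @return An object of class `lfp_set`.
#' @export
lfp_set <- function(samples, sample_rate, channel_meta, scale = 1) {
  samples <- as.matrix(samples)
  if (sample_rate < 1000) stop("sample_rate must be >= 1000 Hz")
  if (nrow(channel_meta) != nrow(samples)) {
    stop("channel_meta must have one row per channel")
  }
  stopifnot(all(c("region", "shank", "depth_order") %in% names(channel_meta)))
  for (sh in unique(channel_meta$shank)) {
    d <- channel_meta$depth_order[channel_meta$shank == sh]
    if (anyDuplicated(d)) stop("depth_order must be unique within a shank")
  }
  structure(list(samples = samples, sample_rate = as.numeric(sample_rate),
                 channel_meta = as.data.frame(channel_meta), scale = scale),
            class = "lfp_set")
}

#' Assemble a Dataset
#'
#' @param subject_id character subject label.
#' @param spikes list of [spike_train()] objects.
#' @param epochs an [epoch_set()].
#' @param lfp an [lfp_set()] or NULL.
#' @param regions optional character vector of allowed region labels; defaults
#'   to the regions present in `spikes`.
#' @return An object of class `ensemble_dataset`.
#' @export
new_dataset <- function(subject_id, spikes, epochs, lfp = NULL, regions = NULL) {
  stopifnot(is.list(spikes), all(vapply(spikes, inherits, TRUE, "spike_train")))
  ids <- vapply(spikes, `[[`, 1L, "unit_id")
  if (anyDuplicated(ids)) stop("duplicate unit_id in spikes")
  regs <- vapply(spikes, `[[`, "", "region")
  if (is.null(regions)) regions <- sort(unique(regs))
  if (!all(regs %in% regions)) {
    stop("unit region not in configured regions: ",
         paste(setdiff(regs, regions), collapse = ", "))
  }
  if (!inherits(epochs, "epoch_set")) {
    epochs <- epoch_set(epochs$label, epochs$state, epochs$start, epochs$end)
  }
  structure(list(subject_id = as.character(subject_id),
                 spikes = spikes[order(ids)], epochs = epochs, lfp = lfp,
                 regions = regions),
            class = "ensemble_dataset")
}

#' @export
print.ensemble_dataset <- function(x, ...) {
  cat("ensemble_dataset:", x$subject_id, "\n")
  regs <- vapply(x$spikes, `[[`, "", "region")
  for (r in x$regions) {
    cat("  ", r, ": ", sum(regs == r), " units\n", sep = "")
  }
  cat("  epochs:", nrow(x$epochs), "rows, span [",
      min(x$epochs$start), ",", max(x$epochs$end), ") s\n")
  if (!is.null(x$lfp)) {
    cat("  lfp:", nrow(x$lfp$samples), "channels @", x$lfp$sample_rate, "Hz\n")
  }
  invisible(x)
}

#' Write a Dataset to a directory
#'
#' Writes `spikes.csv`, `epochs.csv` and, when LFP is present, `lfp.dat` +
#' `lfp.json`. The inverse of [load_dataset()].
#'
#' @param dataset an `ensemble_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- do.call(rbind, lapply(dataset$spikes, function(s) {
    data.frame(unit_id = s$unit_id, region = s$region, shank = s$shank,
               time_s = s$times, waveform_fwhm_ms = s$waveform_fwhm,
               cell_class = s$cell_class)
  }))
  write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  ep <- dataset$epochs
  write.csv(data.frame(label = ep$label, state = ep$state,
                       start_s = ep$start, end_s = ep$end),
            file.path(dir, "epochs.csv"), row.names = FALSE)
  if (!is.null(dataset$lfp)) {
    lfp <- dataset$lfp
    con <- file(file.path(dir, "lfp.dat"), "wb")
    on.exit(close(con), add = TRUE)
    # channel-interleaved frames: sample 1 of all channels, then sample 2, ...
    writeBin(as.integer(as.vector(lfp$samples)), con, size = 2L,
             endian = "little")
    side <- list(sample_rate = lfp$sample_rate,
                 n_channels = nrow(lfp$samples),
                 n_samples = ncol(lfp$samples),
                 dtype = "int16", scale = lfp$scale,
                 channel_meta = lfp$channel_meta)
    jsonlite::write_json(side, file.path(dir, "lfp.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Load a Dataset from its on-disk files
#'
#' @param spike_path path to `spikes.csv` (columns unit_id, region, shank,
#'   time_s; optional waveform_fwhm_ms, cell_class).
#' @param epoch_path path to `epochs.csv` (columns label, state, start_s, end_s).
#' @param lfp_path path to `lfp.dat`, or NULL; the JSON sidecar is expected at
#'   the same path with extension `.json`.
#' @param subject_id subject label to attach.
#' @return An `ensemble_dataset`.
#' @export
load_dataset <- function(spike_path, epoch_path, lfp_path = NULL,
                         subject_id = "subject") {
  for (p in c(spike_path, epoch_path, lfp_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  sp <- read.csv(spike_path, stringsAsFactors = FALSE)
  need <- c("unit_id", "region", "shank", "time_s")
  if (!all(need %in% names(sp))) {
    stop("spikes.csv missing column(s): ",
         paste(setdiff(need, names(sp)), collapse = ", "))
  }
  if (anyNA(sp$time_s) || any(!is.finite(sp$time_s))) {
    stop("non-finite spike time in ", spike_path)
  }
  has_fwhm <- "waveform_fwhm_ms" %in% names(sp)
  has_class <- "cell_class" %in% names(sp)
  spikes <- lapply(split(sp, sp$unit_id), function(d) {
    spike_train(d$unit_id[1L], d$region[1L], d$shank[1L], d$time_s,
                waveform_fwhm = if (has_fwhm) d$waveform_fwhm_ms[1L] else NA_real_,
                cell_class = if (has_class) d$cell_class[1L] else NA_character_)
  })
  ep <- read.csv(epoch_path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("label", "state", "start_s", "end_s")
  if (!all(need %in% names(ep))) {
    stop("epochs.csv missing column(s): ",
         paste(setdiff(need, names(ep)), collapse = ", "))
  }
  epochs <- epoch_set(ep$label, ep$state, ep$start_s, ep$end_s)
  lfp <- NULL
  if (!is.null(lfp_path)) {
    side_path <- sub("\\.[^.]+$", ".json", lfp_path)
    if (!file.exists(side_path)) stop("LFP sidecar not found: ", side_path)
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!identical(side$dtype, "int16")) stop("unsupported LFP dtype: ", side$dtype)
    nbytes <- file.size(lfp_path)
    if (nbytes %% (side$n_channels * 2L) != 0) {
      stop("lfp.dat size not divisible by n_channels x 2 bytes")
    }
    n_samp <- nbytes / (side$n_channels * 2L)
    con <- file(lfp_path, "rb")
    on.exit(close(con), add = TRUE)
    raw <- readBin(con, "integer", n = side$n_channels * n_samp, size = 2L,
                   signed = TRUE, endian = "little")
    lfp <- lfp_set(matrix(raw, nrow = side$n_channels),
                   side$sample_rate, as.data.frame(side$channel_meta),
                   scale = if (is.null(side$scale)) 1 else side$scale)
  }
  new_dataset(subject_id, spikes, epochs, lfp)
}

#' State mask over a regular bin grid
#'
#' Bin `i` covers `[(i-1)*bin_size, i*bin_size)` from time 0; it is assigned
#' to a state when its center falls inside an epoch of that state (half-open
#' convention).
#'
#' @param epochs an [epoch_set()].
#' @param state one of "NREM", "WAKE", "REM", "NA", or a vector of those (a
#'   bin matches any of them).
#' @param bin_size bin width in seconds.
#' @param n_bins number of bins.
#' @return Logical vector of length `n_bins`.
#' @export
epoch_mask <- function(epochs, state, bin_size, n_bins) {
  if (bin_size <= 0) stop("bin_size must be positive")
  if (!all(state %in% .STATES)) {
    stop("unknown state label(s): ", paste(setdiff(state, .STATES), collapse = ", "))
  }
  centers <- (seq_len(n_bins) - 0.5) * bin_size
  rows <- epochs[epochs$state %in% state, , drop = FALSE]
  mask <- rep(FALSE, n_bins)
  for (i in seq_len(nrow(rows))) {
    mask <- mask | (centers >= rows$start[i] & centers < rows$end[i])
  }
  mask
}

# Epochs of given state(s) restricted to a label subset, as interval matrix.
.state_intervals <- function(epochs, state, labels = NULL) {
  rows <- epochs[epochs$state %in% state, , drop = FALSE]
  if (!is.null(labels)) rows <- rows[rows$label %in% labels, , drop = FALSE]
  rows <- rows[order(rows$start), , drop = FALSE]
  cbind(start = rows$start, end = rows$end)
}
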