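# Internal helpers shared across modules.

# Linear-interpolation percentile (type 6), the package-wide convention for
# all shuffle-null thresholds: with n exchangeable null draws, a fresh draw
# exceeds the type-6 estimate of the p-th quantile with probability ~(1 - p),
# so thresholds realize their nominal level.
.pctile <- function(x, probs) unname(quantile(x, probs, type = 6, names = FALSE))

# Runs of TRUE in a logical vector -> matrix of (start_idx, end_idx), inclusive.
.true_runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  cbind(start = starts[keep], end = ends[keep])
}

# Merge intervals (rows of start,end) whose gap to the next is < gap.
# Intervals must be sorted by start; returns merged rows.
.merge_gaps <- function(iv, gap) {
  if (nrow(iv) <= 1L) return(iv)
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1L]) {
    if (iv[i, 1L] - out[nrow(out), 2L] < gap) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], iv[i, 2L])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

# Union of possibly-overlapping intervals across sources (gap = 0 merge on
# touching/overlapping spans).
.interval_union <- function(iv) {
  if (nrow(iv) <= 1L) return(iv)
  .merge_gaps(iv, gap = 0)
}

# Is each time inside any half-open [start, end) interval row?
.in_intervals <- function(t, iv) {
  if (nrow(iv) == 0L) return(rep(FALSE, length(t)))
  idx <- findInterval(t, as.vector(t(iv[, 1:2, drop = FALSE])))
  idx %% 2L == 1L
}

# Derive a child RNG seed (< 2^31) from a base seed and a stream tag.
# Position-sensitive rolling hash so distinct tags give distinct streams.
.substream_seed <- function(seed, tag) {
  h <- (as.numeric(seed) * 2654435761) %% 2147483647
  for (c in utf8ToInt(tag)) h <- (h * 69069 + c * 97) %% 2147483647
  h
}

# Strict local maxima above a threshold; plateaus count once, at their first
# bin. Returns integer indices.
.peak_indices <- function(x, threshold) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  above <- which(x > threshold)
  above <- above[above > 1L & above < n]
  if (length(above) == 0L) return(integer(0))
  is_peak <- logical(length(above))
  for (j in seq_along(above)) {
    i <- above[j]
    if (x[i] < x[i - 1L]) next
    if (x[i] == x[i - 1L]) next              # not the first bin of a plateau
    # scan forward over any plateau
    k <- i
    while (k < n && x[k + 1L] == x[i]) k <- k + 1L
    if (k < n && x[k + 1L] < x[i]) is_peak[j] <- TRUE
  }
  above[is_peak]
}
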