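#' @name similarity
#' @title Cross-session ensemble similarity and dynamic categories
#'
#' @description
#' Ensemble persistence across template sessions is measured by the absolute
#' cosine similarity between projection vectors with unit ids aligned (the
#' sign of an ICA vector is arbitrary). Significance is assessed per rat and
#' region against a shuffle null: vectors from the conditioning, extinction,
#' and retention ensembles are pooled, 5000 pairs drawn with replacement, each
#' vector's elements (unit ids) independently permuted, and the 99th
#' percentile of the resulting absolute cosines is the threshold. An
#' extinction ensemble is then categorized by whether it has at least one
#' significantly similar partner among conditioning and/or retention
#' ensembles: maintained (both), initiated (retention only), terminated
#' (conditioning only), transient (neither); preserved = maintained or
#' initiated.
NULL

.abs_cos <- function(a, b) {
  abs(sum(a * b)) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

#' Absolute cosine similarity matrix between two ensemble sets
#'
#' @param a,b `ensemble_set` objects from the same region with identical
#'   `unit_ids` ordering.
#' @return |A| x |B| matrix of absolute cosine similarities.
#' @export
similarity_matrix <- function(a, b) {
  if (!identical(a$unit_ids, b$unit_ids)) {
    stop("unit_ids of the two ensemble sets do not match")
  }
  wa <- a$projections; wb <- b$projections
  na <- sqrt(colSums(wa^2)); nb <- sqrt(colSums(wb^2))
  m <- abs(crossprod(wa, wb)) / outer(na, nb)
  matrix(m, nrow = ncol(wa), ncol = ncol(wb))
}

#' Shuffle-null threshold for significant similarity
#'
#' @param sets list of `ensemble_set` objects to pool (same rat and region).
#' @param n_pairs number of null pairs drawn with replacement (field
#'   convention 5000).
#' @param seed RNG seed.
#' @param percentile null percentile used as the threshold.
#' @return scalar threshold in [0, 1].
#' @export
similarity_threshold <- function(sets, n_pairs = 5000L, seed = 1L,
                                 percentile = 0.99) {
  pool <- do.call(cbind, lapply(sets, `[[`, "projections"))
  if (is.null(pool) || ncol(pool) < 2L) stop("need >= 2 pooled vectors")
  d <- nrow(pool)
  set.seed(seed)
  i <- sample.int(ncol(pool), n_pairs, replace = TRUE)
  j <- sample.int(ncol(pool), n_pairs, replace = TRUE)
  sims <- vapply(seq_len(n_pairs), function(k) {
    .abs_cos(pool[sample.int(d), i[k]], pool[sample.int(d), j[k]])
  }, 0)
  .pctile(sims, percentile)
}

#' Categorize extinction ensembles by cross-session partners
#'
#' @param ext,cond,ret `ensemble_set` objects for the extinction,
#'   conditioning, and retention sessions (same region, same unit order).
#' @param threshold similarity threshold from [similarity_threshold()].
#' @return data.frame (ensemble, has_conditioning_partner,
#'   has_retention_partner, category, preserved) of class `dynamics_label`.
#' @export
classify_dynamics <- function(ext, cond, ret, threshold) {
  sc <- similarity_matrix(ext, cond)
  sr <- similarity_matrix(ext, ret)
  has_c <- if (ncol(sc) > 0L) apply(sc, 1L, function(r) any(r > threshold))
           else rep(FALSE, nrow(sc))
  has_r <- if (ncol(sr) > 0L) apply(sr, 1L, function(r) any(r > threshold))
           else rep(FALSE, nrow(sr))
  category <- ifelse(has_c & has_r, "maintained",
              ifelse(!has_c & has_r, "initiated",
              ifelse(has_c & !has_r, "terminated", "transient")))
  out <- data.frame(ensemble = seq_len(ncol(ext$projections)),
                    has_conditioning_partner = has_c,
                    has_retention_partner = has_r,
                    category = category,
                    preserved = category %in% c("maintained", "initiated"),
                    stringsAsFactors = FALSE)
  class(out) <- c("dynamics_label", "data.frame")
  out
}

#' Greedy reordering of a similarity matrix for display
#'
#' Iteratively moves the global maximum of the remaining submatrix to the
#' diagonal (top-left first). With `fix_rows = TRUE` the row order is kept and
#' each row in turn takes the highest-similarity unused column. Ties break
#' toward the lowest original index. Display-only; never feeds statistics.
#'
#' @param sim numeric similarity matrix.
#' @param fix_rows keep row order fixed (retention-style variant).
#' @return list with integer permutations `rows` and `cols`.
#' @export
reorder_for_display <- function(sim, fix_rows = FALSE) {
  nr <- nrow(sim); nc <- ncol(sim)
  if (nr == 0L || nc == 0L) stop("non-empty matrix required")
  if (fix_rows) {
    rows <- seq_len(nr)
    cols <- integer(0)
    for (i in seq_len(min(nr, nc))) {
      avail <- setdiff(seq_len(nc), cols)
      cols <- c(cols, avail[which.max(sim[i, avail])])
    }
    return(list(rows = rows, cols = c(cols, setdiff(seq_len(nc), cols))))
  }
  rows_left <- seq_len(nr); cols_left <- seq_len(nc)
  rows <- integer(0); cols <- integer(0)
  while (length(rows_left) && length(cols_left)) {
    sub <- sim[rows_left, cols_left, drop = FALSE]
    k <- which.max(sub)                       # column-major: first max wins
    ri <- (k - 1L) %% length(rows_left) + 1L
    ci <- (k - 1L) %/% length(rows_left) + 1L
    rows <- c(rows, rows_left[ri]); cols <- c(cols, cols_left[ci])
    rows_left <- rows_left[-ri]; cols_left <- cols_left[-ci]
  }
  list(rows = c(rows, rows_left), cols = c(cols, cols_left))
}
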