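test_that("absolute cosine similarity ignores sign and respects geometry", {
  w <- random_unit_vectors(15, 3)
  a <- as_ensemble_set(w)
  expect_equal(diag(similarity_matrix(a, a)), rep(1, 3))
  neg <- as_ensemble_set(-w)
  expect_equal(diag(similarity_matrix(a, neg)), rep(1, 3))
  orth <- as_ensemble_set(cbind(c(1, rep(0, 14)), c(0, 1, rep(0, 13))))
  one <- as_ensemble_set(matrix(c(0, 0, 1, rep(0, 12)), ncol = 1))
  expect_equal(as.vector(similarity_matrix(orth, one)), c(0, 0))
  b <- as_ensemble_set(w, unit_ids = 2:16)
  expect_error(similarity_matrix(a, b), "unit_ids")
  # invariance to a simultaneous unit permutation
  perm <- sample(15)
  ap <- as_ensemble_set(w[perm, ])
  bp <- as_ensemble_set(random_unit_vectors(15, 2))
  bpp <- as_ensemble_set(bp$projections[perm, ])
  expect_equal(similarity_matrix(ap, bpp), similarity_matrix(a, bp))
})

test_that("shuffle-null threshold is calibrated and tracks dimensionality", {
  set.seed(51)
  pool20 <- as_ensemble_set(random_unit_vectors(20, 12))
  thr20 <- similarity_threshold(list(pool20), seed = 5)
  expect_gt(thr20, 0); expect_lt(thr20, 1)
  # higher dimension concentrates |cos| near zero -> lower threshold
  pool100 <- as_ensemble_set(random_unit_vectors(100, 12))
  thr100 <- similarity_threshold(list(pool100), seed = 5)
  expect_lt(thr100, thr20)
  # type-I: fresh shuffled pairs exceed the threshold ~1% of the time
  d <- 20; pool <- pool20$projections
  n_new <- 4000
  exceed <- vapply(seq_len(n_new), function(k) {
    i <- sample(12, 1); j <- sample(12, 1)
    abs(sum(pool[sample(d), i] * pool[sample(d), j])) > thr20
  }, TRUE)
  expect_lt(abs(mean(exceed) - 0.01), 0.007)
  expect_error(similarity_threshold(list(as_ensemble_set(matrix(1, 5, 1)))),
               ">= 2")
})

test_that("dynamic categories follow the conditioning/retention partner logic", {
  d <- 20
  base <- random_unit_vectors(d, 4)
  # ext ensembles: 1 in both, 2 in retention only, 3 in conditioning only, 4 nowhere
  ext <- as_ensemble_set(base)
  cond <- as_ensemble_set(cbind(base[, 1], base[, 3], random_unit_vectors(d, 1)))
  ret <- as_ensemble_set(cbind(base[, 2], base[, 1], random_unit_vectors(d, 1)))
  dyn <- classify_dynamics(ext, cond, ret, threshold = 0.95)
  expect_equal(dyn$category, c("maintained", "initiated", "terminated", "transient"))
  expect_equal(dyn$preserved, c(TRUE, TRUE, FALSE, FALSE))
  # invariant to internal order of the partner sets
  cond2 <- as_ensemble_set(cond$projections[, c(3, 1, 2)])
  ret2 <- as_ensemble_set(ret$projections[, c(2, 3, 1)])
  expect_equal(classify_dynamics(ext, cond2, ret2, 0.95)$category, dyn$category)
})

test_that("planted cross-session dynamics are recovered end to end", {
  cfg <- synth_config(seed = 29)   # 2 maintained, 2 initiated, 1 terminated, 2 transient
  out <- generate_spikes(cfg)
  planned <- vapply(cfg$ensembles, function(e) {
    has_c <- "conditioning" %in% e$active_sessions
    has_r <- "retention" %in% e$active_sessions
    if (has_c && has_r) "maintained" else if (has_r) "initiated"
    else if (has_c) "terminated" else "transient"
  }, "")
  rep <- run_pipeline(out$dataset, pipeline_config(seed = 2, n_shuffles = 100L))
  got <- table(factor(rep$dynamics$category,
                      c("maintained", "initiated", "terminated", "transient")))
  expect_equal(as.integer(got), as.integer(table(factor(planned,
                      c("maintained", "initiated", "terminated", "transient")))))
})

test_that("greedy display reordering recovers permutations and stays bijective", {
  set.seed(9)
  p <- sample(5)
  m <- diag(5)[, p] * 0.9 + matrix(runif(25, 0, 0.05), 5)
  ord <- reorder_for_display(m)
  expect_setequal(ord$rows, 1:5); expect_setequal(ord$cols, 1:5)
  re <- m[ord$rows, ord$cols]
  expect_true(all(diag(re) == apply(re, 1L, max)))
  # fixed-row variant assigns per-row argmax over unused columns
  ordf <- reorder_for_display(m, fix_rows = TRUE)
  expect_equal(ordf$rows, 1:5)
  expect_setequal(ordf$cols, 1:5)
  expect_equal(ordf$cols[1], which.max(m[1, ]))
  # ties break toward the lowest original index
  tied <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(reorder_for_display(tied)$rows[1], 1L)
  expect_equal(reorder_for_display(tied)$cols[1], 1L)
})
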