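test_that("k = 1 returns the grand centroid and k > I errors", {
  X <- make_two_map_tensor(I = 10, J = 6, K = 3, noise = 0.1, seed = 1)
  m <- fit_factorized_kmeans(X, 1)
  expect_equal(as.vector(m$centroids),
               colMeans(flatten_tensor(X)), tolerance = 1e-12)
  expect_equal(m$assignments, rep(1L, 10))
  expect_error(fit_factorized_kmeans(X, 11), "exceed")
})

test_that("two separated maps are recovered up to label permutation", {
  hits <- vapply(1:20, function(s) {
    X <- make_two_map_tensor(I = 24, J = 10, K = 6, noise = 0.05,
                             seed = 500 + s)
    m <- fit_factorized_kmeans(X, 2, restarts = 10, seed = s)
    truth <- attr(X, "true_labels")
    agree <- mean(m$assignments == truth)
    max(agree, 1 - agree) == 1
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("the Lloyd objective is non-increasing and reconstruction matches centroids", {
  X <- make_two_map_tensor(I = 30, J = 8, K = 5, noise = 0.3, seed = 9)
  m <- fit_factorized_kmeans(X, 3, restarts = 3, seed = 2)
  expect_true(all(diff(m$objective_trace) <= 1e-9))
  Xhat <- reconstruct_map_model(m)
  for (i in 1:30) {
    expect_equal(Xhat[i, ], m$centroids[m$assignments[i], ])
  }
})

test_that("select_k recovers the generative number of maps", {
  for (k_true in 2:3) {
    labels <- rep(seq_len(k_true), length.out = 24)
    X <- make_two_map_tensor(I = 24, J = 10, K = 6, noise = 0.05,
                             seed = 40 + k_true, labels = labels)
    sel <- select_k(X, k_max = 4, reps = 3, restarts = 10, seed = 7)
    expect_equal(sel$k_star, k_true)
  }
})

test_that("speckled CV masks ~10% of entries and separates structure from noise", {
  X <- make_two_map_tensor(I = 20, J = 10, K = 5, noise = 0, seed = 3)
  cv <- speckled_cv(X, 2, replicates = 4, restarts = 5, seed = 5)
  n <- length(flatten_tensor(X))
  for (W in cv$masks) {
    expect_equal(sum(!W), round(0.1 * n))
  }
  expect_true(all(cv$test_r2 > 0.99))
  set.seed(6)
  Xn <- array(rnorm(20 * 10 * 5), dim = c(20, 10, 5))
  cvn <- speckled_cv(Xn, 2, replicates = 4, restarts = 5, seed = 5)
  expect_lt(mean(cvn$test_r2), 0.2)
})

test_that("rotation shuffle preserves norm and bin-cell correlations but kills clustering", {
  X <- make_two_map_tensor(I = 16, J = 8, K = 6, noise = 0.05, seed = 4)
  Y <- rotation_shuffle(X, seed = 8)
  Xf <- flatten_tensor(X)
  Yf <- flatten_tensor(Y)
  expect_equal(sqrt(sum(Yf^2)), sqrt(sum(Xf^2)), tolerance = 1e-8)
  # feature (bin x cell) covariance structure is preserved:
  # crossprod is invariant under orthogonal left-multiplication
  expect_equal(crossprod(Yf), crossprod(Xf), tolerance = 1e-8)
  cv_real <- speckled_cv(X, 2, replicates = 4, restarts = 5, seed = 9)
  cv_shuf <- speckled_cv(Y, 2, replicates = 4, restarts = 5, seed = 9)
  expect_gt(mean(cv_real$test_r2), mean(cv_shuf$test_r2))
})

test_that("one-map detection distinguishes structured from shuffled data", {
  X <- make_two_map_tensor(I = 20, J = 10, K = 5, noise = 0.05, seed = 11)
  cv <- speckled_cv(X, 2, replicates = 8, restarts = 5, seed = 2)
  cv_sh <- speckled_cv(rotation_shuffle(X, seed = 3), 2, replicates = 8,
                       restarts = 5, seed = 2)
  om <- detect_one_map(cv$test_r2, cv_sh$test_r2)
  expect_false(om$one_map)
  # identical scores -> one map
  expect_true(detect_one_map(cv$test_r2, cv$test_r2)$one_map)
  # i.i.d. noise flagged one-map in most seeds
  flags <- vapply(1:10, function(s) {
    set.seed(s)
    Z <- array(rnorm(16 * 8 * 4), dim = c(16, 8, 4))
    cvz <- speckled_cv(Z, 2, replicates = 8, restarts = 5, seed = s)
    cvzs <- speckled_cv(rotation_shuffle(Z, seed = s + 50), 2,
                        replicates = 8, restarts = 5, seed = s)
    detect_one_map(cvz$test_r2, cvzs$test_r2)$one_map
  }, logical(1))
  expect_gte(mean(flags), 0.9)
})

test_that("rank-matched tSVD performs at least as well as k-means on discrete maps", {
  X <- make_two_map_tensor(I = 20, J = 10, K = 5, noise = 0.05, seed = 13)
  cv <- speckled_cv(X, 2, replicates = 5, restarts = 5, seed = 4)
  ts <- tsvd_comparison(X, 2, cv$masks)
  expect_gte(mean(ts$test_r2) + 0.02, mean(cv$test_r2))
  # discrete 2-map data: both models perform comparably
  expect_lt(abs(mean(ts$test_r2) - mean(cv$test_r2)), 0.05)
})

test_that("tSVD completes an exactly rank-1 matrix perfectly (SVD oracle)", {
  set.seed(14)
  X <- outer(runif(15, 0.5, 1.5), runif(9, 0.5, 1.5))  # rank 1
  W <- matrix(TRUE, 15, 9)
  W[sample(length(X), 13)] <- FALSE
  ts <- tsvd_comparison(X, 1, list(W), max_iter = 500, tol = 1e-12)
  # held-out entries of a rank-1 matrix are recovered exactly
  expect_gt(ts$test_r2[1], 0.999)
  # and the complete-data reconstruction is the Eckart-Young optimum
  sv <- svd(X)
  X1 <- sv$d[1] * sv$u[, 1] %*% t(sv$v[, 1])
  expect_equal(X1, X, tolerance = 1e-9)
})

test_that("SM relabeling follows the block-count rules with documented tie-breaks", {
  info <- data.frame(trial = 1:12,
                     context = c(rep("A", 4), rep("B", 4),
                                 c("A", "B", "A", "B")),
                     phase = c(rep("block", 8), rep("alternation", 4)))
  model <- structure(list(k = 2L,
                          assignments = c(2L, 2L, 2L, 2L, 1L, 1L, 1L, 1L,
                                          2L, 1L, 2L, 1L),
                          centroids = matrix(0, 2, 4)),
                     class = "map_model")
  lab <- relabel_maps(model, "SM", trial_info = info)
  # raw 2 dominates Block A -> becomes map 1
  expect_equal(lab$labels[1:4], rep(1L, 4))
  expect_equal(lab$labels[5:8], rep(2L, 4))
  # tie in Block A counts -> lowest raw id wins
  model2 <- structure(list(k = 2L,
                           assignments = c(1L, 1L, 2L, 2L, 1L, 1L, 2L, 2L,
                                           1L, 2L, 1L, 2L),
                           centroids = matrix(0, 2, 4)),
                      class = "map_model")
  lab2 <- relabel_maps(model2, "SM", trial_info = info)
  expect_equal(lab2$raw_to_new[["1"]], 1L)
})

test_that("RF maps are ordered by mean running speed, slowest first", {
  model <- structure(list(k = 2L, assignments = rep(c(1L, 2L), each = 5),
                          centroids = matrix(0, 2, 4)),
                     class = "map_model")
  speeds <- c(rep(35, 5), rep(20, 5))
  lab <- relabel_maps(model, "RF", trial_speeds = speeds)
  expect_equal(lab$labels, rep(c(2L, 1L), each = 5))
})

test_that("context identities: map 1 -> A, map 2 -> B, extras by block similarity", {
  info <- data.frame(trial = 1:12,
                     context = c(rep("A", 4), rep("B", 4),
                                 rep(c("A", "B"), 2)),
                     phase = c(rep("block", 8), rep("alternation", 4)))
  # network similarity: trials 9/11 resemble block A, 10/12 resemble block B
  base <- matrix(0.1, 12, 12)
  base[1:4, 1:4] <- 0.8
  base[5:8, 5:8] <- 0.8
  a_like <- c(9, 11)
  base[a_like, 1:4] <- base[cbind(rep(1:4, each = 2), rep(a_like, 4))] <- 0.7
  base[a_like, 1:4] <- 0.7
  base[1:4, a_like] <- 0.7
  diag(base) <- 1
  labeling <- structure(list(labels = c(rep(1L, 4), rep(2L, 4),
                                        3L, 2L, 3L, 2L)),
                        class = "map_labeling")
  out <- assign_context_identity(labeling, base, info)
  expect_equal(unname(out$context_of_map[c("1", "2")]), c("A", "B"))
  expect_equal(unname(out$context_of_map[["3"]]), "A")
  expect_equal(out$trial_identity[9], "A")
})

test_that("remap detection and per-phase frequency match count oracles", {
  labs <- c(1, 1, 1, 2, 2, 1)
  expect_equal(detect_remaps(labs), c(FALSE, FALSE, TRUE, FALSE, TRUE))
  # strict alternation: 9 remaps over 10 trials
  alt <- rep(c(1, 2), 5)
  expect_equal(remap_frequency(alt)$overall, 0.9)
  # constant labels -> 0
  expect_equal(remap_frequency(rep(1, 8))$overall, 0)
  # phase-wise counts stay within phases
  phase <- rep(c("block", "alternation"), each = 5)
  labs2 <- c(1, 1, 2, 2, 2, 1, 2, 1, 2, 1)
  rf <- remap_frequency(labs2, phase)
  expect_equal(unname(rf$per_phase["block"]), 1 / 5)
  expect_equal(unname(rf$per_phase["alternation"]), 4 / 5)
})

test_that("context alignment hits its anchors", {
  ctx <- rep(c("A", "B"), 10)
  expect_equal(context_alignment(ctx, ctx)$fraction, 1)
  anti <- ifelse(ctx == "A", "B", "A")
  expect_equal(context_alignment(anti, ctx)$fraction, 0)
})

test_that("downstream statistics are invariant to raw cluster label permutation", {
  info <- data.frame(trial = 1:12,
                     context = c(rep("A", 4), rep("B", 4),
                                 rep(c("A", "B"), 2)),
                     phase = c(rep("block", 8), rep("alternation", 4)))
  assigns <- c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 1L, 2L, 1L, 2L)
  perm <- c(2L, 1L)
  m1 <- structure(list(k = 2L, assignments = assigns,
                       centroids = matrix(rnorm(8), 2, 4)),
                  class = "map_model")
  m2 <- structure(list(k = 2L, assignments = perm[assigns],
                       centroids = m1$centroids[perm, ]),
                  class = "map_model")
  l1 <- relabel_maps(m1, "SM", trial_info = info)
  l2 <- relabel_maps(m2, "SM", trial_info = info)
  expect_equal(l1$labels, l2$labels)
})
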