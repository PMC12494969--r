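fake_rate_list <- function(values_list, trials) {
  lapply(values_list, function(v) {
    structure(list(values = v, trials = trials,
                   bin_size = 2), class = "trial_rate_matrix")
  })
}

sm_info <- function(n_dark = 2, nA = 4, nB = 4, n_alt = 4) {
  n <- n_dark + nA + nB + n_alt
  data.frame(trial = seq_len(n),
             context = c(rep("dark", n_dark), rep("A", nA), rep("B", nB),
                         rep(c("B", "A"), length.out = n_alt)),
             trial_type = c(rep("dark", n_dark), rep("vr", nA + nB + n_alt)),
             phase = c(rep("dark", n_dark), rep("blockA", nA),
                       rep("blockB", nB), rep("alternation", n_alt)))
}

test_that("tensor normalization rescales per cell and handles silent cells", {
  info <- sm_info()
  n_tr <- nrow(info)
  v1 <- matrix(seq(2, 6, length.out = 10 * n_tr), n_tr, 10)  # min 2 max 6
  v2 <- matrix(5, n_tr, 10)                                  # constant cell
  X <- normalize_tensor(fake_rate_list(list(v1, v2), info$trial), info)
  vr <- info$trial_type == "vr"
  expect_equal(dim(X), c(sum(vr), 10, 2))
  lo <- min(v1[vr, ])
  hi <- max(v1[vr, ])
  expect_equal(as.vector(X[, , 1]),
               as.vector((v1[vr, ] - lo) / (hi - lo)), tolerance = 1e-12)
  expect_true(all(X[, , 2] == 0))
  expect_equal(min(X[, , 1]), 0)
  expect_equal(max(X[, , 1]), 1)
})

test_that("front/back halves partition the bins", {
  info <- sm_info()
  v <- matrix(runif(nrow(info) * 10), nrow(info), 10)
  rl <- fake_rate_list(list(v), info$trial)
  Xf <- normalize_tensor(rl, info, half = "front")
  Xb <- normalize_tensor(rl, info, half = "back")
  Xall <- normalize_tensor(rl, info)
  expect_equal(dim(Xf)[2] + dim(Xb)[2], dim(Xall)[2])
})

test_that("context-sorting of alternation trials is stable within context", {
  info <- sm_info(n_dark = 0, nA = 2, nB = 2, n_alt = 4)
  v <- matrix(seq_len(nrow(info) * 4), nrow(info), 4)
  X <- normalize_tensor(fake_rate_list(list(v), info$trial), info,
                        sort_alternation = TRUE)
  ti <- attr(X, "trial_info")
  alt <- ti[ti$phase == "alternation", ]
  expect_equal(alt$context, sort(alt$context))
  # chronological order preserved within each context
  expect_true(all(diff(alt$trial[alt$context == "A"]) > 0))
  expect_true(all(diff(alt$trial[alt$context == "B"]) > 0))
})

test_that("cross-trial matrices match the brute-force oracle and are symmetric", {
  set.seed(12)
  mat <- matrix(runif(6 * 8), 6, 8)
  M <- cross_trial_matrix(mat)
  expect_equal(M, oracle_cross_trial(mat), tolerance = 1e-9)
  expect_equal(M, t(M), tolerance = 1e-12)
  expect_equal(diag(M), rep(1, 6))
  # identical trials correlate at 1
  M1 <- cross_trial_matrix(matrix(rep(runif(8), 4), 4, byrow = TRUE))
  expect_true(all(abs(M1 - 1) < 1e-12))
  # zero-variance trials give missing entries
  mat2 <- rbind(mat, rep(3, 8))
  M2 <- cross_trial_matrix(mat2)
  expect_true(all(is.na(M2[7, ])))
})

test_that("trial stability equals the brute-force windowed mean and its invariances", {
  set.seed(13)
  mat <- matrix(runif(9 * 12), 9, 12)
  M <- cross_trial_matrix(mat)
  # brute force: mean over trials of mean correlation with 5 nearest
  brute <- mean(vapply(1:9, function(i) {
    d <- abs(1:9 - i)
    nb <- order(d, 1:9)
    nb <- nb[nb != i][1:5]
    mean(M[i, nb])
  }, numeric(1)))
  expect_equal(trial_stability(M), brute, tolerance = 1e-12)
  # identical trials -> 1
  Mi <- cross_trial_matrix(matrix(rep(runif(12), 6), 6, byrow = TRUE))
  expect_equal(trial_stability(Mi), 1)
  # invariant to adding a constant to all rates
  M_shift <- cross_trial_matrix(mat + 5)
  expect_equal(trial_stability(M_shift), trial_stability(M),
               tolerance = 1e-12)
  expect_true(is.na(trial_stability(M, trials = 1L)))
})

test_that("within-map stability averages per-map stability and penalizes wrong labels", {
  X <- make_two_map_tensor(I = 20, J = 15, K = 5, noise = 0.02, seed = 3)
  M <- cross_trial_matrix(flatten_tensor(X))
  true_lab <- attr(X, "true_labels")
  s_true <- within_map_stability(M, true_lab)
  expect_gt(s_true, 0.8)
  # one map -> equals plain stability
  expect_equal(within_map_stability(M, rep(1, 20)), trial_stability(M))
  set.seed(4)
  s_rand <- within_map_stability(M, sample(true_lab))
  expect_gt(s_true, s_rand)
})

test_that("similarity ratios hit their analytic anchors", {
  # identical tuning everywhere -> every correlation 1 -> both ratios 1
  mat <- matrix(rep(c(1, 3, 2, 5, 4, 2), 12), 12, byrow = TRUE)
  mat <- mat + matrix(rnorm(72, 0, 1e-9), 12)  # break exact zero variance
  M <- cross_trial_matrix(mat)
  A <- 1:3; B <- 4:6; A_alt <- 7:9; B_alt <- 10:12
  expect_equal(similarity_ratio_block(M, A, B), 1, tolerance = 1e-6)
  expect_equal(similarity_ratio_alt(M, A, B, A_alt, B_alt), 1,
               tolerance = 1e-6)
  # swapping A and B leaves the block ratio unchanged
  set.seed(15)
  mat2 <- matrix(runif(12 * 10), 12, 10)
  M2 <- cross_trial_matrix(mat2)
  expect_equal(similarity_ratio_block(M2, A, B),
               similarity_ratio_block(M2, B, A), tolerance = 1e-12)
  # strongly remapped A/B fields (one shared field keeps the mismatched
  # similarity positive) -> ratio well above 1, matching a direct
  # computation from the matrix
  bins <- 1:20
  bump <- function(c0) exp(-0.5 * ((bins - c0) / 1.5)^2)
  pat_a <- 2 * bump(16) + bump(4)
  pat_b <- 2 * bump(16) + bump(10)
  mat3 <- rbind(matrix(rep(pat_a, 3), 3, byrow = TRUE) +
                  matrix(runif(60, 0, 0.02), 3),
                matrix(rep(pat_b, 3), 3, byrow = TRUE) +
                  matrix(runif(60, 0, 0.02), 3))
  M3 <- cross_trial_matrix(mat3)
  r3 <- similarity_ratio_block(M3, 1:3, 4:6)
  matched <- mean(c(mean(M3[1:3, 1:3][upper.tri(M3[1:3, 1:3])]),
                    mean(M3[4:6, 4:6][upper.tri(M3[4:6, 4:6])])))
  mismatched <- mean(M3[1:3, 4:6])
  expect_equal(as.numeric(r3), matched / mismatched, tolerance = 1e-12)
  expect_gt(r3, 1.3)
  # fully orthogonal (negative mismatched similarity) is flagged degenerate
  oh <- rbind(matrix(rep(c(1, 1, 0, 0), 2), 2, byrow = TRUE),
              matrix(rep(c(0, 0, 1, 1), 2), 2, byrow = TRUE)) +
    matrix(runif(16, 0, 0.01), 4)
  r_deg <- similarity_ratio_block(cross_trial_matrix(oh), 1:2, 3:4)
  expect_true(is.na(r_deg))
  expect_true(isTRUE(attr(r_deg, "degenerate")))
})

test_that("exchangeable A/B trials give permutation-null ratios around 1", {
  set.seed(16)
  base <- runif(12)
  mat <- matrix(rep(base, 16), 16, byrow = TRUE) +
    matrix(rnorm(16 * 12, 0, 0.3), 16)
  M <- cross_trial_matrix(mat)
  ratios <- vapply(1:200, function(i) {
    idx <- sample(16)
    similarity_ratio_block(M, idx[1:8], idx[9:16])
  }, numeric(1))
  expect_gt(median(ratios), 0.9)
  expect_lt(median(ratios), 1.1)
})

test_that("rate remapping percent and spatial dissimilarity follow their formulas", {
  mat <- rbind(matrix(rep(c(0.5, 0.2, 0.1), 2), 2, byrow = TRUE),
               matrix(rep(c(1.0, 0.4, 0.2), 2), 2, byrow = TRUE))
  expect_equal(rate_remapping_pct(mat, 1:2, 3:4), 100)
  expect_equal(rate_remapping_pct(mat, 3:4, 1:2), -50)
  expect_equal(rate_remapping_pct(mat, 1:2, 1:2), 0)
  # identical vectors -> dissimilarity 0; orthogonal one-hots -> 1
  expect_equal(spatial_dissimilarity(mat, 1:2, 1:2), 0, tolerance = 1e-12)
  oh <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(spatial_dissimilarity(oh, 1:2, 3:4), 1)
  # arbitrary pair matches brute-force cosine
  set.seed(17)
  m <- matrix(runif(4 * 6), 4, 6)
  va <- colMeans(m[1:2, ]); vb <- colMeans(m[3:4, ])
  expect_equal(spatial_dissimilarity(m, 1:2, 3:4),
               1 - sum(va * vb) / sqrt(sum(va^2) * sum(vb^2)),
               tolerance = 1e-12)
  expect_true(is.na(spatial_dissimilarity(rbind(c(0, 0), c(1, 1)), 1, 2)))
})

test_that("network similarity reduces to the cell matrix for K = 1 and finds block structure", {
  set.seed(18)
  mat <- matrix(runif(6 * 10), 6, 10)
  X <- array(mat, dim = c(6, 10, 1))
  expect_equal(network_similarity_matrix(X, min_cells = 1),
               cross_trial_matrix(mat), tolerance = 1e-12)
  # eligibility gate
  expect_error(network_similarity_matrix(X, min_cells = 10), "ineligible")
  # two-map tensor: within-block similarity exceeds across-block
  X2 <- make_two_map_tensor(I = 20, J = 10, K = 12, noise = 0.05, seed = 5)
  N <- network_similarity_matrix(X2, min_cells = 10)
  expect_equal(N, t(N), tolerance = 1e-12)
  lab <- attr(X2, "true_labels")
  within <- mean(N[lab == 1, lab == 1][upper.tri(N[lab == 1, lab == 1])])
  across <- mean(N[lab == 1, lab == 2])
  expect_gt(within, across)
})

test_that("remapping coordination is high for shared map sequences and ~0 for independent ones", {
  lab <- rep(c(1, 2), each = 10)
  X <- make_two_map_tensor(I = 20, J = 12, K = 8, noise = 0.05, seed = 6,
                           labels = lab)
  unit_M <- cross_trial_matrix(X[, , 1])
  net_M <- network_similarity_matrix(X[, , -1, drop = FALSE], min_cells = 1)
  expect_gt(remapping_coordination(unit_M, net_M), 0.5)
  # a unit remapping on an independent schedule decorrelates
  set.seed(7)
  vals <- vapply(1:10, function(s) {
    ind_lab <- sample(lab)
    Xi <- make_two_map_tensor(I = 20, J = 12, K = 1, noise = 0.05,
                              seed = 100 + s, labels = ind_lab)
    remapping_coordination(cross_trial_matrix(Xi[, , 1]), net_M)
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.25)
})

test_that("gain response is 0 without change and detects an orthogonal post-gain map", {
  pat <- runif(10)
  same <- matrix(rep(pat, 8), 8, byrow = TRUE) +
    matrix(rnorm(80, 0, 0.01), 8)
  M <- cross_trial_matrix(same)
  g0 <- gain_response_magnitude(M, pre = 1:5, post = 6:8)
  expect_equal(g0$magnitude, 0, tolerance = 0.05)
  expect_equal(g0$n_matched, 3)
  # orthogonal post-gain pattern
  pat2 <- c(rep(0, 5), rep(1, 5))
  pat1 <- c(rep(1, 5), rep(0, 5))
  mat <- rbind(matrix(rep(pat1, 5), 5, byrow = TRUE) +
                 matrix(runif(50, 0, 0.05), 5),
               matrix(rep(pat2, 3), 3, byrow = TRUE) +
                 matrix(runif(30, 0, 0.05), 3))
  M2 <- cross_trial_matrix(mat)
  pre_m <- 3:5  # matched count = 3
  within <- mean(M2[pre_m, pre_m][upper.tri(M2[pre_m, pre_m])])
  across <- mean(M2[pre_m, 6:8])
  g1 <- gain_response_magnitude(M2, pre = 1:5, post = 6:8)
  expect_equal(g1$magnitude, within - across, tolerance = 1e-12)
  expect_gt(g1$magnitude, 0.5)
  expect_true(is.na(gain_response_magnitude(M2, 1:5, integer(0))$magnitude))
})
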