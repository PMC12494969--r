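# Independent brute-force oracles used to cross-check the package's
# implementations on small inputs, plus shared synthetic fixtures.

# sparsity / information / coherence from first principles
oracle_sparsity <- function(p, r) {
  p <- p / sum(p)
  rbar <- sum(p * r)
  sum(p * r^2) / rbar^2
}
oracle_information <- function(p, r) {
  p <- p / sum(p)
  rbar <- sum(p * r)
  s <- 0
  for (i in seq_along(r)) {
    if (r[i] > 0) s <- s + p[i] * r[i] * log2(r[i] / rbar)
  }
  s
}
oracle_coherence <- function(r) {
  n <- length(r)
  nb <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(seq_len(n) - i)
    ord <- order(d, seq_len(n))
    ord <- ord[ord != i][1:8]
    nb[i] <- mean(r[ord])
  }
  stats::cor(r, nb)
}

# plain double-loop Pearson cross-trial correlation matrix
oracle_cross_trial <- function(mat) {
  I <- nrow(mat)
  M <- matrix(NA_real_, I, I)
  for (i in seq_len(I)) {
    for (j in seq_len(I)) {
      a <- mat[i, ] - mean(mat[i, ])
      b <- mat[j, ] - mean(mat[j, ])
      da <- sqrt(sum(a^2))
      db <- sqrt(sum(b^2))
      M[i, j] <- if (da == 0 || db == 0) NA_real_ else sum(a * b) / (da * db)
    }
  }
  M
}

# spike-weighted average, written out longhand
oracle_weighted <- function(p, n) {
  num <- 0
  den <- 0
  for (i in seq_along(p)) {
    if (is.finite(p[i]) && n[i] > 0) {
      num <- num + n[i] * p[i]
      den <- den + n[i]
    }
  }
  if (den == 0) NA_real_ else num / den
}

# direct atan2 evaluation of the circular decoder
oracle_atan2_predict <- function(b1, b2, S) {
  out <- numeric(nrow(S))
  for (t in seq_len(nrow(S))) {
    u <- sum(b1 * S[t, ])
    v <- sum(b2 * S[t, ])
    out[t] <- atan2(u, v) %% (2 * pi)
  }
  out
}

# small shared sessions (built once per test run)
small_sm_config <- function(seed = 11L, ...) {
  synth_config(seed = seed,
               n_dark = 6L, n_blockA = 12L, n_blockB = 12L,
               n_alternation = 12L, n_gain = 2L,
               cell_counts = c(grid = 4L, ngs = 2L, speed_pos = 2L,
                               speed_neg = 1L, fs_in = 1L, untuned = 2L),
               speed_mean = 50, ...)
}

small_sm_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_session(small_sm_config())
    cache
  }
})

# two-map population tensor with well-separated centroids
make_two_map_tensor <- function(I = 30, J = 20, K = 8, noise = 0.05,
                                seed = 1, labels = NULL) {
  set.seed(seed)
  if (is.null(labels)) labels <- rep(1:2, length.out = I)
  n_maps <- max(labels)
  cen <- array(runif(n_maps * J * K), dim = c(n_maps, J, K))
  X <- array(0, dim = c(I, J, K))
  for (i in seq_len(I)) {
    X[i, , ] <- cen[labels[i], , ] + rnorm(J * K, 0, noise)
  }
  attr(X, "true_labels") <- labels
  X
}
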