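#' Map track position to a circular angle
#' @param position Position in cm.
#' @param track_length Track length in cm.
#' @return Angle in `[0, 2*pi)`.
#' @export
position_to_angle <- function(position, track_length = 400) {
  (position / track_length * 2 * pi) %% (2 * pi)
}

#' Per-frame spike count matrix
#' @param spikes Spike table (`unit`, `t`).
#' @param frames `session_frames`.
#' @param units Unit ids to include (columns), default all present.
#' @return Frames x units count matrix.
#' @export
spike_count_matrix <- function(spikes, frames, units = NULL) {
  if (is.null(units)) units <- sort(unique(spikes$unit))
  S <- matrix(0L, nrow(frames), length(units),
              dimnames = list(NULL, units))
  idx <- findInterval(spikes$t, frames$t)
  ok <- idx >= 1L & idx <= nrow(frames)
  u <- match(spikes$unit[ok], units)
  keep <- !is.na(u)
  tab <- table(factor(idx[ok][keep], levels = seq_len(nrow(frames))),
               factor(u[keep], levels = seq_along(units)))
  S[] <- as.integer(tab)
  S
}

#' Aggregate frame counts into decoding time bins
#'
#' Sums spike counts over consecutive non-overlapping windows of
#' `bin_frames` frames and takes the circular mean of the position angles in
#' each window. Single-frame counts at 50 Hz are too sparse to decode from;
#' 200 ms bins (the default at 50 Hz) are a practical observation unit.
#'
#' @param counts Frames x neurons count matrix.
#' @param angles Position angle per frame.
#' @param bin_frames Frames per decoding bin (default 10).
#' @return List with `counts` (binned), `angles` (circular means).
#' @export
bin_decoding_data <- function(counts, angles, bin_frames = 10) {
  TT <- nrow(counts)
  n_bins <- TT %/% bin_frames
  if (n_bins < 1L) stop("fewer frames than one decoding bin")
  grp <- rep(seq_len(n_bins), each = bin_frames)
  use <- seq_len(n_bins * bin_frames)
  Sb <- rowsum(counts[use, , drop = FALSE], grp)
  dimnames(Sb) <- NULL
  ang <- vapply(seq_len(n_bins), function(g) {
    a <- angles[use][grp == g]
    atan2(mean(sin(a)), mean(cos(a))) %% (2 * pi)
  }, numeric(1L))
  list(counts = Sb, angles = ang)
}

#' Fit the circular-linear position decoder
#'
#' Fits the spherically projected multivariate linear model
#' `y_hat_t = atan2(sum_n b1_n s_nt, sum_n b2_n s_nt)` that predicts the
#' circular track position from population spike counts. Each neuron
#' contributes one coefficient pair `(b1, b2)`. Coefficients are initialized
#' by ridge least squares of `(sin y, cos y)` on the counts and then refined
#' by maximizing the mean cosine of the angular error,
#' `mean(cos(y - y_hat))`, with a small ridge penalty for stability
#' (BFGS with analytic gradients; deterministic given the data).
#'
#' @param counts Time bins x neurons spike-count matrix (stationary bins
#'   already excluded).
#' @param angles True position angles `y_t` in `[0, 2*pi)`.
#' @param ridge Ridge penalty (default 1e-6).
#' @param max_iter Optimizer iteration cap (default 500).
#' @param tol Convergence tolerance (default 1e-6).
#' @param refine `FALSE` keeps the closed-form least-squares fit (the
#'   documented fallback estimator).
#' @return A `decoder_model` list: `beta1`, `beta2` (per-neuron), `converged`,
#'   `iterations`, `objective` (mean cosine on the training set).
#' @export
fit_circular_decoder <- function(counts, angles, ridge = 1e-6,
                                 max_iter = 500, tol = 1e-6, refine = TRUE) {
  counts <- as.matrix(counts)
  if (all(counts == 0)) stop("all-zero spike count matrix")
  stopifnot(nrow(counts) == length(angles))
  N <- ncol(counts)
  G <- crossprod(counts) + diag(ridge + 1e-10, N)
  beta1 <- solve(G, crossprod(counts, sin(angles)))
  beta2 <- solve(G, crossprod(counts, cos(angles)))
  theta0 <- c(beta1, beta2)
  iterations <- 0L
  converged <- TRUE
  if (refine) {
    negloss <- function(th) {
      b1 <- th[seq_len(N)]
      b2 <- th[N + seq_len(N)]
      u <- counts %*% b1
      v <- counts %*% b2
      r <- sqrt(u^2 + v^2)
      ok <- r > 0
      -(mean(cos(angles[ok] - atan2(u[ok], v[ok]))) -
          ridge * sum(th^2))
    }
    grad <- function(th) {
      b1 <- th[seq_len(N)]
      b2 <- th[N + seq_len(N)]
      u <- as.vector(counts %*% b1)
      v <- as.vector(counts %*% b2)
      r2 <- u^2 + v^2
      ok <- r2 > 0
      s <- sin(angles - atan2(u, v))
      w <- ifelse(ok, s / r2, 0)
      n_ok <- max(1L, sum(ok))
      g1 <- crossprod(counts, w * v) / n_ok
      g2 <- crossprod(counts, -w * u) / n_ok
      -(c(g1, g2) - 2 * ridge * th)
    }
    opt <- stats::optim(theta0, negloss, grad, method = "BFGS",
                        control = list(maxit = max_iter, reltol = tol))
    theta0 <- opt$par
    iterations <- opt$counts[["function"]]
    converged <- opt$convergence == 0L
  }
  structure(list(beta1 = theta0[seq_len(N)], beta2 = theta0[N + seq_len(N)],
                 converged = converged, iterations = iterations,
                 objective = NA_real_),
            class = "decoder_model")
}

#' Predict positions from a fitted decoder
#'
#' Evaluates `atan2(counts %*% beta1, counts %*% beta2)`, wrapped to
#' `[0, 2*pi)`. Time bins with an all-zero count vector have an undefined
#' prediction (`NA`) and are excluded from scoring.
#'
#' @param model A `decoder_model`.
#' @param counts Time bins x neurons count matrix (neuron order as in
#'   fitting).
#' @return Predicted angles, `NA` where undefined.
#' @export
predict_position <- function(model, counts) {
  counts <- as.matrix(counts)
  u <- as.vector(counts %*% model$beta1)
  v <- as.vector(counts %*% model$beta2)
  out <- atan2(u, v) %% (2 * pi)
  out[rowSums(abs(counts)) == 0] <- NA_real_
  out
}

#' Cosine decoder score
#'
#' Mean of `cos(y - y_hat)` over time bins: 1 for perfect prediction, 0 in
#' expectation for uniformly random guesses on the circle, -1 for antipodal
#' predictions. Undefined predictions are excluded.
#'
#' @param y True angles.
#' @param y_hat Predicted angles.
#' @return Score in \[-1, 1\], `NA` for an empty test set.
#' @export
decoder_score <- function(y, y_hat) {
  ok <- is.finite(y) & is.finite(y_hat)
  if (!any(ok)) return(NA_real_)
  mean(cos(y[ok] - y_hat[ok]))
}

#' Down-sample training sets to matched statistics
#'
#' Greedy histogram matching: time bins are stratified by position bin and
#' speed quartile, and each training set is randomly subsampled so that all
#' sets hold the same number of bins per stratum (the minimum across sets).
#' This equalizes position coverage, running speed, and observation count
#' across training sets drawn from the same session.
#'
#' @param sets List of integer index vectors (time bins per training set).
#' @param angles Position angle per time bin.
#' @param speed Running speed per time bin.
#' @param n_pos_bins Position strata (default 10).
#' @param seed RNG seed.
#' @return List of down-sampled index vectors.
#' @export
downsample_match <- function(sets, angles, speed, n_pos_bins = 10,
                             seed = 1L) {
  set.seed(seed)
  pos_bin <- pmin(n_pos_bins,
                  floor(angles / (2 * pi) * n_pos_bins) + 1L)
  qs <- stats::quantile(speed, c(0.25, 0.5, 0.75))
  spd_bin <- findInterval(speed, qs) + 1L
  stratum <- paste(pos_bin, spd_bin)
  strata <- unique(stratum)
  out <- lapply(sets, function(s) integer(0))
  for (st in strata) {
    per_set <- lapply(sets, function(s) s[stratum[s] == st])
    n_min <- min(lengths(per_set))
    if (n_min == 0L) next
    for (i in seq_along(sets)) {
      pool <- per_set[[i]]
      out[[i]] <- c(out[[i]], sort(sample(pool, n_min)))
    }
  }
  lapply(out, sort)
}

#' Evaluate position decoding on a session
#'
#' For each repetition, fits the decoder on a randomly selected
#' `1 - holdout` fraction of running time bins and scores the held-out
#' fraction; also reports a spike-time shuffle control in which each
#' neuron's count series is independently circularly shifted in time
#' (destroying spatial firing patterns while keeping rates), approximating
#' chance performance.
#'
#' @param counts Time bins x neurons count matrix (running bins only).
#' @param angles True angles per time bin.
#' @param reps Repetitions (default 10).
#' @param holdout Test fraction (default 0.10).
#' @param seed RNG seed.
#' @param shuffle_control Compute the shuffle control (default TRUE).
#' @param min_shift Minimum circular shift for the control, in bins.
#' @return A `decode_eval` list: `scores` (per rep), `mean_score`,
#'   `shuffle_scores`, `mean_shuffle`, `reps`.
#' @export
evaluate_decoding <- function(counts, angles, reps = 10, holdout = 0.10,
                              seed = 1L, shuffle_control = TRUE,
                              min_shift = 1000L) {
  counts <- as.matrix(counts)
  TT <- nrow(counts)
  run_once <- function(S, rep_seed) {
    set.seed(rep_seed)
    test <- sample.int(TT, size = max(1L, round(holdout * TT)))
    train <- setdiff(seq_len(TT), test)
    fit <- fit_circular_decoder(S[train, , drop = FALSE], angles[train])
    decoder_score(angles[test],
                  predict_position(fit, S[test, , drop = FALSE]))
  }
  scores <- vapply(seq_len(reps), function(r)
    run_once(counts, child_seed(seed, r)), numeric(1L))
  shuffle_scores <- NULL
  if (shuffle_control) {
    min_shift <- min(min_shift, TT %/% 4L)
    shuffle_scores <- vapply(seq_len(reps), function(r) {
      set.seed(child_seed(seed, 500L + r))
      shifts <- sample(seq.int(min_shift, TT - min_shift),
                       ncol(counts), replace = TRUE)
      Ssh <- counts
      for (j in seq_len(ncol(counts))) {
        s <- shifts[j]
        Ssh[, j] <- c(counts[(TT - s + 1L):TT, j],
                      counts[seq_len(TT - s), j])
      }
      run_once(Ssh, child_seed(seed, 900L + r))
    }, numeric(1L))
  }
  structure(list(scores = scores, mean_score = mean(scores),
                 shuffle_scores = shuffle_scores,
                 mean_shuffle = if (is.null(shuffle_scores)) NA_real_ else
                   mean(shuffle_scores),
                 reps = reps),
            class = "decode_eval")
}
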