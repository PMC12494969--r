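#' Fit a factorized k-means model of the population tensor
#'
#' Approximates the normalized rate tensor `X[i, j, k]` by
#' `sum_r U[i, r] * V[r, j, k]`, where each row of `U` is a one-hot trial
#' assignment and each `V[r, , ]` slice is a spatial-map centroid (every
#' cell's tuning curve under map r) — k-means clustering of trials in
#' flattened bins-x-cells space. Optimization is Lloyd iteration with
#' k-means++-style seeding; the best of `restarts` runs (lowest squared
#' reconstruction error) is kept. Entries can be masked out (speckled
#' holdout): masked entries are ignored both in centroid updates (available
#' -entry means) and in assignment distances (mean squared deviation over a
#' trial's observed entries).
#'
#' @param tensor A `rate_tensor` (or 3-d array / trials x features matrix).
#' @param k Number of maps (model rank); `k = 1` returns the grand-centroid
#'   model.
#' @param restarts Independent seeded restarts (default 100).
#' @param seed RNG seed.
#' @param mask Optional logical array/matrix matching `tensor`; `FALSE`
#'   entries are held out of the fit.
#' @param max_iter Lloyd iteration cap per restart.
#' @return A `map_model` list: `k`, `assignments` (integer per trial),
#'   `centroids` (k x features matrix), `objective` (summed squared error on
#'   observed entries), `objective_trace` of the winning restart, `restarts`.
#' @export
fit_factorized_kmeans <- function(tensor, k, restarts = 100, seed = 1L,
                                  mask = NULL, max_iter = 100) {
  X <- if (is.matrix(tensor)) tensor else flatten_tensor(tensor)
  I <- nrow(X)
  if (k > I) stop("k must not exceed the number of trials (", I, ")")
  if (k < 1L) stop("k must be >= 1")
  W <- if (is.null(mask)) NULL else {
    m <- if (is.matrix(mask)) mask else matrix(mask, nrow = I)
    storage.mode(m) <- "double"
    m
  }
  Xo <- if (is.null(W)) X else X * W

  if (k == 1L) {
    cen <- if (is.null(W)) {
      matrix(colMeans(X), 1L)
    } else {
      cs <- colSums(W)
      matrix(ifelse(cs > 0, colSums(Xo) / cs, 0), 1L)
    }
    resid <- sweep(X, 2L, cen[1L, ])
    obj <- if (is.null(W)) sum(resid^2) else sum(resid^2 * W)
    return(structure(list(k = 1L, assignments = rep(1L, I), centroids = cen,
                          objective = obj, objective_trace = obj,
                          restarts = 1L),
                     class = "map_model"))
  }

  # squared distance of every trial to every centroid, mask-aware
  dist_to <- function(cen) {
    if (is.null(W)) {
      d <- outer(rowSums(X^2), rowSums(cen^2), "+") - 2 * X %*% t(cen)
      pmax(d, 0)
    } else {
      d <- matrix(0, I, nrow(cen))
      for (r in seq_len(nrow(cen))) {
        resid <- sweep(X, 2L, cen[r, ])^2 * W
        d[, r] <- rowSums(resid) / pmax(rowSums(W), 1)
      }
      d
    }
  }
  update_centroids <- function(assign) {
    cen <- matrix(0, k, ncol(X))
    for (r in seq_len(k)) {
      rows <- which(assign == r)
      if (!length(rows)) next
      if (is.null(W)) {
        cen[r, ] <- colMeans(X[rows, , drop = FALSE])
      } else {
        cs <- colSums(W[rows, , drop = FALSE])
        cen[r, ] <- ifelse(cs > 0,
                           colSums(Xo[rows, , drop = FALSE]) / cs, 0)
      }
    }
    cen
  }
  objective_of <- function(assign, cen) {
    resid <- X - cen[assign, , drop = FALSE]
    if (is.null(W)) sum(resid^2) else sum(resid^2 * W)
  }

  best <- NULL
  set.seed(seed)
  for (rs in seq_len(restarts)) {
    # k-means++ seeding on (masked) distances
    centers <- integer(k)
    centers[1L] <- sample.int(I, 1L)
    cen <- X[centers[1L], , drop = FALSE]
    if (k > 1L) {
      for (r in 2:k) {
        d2 <- apply(dist_to(cen), 1L, min)
        d2[centers[seq_len(r - 1L)]] <- 0
        p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / I, I)
        centers[r] <- sample.int(I, 1L, prob = p)
        cen <- X[centers[seq_len(r)], , drop = FALSE]
      }
    }
    assign <- max.col(-dist_to(cen), ties.method = "first")
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      cen <- update_centroids(assign)
      # refill empty clusters with the worst-fit trial
      d <- dist_to(cen)
      for (r in seq_len(k)) {
        if (!any(assign == r)) {
          far <- which.max(d[cbind(seq_len(I), assign)])
          assign[far] <- r
          cen <- update_centroids(assign)
          d <- dist_to(cen)
        }
      }
      new_assign <- max.col(-d, ties.method = "first")
      trace <- c(trace, objective_of(new_assign, cen))
      if (all(new_assign == assign)) {
        assign <- new_assign
        break
      }
      assign <- new_assign
    }
    obj <- objective_of(assign, cen)
    if (is.null(best) || obj < best$objective) {
      best <- list(k = as.integer(k), assignments = assign, centroids = cen,
                   objective = obj, objective_trace = trace,
                   restarts = restarts)
    }
  }
  structure(best, class = "map_model")
}

#' Reconstruct the flattened tensor from a map model
#' @param model A `map_model`.
#' @return Trials x features matrix `X_hat`.
#' @export
reconstruct_map_model <- function(model) {
  model$centroids[model$assignments, , drop = FALSE]
}

#' Select the number of spatial maps by silhouette maximization
#'
#' For each `k` in `2..k_max`, fits the factorized k-means model
#' (`restarts` restarts) on `reps` repetitions and computes the mean
#' silhouette score of the trial assignments (Euclidean distance on
#' flattened trial vectors). The `k` maximizing the repetition-mean
#' silhouette is selected. Whether the session supports any multi-map
#' structure at all (`k = 1`) is decided separately by [detect_one_map()].
#'
#' @param tensor A `rate_tensor` (or matrix).
#' @param k_max Maximum rank swept (default 4).
#' @param reps Repetitions per k (default 10; new restarts each).
#' @param restarts Restarts per fit (default 100).
#' @param seed RNG seed.
#' @return List with `k_star`, `silhouette` (k x reps matrix of mean
#'   silhouette scores), `mean_silhouette` (per k).
#' @export
select_k <- function(tensor, k_max = 4, reps = 10, restarts = 100,
                     seed = 1L) {
  X <- if (is.matrix(tensor)) tensor else flatten_tensor(tensor)
  if (nrow(X) < 4L) stop("need at least 4 trials to select k")
  k_max <- min(k_max, nrow(X) - 1L)
  D <- stats::dist(X)
  ks <- 2:k_max
  sil <- matrix(NA_real_, length(ks), reps,
                dimnames = list(paste0("k", ks), NULL))
  for (ki in seq_along(ks)) {
    for (rp in seq_len(reps)) {
      fit <- fit_factorized_kmeans(X, ks[ki], restarts = restarts,
                                   seed = child_seed(seed, ki * 1000L + rp))
      if (length(unique(fit$assignments)) < 2L) next
      sw <- cluster::silhouette(fit$assignments, D)
      sil[ki, rp] <- mean(sw[, "sil_width"])
    }
  }
  mean_sil <- rowMeans(sil, na.rm = TRUE)
  list(k_star = ks[which.max(mean_sil)], silhouette = sil,
       mean_silhouette = mean_sil)
}

#' Speckled-holdout cross-validation of the map model
#'
#' Randomly censors `holdout` of the tensor entries (uniformly over trials,
#' bins and cells), fits the masked k-means model on the remaining entries,
#' and scores the uncentered R-squared on the censored entries:
#' `1 - sum((x - xhat)^2) / sum(x^2)`. Repeated over `replicates` mask
#' draws.
#'
#' @param tensor A `rate_tensor` (or matrix).
#' @param k Model rank.
#' @param holdout Fraction censored (default 0.10).
#' @param replicates Number of mask draws (default 10).
#' @param restarts Restarts per fit.
#' @param seed RNG seed.
#' @return List with `test_r2` (per replicate), `train_r2`, `masks` (list of
#'   logical matrices, `FALSE` = held out).
#' @export
speckled_cv <- function(tensor, k, holdout = 0.10, replicates = 10,
                        restarts = 10, seed = 1L) {
  X <- if (is.matrix(tensor)) tensor else flatten_tensor(tensor)
  n <- length(X)
  test_r2 <- numeric(replicates)
  train_r2 <- numeric(replicates)
  masks <- vector("list", replicates)
  for (rp in seq_len(replicates)) {
    set.seed(child_seed(seed, 77L + rp))
    held <- sample.int(n, size = round(holdout * n))
    W <- matrix(TRUE, nrow(X), ncol(X))
    W[held] <- FALSE
    fit <- fit_factorized_kmeans(X, k, restarts = restarts,
                                 seed = child_seed(seed, 177L + rp),
                                 mask = W)
    Xhat <- reconstruct_map_model(fit)
    test_r2[rp] <- uncentered_r2(X[!W], Xhat[!W])
    train_r2[rp] <- uncentered_r2(X[W], Xhat[W])
    masks[[rp]] <- W
  }
  list(test_r2 = test_r2, train_r2 = train_r2, masks = masks)
}

uncentered_r2 <- function(x, xhat) {
  denom <- sum(x^2)
  if (denom == 0) return(NA_real_)
  1 - sum((x - xhat)^2) / denom
}

#' Rotation shuffle of the population tensor
#'
#' Left-multiplies the trial-mode unfolding of the tensor by a random
#' orthogonal matrix. This preserves the overall data norm and the
#' correlations between neurons and position bins but destroys the one-hot
#' cluster structure a k-means model could exploit; it is the null control
#' for [detect_one_map()].
#'
#' @param tensor A `rate_tensor` (or matrix).
#' @param seed RNG seed.
#' @return Object of the same shape and class as the input.
#' @export
rotation_shuffle <- function(tensor, seed = 1L) {
  X <- if (is.matrix(tensor)) tensor else flatten_tensor(tensor)
  I <- nrow(X)
  set.seed(seed)
  qr_d <- qr(matrix(stats::rnorm(I * I), I, I))
  Q <- qr.Q(qr_d)
  # fix signs so Q is Haar-distributed
  Q <- Q %*% diag(sign(diag(qr.R(qr_d))), I)
  Y <- Q %*% X
  if (is.matrix(tensor)) return(Y)
  out <- array(Y, dim = dim(tensor))
  attributes(out) <- attributes(tensor)
  out
}

#' Detect one-map sessions
#'
#' A session is a one-map session when the cross-validated model performance
#' at the selected k on the real tensor does not exceed that on the
#' rotation-shuffled tensor (paired one-sided Wilcoxon signed-rank test,
#' alpha 0.05). Such sessions show no detectable trial clustering.
#'
#' @param real_scores Per-replicate test R-squared on the real tensor.
#' @param shuffled_scores Paired per-replicate scores on the shuffled
#'   tensor.
#' @param alpha Significance level (default 0.05).
#' @return List with `one_map` (TRUE when the test fails to reject),
#'   `p_value`, `underpowered` (TRUE with < 5 replicate pairs).
#' @export
detect_one_map <- function(real_scores, shuffled_scores, alpha = 0.05) {
  stopifnot(length(real_scores) == length(shuffled_scores))
  underpowered <- length(real_scores) < 5L
  if (all(real_scores == shuffled_scores)) {
    return(list(one_map = TRUE, p_value = 1, underpowered = underpowered))
  }
  p <- suppressWarnings(
    stats::wilcox.test(real_scores, shuffled_scores, paired = TRUE,
                       alternative = "greater")$p.value)
  list(one_map = !(p < alpha), p_value = p, underpowered = underpowered)
}

#' Truncated-SVD comparison at matched rank
#'
#' Cross-validated test performance of a rank-`k` truncated SVD of the
#' trial-mode unfolding on the same speckled-holdout masks as the k-means
#' model. The tSVD allows trials to mix maps continuously, so comparable
#' performance of the (more constrained) k-means model indicates discrete
#' maps. Held-out entries are fit by EM-style imputation: initialize masked
#' entries at the observed column means, then alternate rank-`k`
#' reconstruction and refill until convergence.
#'
#' @param tensor A `rate_tensor` (or matrix).
#' @param k Rank.
#' @param masks List of logical matrices (`FALSE` = held out), e.g., from
#'   [speckled_cv()].
#' @param max_iter,tol Imputation iteration controls.
#' @return List with `test_r2` per mask.
#' @export
tsvd_comparison <- function(tensor, k, masks, max_iter = 100, tol = 1e-7) {
  X <- if (is.matrix(tensor)) tensor else flatten_tensor(tensor)
  test_r2 <- vapply(masks, function(W) {
    Xw <- X
    cm <- vapply(seq_len(ncol(X)), function(j) {
      obs <- W[, j]
      if (any(obs)) mean(X[obs, j]) else 0
    }, numeric(1L))
    Xw[!W] <- cm[col(X)[!W]]
    prev <- Inf
    for (it in seq_len(max_iter)) {
      sv <- svd(Xw, nu = k, nv = k)
      Xhat <- sv$u %*% (diag(sv$d[seq_len(k)], k) %*% t(sv$v))
      delta <- sum((Xhat[!W] - Xw[!W])^2)
      Xw[!W] <- Xhat[!W]
      if (is.finite(prev) && abs(prev - delta) < tol) break
      prev <- delta
    }
    uncentered_r2(X[!W], Xhat[!W])
  }, numeric(1L))
  list(test_r2 = test_r2)
}

#' Canonical relabeling of spatial maps
#'
#' Raw k-means labels are arbitrary; this relabels them deterministically.
#' Two-context (SM) sessions: map 1 is the map with the most Block A trials;
#' for k = 3-4, map 2 is the remaining map with the most Block B trials; for
#' k = 4, map 3 is the remaining map with more trials before the midpoint of
#' the context-sorted alternation phase. Ties resolve to the lowest raw
#' label. Foraging (RF) sessions: maps are ordered by mean running speed,
#' slowest first.
#'
#' @param model A `map_model`.
#' @param task `"SM"` or `"RF"`.
#' @param trial_info Trial metadata aligned to the model's trials (needs
#'   `context` and `phase` for SM).
#' @param trial_speeds Mean running speed per trial (RF only).
#' @return A `map_labeling` list: `labels` (relabeled map id per trial),
#'   `raw_to_new` (named mapping), `model`.
#' @export
relabel_maps <- function(model, task = c("SM", "RF"), trial_info = NULL,
                         trial_speeds = NULL) {
  task <- match.arg(task)
  raw <- model$assignments
  ids <- sort(unique(raw))
  k <- length(ids)
  new_of <- stats::setNames(rep(NA_integer_, k), ids)
  if (task == "RF") {
    stopifnot(!is.null(trial_speeds))
    sp <- vapply(ids, function(r) mean(trial_speeds[raw == r]), numeric(1L))
    ord <- ids[order(sp, ids)]
    new_of[as.character(ord)] <- seq_len(k)
  } else {
    stopifnot(!is.null(trial_info))
    remaining <- ids
    nA <- vapply(ids, function(r)
      sum(raw == r & trial_info$phase == "block" &
            trial_info$context == "A"), numeric(1L))
    names(nA) <- ids
    pick <- function(score, pool) {
      pool[order(-score[as.character(pool)], pool)][1L]
    }
    m1 <- pick(nA, remaining)
    new_of[as.character(m1)] <- 1L
    remaining <- setdiff(remaining, m1)
    if (length(remaining)) {
      nB <- vapply(ids, function(r)
        sum(raw == r & trial_info$phase == "block" &
              trial_info$context == "B"), numeric(1L))
      names(nB) <- ids
      m2 <- pick(nB, remaining)
      new_of[as.character(m2)] <- 2L
      remaining <- setdiff(remaining, m2)
    }
    if (length(remaining) > 1L) {
      alt <- which(trial_info$phase == "alternation")
      mid <- if (length(alt)) alt[1L] - 1L + length(alt) / 2 else
        length(raw) / 2
      early <- vapply(ids, function(r)
        sum(raw == r & seq_along(raw) <= mid &
              trial_info$phase == "alternation"), numeric(1L))
      names(early) <- ids
      m3 <- pick(early, remaining)
      new_of[as.character(m3)] <- 3L
      remaining <- setdiff(remaining, m3)
    }
    if (length(remaining)) {
      new_of[as.character(sort(remaining))] <-
        seq.int(k - length(remaining) + 1L, k)
    }
  }
  structure(list(labels = unname(new_of[as.character(raw)]),
                 raw_to_new = new_of, model = model),
            class = "map_labeling")
}

#' Assign a VR-context identity to each spatial map
#'
#' Map 1 represents context A and map 2 context B (by construction of the
#' relabeling). Additional maps (3, 4) are assigned to the context whose
#' block trials they resemble more: the argmax of mean pairwise network
#' similarity to Block A vs Block B trials. Ties go to context A with a
#' warning. Multiple maps may share one context.
#'
#' @param labeling A `map_labeling` (SM task).
#' @param network_matrix Network-wide trial similarity matrix.
#' @param trial_info Trial metadata (needs `context`, `phase`).
#' @return `labeling` extended with `context_of_map` (named "A"/"B" per map
#'   label) and `trial_identity` (per-trial context identity).
#' @export
assign_context_identity <- function(labeling, network_matrix, trial_info) {
  labs <- labeling$labels
  ids <- sort(unique(labs))
  ctx <- stats::setNames(rep(NA_character_, length(ids)), ids)
  ctx["1"] <- "A"
  if ("2" %in% names(ctx)) ctx["2"] <- "B"
  extra <- ids[ids > 2L]
  if (length(extra)) {
    blockA <- which(trial_info$phase == "block" & trial_info$context == "A")
    blockB <- which(trial_info$phase == "block" & trial_info$context == "B")
    for (r in extra) {
      tr <- which(labs == r)
      simA <- group_similarity(network_matrix, tr, blockA)
      simB <- group_similarity(network_matrix, tr, blockB)
      if (!is.finite(simA) && !is.finite(simB)) {
        warning("map ", r, ": no defined similarity to either block; ",
                "assigned context A")
        ctx[as.character(r)] <- "A"
      } else if (isTRUE(simA == simB)) {
        warning("map ", r, ": tied block similarity; assigned context A")
        ctx[as.character(r)] <- "A"
      } else {
        ctx[as.character(r)] <-
          if (isTRUE(simB > simA)) "B" else "A"
      }
    }
  }
  labeling$context_of_map <- ctx
  labeling$trial_identity <- unname(ctx[as.character(labs)])
  labeling
}

#' Remap events and remapping frequency
#'
#' A remap is a change of map label between consecutive trials (in
#' chronological order). The remapping frequency of a phase is its remap
#' count divided by its trial count.
#'
#' @param labels Integer map label per trial, chronological.
#' @return Logical vector of length `length(labels) - 1`; `TRUE` where the
#'   label changed.
#' @export
detect_remaps <- function(labels) {
  if (length(labels) < 2L) return(logical(0))
  diff(labels) != 0
}

#' @rdname detect_remaps
#' @param phase Optional factor/character per trial; frequencies are
#'   returned per phase (remaps are counted within consecutive same-phase
#'   pairs) as well as overall.
#' @export
remap_frequency <- function(labels, phase = NULL) {
  remaps <- detect_remaps(labels)
  overall <- sum(remaps) / length(labels)
  if (is.null(phase)) return(list(overall = overall))
  per <- vapply(unique(phase), function(ph) {
    idx <- which(phase == ph)
    if (length(idx) < 2L) return(0)
    pairs <- idx[-length(idx)]
    sum(remaps[pairs[phase[pairs + 1L] == ph]]) / length(idx)
  }, numeric(1L))
  names(per) <- unique(phase)
  list(overall = overall, per_phase = per)
}

#' Context alignment of spatial maps
#'
#' A trial is aligned when its map's context identity matches the displayed
#' VR context. Returns per-trial flags and aligned fractions overall and
#' per phase. Chance level under independent uniform binary map assignment
#' is 0.5.
#'
#' @param trial_identity Per-trial map context identity ("A"/"B").
#' @param context Per-trial VR context.
#' @param phase Optional per-trial phase labels.
#' @return List with `aligned` (logical per trial), `fraction`, and
#'   `per_phase` fractions when `phase` is given.
#' @export
context_alignment <- function(trial_identity, context, phase = NULL) {
  stopifnot(length(trial_identity) == length(context))
  aligned <- trial_identity == context
  out <- list(aligned = aligned, fraction = mean(aligned))
  if (!is.null(phase)) {
    out$per_phase <- vapply(unique(phase), function(ph)
      mean(aligned[phase == ph]), numeric(1L))
    names(out$per_phase) <- unique(phase)
  }
  out
}
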