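#' Build the normalized population rate tensor
#'
#' Stacks per-cell trial-by-bin firing rate matrices (smoothed, SD 5 cm)
#' into an I x J x K tensor and min-max rescales each cell separately to
#' [0, 1], so high-rate neurons do not wash out low-rate neurons in
#' population analyses. Dark and gain trials are omitted. For the
#' two-context task the alternation-phase trials can be stably sorted by
#' context (chronological order preserved within context). The tensor can be
#' restricted to the front or back half of the track.
#'
#' @param rate_list List of `trial_rate_matrix` objects (one per cell, equal
#'   trial sets).
#' @param trial_info Data.frame with `trial`, `context`, `trial_type` for the
#'   session.
#' @param sort_alternation Stable-sort alternation trials by context (trials
#'   after both blocks; default FALSE).
#' @param half `"full"`, `"front"` (bins below the track midpoint) or
#'   `"back"`.
#' @param exclude_types Trial types to drop (default dark and gain).
#' @return A `rate_tensor`: 3-d array `I x J x K` with attributes
#'   `trial_info` (rows aligned to the first dimension, with a `phase`
#'   column: block / alternation / other) and `half`. Cells with a constant
#'   rate (max = min) are kept as all-zero.
#' @export
normalize_tensor <- function(rate_list, trial_info,
                             sort_alternation = FALSE,
                             half = c("full", "front", "back"),
                             exclude_types = c("dark", "gain")) {
  half <- match.arg(half)
  stopifnot(length(rate_list) >= 1L)
  trials <- rate_list[[1L]]$trials
  info <- trial_info[match(trials, trial_info$trial), , drop = FALSE]
  keep <- !(info$trial_type %in% exclude_types)
  info <- info[keep, , drop = FALSE]
  if (is.null(info$phase)) {
    # fall back to inferring the phase: the two leading single-context runs
    # are blocks, everything after the first return to context A is
    # alternation
    info$phase <- "other"
    if (nrow(info)) {
      ctx <- info$context
      first_b <- match("B", ctx)
      if (!is.na(first_b)) {
        info$phase[seq_len(nrow(info))] <- "block"
        back_to_a <- which(ctx == "A" & seq_along(ctx) > first_b)
        if (length(back_to_a)) {
          info$phase[seq(back_to_a[1L], nrow(info))] <- "alternation"
        }
      }
    }
  } else {
    info$phase[info$phase %in% c("blockA", "blockB")] <- "block"
  }
  ord <- seq_len(nrow(info))
  if (sort_alternation && any(info$phase == "alternation")) {
    alt <- which(info$phase == "alternation")
    ord <- c(setdiff(ord, alt), alt[order(info$context[alt])])
  }
  info <- info[ord, , drop = FALSE]
  n_bins <- ncol(rate_list[[1L]]$values)
  j_idx <- switch(half,
                  full = seq_len(n_bins),
                  front = seq_len(n_bins %/% 2L),
                  back = seq.int(n_bins %/% 2L + 1L, n_bins))
  X <- array(0, dim = c(nrow(info), length(j_idx), length(rate_list)))
  row_sel <- match(info$trial, trials)
  for (k in seq_along(rate_list)) {
    v <- rate_list[[k]]$values[row_sel, j_idx, drop = FALSE]
    v[!is.finite(v)] <- 0
    lo <- min(v)
    hi <- max(v)
    X[, , k] <- if (hi > lo) (v - lo) / (hi - lo) else 0
  }
  structure(X, class = "rate_tensor", trial_info = info, half = half)
}

#' Flatten a rate tensor to trials x (bins * cells)
#' @param tensor A `rate_tensor` (or plain 3-d array).
#' @return Matrix with one row per trial.
#' @export
flatten_tensor <- function(tensor) {
  d <- dim(tensor)
  matrix(tensor, nrow = d[1L], ncol = d[2L] * d[3L])
}

#' Cross-trial correlation matrix of one cell
#'
#' Correlation of the spatial firing vectors of every pair of trials (mean
#' rate subtracted per trial; normalized cross-correlation at zero spatial
#' lag, i.e., the Pearson correlation of the two vectors). Zero-variance
#' trials give missing entries.
#'
#' @param mat Trials x bins matrix (e.g., one cell slice `tensor[, , k]`).
#' @return Symmetric I x I matrix with unit diagonal where defined.
#' @export
cross_trial_matrix <- function(mat) {
  stopifnot(nrow(mat) >= 2L)
  mat[!is.finite(mat)] <- NA_real_
  sds <- apply(mat, 1L, stats::sd, na.rm = TRUE)
  M <- suppressWarnings(stats::cor(t(mat), use = "pairwise.complete.obs"))
  M[sds == 0 | !is.finite(sds), ] <- NA_real_
  M[, sds == 0 | !is.finite(sds)] <- NA_real_
  diag(M)[is.finite(sds) & sds > 0] <- 1
  M
}

# mean over the upper triangle of M restricted to rows `a` and columns `b`
group_similarity <- function(M, a, b) {
  sub <- M[a, b, drop = FALSE]
  if (identical(a, b)) {
    if (length(a) < 2L) return(NA_real_)
    vals <- sub[upper.tri(sub)]
  } else {
    vals <- as.vector(sub)
  }
  if (!length(vals) || all(!is.finite(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Moving-neighborhood trial stability
#'
#' For each trial of a phase, the mean correlation with its 5 nearest trials
#' (by trial order within the phase; the neighborhood is truncated at the
#' phase edges), averaged over trials.
#'
#' @param M Cross-trial correlation matrix.
#' @param trials Integer indices (rows of `M`) forming the phase, in order.
#' @param n_neighbors Neighborhood size (default 5).
#' @return Mean stability score, `NA` when fewer than 2 trials.
#' @export
trial_stability <- function(M, trials = seq_len(nrow(M)), n_neighbors = 5) {
  m <- length(trials)
  if (m < 2L) return(NA_real_)
  per_trial <- vapply(seq_len(m), function(i) {
    d <- abs(seq_len(m) - i)
    ord <- order(d, seq_len(m))
    nb <- ord[ord != i][seq_len(min(n_neighbors, m - 1L))]
    vals <- M[trials[i], trials[nb]]
    if (all(!is.finite(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1L))
  if (all(!is.finite(per_trial))) return(NA_real_)
  mean(per_trial, na.rm = TRUE)
}

#' Within-map trial stability
#'
#' [trial_stability()] computed within each clustered spatial map (maps with
#' at least 2 trials) and averaged across maps; controls for stability loss
#' caused by discrete remapping events.
#'
#' @param M Cross-trial correlation matrix.
#' @param map_labels Integer map label per trial (row of `M`).
#' @return Mean across maps, `NA` when every map is a singleton.
#' @export
within_map_stability <- function(M, map_labels) {
  per_map <- vapply(unique(map_labels), function(r) {
    tr <- which(map_labels == r)
    if (length(tr) < 2L) return(NA_real_)
    trial_stability(M, tr)
  }, numeric(1L))
  if (all(!is.finite(per_map))) return(NA_real_)
  mean(per_map, na.rm = TRUE)
}

#' Context-similarity ratios
#'
#' `similarity_ratio_block()` compares context-matched to context-mismatched
#' trial similarity within the block phase:
#' `mean(AxA, BxB) / mean(AxB)`. `similarity_ratio_alt()` compares
#' alternation trials (A', B') to block trials:
#' `mean(AxA', BxB') / mean(AxB', BxA')`. Both equal 1 when context-matched
#' firing is no more similar than context-mismatched firing; values > 1
#' indicate context-specific spatial firing.
#'
#' @param M Cross-trial correlation matrix.
#' @param A,B Row indices of the Block A / Block B trials.
#' @param A_alt,B_alt Row indices of the alternation-phase A' / B' trials.
#' @return The ratio, or `NA` (flagged via attribute `degenerate`) when the
#'   mismatched mean is not positive.
#' @export
similarity_ratio_block <- function(M, A, B) {
  matched <- mean(c(group_similarity(M, A, A), group_similarity(M, B, B)),
                  na.rm = TRUE)
  mismatched <- group_similarity(M, A, B)
  ratio_or_flag(matched, mismatched)
}

#' @rdname similarity_ratio_block
#' @export
similarity_ratio_alt <- function(M, A, B, A_alt, B_alt) {
  matched <- mean(c(group_similarity(M, A, A_alt),
                    group_similarity(M, B, B_alt)), na.rm = TRUE)
  mismatched <- mean(c(group_similarity(M, A, B_alt),
                       group_similarity(M, B, A_alt)), na.rm = TRUE)
  ratio_or_flag(matched, mismatched)
}

ratio_or_flag <- function(matched, mismatched) {
  if (!is.finite(mismatched) || mismatched <= 0) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  matched / mismatched
}

#' Rate remapping magnitude
#'
#' Percent change in the peak firing rate between the trial-averaged
#' normalized spatial firing vectors of Block B vs Block A:
#' `100 * (peak_B - peak_A) / peak_A`.
#'
#' @param cell_mat Trials x bins normalized rates of one cell (a tensor
#'   slice).
#' @param A,B Row indices of the two blocks.
#' @return Percent change, `NA` when the Block A peak is 0.
#' @export
rate_remapping_pct <- function(cell_mat, A, B) {
  pa <- max(colMeans(cell_mat[A, , drop = FALSE]))
  pb <- max(colMeans(cell_mat[B, , drop = FALSE]))
  if (pa == 0) return(NA_real_)
  100 * (pb - pa) / pa
}

#' Spatial dissimilarity (global remapping magnitude)
#'
#' One minus the cosine similarity between the trial-averaged normalized
#' spatial firing vectors of the two blocks: 0 for identical firing
#' patterns, 1 for orthogonal representations.
#'
#' @inheritParams rate_remapping_pct
#' @return Dissimilarity in \[0, 2\] (typically \[0, 1\] for non-negative
#'   rates), `NA` when either mean vector is zero.
#' @export
spatial_dissimilarity <- function(cell_mat, A, B) {
  va <- colMeans(cell_mat[A, , drop = FALSE])
  vb <- colMeans(cell_mat[B, , drop = FALSE])
  na <- sqrt(sum(va^2))
  nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) return(NA_real_)
  1 - sum(va * vb) / (na * nb)
}

#' Network-wide trial similarity matrix
#'
#' Correlation between the flattened (bins x cells) population vectors of
#' every pair of trials. Population analyses require at least `min_cells`
#' co-recorded cells of the relevant type; smaller sessions are flagged
#' ineligible.
#'
#' @param tensor A `rate_tensor` restricted to the relevant cells.
#' @param min_cells Eligibility gate (default 10).
#' @return Symmetric I x I correlation matrix, or an error when the cell
#'   count gate fails.
#' @export
network_similarity_matrix <- function(tensor, min_cells = 10) {
  d <- dim(tensor)
  if (d[3L] < min_cells) {
    stop("session ineligible: only ", d[3L], " cells (need >= ", min_cells,
         ")")
  }
  cross_trial_matrix(flatten_tensor(tensor))
}

#' Remapping coordination of one unit with the network
#'
#' Correlation between the upper-triangle entries of a unit's cross-trial
#' correlation matrix and the network-wide similarity matrix assembled from
#' the remaining co-recorded units (leave-one-out).
#'
#' @param unit_matrix Cross-trial matrix of the unit.
#' @param network_matrix Network similarity matrix computed without the
#'   unit.
#' @return Correlation over defined trial-pair entries.
#' @export
remapping_coordination <- function(unit_matrix, network_matrix) {
  stopifnot(all(dim(unit_matrix) == dim(network_matrix)))
  ut <- upper.tri(unit_matrix)
  safe_cor(unit_matrix[ut], network_matrix[ut])
}

#' Gain-manipulation response magnitude
#'
#' Difference between the mean pairwise similarity within a context's
#' alternation trials before the gain change and the mean similarity of
#' before x after trial pairs (within baseline minus across gain change),
#' using a pre set matched in trial count to the post set. Larger values
#' mean a stronger response to the gain manipulation.
#'
#' @param M Cross-trial correlation matrix.
#' @param pre Row indices of the context's pre-gain alternation trials
#'   (chronological; the last `length(post)` are used).
#' @param post Row indices of the context's gain trials.
#' @return List with `magnitude`, `n_matched`; `NA` magnitude when `post` is
#'   empty or fewer than 2 matched pre trials exist.
#' @export
gain_response_magnitude <- function(M, pre, post) {
  if (!length(post)) return(list(magnitude = NA_real_, n_matched = 0L))
  n <- min(length(pre), length(post))
  if (n < 2L) return(list(magnitude = NA_real_, n_matched = n))
  pre_m <- pre[seq.int(length(pre) - n + 1L, length(pre))]
  within <- group_similarity(M, pre_m, pre_m)
  across <- group_similarity(M, pre_m, post)
  list(magnitude = within - across, n_matched = n)
}
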