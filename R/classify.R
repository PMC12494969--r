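#' Quality-control filter for sorted units
#'
#' Removes clusters failing any of the standard waveform/stability rules:
#' signal-to-noise ratio < 1.0, mean firing rate < 0.10 Hz, repolarization
#' slope < 0, distance > 3200 um from the probe tip, halfwidth > 0.30 ms, or
#' a spike count not greater than 350. Sessions retaining fewer than 10
#' units are flagged for exclusion.
#'
#' @param units Unit metadata data.frame with columns `snr`, `mean_rate`,
#'   `repolarization_slope`, `tip_distance`, `halfwidth_ms`, `n_spikes`.
#' @param min_units Minimum surviving units for an eligible session.
#' @return List with `units` (retained rows), `excluded` (removed rows) and
#'   `session_excluded` (logical).
#' @export
qc_filter_units <- function(units, min_units = 10) {
  bad <- units$snr < 1.0 |
    units$mean_rate < 0.10 |
    units$repolarization_slope < 0 |
    units$tip_distance > 3200 |
    units$halfwidth_ms > 0.30 |
    units$n_spikes <= 350
  bad[is.na(bad)] <- TRUE
  keep <- units[!bad, , drop = FALSE]
  list(units = keep, excluded = units[bad, , drop = FALSE],
       session_excluded = nrow(keep) < min_units)
}

#' Split units into putative fast-spiking interneurons and excitatory cells
#'
#' A unit is a putative fast-spiking interneuron (IN) when its waveform
#' duration is < 0.35 ms or its mean firing rate is > 40 Hz; all other units
#' are putative excitatory cells.
#'
#' @param units Data.frame with `duration_ms` and `mean_rate`.
#' @param duration_cut ms threshold (default 0.35).
#' @param rate_cut Hz threshold (default 40).
#' @return Logical vector `is_IN` (the complement is excitatory).
#' @export
split_in_excitatory <- function(units, duration_cut = 0.35, rate_cut = 40) {
  units$duration_ms < duration_cut | units$mean_rate > rate_cut
}

#' Classify speed-tuned cells against shuffle nulls
#'
#' A (putative excitatory) cell is speed-tuned when the absolute values of
#' both its speed score and its speed stability score strictly exceed the
#' 99th percentiles of the absolute values of the corresponding scores on
#' spike-time-shuffled data. The speed-score sign splits + from - speed
#' cells.
#'
#' @param score,stability Observed speed score and speed stability score.
#' @param null_scores,null_stability Shuffle distributions of the two
#'   statistics (signed; absolute values are taken here).
#' @return List of logicals `is_speed`, `is_speed_pos`, `is_speed_neg`.
#' @export
classify_speed_cells <- function(score, stability, null_scores,
                                 null_stability) {
  q_sc <- percentile(abs(null_scores), 0.99)
  q_st <- percentile(abs(null_stability), 0.99)
  tuned <- isTRUE(abs(score) > q_sc) && isTRUE(abs(stability) > q_st)
  list(is_speed = tuned,
       is_speed_pos = tuned && score > 0,
       is_speed_neg = tuned && score < 0)
}

#' Classify spatial cells against shuffle nulls
#'
#' A cell is spatial when both its spatial coherence and sparsity strictly
#' exceed the 99th percentiles of their shuffle distributions. For the
#' two-context task these metrics are computed on Block A trials only, to
#' keep context-dependent firing changes out of the scores.
#'
#' @param coherence,sparsity Observed metrics.
#' @param null_coherence,null_sparsity Shuffle distributions.
#' @return Logical `is_spatial`.
#' @export
classify_spatial_cells <- function(coherence, sparsity, null_coherence,
                                   null_sparsity) {
  isTRUE(coherence > percentile(null_coherence, 0.99)) &&
    isTRUE(sparsity > percentile(null_sparsity, 0.99))
}

#' Classify grid and non-grid spatial (NGS) cells
#'
#' A putative grid cell is an excitatory, distance-tuned cell with dark mean
#' rate > 0.05 Hz, overall mean rate >= 0.3 Hz, and a trial-averaged firing
#' noise ratio (SEM of the mean spatial rate / mean rate, per context) not
#' exceeding 0.45 in either context (the noise gate filters lickport
#' artifacts with implausibly narrow fields). An NGS cell is a spatial cell
#' that is not distance-tuned.
#'
#' @param is_excitatory,is_spatial,distance_tuned Logicals for the cell.
#' @param dark_rate Mean rate on dark trials (Hz); `NA` when the session has
#'   no dark trials (grid/NGS typing is then unavailable).
#' @param overall_rate Session mean rate (Hz).
#' @param noise_ratios Per-context noise ratios (vector; the cell is
#'   excluded from grid typing if any exceeds `noise_cut`).
#' @param noise_cut Threshold (default 0.45).
#' @return List of logicals `is_grid`, `is_NGS`, plus `available` (FALSE
#'   when dark trials are absent).
#' @export
classify_grid_cells <- function(is_excitatory, is_spatial, distance_tuned,
                                dark_rate, overall_rate,
                                noise_ratios = numeric(0), noise_cut = 0.45) {
  if (is.na(dark_rate)) {
    return(list(is_grid = NA, is_NGS = NA, available = FALSE))
  }
  noisy <- length(noise_ratios) > 0 &&
    any(noise_ratios > noise_cut, na.rm = TRUE)
  grid <- isTRUE(is_excitatory) && isTRUE(distance_tuned) &&
    dark_rate > 0.05 && overall_rate >= 0.3 && !noisy
  ngs <- isTRUE(is_spatial) && !isTRUE(distance_tuned) && !noisy
  list(is_grid = grid, is_NGS = ngs, available = TRUE)
}

#' Mean rate on a subset of trials
#' @param spike_times Spike times (s).
#' @param frames `session_frames`.
#' @param trials Trials defining the subset.
#' @return Spikes per second of time spent on those trials (`NA` if the
#'   subset is empty).
#' @export
subset_mean_rate <- function(spike_times, frames, trials) {
  rows <- frames$trial %in% trials
  if (!any(rows)) return(NA_real_)
  dur <- sum(rows) / (attr(frames, "frame_rate") %||% 50)
  idx <- findInterval(spike_times, frames$t)
  idx <- idx[idx >= 1L & idx <= nrow(frames)]
  sum(rows[idx]) / dur
}

#' Trial-averaged firing noise ratio
#'
#' SEM across trials of the per-trial mean spatial firing rate, divided by
#' the across-trial mean; used to flag units whose apparent fields are
#' delivery artifacts.
#' @param rmat `trial_rate_matrix` restricted to one context's trials.
#' @return SEM/mean ratio (`NA` when undefined).
#' @export
rate_noise_ratio <- function(rmat) {
  per_trial <- rowMeans(rmat$values, na.rm = TRUE)
  per_trial <- per_trial[is.finite(per_trial)]
  if (length(per_trial) < 2L) return(NA_real_)
  m <- mean(per_trial)
  if (m == 0) return(NA_real_)
  (stats::sd(per_trial) / sqrt(length(per_trial))) / m
}

#' Derive conjunctive and exclusive functional subtypes
#'
#' Set algebra over the base labels: + / - "speed only" cells are speed
#' cells that are not spatial; "+IN speed" cells are interneurons with
#' positive speed tuning; "+grid speed" cells are grid cells with positive
#' speed tuning.
#'
#' @param labels List or one-row data.frame with logicals `is_IN`,
#'   `is_speed_pos`, `is_speed_neg`, `is_spatial`, `is_grid`.
#' @return The input extended with `is_speed_only_pos`, `is_speed_only_neg`,
#'   `is_IN_speed`, `is_grid_speed`.
#' @export
derive_subtypes <- function(labels) {
  labels$is_speed_only_pos <- isTRUE(labels$is_speed_pos) &&
    !isTRUE(labels$is_spatial)
  labels$is_speed_only_neg <- isTRUE(labels$is_speed_neg) &&
    !isTRUE(labels$is_spatial)
  labels$is_IN_speed <- isTRUE(labels$is_IN) && isTRUE(labels$is_speed_pos)
  labels$is_grid_speed <- isTRUE(labels$is_grid) &&
    isTRUE(labels$is_speed_pos)
  labels
}
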