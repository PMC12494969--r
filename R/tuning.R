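#' Precompute the occupancy context for rate maps
#'
#' Bins the behavior frames once (occupancy per trial and position bin,
#' trial-row lookup) so that repeated [trial_rate_matrix()] calls on the
#' same session — e.g. the 100 spike-time shuffles of a null distribution —
#' skip the behavior-side work.
#'
#' @inheritParams trial_rate_matrix
#' @return A `rate_map_context` list consumed by [trial_rate_matrix()].
#' @export
rate_map_context <- function(frames, mask = NULL, trials = NULL,
                             bin_size = 2, track_length = NULL) {
  track_length <- track_length %||% attr(frames, "track_length") %||% 400
  frame_rate <- attr(frames, "frame_rate") %||% 50
  dt <- 1 / frame_rate
  n_bins <- as.integer(round(track_length / bin_size))
  if (is.null(mask)) mask <- rep(TRUE, nrow(frames))
  if (is.null(trials)) trials <- sort(unique(frames$trial))
  trial_row <- integer(max(frames$trial, trials))
  trial_row[trials] <- seq_along(trials)
  fr_bin <- pmin(n_bins, floor(frames$position / bin_size) + 1L)
  rows <- which(mask & trial_row[frames$trial] > 0L)
  occ <- matrix(tabulate((trial_row[frames$trial[rows]] - 1L) * n_bins +
                           fr_bin[rows],
                         nbins = length(trials) * n_bins),
                length(trials), n_bins, byrow = TRUE) * dt
  structure(list(mask = mask, trials = trials, trial_row = trial_row,
                 n_bins = n_bins, bin_size = bin_size, occupancy = occ,
                 dt = dt),
            class = "rate_map_context")
}

#' Trial-by-position firing rate matrix
#'
#' Bins track position into `bin_size` cm bins (half-open `[left, right)`
#' bins; 200 bins for a 400 cm track) and divides per-trial spike counts by
#' per-trial occupancy time. Stationary frames (and their spikes) are
#' excluded when a mask is supplied. Bins a trial never occupied are set
#' missing, then linearly interpolated from neighboring bins before optional
#' Gaussian smoothing (SD in cm; 4 cm for tuning curves, 5 cm for population
#' tensors).
#'
#' @param spike_times Numeric spike times (s) of one unit.
#' @param frames `session_frames` with `t`, `position`, `trial`.
#' @param smoothing_sd Gaussian SD in cm, or `NULL`/0 for no smoothing.
#' @param mask Logical per-frame inclusion mask (e.g., from
#'   [filter_stationary()]); `NULL` keeps all frames.
#' @param trials Integer trials to include (default: all in `frames`).
#' @param bin_size Position bin width in cm.
#' @param track_length Track length in cm (frames attribute by default).
#' @param context Optional precomputed occupancy context from
#'   [rate_map_context()] (shared across repeated calls with the same
#'   frames/mask/trials, e.g. over shuffles); overrides `mask`, `trials`,
#'   `bin_size` and `track_length`.
#' @return A `trial_rate_matrix`: list with `values` (trials x bins Hz),
#'   `occupancy` (s), `occ_prob` (occupancy probability over all included
#'   trial-bins), `trials`, `bin_centers`, `smoothing_sd`. Rows of trials
#'   with no occupancy anywhere are all-`NA`.
#' @export
trial_rate_matrix <- function(spike_times, frames, smoothing_sd = NULL,
                              mask = NULL, trials = NULL, bin_size = 2,
                              track_length = NULL, context = NULL) {
  ctx <- context %||% rate_map_context(frames, mask = mask, trials = trials,
                                       bin_size = bin_size,
                                       track_length = track_length)
  trials <- ctx$trials
  n_bins <- ctx$n_bins
  bin_size <- ctx$bin_size
  occ <- ctx$occupancy
  # assign each spike to its frame
  sp_frame <- findInterval(spike_times, frames$t)
  sp_ok <- sp_frame >= 1L & sp_frame <= nrow(frames)
  sp_frame <- sp_frame[sp_ok]
  sp_frame <- sp_frame[ctx$mask[sp_frame]]
  sp_row <- ctx$trial_row[frames$trial[sp_frame]]
  sp_bin <- pmin(n_bins, floor(frames$position[sp_frame] / bin_size) + 1L)
  keep <- !is.na(sp_row) & sp_row > 0L
  values <- matrix(NA_real_, length(trials), n_bins)
  counts <- matrix(tabulate((sp_row[keep] - 1L) * n_bins + sp_bin[keep],
                            nbins = length(trials) * n_bins),
                   length(trials), n_bins, byrow = TRUE)
  for (ti in seq_along(trials)) {
    r <- counts[ti, ] / occ[ti, ]
    r[occ[ti, ] == 0] <- NA_real_
    if (any(is.finite(r))) r <- interp_na(r)
    values[ti, ] <- r
  }
  sd_bins <- if (is.null(smoothing_sd) || smoothing_sd <= 0) 0 else
    smoothing_sd / bin_size
  if (sd_bins > 0) {
    for (ti in seq_len(nrow(values))) {
      if (any(is.finite(values[ti, ]))) {
        # the track is circular within a trial, so smoothing wraps; this
        # also preserves the trial mean rate exactly
        values[ti, ] <- gaussian_smooth(values[ti, ], sd_bins,
                                        edge = "wrap")
      }
    }
  }
  occ_tot <- colSums(occ)
  occ_prob <- if (sum(occ_tot) > 0) occ_tot / sum(occ_tot) else occ_tot
  structure(list(values = values, occupancy = occ, occ_prob = occ_prob,
                 trials = trials,
                 bin_centers = (seq_len(n_bins) - 0.5) * bin_size,
                 bin_size = bin_size,
                 smoothing_sd = if (sd_bins > 0) smoothing_sd else NA_real_),
            class = "trial_rate_matrix")
}

#' Trial-averaged spatial firing rate vector
#' @param rmat A `trial_rate_matrix`.
#' @return Numeric vector of per-bin mean rates (Hz) across trials.
#' @export
mean_rate_vector <- function(rmat) {
  colMeans(rmat$values, na.rm = TRUE)
}

#' Spatial coherence
#'
#' Local smoothness of the (non-smoothed) trial-averaged spatial firing rate
#' vector: the Pearson correlation, across position bins, between each bin's
#' rate and the mean rate of its eight nearest bins. Values near 1 indicate
#' strongly spatial firing.
#'
#' @param rate Trial-averaged rate vector (or a `trial_rate_matrix`).
#' @return Correlation in \[-1, 1\], or `NA` for zero-variance vectors.
#' @export
spatial_coherence <- function(rate) {
  if (inherits(rate, "trial_rate_matrix")) rate <- mean_rate_vector(rate)
  n <- length(rate)
  if (n < 9L) return(NA_real_)
  # the 8 nearest bins are a 9-bin window around each bin, clamped at the
  # track ends, minus the bin itself
  csum <- cumsum(c(0, rate))
  lo <- pmax(1L, pmin(seq_len(n) - 4L, n - 8L))
  neigh <- (csum[lo + 9L] - csum[lo] - rate) / 8
  safe_cor(rate, neigh)
}

#' Spatial sparsity
#'
#' `sum(P_i * R_i^2) / R^2`, where `P_i` is the occupancy probability of bin
#' i, `R_i` its mean rate, and `R = sum(P_i R_i)` the overall mean rate.
#' Equals 1 for spatially uniform firing and `1/P_i` for firing confined to
#' a single bin; larger values mean sparser track coverage.
#'
#' @param rate Trial-averaged rate vector (or a `trial_rate_matrix`, which
#'   also supplies `occ_prob`).
#' @param occ_prob Occupancy probabilities summing to 1.
#' @return Sparsity >= 1 under uniform occupancy; `NA` when the overall mean
#'   rate is 0.
#' @export
spatial_sparsity <- function(rate, occ_prob = NULL) {
  if (inherits(rate, "trial_rate_matrix")) {
    occ_prob <- occ_prob %||% rate$occ_prob
    rate <- mean_rate_vector(rate)
  }
  ok <- is.finite(rate) & is.finite(occ_prob)
  rate <- rate[ok]
  p <- occ_prob[ok] / sum(occ_prob[ok])
  rbar <- sum(p * rate)
  if (rbar <= 0) return(NA_real_)
  sum(p * rate^2) / rbar^2
}

#' Spatial information rate
#'
#' `sum(P_i R_i log2(R_i / R))` in bits per second, with `0 * log(0) = 0`.
#' Zero for spatially uniform firing; invariant to permutation of bins.
#'
#' @inheritParams spatial_sparsity
#' @return Information in bits/s (>= 0), `NA` when the mean rate is 0.
#' @export
spatial_information <- function(rate, occ_prob = NULL) {
  if (inherits(rate, "trial_rate_matrix")) {
    occ_prob <- occ_prob %||% rate$occ_prob
    rate <- mean_rate_vector(rate)
  }
  ok <- is.finite(rate) & is.finite(occ_prob)
  rate <- rate[ok]
  p <- occ_prob[ok] / sum(occ_prob[ok])
  rbar <- sum(p * rate)
  if (rbar <= 0) return(NA_real_)
  terms <- ifelse(rate > 0, p * rate * log2(rate / rbar), 0)
  sum(terms)
}

#' Dark-running spatial autocorrelation
#'
#' Concatenates the smoothed by-trial spatial firing rate vectors of the
#' dark trials into one linearized distance series and computes its
#' Pearson-normalized autocorrelation at lags up to `max_lag` cm (2 cm
#' steps; lag 0 equals 1). Peaks (excluding lag 0) are detected with the
#' periodicity criteria used for distance tuning: width > 10 cm,
#' height > 0.1, prominence > 0.15.
#'
#' @param rmat `trial_rate_matrix` restricted to dark trials (smoothed,
#'   typically SD 4 cm).
#' @param max_lag Maximum lag in cm (default 800).
#' @param peak_height,peak_prominence,peak_width Peak criteria (height and
#'   prominence in correlation units, width in cm; all strict `>`).
#' @return List with `lags` (cm), `values`, `peaks` (data.frame `lag_cm`,
#'   `height`, `prominence`, `width_cm`) and `max_peak` (row of `peaks` with
#'   the largest height, or `NULL`). `NULL` when no dark trial has data.
#' @export
dark_autocorrelation <- function(rmat, max_lag = 800, peak_height = 0.1,
                                 peak_prominence = 0.15, peak_width = 10) {
  x <- as.vector(t(rmat$values))
  x <- x[is.finite(x)]
  if (!length(x)) return(NULL)
  bin <- rmat$bin_size
  nlag <- min(length(x) - 2L, as.integer(round(max_lag / bin)))
  ac <- as.numeric(stats::acf(x, lag.max = nlag, plot = FALSE,
                              demean = TRUE)$acf)
  lags <- (0:nlag) * bin
  pk <- find_peaks(ac, height = peak_height, prominence = peak_prominence,
                   width = peak_width / bin)
  pk <- pk[pk$index > 1L, , drop = FALSE]
  peaks <- data.frame(lag_cm = lags[pk$index], height = pk$height,
                      prominence = pk$prominence, width_cm = pk$width * bin)
  max_peak <- if (nrow(peaks)) peaks[which.max(peaks$height), ] else NULL
  list(lags = lags, values = ac, peaks = peaks, max_peak = max_peak)
}

#' Spike-time shuffle null distribution
#'
#' Recomputes a statistic on `n_shuffles` circularly time-shifted copies of
#' a spike train: each shuffle shifts all spike times by an offset drawn
#' uniformly from `[min_offset, max_t]` seconds and wraps them around the
#' session end, preserving the spike count and interval structure while
#' destroying alignment to behavior.
#'
#' @param spike_times Spike times (s).
#' @param frames `session_frames` (defines the session span).
#' @param statistic Function `(spike_times, frames) -> numeric` (scalar or
#'   fixed-length vector).
#' @param n_shuffles Number of shuffles (default 100).
#' @param min_offset Minimum offset (s, default 20). Session must be longer
#'   than `min_offset`.
#' @param seed RNG seed.
#' @return List with `values` (shuffles x statistic-length matrix), `q99`
#'   (per-statistic 99th percentile, linear interpolation) and `offsets`.
#' @export
shuffle_null <- function(spike_times, frames, statistic, n_shuffles = 100,
                         min_offset = 20, seed = 1L) {
  max_t <- frames$t[nrow(frames)] + 1 / (attr(frames, "frame_rate") %||% 50)
  if (max_t <= min_offset) {
    stop("session duration must exceed the minimum shuffle offset (",
         min_offset, " s)")
  }
  set.seed(seed)
  offsets <- stats::runif(n_shuffles, min_offset, max_t)
  t0 <- frames$t[1L]
  vals <- lapply(offsets, function(off) {
    shifted <- ((spike_times - t0 + off) %% (max_t - t0)) + t0
    statistic(shifted, frames)
  })
  vals <- do.call(rbind, vals)
  q99 <- apply(vals, 2L, percentile, p = 0.99)
  list(values = vals, q99 = q99, offsets = offsets)
}

#' Decide distance tuning from the dark autocorrelation and its null
#'
#' A cell is distance-tuned when its dark autocorrelation has at least one
#' qualifying peak (width > 10 cm, height > 0.1, prominence > 0.15) and the
#' prominence of the maximal peak is greater than or equal to the 99th
#' percentile of the shuffle distribution of autocorrelation heights at that
#' same lag.
#'
#' @param autocorr Result of [dark_autocorrelation()] on the real data.
#' @param shuffle_heights Autocorrelation heights at the max-peak lag for
#'   each shuffle (e.g., from [shuffle_null()] with a statistic returning
#'   the autocorrelation value at that lag).
#' @return Logical.
#' @export
detect_distance_tuning <- function(autocorr, shuffle_heights) {
  if (is.null(autocorr) || is.null(autocorr$max_peak)) return(FALSE)
  q99 <- percentile(shuffle_heights, 0.99)
  isTRUE(autocorr$max_peak$prominence >= q99)
}

#' Estimate grid scale from the dark autocorrelation
#'
#' The grid scale is the lag of the first (not the largest) autocorrelation
#' peak passing relaxed criteria (width > 8 cm, height > 0.05,
#' prominence > 0.05) on dark trials.
#'
#' @param autocorr Result of [dark_autocorrelation()]; peaks are re-detected
#'   here with the relaxed thresholds.
#' @param peak_height,peak_prominence,peak_width Relaxed criteria.
#' @return Scale in cm, or `NA` when no peak qualifies.
#' @export
estimate_grid_scale <- function(autocorr, peak_height = 0.05,
                                peak_prominence = 0.05, peak_width = 8) {
  if (is.null(autocorr)) return(NA_real_)
  bin <- diff(autocorr$lags[1:2])
  pk <- find_peaks(autocorr$values, height = peak_height,
                   prominence = peak_prominence, width = peak_width / bin)
  pk <- pk[pk$index > 1L, , drop = FALSE]
  if (!nrow(pk)) return(NA_real_)
  autocorr$lags[min(pk$index)]
}

#' Estimate unit recording depth from the brain surface
#'
#' Subtracts the median distance of the unit's spikes from the probe tip
#' from the probe's maximum inserted depth.
#' @param tip_distances Per-spike distance from the probe tip (micrometers).
#' @param insertion_depth Maximum inserted probe depth (micrometers).
#' @return Depth from the brain surface in micrometers.
#' @export
estimate_unit_depth <- function(tip_distances, insertion_depth) {
  insertion_depth - stats::median(tip_distances)
}
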