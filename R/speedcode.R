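#' Instantaneous firing rate
#'
#' Smooths the per-frame spike-count series with a Gaussian kernel and
#' divides by the frame duration. The kernel SD is specified in
#' distance-equivalent units (`kernel_sd_cm`, default 40 cm) and converted
#' to time as `kernel_sd_cm / mean running speed`, so the effective temporal
#' smoothing adapts to how fast the animal covers the track; a temporal SD
#' can be given directly via `kernel_sd_s`.
#'
#' @param spike_times Spike times (s).
#' @param frames `session_frames`.
#' @param kernel_sd_cm Kernel SD in cm (default 40); ignored when
#'   `kernel_sd_s` is given.
#' @param kernel_sd_s Kernel SD in seconds (optional override).
#' @return Numeric vector of rates (Hz), one per frame. The kernel is
#'   normalized so the series integrates to the spike count.
#' @export
instantaneous_rate <- function(spike_times, frames, kernel_sd_cm = 40,
                               kernel_sd_s = NULL) {
  frame_rate <- attr(frames, "frame_rate") %||% 50
  dt <- 1 / frame_rate
  idx <- findInterval(spike_times, frames$t)
  idx <- idx[idx >= 1L & idx <= nrow(frames)]
  counts <- tabulate(idx, nbins = nrow(frames))
  sd_s <- kernel_sd_s %||% (kernel_sd_cm / mean(frames$speed, na.rm = TRUE))
  gaussian_smooth(counts, sd = sd_s * frame_rate) / dt
}

#' Speed score, slope, and intercept
#'
#' Speed score is the Pearson correlation between running speed and
#' instantaneous firing rate over running (non-stationary) frames; slope and
#' intercept come from the least-squares regression of rate on speed.
#'
#' @param rate Instantaneous rate series (Hz).
#' @param speed Speed series (cm/s), same length.
#' @param mask Logical inclusion mask (e.g., [filter_stationary()]).
#' @return List with `score`, `slope`, `intercept`, and `degenerate` (TRUE
#'   when speed or rate has zero variance, in which case `score` is 0).
#' @export
speed_score <- function(rate, speed, mask = NULL) {
  if (!is.null(mask)) {
    rate <- rate[mask]
    speed <- speed[mask]
  }
  ok <- is.finite(rate) & is.finite(speed)
  rate <- rate[ok]
  speed <- speed[ok]
  if (length(rate) < 2L || stats::sd(rate) == 0 || stats::sd(speed) == 0) {
    return(list(score = 0, slope = NA_real_, intercept = NA_real_,
                degenerate = TRUE))
  }
  slope <- stats::cov(rate, speed) / stats::var(speed)
  list(score = stats::cor(rate, speed), slope = slope,
       intercept = mean(rate) - slope * mean(speed), degenerate = FALSE)
}

#' Spike-weighted average of stratified speed scores
#'
#' The stability form of the speed score: `sum(n_i * p_i) / n`, where `p_i`
#' is the speed score computed within stratum i (track section or trial) and
#' `n_i` the spike count there. Strata with zero spikes or undefined scores
#' drop out (`n` is the spike total over contributing strata).
#'
#' @param scores Per-stratum speed scores `p_i`.
#' @param spike_counts Per-stratum spike counts `n_i`.
#' @return Weighted average in \[-1, 1\], `NA` when no spikes contribute.
#' @export
weighted_speed_score <- function(scores, spike_counts) {
  ok <- is.finite(scores) & spike_counts > 0
  n <- sum(spike_counts[ok])
  if (n == 0) return(NA_real_)
  sum(spike_counts[ok] * scores[ok]) / n
}

#' Speed stability score across track sections
#'
#' Splits the track into `n_sections` equal sections (5 x 80 cm by default),
#' computes the speed score within each from the frames the animal spent
#' there, and returns the spike-weighted average. Controls for the
#' correlation of speed with track position.
#'
#' @param spike_times Spike times (s).
#' @param rate Instantaneous rate series (from [instantaneous_rate()]).
#' @param frames `session_frames` with `position` and `speed`.
#' @param mask Running-frame mask.
#' @param n_sections Number of equal track sections (default 5).
#' @return List with `score` (the weighted average), `section_scores`,
#'   `section_spikes`.
#' @export
speed_stability_score <- function(spike_times, rate, frames, mask = NULL,
                                  n_sections = 5) {
  track_length <- attr(frames, "track_length") %||% 400
  if (is.null(mask)) mask <- rep(TRUE, nrow(frames))
  section <- pmin(n_sections,
                  floor(frames$position / (track_length / n_sections)) + 1L)
  idx <- findInterval(spike_times, frames$t)
  idx <- idx[idx >= 1L & idx <= nrow(frames)]
  idx <- idx[mask[idx]]
  sec_spikes <- tabulate(section[idx], nbins = n_sections)
  sec_scores <- grouped_pearson(rate[mask], frames$speed[mask],
                                section[mask], n_sections)
  list(score = weighted_speed_score(sec_scores, sec_spikes),
       section_scores = sec_scores, section_spikes = sec_spikes)
}

#' Trial speed stability score
#'
#' As [speed_stability_score()] but stratified by trial: the spike-weighted
#' average of speed scores computed on individual trials. Values below the
#' session speed score indicate unstable speed tuning over trials.
#'
#' @inheritParams speed_stability_score
#' @param trials Trials to include (default all).
#' @return List with `score`, `trial_scores`, `trial_spikes`.
#' @export
trial_speed_stability <- function(spike_times, rate, frames, mask = NULL,
                                  trials = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, nrow(frames))
  if (is.null(trials)) trials <- sort(unique(frames$trial))
  idx <- findInterval(spike_times, frames$t)
  idx <- idx[idx >= 1L & idx <= nrow(frames)]
  idx <- idx[mask[idx]]
  trial_row <- integer(max(frames$trial, trials))
  trial_row[trials] <- seq_along(trials)
  tr_spikes <- tabulate(trial_row[frames$trial[idx]],
                        nbins = length(trials))
  g <- trial_row[frames$trial[mask]]
  sel <- g > 0L
  tr_scores <- grouped_pearson(rate[mask][sel], frames$speed[mask][sel],
                               g[sel], length(trials))
  list(score = weighted_speed_score(tr_scores, tr_spikes),
       trial_scores = tr_scores, trial_spikes = tr_spikes)
}

#' All speed-tuning scores for one unit
#'
#' Convenience wrapper computing the instantaneous rate, the session speed
#' score/slope/intercept, and both stability variants.
#'
#' @inheritParams speed_stability_score
#' @param kernel_sd_cm Smoothing SD in cm for [instantaneous_rate()].
#' @return List with `speed_score`, `slope`, `intercept`, `speed_stability`,
#'   `trial_stability`.
#' @export
speed_scores <- function(spike_times, frames, mask = NULL,
                         kernel_sd_cm = 40) {
  rate <- instantaneous_rate(spike_times, frames, kernel_sd_cm)
  ss <- speed_score(rate, frames$speed, mask)
  stab <- speed_stability_score(spike_times, rate, frames, mask)
  tstab <- trial_speed_stability(spike_times, rate, frames, mask)
  list(speed_score = ss$score, slope = ss$slope, intercept = ss$intercept,
       speed_stability = stab$score, trial_stability = tstab$score)
}
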