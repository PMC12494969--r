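#' Resample behavior frames to a uniform 50 Hz grid
#'
#' VR engines emit frames at slightly irregular intervals; all downstream
#' analyses assume a constant sampling rate. Positions are unwrapped to
#' cumulative distance across teleports (so interpolation never crosses a
#' teleport discontinuity), linearly interpolated onto a uniform grid
#' spanning the raw time range, and re-wrapped. Raw positions slightly below
#' 0 or above the track length are thereby mapped into the neighboring
#' trial's coordinates.
#'
#' @param raw data.frame with at least `t` (s, non-decreasing) and `position`
#'   (cm). Additional numeric columns are linearly interpolated; character
#'   columns are carried over from the nearest preceding raw frame.
#' @param frame_rate Target rate in Hz (default 50).
#' @param track_length Track length in cm (default 400).
#' @return A `session_frames` data.frame on the uniform grid with `t`,
#'   `position`, `trial` and any interpolated extra columns.
#' @export
resample_frames <- function(raw, frame_rate = 50, track_length = 400) {
  if (nrow(raw) < 2L) stop("need at least 2 raw frames to resample")
  if (is.unsorted(raw$t)) stop("raw frame times must be non-decreasing")
  # unwrap: accumulate track lengths at teleports (large negative jumps)
  dp <- c(0, diff(raw$position))
  wraps <- cumsum(dp < -100)
  unwrapped <- raw$position + wraps * track_length
  grid <- seq(raw$t[1L], raw$t[nrow(raw)], by = 1 / frame_rate)
  cum <- stats::approx(raw$t, unwrapped, xout = grid, ties = "ordered")$y
  out <- data.frame(t = grid,
                    position = cum %% track_length,
                    trial = as.integer(cum %/% track_length) + 1L)
  extra <- setdiff(names(raw), c("t", "position", "trial"))
  for (col in extra) {
    v <- raw[[col]]
    if (is.numeric(v)) {
      out[[col]] <- stats::approx(raw$t, v, xout = grid, ties = "ordered")$y
    } else {
      idx <- findInterval(grid, raw$t, rightmost.closed = TRUE)
      out[[col]] <- v[pmax(1L, idx)]
    }
  }
  structure(out, class = c("session_frames", "data.frame"),
            track_length = track_length, frame_rate = frame_rate)
}

#' Assign trial indices from teleport transitions
#'
#' A new trial starts exactly at frames where the position difference from
#' the previous frame is less than -100 cm (the teleport from the track end
#' back to the start). Smaller negative glitches do not open a trial.
#'
#' @param frames data.frame with `position`.
#' @return `frames` with an (overwritten) integer `trial` column starting
#'   at 1.
#' @export
segment_trials <- function(frames) {
  dp <- c(0, diff(frames$position))
  frames$trial <- cumsum(dp < -100) + 1L
  frames
}

#' Compute and clean running speed
#'
#' Speed is the frame-to-frame position difference (unwrapped across
#' teleports) times the frame rate. Frames with speed <= `slow_cut` (5 cm/s)
#' or > `fast_cut` (150 cm/s) are treated as tracking artifacts: removed and
#' refilled by linear interpolation from the surrounding valid frames. The
#' cleaned trace is then smoothed with a Gaussian filter of SD 0.2 samples.
#'
#' @param frames Resampled `session_frames`.
#' @param frame_rate Hz; taken from the frames attribute when present.
#' @param track_length cm, for unwrapping.
#' @param slow_cut,fast_cut Artifact thresholds in cm/s.
#' @param smooth_sd Gaussian SD in samples applied after interpolation.
#' @return `frames` with a `speed` column (cm/s, >= 0).
#' @export
compute_speed <- function(frames, frame_rate = NULL, track_length = NULL,
                          slow_cut = 5, fast_cut = 150, smooth_sd = 0.2) {
  frame_rate <- frame_rate %||% attr(frames, "frame_rate") %||% 50
  track_length <- track_length %||% attr(frames, "track_length") %||% 400
  dp <- c(0, diff(frames$position))
  dp[dp < -100] <- dp[dp < -100] + track_length
  v <- dp * frame_rate
  v[1L] <- v[min(2L, length(v))]
  bad <- v <= slow_cut | v > fast_cut
  if (any(bad) && !all(bad)) {
    v[bad] <- NA_real_
    v <- interp_na(v)
  }
  frames$speed <- pmax(0, gaussian_smooth(v, smooth_sd))
  frames
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Running-frame mask
#'
#' Stationary frames (speed < 2 cm/s) are excluded from all spike-train
#' analyses; this returns the inclusion mask.
#' @param frames Frames with cleaned `speed`.
#' @param threshold cm/s (default 2).
#' @return Logical vector, `FALSE` exactly where `speed < threshold`.
#' @export
filter_stationary <- function(frames, threshold = 2) {
  frames$speed >= threshold
}

#' Fraction of rewards requested
#'
#' A reward zone counts as "requested" when the mouse licked inside the zone
#' before the automatic delivery point (the zone center); the task
#' performance of a phase is the fraction of its eligible zones that were
#' requested.
#'
#' @param frames `session_frames` with `lick`, `reward`, `reward_start`,
#'   `reward_end` and trial labels.
#' @param trials Optional integer vector restricting to a task phase
#'   (default: all trials with a reward zone).
#' @return Fraction in \[0, 1\], or `NA` when no eligible zone exists.
#' @export
task_performance <- function(frames, trials = NULL) {
  elig <- unique(frames$trial[is.finite(frames$reward_start)])
  if (!is.null(trials)) elig <- intersect(elig, trials)
  if (!length(elig)) return(NA_real_)
  requested <- vapply(elig, function(k) {
    rows <- frames$trial == k
    zc <- (frames$reward_start[rows][1L] + frames$reward_end[rows][1L]) / 2
    any(frames$lick[rows] > 0 &
          frames$position[rows] >= frames$reward_start[rows][1L] &
          frames$position[rows] < zc)
  }, logical(1L))
  mean(requested)
}

#' Reward-triggered licking and slowing profiles
#'
#' Averages position-binned lick counts and speed traces (2.5 cm bins) over
#' rewarded trials, in a window from 25 cm before the reward zone start to
#' the zone end (75 cm total, 30 bins for a 50 cm zone). The licking
#' magnitude is the prominence of the absolute maximum of the mean lick
#' trace; the slowing magnitude is the prominence of the absolute maximum of
#' the inverted mean speed trace.
#'
#' @param frames `session_frames` with `lick`, `speed`, `reward`,
#'   `reward_start`, `reward_end`.
#' @param bin_size cm (default 2.5).
#' @return List with `lick_trace`, `speed_trace` (per-bin means),
#'   `bin_centers` (cm relative to zone start), `licking_magnitude`,
#'   `slowing_magnitude`; `NULL` when no rewarded trials exist.
#' @export
reward_triggered_profiles <- function(frames, bin_size = 2.5) {
  rewarded <- unique(frames$trial[frames$reward > 0])
  rewarded <- rewarded[vapply(rewarded, function(k)
    any(is.finite(frames$reward_start[frames$trial == k])), logical(1L))]
  if (!length(rewarded)) return(NULL)
  lick_mat <- NULL
  speed_mat <- NULL
  for (k in rewarded) {
    rows <- which(frames$trial == k)
    zs <- frames$reward_start[rows][1L]
    ze <- frames$reward_end[rows][1L]
    lo <- zs - 25
    n_bins <- as.integer(round((ze - lo) / bin_size))
    rel <- frames$position[rows] - lo
    b <- floor(rel / bin_size) + 1L
    keep <- b >= 1L & b <= n_bins
    lk <- vapply(seq_len(n_bins), function(j)
      sum(frames$lick[rows][keep & b == j]), numeric(1L))
    sp <- vapply(seq_len(n_bins), function(j) {
      sel <- keep & b == j
      if (any(sel)) mean(frames$speed[rows][sel]) else NA_real_
    }, numeric(1L))
    lick_mat <- rbind(lick_mat, lk)
    speed_mat <- rbind(speed_mat, sp)
  }
  lick_trace <- colMeans(lick_mat)
  speed_trace <- colMeans(speed_mat, na.rm = TRUE)
  speed_trace <- interp_na(speed_trace)
  inv_speed <- -speed_trace
  lick_peak <- which.max(lick_trace)
  slow_peak <- which.max(inv_speed)
  list(lick_trace = lick_trace, speed_trace = speed_trace,
       bin_centers = (seq_along(lick_trace) - 0.5) * bin_size - 25,
       licking_magnitude = prominence_at(lick_trace, lick_peak),
       slowing_magnitude = prominence_at(inv_speed, slow_peak))
}

#' Fit a contrast-sensitivity psychometric curve
#'
#' Fits `y = 1 / (1 + exp(-(x - center) / scale))` to the fraction of
#' rewards requested as a function of binned reward-zone opacity by
#' least squares (Levenberg-Marquardt), initialized at `center = 0.1`,
#' `scale = 0.002`. The fitted `center` is the animal's estimated contrast
#' sensitivity threshold.
#'
#' @param opacity Numeric vector of opacity bin centers (alpha units).
#' @param fraction Fraction requested per bin.
#' @param init Named list with starting `center` and `scale`.
#' @return List with `center`, `scale`, `converged`, `degenerate` (TRUE when
#'   the response has no variance or the fit failed; coefficients are then
#'   `NA`) and the `fit` object when available.
#' @export
fit_contrast_sensitivity <- function(opacity, fraction,
                                     init = list(center = 0.1,
                                                 scale = 0.002)) {
  ok <- is.finite(opacity) & is.finite(fraction)
  if (sum(ok) < 3L) stop("need at least 3 opacity bins with defined fractions")
  x <- opacity[ok]
  y <- fraction[ok]
  bad <- list(center = NA_real_, scale = NA_real_, converged = FALSE,
              degenerate = TRUE, fit = NULL)
  if (stats::sd(y) == 0) return(bad)
  # the prescribed initialization (scale = 0.002) makes the sigmoid nearly a
  # step, where least-squares gradients vanish; a derivative-free simplex
  # pass from that start point precedes the Levenberg-Marquardt polish
  sse <- function(par) {
    sum((y - 1 / (1 + exp(-(x - par[1L]) / par[2L])))^2)
  }
  pre <- stats::optim(c(init$center, init$scale), sse,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 / (1 + exp(-(x - center) / scale)),
                      start = list(center = pre$par[1L],
                                   scale = pre$par[2L]),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    if (!is.finite(pre$value)) return(bad)
    return(list(center = pre$par[1L], scale = pre$par[2L],
                converged = pre$convergence == 0L, degenerate = FALSE,
                fit = NULL))
  }
  cf <- stats::coef(fit)
  list(center = unname(cf["center"]), scale = unname(cf["scale"]),
       converged = fit$convInfo$isConv, degenerate = FALSE, fit = fit)
}
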