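#' Canonical LFP frequency bands
#'
#' Theta 6-12 Hz, slow gamma 20-50 Hz, fast gamma 50-110 Hz.
#' @return Named list of `c(lo, hi)` pairs in Hz.
#' @export
lfp_bands <- function() {
  list(theta = c(6, 12), slow_gamma = c(20, 50), fast_gamma = c(50, 110))
}

#' Synthesize a test LFP trace
#'
#' Sum of sinusoids plus white noise; a convenience generator for testing
#' the spectral estimators.
#' @param duration s.
#' @param fs Sampling rate (Hz).
#' @param components data.frame/list with `freq` (Hz) and `amp` per
#'   sinusoid.
#' @param noise_sd White-noise SD.
#' @param seed RNG seed.
#' @return Numeric trace of length `duration * fs`.
#' @export
synth_lfp <- function(duration, fs, components = data.frame(freq = 8,
                                                            amp = 1),
                      noise_sd = 0, seed = 1L) {
  set.seed(seed)
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  x <- rep(0, length(t))
  for (i in seq_len(nrow(as.data.frame(components)))) {
    x <- x + components$amp[i] * sin(2 * pi * components$freq[i] * t)
  }
  x + stats::rnorm(length(t), 0, noise_sd)
}

#' Select the session's LFP channel
#'
#' The analysis channel is the one with the highest theta power among the
#' `n_closest` channels nearest the probe tip that have at least one good
#' recorded cell.
#'
#' @param theta_power Per-channel theta power.
#' @param tip_distance Per-channel distance from the probe tip (um).
#' @param has_cell Logical per channel: at least one good unit recorded.
#' @param n_closest Size of the tip-proximal subset (default 200).
#' @return Selected channel index.
#' @export
select_channel <- function(theta_power, tip_distance, has_cell,
                           n_closest = 200) {
  stopifnot(length(theta_power) == length(tip_distance),
            length(theta_power) == length(has_cell))
  close_set <- order(tip_distance)[seq_len(min(n_closest,
                                               length(tip_distance)))]
  eligible <- intersect(close_set, which(has_cell))
  if (!length(eligible)) stop("no eligible LFP channel")
  eligible[which.max(theta_power[eligible])]
}

# power spectrum of one tapered segment set (sine tapers)
multitaper_psd <- function(seg, fs, n_tapers = 5) {
  n <- length(seg)
  m <- seq_len(n)
  psd <- 0
  for (k in seq_len(n_tapers)) {
    w <- sqrt(2 / (n + 1)) * sin(pi * k * m / (n + 1))
    X <- stats::fft(seg * w)
    psd <- psd + Mod(X)^2 / fs
  }
  psd <- psd / n_tapers
  half <- floor(n / 2) + 1L
  out <- psd[seq_len(half)]
  # one-sided: double the interior bins
  if (n %% 2 == 0) {
    out[2:(half - 1L)] <- 2 * out[2:(half - 1L)]
  } else {
    out[2:half] <- 2 * out[2:half]
  }
  list(freq = (seq_len(half) - 1L) * fs / n, psd = out)
}

#' Time-resolved band power (multitaper spectrogram)
#'
#' Splits the trace into non-overlapping windows (0.5 s by default, giving
#' a 2 Hz power trace), estimates each window's one-sided power spectral
#' density with a sine-taper multitaper estimator (5 tapers), and
#' integrates it over the requested frequency band.
#'
#' @param trace LFP trace.
#' @param fs Sampling rate (Hz); must be at least twice the band's upper
#'   edge.
#' @param band `c(lo, hi)` in Hz or a name from [lfp_bands()].
#' @param window Window length in s (default 0.5).
#' @param n_tapers Number of sine tapers (default 5).
#' @return List with `t` (window centers, s), `power` (band-integrated
#'   power per window), `rate` (trace rate, Hz = 1/window).
#' @export
band_power <- function(trace, fs, band, window = 0.5, n_tapers = 5) {
  if (is.character(band)) band <- lfp_bands()[[band]]
  if (fs < 2 * band[2L]) {
    stop("sampling rate too low for the requested band")
  }
  n_win <- as.integer(round(window * fs))
  if (length(trace) < n_win) stop("trace shorter than one window")
  n_seg <- length(trace) %/% n_win
  power <- numeric(n_seg)
  for (s in seq_len(n_seg)) {
    seg <- trace[((s - 1L) * n_win + 1L):(s * n_win)]
    sp <- multitaper_psd(seg, fs, n_tapers)
    df <- sp$freq[2L] - sp$freq[1L]
    sel <- sp$freq >= band[1L] & sp$freq <= band[2L]
    power[s] <- sum(sp$psd[sel]) * df
  }
  list(t = (seq_len(n_seg) - 0.5) * window, power = power,
       rate = 1 / window)
}

#' Session power spectral density (Welch's method)
#'
#' Averaged modified periodograms: Hann-windowed segments with 50% overlap.
#'
#' @param trace LFP trace.
#' @param fs Sampling rate (Hz).
#' @param seg_length Segment length in samples (default `2 * fs`, i.e. 2 s).
#' @return List with `freq` (Hz) and `psd` (one-sided, power per Hz).
#' @export
welch_psd <- function(trace, fs, seg_length = NULL) {
  n <- length(trace)
  seg_length <- as.integer(seg_length %||% min(n, round(2 * fs)))
  step <- max(1L, seg_length %/% 2L)
  starts <- seq(1L, n - seg_length + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_length) / (seg_length + 1))
  norm <- fs * sum(w^2)
  psd <- 0
  for (s in starts) {
    seg <- trace[s:(s + seg_length - 1L)]
    X <- stats::fft((seg - mean(seg)) * w)
    psd <- psd + Mod(X)^2 / norm
  }
  psd <- psd / length(starts)
  half <- floor(seg_length / 2) + 1L
  out <- psd[seq_len(half)]
  if (seg_length %% 2 == 0) {
    out[2:(half - 1L)] <- 2 * out[2:(half - 1L)]
  } else {
    out[2:half] <- 2 * out[2:half]
  }
  list(freq = (seq_len(half) - 1L) * fs / seg_length, psd = out)
}

#' Speed-restricted mean band power
#'
#' Up-samples a band-power trace (2 Hz) to the VR frame rate with spline
#' interpolation and averages it over frames where the mouse ran at
#' intermediate speeds (20 <= speed <= 40 cm/s by default), controlling for
#' running-speed differences when comparing power across sessions.
#'
#' @param power_t Power-trace time stamps (s).
#' @param power Band power per time stamp.
#' @param frames `session_frames` with `t` and cleaned `speed`.
#' @param speed_range Inclusive `c(lo, hi)` in cm/s.
#' @return Mean power over qualifying frames, `NA` when none qualify.
#' @export
speed_restricted_power <- function(power_t, power, frames,
                                   speed_range = c(20, 40)) {
  up <- stats::spline(power_t, power, xout = frames$t, method = "natural")$y
  sel <- frames$speed >= speed_range[1L] & frames$speed <= speed_range[2L]
  if (!any(sel)) return(NA_real_)
  mean(up[sel])
}
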