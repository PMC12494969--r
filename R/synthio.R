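#' Configuration for a synthetic VR session
#'
#' Builds the full parameter set for the synthetic session generator. The
#' defaults emulate the recorded task structure: a 400 cm circular track
#' sampled at 50 Hz; for the split-maze (SM) task 20 dark trials, ~60-trial
#' blocks of contexts A and B, ~80 pseudorandomly alternated trials with the
#' last 20 run at a VR gain of 0.7; for random foraging (RF) a single
#' invariant context for ~200 trials.
#'
#' @param seed Integer RNG seed; every downstream draw derives from it.
#' @param track_length Track length in cm.
#' @param frame_rate Behavior sampling rate in Hz.
#' @param task `"SM"` (two-context split maze) or `"RF"` (random foraging).
#' @param n_dark,n_blockA,n_blockB,n_alternation Trial counts for the SM
#'   phases. `n_gain` flags that many trailing alternation trials as
#'   gain-manipulation trials (`n_gain <= n_alternation`).
#' @param n_rf Trial count for the RF task (after the dark trials).
#' @param n_gain Number of trailing gain trials.
#' @param gain VR translation gain applied on gain trials.
#' @param speed_mean,speed_sd Running-speed process mean and innovation scale
#'   (cm/s). Speed is a smoothed positive autoregressive process clipped to
#'   (2, 150) cm/s.
#' @param cell_counts Named integer vector of units per archetype; names from
#'   `grid`, `ngs`, `speed_pos`, `speed_neg`, `fs_in`, `untuned`.
#' @param grid_scales Candidate grid scales in cm (sampled per grid unit).
#' @param remap_mode `"context"`: the population map follows the VR context
#'   (switching with `remap_probability` at each context switch);
#'   `"random"`: the map toggles independently of context with probability
#'   `random_remap_prob` per trial.
#' @param remap_probability Probability that a context switch triggers a
#'   population remap in `"context"` mode.
#' @param random_remap_prob Per-trial toggle probability in `"random"` mode.
#' @param drift_sd Per-trial random-walk SD of each cell's field phase (cm).
#' @param rate_noise SD of the per-trial log-normal firing-rate jitter
#'   (dimensionless; 0 = noise-free).
#' @param baseline_rates Named list of archetype baseline/peak rates (Hz):
#'   `grid_peak`, `grid_base`, `ngs_peak`, `ngs_base`, `speed_base`,
#'   `in_rate`, `untuned_rate`.
#' @param lick_prob Probability per rewarded trial that the simulated mouse
#'   licks (requests the reward) before the automatic delivery point.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         track_length = 400,
                         frame_rate = 50,
                         task = c("SM", "RF"),
                         n_dark = 20L,
                         n_blockA = 60L,
                         n_blockB = 60L,
                         n_alternation = 80L,
                         n_rf = 200L,
                         n_gain = 20L,
                         gain = 0.7,
                         speed_mean = 40,
                         speed_sd = 10,
                         cell_counts = c(grid = 20L, ngs = 10L, speed_pos = 5L,
                                         speed_neg = 5L, fs_in = 5L,
                                         untuned = 10L),
                         grid_scales = c(40, 60, 80, 100),
                         remap_mode = c("context", "random"),
                         remap_probability = 1,
                         random_remap_prob = 0.05,
                         drift_sd = 0,
                         rate_noise = 0.1,
                         baseline_rates = list(grid_peak = 8, grid_base = 0.3,
                                               ngs_peak = 10, ngs_base = 0.3,
                                               speed_base = 2, in_rate = 45,
                                               untuned_rate = 3),
                         lick_prob = 0.8) {
  task <- match.arg(task)
  remap_mode <- match.arg(remap_mode)
  counts <- c(n_dark, n_blockA, n_blockB, n_alternation, n_rf, n_gain)
  if (any(counts < 0)) stop("trial counts must be >= 0")
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  if (any(grid_scales <= 0)) stop("grid scales must be > 0")
  if (remap_probability < 0 || remap_probability > 1 ||
      random_remap_prob < 0 || random_remap_prob > 1)
    stop("remap probabilities must lie in [0, 1]")
  if (n_gain > n_alternation) stop("n_gain must be <= n_alternation")
  if (any(unlist(baseline_rates) < 0)) stop("rate parameters must be >= 0")
  if (rate_noise < 0 || drift_sd < 0) stop("noise parameters must be >= 0")
  structure(list(seed = as.integer(seed), track_length = track_length,
                 frame_rate = frame_rate, task = task, n_dark = n_dark,
                 n_blockA = n_blockA, n_blockB = n_blockB,
                 n_alternation = n_alternation, n_rf = n_rf, n_gain = n_gain,
                 gain = gain, speed_mean = speed_mean, speed_sd = speed_sd,
                 cell_counts = cell_counts, grid_scales = grid_scales,
                 remap_mode = remap_mode,
                 remap_probability = remap_probability,
                 random_remap_prob = random_remap_prob, drift_sd = drift_sd,
                 rate_noise = rate_noise, baseline_rates = baseline_rates,
                 lick_prob = lick_prob),
            class = "synth_config")
}

# trial sequence (trial, context, trial_type) implied by a config
trial_sequence <- function(config) {
  if (config$task == "SM") {
    ctx <- c(rep("dark", config$n_dark),
             rep("A", config$n_blockA),
             rep("B", config$n_blockB))
    type <- c(rep("dark", config$n_dark),
              rep("vr", config$n_blockA + config$n_blockB))
    phase <- c(rep("dark", config$n_dark),
               rep("blockA", config$n_blockA),
               rep("blockB", config$n_blockB))
    if (config$n_alternation > 0) {
      # mirrors the task engine's uniform draw per teleport
      alt <- sample(c("A", "B"), config$n_alternation, replace = TRUE)
      alt_type <- rep("vr", config$n_alternation)
      if (config$n_gain > 0) {
        alt_type[seq.int(config$n_alternation - config$n_gain + 1,
                         config$n_alternation)] <- "gain"
      }
      ctx <- c(ctx, alt)
      type <- c(type, alt_type)
      phase <- c(phase, rep("alternation", config$n_alternation))
    }
  } else {
    ctx <- c(rep("dark", config$n_dark), rep("none", config$n_rf))
    type <- c(rep("dark", config$n_dark), rep("vr", config$n_rf))
    phase <- c(rep("dark", config$n_dark), rep("foraging", config$n_rf))
  }
  if (!length(ctx)) {
    return(data.frame(trial = integer(0), context = character(0),
                      trial_type = character(0), phase = character(0)))
  }
  data.frame(trial = seq_along(ctx), context = ctx, trial_type = type,
             phase = phase, stringsAsFactors = FALSE)
}

# population map-label sequence given a trial sequence
map_sequence <- function(config, trials) {
  n <- nrow(trials)
  if (!n) return(integer(0))
  map <- integer(n)
  map[1L] <- 1L
  if (config$remap_mode == "context") {
    ctx_map <- c(A = 1L, B = 2L)
    for (i in seq_len(n)[-1L]) {
      prev <- map[i - 1L]
      ci <- trials$context[i]
      switched <- ci %in% c("A", "B") &&
        trials$context[i - 1L] %in% c("A", "B", "dark", "none") &&
        trials$context[i] != trials$context[i - 1L]
      if (switched && stats::runif(1) <= config$remap_probability &&
          config$remap_probability > 0) {
        map[i] <- ctx_map[[ci]]
      } else {
        map[i] <- prev
      }
    }
  } else {
    for (i in seq_len(n)[-1L]) {
      map[i] <- if (stats::runif(1) < config$random_remap_prob)
        3L - map[i - 1L] else map[i - 1L]
    }
  }
  map
}

#' Generate synthetic VR running behavior
#'
#' Simulates a head-fixed mouse on a circular VR track: a smoothed positive
#' autoregressive running-speed process advances the track position (scaled
#' by the VR gain on gain trials); reaching the track end teleports the mouse
#' seamlessly to the start and increments the trial counter. Licks and reward
#' deliveries are simulated inside each trial's reward zone: with probability
#' `lick_prob` the mouse requests the reward by licking before the zone
#' center, otherwise the reward is delivered automatically at the center.
#'
#' @param config A [synth_config()].
#' @return A `session_frames` data.frame sampled at exactly
#'   `config$frame_rate` with columns `t` (s), `position` (cm, in
#'   `[0, track_length)`), `trial`, `context`, `trial_type`, `speed` (cm/s),
#'   `lick` (count), `reward` (0/1), `reward_start`, `reward_end` (cm; NA
#'   when the trial has no zone). Attributes `track_length`, `frame_rate` and
#'   `trial_info` (per-trial context/type table) are attached. A config with
#'   zero total trials yields a zero-row frame table.
#' @export
generate_behavior <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  trials <- trial_sequence(config)
  n_trials <- nrow(trials)
  empty <- data.frame(t = numeric(0), position = numeric(0),
                      trial = integer(0), context = character(0),
                      trial_type = character(0), speed = numeric(0),
                      lick = numeric(0), reward = numeric(0),
                      reward_start = numeric(0), reward_end = numeric(0),
                      stringsAsFactors = FALSE)
  if (!n_trials) {
    return(structure(empty, class = c("session_frames", "data.frame"),
                     track_length = config$track_length,
                     frame_rate = config$frame_rate, trial_info = trials))
  }
  dt <- 1 / config$frame_rate
  L <- config$track_length

  # speed process: AR(1) relaxation toward the mean, smoothed, clipped
  gen_speed <- function(n) {
    v <- numeric(n)
    v[1L] <- config$speed_mean
    eps <- stats::rnorm(n, 0, config$speed_sd)
    for (i in seq_len(n)[-1L]) {
      v[i] <- v[i - 1L] + 0.02 * (config$speed_mean - v[i - 1L]) + 0.2 * eps[i]
    }
    pmin(pmax(gaussian_smooth(v, sd = 5), 2.000001), 149.999999)
  }
  est_frames <- ceiling(n_trials * L / max(config$speed_mean, 5) *
                          config$frame_rate * 2) + 1000L
  speed <- gen_speed(est_frames)

  gain_of <- ifelse(trials$trial_type == "gain", config$gain, 1)
  pos <- numeric(est_frames)
  tri <- integer(est_frames)
  p <- 0
  k <- 1L
  i <- 0L
  while (k <= n_trials) {
    i <- i + 1L
    if (i > length(speed)) speed <- c(speed, gen_speed(est_frames))
    pos[i] <- p
    tri[i] <- k
    p <- p + speed[i] * dt * gain_of[k]
    if (p >= L) {
      p <- p - L
      k <- k + 1L
    }
    if (i == length(pos)) {
      pos <- c(pos, numeric(est_frames))
      tri <- c(tri, integer(est_frames))
    }
  }
  n <- i
  frames <- data.frame(t = (seq_len(n) - 1L) * dt, position = pos[seq_len(n)],
                       trial = tri[seq_len(n)],
                       context = trials$context[tri[seq_len(n)]],
                       trial_type = trials$trial_type[tri[seq_len(n)]],
                       speed = speed[seq_len(n)], lick = 0, reward = 0,
                       reward_start = NA_real_, reward_end = NA_real_,
                       stringsAsFactors = FALSE)

  # reward zones and licking
  zone_center <- rep(NA_real_, n_trials)
  if (config$task == "SM") {
    zone_center[trials$context == "A"] <- 270
    zone_center[trials$context == "B"] <- 370
  } else {
    vr <- trials$trial_type != "dark"
    zone_center[vr] <- stats::runif(sum(vr), 75, 325)
  }
  for (k in seq_len(n_trials)) {
    zc <- zone_center[k]
    if (!is.finite(zc)) next
    rows <- which(frames$trial == k)
    zs <- zc - 25
    ze <- min(zc + 25, L - 1e-9)
    frames$reward_start[rows] <- zs
    frames$reward_end[rows] <- ze
    in_pre <- rows[frames$position[rows] >= zs & frames$position[rows] < zc]
    post <- rows[frames$position[rows] >= zc]
    if (length(in_pre) && stats::runif(1) < config$lick_prob) {
      hit <- in_pre[max(1L, ceiling(stats::runif(1) * length(in_pre)))]
      frames$lick[hit] <- 1
      frames$reward[hit] <- 1
    } else if (length(post)) {
      frames$reward[post[1L]] <- 1
    }
  }
  structure(frames, class = c("session_frames", "data.frame"),
            track_length = L, frame_rate = config$frame_rate,
            trial_info = trials)
}

# per-frame firing rate (Hz) of one unit given its parameters and the truth
unit_rate <- function(u, frames, truth_trials, config) {
  br <- config$baseline_rates
  n <- nrow(frames)
  tri <- frames$trial
  map <- truth_trials$map[tri]
  pos <- frames$position
  lam <- rep(0, n)
  if (u$archetype == "grid") {
    kappa <- 4
    bump <- function(x, phase, scale) {
      exp(kappa * (cos(2 * pi * (x - phase) / scale) - 1))
    }
    phase <- u$phase + truth_trials$drift[tri]
    shift <- ifelse(map == 2L, u$remap_shift, 0)
    dark <- frames$trial_type == "dark"
    # landmark-anchored periodic tuning in the light; pure distance (path
    # integration) tuning in the dark
    lam <- u$base + u$peak * bump(pos, phase + shift, u$scale)
    if (any(dark)) {
      dist_dark <- (tri[dark] - 1) * config$track_length + pos[dark]
      lam[dark] <- u$base + u$peak * bump(dist_dark, u$phase_dark, u$scale)
    }
  } else if (u$archetype == "ngs") {
    phase <- truth_trials$drift[tri]
    shift <- ifelse(map == 2L, u$remap_shift, 0)
    L <- config$track_length
    d1 <- (pos - (u$field1 + shift + phase)) %% L
    d1 <- pmin(d1, L - d1)
    d2 <- (pos - (u$field2 + shift + phase)) %% L
    d2 <- pmin(d2, L - d2)
    lam <- u$base + u$peak * (exp(-0.5 * (d1 / u$field_width)^2) +
                                exp(-0.5 * (d2 / u$field_width)^2))
    lam[frames$trial_type == "dark"] <- u$base
  } else if (u$archetype == "speed_pos") {
    lam <- pmax(0, u$base + u$slope * frames$speed)
  } else if (u$archetype == "speed_neg") {
    lam <- pmax(0, u$base + u$slope * frames$speed)
  } else if (u$archetype == "fs_in") {
    lam <- pmax(0, br$in_rate + u$slope * (frames$speed - config$speed_mean))
  } else {
    lam <- rep(br$untuned_rate, n)
  }
  lam * truth_trials$gain_jitter[cbind(tri, rep(u$row, n))]
}

#' Generate synthetic spike trains, unit metadata, and ground truth
#'
#' Draws spikes for each configured unit from an inhomogeneous Poisson
#' process whose rate is a function of track position (or traversed distance
#' on dark trials), population map label, and running speed, according to the
#' unit's archetype: distance-periodic context-remapping grid cells,
#' non-grid spatial cells with discrete place fields, positively and
#' negatively speed-modulated cells, fast-spiking interneurons, and untuned
#' cells. Context-B spatial maps are phase-shifted copies of context-A maps
#' (global remapping); per-trial log-normal rate jitter (`rate_noise`) and a
#' per-trial field-phase random walk (`drift_sd`) add controllable noise.
#'
#' @param config A [synth_config()].
#' @param frames Frames from [generate_behavior()] (non-empty).
#' @return List with `spikes` (data.frame `unit`, `t`), `units` (unit
#'   metadata: waveform duration/halfwidth in ms, mean rate, spike count,
#'   signal-to-noise, repolarization slope, tip distance, peak:trough ratio),
#'   and `truth` (list of per-unit generative parameters and the per-trial
#'   map/context table).
#' @export
generate_spikes <- function(config, frames) {
  stopifnot(inherits(config, "synth_config"))
  if (!nrow(frames)) stop("frames must be non-empty")
  set.seed(child_seed(config$seed, 1L))
  trials <- attr(frames, "trial_info")
  n_trials <- nrow(trials)
  counts <- config$cell_counts
  counts <- counts[counts > 0]
  n_units <- sum(counts)
  archetypes <- rep(names(counts), counts)
  br <- config$baseline_rates

  tt <- trials
  tt$map <- map_sequence(config, trials)
  tt$drift <- cumsum(stats::rnorm(n_trials, 0, config$drift_sd))
  # per trial x unit multiplicative rate jitter
  jit <- matrix(exp(stats::rnorm(n_trials * n_units, 0, config$rate_noise)),
                n_trials, n_units)
  if (config$rate_noise == 0) jit[] <- 1

  units <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    a <- archetypes[i]
    u <- list(row = i, archetype = a, scale = NA_real_, phase = NA_real_,
              phase_dark = NA_real_, remap_shift = NA_real_,
              field1 = NA_real_, field2 = NA_real_, field_width = NA_real_,
              base = NA_real_, peak = NA_real_, slope = NA_real_)
    if (a == "grid") {
      u$scale <- config$grid_scales[1L + (i - 1L) %% length(config$grid_scales)]
      u$phase <- stats::runif(1, 0, u$scale)
      u$phase_dark <- stats::runif(1, 0, u$scale)
      u$remap_shift <- stats::runif(1, 0.35, 0.65) * u$scale
      u$base <- br$grid_base
      u$peak <- br$grid_peak * stats::runif(1, 0.8, 1.2)
    } else if (a == "ngs") {
      u$field1 <- stats::runif(1, 0, config$track_length)
      u$field2 <- (u$field1 + stats::runif(1, 120, 280)) %% config$track_length
      u$field_width <- stats::runif(1, 10, 20)
      u$remap_shift <- stats::runif(1, 60, 140)
      u$base <- br$ngs_base
      u$peak <- br$ngs_peak * stats::runif(1, 0.8, 1.2)
    } else if (a == "speed_pos") {
      u$base <- br$speed_base
      u$slope <- stats::runif(1, 0.08, 0.15)
    } else if (a == "speed_neg") {
      u$base <- br$speed_base + 8
      u$slope <- -stats::runif(1, 0.08, 0.15)
    } else if (a == "fs_in") {
      u$slope <- stats::runif(1, 0.1, 0.3)
    }
    units[[i]] <- u
  }

  dt <- 1 / config$frame_rate
  spk_unit <- list()
  meta <- vector("list", n_units)
  duration_s <- nrow(frames) * dt
  tr_jit <- tt
  tr_jit$gain_jitter <- jit
  for (i in seq_len(n_units)) {
    u <- units[[i]]
    lam <- unit_rate(u, frames, tr_jit, config)
    cnt <- stats::rpois(length(lam), lam * dt)
    tot <- sum(cnt)
    st <- if (tot) sort(rep(frames$t, cnt) + stats::runif(tot, 0, dt)) else numeric(0)
    spk_unit[[i]] <- st
    is_in <- u$archetype == "fs_in"
    meta[[i]] <- data.frame(
      unit = i, archetype = u$archetype,
      duration_ms = if (is_in) stats::runif(1, 0.20, 0.32) else stats::runif(1, 0.45, 0.80),
      halfwidth_ms = if (is_in) stats::runif(1, 0.08, 0.15) else stats::runif(1, 0.15, 0.28),
      mean_rate = tot / duration_s, n_spikes = tot,
      snr = stats::runif(1, 1.5, 4),
      repolarization_slope = stats::runif(1, 0.1, 1),
      tip_distance = stats::runif(1, 100, 3000),
      peak_trough = stats::runif(1, 0.3, 0.8),
      stringsAsFactors = FALSE)
  }
  spikes <- data.frame(
    unit = rep(seq_len(n_units), lengths(spk_unit)),
    t = unlist(spk_unit),
    stringsAsFactors = FALSE)
  truth_units <- do.call(rbind, lapply(units, function(u) {
    data.frame(unit = u$row, archetype = u$archetype, grid_scale = u$scale,
               phase = u$phase, remap_shift = u$remap_shift,
               speed_slope = u$slope, stringsAsFactors = FALSE)
  }))
  list(spikes = spikes, units = do.call(rbind, meta),
       truth = list(units = truth_units, trials = tt))
}

#' Generate a complete synthetic session bundle
#'
#' Convenience wrapper running [generate_behavior()] then
#' [generate_spikes()].
#' @param config A [synth_config()].
#' @return A `session_bundle` list with `frames`, `spikes`, `units`, `truth`,
#'   `config`.
#' @export
generate_session <- function(config) {
  frames <- generate_behavior(config)
  sp <- generate_spikes(config, frames)
  structure(list(frames = frames, spikes = sp$spikes, units = sp$units,
                 truth = sp$truth, config = config),
            class = "session_bundle")
}

bundle_required_columns <- list(
  frames = c("t", "position", "trial", "context", "trial_type", "speed",
             "lick", "reward"),
  spikes = c("unit", "t"),
  units = c("unit", "duration_ms", "halfwidth_ms", "mean_rate", "n_spikes",
            "snr", "repolarization_slope", "tip_distance", "peak_trough"))

#' Write / read a session bundle
#'
#' A bundle is a directory holding `frames.csv`, `spikes.csv`, `units.csv`,
#' `truth.json` and `config.yaml`. The column schema is documented in
#' `system.file("extdata", "session-schema.yaml", package = "mecmap")`.
#'
#' @param bundle A `session_bundle` (from [generate_session()] or
#'   [read_session()]).
#' @param path Directory to write to / read from (created if missing).
#' @return `write_session()` returns `path` invisibly; `read_session()`
#'   returns a `session_bundle`. Missing files or columns raise an error
#'   naming the missing piece.
#' @export
write_session <- function(bundle, path) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(bundle$frames), file.path(path, "frames.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$spikes, file.path(path, "spikes.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$units, file.path(path, "units.csv"),
                   row.names = FALSE)
  jsonlite::write_json(bundle$truth, file.path(path, "truth.json"),
                       dataframe = "columns", digits = NA, auto_unbox = TRUE)
  cfg <- bundle$config
  yaml::write_yaml(unclass(cfg), file.path(path, "config.yaml"))
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) stop("bundle directory not found: ", path)
  read_tab <- function(name) {
    f <- file.path(path, paste0(name, ".csv"))
    if (!file.exists(f)) stop("bundle is missing the '", name, "' table")
    tab <- utils::read.csv(f, stringsAsFactors = FALSE)
    need <- bundle_required_columns[[name]]
    missing <- setdiff(need, names(tab))
    if (length(missing)) {
      stop("table '", name, "' is missing column(s): ",
           paste(missing, collapse = ", "))
    }
    tab
  }
  frames <- read_tab("frames")
  spikes <- read_tab("spikes")
  units <- read_tab("units")
  tf <- file.path(path, "truth.json")
  truth <- if (file.exists(tf)) {
    tr <- jsonlite::read_json(tf, simplifyVector = TRUE)
    lapply(tr, as.data.frame)
  } else NULL
  cf <- file.path(path, "config.yaml")
  config <- if (file.exists(cf)) {
    cfg <- yaml::read_yaml(cf)
    cfg$cell_counts <- unlist(cfg$cell_counts)
    cfg$grid_scales <- unlist(cfg$grid_scales)
    structure(cfg, class = "synth_config")
  } else NULL
  trial_info <- if (!is.null(truth)) {
    cols <- intersect(c("trial", "context", "trial_type", "phase"),
                      names(truth$trials))
    unique(truth$trials[cols])
  } else {
    unique(frames[c("trial", "context", "trial_type")])
  }
  rownames(trial_info) <- NULL
  frames <- structure(frames, class = c("session_frames", "data.frame"),
                      track_length = if (!is.null(config)) config$track_length else 400,
                      frame_rate = if (!is.null(config)) config$frame_rate else 50,
                      trial_info = trial_info)
  structure(list(frames = frames, spikes = spikes, units = units,
                 truth = truth, config = config),
            class = "session_bundle")
}
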