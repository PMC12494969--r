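# minimal hand-built frames: one trial per lap, uniform sampling
flat_frames <- function(n_trials = 1, frame_rate = 50, speed = 40,
                        track_length = 400) {
  dt <- 1 / frame_rate
  n_per <- round(track_length / speed / dt)
  pos <- rep(seq(0, track_length - track_length / n_per,
                 length.out = n_per), n_trials)
  structure(data.frame(t = (seq_len(n_per * n_trials) - 1) * dt,
                       position = pos,
                       trial = rep(seq_len(n_trials), each = n_per),
                       speed = speed),
            class = c("session_frames", "data.frame"),
            track_length = track_length, frame_rate = frame_rate)
}

test_that("rates are spike counts over occupancy, per trial and bin", {
  f <- flat_frames(1, frame_rate = 50, speed = 40)
  # occupancy per 2 cm bin = (2 cm / 40 cm/s) = 0.05 s -> 1 spike = 20 Hz
  st <- f$t[f$position >= 100 & f$position < 102][1]
  rm <- trial_rate_matrix(st, f)
  k <- 100 / 2 + 1
  expect_equal(rm$values[1, k], 1 / rm$occupancy[1, k])
  expect_equal(sum(rm$values[1, -k]), 0)
  # no spikes -> zero matrix
  rm0 <- trial_rate_matrix(numeric(0), f)
  expect_true(all(rm0$values == 0))
})

test_that("smoothing preserves the trial mean rate", {
  f <- flat_frames(3)
  set.seed(2)
  st <- sort(runif(200, 0, max(f$t)))
  raw <- trial_rate_matrix(st, f)
  sm <- trial_rate_matrix(st, f, smoothing_sd = 4)
  for (i in 1:3) {
    expect_equal(mean(sm$values[i, ]), mean(raw$values[i, ]),
                 tolerance = 1e-9)
  }
})

test_that("coherence matches its oracle and behaves on canonical inputs", {
  bins <- 200
  sinus <- 3 + 2 * sin(2 * pi * seq_len(bins) / bins)
  expect_gt(spatial_coherence(sinus), 0.95)
  expect_equal(spatial_coherence(sinus), oracle_coherence(sinus),
               tolerance = 1e-12)
  set.seed(7)
  noise_vals <- replicate(50, spatial_coherence(rnorm(bins)))
  expect_lt(abs(mean(noise_vals)), 0.05)
  expect_gte(mean(abs(noise_vals) < 0.2), 0.9)
  expect_true(is.na(spatial_coherence(rep(2, bins))))
})

test_that("sparsity matches hand computations and the oracle", {
  # uniform rate, uniform occupancy -> 1
  expect_equal(spatial_sparsity(rep(3, 200), rep(1 / 200, 200)), 1)
  # single active bin of 200 -> 1/P = 200
  r <- c(rep(0, 199), 5)
  expect_equal(spatial_sparsity(r, rep(1 / 200, 200)), 200)
  # two-bin toy
  expect_equal(spatial_sparsity(c(2, 0), c(0.5, 0.5)), 2)
  set.seed(3)
  rr <- runif(10)
  pp <- runif(10)
  pp <- pp / sum(pp)
  expect_equal(spatial_sparsity(rr, pp), oracle_sparsity(pp, rr),
               tolerance = 1e-12)
  expect_true(is.na(spatial_sparsity(rep(0, 10), rep(0.1, 10))))
})

test_that("information matches hand computations, is >= 0, and is permutation-invariant", {
  expect_equal(spatial_information(rep(3, 200), rep(1 / 200, 200)), 0)
  expect_equal(spatial_information(c(2, 0), c(0.5, 0.5)), 1)
  set.seed(5)
  r <- rexp(20)
  p <- rep(1 / 20, 20)
  expect_equal(spatial_information(r, p), oracle_information(p, r),
               tolerance = 1e-12)
  expect_gte(spatial_information(r, p), 0)
  perm <- sample(20)
  expect_equal(spatial_information(r[perm], p[perm]),
               spatial_information(r, p), tolerance = 1e-12)
})

test_that("sparsity is >= 1 under uniform occupancy", {
  set.seed(11)
  for (i in 1:20) {
    r <- rexp(50)
    expect_gte(spatial_sparsity(r, rep(1 / 50, 50)), 1 - 1e-12)
  }
})

test_that("dark autocorrelation of a periodic rate peaks at multiples of the period", {
  f <- flat_frames(6)
  rm <- trial_rate_matrix(numeric(0), f, trials = 1:6)
  # overwrite with an analytic period-80 cm cosine rate
  bins <- rm$bin_centers
  rate <- 2 + cos(2 * pi * bins / 80)
  rm$values <- matrix(rep(rate, 6), nrow = 6, byrow = TRUE)
  ac <- dark_autocorrelation(rm)
  expect_equal(ac$values[1], 1, tolerance = 1e-9)
  expect_true(all(abs(ac$values) <= 1 + 1e-9))
  expect_true(all(c(80, 160, 240) %in% ac$peaks$lag_cm))
  expect_lte(abs(ac$max_peak$lag_cm %% 80), 2)
})

test_that("white-noise rate vectors rarely produce qualifying peaks", {
  f <- flat_frames(6)
  hits <- 0L
  for (s in 1:40) {
    set.seed(s)
    rm <- trial_rate_matrix(numeric(0), f, trials = 1:6)
    rm$values <- matrix(rnorm(6 * 200), nrow = 6)
    ac <- dark_autocorrelation(rm)
    if (!is.null(ac$max_peak)) hits <- hits + 1L
  }
  expect_lte(hits / 40, 0.05)
})

test_that("spike-time shuffles preserve spike count and stay in the session span", {
  b <- small_sm_session()
  st <- b$spikes$t[b$spikes$unit == 1]
  got_n <- integer(0)
  null <- shuffle_null(st, b$frames, function(ts, fr) {
    got_n <<- c(got_n, length(ts))
    max(ts)
  }, n_shuffles = 10, seed = 3)
  expect_true(all(got_n == length(st)))
  expect_true(all(null$values <= max(b$frames$t) + 1))
  expect_true(all(null$offsets >= 20))
})

test_that("shuffling requires a session longer than the minimum offset", {
  f <- flat_frames(1)  # 10 s
  expect_error(shuffle_null(c(1, 2), f, function(ts, fr) 0),
               "duration")
})

test_that("distance tuning requires a qualifying peak above the shuffle heights", {
  expect_false(detect_distance_tuning(NULL, rnorm(100)))
  ac <- list(max_peak = data.frame(lag_cm = 80, height = 0.5,
                                   prominence = 0.3, width_cm = 20))
  expect_true(detect_distance_tuning(ac, rep(0.1, 100)))
  expect_false(detect_distance_tuning(ac, rep(0.9, 100)))
  # ties at q99 count as exceedance (greater than or equal)
  expect_true(detect_distance_tuning(ac, rep(0.3, 100)))
})

test_that("grid scale takes the first relaxed peak, not the largest", {
  lags <- seq(0, 800, by = 2)
  vals <- 0.2 * exp(-0.5 * ((lags - 50) / 8)^2) +
    0.6 * exp(-0.5 * ((lags - 100) / 8)^2)
  vals[1] <- 1
  ac <- list(lags = lags, values = vals)
  expect_equal(estimate_grid_scale(ac), 50)
})

test_that("grid scale is recovered within one bin across generative scales", {
  errs <- vapply(c(40, 60, 80, 100), function(scale) {
    cfg <- synth_config(seed = 100 + scale, n_dark = 10, n_blockA = 2,
                        n_blockB = 2, n_alternation = 0, n_gain = 0,
                        cell_counts = c(grid = 1), grid_scales = scale,
                        rate_noise = 0, drift_sd = 0)
    b <- generate_session(cfg)
    info <- attr(b$frames, "trial_info")
    rm <- trial_rate_matrix(b$spikes$t, b$frames, smoothing_sd = 4,
                            trials = info$trial[info$trial_type == "dark"])
    est <- estimate_grid_scale(dark_autocorrelation(rm))
    abs(est - scale)
  }, numeric(1))
  expect_lte(median(errs), 2)
})

test_that("unit depth subtracts the median tip distance from the insertion depth", {
  expect_equal(estimate_unit_depth(rep(500, 11), 3000), 2500)
  expect_equal(estimate_unit_depth(rep(0, 5), 2800), 2800)
  # robust to one outlier channel
  expect_equal(estimate_unit_depth(c(rep(500, 10), 5000), 3000), 2500)
})
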