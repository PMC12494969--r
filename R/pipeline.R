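#' Per-cell spatial and speed metrics with shuffle-null cell typing
#'
#' Runs the full single-cell stage on a session bundle: quality control,
#' spatial rate maps, coherence/sparsity/information (on Block A trials for
#' the two-context task), dark-running autocorrelation and distance tuning,
#' grid-scale estimation, speed scores, and shuffle-null classification
#' into functional cell types.
#'
#' @param bundle A `session_bundle`.
#' @param n_shuffles Shuffles per null distribution (default 100).
#' @param seed RNG seed for the shuffle offsets.
#' @param kernel_sd_cm Instantaneous-rate smoothing SD (cm).
#' @param apply_qc Run [qc_filter_units()] first (default TRUE).
#' @return data.frame with one row per retained unit: metrics
#'   (`coherence`, `sparsity`, `information`, `speed_score`, `slope`,
#'   `intercept`, `speed_stability`, `trial_stability`, `grid_scale`,
#'   `dark_rate`, `mean_rate`) and labels (`is_IN`, `is_excitatory`,
#'   `is_speed`, `is_speed_pos`, `is_speed_neg`, `is_spatial`,
#'   `distance_tuned`, `is_grid`, `is_NGS`, and the derived subtypes).
#'   Attribute `session_excluded` carries the QC session flag.
#' @export
cell_metrics <- function(bundle, n_shuffles = 100, seed = 1L,
                         kernel_sd_cm = 40, apply_qc = TRUE) {
  frames <- bundle$frames
  mask <- filter_stationary(frames)
  info <- attr(frames, "trial_info")
  task <- bundle$config$task %||% "SM"
  units <- bundle$units
  session_excluded <- FALSE
  if (apply_qc) {
    qc <- qc_filter_units(units)
    units <- qc$units
    session_excluded <- qc$session_excluded
  }
  dark_trials <- info$trial[info$trial_type == "dark"]
  blockA <- info$trial[!is.na(info$phase) & info$phase == "blockA"]
  blockB <- info$trial[!is.na(info$phase) & info$phase == "blockB"]
  metric_trials <- if (task == "SM" && length(blockA)) blockA else
    info$trial[info$trial_type == "vr"]
  fs <- attr(frames, "frame_rate") %||% 50

  rows <- vector("list", nrow(units))
  for (i in seq_len(nrow(units))) {
    uid <- units$unit[i]
    st <- bundle$spikes$t[bundle$spikes$unit == uid]

    rmat <- trial_rate_matrix(st, frames, mask = mask,
                              trials = metric_trials)
    coh <- spatial_coherence(rmat)
    spars <- spatial_sparsity(rmat)
    info_rate <- spatial_information(rmat)

    spat_stat <- function(ts, fr) {
      rm <- trial_rate_matrix(ts, fr, mask = mask, trials = metric_trials)
      c(spatial_coherence(rm), spatial_sparsity(rm))
    }
    spat_null <- shuffle_null(st, frames, spat_stat, n_shuffles,
                              seed = child_seed(seed, i))
    is_spatial <- classify_spatial_cells(coh, spars,
                                         spat_null$values[, 1L],
                                         spat_null$values[, 2L])

    sp <- speed_scores(st, frames, mask, kernel_sd_cm)
    speed_stat <- function(ts, fr) {
      s <- speed_scores(ts, fr, mask, kernel_sd_cm)
      c(s$speed_score, s$speed_stability)
    }
    speed_null <- shuffle_null(st, frames, speed_stat, n_shuffles,
                               seed = child_seed(seed, 10000L + i))
    spd <- classify_speed_cells(sp$speed_score, sp$speed_stability,
                                speed_null$values[, 1L],
                                speed_null$values[, 2L])

    # dark distance tuning
    dark_rate <- NA_real_
    tuned <- FALSE
    scale <- NA_real_
    if (length(dark_trials)) {
      dark_rate <- subset_mean_rate(st, frames, dark_trials)
      dmat <- trial_rate_matrix(st, frames, smoothing_sd = 4, mask = mask,
                                trials = dark_trials)
      ac <- dark_autocorrelation(dmat)
      if (!is.null(ac) && !is.null(ac$max_peak)) {
        lag_idx <- which(ac$lags == ac$max_peak$lag_cm)
        height_stat <- function(ts, fr) {
          dm <- trial_rate_matrix(ts, fr, smoothing_sd = 4, mask = mask,
                                  trials = dark_trials)
          a <- dark_autocorrelation(dm)
          if (is.null(a) || length(a$values) < lag_idx) return(NA_real_)
          a$values[lag_idx]
        }
        hnull <- shuffle_null(st, frames, height_stat, n_shuffles,
                              seed = child_seed(seed, 20000L + i))
        tuned <- detect_distance_tuning(ac, hnull$values[, 1L])
      }
      if (tuned) scale <- estimate_grid_scale(ac)
    }

    is_in <- split_in_excitatory(units[i, , drop = FALSE])
    noise_ratios <- numeric(0)
    if (task == "SM" && length(blockA) && length(blockB)) {
      noise_ratios <- c(
        rate_noise_ratio(trial_rate_matrix(st, frames, mask = mask,
                                           trials = blockA)),
        rate_noise_ratio(trial_rate_matrix(st, frames, mask = mask,
                                           trials = blockB)))
    }
    overall_rate <- length(st) / (nrow(frames) / fs)
    gr <- classify_grid_cells(!is_in, is_spatial, tuned,
                              if (length(dark_trials)) dark_rate else
                                NA_real_,
                              overall_rate, noise_ratios)

    lab <- derive_subtypes(list(
      is_IN = is_in, is_excitatory = !is_in, is_speed = spd$is_speed,
      is_speed_pos = spd$is_speed_pos, is_speed_neg = spd$is_speed_neg,
      is_spatial = is_spatial, distance_tuned = tuned,
      is_grid = isTRUE(gr$is_grid), is_NGS = isTRUE(gr$is_NGS)))

    rows[[i]] <- data.frame(
      unit = uid, coherence = coh, sparsity = spars,
      information = info_rate, speed_score = sp$speed_score,
      slope = sp$slope, intercept = sp$intercept,
      speed_stability = sp$speed_stability,
      trial_stability = sp$trial_stability, grid_scale = scale,
      dark_rate = dark_rate, mean_rate = overall_rate,
      is_IN = lab$is_IN, is_excitatory = lab$is_excitatory,
      is_speed = lab$is_speed, is_speed_pos = lab$is_speed_pos,
      is_speed_neg = lab$is_speed_neg, is_spatial = lab$is_spatial,
      distance_tuned = lab$distance_tuned, is_grid = lab$is_grid,
      is_NGS = lab$is_NGS, is_speed_only_pos = lab$is_speed_only_pos,
      is_speed_only_neg = lab$is_speed_only_neg,
      is_IN_speed = lab$is_IN_speed, is_grid_speed = lab$is_grid_speed,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "session_excluded") <- session_excluded
  out
}

#' Population spatial-map analysis of a session
#'
#' Builds the normalized population tensor from the selected cells, selects
#' the number of maps (silhouette maximization plus one-map detection
#' against the rotation-shuffle control), fits the final factorized k-means
#' model, relabels maps canonically, assigns context identities
#' (two-context task), and computes remapping and alignment statistics.
#'
#' @param bundle A `session_bundle`.
#' @param cells Unit ids forming the population (e.g., classified grid
#'   cells). Defaults to all units.
#' @param k_max,reps,restarts Model-selection parameters.
#' @param half Track restriction passed to [normalize_tensor()].
#' @param sort_alternation Context-sort alternation trials (default TRUE
#'   for SM).
#' @param seed RNG seed.
#' @param min_cells Population eligibility gate.
#' @return List with `tensor`, `network`, `selection`, `cv`
#'   (real/shuffled test R2), `one_map`, `model`, `labeling`,
#'   `remap` (per-phase frequencies), `alignment`.
#' @export
map_analysis <- function(bundle, cells = NULL, k_max = 4, reps = 10,
                         restarts = 100, half = "full",
                         sort_alternation = NULL, seed = 1L,
                         min_cells = 10) {
  frames <- bundle$frames
  mask <- filter_stationary(frames)
  info <- attr(frames, "trial_info")
  task <- bundle$config$task %||% "SM"
  if (is.null(sort_alternation)) sort_alternation <- task == "SM"
  if (is.null(cells)) cells <- sort(unique(bundle$spikes$unit))
  vr_trials <- info$trial[info$trial_type == "vr"]
  rate_list <- lapply(cells, function(uid) {
    st <- bundle$spikes$t[bundle$spikes$unit == uid]
    trial_rate_matrix(st, frames, smoothing_sd = 5, mask = mask,
                      trials = vr_trials)
  })
  tensor <- normalize_tensor(rate_list, info,
                             sort_alternation = sort_alternation,
                             half = half)
  network <- network_similarity_matrix(tensor, min_cells = min_cells)
  sel <- select_k(tensor, k_max = k_max, reps = reps, restarts = restarts,
                  seed = seed)
  cv <- speckled_cv(tensor, sel$k_star, restarts = restarts,
                    seed = child_seed(seed, 3L))
  shuf <- rotation_shuffle(tensor, seed = child_seed(seed, 4L))
  cv_sh <- speckled_cv(shuf, sel$k_star, restarts = restarts,
                       seed = child_seed(seed, 3L))
  om <- detect_one_map(cv$test_r2, cv_sh$test_r2)
  k_final <- if (om$one_map) 1L else sel$k_star
  model <- fit_factorized_kmeans(tensor, k_final, restarts = restarts,
                                 seed = child_seed(seed, 5L))
  tinfo <- attr(tensor, "trial_info")
  speeds <- vapply(tinfo$trial, function(k)
    mean(frames$speed[frames$trial == k]), numeric(1L))
  labeling <- relabel_maps(model, task = if (task == "SM") "SM" else "RF",
                           trial_info = tinfo, trial_speeds = speeds)
  alignment <- NULL
  if (task == "SM") {
    labeling <- assign_context_identity(labeling, network, tinfo)
    alignment <- context_alignment(labeling$trial_identity, tinfo$context,
                                   tinfo$phase)
  }
  # remapping statistics in chronological trial order
  chron <- order(tinfo$trial)
  remap <- remap_frequency(labeling$labels[chron], tinfo$phase[chron])
  list(tensor = tensor, network = network, selection = sel, cv = cv,
       cv_shuffled = cv_sh, one_map = om, model = model,
       labeling = labeling, remap = remap, alignment = alignment)
}

#' Export per-cell metrics as tidy CSV
#' @param metrics data.frame from [cell_metrics()].
#' @param path Output CSV path.
#' @return `path` invisibly.
#' @export
export_cell_metrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
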