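# Validation studies: seeded phantom batteries that exercise the full
# pipeline against generator ground truth. The acceptance script and the
# test suite both run these; problem sizes are chosen so a full battery
# completes in minutes on one CPU (the methods vignette records them).

#' Core-localization study on seeded rotor phantoms
#'
#' Rotor phantoms cycling through the three observed core classes (line,
#' line plus patch, multiple lines) with randomized geometry and period,
#' each analysed blind by [detect_core()]; matched planar-wave controls
#' check that uniform propagation yields no core.
#'
#' @param n_phantoms Number of rotor phantoms.
#' @param n_controls Number of planar-wave control recordings.
#' @param dim Field size for the rotor phantoms, pixels.
#' @param control_dim Field size for the planar controls.
#' @param duration_s Recording length, s.
#' @param noise_sd Rendering noise.
#' @param seed Base seed.
#' @return List with `phantoms` (per-phantom data frame: type, period,
#'   found, IoU, Hausdorff, morphology, perimeter, DF) and `controls`
#'   (per-control `false_core` flags).
#' @export
study_core_localization <- function(n_phantoms = 20L, n_controls = 20L,
                                    dim = c(256L, 256L),
                                    control_dim = c(200L, 200L),
                                    duration_s = 3, noise_sd = 0.05,
                                    seed = 1L) {
  cfg <- reentry_config(df_band_hz = c(1, 10))
  types <- c("line", "line_plus_patch", "multi_line")
  rows <- vector("list", n_phantoms)
  for (i in seq_len(n_phantoms)) {
    s <- child_seed(seed, i)
    set.seed(s)
    type <- types[(i - 1L) %% 3L + 1L]
    core <- core_structure(
      type,
      center = dim / 2 + runif(2, -15, 15),
      angle_deg = runif(1, 0, 360),
      length_px = switch(type, multi_line = runif(1, 25, 35),
                         line_plus_patch = runif(1, 35, 45),
                         runif(1, 45, 70)),
      n_branches = 3L,
      patch_radius_px = runif(1, 10, 12))
    period <- runif(1, 310, 480)
    ph <- make_rotor_phantom(core, period_ms = period, dim = dim,
                             duration_s = duration_s, noise_sd = noise_sd,
                             seed = s)
    cg <- detect_core(ph$movie, cfg, max_cycles = 6L)
    rows[[i]] <- data.frame(
      phantom = i, type = type, period_ms = period, found = cg$found,
      iou = mask_iou(cg$mask, ph$truth$core_mask),
      hausdorff_px = mask_hausdorff(cg$mask, ph$truth$core_mask),
      morphology = cg$morphology, perimeter_mm = cg$perimeter_mm,
      dominant_frequency_hz = cg$dominant_frequency_hz, seed = s)
  }
  controls <- vector("list", n_controls)
  for (i in seq_len(n_controls)) {
    s <- child_seed(seed, 1000L + i)
    set.seed(s)
    period <- runif(1, 330, 450)
    onsets <- seq(0, by = period, length.out = ceiling(duration_s * 1000 / period))
    pw <- planar_wave_phantom(onsets_ms = onsets, dim = control_dim,
                              duration_s = duration_s,
                              direction_deg = runif(1, 0, 360),
                              noise_sd = noise_sd, seed = s)
    cg <- tryCatch(detect_core(pw$movie, cfg, max_cycles = 6L),
                   error = function(e) NULL)
    controls[[i]] <- data.frame(control = i,
                                false_core = !is.null(cg) && cg$found,
                                seed = s)
  }
  list(phantoms = do.call(rbind, rows), controls = do.call(rbind, controls))
}

#' Dominant-frequency and wavefront-counting study
#'
#' Dominant-frequency recovery on noise-free periodic transient trains
#' across the physiological rotor band, and exact wavefront counting on
#' noise-free planar-wave trains.
#'
#' @param frequencies_hz Frequencies probed.
#' @param duration_s Trace duration, s.
#' @param wave_counts Planar-wave train lengths checked.
#' @param dim Field size for the counting movies.
#' @param seed Base seed.
#' @return List with `df_table` (`frequency_hz`, `estimate_hz`, `error_hz`)
#'   and `count_table` (`n_waves`, `n_detected`).
#' @export
study_frequency_counting <- function(frequencies_hz = seq(1.4, 3.3, by = 0.1),
                                     duration_s = 10,
                                     wave_counts = c(3L, 8L, 14L, 20L),
                                     dim = c(160L, 160L), seed = 1L) {
  kern <- transient_kernel("calcium")
  fr <- 100
  df_rows <- lapply(frequencies_hz, function(f0) {
    period <- 1000 / f0
    tab <- periodic_kernel_table(kern, period)
    t_ms <- (seq_len(duration_s * fr) - 1L) * 1000 / fr
    tr <- new_trace(tab$values[as.integer(t_ms %% period + 0.5) + 1L], fr)
    est <- dominant_frequency(tr, band = c(0.5, 10))
    data.frame(frequency_hz = f0, estimate_hz = est$frequency,
               error_hz = est$frequency - f0)
  })
  cfg <- reentry_config()
  cnt_rows <- lapply(seq_along(wave_counts), function(i) {
    k <- wave_counts[i]
    set.seed(child_seed(seed, i))
    pw <- planar_wave_phantom(onsets_ms = seq(0, by = 400, length.out = k),
                              dim = dim, noise_sd = 0,
                              direction_deg = runif(1, 0, 360),
                              seed = child_seed(seed, i))
    wf <- segment_wavefronts(pw$movie, cfg)
    data.frame(n_waves = k, n_detected = nrow(wf))
  })
  list(df_table = do.call(rbind, df_rows),
       count_table = do.call(rbind, cnt_rows))
}

#' Core-cell activity study
#'
#' One phantom per core-cell mode: a double-rate core cell (driven
#' alternately from both sides) must yield twice the rotor rate within one
#' event, and a silent core cell must yield zero detected events at the
#' reference noise level.
#'
#' @param period_ms Rotor period.
#' @param duration_s Recording length (10 s gives ~29 rotor cycles at
#'   345 ms).
#' @param noise_sd Rendering noise.
#' @param dim Field size.
#' @param seed Seed.
#' @return List with `off_core_events`, `double_rate_events`,
#'   `silent_events`, `expected_cycles`.
#' @export
study_core_cell_activity <- function(period_ms = 345, duration_s = 10,
                                     noise_sd = 0.05, dim = c(128L, 128L),
                                     seed = 1L) {
  cfg <- reentry_config(df_band_hz = c(1, 10))
  core <- core_structure("line", center = dim / 2, angle_deg = 15,
                         length_px = 40)
  run_mode <- function(mode) {
    make_rotor_phantom(core, period_ms = period_ms, dim = dim,
                       duration_s = duration_s, noise_sd = noise_sd,
                       core_cell_mode = mode, seed = seed)
  }
  events_at <- function(ph, px) {
    tr <- extract_trace(ph$movie, matrix(px, 1))
    length(detect_activations(tr, cfg))
  }
  dbl <- run_mode("double_rate")
  sil <- run_mode("silent")
  core_px <- which(dbl$truth$core_mask & !dbl$truth$patch_mask,
                   arr.ind = TRUE)[1, ] - 1L
  off_px <- c(dim[1] / 2 + 30L, dim[2] / 2 - 30L)
  list(off_core_events = events_at(dbl, off_px),
       double_rate_events = events_at(dbl, core_px),
       silent_events = events_at(sil, core_px),
       expected_cycles = floor(duration_s * 1000 / period_ms))
}

#' Dual-channel concordance study
#'
#' A dual voltage/calcium rotor phantom with the imposed three-frame
#' calcium lag: recovers the lag from paired single-cell traces and
#' compares the voltage- and calcium-derived core masks.
#'
#' @param ca_lag_frames Imposed lag.
#' @param noise_sd Rendering noise.
#' @param dim Field size.
#' @param duration_s Recording length.
#' @param seed Seed.
#' @return List with `lag_frames` (median over probed cells), `lag_all`,
#'   `dice`, `area_voltage`, `area_calcium`, `iou_voltage`, `iou_calcium`.
#' @export
study_dual_channel <- function(ca_lag_frames = 3L, noise_sd = 0.05,
                               dim = c(192L, 192L), duration_s = 4,
                               seed = 1L) {
  cfg <- reentry_config(df_band_hz = c(1, 10))
  core <- core_structure("line", center = dim / 2, angle_deg = 70,
                         length_px = 50)
  ph <- make_rotor_phantom(core, period_ms = 345, dim = dim,
                           duration_s = duration_s, noise_sd = noise_sd,
                           dual = TRUE, ca_lag_frames = ca_lag_frames,
                           seed = seed)
  set.seed(child_seed(seed, 5L))
  lags <- vapply(seq_len(6L), function(i) {
    repeat {
      px <- c(sample.int(dim[1], 1L), sample.int(dim[2], 1L)) - 1L
      if (!ph$truth$inactive_voltage[px[1] + 1L, px[2] + 1L]) break
    }
    tv <- extract_trace(ph$movie_voltage, matrix(px, 1))
    tc <- extract_trace(ph$movie, matrix(px, 1))
    as.numeric(estimate_channel_lag(tv, tc, config = cfg)$lag)
  }, 0)
  core_v <- detect_core(ph$movie_voltage, cfg)
  core_c <- detect_core(ph$movie, cfg)
  cmp <- compare_block_maps(core_v$mask, core_c$mask)
  list(lag_frames = median(lags, na.rm = TRUE), lag_all = lags,
       dice = cmp$dice, area_voltage = cmp$area_a,
       area_calcium = cmp$area_b,
       iou_voltage = mask_iou(core_v$mask, ph$truth$core_mask),
       iou_calcium = mask_iou(core_c$mask, ph$truth$core_mask))
}

#' Perimeter-frequency direction study
#'
#' Families of rotor phantoms whose period scales with the core path length
#' (constant loop speed with a small jitter): within each family the fitted
#' regression of measured hull perimeter on measured dominant frequency
#' must slope downward, the direction of the study's perimeter-frequency
#' relationship.
#'
#' @param n_families Number of independent families.
#' @param rotors_per_family Rotors per family.
#' @param dim Field size.
#' @param duration_s Recording length.
#' @param loop_speed_mm_s Conduction speed around the core loop.
#' @param noise_sd Rendering noise.
#' @param seed Base seed.
#' @return List with `slopes` (per-family regression slope), `n_negative`,
#'   `detail` (per-rotor measurements).
#' @export
study_perimeter_frequency <- function(n_families = 20L,
                                      rotors_per_family = 5L,
                                      dim = c(96L, 96L), duration_s = 3,
                                      loop_speed_mm_s = 1.3,
                                      noise_sd = 0.05, seed = 1L) {
  cfg <- reentry_config(df_band_hz = c(1, 10))
  detail <- list(); slopes <- numeric(n_families)
  for (fam in seq_len(n_families)) {
    lengths_px <- seq(20, 42, length.out = rotors_per_family)
    per <- numeric(rotors_per_family); dfs <- numeric(rotors_per_family)
    for (r in seq_len(rotors_per_family)) {
      s <- child_seed(seed, fam * 100L + r)
      set.seed(s)
      L <- lengths_px[r]
      path_um <- 2 * L * 10                       # out and back along the line
      period <- path_um / (1000 * loop_speed_mm_s) * 1000 *
        exp(rnorm(1, 0, 0.05))
      period <- min(660, max(300, period))
      core <- core_structure("line", center = dim / 2 + runif(2, -4, 4),
                             angle_deg = runif(1, 0, 360), length_px = L)
      ph <- make_rotor_phantom(core, period_ms = period, dim = dim,
                               duration_s = duration_s, noise_sd = noise_sd,
                               pixel_pitch = 10, seed = s)
      cg <- detect_core(ph$movie, cfg, max_cycles = 5L)
      per[r] <- cg$perimeter_mm
      dfs[r] <- cg$dominant_frequency_hz
      detail[[length(detail) + 1L]] <- data.frame(
        family = fam, rotor = r, length_px = L, period_ms = period,
        perimeter_mm = per[r], dominant_frequency_hz = dfs[r])
    }
    ok <- is.finite(per) & is.finite(dfs)
    slopes[fam] <- if (sum(ok) >= 3L) {
      linear_regression(dfs[ok], per[ok])$slope
    } else NA_real_
  }
  list(slopes = slopes, n_negative = sum(slopes < 0, na.rm = TRUE),
       detail = do.call(rbind, detail))
}

#' Statistics-oracle study
#'
#' Compares the Fisher and Mann-Whitney implementations against independent
#' enumeration oracles: full hypergeometric enumeration over all 2x2 tables
#' up to `exhaustive_total` (plus a seeded random sample of larger tables),
#' and full rank-assignment enumeration for small two-sample comparisons.
#'
#' @param exhaustive_total Exhaustive sweep bound on the table total.
#' @param n_random Random larger tables (totals up to 40).
#' @param seed Seed.
#' @return List with `fisher_max_abs_diff`, `fisher_n_tables`,
#'   `mw_max_abs_diff`, `mw_n_cases`.
#' @export
study_stats_oracles <- function(exhaustive_total = 14L, n_random = 300L,
                                seed = 1L) {
  dmax <- 0; n_tab <- 0L
  for (a in 0:exhaustive_total) for (b in 0:(exhaustive_total - a)) {
    for (cc in 0:(exhaustive_total - a - b)) {
      for (d in 0:(exhaustive_total - a - b - cc)) {
        tab <- matrix(c(a, b, cc, d), 2L, byrow = TRUE)
        dmax <- max(dmax, abs(fisher_exact_two_sided(tab)$p -
                                fisher_oracle(tab)))
        n_tab <- n_tab + 1L
      }
    }
  }
  set.seed(seed)
  for (i in seq_len(n_random)) {
    tab <- matrix(rmultinom(1, sample(15:40, 1), runif(4, 0.05, 1)), 2L)
    dmax <- max(dmax, abs(fisher_exact_two_sided(tab)$p - fisher_oracle(tab)))
    n_tab <- n_tab + 1L
  }
  mw_max <- 0; n_mw <- 0L
  set.seed(seed + 1L)
  for (n1 in 3:6) for (n2 in 3:6) {
    for (rep in 1:3) {
      x <- sample(100L, n1); y <- sample(setdiff(1:100, x), n2)
      p_imp <- mann_whitney_dunn(list(a = x, b = y))$p_raw[1]
      mw_max <- max(mw_max, abs(p_imp - mw_oracle(x, y)))
      n_mw <- n_mw + 1L
    }
  }
  list(fisher_max_abs_diff = dmax, fisher_n_tables = n_tab,
       mw_max_abs_diff = mw_max, mw_n_cases = n_mw)
}

#' Enumeration oracle for the two-sided Fisher p-value
#'
#' Direct summation of hypergeometric point probabilities over every table
#' with the observed margins; independent of [fisher_exact_two_sided()].
#' @param table 2x2 count matrix.
#' @keywords internal
#' @export
fisher_oracle <- function(table) {
  m <- as.matrix(table)
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(m[, 2]) == 0) return(1)
  ks <- max(0L, c1 - r2):min(r1, c1)
  probs <- vapply(ks, function(k) {
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(r1 + r2, c1))
  }, 0)
  p_obs <- probs[ks == m[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Enumeration oracle for the exact two-sided Mann-Whitney p-value
#'
#' Enumerates all assignments of ranks to the first sample and counts
#' U-statistics at least as extreme as observed.
#' @param x,y Numeric samples without ties, small n.
#' @keywords internal
#' @export
mw_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- rank(c(x, y))
  u_obs <- sum(pooled[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
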