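test_that("lattice generation is reproducible and tiles the colony", {
  lat <- generate_cell_lattice(0.3, mean_cell_diameter_um = 30,
                               n_triggers = 3L, seed = 1L)
  expect_equal(sum(lat$automatic), 3L)
  lat2 <- generate_cell_lattice(0.3, mean_cell_diameter_um = 30,
                                n_triggers = 3L, seed = 1L)
  expect_identical(lat$centroids_um, lat2$centroids_um)
  # raster Voronoi areas tile the colony disc
  expect_lt(abs(sum(lat$cell_area_um2) / (0.3 * 1e6) - 1), 0.01)
  # cell count consistent with mean territory over seeds (15% band)
  counts <- vapply(1:5, function(s) {
    nrow(generate_cell_lattice(0.3, 30, 0L, seed = s)$centroids_um)
  }, 0)
  mean_area <- 0.3e6 / mean(counts)
  expect_lt(abs(mean(counts) - 0.3e6 / mean_area) / mean(counts), 0.15)
  expect_true(Matrix::isSymmetric(lat$coupling))
  expect_true(all(Matrix::diag(lat$coupling) == 0))
  expect_error(generate_cell_lattice(0.3, 30, n_triggers = 10000L, seed = 1),
               "exceeds")
  expect_error(generate_cell_lattice(0.001, 300, 0L, seed = 1), "too large")
  # zero triggers stay fully quiescent
  still <- simulate_lattice(generate_cell_lattice(0.2, 30, 0L, seed = 2),
                            duration_s = 2, seed = 1)
  expect_equal(sum(lengths(still$events)), 0L)
})

test_that("decoupled automatic cells fire at their own cycle and nothing else", {
  lat <- generate_cell_lattice(0.2, 30, n_triggers = 1L, seed = 5L,
                               trigger_cycle_ms = 1000, trigger_cv = 0)
  lat$coupling <- lat$coupling * 0
  tr <- simulate_lattice(lat, duration_s = 10, dt_ms = 1, seed = 2L)
  auto <- which(lat$automatic)
  expect_lte(abs(length(tr$events[[auto]]) - 10L), 1L)
  expect_equal(sum(lengths(tr$events[-auto])), 0L)
  # refractory safety across every cell
  gaps_ok <- vapply(seq_along(tr$events), function(i) {
    e <- tr$events[[i]]
    length(e) < 2L || all(diff(e) >= lat$refractory_ms[i])
  }, TRUE)
  expect_true(all(gaps_ok))
})

test_that("propagation is causal and the planar velocity is calibrated", {
  lat <- generate_cell_lattice(0.8, 25, n_triggers = 0L, seed = 2L)
  edge <- cells_in_disc(lat, c(0, -lat$radius_um * 0.8), 60)
  tr <- simulate_lattice(lat, duration_s = 0.06, seed = 1L,
                         stimuli = list(list(time_ms = 20, cells = edge)))
  # activation time grows with distance from the stimulus (causality)
  first <- vapply(tr$events, function(e) if (length(e)) e[1] else NA_real_, 0)
  act <- which(!is.na(first))
  d <- sqrt((lat$centroids_um[act, 1])^2 +
            (lat$centroids_um[act, 2] + lat$radius_um * 0.8)^2)
  near <- act[d < 200]; far <- act[d > 800]
  expect_lt(max(first[near]), min(first[far]))
  cv <- fit_conduction_velocity(tr, c(0, -lat$radius_um * 0.8), t_min_ms = 21)
  expect_lt(abs(cv$v_mm_s - 41) / 41, 0.2)
  expect_gt(cv$r_squared, 0.95)
})

test_that("a block line forces the wave to detour around its ends", {
  base <- generate_cell_lattice(0.8, 25, n_triggers = 0L, seed = 2L)
  blocked <- impose_block_structure(base, "line", center_um = c(0, 0),
                                    angle_deg = 0, length_um = 700,
                                    slow_factor = 1)
  unchanged <- impose_block_structure(base, "line", length_um = 0)
  expect_identical(unchanged$coupling, base$coupling)
  stim <- list(list(time_ms = 10,
                    cells = cells_in_halfplane(base, c(base$radius_um - 40, 0),
                                               normal_deg = -90,
                                               depth_um = 60)))
  t_free <- simulate_lattice(base, 0.12, seed = 1L, stimuli = stim)
  t_block <- simulate_lattice(blocked, 0.12, seed = 1L, stimuli = stim)
  first <- function(tr) vapply(tr$events, function(e)
    if (length(e)) e[1] else NA_real_, 0)
  shadow <- cells_in_disc(base, c(-30, 0), 40)   # just past the line centre
  delay_free <- mean(first(t_free)[shadow], na.rm = TRUE)
  delay_block <- mean(first(t_block)[shadow], na.rm = TRUE)
  # detour via a tip at |col| = 350 um: extra path ~ sqrt(30^2+350^2) - 30
  expect_gt(delay_block, delay_free + 5)
  # no shadow cell activates before the wave has rounded a line tip
  tip_cells <- c(cells_in_disc(base, c(0, -350), 60),
                 cells_in_disc(base, c(0, 350), 60))
  entry <- min(first(t_block)[tip_cells], na.rm = TRUE)
  expect_gte(min(first(t_block)[shadow], na.rm = TRUE), entry)
})

test_that("driven rotation sustains five-plus cycles at a fixed period", {
  lat <- generate_cell_lattice(1.4, 25, n_triggers = 0L, seed = 2L)
  lat <- impose_block_structure(lat, "line_plus_patch", center_um = c(0, 0),
                                angle_deg = 180, length_um = 900,
                                patch_radius_um = 90, isolate_core = TRUE)
  stim <- rotor_drive_stimuli(lat, period_ms = 400, t_start_ms = 50,
                              n_laps = 12L)
  tr <- simulate_lattice(lat, duration_s = 5, seed = 1L, stimuli = stim)
  probe <- cells_in_disc(lat, c(-400, 200), 60)[1]
  iv <- diff(tr$events[[probe]])
  iv <- iv[-(1:2)]                       # allow the first laps to settle
  expect_gte(length(iv), 5L)
  expect_lt(sd(iv) / mean(iv), 0.05)
  expect_lt(abs(mean(iv) - 400), 20)
})

test_that("rendering produces kernel-shaped transients with the stated timing", {
  lab <- matrix(1L, 4, 4)
  flat <- render_fluorescence(list(numeric(0)), lab, duration_s = 1,
                              noise_sd = 0, ca_lag_frames = 0L)
  expect_equal(diff(range(flat$data)), 0)
  one <- render_fluorescence(list(200), lab, duration_s = 1, noise_sd = 0,
                             ca_lag_frames = 0L)
  tr <- as.numeric(extract_trace(one, rbind(c(0L, 0L))))
  peak_ms <- (which.max(tr) - 1L) * 10
  expect_equal(peak_ms, 200 + attr(transient_kernel("calcium"), "rise_ms"))
  expect_error(render_fluorescence(list(200), lab, 1, ca_lag_frames = -1L),
               "voltage leads")
  expect_error(render_fluorescence(list(200), lab, 1, noise_sd = -0.1),
               "noise_sd")
})

test_that("voltage and calcium renderings of the same events show the set lag", {
  lab <- matrix(1L, 3, 3)
  events <- list(seq(300, 7000, by = 400))
  v <- render_fluorescence(events, lab, duration_s = 8, channel = "voltage",
                           noise_sd = 0, seed = 1)
  ca <- render_fluorescence(events, lab, duration_s = 8, channel = "calcium",
                            noise_sd = 0, ca_lag_frames = 3L, seed = 1)
  tv <- extract_trace(v, rbind(c(1L, 1L)))
  tc <- extract_trace(ca, rbind(c(1L, 1L)))
  est <- estimate_channel_lag(tv, tc)
  # imposed 3-frame event lag plus the slower calcium upstroke
  expect_lte(abs(est$lag - 3L), 1L)
})

test_that("phantoms are seed-deterministic and self-consistent", {
  a <- small_rotor(seed = 9L, dim = c(64L, 64L), duration_s = 2)
  b <- small_rotor(seed = 9L, dim = c(64L, 64L), duration_s = 2)
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$truth$core_mask, b$truth$core_mask)
  # off-core dominant frequency equals 1000/period within 1/duration
  ph <- small_rotor(seed = 10L, dim = c(64L, 64L), duration_s = 10,
                    noise_sd = 0)
  tr <- extract_trace(ph$movie, rbind(c(12L, 50L)))
  est <- dominant_frequency(tr, band = c(1, 10))
  expect_lt(abs(est$frequency - 1000 / 345), est$resolution)
  # double-rate core pixels fire at twice the off-core count
  dbl <- small_rotor(seed = 12L, dim = c(64L, 64L), duration_s = 10,
                     core_cell_mode = "double_rate")
  core_px <- which(dbl$truth$double_rate, arr.ind = TRUE)[1, ] - 1L
  n_core <- length(truth_events(dbl$truth, core_px))
  n_off <- length(truth_events(dbl$truth, c(12L, 50L)))
  expect_lte(abs(n_core - 2L * n_off), 1L)
  # geometry checks
  expect_error(make_rotor_phantom(core_structure("line", c(2, 32),
                                                 angle_deg = 90,
                                                 length_px = 40),
                                  dim = c(64L, 64L)), "border")
})
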