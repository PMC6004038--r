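test_that("planar activation maps are affine in position with the right slope", {
  pw <- planar_wave_phantom(onsets_ms = 100, dim = c(96L, 96L),
                            duration_s = 1.2, direction_deg = 0,
                            noise_sd = 0, seed = 1L)
  am <- compute_activation_map(pw$movie, c(1L, 110L))
  pts <- which(!is.na(am), arr.ind = TRUE)
  fit <- lm(am[pts] ~ pts[, 2] + pts[, 1])
  grad <- coef(fit)[-1] / pw$movie$pixel_pitch    # ms per um
  # gradient magnitude is 1/velocity within 10%
  expect_lt(abs(sqrt(sum(grad^2)) - 1 / 41) / (1 / 41), 0.1)
  expect_lt(abs(grad[2]), abs(grad[1]) * 0.05)    # propagation along columns
})

test_that("quiescent movies yield no maps, no wavefronts, no sites", {
  set.seed(8)
  quiet <- reentry_movie(array(0.2 + rnorm(64 * 64 * 120, sd = 0.004),
                               c(64, 64, 120)), 100, 10)
  expect_error(activation_cycles(quiet), "no activity")
  wf <- segment_wavefronts(quiet)
  expect_equal(nrow(wf), 0L)
  expect_equal(classify_recording(wf), "quiescent")
  expect_equal(nrow(localize_triggers(quiet)), 0L)
})

test_that("rotor maps increase monotonically with angle about the core", {
  ph <- small_rotor(seed = 6L, noise_sd = 0)
  cyc <- activation_cycles(ph$movie, cfg_rotor())
  am <- cyc$maps[[2]]
  pts <- which(!is.na(am), arr.ind = TRUE)
  r <- sqrt((pts[, 1] - 65)^2 + (pts[, 2] - 65)^2)
  sel <- r > 30 & r < 55
  ang <- (atan2(pts[sel, 1] - 65, pts[sel, 2] - 65) / (2 * pi)) %% 1
  tt <- am[pts[sel, , drop = FALSE]]
  # circular rank correlation via the best rotation of the angular origin
  best <- max(vapply(seq(0, 0.95, by = 0.05), function(o) {
    cor(rank((ang + o) %% 1), rank(tt), method = "spearman")
  }, 0))
  expect_gt(best, 0.95)
})

test_that("wavefront counts are exact for planar trains and focal pairs", {
  for (k in c(2L, 5L)) {
    pw <- planar_wave_phantom(onsets_ms = seq(0, by = 400, length.out = k),
                              dim = c(128L, 128L), noise_sd = 0, seed = k)
    wf <- segment_wavefronts(pw$movie)
    expect_equal(nrow(wf), k)
    expect_true(all(rotormap:::angle_diff_deg(wf$direction_deg,
                                              wf$direction_deg[1]) < 5))
  }
  fp <- focal_phantom(sites = rbind(c(60L, 60L), c(200L, 200L)),
                      onsets = list(c(200, 1500, 2800), c(205, 1505, 2805)),
                      dim = c(256L, 256L), duration_s = 4, noise_sd = 0.05,
                      seed = 5L)
  wf <- segment_wavefronts(fp$movie)
  expect_equal(nrow(wf), 6L)
})

test_that("the re-entry rule needs five very regular consecutive wavefronts", {
  mk <- function(n, dirs, intervals) {
    data.frame(wave = seq_len(n), time_ms = cumsum(c(500, intervals))[1:n],
               direction_deg = dirs, interval_ms = c(NA, intervals)[1:n],
               n_rois = 50L, origin_row = 1, origin_col = 1,
               speed_mm_s = 40, edge_origin = FALSE)
  }
  five <- mk(5, rep(90, 5), rep(400, 4))
  expect_equal(classify_recording(five), "re_entry")
  four <- mk(4, rep(90, 4), rep(400, 3))
  expect_equal(classify_recording(four), "triggers_only")
  set.seed(1)
  messy <- mk(8, seq(0, 180, length.out = 8),
              400 * exp(rnorm(7, 0, 0.6)))
  expect_equal(classify_recording(messy), "triggers_only")
  # boundary: same five waves but one direction outlier breaks the run
  bent <- mk(5, c(90, 90, 170, 90, 90), rep(400, 4))
  expect_equal(classify_recording(bent), "triggers_only")
})

test_that("trigger localization finds focal sources within tolerance", {
  truth_sites <- rbind(c(60, 60), c(200, 200))
  for (ns in c(0, 0.05)) {
    fp <- focal_phantom(sites = truth_sites,
                        onsets = list(c(200, 1500, 2800), c(205, 1505, 2805)),
                        dim = c(256L, 256L), duration_s = 4, noise_sd = ns,
                        seed = 3L)
    st <- localize_triggers(fp$movie)
    expect_equal(nrow(st), 2L)
    err <- vapply(seq_len(2), function(i) {
      min(sqrt((st$row_px - truth_sites[i, 1])^2 +
               (st$col_px - truth_sites[i, 2])^2))
    }, 0)
    expect_true(all(err <= if (ns == 0) 3 else 6))
  }
  # refuses re-entry recordings
  ph <- small_rotor(seed = 2L, duration_s = 4)
  expect_error(localize_triggers(ph$movie, cfg_rotor()), "re-entry present")
  # planar wave entering at the field edge is flagged as an edge source
  pw <- planar_wave_phantom(onsets_ms = c(100, 1600, 3100), dim = c(96L, 96L),
                            duration_s = 4, noise_sd = 0.05, seed = 4L)
  st <- localize_triggers(pw$movie)
  expect_true(all(st$edge_source))
})

test_that("location matching is boundary-inclusive and category-complete", {
  pre <- data.frame(row_um = c(0, 500), col_um = c(0, 0))
  expect_equal(match_locations(pre, pre, 100),
               c("same_location", "same_location"))
  none <- data.frame(row_um = numeric(0), col_um = numeric(0))
  expect_equal(match_locations(pre, none, 100),
               c("no_activity", "no_activity"))
  post <- data.frame(row_um = c(100, 680), col_um = c(0, 0))
  expect_equal(match_locations(pre, post, 100),
               c("same_location", "other_location"))
  # exactly at tolerance counts as the same location
  at_tol <- data.frame(row_um = 100, col_um = 0)
  expect_equal(match_locations(data.frame(row_um = 0, col_um = 0),
                               at_tol, 100), "same_location")
  expect_error(match_locations(pre, post, -5), "tolerance")
})
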