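test_that("trigger sites scale with colony area and no re-entry means p = 1", {
  cfg <- reentry_config(wavefront_block_px = 4L)
  ex <- run_colony_size_experiment(area_classes_mm2 = c(0.6, 1.0, 1.5),
                                   n_per_class = 3L,
                                   reentry_prob = c(0, 0, 0),
                                   trigger_density_per_mm2 = 3,
                                   duration_s = 8, config = cfg, seed = 11L)
  expect_equal(nrow(ex$records), 9L)
  means <- tapply(ex$records$n_trigger_sites, ex$records$area_mm2, mean)
  expect_true(all(diff(means) > 0))
  expect_true(all(ex$records$n_wavefronts > 0))
  # with re-entry forced off, every contingency p is 1
  expect_true(all(ex$contingency$p_raw == 1))
  expect_true(all(ex$contingency$p_adjusted == 1))
  expect_false(any(ex$records$reentry))
})

test_that("a driven-rotor colony recording is classified as re-entry", {
  cfg <- reentry_config(wavefront_block_px = 4L, df_band_hz = c(1, 10))
  ex <- run_colony_size_experiment(area_classes_mm2 = 1.5, n_per_class = 1L,
                                   reentry_prob = 1, duration_s = 6,
                                   config = cfg, seed = 21L)
  expect_true(ex$records$reentry_truth)
  expect_true(ex$records$reentry)
  expect_true(is.na(ex$records$n_trigger_sites))   # excluded under re-entry
})

test_that("stability outcomes follow the generating persistence", {
  sure <- run_stability_experiment(n_pairs = 15L, persistence_prob = 1,
                                   p_silent = 0, jitter_um = 10, seed = 3L)
  expect_true(all(sure$outcomes$outcome == "same_location"))
  never <- run_stability_experiment(n_pairs = 15L, persistence_prob = 0,
                                    p_silent = 0, jitter_um = 10, seed = 4L)
  expect_true(all(never$outcomes$outcome != "same_location"))
  mid <- run_stability_experiment(n_pairs = 134L, persistence_prob = 0.35,
                                  p_silent = 0, n_triggers_per_colony = 3L,
                                  jitter_um = 10, seed = 5L)
  frac <- mean(mid$outcomes$outcome == "same_location")
  expect_lt(abs(frac - 0.35), 0.05)
})

test_that("known reassignments produce a diagonal confusion matrix", {
  res <- run_stability_experiment(n_pairs = 20L, persistence_prob = 0.4,
                                  p_silent = 0.15, jitter_um = 10, seed = 6L)
  cm <- res$confusion
  expect_equal(sum(cm) , sum(diag(cm)))
  # re-entries never return to the same location
  ro <- run_stability_experiment(n_pairs = 12L, kind = "reentry",
                                 p_silent = 0, p_reentry_post = 0.5,
                                 seed = 7L)
  expect_false(any(ro$outcomes$outcome == "same_location"))
})
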