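test_that("delay scores fold activation differences onto the half-period", {
  expect_equal(circular_delay(0, 5, 345), 5)
  expect_equal(circular_delay(0, 340, 345), 5)
  expect_equal(circular_delay(10, 10 + 345, 345), 0)
  expect_equal(circular_delay(0, 172.5, 345), 172.5)
  # two adjacent pixels 5 ms apart both score 5
  maps <- list(structure(matrix(c(0, 5), 1, 2), class = "activation_map"))
  hm <- delay_score_map(maps, radius = 1, period_ms = 345)
  expect_equal(as.numeric(hm$score), c(5, 5))
  expect_error(delay_score_map(list(matrix(NA_real_, 2, 2)), 1, 345),
               "no activity")
})

test_that("delay maps are pair-symmetric and shift-invariant in time", {
  set.seed(3)
  base <- matrix(runif(20 * 20, 0, 345), 20, 20)
  hm1 <- delay_score_map(list(base), radius = 2, period_ms = 345)
  hm2 <- delay_score_map(list(base + 123.4), radius = 2, period_ms = 345)
  expect_equal(hm1$score, hm2$score, tolerance = 1e-9)
})

test_that("planar waves produce only tiny delays and no core", {
  pw <- planar_wave_phantom(onsets_ms = seq(0, 2800, by = 400),
                            dim = c(128L, 128L), duration_s = 3.2,
                            noise_sd = 0, seed = 2L)
  cyc <- activation_cycles(pw$movie, cfg_rotor())
  hm <- delay_score_map(cyc$maps, radius = 2,
                        period_ms = cyc$period_ms)
  # expected neighbour delay at 41 mm/s and 10 um pitch, plus one frame of
  # quantization
  expect_lt(quantile(hm$score, 0.99, na.rm = TRUE), 2 * 10 / 41 + 10)
  mask <- segment_core(hm)
  expect_true(isTRUE(attr(mask, "no_core_found")))
})

test_that("segmentation recovers an imposed line core against ground truth", {
  ph <- small_rotor(seed = 4L)
  cg <- detect_core(ph$movie, cfg_rotor())
  expect_true(cg$found)
  expect_gte(mask_iou(cg$mask, ph$truth$core_mask), 0.6)
  expect_lte(mask_hausdorff(cg$mask, ph$truth$core_mask), 2)
  expect_equal(cg$morphology, "single_line")
  # perimeter close to twice the line length (40 px at 10 um)
  expect_lt(abs(cg$perimeter_mm - 2 * 40 * 10 / 1000), 0.12)
})

test_that("two disjoint rotors give two components when allowed", {
  dims <- c(96L, 192L)
  c1 <- core_structure("line", center = c(48, 48), angle_deg = 10,
                       length_px = 30)
  c2 <- core_structure("line", center = c(48, 144), angle_deg = 100,
                       length_px = 30)
  p1 <- make_rotor_phantom(c1, period_ms = 345, dim = dims, duration_s = 3,
                           noise_sd = 0.03, seed = 5L)
  p2 <- make_rotor_phantom(c2, period_ms = 345, dim = dims, duration_s = 3,
                           noise_sd = 0.03, seed = 6L)
  both <- p1$movie
  # splice the second rotor into the right half-field
  both$data[, 97:192, ] <- p2$movie$data[, 97:192, ]
  cyc <- activation_cycles(both, cfg_rotor())
  hm <- delay_score_map(cyc$maps, radius = 3, period_ms = cyc$period_ms)
  mask_all <- segment_core(hm, keep = "all")
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::as.Image(mask_all + 0)))
  expect_gte(length(setdiff(unique(as.integer(lab)), 0L)), 2L)
  mask_one <- segment_core(hm, keep = "largest")
  lab1 <- EBImage::imageData(EBImage::bwlabel(EBImage::as.Image(mask_one + 0)))
  expect_equal(length(setdiff(unique(as.integer(lab1)), 0L)), 1L)
})

test_that("morphology classes follow skeleton endpoints and thickness", {
  side <- 64L
  line <- matrix(FALSE, side, side); line[32, 10:54] <- TRUE
  expect_equal(classify_core_morphology(line, pitch = 10), "single_line")
  y <- matrix(FALSE, side, side)
  y[32, 10:32] <- TRUE
  for (k in 0:20) { y[32 - k, 32 + k] <- TRUE; y[32 + k, 32 + k] <- TRUE }
  expect_equal(classify_core_morphology(y, pitch = 10), "multi_line")
  blob <- disc_mask(side, c(31, 31), 10)
  blob[32, 10:21] <- TRUE
  expect_equal(classify_core_morphology(blob, pitch = 10), "lines_plus_area")
  expect_equal(classify_core_morphology(matrix(FALSE, 4, 4), 10),
               "indeterminate")
  # thickness-ratio oracle by pixel counting for the disc-plus-line case
  skel <- skeletonize_mask(blob)
  rho <- sum(blob) / (sum(skel) * 2 * 25 / 10)
  expect_gt(rho, 1.5)
})

test_that("hull perimetry matches analytic shapes", {
  disc <- disc_mask(64L, c(31, 31), 20)
  per <- core_perimeter(disc, pitch = 2.6)
  expect_false(per$degenerate)
  expect_lt(abs(per$perimeter_mm - 2 * pi * 20 * 2.6 / 1000) /
            (2 * pi * 20 * 2.6 / 1000), 0.03)
  line <- matrix(FALSE, 4L, 128L); line[2, 11:110] <- TRUE
  perl <- core_perimeter(line, pitch = 2.6)
  expect_true(perl$degenerate)
  expect_equal(perl$perimeter_mm, 2 * 99 * 2.6 / 1000)
  sq <- matrix(FALSE, 16L, 16L); sq[4:13, 4:13] <- TRUE
  expect_equal(core_perimeter(sq, pitch = 10)$perimeter_mm,
               4 * 9 * 10 / 1000)
  single <- matrix(FALSE, 8, 8); single[3, 3] <- TRUE
  expect_true(core_perimeter(single, pitch = 10)$indeterminate)
})

test_that("hull perimeter is monotone under mask inclusion", {
  set.seed(9)
  for (i in 1:10) {
    big <- matrix(runif(30 * 30) < 0.2, 30, 30)
    if (sum(big) < 4) next
    pts <- which(big)
    small <- big
    small[sample(pts, ceiling(length(pts) / 2))] <- FALSE
    if (sum(small) < 2) next
    expect_gte(core_perimeter(big, 10)$perimeter_mm,
               core_perimeter(small, 10)$perimeter_mm)
  }
})

test_that("mask comparison handles identity, disjointness and emptiness", {
  a <- disc_mask(32L, c(10, 10), 5)
  b <- disc_mask(32L, c(22, 22), 5)
  expect_equal(compare_block_maps(a, a)$dice, 1)
  expect_equal(compare_block_maps(a, b)$dice, 0)
  none <- matrix(FALSE, 32L, 32L)
  expect_true(compare_block_maps(none, none)$undefined)
})
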