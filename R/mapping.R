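# Activation mapping and wavefront analysis.
#
# An activation map holds, per pixel, the time (ms) of the steepest
# fluorescence upstroke within one cycle window; pixels without a detected
# activation are NA. Wavefronts are segmented by pooling activations on a
# coarse ROI grid, grouping them into beats (temporal bursts, or fixed
# period windows when the recording is strongly periodic) and splitting each
# beat into basins of the activation-time surface by watershed, so colliding
# waves from distinct origins stay distinct.

#' Compute a single-cycle activation map
#'
#' Per-pixel activation time within a frame window: the frame of the maximum
#' lightly-smoothed derivative (the steepest upstroke), tie-broken to the
#' earliest frame. Pixels whose within-window dynamic range falls below the
#' prominence fraction of the movie-wide range are reported NA (inactive).
#' Equivalent to taking the first event of [detect_activations()] per pixel
#' on a window containing at most one cycle, but vectorized across pixels.
#'
#' @param movie A [reentry_movie()].
#' @param window Integer frame range `c(first, last)`, 1-based inclusive.
#' @param config A [reentry_config()].
#' @param cycle Cycle index stored with the map.
#' @return An `activation_map`: H x W matrix of times (ms, from recording
#'   start), attributes `cycle`, `window`, `frame_rate`, `pixel_pitch`.
#' @export
compute_activation_map <- function(movie, window, config = reentry_config(),
                                   cycle = 1L) {
  stopifnot(inherits(movie, "reentry_movie"))
  nf <- n_frames(movie)
  window <- as.integer(window)
  if (length(window) != 2L || window[1] < 1L || window[2] > nf ||
      window[2] <= window[1]) {
    stop("window must lie inside the movie and span at least 2 frames")
  }
  d <- dim(movie$data)
  fm <- matrix(movie$data, d[1] * d[2], d[3])  # pixels x frames
  .map_from_frames(fm, window, d[1:2], movie$frame_rate, movie$pixel_pitch,
                   movie_amplitude(movie), config, cycle)
}

.map_from_frames <- function(fm, window, hw, frame_rate, pixel_pitch, amp,
                             config, cycle) {
  dt_ms <- 1000 / frame_rate
  sub <- t(fm[, window[1]:window[2], drop = FALSE])  # frames x pixels
  n <- nrow(sub)
  w <- config$smooth_window
  if (w > 1L && n > w) sub <- smooth_rows(sub, w)
  dr <- matrix(0, n, ncol(sub))
  dr[2:(n - 1L), ] <- (sub[3:n, , drop = FALSE] - sub[1:(n - 2L), , drop = FALSE]) / 2
  am <- max.col(t(dr), ties.method = "first")
  rng_lo <- sub[1, ]; rng_hi <- sub[1, ]
  for (i in 2:n) {
    rng_lo <- pmin(rng_lo, sub[i, ])
    rng_hi <- pmax(rng_hi, sub[i, ])
  }
  active <- (rng_hi - rng_lo) >= config$prominence * amp
  times <- (window[1] - 1L + am - 1L) * dt_ms
  times[!active] <- NA_real_
  if (all(is.na(times))) stop("no activity in window")
  structure(matrix(times, hw[1], hw[2]),
            cycle = cycle, window = window, frame_rate = frame_rate,
            pixel_pitch = pixel_pitch,
            class = c("activation_map", "matrix", "array"))
}

#' Slice a recording into per-cycle activation maps
#'
#' Estimates the dominant frequency of the field-mean trace, tiles the
#' recording into period-length windows and computes one activation map per
#' complete window.
#'
#' @param movie A [reentry_movie()].
#' @param config A [reentry_config()].
#' @param max_cycles Cap on the number of cycle maps (earliest kept).
#' @return List with `maps` (list of `activation_map`), `period_ms`,
#'   `frequency_hz`.
#' @export
activation_cycles <- function(movie, config = reentry_config(),
                              max_cycles = 7L) {
  df <- recording_dominant_frequency(movie, band = config$df_band_hz,
                                     config = config)
  if (!is.finite(df$frequency_hz)) {
    stop("no activity: dominant frequency undefined")
  }
  period_ms <- df$period_ms
  dt_ms <- 1000 / movie$frame_rate
  nf <- n_frames(movie)
  n_cyc <- floor(nf * dt_ms / period_ms)
  if (n_cyc < 1L) stop("recording shorter than one cycle")
  n_cyc <- min(n_cyc, max_cycles)
  d <- dim(movie$data)
  fm <- matrix(movie$data, d[1] * d[2], d[3])
  amp <- movie_amplitude(movie)
  maps <- vector("list", n_cyc)
  for (k in seq_len(n_cyc)) {
    a <- floor((k - 1L) * period_ms / dt_ms) + 1L
    b <- min(nf, floor(k * period_ms / dt_ms) + 1L)
    maps[[k]] <- .map_from_frames(fm, c(a, b), d[1:2], movie$frame_rate,
                                  movie$pixel_pitch, amp, config, cycle = k)
  }
  list(maps = maps, period_ms = period_ms, frequency_hz = df$frequency_hz)
}

global_trace <- function(movie) {
  d <- dim(movie$data)
  samples <- colMeans(matrix(movie$data, d[1] * d[2], d[3]))
  new_trace(samples, movie$frame_rate, movie_range = movie_amplitude(movie))
}

#' Recording-level dominant frequency
#'
#' Median dominant frequency over a grid of sampled pixel traces. Per-pixel
#' estimation matters for rotors: activation phases cover the whole cycle,
#' so the field-mean trace largely cancels its own fundamental and its
#' spectral peak can land on a harmonic.
#'
#' @param movie A [reentry_movie()].
#' @param band Search band, Hz.
#' @param config A [reentry_config()] (silent-trace gating).
#' @param grid_n Sampling grid size per axis.
#' @return List with `frequency_hz` (median; NA when no pixel has a defined
#'   peak), `period_ms`, `strong` (majority of sampled pixels show a sharp,
#'   mutually consistent peak), `n_defined`.
#' @export
recording_dominant_frequency <- function(movie, band = c(0.5, 10),
                                         config = reentry_config(),
                                         grid_n = 5L) {
  d <- dim(movie$data)
  fm <- matrix(movie$data, d[1] * d[2], d[3])
  amp <- movie_amplitude(movie)
  rows <- round(seq(0.15, 0.85, length.out = grid_n) * d[1])
  cols <- round(seq(0.15, 0.85, length.out = grid_n) * d[2])
  freqs <- c(); strongs <- c()
  for (r in rows) for (cc in cols) {
    tr <- new_trace(fm[(cc - 1L) * d[1] + r, ], movie$frame_rate,
                    movie_range = amp)
    if (diff(range(tr)) < config$silent_range_frac * amp) next
    est <- tryCatch(dominant_frequency(tr, band = band),
                    error = function(e) list(undefined = TRUE))
    if (isTRUE(est$undefined)) next
    freqs <- c(freqs, est$frequency)
    strongs <- c(strongs, spectral_peak_strong(tr, est$frequency, band))
  }
  if (length(freqs) == 0L) {
    return(list(frequency_hz = NA_real_, period_ms = NA_real_,
                strong = FALSE, n_defined = 0L))
  }
  f_med <- median(freqs)
  consistent <- mean(abs(freqs - f_med) < 0.25 * f_med) >= 0.5
  list(frequency_hz = f_med, period_ms = 1000 / f_med,
       strong = mean(strongs) >= 0.5 && consistent,
       n_defined = length(freqs))
}

#' Segment wavefronts in a recording
#'
#' Activation events are pooled over a coarse ROI grid, grouped into beats
#' and split by watershed on the activation-time surface; each basin is one
#' wavefront with an origin, an arrival time and a mean propagation
#' direction from a plane fit of activation time against position.
#'
#' @param movie A [reentry_movie()].
#' @param config A [reentry_config()].
#' @param gap_ms Temporal gap defining separate beats when the recording is
#'   not strongly periodic.
#' @param tolerance_ms Watershed tolerance: origin-time minima closer than
#'   this are merged into one wavefront.
#' @return A data frame of wavefront records: `wave`, `time_ms` (arrival at
#'   origin), `direction_deg`, `interval_ms` (to previous wave, NA for the
#'   first), `n_rois`, `origin_row`, `origin_col` (pixels), `speed_mm_s`,
#'   `edge_origin`. Zero rows when quiescent.
#' @export
segment_wavefronts <- function(movie, config = reentry_config(),
                               gap_ms = 150, tolerance_ms = 10) {
  pooled <- pooled_events(movie, config)
  empty <- data.frame(wave = integer(0), time_ms = numeric(0),
                      direction_deg = numeric(0), interval_ms = numeric(0),
                      n_rois = integer(0), origin_row = numeric(0),
                      origin_col = numeric(0), speed_mm_s = numeric(0),
                      edge_origin = logical(0))
  if (nrow(pooled$events) == 0L) return(empty)
  ev <- pooled$events[order(pooled$events$t), ]
  df <- recording_dominant_frequency(movie, band = config$df_band_hz,
                                     config = config)
  # the per-cycle path needs an established rhythm: sharp consistent
  # per-pixel spectral peaks and at least five cycles in the recording
  strong <- df$strong && is.finite(df$frequency_hz) &&
    movie_duration(movie) * df$frequency_hz >= 5
  recs <- list()
  if (strong) {
    # Strongly periodic recording (rotor or regular train): one wavefront
    # per cycle. Arrival times come from the most active ROI (the reference
    # point); each cycle's direction is the plane-fit gradient of that
    # cycle's ROI activation map. A rotor's phase field covers the whole
    # cycle continuously, so period-sliced watershed would always cut it at
    # an arbitrary phase; per-cycle maps avoid that.
    period_ms <- df$period_ms
    ref <- as.integer(names(which.max(table(ev$roi))))
    t_ref <- sort(ev$t[ev$roi == ref])
    keep <- c(TRUE, diff(t_ref) > period_ms / 2)
    t_ref <- t_ref[keep]
    for (tk in t_ref) {
      wv <- ev[ev$t >= tk - period_ms / 2 & ev$t < tk + period_ms / 2, ,
               drop = FALSE]
      r <- cycle_wavefront_record(wv, tk, pooled, movie)
      if (!is.null(r)) recs[[length(recs) + 1L]] <- r
    }
  } else {
    beat <- cumsum(c(1, diff(ev$t) > gap_ms))
    for (b in unique(beat)) {
      wv <- ev[beat == b, , drop = FALSE]
      recs <- c(recs, wavefronts_in_window(wv, pooled, movie, config,
                                           tolerance_ms))
    }
  }
  if (length(recs) == 0L) return(empty)
  out <- do.call(rbind, recs)
  out <- out[order(out$time_ms), ]
  out$wave <- seq_len(nrow(out))
  out$interval_ms <- c(NA_real_, diff(out$time_ms))
  rownames(out) <- NULL
  out
}

cycle_wavefront_record <- function(wv, tk, pooled, movie) {
  t_roi <- rep(NA_real_, pooled$nbr * pooled$nbc)
  agg <- tapply(wv$t, wv$roi, min)
  t_roi[as.integer(names(agg))] <- agg
  tm <- matrix(t_roi, pooled$nbr, pooled$nbc)
  act <- !is.na(tm)
  if (sum(act) < 4L) return(NULL)
  tt <- tm[act]
  rr <- pooled$roi_row[as.logical(act)] * pooled$block + pooled$block / 2
  cc <- pooled$roi_col[as.logical(act)] * pooled$block + pooled$block / 2
  dir <- NA_real_; speed <- NA_real_
  if (length(unique(tt)) > 1L) {
    fit <- lm(tt ~ cc + rr)
    g <- coef(fit)[c("cc", "rr")] / movie$pixel_pitch
    if (all(is.finite(g)) && sqrt(sum(g^2)) > 0) {
      dir <- (atan2(g[2], g[1]) * 180 / pi) %% 360
      speed <- 1 / sqrt(sum(g^2))
    }
  }
  t0 <- min(tt)
  slack <- if (is.finite(speed) && speed > 0) {
    1.5 * pooled$block * movie$pixel_pitch / speed + 10
  } else 20
  o_sel <- tt <= t0 + slack
  edge <- any(pooled$roi_row[as.logical(act)][o_sel] %in%
                c(0L, pooled$nbr - 1L)) ||
          any(pooled$roi_col[as.logical(act)][o_sel] %in%
                c(0L, pooled$nbc - 1L))
  data.frame(wave = NA_integer_, time_ms = tk, direction_deg = as.numeric(dir),
             interval_ms = NA_real_, n_rois = sum(act),
             origin_row = mean(rr[o_sel]), origin_col = mean(cc[o_sel]),
             speed_mm_s = as.numeric(speed), edge_origin = edge)
}

spectral_peak_strong <- function(trace, freq, band, ratio = 5) {
  x <- as.numeric(trace) - mean(trace)
  n <- length(x)
  fr <- attr(trace, "frame_rate")
  spec <- Mod(fft(x))[seq_len(n %/% 2L)]^2
  freqs <- (seq_len(n %/% 2L) - 1L) * fr / n
  in_band <- freqs >= band[1] & freqs <= band[2]
  if (sum(in_band) < 8L) return(FALSE)
  pk <- max(spec[in_band])
  pk > ratio * median(spec[in_band])
}

pooled_events <- function(movie, config) {
  d <- dim(movie$data)
  b <- config$wavefront_block_px
  nbr <- d[1] %/% b; nbc <- d[2] %/% b
  if (nbr < 2L || nbc < 2L) stop("movie too small for the ROI grid")
  fm <- matrix(movie$data, d[1] * d[2], d[3])
  rows <- rep(0:(d[1] - 1L), d[2]); cols <- rep(0:(d[2] - 1L), each = d[1])
  br <- rows %/% b; bc <- cols %/% b
  keep <- br < nbr & bc < nbc
  grp <- (bc[keep] * nbr + br[keep]) + 1L
  n_roi <- nbr * nbc
  pool <- rowsum(fm[keep, , drop = FALSE], grp)    # n_roi x frames sums
  cnt <- tabulate(grp, n_roi)
  pool <- pool / cnt
  mrange <- movie_amplitude(movie)
  evs <- list()
  for (i in seq_len(n_roi)) {
    tr <- new_trace(pool[i, ], movie$frame_rate, movie_range = mrange)
    e <- detect_activations(tr, config)
    if (length(e) > 0L) {
      evs[[length(evs) + 1L]] <- data.frame(roi = i, t = as.numeric(e))
    }
  }
  events <- if (length(evs)) do.call(rbind, evs) else
    data.frame(roi = integer(0), t = numeric(0))
  roi_row <- (seq_len(n_roi) - 1L) %% nbr
  roi_col <- (seq_len(n_roi) - 1L) %/% nbr
  list(events = events, nbr = nbr, nbc = nbc, block = b,
       roi_row = roi_row, roi_col = roi_col)
}

wavefronts_in_window <- function(wv, pooled, movie, config, tolerance_ms) {
  # earliest event per ROI in this window -> activation-time surface
  t_roi <- rep(NA_real_, pooled$nbr * pooled$nbc)
  agg <- tapply(wv$t, wv$roi, min)
  t_roi[as.integer(names(agg))] <- agg
  tm <- matrix(t_roi, pooled$nbr, pooled$nbc)
  act <- !is.na(tm)
  if (sum(act) < 4L) return(list())
  relief <- max(tm, na.rm = TRUE) - tm + tolerance_ms
  relief[!act] <- 0
  lab <- EBImage::watershed(EBImage::as.Image(relief), tolerance = tolerance_ms,
                            ext = 1)
  lab <- EBImage::imageData(lab)
  # A wavefront can be split by watershed where it flows from one region
  # into another (e.g. a rotor's core rotation continuing into the colony):
  # a later basin whose ORIGIN touches an earlier basin with matching
  # activation times is a continuation, not a new wave, and is merged.
  # Head-on collisions meet at their latest points, never at an origin, so
  # colliding waves from distinct sources stay distinct.
  labs <- setdiff(unique(as.integer(lab)), 0L)
  if (length(labs) > 1L) {
    t0s <- vapply(labs, function(l) min(tm[lab == l & act]), 0)
    ord <- order(t0s)
    parent <- seq_along(labs)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    nbr_offsets <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                         c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
    for (bi in seq_along(ord)[-1]) {
      i <- ord[bi]
      sel_o <- which(lab == labs[i] & act & !is.na(tm) &
                       tm <= t0s[i] + tolerance_ms, arr.ind = TRUE)
      if (nrow(sel_o) == 0L) next
      for (bj in seq_len(bi - 1L)) {
        j <- ord[bj]
        if (find(i) == find(j)) next
        merged <- FALSE
        for (oo in seq_len(nrow(nbr_offsets))) {
          rr <- sel_o[, 1] + nbr_offsets[oo, 1]
          cc <- sel_o[, 2] + nbr_offsets[oo, 2]
          okb <- rr >= 1L & rr <= nrow(tm) & cc >= 1L & cc <= ncol(tm)
          if (!any(okb)) next
          idx <- cbind(rr[okb], cc[okb])
          hit <- lab[idx] == labs[j] & !is.na(tm[idx]) &
            abs(tm[idx] - tm[sel_o[okb, , drop = FALSE]]) <= 2 * tolerance_ms
          if (any(hit)) { merged <- TRUE; break }
        }
        if (merged) parent[find(i)] <- find(j)
      }
    }
    group <- vapply(seq_along(labs), find, 1L)
    relab <- lab
    for (k in seq_along(labs)) relab[lab == labs[k]] <- labs[group[k]]
    lab <- relab
  }
  out <- list()
  pitch_um <- movie$pixel_pitch * pooled$block
  min_rois <- max(4L, ceiling(0.08 * sum(act)))
  for (l in setdiff(unique(as.integer(lab)), 0L)) {
    sel <- lab == l & act
    if (sum(sel) < min_rois) next
    tt <- tm[sel]
    rr <- pooled$roi_row[as.logical(sel)] * pooled$block + pooled$block / 2
    cc <- pooled$roi_col[as.logical(sel)] * pooled$block + pooled$block / 2
    dir <- NA_real_; speed <- NA_real_
    if (length(unique(tt)) > 1L && sum(sel) >= 3L) {
      fit <- lm(tt ~ cc + rr)
      g <- coef(fit)[c("cc", "rr")] / movie$pixel_pitch   # ms per um, (x, y)
      if (all(is.finite(g)) && sqrt(sum(g^2)) > 0) {
        dir <- (atan2(g[2], g[1]) * 180 / pi) %% 360
        speed <- 1 / sqrt(sum(g^2))                       # um/ms = mm/s
      }
    }
    t0 <- min(tt)
    slack <- if (is.finite(speed) && speed > 0) {
      1.5 * pitch_um / speed + 10
    } else 20
    o_sel <- tt <= t0 + slack
    orow <- mean(rr[o_sel]); ocol <- mean(cc[o_sel])
    edge <- any(pooled$roi_row[as.logical(sel)][o_sel] %in%
                  c(0L, pooled$nbr - 1L)) ||
            any(pooled$roi_col[as.logical(sel)][o_sel] %in%
                  c(0L, pooled$nbc - 1L))
    out[[length(out) + 1L]] <- data.frame(
      wave = NA_integer_, time_ms = t0, direction_deg = as.numeric(dir),
      interval_ms = NA_real_, n_rois = sum(sel), origin_row = orow,
      origin_col = ocol, speed_mm_s = as.numeric(speed), edge_origin = edge)
  }
  out
}

#' Classify a recording as re-entry, triggers-only or quiescent
#'
#' Re-entry requires at least `min_reentry_wavefronts` consecutive wavefronts
#' ("over four") that are very regular: pairwise propagation directions
#' within the direction tolerance and an inter-wave interval coefficient of
#' variation at or below the regularity threshold.
#'
#' @param wavefronts Data frame from [segment_wavefronts()].
#' @param config A [reentry_config()].
#' @return `"re_entry"`, `"triggers_only"` or `"quiescent"`.
#' @export
classify_recording <- function(wavefronts, config = reentry_config()) {
  if (nrow(wavefronts) == 0L) return("quiescent")
  k <- config$min_reentry_wavefronts
  n <- nrow(wavefronts)
  if (n >= k) {
    dirs <- wavefronts$direction_deg
    times <- wavefronts$time_ms
    for (s in seq_len(n - k + 1L)) {
      idx <- s:(s + k - 1L)
      dd <- dirs[idx]
      if (any(is.na(dd))) next
      pair_ok <- TRUE
      for (i in seq_along(idx)) {
        if (any(angle_diff_deg(dd[i], dd) > config$direction_tol_deg)) {
          pair_ok <- FALSE; break
        }
      }
      if (!pair_ok) next
      iv <- diff(times[idx])
      if (any(iv <= 0)) next
      cv <- sd(iv) / mean(iv)
      if (is.finite(cv) && cv <= config$regularity_cv) return("re_entry")
    }
  }
  "triggers_only"
}

#' Localize trigger sites
#'
#' For each segmented wavefront, the origin (the earliest-activating ROI
#' cluster) is refined to pixel precision on a local activation map; origins
#' within the matching tolerance are merged into sites. Refuses recordings
#' classified as re-entry, where wavefronts originate from the circuit
#' rather than from triggers.
#'
#' @param movie A [reentry_movie()].
#' @param config A [reentry_config()].
#' @param wavefronts Optional precomputed [segment_wavefronts()] table.
#' @return A data frame of sites: `site`, `row_px`, `col_px`, `row_um`,
#'   `col_um`, `n_firings`, `edge_source`, plus attribute `firings` (list of
#'   per-site firing-time vectors, ms).
#' @export
localize_triggers <- function(movie, config = reentry_config(),
                              wavefronts = NULL) {
  if (is.null(wavefronts)) wavefronts <- segment_wavefronts(movie, config)
  cls <- classify_recording(wavefronts, config)
  if (cls == "re_entry") stop("re-entry present: trigger counts are not defined")
  empty <- data.frame(site = integer(0), row_px = numeric(0),
                      col_px = numeric(0), row_um = numeric(0),
                      col_um = numeric(0), n_firings = integer(0),
                      edge_source = logical(0))
  if (nrow(wavefronts) == 0L) return(empty)
  dt_ms <- 1000 / movie$frame_rate
  nf <- n_frames(movie)
  origins <- lapply(seq_len(nrow(wavefronts)), function(i) {
    wf <- wavefronts[i, ]
    f0 <- max(1L, floor(wf$time_ms / dt_ms) - 4L)
    f1 <- min(nf, f0 + as.integer(120 / dt_ms))
    if (f1 - f0 < 4L) f0 <- max(1L, f1 - 5L)
    # the halo must contain the first-frame activation disc, whose radius is
    # one frame of travel at the wave speed
    sp <- wf$speed_mm_s
    if (!is.finite(sp) || sp <= 0) sp <- 41
    halo <- min(64L, max(16L, ceiling(1.3 * sp * dt_ms / movie$pixel_pitch)))
    refine_origin(movie, c(wf$origin_row, wf$origin_col), c(f0, f1), config,
                  halo = halo)
  })
  org <- do.call(rbind, origins)
  org <- cbind(org, time_ms = wavefronts$time_ms,
               edge = wavefronts$edge_origin)
  # greedy agglomeration into sites within the match tolerance
  tol_px <- config$match_tolerance_um / movie$pixel_pitch
  site_id <- integer(nrow(org))
  centers <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(nrow(org))) {
    if (nrow(centers) > 0L) {
      dd <- sqrt((centers[, 1] - org[i, 1])^2 + (centers[, 2] - org[i, 2])^2)
      j <- which.min(dd)
      if (dd[j] <= tol_px) {
        site_id[i] <- j
        members <- which(site_id == j)
        centers[j, ] <- colMeans(org[members, 1:2, drop = FALSE])
        next
      }
    }
    centers <- rbind(centers, org[i, 1:2])
    site_id[i] <- nrow(centers)
  }
  firings <- split(org[, "time_ms"], site_id)
  edges <- vapply(split(org[, "edge"], site_id), function(e) any(e > 0), TRUE)
  out <- data.frame(site = seq_len(nrow(centers)),
                    row_px = centers[, 1], col_px = centers[, 2],
                    row_um = centers[, 1] * movie$pixel_pitch,
                    col_um = centers[, 2] * movie$pixel_pitch,
                    n_firings = as.integer(lengths(firings)),
                    edge_source = as.logical(edges))
  attr(out, "firings") <- firings
  out
}

refine_origin <- function(movie, origin_px, window, config, halo = 16L) {
  d <- dim(movie$data)
  r0 <- max(0L, floor(origin_px[1]) - halo); r1 <- min(d[1] - 1L, ceiling(origin_px[1]) + halo)
  c0 <- max(0L, floor(origin_px[2]) - halo); c1 <- min(d[2] - 1L, ceiling(origin_px[2]) + halo)
  subm <- reentry_movie(movie$data[(r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L), , drop = FALSE],
                        movie$frame_rate, movie$pixel_pitch, movie$channel)
  am <- tryCatch(compute_activation_map(subm, window, config),
                 error = function(e) NULL)
  if (is.null(am) || all(is.na(am))) {
    return(cbind(origin_px[1], origin_px[2]))
  }
  # pixels activating in the first frame of the wave: a disc centred on the
  # origin no wider than one frame's travel; the spatial median resists
  # stray early pixels under noise
  dt_ms <- 1000 / movie$frame_rate
  tmin <- min(am, na.rm = TRUE)
  sel <- which(!is.na(am) & am <= tmin + 0.51 * dt_ms, arr.ind = TRUE)
  if (nrow(sel) < 5L) {
    sel <- which(!is.na(am) & am <= tmin + 1.1 * dt_ms, arr.ind = TRUE)
  }
  cbind(median(sel[, 1]) - 1 + r0, median(sel[, 2]) - 1 + c0)
}

#' Match activity locations between two recordings
#'
#' Compares pre-perturbation sites to post-perturbation sites: a pre site is
#' `same_location` when any post site lies within the tolerance (boundary
#' inclusive), `other_location` when post sites exist but none is within
#' tolerance, and `no_activity` when the post recording is quiescent.
#'
#' @param pre_sites,post_sites Data frames with `row_um`, `col_um` columns
#'   (e.g. from [localize_triggers()]); `post_sites` may have zero rows.
#' @param tolerance_um Matching tolerance, micrometres (> 0).
#' @return Character vector, one outcome per pre site.
#' @export
match_locations <- function(pre_sites, post_sites, tolerance_um = 100) {
  stopifnot(tolerance_um > 0)
  if (nrow(pre_sites) == 0L) return(character(0))
  if (nrow(post_sites) == 0L) return(rep("no_activity", nrow(pre_sites)))
  vapply(seq_len(nrow(pre_sites)), function(i) {
    dd <- sqrt((post_sites$row_um - pre_sites$row_um[i])^2 +
               (post_sites$col_um - pre_sites$col_um[i])^2)
    if (min(dd) <= tolerance_um) "same_location" else "other_location"
  }, "")
}
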