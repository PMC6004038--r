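# Analytic phantoms: rotors pinned to a block structure, planar waves and
# focal sources, all with exact per-pixel ground truth. The rotor phase field
# is an atan2 winding about the structure centroid plus a sector-offset
# "sideness" term that decays within a few pixels of the structure, so that
# isochrones terminate on the block with an activation-time jump of at least
# ~0.3 cycles along the structure's full length.

#' Describe a conduction-block core structure
#'
#' The three observed core shapes: a single line, a line connected to a small
#' patch of cells, or three or more connected lines. Lines are represented as
#' straight branches radiating from a common centre; the patch is a disc at a
#' branch tip.
#'
#' @param type `"line"`, `"line_plus_patch"` or `"multi_line"`.
#' @param center `(row, col)` centre, 0-based pixels; small fractional
#'   offsets are added so branch lines never pass exactly through pixel
#'   centres (a rasterization convention, recorded in the output).
#' @param angle_deg Orientation of the first branch, degrees (image
#'   convention: 0 along +col, angles increase towards +row).
#' @param length_px For `"line"`/`"line_plus_patch"`, the full line length;
#'   for `"multi_line"`, the length of each branch.
#' @param n_branches Number of branches for `"multi_line"` (3-5).
#' @param patch_radius_px Radius of the cell patch for `"line_plus_patch"`.
#' @return An object of class `core_structure`.
#' @export
core_structure <- function(type = c("line", "line_plus_patch", "multi_line"),
                           center, angle_deg = 0, length_px = 50,
                           n_branches = 3L, patch_radius_px = 9) {
  type <- match.arg(type)
  stopifnot(length(center) == 2L, length_px >= 0)
  center <- as.numeric(center) + c(0.23, 0.37)
  a0 <- angle_deg * pi / 180
  if (type %in% c("line", "line_plus_patch")) {
    branches <- list(c(angle = a0, length = length_px / 2),
                     c(angle = a0 + pi, length = length_px / 2))
  } else {
    if (n_branches < 3L || n_branches > 4L) {
      stop("multi_line supports 3 or 4 branches")
    }
    branches <- lapply(seq_len(n_branches) - 1L, function(j) {
      c(angle = a0 + j * 2 * pi / n_branches, length = length_px)
    })
  }
  patch <- NULL
  if (type == "line_plus_patch") {
    tip <- center + length_px / 2 * c(sin(a0), cos(a0))
    patch <- list(center = tip, radius = patch_radius_px)
  }
  structure(list(type = type, center = center, branches = branches,
                 patch = patch),
            class = "core_structure")
}

branch_segments <- function(core) {
  # each row: r0 c0 r1 c1 (pixel units, row/col)
  t(vapply(core$branches, function(b) {
    tip <- core$center + b["length"] * c(sin(b["angle"]), cos(b["angle"]))
    c(core$center, tip)
  }, numeric(4)))
}

point_segment_distance <- function(pr, pc, seg) {
  vr <- seg[3] - seg[1]; vc <- seg[4] - seg[2]
  len2 <- vr^2 + vc^2
  if (len2 == 0) return(sqrt((pr - seg[1])^2 + (pc - seg[2])^2))
  t <- pmin(1, pmax(0, ((pr - seg[1]) * vr + (pc - seg[2]) * vc) / len2))
  sqrt((pr - seg[1] - t * vr)^2 + (pc - seg[2] - t * vc)^2)
}

segments_cross <- function(pr, pc, qr, qc, seg) {
  # does segment p->q cross the branch segment? vectorized over p/q
  o1 <- (seg[3] - seg[1]) * (pc - seg[2]) - (seg[4] - seg[2]) * (pr - seg[1])
  o2 <- (seg[3] - seg[1]) * (qc - seg[2]) - (seg[4] - seg[2]) * (qr - seg[1])
  o3 <- (qr - pr) * (seg[2] - pc) - (qc - pc) * (seg[1] - pr)
  o4 <- (qr - pr) * (seg[4] - pc) - (qc - pc) * (seg[3] - pr)
  (o1 * o2 < 0) & (o3 * o4 <= 0)
}

#' Rotor phase field for a block structure
#'
#' Phase (in turns, `[0, 1)`) winding once about the structure centre, with a
#' sector-dependent offset near the structure so pixels on opposite sides of
#' any branch are at least `jump` turns apart. The true core mask is the
#' one-pixel lining of the block interface (pixels whose 8-neighbourhood
#' straddles a branch) plus any patch pixels.
#'
#' @param h,w Field dimensions, pixels.
#' @param core A [core_structure()].
#' @param rho Lateral decay length of the sideness term, pixels. The decay
#'   is anisotropic: full strength within one pixel of a branch with a
#'   gentle lateral falloff (so the smooth far field never fakes a block),
#'   but cut off within ~1.5 px beyond a branch tip (so the discontinuity
#'   does not leak past the structure).
#' @param jump Minimum cross-branch phase offset, turns.
#' @return List with `phase` (H x W, turns), `core_mask`, `patch_mask`
#'   (logical H x W) and `d_struct` (distance to the structure, pixels).
#' @keywords internal
rotor_phase_field <- function(h, w, core, rho = 10, jump = 0.35) {
  rows <- matrix(rep(0:(h - 1L), w), h)
  cols <- matrix(rep(0:(w - 1L), each = h), h)
  dr <- rows - core$center[1]
  dc <- cols - core$center[2]
  ang <- atan2(dr, dc)
  a <- (ang / (2 * pi)) %% 1
  # Each branch contributes an antisymmetric "dipole": +jump/2 on one side
  # of its line, -jump/2 on the other, attenuated laterally over rho pixels
  # and notched off just past the branch tip. The activation-time jump
  # across any branch is `jump` along its full length, decays below any
  # block threshold within ~1.5 px beyond the tips, and the smooth far
  # field never fakes a block.
  segs <- branch_segments(core)
  d_struct <- matrix(Inf, h, w)
  sideness <- matrix(0, h, w)
  for (j in seq_len(nrow(segs))) {
    d_struct <- pmin(d_struct, point_segment_distance(rows, cols, segs[j, ]))
    vr <- segs[j, 3] - segs[j, 1]; vc <- segs[j, 4] - segs[j, 2]
    len <- sqrt(vr^2 + vc^2)
    if (len == 0) next
    s_along <- ((rows - segs[j, 1]) * vr + (cols - segs[j, 2]) * vc) / len
    cross <- ((rows - segs[j, 1]) * vc - (cols - segs[j, 2]) * vr) / len
    perp <- abs(cross)
    over <- pmax(0, pmax(-s_along, s_along - len))
    g_lat <- pmax(0, pmin(1, 1 - (perp - 1) / (rho - 1)))
    g_tip <- ifelse(over <= 0, 1, 0.68 * pmax(0, 1 - over / 6))
    sideness <- sideness + sign(cross) * (jump / 2) * g_lat * g_tip
  }
  phase <- (a + sideness) %% 1
  # true core: 8-neighbourhood straddles a branch
  core_mask <- matrix(FALSE, h, w)
  cand <- which(d_struct < 1.6)
  if (length(cand) > 0) {
    offs <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
    pr <- rows[cand]; pc <- cols[cand]
    for (oi in seq_len(nrow(offs))) {
      qr <- pr + offs[oi, 1]; qc <- pc + offs[oi, 2]
      ok <- qr >= 0 & qr < h & qc >= 0 & qc < w
      hit <- rep(FALSE, length(cand))
      for (j in seq_len(nrow(segs))) {
        hit <- hit | (ok & segments_cross(pr, pc, qr, qc, segs[j, ]))
      }
      core_mask[cand[hit]] <- TRUE
      qi <- (qc[hit]) * h + qr[hit] + 1L
      core_mask[qi] <- TRUE
    }
  }
  patch_mask <- matrix(FALSE, h, w)
  if (!is.null(core$patch)) {
    dpr <- rows - core$patch$center[1]
    dpc <- cols - core$patch$center[2]
    patch_mask <- (dpr^2 + dpc^2) <= core$patch$radius^2
  }
  list(phase = phase, core_mask = core_mask | patch_mask,
       patch_mask = patch_mask, d_struct = d_struct)
}

#' Generate a rotor phantom with exact ground truth
#'
#' An analytic rotor circulating about a block structure: every off-core
#' pixel fires periodically at the rotor period, with activation phase given
#' by the winding field of [rotor_phase_field()]. Core-lining cells behave
#' per `core_cell_mode`: `"noise_only"` (random sub-threshold fluctuations,
#' the default), `"silent"` (flat), or `"double_rate"` (driven alternately
#' from both sides, firing at twice the rotor rate). Patch cells are always
#' inactive.
#'
#' With `dual = TRUE` a voltage channel is rendered alongside calcium: the
#' calcium upstrokes trail the voltage upstrokes by `ca_lag_frames`, and a
#' one-pixel margin of cells around the core shows calcium transients but no
#' propagated action-potential upstroke, so the voltage-derived core is
#' slightly larger than the calcium-derived one.
#'
#' @param core A [core_structure()]; must not touch the field border.
#' @param period_ms Rotor period, ms (> 0).
#' @param dim `c(height, width)` in pixels.
#' @param duration_s Recording length, s.
#' @param frame_rate Frames per second.
#' @param pixel_pitch Micrometres per pixel.
#' @param core_cell_mode Behaviour of core-lining cells.
#' @param noise_sd Additive noise, fraction of transient amplitude.
#' @param dual Also render a voltage channel.
#' @param ca_lag_frames Voltage-to-calcium lag, frames (>= 0).
#' @param voltage_core_margin Extra inactive margin (pixels) of the voltage
#'   channel around the core.
#' @param bleach_tau_s Photobleaching time constant, s (`Inf` disables).
#' @param seed Random seed.
#' @return List with `movie` (calcium), `movie_voltage` (when `dual`), and
#'   `truth` (class `ground_truth`): `core_mask`, `patch_mask`, `phase`,
#'   `period_ms`, `mode`, `inactive` / `inactive_voltage` masks,
#'   `ca_lag_frames`, `seed`.
#' @export
make_rotor_phantom <- function(core, period_ms = 345, dim = c(256L, 256L),
                               duration_s = 4, frame_rate = 100,
                               pixel_pitch = 10,
                               core_cell_mode = c("noise_only", "silent",
                                                  "double_rate"),
                               noise_sd = 0.05, dual = FALSE,
                               ca_lag_frames = 3L, voltage_core_margin = 1L,
                               bleach_tau_s = Inf, seed = 1L) {
  core_cell_mode <- match.arg(core_cell_mode)
  stopifnot(inherits(core, "core_structure"), period_ms > 0)
  if (ca_lag_frames < 0) stop("ca_lag_frames must be >= 0 (voltage leads calcium)")
  h <- dim[1]; w <- dim[2]
  fld <- rotor_phase_field(h, w, core)
  if (!any(fld$core_mask)) stop("core mask is empty")
  border <- which(fld$core_mask, arr.ind = TRUE)
  if (any(border == 1L) || any(border[, 1] == h) || any(border[, 2] == w)) {
    stop("core structure touches the field border")
  }
  lining <- fld$core_mask & !fld$patch_mask
  inactive <- fld$patch_mask
  double_rate <- matrix(FALSE, h, w)
  if (core_cell_mode == "double_rate") double_rate <- lining else inactive <- inactive | lining
  t0 <- fld$phase * period_ms
  mk_channel <- function(channel, inact, lag_ms, chan_seed) {
    kern <- transient_kernel(channel)
    tab1 <- periodic_kernel_table(kern, period_ms)
    tab2 <- periodic_kernel_table(kern, period_ms / 2)
    nf <- as.integer(round(duration_s * frame_rate))
    dt_ms <- 1000 / frame_rate
    t0v <- as.numeric(t0) + lag_ms
    ia <- as.logical(inact)
    dbl <- as.logical(double_rate) & !ia
    any_dbl <- any(dbl)
    sig <- matrix(0, h * w, nf)
    for (f in seq_len(nf)) {
      tf <- (f - 1L) * dt_ms
      s <- (tf - t0v) %% period_ms
      v <- tab1$values[as.integer(s + 0.5) + 1L]
      if (any_dbl) {
        s2 <- (tf - t0v[dbl]) %% (period_ms / 2)
        v[dbl] <- tab2$values[as.integer(s2 + 0.5) + 1L]
      }
      v[ia] <- 0
      sig[, f] <- v
    }
    set.seed(chan_seed)
    if (core_cell_mode == "noise_only" && any(as.logical(lining) & ia)) {
      idx <- which(as.logical(lining) & ia)
      t_s <- (seq_len(nf) - 1L) / frame_rate
      for (p in idx) {
        fr <- runif(1, 0.2, 0.8); ph <- runif(1, 0, 2 * pi)
        sig[p, ] <- 0.12 * (1 + sin(2 * pi * fr * t_s + ph)) / 2
      }
    }
    finish_movie(sig, h, w, frame_rate, pixel_pitch, channel, noise_sd,
                 bleach_tau_s)
  }
  dt_ms <- 1000 / frame_rate
  movie <- mk_channel("calcium", inactive,
                      if (dual) ca_lag_frames * dt_ms else 0,
                      child_seed(seed, 1L))
  movie_voltage <- NULL
  inactive_voltage <- NULL
  if (dual) {
    inactive_voltage <- dilate_mask(fld$core_mask, voltage_core_margin) |
      inactive
    movie_voltage <- mk_channel("voltage", inactive_voltage, 0,
                                child_seed(seed, 2L))
  }
  truth <- structure(
    list(core_mask = fld$core_mask, patch_mask = fld$patch_mask,
         phase = fld$phase, period_ms = period_ms, mode = core_cell_mode,
         inactive = inactive, inactive_voltage = inactive_voltage,
         double_rate = double_rate, ca_lag_frames = if (dual) ca_lag_frames else 0L,
         frame_rate = frame_rate, duration_s = duration_s, seed = seed),
    class = "ground_truth")
  list(movie = movie, movie_voltage = movie_voltage, truth = truth)
}

# binary dilation with a disc of the given radius (pixels)
dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  offs <- rbind(c(0, 0), disc_offsets(radius + 0.01))
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offs))) {
    sh <- shift_matrix(mask + 0, offs[i, 1], offs[i, 2])
    out <- out | (!is.na(sh) & sh > 0)
  }
  out
}

#' Ground-truth event times for one phantom pixel
#'
#' @param truth A `ground_truth` from [make_rotor_phantom()].
#' @param px `(row, col)`, 0-based.
#' @param channel `"calcium"` or `"voltage"` (lag applied accordingly).
#' @return Numeric event times, ms (empty for inactive pixels).
#' @export
truth_events <- function(truth, px, channel = c("calcium", "voltage")) {
  channel <- match.arg(channel)
  stopifnot(inherits(truth, "ground_truth"))
  r <- px[1] + 1L; c <- px[2] + 1L
  inact <- if (channel == "voltage" && !is.null(truth$inactive_voltage)) {
    truth$inactive_voltage
  } else truth$inactive
  if (inact[r, c]) return(numeric(0))
  dt_ms <- 1000 / truth$frame_rate
  lag_ms <- if (channel == "calcium") truth$ca_lag_frames * dt_ms else 0
  per <- if (truth$double_rate[r, c]) truth$period_ms / 2 else truth$period_ms
  t0 <- (truth$phase[r, c] * truth$period_ms + lag_ms) %% per
  tmax <- truth$duration_s * 1000
  if (t0 > tmax) return(numeric(0))
  seq(t0, tmax, by = per)
}

arrival_movie <- function(arrivals, h, w, duration_s, frame_rate, pixel_pitch,
                          channel, noise_sd, bleach_tau_s, seed) {
  # arrivals: list of H*W vectors (ms), one per wave (NA = wave misses pixel)
  kern <- transient_kernel(channel)
  nf <- as.integer(round(duration_s * frame_rate))
  dt_ms <- 1000 / frame_rate
  span <- attr(kern, "rise_ms") + 5 * attr(kern, "decay_ms")
  klen_f <- as.integer(ceiling(span / dt_ms)) + 1L
  ktab_f <- kern((0:(klen_f - 1L)) * dt_ms)
  sig <- matrix(0, h * w, nf)
  for (a in arrivals) {
    f0 <- as.integer(round(a / dt_ms)) + 1L        # arrival frame, 1-based
    f0[is.na(f0)] <- NA_integer_
    groups <- split(which(!is.na(f0) & f0 <= nf), f0[!is.na(f0) & f0 <= nf])
    for (g in names(groups)) {
      s <- as.integer(g)
      cols <- max(1L, s):min(nf, s + klen_f - 1L)
      kseg <- ktab_f[cols - s + 1L]
      rows <- groups[[g]]
      sig[rows, cols] <- sig[rows, cols] +
        rep(kseg, each = length(rows))
    }
  }
  set.seed(seed)
  finish_movie(sig, h, w, frame_rate, pixel_pitch, channel, noise_sd,
               bleach_tau_s)
}

#' Planar-wave phantom
#'
#' A train of plane waves crossing the field at a fixed conduction velocity.
#'
#' @param onsets_ms Onset time of each wave at the entry edge, ms.
#' @param v_mm_s Conduction velocity, mm/s.
#' @param direction_deg Propagation direction, degrees (0 = towards +col).
#' @param dim,duration_s,frame_rate,pixel_pitch,noise_sd,channel,bleach_tau_s,seed
#'   As in [make_rotor_phantom()].
#' @return List with `movie` and `truth` (`arrivals`: per-wave H x W arrival
#'   matrices, ms; `v_mm_s`; `direction_deg`).
#' @export
planar_wave_phantom <- function(onsets_ms, v_mm_s = 41, direction_deg = 0,
                                dim = c(256L, 256L), duration_s = NULL,
                                frame_rate = 100, pixel_pitch = 10,
                                noise_sd = 0.05,
                                channel = c("calcium", "voltage"),
                                bleach_tau_s = Inf, seed = 1L) {
  channel <- match.arg(channel)
  h <- dim[1]; w <- dim[2]
  rows <- matrix(rep(0:(h - 1L), w), h)
  cols <- matrix(rep(0:(w - 1L), each = h), h)
  th <- direction_deg * pi / 180
  proj <- (cos(th) * cols + sin(th) * rows) * pixel_pitch   # um along direction
  proj <- proj - min(proj)
  delay <- proj / v_mm_s                                     # um / (um/ms) = ms
  arrivals <- lapply(onsets_ms, function(o) as.numeric(o + delay))
  if (is.null(duration_s)) {
    duration_s <- (max(onsets_ms) + max(delay) + 600) / 1000
  }
  movie <- arrival_movie(arrivals, h, w, duration_s, frame_rate, pixel_pitch,
                         channel, noise_sd, bleach_tau_s, seed)
  truth <- list(arrivals = lapply(arrivals, matrix, nrow = h),
                v_mm_s = v_mm_s, direction_deg = direction_deg,
                onsets_ms = onsets_ms)
  list(movie = movie, truth = truth)
}

#' Focal-source phantom
#'
#' One or more point sources firing at given times; waves expand radially at
#' a fixed velocity and annihilate on collision (each pixel activates at the
#' earliest arrival among waves of overlapping beats).
#'
#' @param sites Matrix of source `(row, col)` positions, 0-based pixels.
#' @param onsets List of numeric onset-time vectors (ms), one per site.
#' @param v_mm_s Conduction velocity, mm/s.
#' @param dim,duration_s,frame_rate,pixel_pitch,noise_sd,channel,bleach_tau_s,seed
#'   As in [make_rotor_phantom()].
#' @return List with `movie` and `truth` (`sites`, `onsets`, per-beat arrival
#'   matrices and originating-site index maps).
#' @export
focal_phantom <- function(sites, onsets, v_mm_s = 41, dim = c(256L, 256L),
                          duration_s = NULL, frame_rate = 100,
                          pixel_pitch = 10, noise_sd = 0.05,
                          channel = c("calcium", "voltage"),
                          bleach_tau_s = Inf, seed = 1L) {
  channel <- match.arg(channel)
  sites <- matrix(sites, ncol = 2L)
  stopifnot(length(onsets) == nrow(sites))
  h <- dim[1]; w <- dim[2]
  rows <- matrix(rep(0:(h - 1L), w), h)
  cols <- matrix(rep(0:(w - 1L), each = h), h)
  waves <- do.call(rbind, lapply(seq_len(nrow(sites)), function(s) {
    data.frame(site = s, onset = onsets[[s]])
  }))
  waves <- waves[order(waves$onset), ]
  crossing <- sqrt(h^2 + w^2) * pixel_pitch / v_mm_s      # ms to cross field
  # group waves whose expansions can meet (onsets within one crossing time)
  grp <- cumsum(c(1, diff(waves$onset) > crossing))
  arrivals <- list(); origin_maps <- list()
  for (g in unique(grp)) {
    sub <- waves[grp == g, , drop = FALSE]
    arr <- matrix(Inf, h, w); org <- matrix(NA_integer_, h, w)
    for (i in seq_len(nrow(sub))) {
      d <- sqrt((rows - sites[sub$site[i], 1])^2 +
                (cols - sites[sub$site[i], 2])^2) * pixel_pitch
      a <- sub$onset[i] + d / v_mm_s
      upd <- a < arr
      arr[upd] <- a[upd]; org[upd] <- sub$site[i]
    }
    arrivals[[length(arrivals) + 1L]] <- as.numeric(arr)
    origin_maps[[length(origin_maps) + 1L]] <- org
  }
  if (is.null(duration_s)) {
    duration_s <- (max(waves$onset) + crossing + 600) / 1000
  }
  movie <- arrival_movie(arrivals, h, w, duration_s, frame_rate, pixel_pitch,
                         channel, noise_sd, bleach_tau_s, seed)
  truth <- list(sites = sites, onsets = onsets, v_mm_s = v_mm_s,
                arrivals = lapply(arrivals, matrix, nrow = h),
                origin_maps = origin_maps, n_waves = nrow(waves))
  list(movie = movie, truth = truth)
}
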