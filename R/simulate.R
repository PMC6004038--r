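# Discrete-time excitable-lattice simulation: threshold/refractory event
# dynamics with per-link conduction latency. A phenomenological model, not an
# ionic one: the analyses downstream only use event timing and propagation
# geometry, which this reproduces with exact ground truth.

#' Simulate a cell lattice
#'
#' At each step, a cell fires if it is excitable (not refractory) and either
#' (a) it is automatic and its jittered cycle timer has elapsed, or (b) the
#' coupling-weighted input from neighbours that fired one conduction latency
#' earlier, accumulated over the integration window, reaches its threshold
#' fraction of total neighbour weight. Firing makes the cell refractory for
#' its refractory period and schedules input to each neighbour after a
#' latency `distance / conduction speed` (times the pair's slowing factor).
#'
#' @param lattice A `cell_lattice` (optionally with an imposed block).
#' @param duration_s Simulated time, s.
#' @param dt_ms Time step, ms (must be <= 1).
#' @param seed Random seed (trigger jitter).
#' @param stimuli Optional list of external stimuli, each
#'   `list(time_ms =, cells =)` forcing the listed cells to fire (if
#'   excitable) at the given time. Use [cells_in_disc()] / edge selections
#'   to build the cell sets (e.g. S1-S2 cross-field protocols).
#' @param integration_window_ms Input accumulation window, ms.
#' @param relative_window_ms Post-repolarization waiting window: input
#'   arriving within this many ms of the end of a cell's refractory period is
#'   held and re-applied at recovery (the wavefront "waits" on the tail's
#'   recovery, as in leading-circle re-entry), instead of being discarded as
#'   it is earlier in the refractory period.
#' @return A `lattice_ground_truth`: `events` (list of per-cell firing
#'   times, ms), the lattice, and scalar truths (`duration_s`, `seed`).
#' @export
simulate_lattice <- function(lattice, duration_s, dt_ms = 0.5, seed = 1L,
                             stimuli = list(), integration_window_ms = 5,
                             relative_window_ms = 60) {
  stopifnot(inherits(lattice, "cell_lattice"), duration_s > 0)
  if (dt_ms > 1) stop("dt_ms must be <= 1 ms")
  cp <- lattice$coupling
  if (!Matrix::isSymmetric(cp)) stop("coupling matrix must be symmetric")
  n <- nrow(lattice$centroids_um)
  n_steps <- as.integer(ceiling(duration_s * 1000 / dt_ms))
  set.seed(seed)
  # neighbour lists with per-link latency in steps
  cpt <- as(cp, "TsparseMatrix")
  src <- cpt@i + 1L; dst <- cpt@j + 1L; wgt <- cpt@x
  dist_um <- sqrt(rowSums((lattice$centroids_um[src, , drop = FALSE] -
                           lattice$centroids_um[dst, , drop = FALSE])^2))
  slow <- pmax(lattice$link_delay_scale[src], lattice$link_delay_scale[dst])
  lat_ms <- dist_um / lattice$conduction_mm_s * slow   # um / (um/ms) = ms
  lat_steps <- pmax(1L, as.integer(round(lat_ms / dt_ms)))
  nb_idx <- split(seq_along(src), src)
  tot_w <- as.numeric(Matrix::rowSums(cp))
  thr <- lattice$threshold_frac * pmax(tot_w, 1e-12)
  win_steps <- max(1L, as.integer(round(integration_window_ms / dt_ms)))
  # automatic timers
  next_auto <- rep(Inf, n)
  auto <- which(lattice$automatic)
  jitter_sd <- lattice$trigger_cv * lattice$trigger_cycle_ms
  draw_cycle <- function(k) {
    pmax(lattice$refractory_ms[k] + dt_ms,
         rnorm(length(k), lattice$trigger_cycle_ms, jitter_sd))
  }
  if (length(auto) > 0) {
    next_auto[auto] <- runif(length(auto), 0, lattice$trigger_cycle_ms)
  }
  stim_steps <- if (length(stimuli) > 0) {
    vapply(stimuli, function(s) as.integer(round(s$time_ms / dt_ms)) + 1L, 1L)
  } else integer(0)
  arrivals <- vector("list", n_steps + max(lat_steps) + win_steps + 1L)
  acc <- numeric(n)
  refract_until <- rep(-Inf, n)
  events <- vector("list", n)
  max_step <- length(arrivals)
  for (step in seq_len(n_steps)) {
    t_ms <- (step - 1L) * dt_ms
    inc <- arrivals[[step]]
    if (!is.null(inc)) {
      ref <- refract_until[inc$cell] > t_ms
      if (any(ref)) {
        # late-refractory input waits for recovery; earlier input is lost
        waitable <- ref & (refract_until[inc$cell] - t_ms <= relative_window_ms)
        if (any(waitable)) {
          wcell <- inc$cell[waitable]
          wstep <- pmin(max_step,
                        as.integer(ceiling(refract_until[wcell] / dt_ms)) + 2L)
          for (u in unique(wstep)) {
            sel <- wstep == u
            prev <- arrivals[[u]]
            arrivals[[u]] <- list(cell = c(prev$cell, wcell[sel]),
                                  w = c(prev$w, inc$w[waitable][sel]))
          }
        }
        inc <- list(cell = inc$cell[!ref], w = inc$w[!ref])
      }
      if (length(inc$cell) > 0) {
        agg <- rowsum(inc$w, inc$cell)
        acc[as.integer(rownames(agg))] <- acc[as.integer(rownames(agg))] + agg[, 1]
        arrivals[[step]] <- inc   # only applied input expires later
      } else {
        arrivals[step] <- list(NULL)
      }
    }
    expire_step <- step - win_steps
    if (expire_step >= 1L && !is.null(arrivals[[expire_step]])) {
      old <- arrivals[[expire_step]]
      agg <- rowsum(old$w, old$cell)
      acc[as.integer(rownames(agg))] <- acc[as.integer(rownames(agg))] - agg[, 1]
    }
    excitable <- t_ms >= refract_until
    fire <- which(excitable & (acc >= thr | next_auto <= t_ms))
    if (length(stim_steps) > 0) {
      hit <- which(stim_steps == step)
      for (s in hit) {
        fire <- union(fire, stimuli[[s]]$cells[excitable[stimuli[[s]]$cells]])
      }
    }
    if (length(fire) > 0) {
      for (cell in fire) {
        events[[cell]] <- c(events[[cell]], t_ms)
        refract_until[cell] <- t_ms + lattice$refractory_ms[cell]
        if (lattice$automatic[cell]) {
          next_auto[cell] <- t_ms + draw_cycle(cell)
        }
        links <- nb_idx[[as.character(cell)]]
        if (!is.null(links)) {
          at <- step + lat_steps[links]
          for (u in unique(at)) {
            sel <- links[at == u]
            prev <- arrivals[[u]]
            arrivals[[u]] <- list(cell = c(prev$cell, dst[sel]),
                                  w = c(prev$w, wgt[sel]))
          }
        }
      }
    }
  }
  structure(list(events = events, lattice = lattice,
                 duration_s = duration_s, dt_ms = dt_ms, seed = seed),
            class = "lattice_ground_truth")
}

#' Cells within a disc of the colony
#' @param lattice A `cell_lattice`.
#' @param center_um `(row, col)` um about the colony centre.
#' @param radius_um Disc radius, um.
#' @return Integer cell ids.
#' @export
cells_in_disc <- function(lattice, center_um, radius_um) {
  p <- lattice$centroids_um
  which((p[, 1] - center_um[1])^2 + (p[, 2] - center_um[2])^2 <= radius_um^2)
}

#' Cells in a half-plane of the colony
#'
#' Selects cells on one side of a line through `center_um` with normal at
#' `normal_deg` — building block for cross-field (S1-S2) stimulation.
#' @param lattice A `cell_lattice`.
#' @param center_um Point on the boundary line, um.
#' @param normal_deg Direction of the selected side, degrees.
#' @param depth_um Optional maximum distance from the line (a stimulation
#'   band rather than the whole half-plane).
#' @return Integer cell ids.
#' @export
cells_in_halfplane <- function(lattice, center_um = c(0, 0), normal_deg = 0,
                               depth_um = Inf) {
  p <- lattice$centroids_um
  nr <- sin(normal_deg * pi / 180); nc <- cos(normal_deg * pi / 180)
  d <- (p[, 1] - center_um[1]) * nr + (p[, 2] - center_um[2]) * nc
  which(d >= 0 & d <= depth_um)
}

#' Fit conduction velocity from simulated events
#'
#' Distance-versus-first-activation-time regression over cells activated by
#' a point stimulus (the isochrone fit).
#'
#' @param truth A `lattice_ground_truth`.
#' @param origin_um Stimulation origin, um.
#' @param t_min_ms Ignore events before this time (the stimulus itself).
#' @return List with `v_mm_s` (the fitted speed), `r_squared`, `n_cells`.
#' @export
fit_conduction_velocity <- function(truth, origin_um, t_min_ms = 0) {
  lat <- truth$lattice
  first <- vapply(truth$events, function(e) {
    e <- e[e >= t_min_ms]
    if (length(e) == 0) NA_real_ else e[1]
  }, 0)
  act <- which(!is.na(first))
  if (length(act) < 10L) stop("too few activated cells for an isochrone fit")
  d_um <- sqrt((lat$centroids_um[act, 1] - origin_um[1])^2 +
               (lat$centroids_um[act, 2] - origin_um[2])^2)
  fit <- lm(first[act] ~ d_um)
  slope <- coef(fit)[["d_um"]]                  # ms per um
  list(v_mm_s = 1 / slope, r_squared = summary(fit)$r.squared,
       n_cells = length(act))
}

#' Render a simulated lattice to a fluorescence movie
#'
#' @param truth A `lattice_ground_truth` from [simulate_lattice()].
#' @param frame_rate Frames per second.
#' @param channel,noise_sd,bleach_tau_s,ca_lag_frames,seed Passed to
#'   [render_fluorescence()].
#' @param downsample Integer factor applied to the label raster before
#'   rendering (camera binning: the movie pitch is the raster pitch times
#'   this factor).
#' @return A [reentry_movie()].
#' @export
render_lattice_movie <- function(truth, frame_rate = 100,
                                 channel = "calcium", noise_sd = 0.05,
                                 bleach_tau_s = Inf, ca_lag_frames = 3L,
                                 seed = 1L, downsample = 1L) {
  stopifnot(inherits(truth, "lattice_ground_truth"))
  lab <- unclass(truth$lattice$raster)
  pitch <- truth$lattice$raster_pitch_um
  if (downsample > 1L) {
    lab <- lab[seq(1L, nrow(lab), by = downsample),
               seq(1L, ncol(lab), by = downsample)]
    pitch <- pitch * downsample
  }
  render_fluorescence(truth$events, lab,
                      duration_s = truth$duration_s,
                      frame_rate = frame_rate,
                      pixel_pitch = pitch,
                      channel = channel, noise_sd = noise_sd,
                      bleach_tau_s = bleach_tau_s,
                      ca_lag_frames = ca_lag_frames, seed = seed)
}
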