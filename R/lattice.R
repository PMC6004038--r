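# Synthetic monolayer: Poisson-disc cell centroids on a colony disc, raster
# (nearest-centroid) Voronoi tessellation for cell territories and the
# neighbour graph, per-cell automaticity/refractoriness, and imposed
# conduction-block structures.

#' Generate a synthetic cell lattice
#'
#' Cell centroids are Poisson-disc sampled over a circular colony of the
#' requested area; cell territories and the coupling graph come from the
#' discrete Voronoi tessellation rasterized at `raster_pitch`. Exactly
#' `n_triggers` cells are flagged automatic (spontaneously firing at a low,
#' irregular rate).
#'
#' @param colony_area_mm2 Colony area, mm^2 (study sizes: 3.5, 6.4, 9.8).
#' @param mean_cell_diameter_um Mean cell diameter, um.
#' @param n_triggers Number of automatic (trigger) cells; `0 <= n <= cells`.
#' @param seed Random seed.
#' @param raster_pitch_um Label-raster pitch, um/pixel.
#' @param trigger_cycle_ms Mean automatic cycle length, ms.
#' @param trigger_cv Coefficient of variation of the automatic cycle
#'   (triggers fire at low, irregular rates).
#' @param refractory_ms Refractory period, ms.
#' @param threshold_frac Excitation threshold as a fraction of total
#'   neighbour coupling weight.
#' @param conduction_mm_s Conduction speed along cell-to-cell links, mm/s
#'   (calibrated so a planar wave crosses the lattice at ~41 mm/s).
#' @return A `cell_lattice`: centroids (um), label raster, sparse symmetric
#'   coupling matrix, per-cell parameters, colony geometry.
#' @export
generate_cell_lattice <- function(colony_area_mm2, mean_cell_diameter_um = 25,
                                  n_triggers = 3L, seed = 1L,
                                  raster_pitch_um = mean_cell_diameter_um / 3,
                                  trigger_cycle_ms = 1500, trigger_cv = 0.3,
                                  refractory_ms = 300, threshold_frac = 0.15,
                                  conduction_mm_s = 41) {
  stopifnot(colony_area_mm2 > 0, n_triggers >= 0)
  radius_um <- sqrt(colony_area_mm2 * 1e6 / pi)
  if (mean_cell_diameter_um > radius_um) {
    stop("mean_cell_diameter_um too large for the colony area")
  }
  set.seed(seed)
  pts <- poisson_disc(radius_um, r_min = 0.85 * mean_cell_diameter_um)
  n <- nrow(pts)
  if (n_triggers > n) stop("n_triggers exceeds the cell count (", n, ")")
  vor <- raster_voronoi(pts, radius_um, raster_pitch_um)
  trig <- sort(sample.int(n, n_triggers))
  lat <- structure(list(
    centroids_um = pts,                     # (row_um, col_um) about centre
    radius_um = radius_um,
    colony_area_mm2 = colony_area_mm2,
    raster = vor$labels,                    # label_image, 0 outside colony
    raster_pitch_um = raster_pitch_um,
    cell_area_um2 = vor$areas,
    coupling = vor$coupling,                # sparse symmetric, 0 diagonal
    link_delay_scale = rep(1, n),           # per-cell conduction slowing
    refractory_ms = rep(refractory_ms, n),
    threshold_frac = rep(threshold_frac, n),
    automatic = seq_len(n) %in% trig,
    trigger_cycle_ms = trigger_cycle_ms,
    trigger_cv = trigger_cv,
    conduction_mm_s = conduction_mm_s,
    block = NULL,
    seed = seed), class = "cell_lattice")
  lat
}

#' @export
print.cell_lattice <- function(x, ...) {
  cat(sprintf(
    "<cell_lattice> %d cells, colony %.2f mm^2, %d triggers, raster %dx%d @ %g um/px%s\n",
    nrow(x$centroids_um), x$colony_area_mm2, sum(x$automatic),
    nrow(x$raster), ncol(x$raster), x$raster_pitch_um,
    if (!is.null(x$block)) paste0(", block: ", x$block$type) else ""))
  invisible(x)
}

# Bridson Poisson-disc sampling on a disc of the given radius (um)
poisson_disc <- function(radius, r_min, k = 20L) {
  cell <- r_min / sqrt(2)
  g <- ceiling(2 * radius / cell)
  grid <- matrix(NA_integer_, g, g)
  pts <- matrix(0, 0, 2)
  active <- integer(0)
  to_grid <- function(p) pmin(g, pmax(1L, floor((p + radius) / cell) + 1L))
  push <- function(p) {
    pts <<- rbind(pts, p)
    i <- nrow(pts)
    gc <- to_grid(p)
    grid[gc[1], gc[2]] <<- i
    active <<- c(active, i)
    i
  }
  ok <- function(p) {
    if (sum(p^2) > radius^2) return(FALSE)
    gc <- to_grid(p)
    r0 <- max(1L, gc[1] - 2L):min(g, gc[1] + 2L)
    c0 <- max(1L, gc[2] - 2L):min(g, gc[2] + 2L)
    near <- grid[r0, c0]
    near <- near[!is.na(near)]
    if (length(near) == 0L) return(TRUE)
    all((pts[near, 1] - p[1])^2 + (pts[near, 2] - p[2])^2 >= r_min^2)
  }
  push(runif(2, -radius / 4, radius / 4))
  while (length(active) > 0L) {
    ai <- sample(seq_along(active), 1L)
    base <- pts[active[ai], ]
    placed <- FALSE
    for (t in seq_len(k)) {
      ang <- runif(1, 0, 2 * pi)
      rr <- runif(1, r_min, 2 * r_min)
      p <- base + rr * c(cos(ang), sin(ang))
      if (ok(p)) {
        push(p)
        placed <- TRUE
        break
      }
    }
    if (!placed) active <- active[-ai]
  }
  colnames(pts) <- c("row_um", "col_um")
  pts
}

# discrete Voronoi: nearest-centroid labels on a raster covering the colony
# disc; neighbour pairs and polygon areas from the raster
raster_voronoi <- function(pts, radius, pitch) {
  n <- nrow(pts)
  side <- ceiling(2 * radius / pitch)
  ax <- (seq_len(side) - 0.5) * pitch - radius   # pixel-centre coords (um)
  rows <- matrix(ax, side, side)
  cols <- matrix(ax, side, side, byrow = TRUE)
  inside <- rows^2 + cols^2 <= radius^2
  # bucket grid over centroids for a bounded candidate search
  bs <- max(pitch, 2.2 * sqrt(pi * radius^2 / n / pi))
  nb <- ceiling(2 * radius / bs)
  bx <- pmin(nb, pmax(1L, floor((pts[, 1] + radius) / bs) + 1L))
  by <- pmin(nb, pmax(1L, floor((pts[, 2] + radius) / bs) + 1L))
  bucket <- split(seq_len(n), (by - 1L) * nb + bx)
  labels <- matrix(0L, side, side)
  idx_in <- which(inside)
  pr <- rows[idx_in]; pc <- cols[idx_in]
  pbx <- pmin(nb, pmax(1L, floor((pr + radius) / bs) + 1L))
  pby <- pmin(nb, pmax(1L, floor((pc + radius) / bs) + 1L))
  pixel_bucket <- (pby - 1L) * nb + pbx
  for (b in unique(pixel_bucket)) {
    sel <- pixel_bucket == b
    bxi <- ((b - 1L) %% nb) + 1L
    byi <- ((b - 1L) %/% nb) + 1L
    cand <- integer(0)
    ring <- 1L
    while (length(cand) == 0L && ring <= nb) {
      for (dx in -ring:ring) for (dy in -ring:ring) {
        key <- as.character((byi + dy - 1L) * nb + bxi + dx)
        if (!is.null(bucket[[key]])) cand <- c(cand, bucket[[key]])
      }
      ring <- ring + 1L
    }
    cand <- unique(cand)
    d2 <- outer(pr[sel], pts[cand, 1], "-")^2 +
          outer(pc[sel], pts[cand, 2], "-")^2
    labels[idx_in[sel]] <- cand[max.col(-d2, ties.method = "first")]
  }
  areas <- tabulate(labels[labels > 0L], n) * pitch^2
  # raster adjacency -> Voronoi neighbour pairs
  pair_of <- function(a, b) {
    sel <- a > 0L & b > 0L & a != b
    if (!any(sel)) return(NULL)
    cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel]))
  }
  right <- pair_of(labels[, -side], labels[, -1])
  down <- pair_of(labels[-side, ], labels[-1, ])
  prs <- unique(rbind(right, down))
  coupling <- Matrix::sparseMatrix(i = c(prs[, 1], prs[, 2]),
                                   j = c(prs[, 2], prs[, 1]),
                                   x = 1, dims = c(n, n))
  list(labels = as_label_image(labels), areas = areas, coupling = coupling)
}

#' Impose a conduction-block structure on a lattice
#'
#' Cuts coupling across the branches of a [core_structure()]-style geometry
#' (given in lattice um coordinates about the colony centre) and, for
#' patches, makes the patch cells effectively inexcitable by a large
#' refractory multiplier. Cells within `slow_margin_um` of the structure
#' propagate `slow_factor` times slower, the source-sink surrogate that lets
#' a re-entrant loop of a few hundred ms period fit inside a mm-scale
#' colony.
#'
#' @param lattice A `cell_lattice`.
#' @param structure `"line"`, `"line_plus_patch"` or `"multi_line"`.
#' @param center_um `(row, col)` structure centre, um about the colony
#'   centre.
#' @param angle_deg Orientation of the first branch.
#' @param length_um Full line length (or branch length for `multi_line`).
#' @param n_branches Branches for `multi_line`.
#' @param patch_radius_um Patch radius for `line_plus_patch`.
#' @param slow_margin_um Width of the slow-conduction margin.
#' @param slow_factor Conduction slowing within the margin.
#' @param core_refractory_ms Refractory period of the margin cells. Shorter
#'   than the bulk default: the re-entrant loop must re-excite its own path
#'   every rotation, while the surrounding colony only needs to follow at
#'   the (slower) rotor rate. The rotor period is then set by the loop
#'   transit time at the slowed margin speed.
#' @param isolate_core Cut coupling between the slow margin and the bulk
#'   except at one emission port near a branch tip. Core cells then activate
#'   but do not transmit laterally; the circulating loop is protected from
#'   re-invasion by colony-wide waves while still capturing the colony once
#'   per rotation through the port.
#' @param port_radius_um Radius of the emission port.
#' @return The modified lattice; `$block` holds the geometry and
#'   `$block$core_mask` the true core pixels on the raster (interface lining
#'   plus patch cells). A zero-length structure returns the lattice
#'   unchanged.
#' @export
impose_block_structure <- function(lattice,
                                   structure = c("line", "line_plus_patch",
                                                 "multi_line"),
                                   center_um = c(0, 0), angle_deg = 0,
                                   length_um = 600, n_branches = 3L,
                                   patch_radius_um = 90,
                                   slow_margin_um = 100, slow_factor = 8,
                                   core_refractory_ms = 250,
                                   isolate_core = FALSE,
                                   port_radius_um = 1.3 * slow_margin_um) {
  structure <- match.arg(structure)
  stopifnot(inherits(lattice, "cell_lattice"))
  if (length_um == 0) return(lattice)
  pitch <- lattice$raster_pitch_um
  side <- nrow(lattice$raster)
  # geometry in raster pixel coordinates
  center_px <- (center_um + lattice$radius_um) / pitch - 0.5
  core <- core_structure(structure, center = center_px,
                         angle_deg = angle_deg,
                         length_px = length_um / pitch,
                         n_branches = n_branches,
                         patch_radius_px = patch_radius_um / pitch)
  if (max(abs(center_um)) + length_um / 2 > lattice$radius_um) {
    stop("block structure extends outside the colony")
  }
  segs <- branch_segments(core)                      # pixel coords
  segs_um <- (segs + 0.5) * pitch - lattice$radius_um
  pts <- lattice$centroids_um
  # cut coupling for neighbour pairs whose connecting segment crosses a branch
  cp <- as(lattice$coupling, "TsparseMatrix")
  keep <- rep(TRUE, length(cp@i))
  for (j in seq_len(nrow(segs_um))) {
    cross <- segments_cross(pts[cp@i + 1L, 1], pts[cp@i + 1L, 2],
                            pts[cp@j + 1L, 1], pts[cp@j + 1L, 2],
                            segs_um[j, ])
    keep <- keep & !cross
  }
  lattice$coupling <- Matrix::sparseMatrix(i = cp@i[keep] + 1L,
                                           j = cp@j[keep] + 1L,
                                           x = cp@x[keep],
                                           dims = dim(cp))
  # distance of each cell to the structure
  dmin <- rep(Inf, nrow(pts))
  for (j in seq_len(nrow(segs_um))) {
    dmin <- pmin(dmin, point_segment_distance(pts[, 1], pts[, 2], segs_um[j, ]))
  }
  patch_cells <- logical(nrow(pts))
  if (structure == "line_plus_patch") {
    pc_um <- (core$patch$center + 0.5) * pitch - lattice$radius_um
    patch_cells <- (pts[, 1] - pc_um[1])^2 + (pts[, 2] - pc_um[2])^2 <=
      patch_radius_um^2
    lattice$refractory_ms[patch_cells] <- lattice$refractory_ms[patch_cells] * 50
  }
  slow <- dmin <= slow_margin_um
  lattice$link_delay_scale[slow] <- slow_factor
  lattice$refractory_ms[slow & !patch_cells] <- core_refractory_ms
  port_center_um <- segs_um[min(2L, nrow(segs_um)), 3:4]
  if (isolate_core) {
    cpt <- as(lattice$coupling, "TsparseMatrix")
    ii <- cpt@i + 1L; jj <- cpt@j + 1L
    in_port <- (pts[, 1] - port_center_um[1])^2 +
               (pts[, 2] - port_center_um[2])^2 <= port_radius_um^2
    cut2 <- (slow[ii] != slow[jj]) & !(in_port[ii] | in_port[jj])
    lattice$coupling <- Matrix::sparseMatrix(i = ii[!cut2], j = jj[!cut2],
                                             x = cpt@x[!cut2], dims = dim(cpt))
  }
  # true core on the raster: interface lining plus patch-cell territories
  fld <- rotor_phase_field(side, side, core)
  core_mask <- fld$core_mask
  if (any(patch_cells)) {
    core_mask <- core_mask |
      matrix(unclass(lattice$raster) %in% which(patch_cells), side, side)
  }
  lattice$block <- list(type = structure, core = core,
                        core_mask = core_mask, segments_um = segs_um,
                        center_um = center_um, patch_cells = which(patch_cells),
                        slow_cells = which(slow), isolated = isolate_core,
                        port_center_um = port_center_um)
  lattice
}

#' Build a rotational (cross-field series) induction protocol
#'
#' Stimuli that excite the block structure's margin cells in rotational phase
#' order at the target period. The protocol imposes the rotation
#' kinematically: sustained emergent re-entry is outside the scope of the
#' threshold/refractory model, but a driven rotation reproduces every
#' analysis-level signature of re-entry — regular rotational wavefronts at a
#' fixed period, half-cycle conduction delays across the block, and 1:1
#' capture of the colony through the core's emission port.
#'
#' @param lattice A `cell_lattice` with an imposed block structure (use
#'   `isolate_core = TRUE` for a clean rotational phase pattern).
#' @param period_ms Rotation period.
#' @param t_start_ms First-lap start time.
#' @param n_laps Number of driven laps (e.g. `duration / period`).
#' @param n_bins Phase bins per lap.
#' @param direction `+1` or `-1` rotation sense.
#' @return A stimuli list for [simulate_lattice()].
#' @export
rotor_drive_stimuli <- function(lattice, period_ms = 400, t_start_ms = 50,
                                n_laps = 10L, n_bins = 12L, direction = 1) {
  if (is.null(lattice$block)) stop("lattice has no imposed block structure")
  margin <- setdiff(lattice$block$slow_cells, lattice$block$patch_cells)
  p <- lattice$centroids_um[margin, , drop = FALSE]
  ctr <- lattice$block$center_um
  phase <- (direction * atan2(p[, 1] - ctr[1], p[, 2] - ctr[2]) /
              (2 * pi)) %% 1
  bin <- pmin(n_bins, floor(phase * n_bins) + 1L)
  stimuli <- list()
  for (m in seq_len(n_laps) - 1L) {
    for (b in seq_len(n_bins)) {
      cells <- margin[bin == b]
      if (length(cells) == 0L) next
      stimuli[[length(stimuli) + 1L]] <- list(
        time_ms = t_start_ms + m * period_ms + (b - 0.5) / n_bins * period_ms,
        cells = cells)
    }
  }
  stimuli
}
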