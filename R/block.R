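# Conduction-block core detection.
#
# The delay score highlights pixels in close spatial proximity whose
# activation times differ by a large fraction of the cycle: activation-time
# differences are taken modulo the rotor period and folded, so pixels on
# opposite sides of a block line (half a cycle apart) score ~period/2
# regardless of which cycle either activation fell in, while a frame-period
# wrap line in a single-cycle map scores ~0. Scores are aggregated as the
# per-neighbour median across cycles, then the maximum over neighbours.

#' Conduction-delay score map
#'
#' @param maps List of `activation_map`s (one per cycle), e.g. from
#'   [activation_cycles()].
#' @param radius Neighbourhood radius, pixels (>= 1).
#' @param period_ms Cycle length, ms (from the dominant frequency).
#' @return A `block_heatmap`: list with `score` (H x W, ms; NA where a pixel
#'   has no active neighbour), `sharp` (same score restricted to 8-adjacent
#'   neighbour pairs, used for core delineation), `inactive` (pixels never
#'   active), `radius`, `period_ms`, `n_cycles`, `aggregation`.
#' @export
delay_score_map <- function(maps, radius = 3L, period_ms) {
  stopifnot(length(maps) >= 1L, radius >= 1L, period_ms > 0)
  dims <- dim(maps[[1]])
  for (m in maps) stopifnot(identical(dim(m), dims))
  if (all(vapply(maps, function(m) all(is.na(m)), TRUE))) {
    stop("no activity: all activation maps are empty")
  }
  score_for <- function(offs) {
    # pair symmetry: the median delay for offset -o is the median for o
    # shifted by -o, so only half the offsets need computing
    offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0), ,
                 drop = FALSE]
    best <- matrix(NA_real_, dims[1], dims[2])
    for (i in seq_len(nrow(offs))) {
      per_cycle <- lapply(maps, function(m) {
        sh <- shift_matrix(unclass(m), offs[i, 1], offs[i, 2])
        circular_delay(unclass(m), sh, period_ms)
      })
      med <- matrix(rowwise_median(per_cycle), dims[1], dims[2])
      best <- pmax(best, med, na.rm = TRUE)
      best <- pmax(best, shift_matrix(med, -offs[i, 1], -offs[i, 2]),
                   na.rm = TRUE)
    }
    best
  }
  score <- score_for(disc_offsets(radius))
  sharp <- score_for(disc_offsets(1.5))
  inactive <- Reduce(`&`, lapply(maps, is.na))
  structure(list(score = score, sharp = sharp, inactive = inactive,
                 ref_map = unclass(maps[[1]]),
                 radius = radius, period_ms = period_ms,
                 n_cycles = length(maps),
                 aggregation = "per-cycle median, max over neighbours"),
            class = "block_heatmap")
}

# elementwise NA-aware median over a list of equal-length numeric vectors,
# vectorized via a pmin/pmax sorting network (list lengths are small)
rowwise_median <- function(vecs) {
  C <- length(vecs)
  if (C == 1L) return(as.numeric(vecs[[1]]))
  vs <- lapply(vecs, function(v) {
    v <- as.numeric(v); v[is.na(v)] <- Inf; v
  })
  for (i in seq_len(C - 1L)) {
    for (j in seq_len(C - i)) {
      lo <- pmin(vs[[j]], vs[[j + 1L]])
      hi <- pmax(vs[[j]], vs[[j + 1L]])
      vs[[j]] <- lo; vs[[j + 1L]] <- hi
    }
  }
  S <- do.call(cbind, vs)
  k <- rowSums(is.finite(S))
  n <- nrow(S)
  out <- rep(NA_real_, n)
  has <- k > 0L
  lo_i <- pmax(1L, (k + 1L) %/% 2L)
  hi_i <- pmax(1L, (k + 2L) %/% 2L)
  out[has] <- (S[cbind(seq_len(n), lo_i)][has] +
               S[cbind(seq_len(n), hi_i)][has]) / 2
  out
}

#' Segment the conduction-block core from a delay heatmap
#'
#' Pixels whose 8-adjacent circular delay reaches `threshold` of the period
#' form the core seed (the immediate lining of the block interface); never-
#' active pixel groups adjacent to the thresholded delay band are added
#' (silent cells at the core are themselves conduction block); the result is
#' closed with a 1-pixel structuring element and filtered to connected
#' components of at least `min_px` pixels.
#'
#' @param heatmap A `block_heatmap` from [delay_score_map()].
#' @param threshold Fraction of the cycle length in `(0, 0.5]`.
#' @param keep `"largest"` (default) or `"all"` qualifying components, for
#'   fields that may contain more than one core.
#' @param min_px Minimum component size, pixels.
#' @return Logical H x W core mask. When nothing qualifies the mask is all
#'   `FALSE` with attribute `no_core_found = TRUE`.
#' @export
segment_core <- function(heatmap, threshold = 0.25,
                         keep = c("largest", "all"), min_px = 6L) {
  keep <- match.arg(keep)
  stopifnot(inherits(heatmap, "block_heatmap"),
            threshold > 0, threshold <= 0.5)
  thr <- threshold * heatmap$period_ms
  seed <- !is.na(heatmap$sharp) & heatmap$sharp >= thr
  # Never-active regions whose surroundings are out of phase are themselves
  # conduction block (the paper's core cells are inactive): include an
  # inactive component when the activation times of its active boundary
  # pixels span at least the block threshold in circular delay. Components
  # touching the image border (unobserved tissue) or dominating the field
  # are never included.
  inact <- heatmap$inactive
  h <- nrow(inact); w <- ncol(inact)
  if (any(inact)) {
    lab <- EBImage::bwlabel(EBImage::as.Image(inact + 0))
    lab <- EBImage::imageData(lab)
    for (l in setdiff(unique(as.integer(lab)), 0L)) {
      comp <- lab == l
      px <- which(comp, arr.ind = TRUE)
      touches_border <- any(px == 1L) || any(px[, 1] == h) || any(px[, 2] == w)
      if (touches_border || sum(comp) > 0.2 * h * w) next
      ring <- dilate_mask(comp, 1.5) & !comp
      bt <- heatmap$ref_map[ring]
      bt <- bt[!is.na(bt)]
      if (length(bt) > 200L) bt <- bt[seq(1L, length(bt), length.out = 200L)]
      if (length(bt) < 2L) next
      spread <- max(circular_delay(rep(bt, each = length(bt)), rep(bt, length(bt)),
                                   heatmap$period_ms))
      if (spread >= thr) seed <- seed | comp
    }
  }
  if (!any(seed)) {
    out <- matrix(FALSE, h, w)
    attr(out, "no_core_found") <- TRUE
    return(out)
  }
  closed <- EBImage::closing(EBImage::as.Image(seed + 0),
                             EBImage::makeBrush(3L, "box"))
  closed <- EBImage::imageData(closed) > 0
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::as.Image(closed + 0)))
  sizes <- table(as.integer(lab)[as.integer(lab) > 0L])
  ok <- as.integer(names(sizes))[sizes >= min_px]
  if (length(ok) == 0L) {
    out <- matrix(FALSE, h, w)
    attr(out, "no_core_found") <- TRUE
    return(out)
  }
  if (keep == "largest") {
    ok <- as.integer(names(sizes))[which.max(sizes)]
  }
  matrix(lab %in% ok, h, w)
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Iterative thinning to a 1-pixel-wide skeleton; used for core-morphology
#' classification.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize_mask <- function(mask) {
  img <- (unclass(mask) > 0) + 0L
  h <- nrow(img); w <- ncol(img)
  if (h < 3L || w < 3L) return(img > 0)
  nb <- function(m, dr, dc) {
    out <- matrix(0L, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- nb(img, -1, 0); p3 <- nb(img, -1, 1); p4 <- nb(img, 0, 1)
      p5 <- nb(img, 1, 1);  p6 <- nb(img, 1, 0);  p7 <- nb(img, 1, -1)
      p8 <- nb(img, 0, -1); p9 <- nb(img, -1, -1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seq9 <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0L, h, w)
      for (i in 1:8) a <- a + (seq9[[i]] == 0L & seq9[[i + 1L]] == 1L)
      if (pass == 1L) {
        cond <- p2 * p4 * p6 == 0L & p4 * p6 * p8 == 0L
      } else {
        cond <- p2 * p4 * p8 == 0L & p2 * p6 * p8 == 0L
      }
      del <- img == 1L & bsum >= 2L & bsum <= 6L & a == 1L & cond
      if (any(del)) {
        img[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img > 0
}

#' Classify core morphology
#'
#' Skeletonizes the core mask, counts skeleton endpoints and compares the
#' mask area with the area a thin line of the expected width (two cell
#' diameters) would occupy: `single_line` for a two-ended thin skeleton,
#' `multi_line` for three or more endpoints while thin, `lines_plus_area`
#' when the mask is substantially thicker than a line.
#'
#' @param mask Logical core mask.
#' @param pitch Micrometres per pixel.
#' @param cell_diameter_um Nominal cell diameter.
#' @param thickness_ratio Threshold on area / (skeleton length x expected
#'   width).
#' @return `"single_line"`, `"multi_line"`, `"lines_plus_area"`, or
#'   `"indeterminate"` for masks under 3 pixels.
#' @export
classify_core_morphology <- function(mask, pitch, cell_diameter_um = 25,
                                     thickness_ratio = 1.5) {
  area <- sum(mask)
  if (area < 3L) return("indeterminate")
  skel <- skeletonize_mask(mask)
  sk_len <- max(1L, sum(skel))
  ends <- skeleton_endpoints(skel)
  width_px <- 2 * cell_diameter_um / pitch
  rho <- area / (sk_len * width_px)
  if (rho > thickness_ratio) return("lines_plus_area")
  if (ends >= 3L) "multi_line" else "single_line"
}

skeleton_endpoints <- function(skel) {
  m <- (skel > 0) + 0L
  h <- nrow(m); w <- ncol(m)
  cnt <- matrix(0L, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    sh <- matrix(0L, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    sh[rs, cs] <- m[rs - dr, cs - dc]
    cnt <- cnt + sh
  }
  sum(m == 1L & cnt == 1L)
}

#' Core perimeter by convex-hull fitting
#'
#' Convex hull of the core-mask pixel centres; the perimeter is the hull
#' polygon length converted to millimetres. Degenerate (collinear) masks
#' return exactly twice the span — out and back along the line.
#'
#' @param mask Logical core mask with at least 2 pixels.
#' @param pitch Micrometres per pixel.
#' @return List with `perimeter_mm`, `hull` (n x 2 matrix of 0-based
#'   `(row, col)` vertices), `degenerate`. Single-pixel masks return
#'   `perimeter_mm = NA` with `indeterminate = TRUE`.
#' @export
core_perimeter <- function(mask, pitch) {
  pts <- which(unclass(mask) > 0, arr.ind = TRUE) - 1L
  if (nrow(pts) < 2L) {
    return(list(perimeter_mm = NA_real_, hull = pts, degenerate = TRUE,
                indeterminate = TRUE))
  }
  hull_idx <- chull(pts[, 2], pts[, 1])
  hull <- pts[hull_idx, , drop = FALSE]
  area2 <- 0
  n <- nrow(hull)
  if (n >= 3L) {
    xs <- hull[, 2]; ys <- hull[, 1]
    area2 <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys))
  }
  if (n < 3L || area2 == 0) {
    d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
    span <- sqrt(max(d2))
    return(list(perimeter_mm = 2 * span * pitch / 1000, hull = hull,
                degenerate = TRUE, indeterminate = FALSE))
  }
  per <- sum(sqrt(rowSums((hull - hull[c(2:n, 1), , drop = FALSE])^2)))
  list(perimeter_mm = per * pitch / 1000, hull = hull, degenerate = FALSE,
       indeterminate = FALSE)
}

#' Compare two block masks
#'
#' Dice coefficient of two core masks (e.g. voltage- vs calcium-derived).
#'
#' @param mask_a,mask_b Logical masks of equal dimension.
#' @return List with `dice` (NaN with `undefined` when both masks are
#'   empty), `area_a`, `area_b`.
#' @export
compare_block_maps <- function(mask_a, mask_b) {
  d <- mask_dice(mask_a, mask_b)
  list(dice = as.numeric(d),
       undefined = isTRUE(attr(d, "undefined")),
       area_a = sum(mask_a), area_b = sum(mask_b))
}

#' Full core-detection pipeline for one recording
#'
#' Dominant frequency, per-cycle activation maps, delay heatmap, core
#' segmentation, morphology and convex-hull perimetry in one call.
#'
#' @param movie A [reentry_movie()].
#' @param config A [reentry_config()].
#' @param keep Passed to [segment_core()].
#' @param max_cycles Cycle cap for the delay aggregation.
#' @return A `core_geometry` list: `mask`, `found`, `heatmap`, `hull`,
#'   `perimeter_mm`, `morphology`, `dominant_frequency_hz`, `period_ms`.
#' @export
detect_core <- function(movie, config = reentry_config(), keep = "largest",
                        max_cycles = 7L) {
  cyc <- activation_cycles(movie, config, max_cycles = max_cycles)
  hm <- delay_score_map(cyc$maps, radius = config$delay_radius,
                        period_ms = cyc$period_ms)
  mask <- segment_core(hm, threshold = config$block_threshold, keep = keep)
  found <- !isTRUE(attr(mask, "no_core_found"))
  per <- if (found) core_perimeter(mask, movie$pixel_pitch) else
    list(perimeter_mm = NA_real_, hull = NULL, degenerate = NA)
  morph <- if (found) {
    classify_core_morphology(mask, movie$pixel_pitch, config$cell_diameter_um)
  } else NA_character_
  structure(list(mask = mask, found = found, heatmap = hm, hull = per$hull,
                 perimeter_mm = per$perimeter_mm, morphology = morph,
                 dominant_frequency_hz = cyc$frequency_hz,
                 period_ms = cyc$period_ms),
            class = "core_geometry")
}
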