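# Small shared numerics: circular time differences, mask metrics, smoothing.

#' Circular activation-time difference
#'
#' Absolute difference of two activation times taken modulo the cycle length,
#' folded onto `[0, period/2]`: two pixels activating half a cycle apart are
#' maximally discordant no matter which cycle index either event fell in.
#'
#' @param a,b Activation times, ms (vectors recycle).
#' @param period Cycle length, ms.
#' @return Circular differences in `[0, period/2]`, ms.
#' @export
circular_delay <- function(a, b, period) {
  stopifnot(period > 0)
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

#' Intersection-over-union of two logical masks
#' @param a,b Logical matrices of equal dimension.
#' @return IoU in `[0, 1]`; `NaN` when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0) return(NaN)
  sum(a & b) / u
}

#' Symmetric Hausdorff distance between two masks, pixels
#'
#' Maximum over both directions of the distance from a pixel of one mask to
#' the nearest pixel of the other. Infinite when exactly one mask is empty.
#' @param a,b Logical matrices of equal dimension.
#' @export
mask_hausdorff <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  pa <- which(a, arr.ind = TRUE)
  pb <- which(b, arr.ind = TRUE)
  if (nrow(pa) == 0 && nrow(pb) == 0) return(0)
  if (nrow(pa) == 0 || nrow(pb) == 0) return(Inf)
  one_sided <- function(p, q) {
    # max over p of min distance to q; chunked to bound memory
    mx <- 0
    step <- 2048L
    for (i0 in seq(1L, nrow(p), by = step)) {
      idx <- i0:min(i0 + step - 1L, nrow(p))
      d2 <- outer(p[idx, 1], q[, 1], "-")^2 + outer(p[idx, 2], q[, 2], "-")^2
      mx <- max(mx, sqrt(max(apply(d2, 1, min))))
    }
    mx
  }
  max(one_sided(pa, pb), one_sided(pb, pa))
}

#' Dice coefficient of two logical masks
#' @param a,b Logical matrices of equal dimension.
#' @return `2|A&B| / (|A|+|B|)`; `NaN` with an attribute `undefined = TRUE`
#'   when both masks are empty.
#' @export
mask_dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  s <- sum(a) + sum(b)
  if (s == 0) {
    out <- NaN
    attr(out, "undefined") <- TRUE
    return(out)
  }
  2 * sum(a & b) / s
}

# centred moving average, ends padded by replication; w <= 1 is identity
moving_average <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  n <- length(x)
  half <- w %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[n], w - half - 1L))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 1)[(w - 1L + 1L):(w - 1L + n)])
}

# centred moving average along the rows (time axis) of a frames x pixels
# matrix, edges replicated; direct shifted sums (no ts dispatch overhead)
smooth_rows <- function(m, w) {
  w <- as.integer(w)
  if (w <= 1L) return(m)
  n <- nrow(m)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w - 1L - half_lo
  acc <- matrix(0, n, ncol(m))
  for (off in (-half_lo):half_hi) {
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    acc <- acc + m[idx, , drop = FALSE]
  }
  acc / w
}

# centred finite-difference slope per frame (units of x per frame)
centered_diff <- function(x) {
  n <- length(x)
  if (n < 3L) return(rep(0, n))
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1L]
  d
}

# circular absolute difference of angles in degrees, result in [0, 180]
angle_diff_deg <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# shift a matrix by (dr, dc), vacated entries NA
shift_matrix <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(NA_real_, h, w)
  if (abs(dr) >= h || abs(dc) >= w) return(out)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# offsets (dr, dc) with 0 < norm <= radius
disc_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= radius^2 & !(g$dr == 0 & g$dc == 0), ]
  as.matrix(g)
}

# derive a bounded child seed from a base seed and a stream index
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483563) + 1L
}
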