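# Fluorescence rendering: each activation event contributes a stereotyped
# transient kernel; traces are the kernel train plus baseline, slow
# photobleaching and additive Gaussian noise, quantized to 16 bits.

#' Fluorescence transient kernel
#'
#' Unit-peak transient: smooth (sine-squared) rise over `rise_ms` followed by
#' exponential decay with time constant `decay_ms`. Calcium transients are
#' slow (20 ms rise, 150 ms decay); action-potential (voltage) upstrokes are
#' fast (5 ms rise, 50 ms decay).
#'
#' @param channel `"calcium"` or `"voltage"`.
#' @param rise_ms,decay_ms Override the channel defaults.
#' @return A function of time since the event (ms), vectorized, zero before
#'   the event; attributes `rise_ms` and `decay_ms`.
#' @export
transient_kernel <- function(channel = c("calcium", "voltage"),
                             rise_ms = NULL, decay_ms = NULL) {
  channel <- match.arg(channel)
  if (is.null(rise_ms)) rise_ms <- if (channel == "calcium") 20 else 5
  if (is.null(decay_ms)) decay_ms <- if (channel == "calcium") 150 else 50
  force(rise_ms); force(decay_ms)
  f <- function(t_ms) {
    out <- numeric(length(t_ms))
    up <- t_ms >= 0 & t_ms < rise_ms
    dn <- t_ms >= rise_ms
    out[up] <- sin(pi * t_ms[up] / (2 * rise_ms))^2
    out[dn] <- exp(-(t_ms[dn] - rise_ms) / decay_ms)
    out
  }
  attr(f, "rise_ms") <- rise_ms
  attr(f, "decay_ms") <- decay_ms
  f
}

# kernel wrapped around a period: steady-state response of a pixel firing
# periodically, tabulated on a 1 ms grid for fast lookup
periodic_kernel_table <- function(kernel, period_ms) {
  grid <- seq(0, ceiling(period_ms) + 1, by = 1)
  n_back <- ceiling(5 * attr(kernel, "decay_ms") / period_ms) + 1L
  val <- numeric(length(grid))
  for (k in 0:n_back) val <- val + kernel(grid + k * period_ms)
  list(grid = grid, values = val, period = period_ms)
}

lookup_periodic <- function(tab, s) {
  # s in [0, period); nearest 1 ms bin
  tab$values[pmin(length(tab$values), round(s) + 1L)]
}

finish_movie <- function(signal_mat, h, w, frame_rate, pixel_pitch, channel,
                         noise_sd, bleach_tau_s, baseline = 0.08, amplitude = 0.8) {
  # signal_mat: pixels x frames in [0, 1] kernel units
  nf <- ncol(signal_mat)
  x <- baseline + amplitude * signal_mat
  if (is.finite(bleach_tau_s) && bleach_tau_s > 0) {
    t_s <- (seq_len(nf) - 1L) / frame_rate
    x <- x * rep(exp(-t_s / bleach_tau_s), each = nrow(x))
  }
  if (noise_sd > 0) {
    x <- x + rnorm(length(x), sd = noise_sd * amplitude)
  }
  x <- pmin(pmax(x, 0), 1)
  x <- round(x * 65535) / 65535
  arr <- array(x, c(h, w, nf))
  reentry_movie(arr, frame_rate, pixel_pitch, channel)
}

#' Render a fluorescence movie from per-cell event times
#'
#' Every event of cell `k` adds one transient kernel to the traces of all
#' pixels labelled `k`. The calcium channel is shifted late by `ca_lag_frames`
#' relative to the underlying (electrical) event times; the voltage channel
#' is rendered at the event times themselves.
#'
#' @param events List of numeric vectors: event times (ms) per cell id.
#' @param labels Integer label matrix (0 = background) mapping pixels to
#'   cells, e.g. the raster of [generate_cell_lattice()].
#' @param duration_s Movie length, s.
#' @param frame_rate Frames per second.
#' @param pixel_pitch Micrometres per pixel.
#' @param channel `"calcium"` or `"voltage"`.
#' @param noise_sd Additive Gaussian noise, as a fraction of the transient
#'   amplitude; `>= 0`.
#' @param bleach_tau_s Photobleaching time constant, s (`Inf` disables).
#' @param ca_lag_frames Voltage-to-calcium upstroke delay, frames; must be
#'   `>= 0` (voltage leads by convention).
#' @param kernel Optional kernel override from [transient_kernel()].
#' @param seed Random seed for the noise.
#' @return A [reentry_movie()].
#' @export
render_fluorescence <- function(events, labels, duration_s, frame_rate = 100,
                                pixel_pitch = 10,
                                channel = c("calcium", "voltage"),
                                noise_sd = 0.05, bleach_tau_s = Inf,
                                ca_lag_frames = 3L, kernel = NULL,
                                seed = 1L) {
  channel <- match.arg(channel)
  if (ca_lag_frames < 0) stop("ca_lag_frames must be >= 0 (voltage leads calcium)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!(bleach_tau_s > 0)) stop("bleach_tau_s must be positive (Inf disables)")
  lab <- unclass(labels)
  h <- nrow(lab); w <- ncol(lab)
  nf <- as.integer(round(duration_s * frame_rate))
  dt_ms <- 1000 / frame_rate
  if (is.null(kernel)) kernel <- transient_kernel(channel)
  lag_ms <- if (channel == "calcium") ca_lag_frames * dt_ms else 0
  klen <- as.integer(ceiling((attr(kernel, "rise_ms") +
                              5 * attr(kernel, "decay_ms")) / dt_ms)) + 1L
  kvals <- kernel((0:(klen - 1L)) * dt_ms)
  n_cells <- max(lab)
  traces <- matrix(0, nf, n_cells + 1L)   # column 1 = background (flat)
  for (cell in seq_len(n_cells)) {
    ev <- events[[cell]]
    if (is.null(ev) || length(ev) == 0L) next
    f0 <- floor((ev + lag_ms) / dt_ms) + 1L
    frac <- (ev + lag_ms) / dt_ms - (f0 - 1L)
    tr <- numeric(nf)
    for (j in seq_along(f0)) {
      if (f0[j] > nf) next
      idx <- max(1L, f0[j]):min(nf, f0[j] + klen - 1L)
      tr[idx] <- tr[idx] + kernel((idx - 1L) * dt_ms - ev[j] - lag_ms)
    }
    traces[, cell + 1L] <- tr
  }
  set.seed(seed)
  # pixel order is column-major over (row, col), matching frame_matrix()
  sig <- t(traces[, as.integer(lab) + 1L, drop = FALSE])
  finish_movie(sig, h, w, frame_rate, pixel_pitch, channel, noise_sd,
               bleach_tau_s)
}
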