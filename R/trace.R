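#' Extract a fluorescence trace from a movie
#'
#' Per-frame mean over an ROI, given either as a pixel set or a cell label.
#' Traces keep the movie's frame rate and a movie-wide amplitude reference
#' (robust dynamic range) used later to recognise silent ROIs.
#'
#' @param movie A [reentry_movie()].
#' @param roi Either a two-column matrix of 0-based `(row, col)` pixel
#'   coordinates, or a single cell id to be looked up in `labels`.
#' @param labels Optional `label_image` when `roi` is a cell id.
#' @return An object of class `reentry_trace`: numeric samples with
#'   attributes `frame_rate`, `movie_range`, `normalized`, `silent`.
#' @export
extract_trace <- function(movie, roi, labels = NULL) {
  stopifnot(inherits(movie, "reentry_movie"))
  d <- dim(movie$data)
  if (length(roi) == 1L && is.null(dim(roi))) {
    if (is.null(labels)) stop("a cell-id roi requires a label image")
    px <- which(unclass(labels) == as.integer(roi), arr.ind = TRUE) - 1L
    if (nrow(px) == 0L) stop("cell id ", roi, " not present in label image")
    roi <- px
  }
  roi <- matrix(as.integer(roi), ncol = 2L)
  if (nrow(roi) == 0L) stop("empty roi")
  if (any(roi < 0L) || any(roi[, 1] >= d[1]) || any(roi[, 2] >= d[2])) {
    stop("roi extends outside the frame")
  }
  idx <- roi[, 2] * d[1] + roi[, 1] + 1L   # column-major pixel index (0-based coords)
  m <- matrix(movie$data, d[1] * d[2], d[3])
  samples <- colMeans(m[idx, , drop = FALSE])
  new_trace(samples, movie$frame_rate, movie_range = movie_amplitude(movie))
}

new_trace <- function(samples, frame_rate, movie_range = NA_real_,
                      normalized = FALSE, silent = FALSE) {
  stopifnot(length(samples) >= 2L, frame_rate > 0)
  structure(as.numeric(samples),
            frame_rate = frame_rate, movie_range = movie_range,
            normalized = normalized, silent = silent,
            class = "reentry_trace")
}

#' @export
print.reentry_trace <- function(x, ...) {
  cat(sprintf("<reentry_trace> %d samples @ %g fps%s%s\n", length(x),
              attr(x, "frame_rate"),
              if (isTRUE(attr(x, "normalized"))) ", normalized" else "",
              if (isTRUE(attr(x, "silent"))) ", silent" else ""))
  invisible(x)
}

#' Detrend and normalize a trace
#'
#' Optional slow-baseline removal (robust second-order polynomial fit to the
#' running 10th-percentile floor, correcting photobleaching), then min-max
#' scaling to `[0, 1]`. Constant traces come back as zeros with the silent
#' flag set rather than raising.
#'
#' @param trace A `reentry_trace`.
#' @param bleach_correction Remove a slow multiplicative baseline first.
#' @return A normalized `reentry_trace`.
#' @export
detrend_normalize <- function(trace, bleach_correction = FALSE) {
  stopifnot(inherits(trace, "reentry_trace"))
  x <- as.numeric(trace)
  fr <- attr(trace, "frame_rate")
  raw_range <- diff(range(x))
  if (raw_range == 0) {
    out <- new_trace(rep(0, length(x)), fr, attr(trace, "movie_range"),
                     normalized = TRUE, silent = TRUE)
    attr(out, "raw_range") <- 0
    return(out)
  }
  if (bleach_correction) {
    # running-percentile floor on ~1 s windows, interpolated and divided
    # out: under multiplicative bleaching the inter-event floor tracks the
    # bleach curve, so division restores event-peak heights
    w <- max(5L, as.integer(round(fr)))
    n <- length(x)
    starts <- seq(1L, max(1L, n - w + 1L), by = max(1L, w %/% 2L))
    cent <- pmin(starts + w %/% 2L, n)
    floors <- vapply(starts, function(s) {
      quantile(x[s:min(s + w - 1L, n)], 0.1, names = FALSE)
    }, 0)
    floors <- moving_average(floors, 3L)
    base <- approx(cent, floors, xout = seq_len(n), rule = 2)$y
    base <- pmax(base, 1e-8 * max(abs(base), 1))
    x <- x / base
  }
  rng <- range(x)
  x <- if (diff(rng) > 0) (x - rng[1]) / diff(rng) else rep(0, length(x))
  out <- new_trace(x, fr, attr(trace, "movie_range"),
                   normalized = TRUE, silent = FALSE)
  attr(out, "raw_range") <- raw_range
  out
}

#' Detect activation events in a trace
#'
#' An activation is the point of steepest upstroke of the fluorescence
#' signal: a local maximum of the lightly smoothed derivative, subject to a
#' prominence threshold (fraction of the dynamic range) and a minimum
#' refractory spacing. Ties within a constant-slope run break to the earliest
#' frame. Traces flagged silent, or whose dynamic range is a small fraction
#' of the movie-wide range, yield an empty train.
#'
#' @param trace A `reentry_trace`.
#' @param config A [reentry_config()].
#' @return An object of class `event_train`: numeric activation times (ms,
#'   strictly increasing) with attribute `slopes` (a.u./ms) and `silent`.
#' @export
detect_activations <- function(trace, config = reentry_config()) {
  stopifnot(inherits(trace, "reentry_trace"))
  fr <- attr(trace, "frame_rate")
  dt_ms <- 1000 / fr
  x <- as.numeric(trace)
  n <- length(x)
  empty <- function(silent) {
    structure(numeric(0), slopes = numeric(0), silent = silent,
              class = "event_train")
  }
  if (isTRUE(attr(trace, "silent"))) return(empty(TRUE))
  rng <- diff(range(x))
  if (rng == 0) return(empty(TRUE))
  mrange <- attr(trace, "movie_range")
  raw_range <- attr(trace, "raw_range")
  if (is.null(raw_range)) raw_range <- rng
  if (is.finite(mrange) && !is.na(mrange) && mrange > 0 &&
      raw_range < config$silent_range_frac * mrange) {
    return(empty(TRUE))
  }
  xs <- moving_average(x, config$smooth_window)
  d <- centered_diff(xs)
  # candidate steepest-upstroke frames: strict rise from the left, ties to the
  # earliest frame of the run (d[i] > d[i-1] and d[i] >= d[i+1])
  cand <- which(d > 0)
  cand <- cand[cand > 1L & cand < n]
  # slope ties are compared with a relative tolerance so constant-slope runs
  # are not split by floating-point noise
  tol <- 1e-9 * max(abs(d))
  cand <- cand[d[cand] > d[cand - 1L] + tol & d[cand] >= d[cand + 1L] - tol]
  monotone_run <- FALSE
  if (length(cand) == 0L && any(d > 0)) {
    # monotone ramp: the whole trace is one upstroke; the event sits at the
    # earliest frame of the steepest constant-slope run
    cand <- min(which(d >= max(d) - tol))
    monotone_run <- TRUE
  }
  if (length(cand) == 0L) return(empty(FALSE))
  # prominence: the local rise around the candidate must clear a fraction of
  # the trace's own dynamic range (a monotone ramp's rise is its full range)
  half <- max(2L, as.integer(round(config$refractory_ms / dt_ms / 2)))
  rise <- if (monotone_run) diff(range(xs)) else vapply(cand, function(i) {
    lo <- min(xs[max(1L, i - half):i])
    hi <- max(xs[i:min(n, i + half)])
    hi - lo
  }, 0)
  keep <- rise >= config$prominence * diff(range(xs))
  cand <- cand[keep]
  if (length(cand) == 0L) return(empty(FALSE))
  # refractory suppression, strongest upstrokes first
  ord <- cand[order(d[cand], decreasing = TRUE)]
  min_gap <- config$refractory_ms / dt_ms
  accepted <- integer(0)
  for (i in ord) {
    if (all(abs(i - accepted) >= min_gap)) accepted <- c(accepted, i)
  }
  accepted <- sort(accepted)
  structure((accepted - 1L) * dt_ms,
            slopes = d[accepted] / dt_ms, silent = FALSE,
            class = "event_train")
}

#' Dominant frequency of a trace
#'
#' Frequency of the largest peak of the zero-padded periodogram of the
#' mean-subtracted trace within a search band. The spectral resolution,
#' `1/duration` Hz, is reported alongside.
#'
#' @param trace A `reentry_trace`.
#' @param band Length-2 search band, Hz.
#' @param pad_factor Zero-padding factor refining the peak-location grid.
#' @return A list with `frequency` (Hz; `NA` with `undefined = TRUE` for a
#'   silent trace) and `resolution` (Hz).
#' @export
dominant_frequency <- function(trace, band = c(0.5, 10), pad_factor = 8L) {
  stopifnot(inherits(trace, "reentry_trace"), length(band) == 2L, band[1] > 0)
  fr <- attr(trace, "frame_rate")
  n <- length(trace)
  duration <- n / fr
  if (duration < 2 / band[1]) {
    stop("trace too short for the requested band: need at least ",
         2 / band[1], " s")
  }
  res <- 1 / duration
  x <- as.numeric(trace) - mean(trace)
  if (isTRUE(attr(trace, "silent")) || all(x == 0)) {
    return(list(frequency = NA_real_, resolution = res, undefined = TRUE))
  }
  nfft <- n * as.integer(pad_factor)
  spec <- Mod(fft(c(x, rep(0, nfft - n))))[seq_len(nfft %/% 2L)]
  freqs <- (seq_len(nfft %/% 2L) - 1L) * fr / nfft
  in_band <- freqs >= band[1] & freqs <= band[2]
  if (!any(in_band)) stop("band contains no spectral bins")
  k <- which(in_band)[which.max(spec[in_band])]
  list(frequency = freqs[k], resolution = res, undefined = FALSE)
}

#' Estimate the voltage-to-calcium frame lag
#'
#' Lag maximizing the discrete cross-correlation of the two smoothed
#' derivative signals, searched over a bounded window. Positive lags mean the
#' calcium channel trails the voltage channel.
#'
#' @param trace_voltage,trace_calcium `reentry_trace`s of equal length and
#'   frame rate.
#' @param max_lag Largest absolute lag searched, frames.
#' @param config A [reentry_config()]; both traces must carry at least 3
#'   detected events for the lag to be defined.
#' @return A list with `lag` (frames; `NA` with `undefined = TRUE` when a
#'   channel is silent or underpopulated) and `correlation`.
#' @export
estimate_channel_lag <- function(trace_voltage, trace_calcium, max_lag = 20L,
                                 config = reentry_config()) {
  stopifnot(inherits(trace_voltage, "reentry_trace"),
            inherits(trace_calcium, "reentry_trace"),
            length(trace_voltage) == length(trace_calcium))
  if (!isTRUE(all.equal(attr(trace_voltage, "frame_rate"),
                        attr(trace_calcium, "frame_rate")))) {
    stop("traces must share a frame rate")
  }
  ev_v <- detect_activations(trace_voltage, config)
  ev_c <- detect_activations(trace_calcium, config)
  if (length(ev_v) < 3L || length(ev_c) < 3L) {
    return(list(lag = NA_integer_, correlation = NA_real_, undefined = TRUE))
  }
  dv <- centered_diff(moving_average(as.numeric(trace_voltage), config$smooth_window))
  dc <- centered_diff(moving_average(as.numeric(trace_calcium), config$smooth_window))
  n <- length(dv)
  lags <- -as.integer(max_lag):as.integer(max_lag)
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      a <- dv[seq_len(n - l)]; b <- dc[seq_len(n - l) + l]
    } else {
      a <- dv[seq_len(n + l) - l]; b <- dc[seq_len(n + l)]
    }
    if (sd(a) == 0 || sd(b) == 0) return(-Inf)
    cor(a, b)
  }, 0)
  k <- which.max(cc)
  list(lag = lags[k], correlation = cc[k], undefined = FALSE)
}

#' Export an event train as a one-column data frame
#' @param events An `event_train`.
#' @export
as.data.frame.event_train <- function(x, ...) {
  data.frame(event_ms = as.numeric(x), slope_au_per_ms = attr(x, "slopes"))
}
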