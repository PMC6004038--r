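#' Fluorescence movie container
#'
#' A movie is a `height x width x frames` numeric array with frame-rate (Hz),
#' pixel-pitch (um/pixel) and channel metadata attached. Values are arbitrary
#' fluorescence units; [write_movie()] quantizes to 16 bits.
#'
#' @param data Numeric `H x W x T` array (a matrix is treated as one frame).
#' @param frame_rate Frames per second, positive.
#' @param pixel_pitch Micrometres per pixel, positive.
#' @param channel `"calcium"` or `"voltage"`.
#' @return An object of class `reentry_movie`.
#' @export
reentry_movie <- function(data, frame_rate, pixel_pitch,
                          channel = c("calcium", "voltage")) {
  channel <- match.arg(channel)
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (dim(data)[3] == 0L) stop("movie has zero frames")
  if (!is.numeric(frame_rate) || frame_rate <= 0) stop("frame_rate must be positive")
  if (!is.numeric(pixel_pitch) || pixel_pitch <= 0) stop("pixel_pitch must be positive")
  m <- structure(
    list(data = data, frame_rate = frame_rate, pixel_pitch = pixel_pitch,
         channel = channel, amplitude = NA_real_),
    class = "reentry_movie"
  )
  m$amplitude <- .robust_amplitude(data)
  m
}

#' @export
print.reentry_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<reentry_movie> %d x %d px, %d frames @ %g fps (%.2f s), %g um/px, %s channel\n",
    d[1], d[2], d[3], x$frame_rate, movie_duration(x), x$pixel_pitch, x$channel))
  invisible(x)
}

#' Movie duration in seconds (frames / frame rate)
#' @param movie A `reentry_movie`.
#' @export
movie_duration <- function(movie) {
  dim(movie$data)[3] / movie$frame_rate
}

#' Number of frames of a movie
#' @param movie A `reentry_movie`.
#' @export
n_frames <- function(movie) dim(movie$data)[3]

# frames x pixels matrix view (pixels in column-major (row, col) order)
frame_matrix <- function(movie) {
  d <- dim(movie$data)
  t(matrix(movie$data, d[1] * d[2], d[3]))
}

# robust movie-wide dynamic range, used as the amplitude reference for
# silent-trace gating and prominence checks; cached at construction,
# estimated on a deterministic subsample for large stacks
movie_amplitude <- function(movie) {
  if (is.finite(movie$amplitude)) return(movie$amplitude)
  .robust_amplitude(movie$data)
}

.robust_amplitude <- function(data) {
  n <- length(data)
  x <- if (n > 2^20) data[seq(1L, n, by = max(1L, n %/% 2^20))] else data
  qs <- quantile(x, c(0.005, 0.995), names = FALSE)
  diff(qs)
}

#' Read a multi-page TIFF stack as a movie
#'
#' Metadata are supplied by the caller: TIFF tags are unreliable across
#' dialects, so frame rate and pixel pitch travel in the config or call.
#'
#' @param path Path to a multi-page grayscale TIFF.
#' @param frame_rate Frames per second.
#' @param pixel_pitch Micrometres per pixel.
#' @param channel `"calcium"` or `"voltage"`.
#' @return A `reentry_movie`. Pixel values are exactly those stored (the
#'   16-bit code divided by 65535).
#' @export
read_movie <- function(path, frame_rate, pixel_pitch,
                       channel = c("calcium", "voltage")) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("movie file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("movie file contains zero frames: ", path)
  dims <- lapply(pages, dim)
  if (any(vapply(dims, length, 1L) != 2L)) {
    stop("movie pages must be single-channel grayscale")
  }
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("non-uniform page shapes in ", path)
  }
  arr <- array(unlist(pages, use.names = FALSE), c(dims[[1]], length(pages)))
  reentry_movie(arr, frame_rate, pixel_pitch, channel)
}

#' Write a movie as a 16-bit multi-page TIFF
#'
#' Values are min-max scaled to the stored 16-bit range unless the movie is
#' already in `[0, 1]`, in which case codes are preserved bit-exactly.
#'
#' @param movie A `reentry_movie`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "reentry_movie"))
  x <- movie$data
  rng <- range(x)
  if (rng[1] < 0 || rng[2] > 1) {
    span <- if (diff(rng) > 0) diff(rng) else 1
    x <- (x - rng[1]) / span
  }
  x <- round(x * 65535) / 65535
  pages <- lapply(seq_len(dim(x)[3]), function(f) x[, , f])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an integer-valued cell-segmentation label mask
#'
#' 0 is background; positive integers are cell ids. Labels are relabelled to
#' a contiguous `1..n` range (order preserved); background is kept.
#'
#' @param path Path to a TIFF or PNG label image (16-bit codes).
#' @return An integer matrix of class `label_image` with attribute
#'   `n_cells`.
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) stop("label mask not found: ", path)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  lab <- round(img * 65535)
  if (any(lab < 0)) stop("negative labels in ", path)
  as_label_image(matrix(as.integer(lab), nrow(lab), ncol(lab)))
}

as_label_image <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  relab <- lab
  if (length(ids) > 0L && !identical(ids, seq_along(ids))) {
    lut <- integer(max(ids))
    lut[ids] <- seq_along(ids)
    relab[lab > 0L] <- lut[lab[lab > 0L]]
  }
  structure(relab, class = c("label_image", "matrix", "array"),
            n_cells = length(ids))
}

#' Write a label image as a 16-bit TIFF
#' @param labels Integer matrix (0 background).
#' @param path Output path.
#' @export
write_label_mask <- function(labels, path) {
  lab <- unclass(labels)
  if (any(lab < 0)) stop("negative labels")
  if (max(lab) > 65535) stop("more than 65535 labels cannot be stored at 16 bits")
  tiff::writeTIFF(matrix(lab / 65535, nrow(lab), ncol(lab)), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Write/read a results table as CSV
#'
#' Plain CSV with a header row; the reader restores an equal data frame.
#'
#' @param records A data frame (possibly with zero rows).
#' @param path Output path.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  ok <- tryCatch({
    write.csv(records, path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write results table to ", path)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("results table not found: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}
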