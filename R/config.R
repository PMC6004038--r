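#' Analysis configuration
#'
#' Validated container for every tunable constant of the analysis pipeline.
#' Defaults are chosen for 100 fps recordings of monolayers with rotor
#' periods of roughly 300-700 ms (dominant frequencies ~1.4-3.3 Hz) and are
#' reported alongside results for provenance.
#'
#' @param smooth_window Upstroke-smoothing window for the derivative, frames.
#'   A light 3-frame moving average: traces are displayed unfiltered, but
#'   derivative-based steepest-upstroke detection on raw noise is unusable.
#' @param prominence Activation prominence threshold as a fraction of the
#'   trace (or movie) dynamic range.
#' @param refractory_ms Minimum spacing between detected events, ms. The
#'   default 100 ms sits well below the fastest rotor period of interest
#'   (~300 ms) so 3.3 Hz activity is never suppressed, while double counts on
#'   noisy upstrokes are.
#' @param silent_range_frac A trace whose dynamic range is below this fraction
#'   of the movie-wide dynamic range is flagged silent (no events reported).
#' @param delay_radius Neighbourhood radius for the conduction-delay score,
#'   pixels (about one cell diameter at the default fixture scale).
#' @param block_threshold Core threshold as a fraction of the cycle length;
#'   neighbouring pixels whose circular activation-time difference exceeds
#'   this fraction of the period are treated as separated by block.
#' @param hull_quantile Binarization quantile used when a heatmap must be
#'   thresholded without a period estimate (fallback only), in (0, 1).
#' @param regularity_cv Maximum coefficient of variation of wavefront
#'   intervals for a run to count as "very regular".
#' @param direction_tol_deg Maximum pairwise direction difference (degrees)
#'   within a regular run of wavefronts.
#' @param min_reentry_wavefronts Minimum number of consecutive regular
#'   wavefronts for a re-entry call; "over four" reads as at least 5.
#' @param match_tolerance_um Site-matching tolerance for pre/post location
#'   comparisons, micrometres (a few cell diameters).
#' @param cell_diameter_um Nominal cell diameter, used for the expected block
#'   line width in morphology classification.
#' @param df_band_hz Length-2 numeric, dominant-frequency search band in Hz.
#' @param wavefront_block_px Coarse-grid block size (pixels) used when pooling
#'   activation events for wavefront segmentation.
#' @param seed Default random seed recorded in output tables.
#'
#' @return An object of class `reentry_config` (a validated named list).
#' @export
reentry_config <- function(smooth_window = 3L,
                           prominence = 0.2,
                           refractory_ms = 100,
                           silent_range_frac = 0.3,
                           delay_radius = 3L,
                           block_threshold = 0.25,
                           hull_quantile = 0.95,
                           regularity_cv = 0.15,
                           direction_tol_deg = 30,
                           min_reentry_wavefronts = 5L,
                           match_tolerance_um = 100,
                           cell_diameter_um = 25,
                           df_band_hz = c(0.5, 10),
                           wavefront_block_px = 8L,
                           seed = 1L) {
  cfg <- list(
    smooth_window = as.integer(smooth_window),
    prominence = prominence,
    refractory_ms = refractory_ms,
    silent_range_frac = silent_range_frac,
    delay_radius = as.integer(delay_radius),
    block_threshold = block_threshold,
    hull_quantile = hull_quantile,
    regularity_cv = regularity_cv,
    direction_tol_deg = direction_tol_deg,
    min_reentry_wavefronts = as.integer(min_reentry_wavefronts),
    match_tolerance_um = match_tolerance_um,
    cell_diameter_um = cell_diameter_um,
    df_band_hz = df_band_hz,
    wavefront_block_px = as.integer(wavefront_block_px),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  class(cfg) <- "reentry_config"
  cfg
}

validate_config <- function(cfg) {
  pos <- c("smooth_window", "prominence", "refractory_ms", "silent_range_frac",
           "delay_radius", "block_threshold", "regularity_cv",
           "direction_tol_deg", "min_reentry_wavefronts", "match_tolerance_um",
           "cell_diameter_um", "wavefront_block_px")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || !is.finite(cfg[[f]]) ||
        cfg[[f]] <= 0) {
      stop("config field '", f, "' must be a single positive number")
    }
  }
  if (cfg$hull_quantile <= 0 || cfg$hull_quantile >= 1) {
    stop("hull_quantile must lie strictly in (0, 1)")
  }
  if (cfg$block_threshold > 0.5) {
    stop("block_threshold is a fraction of the cycle length and cannot exceed 0.5")
  }
  if (cfg$min_reentry_wavefronts < 5L) {
    stop("min_reentry_wavefronts must be at least 5 ('over four' consecutive wavefronts)")
  }
  if (length(cfg$df_band_hz) != 2L || cfg$df_band_hz[1] <= 0 ||
      diff(cfg$df_band_hz) <= 0) {
    stop("df_band_hz must be an increasing positive range")
  }
  invisible(cfg)
}

#' Read or write an analysis configuration as YAML
#'
#' @param path File path.
#' @return `read_config()` returns a `reentry_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(reentry_config, vals)
}

#' @rdname read_config
#' @param config A `reentry_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "reentry_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.reentry_config <- function(x, ...) {
  cat("<reentry_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
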