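# End-to-end synthetic experiments mirroring the study design: colony-size
# dependence of triggers/wavefronts/re-entry, and spatial stability of
# activity sources across a stop-and-restart perturbation.

#' Colony-size experiment on synthetic monolayers
#'
#' For each colony-area class, simulates monolayer recordings (triggers
#' firing at low irregular rates; a driven rotor around an imposed block
#' structure in the recordings designated re-entrant), renders them to
#' fluorescence movies, and analyses each with the full wavefront pipeline:
#' wavefront counting, re-entry classification, and trigger-site counts
#' (excluded, per the study design, for recordings classified re-entrant).
#' The Fisher/Bonferroni contingency chain and Mann-Whitney/Dunn group
#' comparisons are run on the resulting tables.
#'
#' @param area_classes_mm2 Colony areas, mm^2.
#' @param n_per_class Recordings per class.
#' @param reentry_prob Probability that a recording contains re-entry, per
#'   class (defaults follow the observed per-class rates of the study
#'   design: 1/25, 7/22, 6/16 from smallest to largest).
#' @param trigger_density_per_mm2 Trigger cells per mm^2 (fixed across
#'   classes; the expected count scales with area).
#' @param duration_s Recording length, s.
#' @param mean_cell_diameter_um Cell diameter for the lattices.
#' @param render_downsample Label-raster downsampling factor for rendering.
#' @param noise_sd Rendering noise.
#' @param config Analysis configuration.
#' @param seed Base seed; each recording derives its own.
#' @return List with `records` (one row per recording: `area_mm2`,
#'   `n_wavefronts`, `n_trigger_sites` (NA under re-entry), `reentry`,
#'   `reentry_truth`, `seed`), `contingency` (pairwise Fisher table),
#'   `mw_wavefronts`, `mw_triggers` (Mann-Whitney/Dunn tables, NULL when a
#'   class has fewer than 2 usable recordings).
#' @export
run_colony_size_experiment <- function(area_classes_mm2 = c(3.5, 6.4, 9.8),
                                       n_per_class = 5L,
                                       reentry_prob = c(1 / 25, 7 / 22, 6 / 16),
                                       trigger_density_per_mm2 = 0.9,
                                       duration_s = 10,
                                       mean_cell_diameter_um = 25,
                                       render_downsample = 3L,
                                       noise_sd = 0.05,
                                       config = reentry_config(),
                                       seed = 1L) {
  stopifnot(length(reentry_prob) == length(area_classes_mm2))
  records <- list()
  rec_id <- 0L
  for (ci in seq_along(area_classes_mm2)) {
    area <- area_classes_mm2[ci]
    for (rep in seq_len(n_per_class)) {
      rec_id <- rec_id + 1L
      s <- child_seed(seed, rec_id)
      set.seed(s)
      has_reentry <- runif(1) < reentry_prob[ci]
      n_trig <- max(1L, round(trigger_density_per_mm2 * area))
      res <- simulate_colony_recording(area, n_trig, has_reentry,
                                       duration_s, mean_cell_diameter_um,
                                       render_downsample, noise_sd, config, s)
      records[[rec_id]] <- data.frame(
        area_mm2 = area, n_wavefronts = res$n_wavefronts,
        n_trigger_sites = res$n_trigger_sites,
        reentry = res$classification == "re_entry",
        reentry_truth = has_reentry, seed = s)
    }
  }
  records <- do.call(rbind, records)
  cls <- factor(records$area_mm2, levels = area_classes_mm2)
  contingency <- NULL
  if (length(area_classes_mm2) >= 2L) {
    reentry_counts <- tapply(records$reentry, cls, sum)
    n_counts <- tapply(rep(1L, nrow(records)), cls, sum)
    contingency <- colony_contingency_analysis(
      reentry = rev(as.integer(reentry_counts)),
      n = rev(as.integer(n_counts)),
      labels = rev(as.character(area_classes_mm2)))
  }
  wf_groups <- split(records$n_wavefronts, cls)
  tr_groups <- split(records$n_trigger_sites[!records$reentry],
                     cls[!records$reentry])
  tr_groups <- lapply(tr_groups, function(x) x[!is.na(x)])
  mw_wf <- if (all(lengths(wf_groups) >= 2L)) mann_whitney_dunn(wf_groups)
  mw_tr <- if (all(lengths(tr_groups) >= 2L)) mann_whitney_dunn(tr_groups)
  list(records = records, contingency = contingency,
       mw_wavefronts = mw_wf, mw_triggers = mw_tr)
}

simulate_colony_recording <- function(area_mm2, n_triggers, has_reentry,
                                      duration_s, cell_diameter_um,
                                      render_downsample, noise_sd, config,
                                      seed) {
  lat <- generate_cell_lattice(area_mm2,
                               mean_cell_diameter_um = cell_diameter_um,
                               n_triggers = if (has_reentry) 0L else n_triggers,
                               seed = seed)
  stimuli <- list()
  if (has_reentry) {
    # the block must dwarf the emission port and slow margin, or
    # port-adjacent cells see inputs spanning a large phase range and the
    # colony stops following the rotor 1:1
    r <- lat$radius_um
    len <- min(1.3 * r, max(700, runif(1, 0.45, 0.65) * r))
    period <- runif(1, 360, 480)
    lat <- impose_block_structure(lat, "line_plus_patch",
                                  center_um = c(0, 0),
                                  angle_deg = runif(1, 0, 360),
                                  length_um = len,
                                  patch_radius_um = 90,
                                  port_radius_um = 80,
                                  isolate_core = TRUE)
    stimuli <- rotor_drive_stimuli(lat, period_ms = period, t_start_ms = 50,
                                   n_laps = ceiling(duration_s * 1000 / period))
  }
  truth <- simulate_lattice(lat, duration_s, dt_ms = 0.5,
                            seed = child_seed(seed, 91L), stimuli = stimuli)
  movie <- render_lattice_movie(truth, noise_sd = noise_sd,
                                seed = child_seed(seed, 92L),
                                downsample = render_downsample)
  wf <- segment_wavefronts(movie, config)
  cls <- classify_recording(wf, config)
  n_sites <- NA_integer_
  if (cls != "re_entry") {
    sites <- tryCatch(localize_triggers(movie, config, wf),
                      error = function(e) NULL)
    n_sites <- if (is.null(sites)) 0L else nrow(sites)
  }
  list(n_wavefronts = nrow(wf), classification = cls,
       n_trigger_sites = n_sites, truth = truth)
}

#' Spatial-stability experiment (stop-and-restart perturbation)
#'
#' Pre/post recording pairs in which all activity is stopped and restarted:
#' each pre trigger persists at its location with probability
#' `persistence_prob` (automaticity is a property of the cell) or is
#' replaced by a trigger elsewhere; with probability `p_silent` the post
#' recording is quiescent. Re-entry cores are never re-established at the
#' same location. Pre and post sites are compared with [match_locations()]
#' at the configured tolerance, and localization noise is modelled as a
#' small jitter on every reported site.
#'
#' @param n_pairs Number of pre/post pairs.
#' @param kind `"triggers"` or `"reentry"`.
#' @param persistence_prob Per-trigger persistence probability (the study
#'   observed ~35% after depolarisation and ~38% after uncoupling).
#' @param p_silent Probability of a quiescent post recording.
#' @param p_reentry_post For `kind = "reentry"`: probability that re-entry
#'   re-forms at all (elsewhere); the study observed none.
#' @param n_triggers_per_colony Trigger sites per pre recording.
#' @param colony_area_mm2 Colony area.
#' @param tolerance_um Location-match tolerance.
#' @param jitter_um SD of the localization jitter applied to each reported
#'   site position.
#' @param seed Random seed.
#' @return List with `outcomes` (one row per pre site: `pair`, `truth`,
#'   `outcome`), `proportions` (named fractions), `confusion` (truth x
#'   outcome table).
#' @export
run_stability_experiment <- function(n_pairs = 20L,
                                     kind = c("triggers", "reentry"),
                                     persistence_prob = 0.35,
                                     p_silent = 0.10,
                                     p_reentry_post = 0,
                                     n_triggers_per_colony = 3L,
                                     colony_area_mm2 = 3.5,
                                     tolerance_um = 100,
                                     jitter_um = 15,
                                     seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  radius_um <- sqrt(colony_area_mm2 * 1e6 / pi)
  draw_site <- function(avoid = NULL, min_dist = 2 * tolerance_um) {
    repeat {
      ang <- runif(1, 0, 2 * pi)
      rr <- sqrt(runif(1)) * 0.9 * radius_um
      p <- c(rr * sin(ang), rr * cos(ang))
      if (is.null(avoid) || nrow(avoid) == 0L ||
          all(sqrt(rowSums((avoid - matrix(p, nrow(avoid), 2,
                                           byrow = TRUE))^2)) >= min_dist)) {
        return(p)
      }
    }
  }
  jitter <- function(p) p + rnorm(2, 0, jitter_um)
  rows <- list()
  for (pair in seq_len(n_pairs)) {
    n_pre <- if (kind == "triggers") n_triggers_per_colony else 1L
    pre <- matrix(0, 0, 2)
    for (i in seq_len(n_pre)) pre <- rbind(pre, draw_site(pre))
    silent <- runif(1) < p_silent
    post <- matrix(0, 0, 2)
    truth <- character(n_pre)
    if (silent) {
      truth[] <- "no_activity"
    } else if (kind == "triggers") {
      persists <- runif(n_pre) < persistence_prob
      truth[persists] <- "same_location"
      truth[!persists] <- "other_location"
      for (i in seq_len(n_pre)) {
        post <- rbind(post, if (persists[i]) pre[i, ] else
          draw_site(rbind(pre, post)))
      }
    } else {
      reforms <- runif(1) < p_reentry_post
      if (reforms) {
        truth[] <- "other_location"
        post <- rbind(post, draw_site(pre))
      } else {
        truth[] <- "no_activity"
      }
    }
    pre_j <- t(vapply(seq_len(n_pre), function(i) jitter(pre[i, ]),
                      numeric(2)))
    pre_df <- data.frame(row_um = pre_j[, 1], col_um = pre_j[, 2])
    post_df <- if (nrow(post) > 0L) {
      post_j <- t(vapply(seq_len(nrow(post)), function(i) jitter(post[i, ]),
                         numeric(2)))
      data.frame(row_um = post_j[, 1], col_um = post_j[, 2])
    } else data.frame(row_um = numeric(0), col_um = numeric(0))
    outcome <- match_locations(pre_df, post_df, tolerance_um)
    rows[[pair]] <- data.frame(pair = pair, truth = truth, outcome = outcome)
  }
  outcomes <- do.call(rbind, rows)
  levs <- c("same_location", "other_location", "no_activity")
  props <- table(factor(outcomes$outcome, levels = levs)) / nrow(outcomes)
  confusion <- table(truth = factor(outcomes$truth, levels = levs),
                     outcome = factor(outcomes$outcome, levels = levs))
  list(outcomes = outcomes, proportions = as.numeric(props),
       proportion_names = levs, confusion = confusion)
}
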