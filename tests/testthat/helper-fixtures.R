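# Shared fixture builders: everything is generated in code at test time.

# single-pixel periodic transient trace at a given frequency (noise-free)
kernel_train_trace <- function(freq_hz, duration_s = 10, frame_rate = 100,
                               channel = "calcium") {
  kern <- transient_kernel(channel)
  period <- 1000 / freq_hz
  tab <- rotormap:::periodic_kernel_table(kern, period)
  t_ms <- (seq_len(duration_s * frame_rate) - 1L) * 1000 / frame_rate
  rotormap:::new_trace(tab$values[as.integer(t_ms %% period + 0.5) + 1L],
                       frame_rate)
}

# rasterized filled disc mask
disc_mask <- function(side, center, radius) {
  rows <- matrix(rep(seq_len(side) - 1L, side), side)
  cols <- matrix(rep(seq_len(side) - 1L, each = side), side)
  (rows - center[1])^2 + (cols - center[2])^2 <= radius^2
}

# small rotor phantom used by several mapping/block tests
small_rotor <- function(seed = 11L, period_ms = 345, dim = c(128L, 128L),
                        noise_sd = 0.05, duration_s = 3, ...) {
  core <- core_structure("line", center = dim / 2, angle_deg = 25,
                         length_px = 40)
  make_rotor_phantom(core, period_ms = period_ms, dim = dim,
                     duration_s = duration_s, noise_sd = noise_sd,
                     seed = seed, ...)
}

cfg_rotor <- function(...) reentry_config(df_band_hz = c(1, 10), ...)
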