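# Shared fixtures, built once per test run. The default session is the
# 288-trial presented sequence (216 analyzed); the small recording uses the
# 15.5 Hz acquisition rate to keep the suite fast.

fx_session <- generate_session(design_config())

fx_recording <- function(preset = "WT_SC", n_cells = 30, seed = 1,
                         frame_rate = 15.5, ...) {
  simulate_recording(fx_session, cohort_preset(preset), n_cells = n_cells,
                     seed = seed, frame_rate = frame_rate, ...)
}

# Tiny toy design: 12-trial blocks, 2 aversive types.
fx_toy_config <- function(...) {
  design_config(trials_per_block = 12L, volatile_block_len = 4L,
                volatile_probs = c(1 / 2, 1 / 2, 1 / 2),
                n_aversive_types = 2L, ...)
}
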