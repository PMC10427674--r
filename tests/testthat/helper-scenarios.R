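# Shared fixture builders: small scenarios keep the suite fast while the
# epoch structure (normoxia / hypoxia / normoxia) mirrors the protocol.

short_timeline <- function(duration_s = 120, hypoxia = c(30, 60)) {
  data.frame(label = c("normoxia", "hypoxia", "normoxia"),
             start_s = c(0, hypoxia[1], hypoxia[2]),
             end_s = c(hypoxia[1], hypoxia[2], duration_s),
             stringsAsFactors = FALSE)
}

small_scenario <- function(shape = c(24, 24), duration_s = 120,
                           oxygen_level = 8, noise_sd = 0, seed = 1, ...) {
  scenario_config(image_shape = shape, duration_s = duration_s,
                  epoch_timeline = if (oxygen_level < 21)
                    short_timeline(duration_s,
                                   c(duration_s / 4, duration_s / 2)) else NULL,
                  oxygen_level = oxygen_level, noise_sd = noise_sd,
                  rng_seed = seed, ...)
}

# Region-trace cohort for connectivity recovery: full-length protocol
# timeline, traces only (no pixel rendering), one RNG substream per subject.
trace_cohort <- function(n_subjects = 7, seed0 = 100, within = 0.8,
                         between = 0.5, between_hyp = 0.1) {
  lapply(seq_len(n_subjects), function(s) {
    cfg <- scenario_config(image_shape = c(16, 16), duration_s = 2400,
                           oxygen_level = 8, within_cluster_r = within,
                           between_cluster_r = between,
                           between_cluster_r_hypoxia = between_hyp,
                           rng_seed = seed0 + s)
    simulate_calcium(cfg)
  })
}
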