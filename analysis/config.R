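# Shared configuration for the numbered analysis scripts. Every script
# re-runs the deterministic pipeline prefix it needs, so they can be run in
# any order; identical seeds make the stages reproduce bit-identical tables.

pipeline_config <- function(seed = 20260) {
  list(
    seed = seed,
    output_dir = file.path("results", "pipeline_run"),
    simulate = list(
      time_points = c(seq(0.75, 8.5, length.out = 8),
                      seq(16, 30, length.out = 8)),
      schedules = c("plin3_like", "plin2_like"),
      scenes_per_point = 6),
    timecourse = list(early_window = c(0.75, 8.5), late_window = c(16, 30)))
}
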