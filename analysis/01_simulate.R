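#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study panel.
#
# Simulates the packaged 9-node, 6-cohort scenario whose ground truth is
# the 13-edge exploratory connectivity model: each cohort's lagged-path
# coefficients follow the packaged per-decade schedule, innovations are
# calibrated to unit stationary variance, and every cohort holds 20
# subjects (10 F / 10 M) of 600 time points.  Writes one TSV per subject
# plus a JSON manifest under results/panel/.

library(usemnet)

seed <- 1L
cfg <- default_dmn_scenario(seed = seed)
panel <- simulate_panel(cfg)
manifest <- write_panel(panel, "results/panel", seed = seed,
                        note = "innovation SDs calibrated to unit stationary variance")

cat("simulated", length(panel$subjects), "subjects x",
    cfg$timepoints_per_subject, "time points over",
    cfg$n_cohorts, "cohorts\n")
cat("manifest:", manifest, "\n")
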