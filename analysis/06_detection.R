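#!/usr/bin/env Rscript
# Sonar-equation detection ranges versus swarm size and call frequency, the
# temporal-integration gain from echo elongation, and the impulse-response
# cross-validation of the spectral model.
# Writes results/detection_ranges.csv, results/integration_gain.csv,
# results/impulse_validation.csv.

suppressPackageStartupMessages(library(swarmecho))
dir.create("results", showWarnings = FALSE)
seed <- 1L

det <- run_experiment(list(experiment = "detection", seed = seed),
                      out_dir = NULL)
write_table(det, "results/detection_ranges.csv")
r1 <- det$detection_range_m[det$n_targets == 1 & det$alpha_db_per_m == 0.5]
r300 <- det$detection_range_m[det$n_targets == 300 & det$alpha_db_per_m == 0.5]
cat(sprintf(
  "At 25 kHz (0.5 dB/m) a single midge is detectable from %.1f m, a swarm of\n300 from %.1f m; at 60 kHz (2.3 dB/m) the same swarm only from %.1f m.\n\n",
  r1, r300,
  det$detection_range_m[det$n_targets == 300 & det$alpha_db_per_m == 2.3]))

intg <- run_experiment(list(experiment = "integration", seed = seed),
                       out_dir = NULL)
write_table(intg, "results/integration_gain.csv")
cat("Echo elongation by swarm depth (8 ms pulse, N = 300) and the resulting\n",
    "perfect-integration gain:\n", sep = "")
print(intg, row.names = FALSE, digits = 3)
cat("\n")

val <- run_experiment(list(experiment = "validate_impulse", seed = seed),
                      out_dir = NULL)
write_table(val, "results/impulse_validation.csv")
s <- attr(val, "summary")
cat(sprintf(
  "Impulse-response cross-check: 10 known target ranges recovered with a\nmaximum delay error of %.2f us against a %.1f us resolution cell.\n",
  s$max_error_s * 1e6, s$resolution_s * 1e6))
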