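#!/usr/bin/env Rscript
# Spectral interference: example spectra, pooled trough-width distributions
# and the critical bandwidth versus swarm size and density.
# Writes results/example_spectra.csv, results/trough_widths.csv,
# results/critical_bandwidth.csv.

suppressPackageStartupMessages(library(swarmecho))
dir.create("results", showWarnings = FALSE)
seed <- 1L

# two realizations of each of two conditions: the spectra look completely
# different even though (N, R) are identical
ex <- do.call(rbind, lapply(c(8, 110), function(N) {
  do.call(rbind, lapply(1:2, function(k) {
    sp <- echo_spectrum(generate_swarm(swarm_spec(N, 120, seed = seed), k))
    data.frame(n_targets = N, realization = k, freq_hz = sp$frequencies,
               mag_db = 20 * log10(Mod(sp$pressure)))
  }))
}))
write_table(ex, "results/example_spectra.csv")

insect <- build_synthetic_insect_response(seed = seed)
grid_conds <- expand.grid(n_targets = c(4, 8, 16, 50),
                          spacing_mm = c(15, 35, 60, 120))
bwc <- do.call(rbind, lapply(seq_len(nrow(grid_conds)), function(i) {
  N <- grid_conds$n_targets[i]; R <- grid_conds$spacing_mm[i]
  w <- pooled_trough_widths(N, R, n_realizations = 100,
                            peak_criterion = 0.2, reflector = insect,
                            orientation_mode = "aligned_dorsal",
                            seed = seed + 17L, method = "threshold_run")
  data.frame(n_targets = N, spacing_mm = R, n_widths = length(w),
             critical_bandwidth_khz = critical_bandwidth(w) / 1000)
}))
write_table(bwc, "results/critical_bandwidth.csv")

w16 <- pooled_trough_widths(16, 35, n_realizations = 100,
                            peak_criterion = 0.2, reflector = insect,
                            orientation_mode = "aligned_dorsal",
                            seed = seed + 17L, method = "threshold_run")
write_table(data.frame(width_hz = w16), "results/trough_widths.csv")

cat("Critical bandwidth (70% coverage, 20% peak criterion):\n")
print(reshape(bwc[, -3], idvar = "n_targets", timevar = "spacing_mm",
              direction = "wide"), row.names = FALSE, digits = 3)
cat("\nFor the reference condition (16 insects, R = 35 mm) the critical",
    sprintf("bandwidth is %.1f kHz.", critical_bandwidth(w16) / 1000),
    "It scarcely depends on the number of insects but grows as swarms get",
    "denser: dense swarms are shallow, their interference pattern varies",
    "slowly with frequency, and their spectral troughs are wide.\n")
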