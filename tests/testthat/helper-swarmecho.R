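# shared fixtures: tiny deterministic swarms and a brute-force phasor oracle
# kept deliberately independent of the package's vectorised echo engine.

# swarm object around explicit positions (metres)
manual_swarm <- function(positions, spacing_mm = 35) {
  sp <- swarm_spec(nrow(positions), spacing_mm, jitter_sd_mm = 0, seed = 0L)
  structure(list(positions = as.matrix(positions), orientations = NULL,
                 spec = sp, realization_id = 0L),
            class = "swarm")
}

# brute-force complex sum of the echo model, scalar loops only
brute_force_pressure <- function(positions, freqs, emitter,
                                 c_sound = 343, ts_db = -60, d_ref = 0.1) {
  P <- complex(real = rep(0, length(freqs)))
  for (i in seq_len(nrow(positions))) {
    d <- sqrt(sum((positions[i, ] - emitter)^2))
    D <- 2 * d
    a <- 10^(ts_db / 20) * d_ref / d
    for (j in seq_along(freqs)) {
      lambda <- c_sound / freqs[j]
      frac <- D / lambda - floor(D / lambda)
      P[j] <- P[j] + a * exp(-1i * (2 * pi * frac + pi))
    }
  }
  P
}
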