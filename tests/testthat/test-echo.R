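test_that("single point target yields the flat reference spectrum", {
  sw <- manual_swarm(matrix(c(0, 0, 1), 1))
  sp <- echo_spectrum(sw, emitter = c(0, 0, 0))
  expect_equal(Mod(sp$pressure), rep(10^(-60 / 20) * 0.1, 681))
  expect_equal(unname(diff(spectrum_stats(sp))), 0)  # peak == mean when flat
})

test_that("two equidistant targets double the pressure (+6 dB)", {
  one <- echo_spectrum(manual_swarm(matrix(c(0, 0, 1), 1)),
                       emitter = c(0, 0, 0))
  two <- echo_spectrum(manual_swarm(rbind(c(0, 0, 1), c(0, 0, -1))),
                       emitter = c(0, 0, 0))
  expect_equal(Mod(two$pressure), 2 * Mod(one$pressure))
})

test_that("half-wavelength path difference cancels at the design frequency", {
  # round-trip distances differ by lambda/2 at 25 kHz
  lambda <- 343 / 25000
  pos <- rbind(c(0, 0, 1), c(0, 0, 1 + lambda / 4))
  sp <- echo_spectrum(manual_swarm(pos), emitter = c(0, 0, 0))
  oracle <- brute_force_pressure(pos, sp$frequencies, c(0, 0, 0))
  expect_equal(sp$pressure, oracle, tolerance = 1e-10)
  m <- Mod(sp$pressure)
  at_null <- m[sp$frequencies == 25000]
  # near-total cancellation (residual from the slight amplitude mismatch)
  expect_lt(at_null, 0.01 * max(m))
})

test_that("engine matches the brute-force phasor oracle on a random cloud", {
  set.seed(99)
  pos <- cbind(runif(7, -0.1, 0.1), runif(7, -0.1, 0.1), runif(7, -0.1, 0.1))
  grid <- frequency_grid(12000, 80000, 5000)
  sp <- echo_spectrum(manual_swarm(pos), grid = grid)
  oracle <- brute_force_pressure(pos, grid_frequencies(grid),
                                 emitter_position())
  expect_equal(sp$pressure, oracle, tolerance = 1e-10)
})

test_that("fractional-cycle phase equals the unwrapped phase", {
  D <- c(1.77, 3.4, 4.000113, 8.5)
  lambda <- 343 / 63700
  frac <- D / lambda - floor(D / lambda)
  expect_equal(exp(-1i * (2 * pi * frac + pi)),
               exp(-1i * (2 * pi * D / lambda + pi)), tolerance = 1e-9)
})

test_that("triangle inequality bounds the coherent sum", {
  sw <- generate_swarm(swarm_spec(24, 35, seed = 8), 1)
  sp <- echo_spectrum(sw)
  d1 <- sqrt(colSums((t(sw$positions) - emitter_position())^2))
  bound <- sum(10^(-60 / 20) * 0.1 / d1)
  expect_true(all(Mod(sp$pressure) <= bound * (1 + 1e-12)))
})

test_that("incoherent summation: mean echo power scales with N", {
  # E |sum of N unit phasors with random phases|^2 = N, so the mean power
  # ratio of 4-target to single-target swarms is ~4 (sampling error aside)
  mean_power <- function(N) {
    mean(vapply(1:100, function(k) {
      sp <- echo_spectrum(generate_swarm(swarm_spec(N, 35, seed = 17), k))
      mean(Mod(sp$pressure)^2)
    }, numeric(1)))
  }
  expect_equal(mean_power(4) / mean_power(1), 4, tolerance = 0.15)
})

test_that("spectra of two realizations of one condition are distinct", {
  sp1 <- echo_spectrum(generate_swarm(swarm_spec(16, 35, seed = 10), 1))
  sp2 <- echo_spectrum(generate_swarm(swarm_spec(16, 35, seed = 10), 2))
  expect_false(which.max(Mod(sp1$pressure)) == which.max(Mod(sp2$pressure)))
  expect_lt(cor(Mod(sp1$pressure), Mod(sp2$pressure)), 0.5)
})

test_that("attenuation tilts the spectrum down at high frequencies", {
  sw <- manual_swarm(matrix(c(0, 0, 2), 1))
  dry <- echo_spectrum(sw, emitter = c(0, 0, 0))
  wet <- echo_spectrum(sw, emitter = c(0, 0, 0), include_attenuation = TRUE)
  ratio_db <- 20 * log10(Mod(wet$pressure) / Mod(dry$pressure))
  # one-way 2 m target: round trip 4 m at the table's alpha
  expect_equal(ratio_db[dry$frequencies == 25000], -0.5 * 4, tolerance = 1e-9)
  expect_equal(ratio_db[dry$frequencies == 60000], -2.3 * 4, tolerance = 1e-9)
  expect_true(all(diff(ratio_db) <= 1e-12))
})

test_that("band_max is monotone in bandwidth and attains the peak", {
  sp <- echo_spectrum(generate_swarm(swarm_spec(16, 35, seed = 12), 1))
  bws <- seq(500, 12500, by = 500)
  lev <- vapply(bws, function(b) band_max(sp, 25000, b), numeric(1))
  expect_true(all(diff(lev) >= 0))
  full <- band_max(sp, 80000, 68000)
  expect_equal(full, spectrum_stats(sp)[["peak_db"]])
  expect_error(band_max(sp, 25000, 20000), "outside")
  expect_error(band_max(sp, 25000, 10), "resolution")
})

test_that("impulse response recovers round-trip delays and energy", {
  # ten targets at known ranges, spaced well beyond the resolution cell
  set.seed(5)
  d1 <- seq(0.5, 1.2, length.out = 10) + runif(10, -0.01, 0.01)
  pos <- cbind(runif(10, -0.1, 0.1), runif(10, -0.1, 0.1), 0)
  pos[, 3] <- sqrt(d1^2 - pos[, 1]^2 - pos[, 2]^2)
  sw <- manual_swarm(pos)
  sp <- echo_spectrum(sw, emitter = c(0, 0, 0))
  ir <- impulse_response(sp)
  true_t <- sort(2 * d1 / 343)
  got_t <- recover_delays(ir, 10)
  res_cell <- 1 / (80000 - 12000)
  expect_equal(length(got_t), 10L)
  expect_true(all(abs(got_t - true_t) <= res_cell))
  # Parseval: time-domain energy equals spectral energy
  n_fft <- nrow(ir)
  expect_equal(sum(ir$envelope^2) * n_fft, sum(Mod(sp$pressure)^2),
               tolerance = 1e-9)
  # single target: one dominant peak at its round trip delay
  one <- impulse_response(echo_spectrum(manual_swarm(matrix(c(0, 0, 1), 1)),
                                        emitter = c(0, 0, 0)))
  expect_lt(abs(one$time_s[which.max(one$envelope)] - 2 / 343), res_cell)
})

test_that("echo duration adds the swarm's round-trip depth to the pulse", {
  single <- manual_swarm(matrix(c(0, 0, 1), 1))
  expect_equal(echo_duration(single, c(0, 0, 0), 8), 8)
  # round-trip spread 0.343 m at c = 343 m/s: exactly +1 ms
  two <- manual_swarm(rbind(c(0, 0, 1), c(0, 0, 1.1715)))
  expect_equal(echo_duration(two, c(0, 0, 0), 8), 9)
  # dense 300-target swarm stretches an 8 ms pulse to about 8.9 ms
  dense <- generate_swarm(swarm_spec(300, 15, seed = 2), 1)
  expect_equal(echo_duration(dense, pulse_duration_ms = 8), 8.9,
               tolerance = 0.05)
})
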