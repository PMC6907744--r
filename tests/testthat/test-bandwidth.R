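test_that("pressure_vs_n normalizes the loudest condition to 0 dB", {
  tab <- pressure_vs_n(c(1, 2, 4), 35, n_realizations = 10, seed = 3)
  expect_equal(max(tab$peak_db), 0)
  expect_true(all(tab$peak_db >= tab$mean_db))
  expect_error(pressure_vs_n(numeric(0), 35), "empty")
})

test_that("single-target rows are nearly invariant to the nominal spacing", {
  # spacing enters a 1-target swarm only through the jitter calibration,
  # which perturbs the emitter distance by a few cm at most
  tab <- pressure_vs_n(1, c(15, 35, 60, 120), n_realizations = 5,
                       seed = 3, normalize = FALSE)
  expect_lt(diff(range(tab$peak_db)), 0.5)
  expect_lt(diff(range(tab$mean_db)), 0.5)
})

test_that("guaranteed level is non-decreasing in bandwidth", {
  crv <- bandwidth_curve(25000, 30, 35, n_realizations = 40, seed = 5)
  expect_true(all(diff(crv$guaranteed_level_db) >= 0))
  expect_equal(dim(attr(crv, "band_max")), c(40L, 25L))
  expect_error(bandwidth_curve(percentile = 1.2), "percentile")
  expect_error(bandwidth_curve(upper_freq = 20000), "below the frequency grid")
})

test_that("marginal bandwidth gain saturates beyond 10 kHz", {
  crv <- bandwidth_curve(25000, 100, 35, n_realizations = 100, seed = 6)
  lev <- crv$guaranteed_level_db
  b <- crv$bandwidth_hz
  gains <- diff(lev[b >= 10000])
  expect_true(all(gains < 0.5))
})

test_that("bandwidth curves are invariant to the upper frequency", {
  lev <- lapply(c(25000, 45000, 80000), function(uf)
    bandwidth_curve(uf, 50, 35, n_realizations = 60,
                    seed = 7)$guaranteed_level_db)
  # same Monte-Carlo seed, different band position: curves should coincide
  # within Monte-Carlo error
  expect_lt(max(abs(lev[[1]] - lev[[2]])), 1.5)
  expect_lt(max(abs(lev[[1]] - lev[[3]])), 1.5)
})

test_that("two-target interference yields the analytic peak spacing", {
  # round-trip path difference DeltaD gives spectral peaks every c/DeltaD
  delta <- 0.05                      # one-way offset, m
  pos <- rbind(c(0, 0, 1), c(0, 0, 1 + delta))
  sp <- echo_spectrum(manual_swarm(pos), emitter = c(0, 0, 0))
  w <- trough_widths(sp, peak_criterion = 0.2)
  expect_gt(length(w), 3)
  expect_equal(mean(w), 343 / (2 * delta), tolerance = 0.05)
})

test_that("an exactly flat spectrum has no troughs (plateau rule)", {
  # ties are not strict rises, so a constant spectrum holds no local maxima
  sp <- echo_spectrum(manual_swarm(matrix(c(0, 0, 1), 1)),
                      emitter = c(0, 0, 0))
  sp$pressure <- rep(1e-4 + 0i, length(sp$pressure))
  expect_length(trough_widths(sp, peak_criterion = 0.2), 0)
  expect_length(trough_widths(sp, peak_criterion = 0.2,
                              method = "threshold_run"), 0)
})

test_that("trough widths grow as swarms get denser", {
  r <- build_synthetic_insect_response(seed = 11)
  w15 <- pooled_trough_widths(16, 15, n_realizations = 40, reflector = r,
                              orientation_mode = "aligned_dorsal", seed = 13)
  w120 <- pooled_trough_widths(16, 120, n_realizations = 40, reflector = r,
                               orientation_mode = "aligned_dorsal", seed = 13)
  expect_gt(mean(w15), mean(w120))
  expect_gt(critical_bandwidth(w15), critical_bandwidth(w120))
})

test_that("critical bandwidth is the coverage quantile", {
  expect_equal(critical_bandwidth(rep(4000, 10)), 4000)
  expect_equal(critical_bandwidth(c(1000, 2000, 3000), coverage = 0.5), 2000)
  expect_error(critical_bandwidth(numeric(0)), "empty")
})

test_that("expected pulses fall as bandwidth grows, near 2 at full band", {
  tb <- pulses_vs_bandwidth(16, 35, bandwidths = c(500, 2000, 6000, 12500),
                            n_realizations = 100, seed = 19)
  ok <- is.finite(tb$expected_pulses)
  expect_true(all(diff(tb$expected_pulses[ok]) <= 0))
  # at the reference bandwidth p is the mass at or above the mean: near 1/2
  full <- tb$expected_pulses[tb$bandwidth_hz == 12500]
  expect_gt(full, 1.4)
  expect_lt(full, 3)
})

test_that("Monte-Carlo outputs are reproducible bit-for-bit under a seed", {
  a <- bandwidth_curve(25000, 20, 35, n_realizations = 10, seed = 23)
  b <- bandwidth_curve(25000, 20, 35, n_realizations = 10, seed = 23)
  expect_identical(a, b)
  tb1 <- pulses_vs_bandwidth(8, 35, bandwidths = 1000, n_realizations = 10,
                             seed = 23)
  tb2 <- pulses_vs_bandwidth(8, 35, bandwidths = 1000, n_realizations = 10,
                             seed = 23)
  expect_identical(tb1, tb2)
})
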