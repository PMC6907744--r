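test_that("degenerate single-target swarm sits at the origin", {
  sw <- generate_swarm(swarm_spec(1, 120, jitter_sd_mm = 0))
  expect_equal(dim(sw$positions), c(1L, 3L))
  expect_equal(unname(sw$positions[1, ]), c(0, 0, 0))
})

test_that("spec validation rejects non-physical parameters", {
  expect_error(swarm_spec(0, 35), "positive integer")
  expect_error(swarm_spec(10, -5), "positive length")
  expect_error(swarm_spec(10, 35, jitter_sd_mm = -1), "non-negative")
})

test_that("default jitter follows the spacing calibration table", {
  expect_equal(default_jitter_sd(c(15, 35, 60, 120)), c(6, 15, 26, 52))
})

test_that("swarm generation is reproducible and seed-sensitive", {
  sp <- swarm_spec(50, 35, seed = 11)
  a <- generate_swarm(sp, 3)
  b <- generate_swarm(sp, 3)
  expect_identical(a$positions, b$positions)
  d <- generate_swarm(sp, 4)
  expect_false(isTRUE(all.equal(a$positions, d$positions)))
  expect_false(any(duplicated(a$positions)))
})

test_that("unjittered lattice fill matches brute-force geometry", {
  # diameter of the N=300, R=15, sigma=0 fill by exhaustive pairwise search
  sw <- generate_swarm(swarm_spec(300, 15, jitter_sd_mm = 0))
  pos <- sw$positions
  dmax <- 0
  for (i in 1:299) for (j in (i + 1):300)
    dmax <- max(dmax, sqrt(sum((pos[i, ] - pos[j, ])^2)))
  expect_equal(swarm_diameter(sw), dmax)
  expect_equal(dmax, 0.125, tolerance = 0.02)
})

test_that("doubling the pitch doubles all pairwise distances (sigma = 0)", {
  a <- generate_swarm(swarm_spec(40, 35, jitter_sd_mm = 0))
  b <- generate_swarm(swarm_spec(40, 70, jitter_sd_mm = 0))
  expect_equal(as.numeric(dist(b$positions)), 2 * as.numeric(dist(a$positions)))
})

test_that("spherical fill is symmetric under point reflection", {
  # exact symmetry is only attainable when N fills whole lattice shells
  # (a partially filled tie shell cannot be closed under negation)
  for (n in c(7, 19, 27, 33, 57)) {
    pos <- generate_swarm(swarm_spec(n, 35, jitter_sd_mm = 0))$positions
    key <- function(m) sort(apply(round(m, 9), 1, paste, collapse = ","))
    expect_identical(key(pos), key(-pos))
  }
})

test_that("mean realized diameters reproduce the reference table", {
  # 0.13 / 0.31 / 0.52 / 1.0 m at N = 300 for R = 15/35/60/120 mm
  expected <- c(`15` = 0.13, `35` = 0.31, `60` = 0.52, `120` = 1.0)
  for (R in c(15, 35, 60, 120)) {
    dm <- mean(vapply(1:20, function(k)
      swarm_diameter(generate_swarm(swarm_spec(300, R, seed = 5), k)),
      numeric(1)))
    expect_lt(abs(dm - expected[[as.character(R)]]) / expected[[as.character(R)]],
              0.15)
  }
})

test_that("swarm diameter bounds the largest nearest-neighbour distance", {
  sw <- generate_swarm(swarm_spec(30, 60, seed = 3), 1)
  d <- as.matrix(dist(sw$positions))
  diag(d) <- Inf
  expect_gte(swarm_diameter(sw), max(apply(d, 1, min)))
  expect_error(swarm_diameter(generate_swarm(swarm_spec(1, 35))), "2 targets")
})

test_that("aligned orientations scatter with SD = spread/2, random is uniform", {
  sw <- generate_swarm(swarm_spec(2000, 35, seed = 21), 1)
  al <- assign_orientations(sw, "aligned_dorsal", spread_deg = 30)
  expect_equal(sd(al$orientations[, "yaw_deg"]), 15, tolerance = 0.08)
  expect_true(all(al$orientations[, "pitch_deg"] == 0))

  z <- assign_orientations(sw, "aligned_dorsal", spread_deg = 0)
  expect_true(all(z$orientations[, "yaw_deg"] == z$orientations[1, "yaw_deg"]))

  rn <- assign_orientations(sw, "random")
  th <- rn$orientations[, "yaw_deg"] * pi / 180
  resultant <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  expect_lt(resultant, 0.06)
  expect_error(assign_orientations(sw, "sideways"), "arg")
})

test_that("bead cloud fixture meets the laboratory summary statistics", {
  b <- fixture_bead_cloud(seed = 0)
  expect_equal(nrow(b$positions), 16L)
  d <- sqrt(rowSums(b$positions^2))
  expect_true(all(d >= 0.93 & d <= 1.18))
  nn <- mean_nn_distance(b)
  expect_gte(nn, 0.0737)
  expect_lte(nn, 0.0901)
  # a different seed gives different coordinates but the same constraints
  b2 <- fixture_bead_cloud(seed = 1)
  expect_false(isTRUE(all.equal(b$positions, b2$positions)))
  d2 <- sqrt(rowSums(b2$positions^2))
  expect_true(all(d2 >= 0.93 & d2 <= 1.18))
})

test_that("positions CSV round-trips exactly", {
  sw <- assign_orientations(generate_swarm(swarm_spec(300, 35, seed = 9), 2),
                            "aligned_dorsal")
  path <- withr::local_tempfile(fileext = ".csv")
  write_positions_csv(sw, path)
  back <- read_positions_csv(path)
  expect_equal(back$positions, sw$positions)
  expect_equal(back$orientations, sw$orientations,
               ignore_attr = TRUE, tolerance = 1e-12)
})
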