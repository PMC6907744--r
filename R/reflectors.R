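#' Ideal point reflector
#'
#' A frequency- and angle-flat reflector of unit complex amplitude. Used to
#' isolate the contribution of swarm geometry (inter-target interference)
#' from the frequency response of individual insects.
#'
#' @return an object of class `point_reflector`.
#' @export
point_reflector <- function() structure(list(), class = "point_reflector")

#' @export
print.point_reflector <- function(x, ...) {
  cat("point reflector (unit amplitude at all frequencies and angles)\n")
  invisible(x)
}

#' Single-frequency response of the point reflector
#'
#' @param frequency frequency in Hz.
#' @param azimuth,elevation aspect angles in degrees (ignored).
#' @return `1+0i` for all inputs.
#' @export
point_response <- function(frequency, azimuth = 0, elevation = 0) {
  rep(1 + 0i, length(frequency))
}

#' Synthetic insect reflector response table
#'
#' A stand-in for a numerically computed insect scattering table: a complex
#' response on a (frequency x azimuth x elevation) grid with 5 degree angle
#' steps, dimensionless relative to the point reflector. The mean magnitude
#' rises monotonically with frequency following a Rayleigh-like law for a
#' scatterer of characteristic size `wing_length_mm`,
#' \deqn{|r|(f) = \frac{(ka)^2}{1 + (ka)^2}, \qquad k = 2\pi f / c,}
#' (proportional to f^2 well below the size-set rolloff, saturating above
#' it), modulated by a smooth seeded angular gain; the phase varies smoothly
#' over the angle grid. Deterministic given `seed`.
#'
#' @param wing_length_mm wing length of the insect, mm (default 2.7, a small
#'   mosquito).
#' @param seed RNG seed for the angular modulation.
#' @param grid a [frequency_grid()].
#' @param angular_depth relative depth of the angular gain modulation.
#' @param sound_speed speed of sound, m/s.
#' @return object of class `reflector_response`: list with `frequencies`,
#'   `azimuths` (0..355), `elevations` (-90..90), and `response`, a complex
#'   array of dim (freq, az, el).
#' @export
build_synthetic_insect_response <- function(wing_length_mm = 2.7, seed = 1L,
                                            grid = frequency_grid(),
                                            angular_depth = 0.3,
                                            sound_speed = 343) {
  if (wing_length_mm <= 0) stop("`wing_length_mm` must be positive")
  f <- grid_frequencies(grid)
  az <- seq(0, 355, by = 5)
  el <- seq(-90, 90, by = 5)
  a <- wing_length_mm / 1000
  ka <- 2 * pi * f / sound_speed * a
  mag_f <- ka^2 / (1 + ka^2)

  # smooth angular modulation from a few low-order seeded harmonics
  set.seed(as.integer(seed))
  ca <- stats::rnorm(3, 0, 1)
  cb <- stats::rnorm(3, 0, 1)
  ce <- stats::rnorm(3, 0, 1)
  azr <- az * pi / 180
  elr <- el * pi / 180
  gaz <- ca[1] * cos(azr) + ca[2] * sin(azr) + ca[3] * cos(2 * azr)
  gel <- ce[1] * cos(elr) + ce[2] * sin(elr) + ce[3] * cos(2 * elr)
  paz <- cb[1] * sin(azr) + cb[2] * cos(2 * azr) + cb[3] * sin(3 * azr)

  nf <- length(f); na <- length(az); ne <- length(el)
  gain <- exp(angular_depth * outer(gaz, gel, `+`))      # na x ne, positive
  phase <- pi / 4 * outer(paz, sin(elr), `+`)            # na x ne, smooth
  resp <- array(0 + 0i, dim = c(nf, na, ne))
  ang <- gain * exp(1i * phase)
  for (k in seq_len(ne)) resp[, , k] <- outer(mag_f, ang[, k])

  structure(list(frequencies = f, azimuths = az, elevations = el,
                 response = resp, wing_length_mm = wing_length_mm,
                 seed = as.integer(seed)),
            class = "reflector_response")
}

#' @export
print.reflector_response <- function(x, ...) {
  cat(sprintf(
    "reflector_response: wing %.1f mm, %d freqs x %d az x %d el (5 deg grid)\n",
    x$wing_length_mm, length(x$frequencies), length(x$azimuths),
    length(x$elevations)))
  invisible(x)
}

# index of the nearest 5-degree azimuth node (wrapping at 360)
.nearest_az_idx <- function(resp, azimuth) {
  az <- ((azimuth %% 360) + 360) %% 360
  idx <- round(az / 5) %% length(resp$azimuths)
  as.integer(idx) + 1L
}

.nearest_el_idx <- function(resp, elevation) {
  el <- pmin(pmax(elevation, -90), 90)
  as.integer(round((el + 90) / 5)) + 1L
}

#' Look up the complex response of a reflector table
#'
#' Nearest-node interpolation on the 5 degree angle grid (a query 2 degrees
#' past a node returns that node; 3 degrees past returns the next), linear
#' interpolation in frequency.
#'
#' @param resp a `reflector_response`.
#' @param frequency frequencies in Hz (vector allowed); must lie within the
#'   table's frequency range.
#' @param azimuth,elevation aspect angles in degrees (scalars).
#' @return complex response, one value per frequency.
#' @export
lookup_response <- function(resp, frequency, azimuth = 0, elevation = 0) {
  stopifnot(inherits(resp, "reflector_response"))
  f <- resp$frequencies
  if (any(frequency < min(f) - 1e-9 | frequency > max(f) + 1e-9))
    stop("frequency outside the reflector table range")
  ia <- .nearest_az_idx(resp, azimuth)
  ie <- .nearest_el_idx(resp, elevation)
  col <- resp$response[, ia, ie]
  re <- stats::approx(f, Re(col), xout = frequency, rule = 2)$y
  im <- stats::approx(f, Im(col), xout = frequency, rule = 2)$y
  complex(real = re, imaginary = im)
}

# complex response matrix (n_targets x n_freq) for a swarm seen from
# `emitter`; dispatches on reflector type. Frequencies must equal the grid
# the insect table was built on (checked), so no per-target interpolation is
# needed in the hot path.
reflector_matrix <- function(reflector, swarm, emitter, frequencies) {
  UseMethod("reflector_matrix")
}

#' @export
reflector_matrix.point_reflector <- function(reflector, swarm, emitter,
                                             frequencies) {
  matrix(1 + 0i, nrow(swarm$positions), length(frequencies))
}

#' @export
reflector_matrix.reflector_response <- function(reflector, swarm, emitter,
                                                frequencies) {
  if (!isTRUE(all.equal(reflector$frequencies, frequencies)))
    stop("reflector table was built on a different frequency grid")
  n <- nrow(swarm$positions)
  ori <- swarm$orientations
  if (is.null(ori)) ori <- matrix(0, n, 3L)
  asp <- aspect_angles(swarm$positions, ori, emitter)
  out <- matrix(0 + 0i, n, length(frequencies))
  for (i in seq_len(n)) {
    ia <- .nearest_az_idx(reflector, asp[i, 1])
    ie <- .nearest_el_idx(reflector, asp[i, 2])
    out[i, ] <- reflector$response[, ia, ie]
  }
  out
}

# aspect (azimuth, elevation) of the emitter in each target's body frame.
# Body frame: x forward (heading), y left, z up; yaw about z, pitch about y,
# roll about x, applied in yaw-pitch-roll order.
aspect_angles <- function(positions, orientations, emitter) {
  n <- nrow(positions)
  v <- sweep(-positions, 2L, -emitter)      # target -> emitter vectors
  v <- v / sqrt(rowSums(v^2))
  yaw <- orientations[, 1] * pi / 180
  pitch <- orientations[, 2] * pi / 180
  roll <- orientations[, 3] * pi / 180
  out <- matrix(0, n, 2L, dimnames = list(NULL, c("az_deg", "el_deg")))
  for (i in seq_len(n)) {
    cz <- cos(yaw[i]); sz <- sin(yaw[i])
    cy <- cos(pitch[i]); sy <- sin(pitch[i])
    cx <- cos(roll[i]); sx <- sin(roll[i])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
    vb <- crossprod(Rz %*% Ry %*% Rx, v[i, ])  # world -> body
    out[i, 1] <- atan2(vb[2], vb[1]) * 180 / pi
    out[i, 2] <- asin(pmin(pmax(vb[3], -1), 1)) * 180 / pi
  }
  out
}

#' Serialize a reflector response table to CSV
#'
#' Long format with columns `freq_hz,az_deg,el_deg,re,im`.
#'
#' @param resp a `reflector_response`.
#' @param path file path.
#' @export
write_reflector_csv <- function(resp, path) {
  stopifnot(inherits(resp, "reflector_response"))
  g <- expand.grid(freq_hz = resp$frequencies, az_deg = resp$azimuths,
                   el_deg = resp$elevations)
  g$re <- Re(as.vector(resp$response))
  g$im <- Im(as.vector(resp$response))
  utils::write.csv(g, path, row.names = FALSE)
  invisible(path)
}
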