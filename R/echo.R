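#' Uniform frequency grid of the sonar signal
#'
#' The emitted signal is modeled as flat-spectrum between `f_min` and `f_max`;
#' spectra are evaluated on this grid. Defaults cover 12-80 kHz in 100 Hz
#' steps.
#'
#' @param f_min,f_max band edges, Hz.
#' @param step grid step, Hz.
#' @return object of class `frequency_grid`.
#' @export
frequency_grid <- function(f_min = 12000, f_max = 80000, step = 100) {
  if (!(f_min < f_max) || step <= 0) stop("need f_min < f_max and step > 0")
  structure(list(f_min = f_min, f_max = f_max, step = step),
            class = "frequency_grid")
}

#' @rdname frequency_grid
#' @param grid a `frequency_grid`.
#' @return `grid_frequencies` returns the numeric vector of grid frequencies.
#' @export
grid_frequencies <- function(grid) {
  stopifnot(inherits(grid, "frequency_grid"))
  seq(grid$f_min, grid$f_max, by = grid$step)
}

#' Acoustic constants of the echo model
#'
#' @param sound_speed speed of sound in air, m/s (343 at 20 C).
#' @param reference_distance distance at which target strength is referenced,
#'   m.
#' @param reference_ts_db target strength at the reference distance, dB
#'   (-60 dB at 0.1 m, equivalently -80 dB at 1 m).
#' @param attenuation function mapping frequency (Hz) to atmospheric
#'   attenuation in dB/m; defaults to [attenuation_at()] in table mode.
#' @return object of class `acoustic_params`.
#' @export
acoustic_params <- function(sound_speed = 343, reference_distance = 0.1,
                            reference_ts_db = -60,
                            attenuation = function(f) attenuation_at(f)) {
  if (sound_speed <= 0) stop("`sound_speed` must be positive")
  structure(list(sound_speed = sound_speed,
                 reference_distance = reference_distance,
                 reference_ts_db = reference_ts_db,
                 attenuation = attenuation),
            class = "acoustic_params")
}

#' Default emitter (bat) position
#'
#' The bat faces the swarm centre from `distance` metres, viewing from above
#' at `off_axis_deg` away from the vertical (dorsal) axis. An exactly
#' axis-aligned view would leave all targets of one lattice layer
#' near-equidistant, an artifact of the cubic voxel fill; the oblique dorsal
#' view is the default.
#'
#' @param distance emitter distance from the swarm centroid, m.
#' @param off_axis_deg angle between the view axis and vertical, degrees.
#' @return length-3 numeric position (m) in swarm coordinates.
#' @export
emitter_position <- function(distance = 2, off_axis_deg = 15) {
  th <- off_axis_deg * pi / 180
  distance * c(sin(th), 0, cos(th))
}

#' Complex echo spectrum of a swarm
#'
#' Coherent phasor sum over targets. For each grid frequency `f` with
#' wavelength `lambda = c / f`,
#' \deqn{P(f) = \sum_i r_i(f)\, a_i\,
#'   e^{-j\,(2\pi\,\mathrm{frac}(D_i/\lambda) + \pi)},}
#' where `D_i` is the round-trip (two-way) distance to target i, `frac` the
#' fractional part, `r_i` the complex reflector response at the target's
#' aspect angle, and `a_i` the spherical spreading amplitude
#' `10^(TS_ref/20) * (d_ref / d_i)` with `d_i` the one-way distance (6 dB
#' pressure loss per doubling of distance). With `spreading = "two_way"` the
#' loss is applied on both legs (`(d_ref/d_i)^2`). If `include_attenuation`,
#' each term is further scaled by `10^(-alpha(f) D_i / 20)`.
#'
#' @param swarm a `swarm`.
#' @param grid a [frequency_grid()].
#' @param reflector a [point_reflector()] or
#'   [build_synthetic_insect_response()] table.
#' @param emitter emitter/receiver position, m.
#' @param acoustics an [acoustic_params()].
#' @param include_attenuation add atmospheric attenuation per term.
#' @param spreading one-way (as in the analytic spectrum model) or two-way
#'   spherical loss.
#' @return object of class `echo_spectrum`: list with `frequencies`,
#'   complex `pressure`, `grid`, and metadata.
#' @examples
#' sp <- echo_spectrum(generate_swarm(swarm_spec(8, 35)))
#' spectrum_stats(sp)
#' @export
echo_spectrum <- function(swarm, grid = frequency_grid(),
                          reflector = point_reflector(),
                          emitter = emitter_position(),
                          acoustics = acoustic_params(),
                          include_attenuation = FALSE,
                          spreading = c("one_way", "two_way")) {
  stopifnot(inherits(swarm, "swarm"))
  spreading <- match.arg(spreading)
  f <- grid_frequencies(grid)
  if (!length(f)) stop("empty frequency grid")
  pos <- swarm$positions
  d1 <- sqrt(colSums((t(pos) - emitter)^2))   # one-way distances
  if (any(d1 < 1e-9)) stop("a target coincides with the emitter")
  D <- 2 * d1
  ratio <- acoustics$reference_distance / d1
  if (spreading == "two_way") ratio <- ratio^2
  a <- 10^(acoustics$reference_ts_db / 20) * ratio

  # phase via the fractional number of wavelengths in the round trip
  cycles <- outer(D, f) / acoustics$sound_speed     # D_i / lambda
  ph <- 2 * pi * (cycles - floor(cycles)) + pi
  r <- reflector_matrix(reflector, swarm, emitter, f)
  terms <- (r * a) * (cos(ph) - 1i * sin(ph))       # e^{-j ph}
  if (include_attenuation) {
    alpha <- acoustics$attenuation(f)
    terms <- terms * 10^(-outer(D, alpha * 0.05))   # alpha * D / 20
  }
  P <- colSums(terms)
  structure(list(frequencies = f, pressure = P, grid = grid,
                 realization_id = swarm$realization_id,
                 reflector = class(reflector)[1], emitter = emitter),
            class = "echo_spectrum")
}

#' @export
print.echo_spectrum <- function(x, ...) {
  s <- spectrum_stats(x)
  cat(sprintf("echo_spectrum: %d frequencies (%g-%g kHz), peak %.1f dB, mean %.1f dB\n",
              length(x$frequencies), min(x$frequencies) / 1000,
              max(x$frequencies) / 1000, s[["peak_db"]], s[["mean_db"]]))
  invisible(x)
}

#' Peak and mean spectrum level
#'
#' @param spectrum an `echo_spectrum`.
#' @return named vector: `peak_db` = 20 log10 max |P(f)|,
#'   `mean_db` = 20 log10 mean |P(f)|.
#' @export
spectrum_stats <- function(spectrum) {
  stopifnot(inherits(spectrum, "echo_spectrum"))
  m <- Mod(spectrum$pressure)
  if (all(m == 0)) stop("all-zero spectrum")
  c(peak_db = 20 * log10(max(m)), mean_db = 20 * log10(mean(m)))
}

#' Band-limited maximum echo level
#'
#' The maximum of |P(f)| over the band `[upper_freq - bandwidth, upper_freq]`,
#' in dB: what a signal of that bandwidth ending at `upper_freq` could at
#' best receive from this swarm realization (its energy is spread over the
#' band, and the best-placed frequency sets the attainable peak).
#'
#' @param spectrum an `echo_spectrum`.
#' @param upper_freq upper edge of the signal band, Hz.
#' @param bandwidth signal bandwidth, Hz (at least one grid step).
#' @return level in dB.
#' @export
band_max <- function(spectrum, upper_freq, bandwidth) {
  stopifnot(inherits(spectrum, "echo_spectrum"))
  f <- spectrum$frequencies
  if (bandwidth < spectrum$grid$step) stop("bandwidth below grid resolution")
  lo <- upper_freq - bandwidth
  if (lo < min(f) - 1e-9 || upper_freq > max(f) + 1e-9)
    stop("band outside the frequency grid")
  sel <- f >= lo - 1e-9 & f <= upper_freq + 1e-9
  20 * log10(max(Mod(spectrum$pressure[sel])))
}

#' Impulse response (range profile) of an echo spectrum
#'
#' Inverse Fourier transform of the band-limited complex spectrum, returning
#' the magnitude envelope on a time axis with period `1/step`. Peaks occur at
#' the round-trip delays `D_i / c`; the nominal time resolution is the
#' reciprocal of the grid span. Round-trip delays beyond `1/step` (10 ms on
#' the default grid) alias.
#'
#' @param spectrum an `echo_spectrum` on a uniform grid.
#' @param n_fft transform length (zero-padded; controls plotting smoothness,
#'   not resolution).
#' @return data.frame with columns `time_s`, `envelope`.
#' @export
impulse_response <- function(spectrum, n_fft = 8192) {
  stopifnot(inherits(spectrum, "echo_spectrum"))
  f <- spectrum$frequencies
  step <- spectrum$grid$step
  if (max(abs(diff(f) - step)) > 1e-6) stop("non-uniform frequency grid")
  bins <- as.integer(round(f / step))
  if (max(bins) >= n_fft) stop("`n_fft` too small for the frequency grid")
  X <- complex(real = rep(0, n_fft))
  X[bins + 1L] <- spectrum$pressure
  x <- stats::fft(X, inverse = TRUE) / n_fft
  data.frame(time_s = (seq_len(n_fft) - 1L) / (n_fft * step),
             envelope = Mod(x))
}

#' Echo duration after reflection from a swarm
#'
#' A swarm's depth stretches the returning echo: the first and last
#' round-trip arrivals differ by `(D_max - D_min)/c`.
#'
#' @param swarm a `swarm`.
#' @param emitter emitter position, m.
#' @param pulse_duration_ms emitted pulse duration, ms.
#' @param sound_speed m/s.
#' @return echo duration in ms.
#' @export
echo_duration <- function(swarm, emitter = emitter_position(),
                          pulse_duration_ms = 8, sound_speed = 343) {
  stopifnot(inherits(swarm, "swarm"))
  if (pulse_duration_ms <= 0) stop("`pulse_duration_ms` must be positive")
  d1 <- sqrt(colSums((t(swarm$positions) - emitter)^2))
  D <- 2 * d1
  pulse_duration_ms + (max(D) - min(D)) / sound_speed * 1000
}

#' Write an echo spectrum or impulse response as CSV
#'
#' Spectra use columns `freq_hz,re,im,mag_db`; impulse responses
#' `time_s,envelope`.
#'
#' @param x an `echo_spectrum` or the data.frame from [impulse_response()].
#' @param path file path.
#' @export
write_spectrum_csv <- function(x, path) {
  if (inherits(x, "echo_spectrum")) {
    df <- data.frame(freq_hz = x$frequencies, re = Re(x$pressure),
                     im = Im(x$pressure),
                     mag_db = 20 * log10(Mod(x$pressure)))
  } else df <- x
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
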