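#' Sonar parameters of the emitting bat
#'
#' @param source_level_db emitted sound pressure level at 0.1 m from the
#'   mouth, dB SPL (default 130).
#' @param threshold_db detection threshold at the ear, dB SPL (default 10).
#' @param target_strength_db_1m target strength of one insect at 1 m, dB
#'   (default -80, equivalently -60 dB at 0.1 m).
#' @param pulse_duration_ms emitted pulse duration, ms.
#' @return object of class `sonar_params`.
#' @export
sonar_params <- function(source_level_db = 130, threshold_db = 10,
                         target_strength_db_1m = -80, pulse_duration_ms = 8) {
  if (source_level_db <= threshold_db)
    stop("source level must exceed the detection threshold")
  structure(list(source_level_db = source_level_db,
                 threshold_db = threshold_db,
                 target_strength_db_1m = target_strength_db_1m,
                 pulse_duration_ms = pulse_duration_ms),
            class = "sonar_params")
}

#' Atmospheric attenuation coefficient
#'
#' `mode = "table"` linearly interpolates the three-point table
#' 25 kHz -> 0.5, 40 kHz -> 1.2, 60 kHz -> 2.3 dB/m (clamped at the ends).
#' `mode = "formula"` evaluates the standard humid-air absorption model
#' (ISO 9613-1 style: classical absorption plus the O2 and N2 vibrational
#' relaxation terms) at the given temperature and relative humidity, at
#' reference ambient pressure.
#'
#' @param frequency frequency in Hz (vectorised).
#' @param mode `"table"` or `"formula"`.
#' @param temperature_c air temperature, degrees C (formula mode).
#' @param rel_humidity relative humidity, percent (formula mode).
#' @return attenuation in dB/m.
#' @export
attenuation_at <- function(frequency, mode = c("table", "formula"),
                           temperature_c = 20, rel_humidity = 50) {
  mode <- match.arg(mode)
  if (mode == "table") {
    stats::approx(x = c(25000, 40000, 60000), y = c(0.5, 1.2, 2.3),
                  xout = frequency, rule = 2)$y
  } else {
    TK <- temperature_c + 273.15
    T0 <- 293.15
    # saturation vapour pressure ratio (ISO 9613-1), reference pressure
    psat_ratio <- 10^(-6.8346 * (273.16 / TK)^1.261 + 4.6151)
    h <- rel_humidity * psat_ratio            # molar concentration, %
    frO <- 24 + 4.04e4 * h * (0.02 + h) / (0.391 + h)
    frN <- (TK / T0)^(-1 / 2) *
      (9 + 280 * h * exp(-4.170 * ((TK / T0)^(-1 / 3) - 1)))
    f2 <- frequency^2
    alpha <- 8.686 * f2 *
      (1.84e-11 * (TK / T0)^(1 / 2) +
         (TK / T0)^(-5 / 2) *
           (0.01275 * exp(-2239.1 / TK) / (frO + f2 / frO) +
              0.1068 * exp(-3352 / TK) / (frN + f2 / frN)))
    alpha
  }
}

#' Received echo level of a swarm at a given range
#'
#' Closed-form sonar equation with incoherent summation over targets:
#' \deqn{RL = SL - 2\,[20 \log_{10}(d/d_{ref}) + \alpha (d - d_{ref})]
#'   + TS_{ref} + 10 \log_{10} N,}
#' where the `10 log10 N` term encodes the 3 dB-per-doubling gain of
#' incoherent summation and transmission loss is counted on both legs.
#'
#' @param range_m one-way range to the swarm, m (> 0.1).
#' @param n_targets number of insects (>= 1).
#' @param sonar a [sonar_params()].
#' @param attenuation_db_per_m atmospheric attenuation at the call
#'   frequency, dB/m.
#' @return received level, dB SPL.
#' @export
received_level <- function(range_m, n_targets, sonar = sonar_params(),
                           attenuation_db_per_m = 0.5) {
  if (any(range_m < 0.1)) stop("range must be at least the 0.1 m reference")
  if (any(n_targets < 1)) stop("`n_targets` must be >= 1")
  ts_ref <- sonar$target_strength_db_1m + 20  # back to the 0.1 m reference
  sonar$source_level_db -
    2 * (20 * log10(range_m / 0.1) + attenuation_db_per_m * (range_m - 0.1)) +
    ts_ref + 10 * log10(n_targets)
}

#' Maximum detection range of a swarm
#'
#' The largest range at which [received_level()] still meets the detection
#' threshold, solved by bisection to `tol` metres. The level is strictly
#' decreasing in range, so the root is unique.
#'
#' @inheritParams received_level
#' @param tol range tolerance, m (default 1 cm).
#' @param max_range bracketing upper bound, m.
#' @return detection range in metres.
#' @export
detection_range <- function(n_targets, sonar = sonar_params(),
                            attenuation_db_per_m = 0.5, tol = 0.01,
                            max_range = 1000) {
  excess <- function(d) received_level(d, n_targets, sonar,
                                       attenuation_db_per_m) -
    sonar$threshold_db
  if (excess(0.1) < 0) stop("swarm undetectable even at the reference distance")
  lo <- 0.1
  hi <- max_range
  if (excess(hi) > 0) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (excess(mid) >= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Temporal-integration gain from echo elongation
#'
#' A swarm's depth stretches the echo beyond the emitted pulse; a perfectly
#' integrating receiver gains 6 dB per doubling of echo duration:
#' `gain = 6.02 * log2(echo_duration / pulse_duration)`.
#'
#' @param echo_duration_ms received echo duration, ms.
#' @param pulse_duration_ms emitted pulse duration, ms.
#' @return gain in dB.
#' @export
integration_gain <- function(echo_duration_ms, pulse_duration_ms) {
  if (any(pulse_duration_ms <= 0)) stop("pulse duration must be positive")
  if (any(echo_duration_ms < pulse_duration_ms))
    stop("echo cannot be shorter than the emitted pulse")
  6.02 * log2(echo_duration_ms / pulse_duration_ms)
}
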