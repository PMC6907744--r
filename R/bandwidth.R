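# shared Monte-Carlo driver: one spectrum per realization of (N, R)
# conditions; optionally assigns orientations (needed by the insect
# reflector). `condition_seed` offsets keep streams distinct per condition.
mc_spectrum <- function(n_targets, spacing_mm, realization_id, seed,
                        grid, reflector, emitter,
                        orientation_mode = "none", acoustics = acoustic_params()) {
  sp <- swarm_spec(n_targets, spacing_mm, seed = seed)
  sw <- generate_swarm(sp, realization_id)
  if (orientation_mode != "none")
    sw <- assign_orientations(sw, orientation_mode,
                              seed = seed + 500000L)
  echo_spectrum(sw, grid = grid, reflector = reflector, emitter = emitter,
                acoustics = acoustics)
}

#' Mean echo level as a function of swarm size
#'
#' Monte-Carlo estimate of the peak and mean spectrum level for each
#' combination of swarm size N and spacing R, averaged over realizations.
#' Levels are reported relative to the loudest condition (global maximum
#' normalized to 0 dB) unless `normalize = FALSE`.
#'
#' @param n_values vector of swarm sizes N.
#' @param r_values vector of nominal spacings R, mm.
#' @param n_realizations realizations per condition (>= 2).
#' @param reflector reflector model.
#' @param grid a [frequency_grid()].
#' @param emitter emitter position.
#' @param seed base seed; each condition uses an offset stream.
#' @param orientation_mode orientation assignment per realization
#'   (`"none"` for point reflectors).
#' @param normalize shift levels so the global maximum is 0 dB.
#' @return data.frame with columns `n_targets`, `spacing_mm`, `peak_db`,
#'   `mean_db`; the dB offset applied is stored in `attr(, "offset_db")`.
#' @export
pressure_vs_n <- function(n_values, r_values, n_realizations = 100,
                          reflector = point_reflector(),
                          grid = frequency_grid(),
                          emitter = emitter_position(), seed = 1L,
                          orientation_mode = "none", normalize = TRUE) {
  if (!length(n_values) || !length(r_values)) stop("empty condition lists")
  if (n_realizations < 2) stop("need at least 2 realizations")
  conds <- expand.grid(n_targets = n_values, spacing_mm = r_values)
  res <- t(mapply(function(N, R, ci) {
    stats <- vapply(seq_len(n_realizations), function(k) {
      spectrum_stats(mc_spectrum(N, R, k, seed + 1000L * ci, grid, reflector,
                                 emitter, orientation_mode))
    }, numeric(2))
    rowMeans(stats)
  }, conds$n_targets, conds$spacing_mm, seq_len(nrow(conds))))
  out <- data.frame(conds, peak_db = res[, 1], mean_db = res[, 2])
  offset <- if (normalize) max(out$peak_db) else 0
  out$peak_db <- out$peak_db - offset
  out$mean_db <- out$mean_db - offset
  attr(out, "offset_db") <- offset
  out
}

# matrix of band-limited maxima: realizations x bandwidths
mc_band_max <- function(n_targets, spacing_mm, bandwidths, upper_freq,
                        n_realizations, reflector, grid, emitter, seed,
                        orientation_mode = "none") {
  t(vapply(seq_len(n_realizations), function(k) {
    sp <- mc_spectrum(n_targets, spacing_mm, k, seed, grid, reflector,
                      emitter, orientation_mode)
    vapply(bandwidths, function(b) band_max(sp, upper_freq, b), numeric(1))
  }, numeric(length(bandwidths))))
}

#' Percentile-guaranteed echo level versus signal bandwidth
#'
#' For each bandwidth `b`, the band-limited maximum level is computed for
#' every swarm realization over `[upper_freq - b, upper_freq]`; the
#' realizations are sorted and the mean of the lowest
#' `floor((1 - percentile) * n_realizations)` values is returned. With
#' `percentile = 0.75` this is the level the bat is guaranteed to reach or
#' exceed 75% of the time (25 worst cases of 100); `percentile = 0.90` keeps
#' the 10 worst.
#'
#' @param upper_freq upper frequency of the signal, Hz.
#' @param n_targets,spacing_mm swarm condition.
#' @param bandwidths bandwidths evaluated, Hz (default 0.5-12.5 kHz in
#'   500 Hz steps).
#' @param n_realizations Monte-Carlo sample size.
#' @param percentile guarantee level, in (0, 1).
#' @param reflector,grid,emitter,seed,orientation_mode see [pressure_vs_n()].
#' @return data.frame `bandwidth_hz`, `guaranteed_level_db`; the full
#'   realizations x bandwidths matrix of band maxima is attached as
#'   `attr(, "band_max")`.
#' @export
bandwidth_curve <- function(upper_freq = 25000, n_targets = 100,
                            spacing_mm = 35,
                            bandwidths = seq(500, 12500, by = 500),
                            n_realizations = 100, percentile = 0.75,
                            reflector = point_reflector(),
                            grid = frequency_grid(),
                            emitter = emitter_position(), seed = 1L,
                            orientation_mode = "none") {
  if (percentile <= 0 || percentile >= 1) stop("`percentile` must be in (0,1)")
  if (upper_freq - max(bandwidths) < grid$f_min)
    stop("widest band extends below the frequency grid")
  bm <- mc_band_max(n_targets, spacing_mm, bandwidths, upper_freq,
                    n_realizations, reflector, grid, emitter, seed,
                    orientation_mode)
  n_low <- max(1L, floor((1 - percentile) * n_realizations))
  lev <- apply(bm, 2L, function(x) mean(sort(x)[seq_len(n_low)]))
  out <- data.frame(bandwidth_hz = bandwidths, guaranteed_level_db = lev)
  attr(out, "band_max") <- bm
  attr(out, "percentile") <- percentile
  out
}

#' Spectral trough widths of one echo spectrum
#'
#' Qualifying peaks are local maxima of |P(f)| whose magnitude is no more
#' than `peak_criterion` below the global maximum of the spectrum (on the
#' linear pressure scale by default; `scale = "db"` applies the criterion as
#' a fraction of the dB dynamic range instead). Troughs are the intervals
#' between consecutive qualifying peaks; `method = "peak_gap"` returns the
#' frequency gaps between those peaks, `method = "threshold_run"` the widths
#' of the below-threshold intervals between supra-threshold regions.
#' Plateaus count once, at their leftmost point. Fewer than two qualifying
#' peaks yield an empty result.
#'
#' @param spectrum an `echo_spectrum`.
#' @param peak_criterion allowed drop below the global maximum, fraction in
#'   (0, 1).
#' @param scale criterion scale, `"linear"` (pressure) or `"db"`.
#' @param method trough width definition.
#' @return numeric vector of widths, Hz (possibly empty).
#' @export
trough_widths <- function(spectrum, peak_criterion = 0.2,
                          scale = c("linear", "db"),
                          method = c("peak_gap", "threshold_run")) {
  stopifnot(inherits(spectrum, "echo_spectrum"))
  scale <- match.arg(scale)
  method <- match.arg(method)
  if (peak_criterion <= 0 || peak_criterion >= 1)
    stop("`peak_criterion` must be in (0, 1)")
  f <- spectrum$frequencies
  m <- Mod(spectrum$pressure)
  th <- if (scale == "linear") {
    (1 - peak_criterion) * max(m)
  } else {
    mdb <- 20 * log10(m)
    10^((max(mdb) - peak_criterion * (max(mdb) - min(mdb))) / 20)
  }
  if (method == "peak_gap") {
    n <- length(m)
    # strict rise from the left, non-strict to the right: plateaus keep
    # their leftmost point
    loc <- which(m[2:(n - 1)] > m[1:(n - 2)] & m[2:(n - 1)] >= m[3:n]) + 1L
    pk <- loc[m[loc] >= th]
    if (length(pk) < 2L) return(numeric(0))
    diff(f[pk])
  } else {
    r <- rle(m < th)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- which(r$values)
    k <- k[k > 1L & k < length(r$values)]   # internal troughs only
    if (!length(k)) return(numeric(0))
    f[ends[k] + 1L] - f[starts[k] - 1L]
  }
}

#' Pooled trough widths over Monte-Carlo realizations
#'
#' Convenience wrapper running [trough_widths()] on `n_realizations`
#' independent swarm realizations of one condition and pooling the widths.
#'
#' @inheritParams pressure_vs_n
#' @param n_targets,spacing_mm swarm condition.
#' @param peak_criterion,scale,method passed to [trough_widths()].
#' @return numeric vector of pooled widths, Hz.
#' @export
pooled_trough_widths <- function(n_targets, spacing_mm, n_realizations = 100,
                                 peak_criterion = 0.2,
                                 reflector = point_reflector(),
                                 grid = frequency_grid(),
                                 emitter = emitter_position(), seed = 1L,
                                 orientation_mode = "none",
                                 scale = "linear", method = "peak_gap") {
  unlist(lapply(seq_len(n_realizations), function(k) {
    trough_widths(mc_spectrum(n_targets, spacing_mm, k, seed, grid,
                              reflector, emitter, orientation_mode),
                  peak_criterion, scale, method)
  }))
}

#' Critical bandwidth from a pooled trough-width distribution
#'
#' The `coverage` quantile of the pooled widths: the minimal signal
#' bandwidth that bridges the trough (i.e. still contains a near-maximal
#' spectral peak) for that fraction of echoes.
#'
#' @param widths pooled trough widths, Hz.
#' @param coverage fraction of echoes to cover (default 0.70).
#' @return critical bandwidth, Hz.
#' @export
critical_bandwidth <- function(widths, coverage = 0.70) {
  if (!length(widths)) stop("empty trough-width vector")
  unname(stats::quantile(widths, coverage))
}

#' Expected pulse count needed to match full-bandwidth detection
#'
#' For each bandwidth `b`, the probability `p(b)` that a single pulse's
#' band-limited maximum reaches or exceeds the across-realization mean of
#' the reference (full, 12.5 kHz) bandwidth maximum is estimated over
#' `n_realizations` swarms; the expected number of pulses is `1/p(b)`
#' (`Inf` when no realization reaches the reference level).
#'
#' @inheritParams bandwidth_curve
#' @param reference_bandwidth bandwidth defining the detection level, Hz.
#' @return data.frame `bandwidth_hz`, `prob`, `expected_pulses`.
#' @export
pulses_vs_bandwidth <- function(n_targets = 16, spacing_mm = 35,
                                bandwidths = seq(500, 12500, by = 500),
                                upper_freq = 25000, n_realizations = 100,
                                reference_bandwidth = 12500,
                                reflector = point_reflector(),
                                grid = frequency_grid(),
                                emitter = emitter_position(), seed = 1L,
                                orientation_mode = "none") {
  if (n_realizations < 1) stop("need at least one realization")
  if (upper_freq - reference_bandwidth < grid$f_min)
    stop("reference bandwidth extends below the frequency grid")
  all_b <- unique(c(bandwidths, reference_bandwidth))
  bm <- mc_band_max(n_targets, spacing_mm, all_b, upper_freq,
                    n_realizations, reflector, grid, emitter, seed,
                    orientation_mode)
  ref_level <- mean(bm[, match(reference_bandwidth, all_b)])
  p <- vapply(match(bandwidths, all_b),
              function(j) mean(bm[, j] >= ref_level), numeric(1))
  data.frame(bandwidth_hz = bandwidths, prob = p,
             expected_pulses = ifelse(p > 0, 1 / p, Inf))
}
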