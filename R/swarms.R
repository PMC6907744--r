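#' Default positional jitter for a nominal spacing
#'
#' Natural insect swarms become positionally noisier as they become sparser.
#' The simulated swarms follow a fixed calibration table pairing each nominal
#' nearest-neighbour spacing with the standard deviation of the Gaussian
#' positional noise: R = 15 -> 6 mm, 35 -> 15 mm, 60 -> 26 mm,
#' 120 -> 52 mm. Spacings off the table use the table's common noise-to-pitch
#' ratio (~0.43).
#'
#' @param spacing_mm nominal nearest-neighbour spacing in mm.
#' @return jitter standard deviation in mm.
#' @export
default_jitter_sd <- function(spacing_mm) {
  tab <- c(`15` = 6, `35` = 15, `60` = 26, `120` = 52)
  key <- as.character(spacing_mm)
  out <- unname(tab[key])
  miss <- is.na(out)
  if (any(miss)) out[miss] <- 0.433 * spacing_mm[miss]
  out
}

#' Specification of a stochastic swarm
#'
#' Bundles the parameters that define one swarm condition: the number of
#' targets N, the nominal nearest-neighbour spacing R (the pitch of the
#' underlying voxel lattice, in mm), and the positional jitter. `jitter_sd_mm`
#' is the standard deviation of the 3D Gaussian displacement vector applied to
#' each lattice site (per-axis SD is `jitter_sd_mm / sqrt(3)`); this
#' calibration reproduces the realized overall swarm diameters of
#' 0.13/0.31/0.52/1.0 m at N = 300 for R = 15/35/60/120 mm.
#'
#' @param n_targets number of point targets (N >= 1).
#' @param spacing_mm lattice pitch / nominal nearest-neighbour distance R, mm.
#' @param jitter_sd_mm SD of the Gaussian positional noise vector, mm.
#' @param arrangement lattice fill; only `"sphere_fill"` is defined.
#' @param seed base RNG seed; realization `k` uses stream `seed + k`.
#' @return an object of class `swarm_spec`.
#' @seealso [generate_swarm()]
#' @export
swarm_spec <- function(n_targets, spacing_mm,
                       jitter_sd_mm = default_jitter_sd(spacing_mm),
                       arrangement = "sphere_fill", seed = 1L) {
  if (length(n_targets) != 1L || !is.finite(n_targets) || n_targets < 1 ||
      n_targets != round(n_targets))
    stop("`n_targets` must be a positive integer")
  if (length(spacing_mm) != 1L || !is.finite(spacing_mm) || spacing_mm <= 0)
    stop("`spacing_mm` must be a positive length in mm")
  if (length(jitter_sd_mm) != 1L || !is.finite(jitter_sd_mm) || jitter_sd_mm < 0)
    stop("`jitter_sd_mm` must be a non-negative length in mm")
  arrangement <- match.arg(arrangement, "sphere_fill")
  structure(
    list(n_targets = as.integer(n_targets), spacing_mm = spacing_mm,
         jitter_sd_mm = jitter_sd_mm, arrangement = arrangement,
         seed = as.integer(seed)),
    class = "swarm_spec")
}

#' @export
print.swarm_spec <- function(x, ...) {
  cat(sprintf("swarm_spec: N = %d, R = %g mm, jitter SD = %g mm (%s, seed %d)\n",
              x$n_targets, x$spacing_mm, x$jitter_sd_mm, x$arrangement, x$seed))
  invisible(x)
}

# N cubic-lattice sites nearest the origin (spherical fill), ties broken
# lexicographically in (x, y, z); coordinates in lattice units.
lattice_sphere_fill <- function(n) {
  m <- ceiling((3 * n / (4 * pi))^(1 / 3)) + 2
  g <- as.matrix(expand.grid(x = -m:m, y = -m:m, z = -m:m))
  d2 <- rowSums(g^2)
  o <- order(d2, g[, 1], g[, 2], g[, 3])
  g[o[seq_len(n)], , drop = FALSE]
}

#' Generate one stochastic swarm realization
#'
#' Places `n_targets` point reflectors at the centres of cubic voxels of pitch
#' R, restricted to the sites nearest the lattice origin (a spherical fill),
#' then perturbs each by isotropic Gaussian noise. Positions are returned in
#' metres, centred on the lattice origin. Deterministic given
#' `spec$seed + realization_id`.
#'
#' @param spec a [swarm_spec()].
#' @param realization_id integer; distinguishes Monte-Carlo realizations of
#'   the same spec.
#' @return an object of class `swarm`: list with `positions` (N x 3 matrix,
#'   metres), `orientations` (NULL until [assign_orientations()] is called),
#'   `spec`, `realization_id`.
#' @examples
#' sw <- generate_swarm(swarm_spec(16, 35))
#' swarm_diameter(sw)
#' @export
generate_swarm <- function(spec, realization_id = 0L) {
  stopifnot(inherits(spec, "swarm_spec"))
  n <- spec$n_targets
  pos <- lattice_sphere_fill(n) * (spec$spacing_mm / 1000)
  if (spec$jitter_sd_mm > 0) {
    set.seed(spec$seed + as.integer(realization_id))
    sd_axis <- spec$jitter_sd_mm / sqrt(3) / 1000
    pos <- pos + matrix(stats::rnorm(3L * n, 0, sd_axis), n, 3L)
  }
  dimnames(pos) <- list(NULL, c("x", "y", "z"))
  structure(
    list(positions = pos, orientations = NULL, spec = spec,
         realization_id = as.integer(realization_id)),
    class = "swarm")
}

#' @export
print.swarm <- function(x, ...) {
  cat(sprintf("swarm: %d targets (R = %g mm, realization %d)\n",
              nrow(x$positions), x$spec$spacing_mm, x$realization_id))
  invisible(x)
}

#' Assign body orientations to the targets of a swarm
#'
#' Swarming insects tend to align their bodies. In the aligned modes all
#' insects are horizontal (pitch 0) with a common heading, and yaw and roll
#' scatter around it with Gaussian noise whose SD is `spread_deg / 2`, so that
#' +/- `spread_deg` covers about two standard deviations. `"aligned_dorsal"`
#' heads along +x (the bat's dorsal view plane), `"aligned_lateral"` along +y.
#' `"random"` draws yaw uniformly on [0, 360).
#'
#' @param swarm a `swarm`.
#' @param mode one of `"aligned_dorsal"`, `"aligned_lateral"`, `"random"`.
#' @param spread_deg full scatter width in degrees (aligned modes).
#' @param seed RNG seed for the orientation draw.
#' @return the swarm with an `orientations` matrix (columns
#'   `yaw_deg`, `pitch_deg`, `roll_deg`).
#' @export
assign_orientations <- function(swarm, mode = c("aligned_dorsal",
                                                "aligned_lateral", "random"),
                                spread_deg = 30, seed = swarm$spec$seed) {
  stopifnot(inherits(swarm, "swarm"))
  mode <- match.arg(mode)
  n <- nrow(swarm$positions)
  set.seed(as.integer(seed) + 7L * swarm$realization_id)
  sdv <- spread_deg / 2
  ori <- switch(mode,
    aligned_dorsal = cbind(yaw_deg = stats::rnorm(n, 0, sdv),
                           pitch_deg = rep(0, n),
                           roll_deg = stats::rnorm(n, 0, sdv)),
    aligned_lateral = cbind(yaw_deg = 90 + stats::rnorm(n, 0, sdv),
                            pitch_deg = rep(0, n),
                            roll_deg = stats::rnorm(n, 0, sdv)),
    random = cbind(yaw_deg = stats::runif(n, 0, 360),
                   pitch_deg = rep(0, n),
                   roll_deg = rep(0, n)))
  swarm$orientations <- ori
  swarm$orientation_mode <- mode
  swarm
}

#' Overall swarm diameter
#'
#' The maximum pairwise Euclidean distance between targets, the "overall
#' diameter" used to characterise simulated swarms.
#'
#' @param swarm a `swarm`, or an N x 3 position matrix.
#' @return diameter in metres.
#' @export
swarm_diameter <- function(swarm) {
  pos <- if (inherits(swarm, "swarm")) swarm$positions else as.matrix(swarm)
  if (nrow(pos) < 2L) stop("diameter needs at least 2 targets")
  max(stats::dist(pos))
}

#' Mean nearest-neighbour distance of a point set
#'
#' @param swarm a `swarm` or an N x 3 position matrix.
#' @return mean over targets of the distance to the nearest other target,
#'   in metres.
#' @export
mean_nn_distance <- function(swarm) {
  pos <- if (inherits(swarm, "swarm")) swarm$positions else as.matrix(swarm)
  if (nrow(pos) < 2L) stop("nearest-neighbour distance needs >= 2 targets")
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

#' A 16-bead reference cloud
#'
#' Generates a cloud of 16 targets mimicking the summary statistics of a
#' laboratory bead constellation: all emitter distances within
#' [0.93, 1.18] m of an emitter at the origin, lateral spreads of about
#' 0.15 m (width, x) and 0.09 m (height, y) expressed as standard deviations,
#' and a mean nearest-neighbour distance within 10% of 81.9 mm. Candidate
#' clouds are drawn (x, y Gaussian, range uniform) and resampled until the
#' nearest-neighbour constraint is met.
#'
#' @param seed RNG seed.
#' @param max_tries resampling budget before erroring.
#' @return a `swarm` with 16 positions (metres); the emitter position used by
#'   the constraints is stored in `attr(, "emitter")` (the origin).
#' @export
fixture_bead_cloud <- function(seed = 0L, max_tries = 1000L) {
  set.seed(as.integer(seed))
  target_nn <- 0.0819
  for (k in seq_len(max_tries)) {
    x <- stats::rnorm(16, 0, 0.15)
    y <- stats::rnorm(16, 0, 0.09)
    d <- stats::runif(16, 0.93, 1.18)
    bad <- x^2 + y^2 >= d^2
    if (any(bad)) next
    z <- sqrt(d^2 - x^2 - y^2)
    pos <- cbind(x = x, y = y, z = z)
    nn <- mean_nn_distance(pos)
    if (abs(nn - target_nn) <= 0.1 * target_nn) {
      sp <- swarm_spec(16L, 81.9, jitter_sd_mm = 0, seed = as.integer(seed))
      sw <- structure(list(positions = pos, orientations = NULL, spec = sp,
                           realization_id = 0L), class = "swarm")
      attr(sw, "emitter") <- c(0, 0, 0)
      return(sw)
    }
  }
  stop("bead cloud constraints not satisfied within `max_tries` draws")
}

#' Write / read swarm positions as CSV
#'
#' Plain-text exchange format with header
#' `id,x_m,y_m,z_m,yaw_deg,pitch_deg,roll_deg`; orientation columns are NA
#' when unassigned.
#'
#' @param swarm a `swarm`.
#' @param path file path.
#' @return `write_positions_csv` returns `path` invisibly;
#'   `read_positions_csv` returns a `swarm` (spec fields reconstructed
#'   minimally from the data).
#' @export
write_positions_csv <- function(swarm, path) {
  stopifnot(inherits(swarm, "swarm"))
  n <- nrow(swarm$positions)
  ori <- swarm$orientations
  if (is.null(ori)) ori <- matrix(NA_real_, n, 3L)
  df <- data.frame(id = seq_len(n),
                   x_m = swarm$positions[, 1], y_m = swarm$positions[, 2],
                   z_m = swarm$positions[, 3],
                   yaw_deg = ori[, 1], pitch_deg = ori[, 2],
                   roll_deg = ori[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_positions_csv
#' @export
read_positions_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("id", "x_m", "y_m", "z_m", "yaw_deg", "pitch_deg", "roll_deg")
  if (!identical(names(df), need))
    stop("positions CSV schema mismatch; expected columns: ",
         paste(need, collapse = ","))
  pos <- as.matrix(df[, c("x_m", "y_m", "z_m")])
  dimnames(pos) <- list(NULL, c("x", "y", "z"))
  ori <- as.matrix(df[, c("yaw_deg", "pitch_deg", "roll_deg")])
  if (all(is.na(ori))) ori <- NULL
  sp <- swarm_spec(nrow(pos), spacing_mm = 1, jitter_sd_mm = 0, seed = 0L)
  structure(list(positions = pos, orientations = ori, spec = sp,
                 realization_id = 0L), class = "swarm")
}
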