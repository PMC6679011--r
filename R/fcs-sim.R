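#' Confocal detection volume
#'
#' The 3D Gaussian observation volume of a confocal FCS setup, described by
#' its lateral 1/e^2 radius `w` and the structure parameter `s` (ratio of
#' axial to lateral extent, z/w). The effective volume is
#' `V_eff = pi^(3/2) * w^3 * s`.
#'
#' @param w Lateral 1/e^2 radius in um; `> 0`.
#' @param s Structure parameter (dimensionless); `>= 1`.
#' @return A `detection_volume` list.
#' @export
detection_volume <- function(w = 0.2, s = 5) {
  if (w <= 0) stop("`w` must be > 0")
  if (s < 1) stop("structure parameter `s` must be >= 1")
  structure(list(w = w, s = s), class = "detection_volume")
}

#' Effective detection volume in um^3
#' @param volume A [detection_volume()].
#' @return `pi^(3/2) * w^3 * s`.
#' @export
effective_volume <- function(volume) {
  pi^1.5 * volume$w^3 * volume$s
}

#' FCS simulation specification
#'
#' Parameters of a Brownian-dynamics simulation of point emitters diffusing
#' through the detection volume inside a periodic cubic box. One or two
#' diffusing species are supported; the expected number of particles in the
#' effective detection volume sets the particle density.
#'
#' @param components List of `list(D = , fraction = )` pairs: diffusion
#'   coefficient in um^2/s (`>= 0`) and number fraction. Fractions must sum
#'   to 1. A single `D` value is accepted as shorthand for one component.
#' @param mean_particles_in_volume Expected particle number N in the
#'   effective detection volume (sets the box-wide density).
#' @param box Periodic box edge lengths `(x, y, z)` in um; a single number
#'   gives a cube. The box must extend to at least 6 times the detection
#'   volume's 1/e^2 radius along each axis (`6 w` laterally, `6 s w`
#'   axially) so the Gaussian profile is negligible (< 2e-8 of peak) at the
#'   boundary; smaller boxes truncate the axial tail and bias recovered D
#'   upward. The default `NULL` resolves to exactly `(6 w, 6 w, 6 s w)` for
#'   the detection volume in use, the cheapest valid geometry.
#' @param duration Trace duration in seconds.
#' @param dt Sampling interval in seconds (default 2 us).
#' @param brightness Expected counts per particle per sample at the volume
#'   centre.
#' @param background Expected background counts per sample.
#' @param shot_noise If `TRUE` (default) counts are Poisson-distributed about
#'   the expected signal; otherwise the analog expectation is returned.
#' @param boundary `"reservoir"` (default) or `"periodic"`. Under
#'   `"reservoir"`, a particle crossing a box face re-enters on the
#'   opposite side with its transverse coordinates re-drawn uniformly,
#'   emulating exchange with an open reservoir; crossing particles are
#'   always at least 3 detection radii from the volume centre (guaranteed
#'   by the box-size contract), so the re-draw never touches a visible
#'   particle. `"periodic"` is the plain wrapped box, whose particles
#'   return as correlated images and impose a small spurious slow
#'   correlation.
#' @param triplet Optional `list(T = , tau_T = )`: stationary dark-state
#'   fraction and relaxation time in seconds, realised as a two-state
#'   telegraph process per particle.
#' @param seed Integer seed; every simulation is deterministic given it.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(components = list(list(D = 25, fraction = 1)),
                     mean_particles_in_volume = 2,
                     box = NULL, duration = 10, dt = 2e-6,
                     brightness = 0.5, background = 0,
                     shot_noise = TRUE, boundary = c("reservoir", "periodic"),
                     triplet = NULL, seed = 0L) {
  boundary <- match.arg(boundary)
  if (is.numeric(components)) components <- list(list(D = components, fraction = 1))
  if (length(components) == 1L && is.null(components[[1]]$fraction))
    components[[1]]$fraction <- 1
  fr <- vapply(components, `[[`, numeric(1), "fraction")
  Ds <- vapply(components, `[[`, numeric(1), "D")
  if (abs(sum(fr) - 1) > 1e-8) stop("component fractions must sum to 1")
  if (any(Ds < 0)) stop("diffusion coefficients must be >= 0")
  if (dt <= 0) stop("`dt` must be > 0")
  if (duration < dt) stop("`duration` must be >= dt")
  if (mean_particles_in_volume < 0) stop("`mean_particles_in_volume` must be >= 0")
  if (!is.null(box)) {
    if (length(box) == 1L) box <- rep(box, 3L)
    if (length(box) != 3L || any(box <= 0))
      stop("`box` must be 1 or 3 strictly positive edge lengths in um")
  }
  if (!is.null(triplet)) {
    if (triplet$T < 0 || triplet$T >= 1) stop("triplet fraction T must be in [0, 1)")
    if (triplet$tau_T <= 0) stop("triplet relaxation time must be > 0")
  }
  structure(list(components = components, fractions = fr, D = Ds,
                 mean_particles_in_volume = mean_particles_in_volume,
                 box = box, duration = duration, dt = dt,
                 brightness = brightness, background = background,
                 shot_noise = shot_noise, boundary = boundary, triplet = triplet,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Uniformly sampled fluorescence intensity trace
#'
#' @param counts Non-negative counts (or analog intensities) per sample.
#' @param dt Sampling interval in seconds.
#' @return An `intensity_trace` list.
#' @export
intensity_trace <- function(counts, dt) {
  if (any(counts < 0)) stop("counts must be >= 0")
  if (dt <= 0) stop("`dt` must be > 0")
  structure(list(counts = as.numeric(counts), dt = dt), class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace> %d samples, dt = %.3g s (%.3g s), mean %.3g counts/sample\n",
              length(x$counts), x$dt, length(x$counts) * x$dt, mean(x$counts)))
  invisible(x)
}

# box edges (x, y, z) in um: user value or the minimal valid geometry
resolve_box <- function(spec, volume) {
  if (is.null(spec$box)) 6 * volume$w * c(1, 1, volume$s) else spec$box
}

# particle counts per component: total fixed at round(density * box volume)
particle_counts <- function(spec, volume, box) {
  density <- spec$mean_particles_in_volume / effective_volume(volume)
  n_tot <- round(density * prod(box))
  n <- floor(spec$fractions * n_tot)
  rem <- n_tot - sum(n)
  if (rem > 0) {
    extra <- order(spec$fractions * n_tot - n, decreasing = TRUE)[seq_len(rem)]
    n[extra] <- n[extra] + 1L
  }
  as.integer(n)
}

#' Simulate a fluorescence intensity trace
#'
#' Brownian dynamics of point emitters in a periodic cubic box observed
#' through a 3D Gaussian detection volume centred in the box. Each particle
#' takes i.i.d. Gaussian steps with per-axis SD `sqrt(2 * D * dt)`; the
#' expected signal of a particle at (x, y, z) relative to the box centre is
#' `brightness * exp(-2 (x^2 + y^2) / w^2 - 2 z^2 / (s w)^2)`. The particle
#' number is fixed at `round(density * box^3)` per run (not Poisson
#' re-sampled), trading open-volume number fluctuations for lower variance
#' in recovery studies.
#'
#' @param spec A [sim_spec()].
#' @param volume A [detection_volume()].
#' @param init_pos Optional matrix (n_particles x 3, columns x, y, z in um
#'   relative to the box centre) overriding the uniform random initial
#'   positions; mainly for pinned-particle oracle tests.
#' @param seed Optional seed overriding `spec$seed`.
#' @return An [intensity_trace()].
#' @export
simulate_trace <- function(spec, volume = detection_volume(), init_pos = NULL,
                           seed = NULL) {
  stopifnot(inherits(spec, "sim_spec"), inherits(volume, "detection_volume"))
  box <- resolve_box(spec, volume)
  need <- 6 * volume$w * c(1, 1, volume$s)
  if (any(box < need - 1e-12))
    stop(sprintf(paste0("box (%g, %g, %g um) must be >= 6x the detection-volume ",
                        "1/e^2 radius per axis (%g, %g, %g um), else the Gaussian ",
                        "profile is truncated and D is biased"),
                 box[1], box[2], box[3], need[1], need[2], need[3]))
  n_steps <- floor(spec$duration / spec$dt)
  n_part <- particle_counts(spec, volume, box)
  step_sd <- sqrt(2 * spec$D * spec$dt)
  trip <- spec$triplet
  counts <- cpp_simulate_trace(
    n_steps = n_steps, dt = spec$dt,
    n_particles = n_part, step_sd = step_sd,
    box = box, w = volume$w, s = volume$s,
    brightness = spec$brightness, background = spec$background,
    shot_noise = spec$shot_noise,
    use_triplet = !is.null(trip),
    reservoir = identical(spec$boundary, "reservoir"),
    trip_T = if (is.null(trip)) 0 else trip$T,
    trip_tau = if (is.null(trip)) 1 else trip$tau_T,
    seed = if (is.null(seed)) spec$seed else as.integer(seed),
    init_pos = init_pos)
  tr <- intensity_trace(counts, spec$dt)
  attr(tr, "n_particles") <- n_part
  attr(tr, "n_effective") <- sum(n_part) * effective_volume(volume) / prod(box)
  attr(tr, "box") <- box
  tr
}

#' Simulate replicate traces
#'
#' Emulates the replicate acquisition protocol of confocal FCS, where a spot
#' is measured repeatedly for a fixed duration (e.g. five 10 s runs) so that
#' non-stationary drift can be recognised and averaged out. Replicates use
#' independent sub-seeds derived deterministically from `spec$seed`.
#'
#' @param spec A [sim_spec()]; `spec$duration` is ignored in favour of
#'   `rep_duration`.
#' @param volume A [detection_volume()].
#' @param n_reps Number of replicate traces (`>= 1`).
#' @param rep_duration Duration of each replicate in seconds.
#' @return List of [intensity_trace()] objects.
#' @export
replicate_traces <- function(spec, volume = detection_volume(), n_reps = 5,
                             rep_duration = 10) {
  if (n_reps < 1) stop("`n_reps` must be >= 1")
  spec$duration <- rep_duration
  seeds <- derive_seeds(spec$seed, n_reps)
  lapply(seeds, function(s) simulate_trace(spec, volume, seed = s))
}

# deterministic sub-seed sequence, kept below 2^31
derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 48271 + 7919 * seq_len(n)) %% 2147483647
}
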