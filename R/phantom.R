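#' RI tomogram container
#'
#' Bundles a 3D grid of refractive-index (RI) values with its voxel
#' dimensions and the reference RI of the culture medium. Axis order is
#' (z, y, x) throughout the package; all physical coordinates are in
#' micrometres measured from the grid corner, with voxel centres at
#' `(i - 0.5) * voxel_size` along each axis.
#'
#' @param values 3D numeric array of dimensionless RI values, axis order
#'   (z, y, x). All values must be finite and within `[1.30, 1.45]`, the
#'   physiological range for cellular material in aqueous medium.
#' @param voxel_size Numeric length-3, voxel edge lengths `(dz, dy, dx)` in
#'   micrometres; strictly positive. Defaults to `c(0.356, 0.11, 0.11)`, the
#'   axial and lateral optical resolutions of a typical ODT system, used as a
#'   stand-in sampling grid.
#' @param medium_ri Reference RI of the culture medium (refractometer value).
#' @param masks Optional named list of logical arrays (same dim as `values`)
#'   giving ground-truth compartment membership; attached by the phantom
#'   generators for oracle tests.
#' @return An object of class `ri_tomogram`.
#' @export
ri_tomogram <- function(values, voxel_size = c(0.356, 0.11, 0.11),
                        medium_ri = 1.337, masks = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array (z, y, x)")
  if (!all(is.finite(values)))
    stop("RI values must all be finite")
  rng <- range(values)
  if (rng[1] < 1.30 || rng[2] > 1.45)
    stop(sprintf("RI values outside the physiological range [1.30, 1.45]: [%g, %g]",
                 rng[1], rng[2]))
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 strictly positive lengths (dz, dy, dx) in um")
  if (!is.null(masks)) {
    ok <- vapply(masks, function(m) is.logical(m) && identical(dim(m), dim(values)),
                 logical(1))
    if (!all(ok)) stop("each mask must be a logical array matching dim(values)")
  }
  structure(list(values = values, voxel_size = voxel_size,
                 medium_ri = medium_ri, masks = masks),
            class = "ri_tomogram")
}

#' @export
print.ri_tomogram <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ri_tomogram> %d x %d x %d voxels (z, y, x), voxel %.3f x %.3f x %.3f um\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  RI range [%.4f, %.4f], medium RI %.4f\n",
              min(x$values), max(x$values), x$medium_ri))
  if (!is.null(x$masks))
    cat("  ground-truth masks:", paste(names(x$masks), collapse = ", "), "\n")
  invisible(x)
}

#' Ellipsoidal compartment description
#'
#' A compartment is an ellipsoid (a sphere when `semi_axes` is scalar) painted
#' into the phantom grid at a target RI. Compartments listed later in a
#' [phantom_spec()] overwrite earlier ones, so nested anatomy (cell >
#' nucleus > nucleolus > sub-nucleolar shells) is described outermost first.
#'
#' @param label Compartment name, e.g. `"cytoplasm"`, `"nucleoplasm"`,
#'   `"nucleolus"`, `"fc"`, `"dfc"`, `"gc"` or any custom tag.
#' @param center Numeric length-3 centre `(z, y, x)` in micrometres from the
#'   grid corner.
#' @param semi_axes Strictly positive semi-axes `(az, ay, ax)` in um; a single
#'   number is a sphere radius.
#' @param ri Target dimensionless RI of the compartment.
#' @return A `compartment_spec` list.
#' @export
compartment_spec <- function(label, center, semi_axes, ri) {
  if (length(semi_axes) == 1L) semi_axes <- rep(semi_axes, 3L)
  semi_axes <- as.numeric(semi_axes)
  center <- as.numeric(center)
  if (length(center) != 3L) stop("`center` must be (z, y, x) in um")
  if (length(semi_axes) != 3L || any(semi_axes <= 0))
    stop("`semi_axes` must be strictly positive (az, ay, ax) in um")
  structure(list(label = label, center = center, semi_axes = semi_axes, ri = ri),
            class = "compartment_spec")
}

#' Phantom specification
#'
#' Everything needed to generate a synthetic RI tomogram: grid geometry,
#' medium RI, an ordered list of compartments, and an additive i.i.d.
#' Gaussian RI noise level.
#'
#' @param grid_shape Integer length-3 voxel counts `(nz, ny, nx)`, positive.
#' @param voxel_size Voxel edge lengths `(dz, dy, dx)` in um.
#' @param medium_ri RI of the surrounding medium.
#' @param compartments List of [compartment_spec()] objects, painted in order
#'   (later overwrites earlier).
#' @param noise_sd Standard deviation of additive Gaussian RI noise; `>= 0`.
#' @param seed Integer seed for the noise; required when `noise_sd > 0`.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape, voxel_size = c(0.356, 0.11, 0.11),
                         medium_ri = 1.337, compartments = list(),
                         noise_sd = 0, seed = 0L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape <= 0L))
    stop("`grid_shape` must be 3 positive voxel counts (nz, ny, nx)")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (!all(vapply(compartments, inherits, logical(1), "compartment_spec")))
    stop("`compartments` must be a list of compartment_spec objects")
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 medium_ri = medium_ri, compartments = compartments,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# logical membership array for one ellipsoid, voxel-centre test
ellipsoid_mask <- function(grid_shape, voxel_size, center, semi_axes) {
  zc <- (seq_len(grid_shape[1]) - 0.5) * voxel_size[1]
  yc <- (seq_len(grid_shape[2]) - 0.5) * voxel_size[2]
  xc <- (seq_len(grid_shape[3]) - 0.5) * voxel_size[3]
  dz2 <- ((zc - center[1]) / semi_axes[1])^2
  dy2 <- ((yc - center[2]) / semi_axes[2])^2
  dx2 <- ((xc - center[3]) / semi_axes[3])^2
  q <- outer(outer(dz2, dy2, `+`), dx2, `+`)
  q <= 1
}

#' Generate a synthetic RI tomogram
#'
#' Paints each compartment's RI into a grid initialised at the medium RI,
#' in list order (later compartments overwrite earlier ones), using a
#' voxel-centre membership test, then adds i.i.d. Gaussian RI noise.
#' Ground-truth ownership masks (one per distinct compartment label, after
#' overwriting) are attached to the returned tomogram for oracle tests.
#'
#' @param spec A [phantom_spec()].
#' @return An [ri_tomogram()] with `masks` set; the noiseless grid is kept in
#'   attribute `"noiseless"` when `noise_sd > 0`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  values <- array(spec$medium_ri, dim = gs)
  owner <- array(0L, dim = gs)   # index of last compartment containing voxel
  comp_masks <- vector("list", length(spec$compartments))
  for (i in seq_along(spec$compartments)) {
    cm <- spec$compartments[[i]]
    m <- ellipsoid_mask(gs, spec$voxel_size, cm$center, cm$semi_axes)
    values[m] <- cm$ri
    owner[m] <- i
    comp_masks[[i]] <- m
  }
  labels <- vapply(spec$compartments, `[[`, character(1), "label")
  masks <- list()
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    m <- array(FALSE, dim = gs)
    for (i in idx) m <- m | (comp_masks[[i]] & owner == i)
    masks[[lab]] <- m
  }
  masks[["medium"]] <- owner == 0L
  noiseless <- values
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    values <- values + array(rnorm(prod(gs), 0, spec$noise_sd), dim = gs)
  }
  tomo <- ri_tomogram(values, spec$voxel_size, spec$medium_ri, masks = masks)
  if (spec$noise_sd > 0) attr(tomo, "noiseless") <- noiseless
  tomo
}

#' Five-nucleoli reference cell phantom
#'
#' Convenience fixture mimicking the anatomy of an S-phase HeLa cell in an
#' RI tomogram: an ellipsoidal cell (cytoplasm, RI 1.349) containing a
#' nested nucleus (nucleoplasm, also 1.349), five spherical nucleoli
#' (RI 1.363) of diameter >= 2 um, and one small distractor sphere of the
#' same high RI but diameter < 2 um, emulating the small dense bodies that
#' are excluded from nucleolus counts by the 2 um rule.
#'
#' @param seed Integer seed for the additive RI noise.
#' @param noise_sd Gaussian RI noise SD; the default 0 gives a noiseless
#'   phantom whose band segmentation is exact.
#' @param voxel_size Voxel edge lengths `(dz, dy, dx)` in um.
#' @return An [ri_tomogram()] with ground-truth masks for `cytoplasm`,
#'   `nucleoplasm`, `nucleolus` (the five large spheres) and `distractor`.
#' @export
five_nucleoli_cell <- function(seed = 0L, noise_sd = 0,
                               voxel_size = c(0.356, 0.11, 0.11)) {
  grid_shape <- ceiling(c(14.0, 18.5, 18.5) / voxel_size)
  ctr <- grid_shape * voxel_size / 2
  nuc <- function(dz, dy, dx, r)
    compartment_spec("nucleolus", ctr + c(dz, dy, dx), r, 1.363)
  spec <- phantom_spec(
    grid_shape = grid_shape, voxel_size = voxel_size, medium_ri = 1.337,
    compartments = list(
      compartment_spec("cytoplasm",   ctr, c(5.0, 8.0, 8.0), 1.349),
      compartment_spec("nucleoplasm", ctr, c(3.4, 5.2, 5.2), 1.349),
      nuc(0,    2.9,  0,   1.5),
      nuc(0,   -2.9,  0,   1.4),
      nuc(0,    0,    2.9, 1.3),
      nuc(0,    0,   -2.9, 1.2),
      nuc(1.6,  0,    0,   1.1),
      compartment_spec("distractor", ctr + c(-1.8, 0, 0), 0.7, 1.363)
    ),
    noise_sd = noise_sd, seed = seed)
  generate_phantom(spec)
}
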