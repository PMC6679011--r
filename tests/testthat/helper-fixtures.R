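# shared fixture builders; everything is generated in code at test time

# small isotropic phantom with a single sphere
sphere_phantom <- function(r = 2, ri = 1.363, voxel = 0.1, pad = 0.5,
                           medium = 1.337, noise_sd = 0, seed = 0L) {
  half <- r + pad
  n <- ceiling(2 * half / voxel)
  ctr <- rep(n * voxel / 2, 3)
  generate_phantom(phantom_spec(
    grid_shape = rep(n, 3), voxel_size = rep(voxel, 3), medium_ri = medium,
    compartments = list(compartment_spec("sphere", ctr, r, ri)),
    noise_sd = noise_sd, seed = seed))
}

# nucleolus phantom with nested GC/DFC/FC shells in distinct RI sub-bands
shell_phantom <- function(voxel = 0.15) {
  n <- ceiling(7 / voxel)
  ctr <- rep(n * voxel / 2, 3)
  generate_phantom(phantom_spec(
    grid_shape = rep(n, 3), voxel_size = rep(voxel, 3), medium_ri = 1.337,
    compartments = list(
      compartment_spec("gc",  ctr, 3.0, 1.360),
      compartment_spec("dfc", ctr, 2.0, 1.372),
      compartment_spec("fc",  ctr, 1.0, 1.384))))
}

# fast low-cost simulation spec for module-level tests
quick_spec <- function(duration = 0.2, seed = 1L, ...) {
  sim_spec(duration = duration, seed = seed, ...)
}

# hand-built fit_result for characteristic_D contract tests
fake_fit <- function(D, y = NULL) {
  nc <- length(D)
  structure(list(n_components = nc, N = 2,
                 y = if (is.null(y)) rep(1 / nc, nc) else y,
                 tau_D = 0.2^2 / (4 * D), s = 5, triplet = NULL,
                 baseline = 0, D = D,
                 goodness = list(rss = 0, wrss = 0, red_chisq = 0,
                                 n_points = 50, n_par = 3),
                 converged = TRUE), class = "fit_result")
}
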