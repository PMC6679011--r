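#' Default pipeline configuration
#'
#' A complete, serialisable run configuration for [run_pipeline()]: a
#' five-nucleoli phantom, nucleolus/cytoplasm band set, the 2 um nucleolus
#' filter, and a short FCS simulate-and-fit study. Every stochastic step
#' derives its seed from the single top-level `seed`.
#'
#' @param seed Integer seed.
#' @return A named list (class `run_config`).
#' @export
default_config <- function(seed = 0L) {
  structure(list(
    seed = as.integer(seed),
    phantom = list(kind = "five_nucleoli", noise_sd = 0),
    bands = list(
      list(label = "nucleolus", lo = 1.356, hi = 1.370),
      list(label = "cytoplasm", lo = 1.343, hi = 1.356)),
    min_diameter = 2.0,
    fcs = list(
      components = list(list(D = 25, fraction = 1)),
      mean_particles_in_volume = 2,
      n_reps = 3, rep_duration = 2, dt = 2e-6,
      volume = list(w = 0.2, s = 5),
      model = "auto", compartment = "nucleolus"),
    timelapse = NULL
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param config A `run_config` list.
#' @param path YAML path.
#' @return `path` / the configuration.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(modifyList(unclass(default_config()), cfg), class = "run_config")
}

# 32-bit FNV-1a over a string, returned as 8 hex digits
fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime, in two 16-bit halves
    lo <- h %% 65536; hi <- (h %/% 65536) %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  fnv1a(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA))
}

# two-compartment phantom used by the time-lapse stage: a cell-sized
# cytoplasm ellipsoid with one nucleolus sphere, at prescribed RIs
simple_cell_phantom <- function(nucleolus_ri, cytoplasm_ri,
                                voxel_size = c(0.356, 0.11, 0.11)) {
  grid_shape <- ceiling(c(8, 10, 10) / voxel_size)
  ctr <- grid_shape * voxel_size / 2
  generate_phantom(phantom_spec(
    grid_shape, voxel_size, medium_ri = 1.337,
    compartments = list(
      compartment_spec("cytoplasm", ctr, c(3.0, 4.2, 4.2), cytoplasm_ri),
      compartment_spec("nucleolus", ctr, 1.6, nucleolus_ri))))
}

#' Run the full synthetic pipeline
#'
#' Executes phantom generation, band segmentation with nucleolus detection,
#' the FCS simulate / autocorrelate / fit arm, and (when configured) a
#' two-frame time-lapse comparison, writing every intermediate artifact and
#' a machine-readable manifest into `out_dir`. Deterministic for a fixed
#' `config$seed`; any stage failure halts with the stage named.
#'
#' @param config A `run_config` (see [default_config()], [read_config()]).
#' @param out_dir Output directory, created if absent.
#' @return Invisibly, a list with `nucleoli` (detected component table),
#'   `fit` (chosen FCS fit), `characteristic_D`, optional `timelapse`
#'   summary, and `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  artifacts <- character(0)
  seed <- as.integer(config$seed)

  tomo <- stage("phantom", {
    ph <- config$phantom
    t0 <- if (identical(ph$kind, "five_nucleoli"))
      five_nucleoli_cell(seed = seed, noise_sd = ph$noise_sd %||% 0)
    else stop("unknown phantom kind: ", ph$kind)
    p <- file.path(out_dir, "cell.tif")
    write_tomogram(t0, p)
    artifacts <<- c(artifacts, p, paste0(p, ".json"))
    t0
  })

  bands <- lapply(config$bands, function(b) ri_band(b$label, b$lo, b$hi))
  nucleoli <- stage("segment", {
    seg <- segment_by_bands(tomo, bands)
    det <- detect_nucleoli(seg, min_diameter = config$min_diameter)
    p <- file.path(out_dir, "components.csv")
    write.csv(seg$components, p, row.names = FALSE)
    pl <- file.path(out_dir, "labels.tif")
    write_labels(seg$labels, pl)
    artifacts <<- c(artifacts, p, pl)
    det
  })

  fcs <- stage("fcs", {
    fc <- config$fcs
    vol <- detection_volume(fc$volume$w, fc$volume$s)
    spec <- sim_spec(components = fc$components,
                     mean_particles_in_volume = fc$mean_particles_in_volume,
                     dt = fc$dt, seed = seed)
    traces <- replicate_traces(spec, vol, n_reps = fc$n_reps,
                               rep_duration = fc$rep_duration)
    curves <- lapply(traces, autocorrelate)
    avg <- average_fafs(curves)
    fit <- if (identical(fc$model, "auto"))
      select_model(avg, c(1L, 2L), w = vol$w)
    else fit_faf(avg, n_components = as.integer(fc$model), w = vol$w)
    pf <- file.path(out_dir, "fit.json"); write_fit(fit, pf)
    pc <- file.path(out_dir, "faf.csv"); write_faf(avg, pc)
    artifacts <<- c(artifacts, pf, pc)
    list(fit = fit, D = characteristic_D(fit, fc$compartment))
  })

  timelapse <- if (!is.null(config$timelapse)) stage("timelapse", {
    tl <- config$timelapse
    tomos <- lapply(seq_along(tl$nucleolus_ri), function(i)
      simple_cell_phantom(tl$nucleolus_ri[[i]], tl$cytoplasm_ri[[i]]))
    tl_bands <- list(
      ri_band("nucleolus", min(unlist(tl$nucleolus_ri)) - 0.004,
              max(unlist(tl$nucleolus_ri)) + 0.004),
      ri_band("cytoplasm", min(unlist(tl$cytoplasm_ri)) - 0.004,
              max(unlist(tl$cytoplasm_ri)) + 0.004))
    ts <- timelapse_summary(tomos, tl_bands,
                            interval_min = tl$interval_min %||% 10)
    p <- file.path(out_dir, "timelapse.csv")
    write.csv(ts$changes, p, row.names = FALSE)
    artifacts <<- c(artifacts, p)
    ts
  }) else NULL

  manifest <- list(
    package = "nucleophys",
    version = as.character(packageVersion("nucleophys")),
    r_version = as.character(getRversion()),
    seed = seed,
    config_hash = config_hash(config),
    n_nucleoli = nrow(nucleoli),
    characteristic_D_um2s = fcs$D,
    fold_ratio = if (!is.null(timelapse)) timelapse$fold_ratio else NULL,
    artifacts = basename(artifacts),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(nucleoli = nucleoli, fit = fcs$fit,
                 characteristic_D = fcs$D, timelapse = timelapse,
                 manifest = manifest, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
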