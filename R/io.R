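#' Write / read an RI tomogram as a TIFF stack with JSON sidecar
#'
#' The tomogram is stored as a 32-bit float multi-page TIFF (one page per z
#' slice, rows = y, columns = x). Because TIFF float storage here is defined
#' on `[0, 1]`, values are written with a fixed offset of 1.0 removed (RI
#' 1.337 is stored as 0.337); the offset is recorded in the sidecar and
#' restored on read. Voxel size, medium RI and grid shape live in a JSON
#' sidecar named `<path>.json`; reading without the sidecar is refused so
#' geometry can never be silently guessed.
#'
#' @param tomo An [ri_tomogram()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_tomogram <- function(tomo, path) {
  stopifnot(inherits(tomo, "ri_tomogram"))
  offset <- 1.0
  d <- dim(tomo$values)
  pages <- lapply(seq_len(d[1]), function(z)
    matrix(tomo$values[z, , ] - offset, nrow = d[2], ncol = d[3]))
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(voxel_size_um = tomo$voxel_size, medium_ri = tomo$medium_ri,
         ri_offset = offset, grid_shape = d, axis_order = "zyx",
         dtype = "float32"),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tomogram
#' @export
read_tomogram <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing sidecar metadata: expected '", sidecar,
         "' next to the TIFF (voxel_size_um, medium_ri, ri_offset)")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- suppressWarnings(tiff::readTIFF(path, all = TRUE, info = TRUE))
  bits <- attr(pages[[1]], "bits.per.sample")
  if (!is.null(bits) && bits != 32L)
    stop("expected 32-bit float TIFF, found ", bits,
         "-bit samples; refusing to cast")
  d <- as.integer(meta$grid_shape)
  values <- array(0, dim = d)
  for (z in seq_len(d[1])) values[z, , ] <- pages[[z]]
  values <- values + meta$ri_offset
  ri_tomogram(values, as.numeric(meta$voxel_size_um), meta$medium_ri)
}

#' Write / read a label map as an 8-bit TIFF
#'
#' Integer labels 0..255 stored one z slice per page.
#'
#' @param labels 3D integer array (z, y, x).
#' @param path Output TIFF path.
#' @return `path` / the label array.
#' @export
write_labels <- function(labels, path) {
  if (max(labels) > 255L) stop("more than 255 labels; 8-bit TIFF cannot hold them")
  d <- dim(labels)
  pages <- lapply(seq_len(d[1]), function(z)
    matrix(labels[z, , ] / 255, nrow = d[2], ncol = d[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- c(length(pages), dim(pages[[1]]))
  labels <- array(0L, dim = d)
  for (z in seq_len(d[1])) labels[z, , ] <- as.integer(round(pages[[z]] * 255))
  labels
}

#' Write / read an intensity trace as CSV
#'
#' Two columns, `time_s` and `counts`, uniform sampling.
#'
#' @param trace An [intensity_trace()].
#' @param path CSV path.
#' @return `path` / the trace.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "intensity_trace"))
  n <- length(trace$counts)
  write.csv(data.frame(time_s = (seq_len(n) - 1) * trace$dt,
                       counts = trace$counts),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  d <- read.csv(path)
  if (!all(c("time_s", "counts") %in% names(d)))
    stop("trace CSV needs columns time_s, counts")
  dts <- diff(d$time_s)
  if (length(dts) < 1 || any(abs(dts - dts[1]) > 1e-9 * dts[1] + 1e-15))
    stop("trace sampling is not uniform")
  intensity_trace(d$counts, dts[1])
}

#' Write / read an autocorrelation curve as CSV
#'
#' Columns `lag_s`, `g` and optional `sd`.
#'
#' @param curve A [faf_curve()].
#' @param path CSV path.
#' @return `path` / the curve.
#' @export
write_faf <- function(curve, path) {
  stopifnot(inherits(curve, "faf_curve"))
  d <- data.frame(lag_s = curve$lags, g = curve$g)
  if (!is.null(curve$sd)) d$sd <- curve$sd
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_faf
#' @export
read_faf <- function(path) {
  d <- read.csv(path)
  if (!all(c("lag_s", "g") %in% names(d)))
    stop("FAF CSV needs columns lag_s, g")
  faf_curve(d$lag_s, d$g, sd = d$sd)
}

#' Write a fit result as JSON
#' @param fit A `fit_result`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read / write an RI band set as YAML
#'
#' The YAML form is a list of maps with keys `label`, `lo`, `hi` and
#' optionally `color`.
#'
#' @param bands List of [ri_band()] objects.
#' @param path YAML path.
#' @return `path` / list of bands.
#' @export
write_bands <- function(bands, path) {
  if (inherits(bands, "ri_band")) bands <- list(bands)
  yaml::write_yaml(lapply(bands, function(b)
    Filter(Negate(is.null),
           list(label = b$label, lo = b$lo, hi = b$hi, color = b$color))),
    path)
  invisible(path)
}

#' @rdname write_bands
#' @export
read_bands <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(b) ri_band(b$label, b$lo, b$hi, b$color))
}
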