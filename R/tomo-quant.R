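#' Refractive-index band
#'
#' A labelled half-open RI interval `[lo, hi)` used to assign voxels to a
#' compartment for rendering and quantification, mirroring the
#' transfer-function ranges adjusted interactively on ODT instruments. The
#' half-open convention gives deterministic tie-breaking at shared
#' boundaries. Bands in a set may be disjoint ("discontinuous"), nested or
#' ordered; overlaps are resolved by list order.
#'
#' @param label Compartment name the band renders (e.g. `"nucleolus"`).
#' @param lo,hi Dimensionless RI bounds, `lo < hi`.
#' @param color Optional display tag.
#' @return An `ri_band` list.
#' @export
ri_band <- function(label, lo, hi, color = NULL) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi)
    stop("`lo` must be < `hi`")
  structure(list(label = label, lo = lo, hi = hi, color = color),
            class = "ri_band")
}

#' Median RI of a band
#'
#' Returns the midpoint `(lo + hi) / 2` of the rendering interval. This is
#' the instrument-side estimator of a compartment's mean RI: the median of
#' the RI range used for rendering stands in for the mean RI of the rendered
#' compartment. Compare with [voxel_mean_ri()], the direct voxel-wise
#' estimator; the two differ by at most half the band width for any mask
#' drawn from the band.
#'
#' @param band An [ri_band()].
#' @return The band midpoint (dimensionless RI).
#' @export
band_median_ri <- function(band) {
  stopifnot(inherits(band, "ri_band"))
  (band$lo + band$hi) / 2
}

#' Segment a tomogram by RI bands
#'
#' Assigns each voxel to the first band whose half-open interval `[lo, hi)`
#' contains its RI; voxels matching no band stay unlabelled (0). Connected
#' components are computed per band with 26-connectivity, and summarised by
#' voxel count, volume, equivalent spherical diameter and centroid.
#'
#' @param tomo An [ri_tomogram()].
#' @param bands List of [ri_band()] objects (non-empty). A single band may
#'   be given bare.
#' @return A `segmentation_result`: `labels` (integer array, 0 = unlabelled,
#'   i = i-th band), `components` (tibble with `band`, `component_id`,
#'   `n_voxels`, `volume_um3`, `equiv_diameter_um`, centroid coordinates in
#'   um), `band_set`, `voxel_size`.
#' @export
segment_by_bands <- function(tomo, bands) {
  stopifnot(inherits(tomo, "ri_tomogram"))
  if (inherits(bands, "ri_band")) bands <- list(bands)
  if (length(bands) == 0) stop("`bands` must be non-empty")
  stopifnot(all(vapply(bands, inherits, logical(1), "ri_band")))
  v <- tomo$values
  labels <- array(0L, dim = dim(v))
  # first matching band wins: paint in reverse order so earlier overwrite later
  for (i in rev(seq_along(bands))) {
    b <- bands[[i]]
    labels[v >= b$lo & v < b$hi] <- i
  }
  voxel_vol <- prod(tomo$voxel_size)
  comp_rows <- list()
  component_masks <- list()
  for (i in seq_along(bands)) {
    mask <- labels == i
    cc <- cpp_label3d(as.logical(mask), dim(v))
    ncc <- attr(cc, "n_components")
    component_masks[[i]] <- array(cc, dim = dim(v))
    if (ncc == 0) next
    idx <- which(cc > 0)
    lab <- cc[idx]
    coord <- arrayInd(idx, dim(v))
    nv <- tabulate(lab, ncc)
    cz <- tapply((coord[, 1] - 0.5) * tomo$voxel_size[1], lab, mean)
    cy <- tapply((coord[, 2] - 0.5) * tomo$voxel_size[2], lab, mean)
    cx <- tapply((coord[, 3] - 0.5) * tomo$voxel_size[3], lab, mean)
    vol <- nv * voxel_vol
    comp_rows[[i]] <- tibble::tibble(
      band = bands[[i]]$label, band_index = i,
      component_id = seq_len(ncc), n_voxels = nv,
      volume_um3 = vol,
      equiv_diameter_um = (6 * vol / pi)^(1 / 3),
      centroid_z = as.numeric(cz), centroid_y = as.numeric(cy),
      centroid_x = as.numeric(cx))
  }
  components <- if (length(comp_rows)) dplyr::bind_rows(comp_rows)
                else tibble::tibble(band = character(), band_index = integer(),
                                    component_id = integer(), n_voxels = integer(),
                                    volume_um3 = numeric(),
                                    equiv_diameter_um = numeric(),
                                    centroid_z = numeric(), centroid_y = numeric(),
                                    centroid_x = numeric())
  structure(list(labels = labels, components = components,
                 component_labels = component_masks,
                 band_set = bands, voxel_size = tomo$voxel_size),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d band(s), %d connected component(s)\n",
              length(x$band_set), nrow(x$components)))
  print(x$components)
  invisible(x)
}

#' Detect nucleoli with the minimum-size rule
#'
#' Filters the connected components of the nucleolus band by equivalent
#' spherical diameter: small high-density bodies below the cutoff are not
#' counted as nucleoli. The default cutoff is 2 um, interpreted as a
#' diameter (equivalent spherical diameter computed from the component
#' voxel volume).
#'
#' @param seg A [segment_by_bands()] result containing a band labelled
#'   `band` (default `"nucleolus"`).
#' @param min_diameter Minimum equivalent spherical diameter in um;
#'   default 2. Set 0 to disable the filter.
#' @param band Label of the nucleolus band.
#' @return Tibble of retained components, sorted by volume descending.
#' @export
detect_nucleoli <- function(seg, min_diameter = 2.0, band = "nucleolus") {
  stopifnot(inherits(seg, "segmentation_result"))
  labs <- vapply(seg$band_set, `[[`, character(1), "label")
  if (!band %in% labs)
    stop(sprintf("segmentation has no band labelled '%s'", band))
  comps <- seg$components
  out <- comps[comps$band == band & comps$equiv_diameter_um >= min_diameter, ,
               drop = FALSE]
  out[order(out$volume_um3, decreasing = TRUE), ]
}

#' Voxel-wise mean RI within a mask
#'
#' Direct arithmetic mean of the RI values under a mask; the oracle
#' counterpart of the instrument-style [band_median_ri()] estimator.
#'
#' @param tomo An [ri_tomogram()].
#' @param mask Logical array matching the tomogram, with at least one voxel.
#' @return Mean RI (dimensionless).
#' @export
voxel_mean_ri <- function(tomo, mask) {
  stopifnot(inherits(tomo, "ri_tomogram"))
  if (!any(mask)) stop("empty mask")
  mean(tomo$values[mask])
}

#' Volume of a mask or component
#'
#' Voxel count times voxel volume, in um^3.
#'
#' @param x A logical mask array, a voxel count, or one row of a
#'   [segment_by_bands()] component table.
#' @param voxel_size Voxel edge lengths `(dz, dy, dx)` in um (not needed for
#'   a component row, which already carries its volume).
#' @return Volume in um^3.
#' @export
compute_volume <- function(x, voxel_size = NULL) {
  if (is.data.frame(x)) return(sum(x$volume_um3))
  n <- if (is.logical(x)) sum(x) else as.numeric(x)
  if (is.null(voxel_size)) stop("`voxel_size` required for a mask or count")
  n * prod(voxel_size)
}

#' Percent change between two values
#'
#' `100 * (after - before) / before`, the change ratio used for time-lapse
#' RI and volume comparisons; the denominator is the earlier time point.
#'
#' @param before,after Numeric values; `before` must be nonzero.
#' @return Percent change.
#' @export
percent_change <- function(before, after) {
  if (any(before == 0)) stop("zero baseline: percent change undefined")
  100 * (after - before) / before
}

#' Time-lapse summary of banded compartments
#'
#' Tracks, frame by frame, each band's voxel-mean RI, band-median RI and
#' volume over an ordered series of tomograms of one cell, then reports
#' endpoint percent changes (computed on the voxel-mean RI and on volume)
#' and the fold-ratio of the nucleolar RI change to the cytoplasmic RI
#' change — the headline contrast of time-lapse experiments in which the
#' nucleolus concentrates while the cytoplasm barely changes.
#'
#' @param tomos Ordered list of [ri_tomogram()] objects (>= 2) of the same
#'   cell on a common grid.
#' @param bands Non-empty list of [ri_band()] objects applied to every frame.
#' @param interval_min Acquisition interval between frames in minutes.
#' @param nucleolus_band,reference_band Labels of the bands compared in the
#'   fold-ratio (defaults `"nucleolus"` and `"cytoplasm"`).
#' @return A `timelapse_summary` list: `frames` (tibble of per-frame,
#'   per-band measurements), `changes` (tibble of endpoint percent changes
#'   per band), and `fold_ratio` (nucleolar over reference RI percent
#'   change; `NA` when either band is absent).
#' @export
timelapse_summary <- function(tomos, bands, interval_min = 10,
                              nucleolus_band = "nucleolus",
                              reference_band = "cytoplasm") {
  if (length(tomos) < 2) stop("need at least 2 time points")
  if (inherits(bands, "ri_band")) bands <- list(bands)
  if (length(bands) == 0) stop("band set must be non-empty")
  frames <- list()
  for (t in seq_along(tomos)) {
    tomo <- tomos[[t]]
    seg <- segment_by_bands(tomo, bands)
    for (i in seq_along(bands)) {
      mask <- seg$labels == i
      frames[[length(frames) + 1L]] <- tibble::tibble(
        frame = t, time_min = (t - 1) * interval_min,
        band = bands[[i]]$label,
        voxel_mean_ri = if (any(mask)) mean(tomo$values[mask]) else NA_real_,
        band_median_ri = band_median_ri(bands[[i]]),
        volume_um3 = sum(mask) * prod(tomo$voxel_size))
    }
  }
  frames <- dplyr::bind_rows(frames)
  changes <- dplyr::bind_rows(lapply(unique(frames$band), function(lab) {
    d <- frames[frames$band == lab & frames$frame %in% c(1L, length(tomos)), ]
    d <- d[order(d$frame), ]
    rb <- d$voxel_mean_ri[1]; ra <- d$voxel_mean_ri[nrow(d)]
    vb <- d$volume_um3[1]; va <- d$volume_um3[nrow(d)]
    tibble::tibble(
      band = lab, ri_before = rb, ri_after = ra,
      ri_pct_change = if (is.finite(rb) && rb != 0) 100 * (ra - rb) / rb
                      else NA_real_,
      volume_before_um3 = vb, volume_after_um3 = va,
      volume_pct_change = if (is.finite(vb) && vb > 0) 100 * (va - vb) / vb
                          else NA_real_)
  }))
  pc <- function(lab) {
    v <- changes$ri_pct_change[changes$band == lab]
    if (length(v) == 1 && is.finite(v)) v else NA_real_
  }
  fold <- pc(nucleolus_band) / pc(reference_band)
  structure(list(frames = frames, changes = changes, fold_ratio = fold),
            class = "timelapse_summary")
}

#' @export
print.timelapse_summary <- function(x, ...) {
  cat("<timelapse_summary>\n")
  print(x$changes)
  cat(sprintf("fold-ratio of RI percent change (nucleolus / reference): %.3g\n",
              x$fold_ratio))
  invisible(x)
}
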