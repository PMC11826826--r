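#' Vessel-isolation parameters
#'
#' Parameters of the filter cascade that isolates arterial voxels from the
#' difference series. Defaults follow common practice where the protocol
#' leaves them open; all are recorded in the mask provenance.
#'
#' @param frangi A [frangi_params()].
#' @param threshold Binarization threshold as a fraction of each directional
#'   response's volume maximum.
#' @param min_size Area-opening minimum component size (voxels). Like the
#'   per-subject tuning it replaces, this typically needs adjustment per
#'   dataset.
#' @param connectivity Component connectivity (6, 18 or 26).
#' @param fwhm_voxels Bilateral-smoothing FWHM per axis in voxels.
#' @param range_sigma Bilateral range sd on the binary guide.
#' @return A list of class `isolation_params`.
#' @export
isolation_params <- function(frangi = frangi_params(c = "auto-volume"),
                             threshold = 0.05,
                             min_size = 50, connectivity = 26,
                             fwhm_voxels = c(5, 5, 4), range_sigma = 0.1) {
  structure(list(frangi = frangi, threshold = threshold,
                 min_size = min_size, connectivity = connectivity,
                 fwhm_voxels = fwhm_voxels, range_sigma = range_sigma),
            class = "isolation_params")
}

#' Isolate arterial voxels from a 4D-MRA label/control series
#'
#' Runs the full pre-processing cascade: pairwise subtraction, brain
#' masking, temporal-maximum image, slice-wise 2D Frangi vesselness in the
#' three cartesian planes, binarization and intersection of the directional
#' masks, area opening, restriction to the brain mask, and mask-guided joint
#' bilateral smoothing of the difference series.
#'
#' @param label,control 4D arrays (x, y, z, time).
#' @param brain_mask Logical 3D array.
#' @param times Label durations in ms.
#' @param voxel_dims Voxel sizes in mm.
#' @param params An [isolation_params()].
#' @return List with `mask` (final [vessel_mask()], provenance of every
#'   stage), `series` (smoothed [inflow_series()]), `raw_series` (unsmoothed
#'   difference series) and `temporal_max`.
#' @export
isolate_vessels <- function(label, control, brain_mask, times,
                            voxel_dims = c(1, 1, 1),
                            params = isolation_params()) {
  series <- pairwise_subtract(label, control, times = times,
                              voxel_dims = voxel_dims)
  series <- apply_brain_mask(series, brain_mask)
  tmax <- temporal_max(series)
  planes <- c("XY", "YZ", "ZX")
  responses <- lapply(planes, function(p)
    frangi_vesselness(tmax, p, params$frangi))
  mask <- binarize_and_intersect(responses, threshold = params$threshold)
  mask <- area_open(mask, min_size = params$min_size,
                    connectivity = params$connectivity)
  final <- mask$mask & as_mask_array(brain_mask)
  prov <- c(mask$provenance,
            list(frangi = unclass(params$frangi),
                 planes = planes,
                 brain_mask_applied = TRUE,
                 smoothing = list(fwhm_voxels = params$fwhm_voxels,
                                  range_sigma = params$range_sigma,
                                  kernel_extent_mm =
                                    kernel_extent_mm(params$fwhm_voxels,
                                                     voxel_dims))))
  mask <- vessel_mask(final, provenance = prov)
  smoothed <- guided_bilateral_smooth(series, mask,
                                      fwhm_voxels = params$fwhm_voxels,
                                      range_sigma = params$range_sigma)
  list(mask = mask, series = smoothed, raw_series = series,
       temporal_max = tmax)
}
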