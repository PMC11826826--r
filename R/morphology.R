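#' Vessel mask container
#'
#' A binary 3D mask of retained arterial voxels together with a provenance
#' record of the filter parameters that produced it.
#'
#' @param mask Logical 3D array.
#' @param provenance List describing the producing step and its parameters.
#' @return An object of class `vessel_mask`.
#' @export
vessel_mask <- function(mask, provenance = list()) {
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3D array", call. = FALSE)
  structure(list(mask = array(as.logical(mask), dim = dim(mask)),
                 provenance = provenance), class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("vessel mask: %d of %d voxels retained\n",
              sum(x$mask), length(x$mask)))
  invisible(x)
}

as_mask_array <- function(mask) {
  if (inherits(mask, "vessel_mask")) return(mask$mask)
  if (is.logical(mask) && length(dim(mask)) == 3L) return(mask)
  if (is.numeric(mask) && length(dim(mask)) == 3L) {
    return(array(mask != 0, dim = dim(mask)))
  }
  stop("expected a vessel_mask or a 3D logical array", call. = FALSE)
}

#' Label connected components of a 3D binary mask
#'
#' @param mask Logical 3D array (or [vessel_mask()]).
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (full
#'   neighbourhood).
#' @return Integer 3D array: 0 for background, components numbered from 1 in
#'   scan order.
#' @export
label_components <- function(mask, connectivity = 26) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  }
  m <- as_mask_array(mask)
  .cc_label(as.vector(m), dim(m), connectivity)
}

#' Morphological area opening
#'
#' Removes connected components with fewer than `min_size` voxels; all larger
#' components are untouched. Used to suppress small blob-like structures
#' (e.g. pulsatility artifacts near the brain base) that survive the
#' vesselness intersection.
#'
#' @param mask Logical 3D array or [vessel_mask()].
#' @param min_size Minimum component size in voxels (>= 1).
#' @param connectivity 6, 18 or 26.
#' @return A [vessel_mask()] (provenance extended when the input carried one).
#' @export
#' @examples
#' m <- array(FALSE, c(8, 8, 8)); m[2:6, 4, 4] <- TRUE; m[8, 8, 8] <- TRUE
#' sum(area_open(m, min_size = 3)$mask)
area_open <- function(mask, min_size = 50, connectivity = 26) {
  if (min_size < 1) stop("`min_size` must be >= 1", call. = FALSE)
  m <- as_mask_array(mask)
  lab <- label_components(m, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep_labels <- which(sizes >= min_size)
  out <- array(lab %in% keep_labels, dim = dim(m))
  prov <- if (inherits(mask, "vessel_mask")) mask$provenance else list()
  prov <- c(prov, list(area_open = list(min_size = min_size,
                                        connectivity = connectivity,
                                        removed_components = sum(sizes < min_size))))
  vessel_mask(out, provenance = prov)
}

# binary dilation by r steps of the 26-neighbourhood (used for the
# mask-adjacent background ring in the automatic noise floor)
dilate_mask <- function(mask, r = 1L) {
  m <- as_mask_array(mask)
  for (i in seq_len(r)) {
    # sequential per-axis dilation = one step of the 26-neighbourhood box
    for (ax in 1:3) {
      m <- m | shift_replicate(m, 1L, ax) | shift_replicate(m, -1L, ax)
    }
  }
  m
}
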