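#' Inflow difference series
#'
#' Container for a 4D stack of label-control difference volumes: one 3D
#' volume per label duration, with voxel geometry and an optional brain mask.
#'
#' @param data 4D numeric array (x, y, z, time).
#' @param times Label durations in ms; length must equal the 4th-axis extent
#'   and be strictly increasing.
#' @param voxel_dims Voxel sizes in mm.
#' @param brain_mask Optional logical 3D array on the same grid.
#' @return An object of class `inflow_series`.
#' @export
inflow_series <- function(data, times, voxel_dims = c(1, 1, 1),
                          brain_mask = NULL) {
  if (length(dim(data)) != 4L) stop("`data` must be a 4D array", call. = FALSE)
  times <- check_times(times)
  if (dim(data)[4] != length(times)) {
    stop(sprintf("4th axis has %d volumes but %d times were given",
                 dim(data)[4], length(times)), call. = FALSE)
  }
  voxel_dims <- check_voxel_dims(voxel_dims)
  if (!is.null(brain_mask)) {
    if (!identical(dim(brain_mask), dim(data)[1:3])) {
      stop("brain mask grid differs from the series grid", call. = FALSE)
    }
    brain_mask <- array(as.logical(brain_mask), dim = dim(brain_mask))
  }
  structure(list(data = data, times = times, voxel_dims = voxel_dims,
                 brain_mask = brain_mask), class = "inflow_series")
}

#' @export
print.inflow_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("inflow series: %d x %d x %d voxels, %d time points (%g-%g ms)\n",
              d[1], d[2], d[3], d[4], min(x$times), max(x$times)))
  invisible(x)
}

#' Pairwise label/control subtraction
#'
#' Forms the inflow difference series `control - label` per time point; with
#' this sign, inflowing labelled blood appears as positive signal.
#'
#' @param label,control 4D arrays of identical shape (x, y, z, time).
#' @param times Label durations in ms.
#' @param voxel_dims Voxel sizes in mm.
#' @param brain_mask Optional logical 3D array.
#' @return An [inflow_series()].
#' @export
#' @examples
#' lab <- array(0, c(4, 4, 4, 2)); ctl <- lab + 5
#' s <- pairwise_subtract(lab, ctl, times = c(100, 200))
#' range(s$data)
pairwise_subtract <- function(label, control, times,
                              voxel_dims = c(1, 1, 1), brain_mask = NULL) {
  if (!identical(dim(label), dim(control))) {
    stop(sprintf("label and control shapes differ: (%s) vs (%s)",
                 paste(dim(label), collapse = ","),
                 paste(dim(control), collapse = ",")), call. = FALSE)
  }
  inflow_series(control - label, times = times, voxel_dims = voxel_dims,
                brain_mask = brain_mask)
}

#' Apply a brain mask to an inflow series
#'
#' Zeroes all voxels outside the mask at every time point and records the
#' mask on the series.
#'
#' @param series An [inflow_series()].
#' @param brain_mask Logical 3D array on the series grid.
#' @return The masked [inflow_series()].
#' @export
apply_brain_mask <- function(series, brain_mask) {
  stopifnot(inherits(series, "inflow_series"))
  if (!identical(dim(brain_mask), dim(series$data)[1:3])) {
    stop("brain mask grid differs from the series grid", call. = FALSE)
  }
  keep <- array(as.logical(brain_mask), dim = dim(brain_mask))
  d <- series$data
  nt <- dim(d)[4]
  for (ti in seq_len(nt)) {
    v <- d[, , , ti]
    v[!keep] <- 0
    d[, , , ti] <- v
  }
  inflow_series(d, series$times, series$voxel_dims, brain_mask = keep)
}

#' Temporal maximum image
#'
#' Voxelwise maximum of the difference series over time: each vessel appears
#' at its brightest, which maximizes distal-vessel contrast for mask
#' building.
#'
#' @param series An [inflow_series()].
#' @return 3D numeric array.
#' @export
temporal_max <- function(series) {
  stopifnot(inherits(series, "inflow_series"))
  nt <- dim(series$data)[4]
  out <- series$data[, , , 1]
  for (ti in seq_len(nt)[-1]) out <- pmax(out, series$data[, , , ti])
  out
}
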