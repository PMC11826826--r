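#' Read a 3D NIfTI volume
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return Numeric array with the `RNifti` image attached as attribute
#'   `"reference"` (carrying the affine) and `"voxel_dims"` in mm.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  attr(arr, "reference") <- img
  attr(arr, "voxel_dims") <- RNifti::pixdim(img)[1:3]
  arr
}

#' Write a 3D/4D volume as NIfTI
#'
#' @param vol Numeric or logical array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param reference Optional `RNifti` image or array with a `"reference"`
#'   attribute: its header (affine, voxel sizes) is carried over unchanged.
#' @param voxel_dims Voxel sizes in mm, used when no reference is given.
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path, reference = NULL, voxel_dims = NULL) {
  if (is.null(reference)) reference <- attr(vol, "reference")
  if (!is.null(attr(reference, "reference"))) {
    reference <- attr(reference, "reference")
  }
  v <- vol
  if (is.logical(v)) v <- array(as.integer(v), dim = dim(v))
  attributes(v) <- list(dim = dim(v))
  img <- if (!is.null(reference)) {
    RNifti::asNifti(v, reference = reference)
  } else {
    RNifti::asNifti(v)
  }
  if (is.null(reference) && !is.null(voxel_dims)) {
    RNifti::pixdim(img) <- c(voxel_dims, rep(1, length(dim(v)) - 3L))[seq_along(dim(v))]
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label/control 4D-MRA series pair
#'
#' Reads two 4D NIfTI files (one volume per label duration). The number of
#' volumes must match the number of configured label durations, and the two
#' files must agree in shape and voxel geometry; time metadata lives in the
#' configuration, not in NIfTI headers.
#'
#' @param label_path,control_path Paths to 4D NIfTI files.
#' @param times Label durations in ms (default the eight-point protocol).
#' @return List with 4D arrays `label` and `control`, `times`, `voxel_dims`
#'   and the label image as `reference`.
#' @export
read_series <- function(label_path, control_path,
                        times = default_label_durations()) {
  times <- check_times(times)
  rd <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 4L) {
      stop(sprintf("%s: expected a 4D NIfTI, got %d dimensions",
                   path, length(dim(img))), call. = FALSE)
    }
    if (dim(img)[4] != length(times)) {
      stop(sprintf("%s: has %d volumes but %d label durations are configured",
                   path, dim(img)[4], length(times)), call. = FALSE)
    }
    img
  }
  li <- rd(label_path); ci <- rd(control_path)
  if (!identical(dim(li), dim(ci))) {
    stop("label and control series have different shapes", call. = FALSE)
  }
  vd_l <- RNifti::pixdim(li)[1:3]; vd_c <- RNifti::pixdim(ci)[1:3]
  if (max(abs(vd_l - vd_c)) > 1e-4) {
    stop("label and control series have different voxel sizes", call. = FALSE)
  }
  list(label = array(as.numeric(li), dim = dim(li)),
       control = array(as.numeric(ci), dim = dim(ci)),
       times = times, voxel_dims = as.numeric(vd_l), reference = li)
}

#' Write a label/control series pair as 4D NIfTI
#'
#' @param sim List with `label`, `control` and `voxel_dims` (e.g. from
#'   [simulate_inflow_series()]).
#' @param label_path,control_path Output paths.
#' @param reference Optional header template.
#' @return The two paths, invisibly.
#' @export
write_series <- function(sim, label_path, control_path, reference = NULL) {
  write_volume(sim$label, label_path, reference = reference,
               voxel_dims = sim$voxel_dims)
  write_volume(sim$control, control_path, reference = reference,
               voxel_dims = sim$voxel_dims)
  invisible(c(label_path, control_path))
}

#' Write/read a regional table as CSV
#'
#' @param table A `regional_table` or delta table.
#' @param path CSV path.
#' @return The path (write) or the table (read), invisibly for write.
#' @export
write_regional_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_regional_table
#' @export
read_regional_table <- function(path) {
  tab <- read.csv(path)
  class(tab) <- c("regional_table", "data.frame")
  tab
}

#' Normalize transit-time units to milliseconds
#'
#' Heuristic for tissue transit time inputs: maps with values below 20 are
#' interpreted as seconds and converted to ms (logged); otherwise values are
#' taken as ms already. Override by passing `units`.
#'
#' @param volume Numeric array of transit times.
#' @param units `"auto"` (default), `"ms"` or `"s"`.
#' @return The volume in ms, with attribute `"units_assumed"`.
#' @export
normalize_time_units <- function(volume, units = c("auto", "ms", "s")) {
  units <- match.arg(units)
  if (units == "auto") {
    mx <- suppressWarnings(max(volume, na.rm = TRUE))
    units <- if (is.finite(mx) && mx < 20) "s" else "ms"
    message(sprintf("transit-time units auto-detected as %s (max value %.3g)",
                    units, mx))
  }
  out <- if (units == "s") volume * 1000 else volume
  attr(out, "units_assumed") <- units
  out
}
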