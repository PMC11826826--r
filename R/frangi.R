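#' Frangi filter parameters
#'
#' @param scales Gaussian scales in pixels (sd of the derivative kernels);
#'   non-empty, all positive. The final response is the maximum over scales.
#' @param beta Blobness sensitivity (> 0): smaller values penalize blob-like
#'   structures more strongly.
#' @param c Structureness sensitivity in signal units, or `"auto"` (default)
#'   for half the per-slice maximum Hessian norm, or `"auto-volume"` for half
#'   the volume-wide maximum. The per-slice variant adapts to slice-wise
#'   signal variation but saturates in slices that contain no vessels, where
#'   it renormalizes pure noise to full strength; the volume variant keeps
#'   the structureness scale tied to the brightest vessels and suppresses
#'   noise in vessel-free slices, and is what the pipeline default uses.
#' @param gamma Scale-normalization exponent: second derivatives are
#'   multiplied by `sigma^gamma`. The default 1.5 is the ridge-detection
#'   normalization for which a Gaussian ridge responds maximally at the scale
#'   equal to its profile sd; `gamma = 2` gives the classical normalization
#'   (maximal response at sqrt(2) times the profile sd).
#' @param bright_on_dark If `TRUE` (default), enhance bright tubular
#'   structures on a dark background (inflow signal in difference images).
#' @return A list of class `frangi_params`.
#' @export
frangi_params <- function(scales = c(1, 1.5, 2, 3), beta = 0.5, c = "auto",
                          gamma = 1.5, bright_on_dark = TRUE) {
  if (length(scales) == 0L || any(scales <= 0)) {
    stop("`scales` must be non-empty and positive", call. = FALSE)
  }
  if (beta <= 0) stop("`beta` must be > 0", call. = FALSE)
  if (!identical(c, "auto") && !identical(c, "auto-volume") &&
      (!is.numeric(c) || c <= 0)) {
    stop("`c` must be \"auto\", \"auto-volume\" or a positive number",
         call. = FALSE)
  }
  structure(list(scales = as.numeric(scales), beta = beta, c = c,
                 gamma = gamma, bright_on_dark = isTRUE(bright_on_dark)),
            class = "frangi_params")
}

# Gaussian kernel and its exact derivatives sampled on an integer grid;
# the smoothing kernel is normalized to unit sum
gauss_kernels <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  g2 <- ((x^2 - sigma^2) / sigma^4) * g
  g2 <- g2 - sum(g2) / length(g2)   # exact zero response on constants
  list(g = g, g1 = (-x / sigma^2) * g, g2 = g2, offsets = x)
}

# shift a 3D array by k voxels along an axis with edge replication
shift_replicate <- function(a, k, axis) {
  if (k == 0L) return(a)
  n <- dim(a)[axis]
  idx <- pmin(pmax(seq_len(n) + k, 1L), n)
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# correlate a 3D array with a centered 1D kernel along one axis
# (replicate padding); kernels here are symmetric or antisymmetric, and the
# antisymmetric case is handled by the exact sampled derivative kernels
axis_convolve <- function(a, kernel, offsets, axis) {
  out <- array(0, dim = dim(a))
  for (j in seq_along(kernel)) {
    if (kernel[j] != 0) out <- out + kernel[j] * shift_replicate(a, offsets[j], axis)
  }
  out
}

#' Slice-wise 2D Frangi vesselness
#'
#' Computes the 2D Frangi vesselness of every slice of a volume in one
#' cartesian plane. For each scale, scale-normalized Hessian eigenvalues
#' `|l1| <= |l2|` are computed from Gaussian-derivative convolutions within
#' the plane; the vesselness is zero where `l2 > 0` (bright structures have
#' negative principal curvature) and otherwise
#' `exp(-R_B^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))` with blobness
#' `R_B = l1 / l2` and structureness `S = sqrt(l1^2 + l2^2)`. The output is
#' the maximum over scales and lies in `[0, 1]`.
#'
#' @param volume 3D numeric array with finite values.
#' @param plane `"XY"`, `"YZ"` or `"ZX"`: the plane in which the 2D Hessian
#'   is taken (slices stacked along the remaining axis).
#' @param params A [frangi_params()].
#' @return 3D numeric array of vesselness values in `[0, 1]`.
#' @export
#' @examples
#' v <- array(0, c(16, 16, 4)); v[8, , ] <- 1   # line along y in every slice
#' f <- frangi_vesselness(v, "XY", frangi_params(scales = 1))
#' range(f)
frangi_vesselness <- function(volume, plane = c("XY", "YZ", "ZX"),
                              params = frangi_params()) {
  plane <- match.arg(plane)
  if (any(!is.finite(volume))) stop("volume must be finite-valued", call. = FALSE)
  if (length(dim(volume)) != 3L) stop("volume must be 3D", call. = FALSE)
  axes <- switch(plane, XY = c(1L, 2L), YZ = c(2L, 3L), ZX = c(3L, 1L))
  slice_axis <- setdiff(1:3, axes)
  a1 <- axes[1]; a2 <- axes[2]

  # first pass: scale-normalized eigenvalues per scale
  per_scale <- lapply(params$scales, function(sigma) {
    k <- gauss_kernels(sigma)
    norm <- sigma^params$gamma
    H11 <- axis_convolve(axis_convolve(volume, k$g2, k$offsets, a1),
                         k$g, k$offsets, a2) * norm
    H22 <- axis_convolve(axis_convolve(volume, k$g2, k$offsets, a2),
                         k$g, k$offsets, a1) * norm
    H12 <- axis_convolve(axis_convolve(volume, k$g1, k$offsets, a1),
                         k$g1, k$offsets, a2) * norm
    tr2 <- (H11 + H22) / 2
    disc <- sqrt(((H11 - H22) / 2)^2 + H12^2)
    e1 <- tr2 - disc
    e2 <- tr2 + disc
    swap <- abs(e1) > abs(e2)
    l1 <- ifelse(swap, e2, e1)   # |l1| <= |l2|
    l2 <- ifelse(swap, e1, e2)
    if (!params$bright_on_dark) { l1 <- -l1; l2 <- -l2 }
    list(l1 = l1, l2 = l2, S = sqrt(l1^2 + l2^2))
  })

  # structureness scale c: shared across scales (so the scale of maximal
  # response is meaningful), per slice or per volume when automatic
  if (identical(params$c, "auto")) {
    smax_all <- Reduce(pmax, lapply(per_scale, `[[`, "S"))
    smax <- apply(smax_all, slice_axis, max)
    cvol <- array(0, dim = dim(volume))
    for (s in seq_along(smax)) {
      cvol <- assign_slice(cvol, slice_axis, s, smax[s] / 2)
    }
  } else if (identical(params$c, "auto-volume")) {
    smax_all <- Reduce(pmax, lapply(per_scale, `[[`, "S"))
    cvol <- array(max(smax_all) / 2, dim = dim(volume))
  } else {
    cvol <- array(params$c, dim = dim(volume))
  }

  # curvature at the level of floating-point residue of the input scale is
  # not structure; without this floor the automatic c would renormalize
  # numerical dust on constant images to full strength
  s_floor <- 1e-8 * max(abs(volume))

  best <- array(0, dim = dim(volume))
  for (ps in per_scale) {
    rb2 <- ifelse(ps$l2 != 0, (ps$l1 / ps$l2)^2, 0)
    v <- exp(-rb2 / (2 * params$beta^2)) *
      (1 - exp(-ps$S^2 / (2 * cvol^2)))
    v[ps$l2 >= 0] <- 0
    v[ps$S <= s_floor] <- 0
    v[cvol <= 0] <- 0
    v[!is.finite(v)] <- 0
    best <- pmax(best, v)
  }
  best
}

# assign a constant to one slice along an arbitrary axis
assign_slice <- function(a, axis, i, value) {
  switch(axis,
         { a[i, , ] <- value; a },
         { a[, i, ] <- value; a },
         { a[, , i] <- value; a })
}

#' Binarize three directional vesselness volumes and intersect
#'
#' Each directional response is binarized at a fraction of its own volume
#' maximum; the final vessel mask keeps only voxels common to all three
#' directional masks, which suppresses blob-like structures that respond in
#' fewer orientations.
#'
#' @param responses List of three co-registered 3D vesselness arrays.
#' @param threshold Fraction of each volume's maximum response in (0, 1).
#' @return A [vessel_mask()] whose provenance records the threshold and the
#'   per-volume maxima.
#' @export
binarize_and_intersect <- function(responses, threshold = 0.05) {
  if (!is.list(responses) || length(responses) != 3L) {
    stop("`responses` must be a list of three vesselness volumes", call. = FALSE)
  }
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly between 0 and 1", call. = FALSE)
  }
  dims <- lapply(responses, dim)
  if (!identical(dims[[1]], dims[[2]]) || !identical(dims[[1]], dims[[3]])) {
    stop("vesselness volumes are not co-registered", call. = FALSE)
  }
  maxima <- vapply(responses, max, numeric(1))
  masks <- mapply(function(r, mx) r >= threshold * mx, responses, maxima,
                  SIMPLIFY = FALSE)
  final <- masks[[1]] & masks[[2]] & masks[[3]]
  vessel_mask(final, provenance = list(step = "binarize_and_intersect",
                                       threshold = threshold,
                                       response_maxima = maxima))
}
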