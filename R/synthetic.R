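#' Simulation configuration for synthetic 4D-MRA
#'
#' Bundles the geometry, timing, signal and noise parameters used by the
#' synthetic data generator. Defaults emulate the statistical structure the
#' pipeline assumes: a branching arterial tree entering at the most caudal
#' slice, breakpoint times increasing linearly with path length at a
#' caudal-to-cranial gradient of a few ms/mm, saturating inflow signal with
#' additive Gaussian subtraction noise, and blob-like pulsatility artifacts
#' near the brain base.
#'
#' @param shape Integer triplet, volume dimensions in voxels (each >= 16).
#' @param voxel_dims Voxel sizes in mm (x, y, z).
#' @param times Label durations in ms, strictly increasing; default is the
#'   eight-point protocol of [default_label_durations()].
#' @param gradient Breakpoint increase per mm of vessel path length (ms/mm).
#' @param b0 Breakpoint at the tree inlet (ms).
#' @param h0 Half-rise time of the saturation model (ms).
#' @param m0 Saturation level at the inlet (arbitrary signal units). Distal
#'   voxels are fainter (see `m_taper`), mirroring the limited visibility of
#'   distal vessels that bounds the measurable maximum transit time.
#' @param m_taper Fractional amplitude loss per reference path length (one
#'   cranio-caudal volume extent); amplitude is floored at 30% of `m0`.
#' @param noise_sigma Standard deviation of the additive Gaussian noise on the
#'   difference signal (same units as `m0`); SNR is `m0 / noise_sigma`.
#' @param background_level Control-image background intensity inside the brain.
#' @param blob_count Number of ellipsoidal non-vessel artifacts placed within
#'   the 8 most caudal slices (to exercise blob suppression and area opening).
#' @param n_trunks Number of independent tree trunks seeded at the inlet slice.
#' @param branch_prob Per-step probability that a walker spawns a branch.
#' @param lateral_prob Per-axis probability of a lateral step; kept small so
#'   vessel paths are nearly straight and path length per mm of caudal-cranial
#'   distance stays close to 1.
#' @param vessel_radius In-plane vessel radius in voxels: each centerline
#'   voxel is expanded to a disk of this radius with a Gaussian intensity
#'   cross-section (sd `profile_sd`), emulating the several-voxel diameter of
#'   the large and medium cerebral arteries at angiographic resolution.
#'   Cross-section voxels inherit the centerline's timing parameters.
#' @param profile_sd Gaussian cross-section sd in voxels.
#' @param variant Saturation-model branch used by the forward simulation,
#'   `"continuous"` (shifted, default) or `"literal"`; see
#'   [piecewise_saturation()].
#' @param seed Integer seed; identical configurations and seeds reproduce
#'   byte-identical outputs.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(shape = c(32, 32, 32), seed = 7)
#' cfg$times
sim_config <- function(shape = c(64, 64, 64),
                       voxel_dims = c(1, 1, 1),
                       times = default_label_durations(),
                       gradient = 5,
                       b0 = 500,
                       h0 = 400,
                       m0 = 10,
                       m_taper = 0.5,
                       noise_sigma = 1,
                       background_level = 100,
                       blob_count = 3,
                       n_trunks = 3,
                       branch_prob = 0.08,
                       lateral_prob = 0.05,
                       vessel_radius = 2,
                       profile_sd = 1,
                       variant = c("continuous", "literal"),
                       seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape))) {
    stop("`shape` must be an integer triplet", call. = FALSE)
  }
  voxel_dims <- check_voxel_dims(voxel_dims)
  times <- check_times(times)
  if (gradient < 0) stop("`gradient` must be >= 0 (ms/mm)", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (b0 < 0) stop("`b0` must be >= 0 (ms)", call. = FALSE)
  if (h0 <= 0) stop("`h0` must be > 0 (ms)", call. = FALSE)
  if (m0 <= 0) stop("`m0` must be > 0", call. = FALSE)
  variant <- match.arg(variant)
  structure(list(
    shape = shape, voxel_dims = voxel_dims, times = times,
    gradient = gradient, b0 = b0, h0 = h0, m0 = m0, m_taper = m_taper,
    noise_sigma = noise_sigma, background_level = background_level,
    blob_count = as.integer(blob_count), n_trunks = as.integer(n_trunks),
    branch_prob = branch_prob, lateral_prob = lateral_prob,
    vessel_radius = vessel_radius, profile_sd = profile_sd,
    variant = variant, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a synthetic branching vessel tree with known transit times
#'
#' Grows `n_trunks` random-walk trees from the inlet (most caudal) slice
#' toward cranial slices with a strong axial drift and occasional lateral
#' steps and branches. Every vessel voxel carries its path distance from the
#' tree inlet in mm; the ground-truth breakpoint is
#' `true_b = b0 + gradient * path_distance`, which is non-decreasing along
#' every root-to-tip path by construction. The saturation level tapers
#' linearly with path distance so distal vessels are fainter.
#'
#' @param config A [sim_config()].
#' @return An object of class `vessel_truth`: a list with a data frame
#'   `voxels` (columns `x`, `y`, `z` 1-based indices, `branch`,
#'   `path_distance` mm, `true_b` ms, `true_m`, `true_h` ms), plus
#'   `inlet_slice`, `shape` and `voxel_dims`.
#' @export
#' @examples
#' tr <- generate_vessel_tree(sim_config(shape = c(24, 24, 24), seed = 2))
#' head(tr$voxels)
generate_vessel_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  shape <- config$shape
  small <- which(shape < 16L)
  if (length(small)) {
    stop(sprintf("volume dimension %d (= %d voxels) is too small to hold a vessel trunk (need >= 16)",
                 small[1], shape[small[1]]), call. = FALSE)
  }
  vd <- config$voxel_dims
  set.seed(config$seed)

  max_walkers <- 40L
  # walker state: position, accumulated path length, branch id
  n_tr <- config$n_trunks
  xs <- round(runif(n_tr, shape[1] * 0.3, shape[1] * 0.7))
  ys <- round(runif(n_tr, shape[2] * 0.3, shape[2] * 0.7))
  walkers <- lapply(seq_len(n_tr), function(i) {
    list(x = xs[i], y = ys[i], z = 1L, path = 0, branch = i)
  })
  next_branch <- n_tr + 1L
  rows <- vector("list", 4096L)
  nrow_used <- 0L
  push <- function(w) {
    nrow_used <<- nrow_used + 1L
    rows[[nrow_used]] <<- c(w$x, w$y, w$z, w$branch, w$path)
  }
  for (w in walkers) push(w)

  zmax <- shape[3] - 1L
  while (length(walkers) > 0) {
    new_walkers <- list()
    for (w in walkers) {
      if (w$z >= zmax) next
      dx <- sample(c(-1L, 0L, 1L), 1L,
                   prob = c(config$lateral_prob, 1 - 2 * config$lateral_prob,
                            config$lateral_prob))
      dy <- sample(c(-1L, 0L, 1L), 1L,
                   prob = c(config$lateral_prob, 1 - 2 * config$lateral_prob,
                            config$lateral_prob))
      w$x <- min(max(w$x + dx, 2L), shape[1] - 1L)
      w$y <- min(max(w$y + dy, 2L), shape[2] - 1L)
      w$z <- w$z + 1L
      w$path <- w$path + sqrt((dx * vd[1])^2 + (dy * vd[2])^2 + vd[3]^2)
      push(w)
      new_walkers[[length(new_walkers) + 1L]] <- w
      if (length(new_walkers) + length(walkers) < max_walkers &&
          runif(1) < config$branch_prob) {
        side <- sample(c(-1L, 1L), 1L)
        axis <- sample(1:2, 1L)
        child <- w
        child$branch <- next_branch
        next_branch <- next_branch + 1L
        if (axis == 1L) child$x <- min(max(child$x + side, 2L), shape[1] - 1L)
        else child$y <- min(max(child$y + side, 2L), shape[2] - 1L)
        child$path <- child$path + vd[axis]
        push(child)
        new_walkers[[length(new_walkers) + 1L]] <- child
      }
    }
    walkers <- new_walkers
  }

  m <- do.call(rbind, rows[seq_len(nrow_used)])
  df <- data.frame(x = as.integer(m[, 1]), y = as.integer(m[, 2]),
                   z = as.integer(m[, 3]), branch = as.integer(m[, 4]),
                   path_distance = m[, 5])
  # collisions between branches: keep the earliest arrival (smallest path)
  df <- df[order(df$path_distance), ]
  key <- paste(df$x, df$y, df$z)
  df <- df[!duplicated(key), ]
  df <- df[order(df$z, df$branch, df$path_distance), ]
  rownames(df) <- NULL

  path_ref <- shape[3] * vd[3]
  df$true_b <- config$b0 + config$gradient * df$path_distance
  df$true_m <- config$m0 * pmax(0.3, 1 - config$m_taper * df$path_distance / path_ref)
  df$true_h <- rep(config$h0, nrow(df))
  df$centerline <- TRUE

  # expand to the vessel cross-section: voxels within `vessel_radius` of the
  # centerline in-plane, amplitude falling off as a Gaussian profile, timing
  # inherited from the centerline (the bolus front fills the whole lumen)
  if (config$vessel_radius > 0) {
    r <- config$vessel_radius
    offs <- expand.grid(dx = -r:r, dy = -r:r)
    offs$d2 <- offs$dx^2 + offs$dy^2
    offs <- offs[offs$d2 <= r^2 & offs$d2 > 0, ]
    shell <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i) {
      w <- df
      w$x <- w$x + offs$dx[i]
      w$y <- w$y + offs$dy[i]
      w$true_m <- w$true_m * exp(-offs$d2[i] / (2 * config$profile_sd^2))
      w$centerline <- FALSE
      w
    }))
    shell <- shell[shell$x >= 2 & shell$x <= shape[1] - 1 &
                     shell$y >= 2 & shell$y <= shape[2] - 1, ]
    df <- rbind(df, shell)
    # on collision the brightest contribution wins (centerlines first)
    df <- df[order(!df$centerline, -df$true_m), ]
    df <- df[!duplicated(paste(df$x, df$y, df$z)), ]
    df <- df[order(df$z, df$branch, df$path_distance), ]
    rownames(df) <- NULL
  }

  structure(list(voxels = df, inlet_slice = 1L, shape = shape,
                 voxel_dims = vd), class = "vessel_truth")
}

#' @export
print.vessel_truth <- function(x, ...) {
  cat(sprintf("Synthetic vessel tree: %d voxels, %d branches, %d slices spanned\n",
              nrow(x$voxels), length(unique(x$voxels$branch)),
              length(unique(x$voxels$z))))
  cat(sprintf("  true breakpoints %.0f-%.0f ms, path 0-%.1f mm\n",
              min(x$voxels$true_b), max(x$voxels$true_b),
              max(x$voxels$path_distance)))
  invisible(x)
}

# default synthetic brain mask: everything except a one-voxel border
default_brain_mask <- function(shape) {
  m <- array(FALSE, dim = shape)
  m[2:(shape[1] - 1), 2:(shape[2] - 1), 2:(shape[3] - 1)] <- TRUE
  m
}

#' Simulate label/control 4D-MRA series from a vessel tree
#'
#' Forward-simulates the control and label volume series. The control image is
#' a flat background inside the brain; the label image is the control minus
#' the inflow difference signal, so pairwise subtraction recovers the
#' difference exactly. The difference signal at a vessel voxel follows the
#' two-piece saturation model with that voxel's ground-truth parameters;
#' Gaussian noise of sd `noise_sigma` is added everywhere inside the brain,
#' and `blob_count` ellipsoidal high-signal artifacts (constant over time) are
#' placed within the 8 most caudal slices to mimic pulsatility artifacts near
#' the circle of Willis.
#'
#' @param truth A [generate_vessel_tree()] result.
#' @param config The matching [sim_config()].
#' @return A list with 4D arrays `label` and `control` (x, y, z, time), the
#'   noise-free vessel difference signal `delta_true`, a logical
#'   `brain_mask`, a logical `blob_mask`, `times` and `voxel_dims`.
#' @export
#' @examples
#' cfg <- sim_config(shape = c(24, 24, 24), noise_sigma = 0, blob_count = 0,
#'                   seed = 3)
#' sim <- simulate_inflow_series(generate_vessel_tree(cfg), cfg)
#' dim(sim$label)
simulate_inflow_series <- function(truth, config) {
  stopifnot(inherits(truth, "vessel_truth"), inherits(config, "sim_config"))
  shape <- config$shape
  vx <- truth$voxels
  if (any(vx$x < 1 | vx$x > shape[1] | vx$y < 1 | vx$y > shape[2] |
          vx$z < 1 | vx$z > shape[3])) {
    stop("vessel voxels fall outside the configured volume shape", call. = FALSE)
  }
  times <- config$times
  nt <- length(times)
  set.seed(config$seed + 1L)

  brain <- default_brain_mask(shape)
  control3 <- array(0, dim = shape)
  control3[brain] <- config$background_level

  lin <- (vx$z - 1L) * shape[1] * shape[2] + (vx$y - 1L) * shape[1] + vx$x
  delta_true <- array(0, dim = c(shape, nt))
  nvox3 <- prod(shape)
  for (ti in seq_len(nt)) {
    dm <- piecewise_saturation(times[ti], vx$true_b, vx$true_m, vx$true_h,
                               variant = config$variant)
    delta_true[(ti - 1L) * nvox3 + lin] <- dm
  }

  # blob artifacts: ellipsoids in the 8 most caudal slices, sizes straddling
  # the default area-opening threshold
  blob_mask <- array(FALSE, dim = shape)
  if (config$blob_count > 0) {
    radii_pool <- c(1L, 2L, 3L)
    vz_caudal <- vx[vx$z <= 12L, c("x", "y")]
    for (i in seq_len(config$blob_count)) {
      # artifacts sit near the brain base but off the arteries: resample
      # until the centre clears the caudal vessel tree
      for (attempt in 1:50) {
        cx <- round(runif(1, 5, shape[1] - 4))
        cy <- round(runif(1, 5, shape[2] - 4))
        if (nrow(vz_caudal) == 0L ||
            min(abs(vz_caudal$x - cx) + abs(vz_caudal$y - cy)) > 7) break
      }
      cz <- round(runif(1, 3, min(8, shape[3] - 3)))
      r <- radii_pool[1L + (i - 1L) %% length(radii_pool)]
      xr <- max(1, cx - r):min(shape[1], cx + r)
      yr <- max(1, cy - r):min(shape[2], cy + r)
      zr <- max(1, cz - r):min(shape[3], cz + r)
      for (zz in zr) for (yy in yr) for (xx in xr) {
        if (((xx - cx)^2 + (yy - cy)^2 + (zz - cz)^2) <= r^2) {
          blob_mask[xx, yy, zz] <- TRUE
        }
      }
    }
  }
  # pulsatility artifacts fluctuate between subtraction pairs: high-variance
  # zero-mean signal with a small positive bias, not a steady bright object
  blob_sd <- 3 * config$noise_sigma + 0.1 * config$m0
  blob_bias <- 0.1 * config$m0

  delta <- delta_true
  if (any(blob_mask)) {
    blin <- which(blob_mask)
    for (ti in seq_len(nt)) {
      delta[(ti - 1L) * nvox3 + blin] <- delta[(ti - 1L) * nvox3 + blin] +
        blob_bias + rnorm(length(blin), 0, blob_sd)
    }
  }
  if (config$noise_sigma > 0) {
    nbrain <- sum(brain)
    blin2 <- which(brain)
    for (ti in seq_len(nt)) {
      delta[(ti - 1L) * nvox3 + blin2] <- delta[(ti - 1L) * nvox3 + blin2] +
        rnorm(nbrain, 0, config$noise_sigma)
    }
  }

  control <- array(control3, dim = c(shape, nt))
  label <- control - delta
  list(label = label, control = control, delta_true = delta_true,
       brain_mask = brain, blob_mask = blob_mask,
       times = times, voxel_dims = config$voxel_dims)
}

#' Generate a rectangular block parcellation
#'
#' Partitions the volume into `blocks[1] x blocks[2] x blocks[3]` contiguous
#' rectangular regions labelled `1..N`, a stand-in for a fine anatomical
#' atlas on the native grid. Label 0 is reserved for background and does not
#' occur in the output.
#'
#' @param shape Integer triplet of volume dimensions.
#' @param blocks Integer triplet: number of blocks per axis (each >= 1 and
#'   <= the corresponding dimension).
#' @return Integer 3D array of region labels.
#' @export
#' @examples
#' a <- generate_block_atlas(c(16, 16, 16), c(2, 2, 2))
#' length(unique(as.vector(a)))
generate_block_atlas <- function(shape, blocks) {
  shape <- as.integer(shape); blocks <- as.integer(blocks)
  stopifnot(length(shape) == 3L, length(blocks) == 3L)
  bad <- which(blocks < 1L | blocks > shape)
  if (length(bad)) {
    stop(sprintf("`blocks` along axis %d must be between 1 and %d (got %d)",
                 bad[1], shape[bad[1]], blocks[bad[1]]), call. = FALSE)
  }
  cuts <- lapply(1:3, function(a) {
    # contiguous, near-equal runs covering the axis
    as.integer(ceiling(seq_len(shape[a]) * blocks[a] / shape[a]))
  })
  ix <- cuts[[1]]; iy <- cuts[[2]]; iz <- cuts[[3]]
  lab <- outer(outer(ix, (iy - 1L) * blocks[1], "+"),
               (iz - 1L) * blocks[1] * blocks[2], "+")
  array(as.integer(lab), dim = shape)
}

#' Simulate a co-registered tissue arterial transit time map
#'
#' Assigns to every brain voxel the ground-truth breakpoint of its nearest
#' vessel voxel (exact Euclidean nearest neighbour in mm) plus a tissue delay
#' and Gaussian noise. This reproduces the expected positive association
#' between macrovascular and tissue transit times, with tissue arrival lagging
#' the feeding artery.
#'
#' @param truth A [generate_vessel_tree()] result (must contain >= 1 voxel).
#' @param shape Volume dimensions; defaults to the truth's shape.
#' @param tissue_delay Mean delay from macrovascular arrival to tissue arrival
#'   (ms, >= 0).
#' @param noise_sigma Gaussian noise on the tissue map (ms).
#' @param seed Integer seed.
#' @param mask Optional logical array restricting computation; defaults to the
#'   full volume.
#' @return 3D numeric array of tissue transit times in ms (NA outside `mask`).
#' @export
simulate_tissue_att <- function(truth, shape = truth$shape, tissue_delay = 600,
                                noise_sigma = 100, seed = 1L, mask = NULL) {
  stopifnot(inherits(truth, "vessel_truth"))
  if (nrow(truth$voxels) == 0L) stop("empty vessel truth", call. = FALSE)
  if (tissue_delay < 0) stop("`tissue_delay` must be >= 0", call. = FALSE)
  shape <- as.integer(shape)
  vd <- truth$voxel_dims
  set.seed(seed)
  if (is.null(mask)) mask <- array(TRUE, dim = shape)
  idx <- which(mask)
  co <- arrayInd(idx, shape)
  P <- cbind(co[, 1] * vd[1], co[, 2] * vd[2], co[, 3] * vd[3])
  V <- cbind(truth$voxels$x * vd[1], truth$voxels$y * vd[2],
             truth$voxels$z * vd[3])
  vb <- truth$voxels$true_b
  v2 <- rowSums(V^2)
  out <- array(NA_real_, dim = shape)
  chunk <- 4000L
  starts <- seq(1L, nrow(P), by = chunk)
  nearest_b <- numeric(nrow(P))
  for (s in starts) {
    e <- min(s + chunk - 1L, nrow(P))
    d2 <- outer(rowSums(P[s:e, , drop = FALSE]^2), v2, "+") -
      2 * tcrossprod(P[s:e, , drop = FALSE], V)
    nearest_b[s:e] <- vb[max.col(-d2, ties.method = "first")]
  }
  vals <- nearest_b + tissue_delay
  if (noise_sigma > 0) vals <- vals + rnorm(length(vals), 0, noise_sigma)
  out[idx] <- vals
  out
}
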