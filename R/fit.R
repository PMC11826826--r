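#' Two-piece saturation signal model
#'
#' Evaluates the inflow signal model: zero before the breakpoint `b` (the
#' label bolus has not yet arrived), and a saturating rise afterwards. `m` is
#' the saturation level the signal approaches at late label durations and `h`
#' is the half-rise time. The breakpoint is interpreted as the macrovascular
#' arterial transit time (mATT).
#'
#' Two branch forms are provided. `"literal"` evaluates `m * t / (h + t)` for
#' `t > b` (discontinuous at the breakpoint; with `b = 0`, the signal is
#' `m/2` at `t = h` and approaches `m` as `t` grows). `"continuous"` shifts
#' the rise to start at the breakpoint: `m * (t - b) / (h + (t - b))`,
#' which is continuous in `t` and identifies `b` between sample times.
#'
#' @param t Time (label duration) in ms; vectorized.
#' @param b Breakpoint in ms (>= 0).
#' @param m Saturation level (>= 0).
#' @param h Half-rise time in ms (> 0).
#' @param variant `"literal"` (default) or `"continuous"`.
#' @return Model signal, recycled over the longest argument.
#' @export
#' @examples
#' piecewise_saturation(c(100, 800, 2200), b = 800, m = 10, h = 400)
piecewise_saturation <- function(t, b, m, h, variant = c("literal", "continuous")) {
  variant <- match.arg(variant)
  if (any(h <= 0)) stop("`h` must be > 0 (ms)", call. = FALSE)
  if (any(m < 0)) stop("`m` must be >= 0", call. = FALSE)
  if (any(b < 0)) stop("`b` must be >= 0 (ms)", call. = FALSE)
  n <- max(length(t), length(b), length(m), length(h))
  t <- rep_len(t, n); b <- rep_len(b, n); m <- rep_len(m, n); h <- rep_len(h, n)
  out <- numeric(n)
  act <- t > b
  if (variant == "literal") {
    out[act] <- m[act] * t[act] / (h[act] + t[act])
  } else {
    dt <- t[act] - b[act]
    out[act] <- m[act] * dt / (h[act] + dt)
  }
  out
}

#' Fitting options for the breakpoint model
#'
#' @param variant Model branch form, `"literal"` (default, the printed form)
#'   or `"continuous"`; see [piecewise_saturation()].
#' @param b_max Upper bound on the breakpoint (ms); default is the last label
#'   duration plus the last inter-sample gap, permitting extrapolation of
#'   arrival times slightly beyond the final sample.
#' @param grid_step Candidate-breakpoint grid step (ms) before local polish;
#'   kept well below the inter-sample spacing.
#' @param n_h Number of log-spaced half-rise candidates in the inner search.
#' @param h_range Half-rise search range (ms).
#' @param noise_floor Curves whose maximum is below this value are flagged
#'   `below_noise` and not fitted. [fit_map()] computes a robust default from
#'   mask-adjacent background when `noise_floor = "auto"`.
#' @param polish Run a local continuous refinement after the grid search.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(variant = c("literal", "continuous"), b_max = NULL,
                        grid_step = 10, n_h = 40, h_range = c(20, 10000),
                        noise_floor = 0, polish = TRUE) {
  variant <- match.arg(variant)
  stopifnot(grid_step > 0, n_h >= 5, length(h_range) == 2L, h_range[1] > 0,
            h_range[2] > h_range[1])
  structure(list(variant = variant, b_max = b_max, grid_step = grid_step,
                 n_h = as.integer(n_h), h_range = h_range,
                 noise_floor = noise_floor, polish = isTRUE(polish)),
            class = "fit_options")
}

default_b_max <- function(times) {
  n <- length(times)
  times[n] + (times[n] - times[n - 1L])
}

# status codes used in the status volume
.fit_status_levels <- c(ok = 0L, below_noise = 1L, no_breakpoint = 2L, fail = 3L)

# candidate grid shared by all voxels of one fit call:
# a (n_t x n_candidates) model-basis matrix with zero rows for t <= b, plus
# the (b, h) value of each candidate column. For the literal variant the SSE
# depends on b only through the active set {t > b}, so candidates collapse to
# the distinct active sets (left interval edges).
build_candidate_grid <- function(times, opts) {
  b_max <- if (is.null(opts$b_max)) default_b_max(times) else opts$b_max
  h_grid <- exp(seq(log(opts$h_range[1]), log(opts$h_range[2]),
                    length.out = opts$n_h))
  if (opts$variant == "literal") {
    b_grid <- c(0, times[times < b_max])
    b_grid <- b_grid[b_grid <= b_max]
  } else {
    b_grid <- seq(0, b_max, by = opts$grid_step)
  }
  nb <- length(b_grid); nh <- length(h_grid); nt <- length(times)
  bcol <- rep(b_grid, each = nh)
  hcol <- rep(h_grid, times = nb)
  V <- matrix(0, nrow = nt, ncol = nb * nh)
  for (j in seq_along(bcol)) {
    V[, j] <- piecewise_saturation(times, bcol[j], 1, hcol[j],
                                   variant = opts$variant)
  }
  list(V = V, b = bcol, h = hcol, vv = colSums(V * V), b_max = b_max)
}

# profiled SSE at fixed (b, h): m has the closed-form least-squares value,
# clamped at zero (a negative amplitude means no inflow signal)
profile_sse <- function(times, y, b, h, variant) {
  v <- piecewise_saturation(times, b, 1, h, variant = variant)
  vv <- sum(v * v)
  yy <- sum(y * y)
  if (vv <= 0) return(list(sse = yy, m = 0))
  m <- sum(y * v) / vv
  if (m <= 0) return(list(sse = yy, m = 0))
  list(sse = yy - m^2 * vv, m = m)
}

# local refinement of all three parameters after the grid search. For the
# continuous variant a Levenberg-Marquardt step polishes (b, m, h) jointly;
# for the literal variant the SSE is piecewise-constant in b, so b keeps its
# active-set left edge and only (m, h) are refined. The polish is accepted
# only when it does not worsen the SSE.
polish_fit <- function(times, y, b, h, sse, opts, b_max) {
  m <- profile_sse(times, y, b, h, opts$variant)$m
  if (opts$variant == "literal") {
    o <- optimize(function(hh) profile_sse(times, y, b, hh, opts$variant)$sse,
                  lower = opts$h_range[1] / 2, upper = opts$h_range[2] * 2,
                  tol = 1e-6)
    if (o$objective <= sse) {
      h <- o$minimum; sse <- o$objective
      m <- profile_sse(times, y, b, h, opts$variant)$m
    }
    return(list(b = b, h = h, m = m, sse = sse))
  }
  resid_fn <- function(par) {
    y - piecewise_saturation(times, par[1], par[2], par[3],
                             variant = opts$variant)
  }
  lm_fit <- tryCatch(
    minpack.lm::nls.lm(par = c(b = b, m = max(m, 1e-8), h = h),
                       fn = resid_fn,
                       lower = c(0, 0, opts$h_range[1] / 10),
                       upper = c(b_max, Inf, opts$h_range[2] * 10),
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-14, ptol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(lm_fit)) {
    sse_lm <- sum(resid_fn(lm_fit$par)^2)
    if (sse_lm <= sse) {
      b <- lm_fit$par[["b"]]; m <- lm_fit$par[["m"]]; h <- lm_fit$par[["h"]]
      sse <- sse_lm
    }
  }
  list(b = b, h = h, m = m, sse = sse)
}

# vectorized engine: Y is n_t x n_curves; returns a data frame of fits
fit_engine <- function(times, Y, opts, grid = NULL) {
  if (is.null(grid)) grid <- build_candidate_grid(times, opts)
  nt <- nrow(Y); nc <- ncol(Y)
  yy <- colSums(Y * Y)
  YV <- crossprod(grid$V, Y)                    # candidates x curves
  vv <- grid$vv
  ok_col <- vv > 0
  out <- data.frame(b = numeric(nc), m = numeric(nc), h = numeric(nc),
                    sse = numeric(nc), r2 = numeric(nc),
                    status = character(nc), stringsAsFactors = FALSE)
  for (i in seq_len(nc)) {
    y <- Y[, i]
    gain <- numeric(length(vv))
    pos <- ok_col & YV[, i] > 0
    gain[pos] <- YV[pos, i]^2 / vv[pos]
    sse_all <- yy[i] - gain
    smin <- min(sse_all)
    tol <- 1e-9 * max(1, yy[i])
    cand <- which(sse_all <= smin + tol)
    # ties: earliest arrival wins, then the smaller half-rise
    cand <- cand[order(grid$b[cand], grid$h[cand])]
    j <- cand[1]
    b <- grid$b[j]; h <- grid$h[j]
    m <- if (pos[j]) YV[j, i] / vv[j] else 0
    sse <- sse_all[j]
    if (m > 0 && opts$polish) {
      p <- polish_fit(times, y, b, h, sse, opts, grid$b_max)
      b <- p$b; h <- p$h; m <- p$m; sse <- p$sse
    }
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) max(0, min(1, 1 - sse / sst)) else 0
    status <- if (m <= 0) "no_breakpoint" else "ok"
    out$b[i] <- b; out$m[i] <- m; out$h[i] <- h
    out$sse[i] <- sse; out$r2[i] <- r2; out$status[i] <- status
  }
  out
}

#' Fit the breakpoint model to a single voxel curve
#'
#' Minimizes the sum of squared residuals over `(b, m, h)` by profiling: for
#' each candidate breakpoint on a grid up to `b_max`, the amplitude has a
#' closed-form least-squares solution and the half-rise time is searched on a
#' log grid; the global best is then locally refined. All time points
#' contribute residuals (the model is zero for `t <= b`). Ties in SSE across
#' breakpoint candidates resolve to the smallest breakpoint (earliest
#' arrival).
#'
#' @param times Label durations in ms (strictly increasing, >= 4 points).
#' @param curve Signal values (same length as `times`).
#' @param options A [fit_options()] list.
#' @return An object of class `saturation_fit`: list with `b` (ms), `m`, `h`
#'   (ms), `sse`, `r2` and `status` (one of `ok`, `below_noise`,
#'   `no_breakpoint`, `fail`).
#' @export
#' @examples
#' t <- default_label_durations()
#' y <- piecewise_saturation(t, b = 800, m = 10, h = 400)
#' fit_voxel(t, y)$b
fit_voxel <- function(times, curve, options = fit_options()) {
  times <- check_times(times)
  if (length(times) < 4L) stop("need at least 4 time points", call. = FALSE)
  if (length(curve) != length(times)) {
    stop("`curve` and `times` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(curve))) stop("`curve` contains non-finite values", call. = FALSE)
  nf <- options$noise_floor
  if (is.numeric(nf) && max(curve) <= nf) {
    return(structure(list(b = NA_real_, m = NA_real_, h = NA_real_,
                          sse = NA_real_, r2 = NA_real_,
                          status = "below_noise"), class = "saturation_fit"))
  }
  res <- fit_engine(times, matrix(curve, ncol = 1), options)
  structure(as.list(res[1, , drop = TRUE]), class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("saturation fit: b = %.1f ms, m = %.3f, h = %.1f ms, r2 = %.3f\n",
                x$b, x$m, x$h, x$r2))
  } else {
    cat(sprintf("saturation fit: status %s\n", x$status))
  }
  invisible(x)
}

#' Fit the breakpoint model over a vessel mask
#'
#' Applies [fit_voxel()]'s engine to every voxel of the vessel mask, producing
#' volumetric maps of the breakpoint (the mATT map), amplitude and fit
#' quality. Voxels whose curve maximum is below the noise floor are flagged
#' `below_noise`; a robust default floor (`"auto"`) is twice the
#' median-absolute-deviation-based sd of the first-time-point signal over the
#' background ring adjacent to the mask.
#'
#' @param series An [inflow_series()] (typically after vessel isolation and
#'   smoothing).
#' @param mask A [vessel_mask()] or logical 3D array with >= 1 voxel.
#' @param options A [fit_options()]; `noise_floor = "auto"` enables the
#'   data-driven floor.
#' @param noise_reference Optional [inflow_series()] used to estimate the
#'   automatic noise floor (e.g. the unsmoothed difference series, so the
#'   floor reflects subtraction noise rather than smoothed noise); defaults
#'   to `series`.
#' @return An object of class `matt_map`: list of 3D arrays `matt` (ms, NA
#'   outside successfully fitted voxels), `amplitude`, `quality` (r2),
#'   `status` (integer codes 0 = ok, 1 = below_noise, 2 = no_breakpoint,
#'   3 = fail), plus the mask, `voxel_dims`, `times`, the applied
#'   `noise_floor` and a tally of fit statuses.
#' @export
fit_map <- function(series, mask, options = fit_options(noise_floor = "auto"),
                    noise_reference = series) {
  stopifnot(inherits(series, "inflow_series"))
  mk <- as_mask_array(mask)
  if (!identical(dim(mk), dim(series$data)[1:3])) {
    stop("mask and series grids differ", call. = FALSE)
  }
  idx <- which(mk)
  if (length(idx) == 0L) stop("empty vessel mask: nothing to fit", call. = FALSE)
  times <- series$times
  nt <- length(times)
  nvox3 <- prod(dim(mk))

  nf <- options$noise_floor
  if (identical(nf, "auto")) {
    ring <- dilate_mask(mk, 3L) & !mk
    if (!is.null(noise_reference$brain_mask)) {
      ring <- ring & noise_reference$brain_mask
    }
    x1 <- noise_reference$data[, , , 1][ring]
    nf <- if (length(x1) >= 10) 2 * mad(x1) else 0
  }

  Yfull <- matrix(series$data[outer(idx, (seq_len(nt) - 1L) * nvox3, "+")],
                  nrow = length(idx), ncol = nt)
  cmax <- apply(Yfull, 1L, max)
  fit_these <- cmax > nf

  shape <- dim(mk)
  matt <- array(NA_real_, shape); amp <- array(NA_real_, shape)
  qual <- array(NA_real_, shape)
  status <- array(NA_integer_, shape)
  status[idx] <- .fit_status_levels[["below_noise"]]

  grid <- build_candidate_grid(times, options)
  sel <- which(fit_these)
  chunk <- 512L
  for (s in if (length(sel)) seq(1L, length(sel), by = chunk) else integer(0)) {
    e <- min(s + chunk - 1L, length(sel))
    part <- sel[s:e]
    res <- fit_engine(times, t(Yfull[part, , drop = FALSE]), options, grid = grid)
    vox <- idx[part]
    okv <- res$status == "ok"
    matt[vox[okv]] <- res$b[okv]
    amp[vox[okv]] <- res$m[okv]
    qual[vox[okv]] <- res$r2[okv]
    status[vox] <- .fit_status_levels[res$status]
  }
  tal <- table(factor(names(.fit_status_levels)[match(status[idx],
                                                      .fit_status_levels)],
                      levels = names(.fit_status_levels)))
  structure(list(matt = matt, amplitude = amp, quality = qual, status = status,
                 mask = mask, voxel_dims = series$voxel_dims, times = times,
                 noise_floor = nf, tally = tal),
            class = "matt_map")
}

#' @export
print.matt_map <- function(x, ...) {
  n <- sum(is.finite(x$matt))
  cat(sprintf("mATT map: %d fitted voxels", n))
  if (n > 0) cat(sprintf(", range %.0f-%.0f ms", min(x$matt, na.rm = TRUE),
                         max(x$matt, na.rm = TRUE)))
  cat("\n  status tally:",
      paste(names(x$tally), as.integer(x$tally), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Global maximum macrovascular transit time
#'
#' The global maximum mATT over fitted voxels (mATT_tot) indicates the total
#' time taken for labelled blood to reach the most distal visible vessels. A
#' lower percentile may be requested as a robust alternative.
#'
#' @param map A [fit_map()] result.
#' @param q Percentile in (0, 100]; the default 100 is the maximum.
#' @return mATT_tot in ms.
#' @export
matt_total <- function(map, q = 100) {
  stopifnot(inherits(map, "matt_map"), q > 0, q <= 100)
  v <- map$matt[is.finite(map$matt)]
  if (length(v) == 0L) stop("mATT map has no defined voxels", call. = FALSE)
  unname(quantile(v, q / 100))
}
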