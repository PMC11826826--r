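#' Slice-wise mATT profile
#'
#' Mean and standard deviation of the fitted mATT per (group of) axial
#' slice(s), as a function of the distance from the most caudal imaging
#' slice. Distances are measured from the centre of slice 1 (0 mm) in the
#' caudal-to-cranial direction; for grouped slices the group-centre distance
#' is used. Slice groups without defined voxels are dropped.
#'
#' @param map A [fit_map()] result or 3D numeric array (NA = undefined).
#' @param slice_thickness Slice thickness in mm (> 0); defaults to the map's
#'   feet-head voxel size when available.
#' @param group_size Number of consecutive slices per profile entry (>= 1).
#' @return An object of class `slice_profile` (data frame with `distance`
#'   mm, `mean_matt`, `sd_matt`, `n_voxels`). The sd of a single voxel is
#'   reported as 0.
#' @export
slice_profile <- function(map, slice_thickness = NULL, group_size = 1) {
  vals <- if (inherits(map, "matt_map")) map$matt else map
  if (is.null(slice_thickness)) {
    slice_thickness <- if (inherits(map, "matt_map")) map$voxel_dims[3] else 1
  }
  if (slice_thickness <= 0) stop("`slice_thickness` must be > 0", call. = FALSE)
  group_size <- as.integer(group_size)
  if (group_size < 1L) stop("`group_size` must be >= 1", call. = FALSE)
  nz <- dim(vals)[3]
  grp <- (seq_len(nz) - 1L) %/% group_size
  rows <- lapply(unique(grp), function(g) {
    zs <- which(grp == g)
    v <- vals[, , zs]
    v <- v[is.finite(v)]
    if (length(v) == 0L) return(NULL)
    data.frame(distance = mean(zs - 1L) * slice_thickness,
               mean_matt = mean(v),
               sd_matt = if (length(v) > 1L) sd(v) else 0,
               n_voxels = length(v))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    stop("no defined mATT voxels in any slice", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("slice_profile", "data.frame")
  out
}

#' Linear regression of mATT on caudal-cranial distance
#'
#' Ordinary least squares of the slice-mean mATT on slice distance,
#' estimating the increase in transit time per mm travelled from the major
#' input arteries; the adjusted r-squared is reported as the goodness of
#' fit. Voxel-count weighting is available but off by default (the profile
#' mean curve is regressed unweighted).
#'
#' @param profile A [slice_profile()] with >= 3 entries.
#' @param weighted Weight slices by their defined-voxel counts.
#' @param exclude_distance_range Optional `c(lo, hi)` in mm: profile entries
#'   in this range are censored before the regression (e.g. an oscillatory
#'   segment near the carotid siphon).
#' @return Object of class `distance_regression`: list with `slope` (ms/mm),
#'   `intercept` (ms), `adj_r2` and `n` (slices used).
#' @export
fit_distance_regression <- function(profile, weighted = FALSE,
                                    exclude_distance_range = NULL) {
  stopifnot(inherits(profile, "data.frame"))
  p <- profile
  if (!is.null(exclude_distance_range)) {
    stopifnot(length(exclude_distance_range) == 2L)
    drop <- p$distance >= exclude_distance_range[1] &
      p$distance <= exclude_distance_range[2]
    p <- p[!drop, , drop = FALSE]
  }
  n <- nrow(p)
  if (n < 3L) stop("need at least 3 profile entries for regression", call. = FALSE)
  w <- if (weighted) p$n_voxels else NULL
  fit <- lm(mean_matt ~ distance, data = p, weights = w)
  sst <- sum((p$mean_matt - mean(p$mean_matt))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 0
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
                 n = n),
            class = "distance_regression")
}

#' @export
print.distance_regression <- function(x, ...) {
  cat(sprintf("mATT-distance regression: slope %.2f ms/mm, intercept %.0f ms, adj. R2 %.3f (n = %d)\n",
              x$slope, x$intercept, x$adj_r2, x$n))
  invisible(x)
}

#' Predicted mATT at a given distance
#'
#' Evaluates the fitted linear distance model, e.g. at 120 mm, approximately
#' the distance from the labelling plane to the most distal visible vessels.
#'
#' @param reg A [fit_distance_regression()] result.
#' @param d Distance in mm.
#' @return Predicted mATT in ms.
#' @export
predict_at_distance <- function(reg, d) {
  stopifnot(inherits(reg, "distance_regression"))
  reg$intercept + reg$slope * d
}

#' Group summary of mATT_tot values
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator; undefined
#' for a single value) and range (max - min) of a set of per-subject or
#' per-group global maximum transit times.
#'
#' @param matt_tot_values Numeric vector (ms), length >= 1.
#' @return List with `mean`, `sd` and `range` in ms.
#' @export
#' @examples
#' group_summary(c(2148, 2205, 2247, 2142))$range
group_summary <- function(matt_tot_values) {
  v <- as.numeric(matt_tot_values)
  if (length(v) == 0L) stop("need at least one value", call. = FALSE)
  list(mean = mean(v),
       sd = if (length(v) > 1L) sd(v) else NA_real_,
       range = max(v) - min(v))
}

#' Slope reduction between two distance regressions
#'
#' `pre - post` slope difference in ms/mm: positive values mean faster
#' arrival (flatter distance dependence) after the challenge.
#'
#' @param pre,post [fit_distance_regression()] results, or bare slopes in
#'   ms/mm.
#' @return Slope difference in ms/mm.
#' @export
slope_difference <- function(pre, post) {
  s <- function(x) if (inherits(x, "distance_regression")) x$slope else as.numeric(x)
  s(pre) - s(post)
}

#' Cross-modal regional correlation
#'
#' Regression of one regional parameter on another over the regions defined
#' in both tables (pairwise complete), e.g. tissue transit time versus
#' macrovascular transit time. Reports the Pearson correlation with its
#' two-sided p-value from the t-distribution with n - 2 degrees of freedom,
#' the OLS slope/intercept of `field_b` on `field_a`, and the adjusted
#' r-squared.
#'
#' @param table_a,table_b `regional_table`s sharing region labels.
#' @param field_a Column of `table_a` (x variable).
#' @param field_b Column of `table_b` (y variable); defaults to `field_a`.
#' @return List with `r`, `slope`, `intercept`, `adj_r2`, `p`, `n`.
#' @export
roi_correlation <- function(table_a, table_b, field_a = "mean_matt_ms",
                            field_b = field_a) {
  m <- merge(table_a[, c("region_label", field_a)],
             table_b[, c("region_label", field_b)],
             by = "region_label", suffixes = c("_a", "_b"))
  ca <- if (field_a == field_b) paste0(field_a, "_a") else field_a
  cb <- if (field_a == field_b) paste0(field_b, "_b") else field_b
  x <- m[[ca]]; y <- m[[cb]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 regions defined in both tables", call. = FALSE)
  fit <- lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 0
  ct <- suppressWarnings(cor.test(x, y))
  list(r = unname(ct$estimate),
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
       p = ct$p.value,
       n = n)
}
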