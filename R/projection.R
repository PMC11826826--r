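#' Project a sparse mATT map into a region-label atlas space
#'
#' For every atlas region, the unweighted mean of the defined (fitted) map
#' voxels inside the region is computed and assigned to the entire region,
#' producing a filled parametric map. Regions containing fewer than
#' `min_voxels` defined voxels remain undefined, as does the background
#' label 0.
#'
#' @param map A [fit_map()] result, or a 3D numeric array with NA outside
#'   defined voxels.
#' @param atlas Integer 3D array of region labels on the same grid (0 =
#'   background).
#' @param min_voxels Minimum number of defined vessel voxels for a region
#'   mean to be reported.
#' @return List with `table` (class `regional_table`: `region_label`,
#'   `mean_matt_ms`, `n_vessel_voxels`, `region_volume`) and `filled` (3D
#'   array, each region's mean assigned to all its voxels, NA where
#'   undefined).
#' @export
#' @examples
#' m <- array(NA_real_, c(4, 4, 2)); m[1, 1, 1] <- 1000; m[2, 1, 1] <- 2000
#' a <- generate_block_atlas(c(4, 4, 2), c(1, 1, 1))
#' project_to_regions(m, a, min_voxels = 1)$table
project_to_regions <- function(map, atlas, min_voxels = 5) {
  vals <- if (inherits(map, "matt_map")) map$matt else map
  if (!identical(dim(vals), dim(atlas))) {
    stop("mATT map and atlas grids differ", call. = FALSE)
  }
  labels <- sort(unique(as.integer(atlas[atlas > 0L])))
  lab_all <- as.integer(atlas)
  region_volume <- tabulate(lab_all, nbins = max(labels))[labels]

  defined <- is.finite(vals) & atlas > 0L
  dl <- factor(lab_all[defined], levels = labels)
  n_def <- as.integer(table(dl))
  sums <- tapply(vals[defined], dl, sum)
  sums[is.na(sums)] <- 0
  mean_matt <- ifelse(n_def >= min_voxels, as.numeric(sums) / n_def, NA_real_)

  tab <- data.frame(region_label = labels, mean_matt_ms = mean_matt,
                    n_vessel_voxels = n_def, region_volume = region_volume)
  class(tab) <- c("regional_table", "data.frame")
  attr(tab, "min_voxels") <- min_voxels

  filled <- array(NA_real_, dim = dim(atlas))
  pos <- match(lab_all, labels)
  inside <- !is.na(pos)
  filled[inside] <- mean_matt[pos[inside]]
  list(table = tab, filled = filled)
}

#' Regional mean of an arbitrary co-registered scalar map
#'
#' Averages a dense scalar map (e.g. a tissue transit time map) over all
#' finite voxels of each atlas region and appends the result to a regional
#' table, enabling cross-modal regional correlation.
#'
#' @param table A `regional_table`.
#' @param atlas Integer 3D label array.
#' @param volume 3D numeric array on the atlas grid.
#' @param name Column name for the new regional mean.
#' @return The extended `regional_table`.
#' @export
add_regional_mean <- function(table, atlas, volume, name = "mean_att_ms") {
  stopifnot(inherits(table, "regional_table"))
  if (!identical(dim(volume), dim(atlas))) {
    stop("volume and atlas grids differ", call. = FALSE)
  }
  ok <- is.finite(volume) & atlas > 0L
  dl <- factor(as.integer(atlas)[ok], levels = table$region_label)
  mn <- tapply(volume[ok], dl, mean)
  table[[name]] <- as.numeric(mn)
  table
}

#' Regional pre/post difference table
#'
#' Per-region difference `post - pre` of the regional mean mATT; with this
#' sign convention, vasodilation (earlier arrival) yields negative values. A
#' region is undefined whenever either side is undefined.
#'
#' @param pre,post `regional_table`s over identical region label sets.
#' @param atlas Optional label array; when given, a filled delta map is also
#'   returned.
#' @param field Column to difference.
#' @return A data frame with `region_label`, the pre/post values and
#'   `delta`; when `atlas` is given, a list with `table` and `filled`.
#' @export
regional_delta <- function(pre, post, atlas = NULL, field = "mean_matt_ms") {
  if (!setequal(pre$region_label, post$region_label)) {
    only_pre <- setdiff(pre$region_label, post$region_label)
    only_post <- setdiff(post$region_label, pre$region_label)
    stop(sprintf("region label sets differ (only in pre: %s; only in post: %s)",
                 paste(only_pre, collapse = ","),
                 paste(only_post, collapse = ",")), call. = FALSE)
  }
  m <- merge(pre[, c("region_label", field)],
             post[, c("region_label", field)],
             by = "region_label", suffixes = c("_pre", "_post"))
  m <- m[order(m$region_label), ]
  rownames(m) <- NULL
  m$delta <- m[[paste0(field, "_post")]] - m[[paste0(field, "_pre")]]
  if (is.null(atlas)) return(m)
  filled <- array(NA_real_, dim = dim(atlas))
  pos <- match(as.integer(atlas), m$region_label)
  inside <- !is.na(pos)
  filled[inside] <- m$delta[pos[inside]]
  list(table = m, filled = filled)
}

#' Restrict a pre/post map pair to a common vessel mask
#'
#' After vasodilation, previously invisible distal vessels (with long
#' transit times) can enter the post-challenge vessel mask and bias regional
#' difference statistics. Restricting both maps to the voxels defined in the
#' pre-challenge analysis (intersected with the post map's defined set)
#' removes that contribution.
#'
#' @param pre_map,post_map [fit_map()] results on the same grid.
#' @return List with the restricted `pre` and `post` maps.
#' @export
apply_common_mask <- function(pre_map, post_map) {
  stopifnot(inherits(pre_map, "matt_map"), inherits(post_map, "matt_map"))
  if (!identical(dim(pre_map$matt), dim(post_map$matt))) {
    stop("pre and post maps are on different grids", call. = FALSE)
  }
  common <- is.finite(pre_map$matt) & is.finite(post_map$matt)
  restrict <- function(mp) {
    for (f in c("matt", "amplitude", "quality")) mp[[f]][!common] <- NA_real_
    mp
  }
  list(pre = restrict(pre_map), post = restrict(post_map))
}
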