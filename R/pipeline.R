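#' Pipeline configuration
#'
#' Full configuration of the processing chain. Every parameter has a
#' default; with no input paths the pipeline runs the seeded synthetic
#' demonstration end-to-end (synthetic series, block atlas and tissue
#' transit time map). Configurations round-trip through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param label_path,control_path Optional 4D NIfTI inputs; `NULL` selects
#'   the synthetic demo.
#' @param brain_mask_path,atlas_path,att_path Optional NIfTI inputs on the
#'   series grid.
#' @param times Label durations (ms).
#' @param sim A [sim_config()] used when inputs are synthetic.
#' @param atlas_blocks Block counts for the synthetic atlas.
#' @param isolation An [isolation_params()].
#' @param fit A [fit_options()]; defaults to the continuous branch form with
#'   the automatic noise floor for map fitting.
#' @param min_voxels Minimum defined voxels per region for projection.
#' @param group_size Slices per profile entry.
#' @param att_units Units of the tissue transit time input.
#' @param output_dir Output directory (created on demand).
#' @param seed Integer seed for the synthetic path.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(label_path = NULL, control_path = NULL,
                            brain_mask_path = NULL, atlas_path = NULL,
                            att_path = NULL,
                            times = default_label_durations(),
                            sim = sim_config(times = times),
                            atlas_blocks = c(4, 4, 2),
                            isolation = isolation_params(),
                            fit = fit_options(variant = "continuous",
                                              noise_floor = "auto"),
                            min_voxels = 5, group_size = 1,
                            att_units = "auto",
                            output_dir = tempfile("matt4d_run_"),
                            seed = 1L) {
  structure(list(label_path = label_path, control_path = control_path,
                 brain_mask_path = brain_mask_path, atlas_path = atlas_path,
                 att_path = att_path, times = check_times(times), sim = sim,
                 atlas_blocks = as.integer(atlas_blocks),
                 isolation = isolation, fit = fit,
                 min_voxels = min_voxels, group_size = as.integer(group_size),
                 att_units = att_units, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return The path (write) or the reconstructed `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config(
    label_path = raw$label_path, control_path = raw$control_path,
    brain_mask_path = raw$brain_mask_path, atlas_path = raw$atlas_path,
    att_path = raw$att_path, times = unlist(raw$times),
    sim = do.call(sim_config, raw$sim),
    atlas_blocks = unlist(raw$atlas_blocks),
    isolation = isolation_params(
      frangi = do.call(frangi_params, raw$isolation$frangi),
      threshold = raw$isolation$threshold,
      min_size = raw$isolation$min_size,
      connectivity = raw$isolation$connectivity,
      fwhm_voxels = unlist(raw$isolation$fwhm_voxels),
      range_sigma = raw$isolation$range_sigma),
    fit = do.call(fit_options, raw$fit),
    min_voxels = raw$min_voxels, group_size = raw$group_size,
    att_units = raw$att_units, output_dir = raw$output_dir,
    seed = raw$seed)
  cfg
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[matt4d] ", fmt), ...))
}

#' Run the full mATT pipeline
#'
#' Executes, in order: input loading (or synthetic generation), vessel
#' isolation, per-voxel breakpoint fitting, atlas projection and slice-wise
#' statistics. Every intermediate product (mask, mATT/amplitude/quality/
#' status maps, filled regional map, tables, profile, JSON summary) is
#' written to the configured output directory, together with a manifest
#' listing each file with its MD5 content hash. Deterministic for a fixed
#' configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @param write_outputs Write NIfTI/CSV/JSON artifacts (set `FALSE` for
#'   purely in-memory use).
#' @param verbose Log stage progress and timings to stderr.
#' @return Invisibly, a result bundle: `mask`, `series`, `map`, `projection`
#'   (table + filled map), `profile`, `regression`, `matt_tot`, `atlas`,
#'   optional `att` products, `outputs` (paths) and `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), write_outputs = TRUE,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    ts <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    log_stage(verbose, "%s done in %.1f s", name,
              as.numeric(difftime(Sys.time(), ts, units = "secs")))
    out
  }

  synthetic <- is.null(config$label_path)
  inputs <- stage("load inputs", {
    if (synthetic) {
      sc <- config$sim
      sc$seed <- config$seed
      truth <- generate_vessel_tree(sc)
      sim <- simulate_inflow_series(truth, sc)
      atlas <- generate_block_atlas(sc$shape, config$atlas_blocks)
      att <- NULL
      if (!is.null(config$att_path)) att <- normalize_time_units(
        read_volume(config$att_path), config$att_units)
      list(label = sim$label, control = sim$control,
           brain_mask = sim$brain_mask, atlas = atlas, att = att,
           times = sc$times, voxel_dims = sc$voxel_dims, reference = NULL,
           truth = truth)
    } else {
      ser <- read_series(config$label_path, config$control_path, config$times)
      brain <- if (!is.null(config$brain_mask_path)) {
        read_volume(config$brain_mask_path) != 0
      } else {
        # fallback: simple intensity threshold on the mean control volume
        ctl <- apply(ser$control, 1:3, mean)
        ctl > 0.25 * max(ctl)
      }
      atlas <- if (!is.null(config$atlas_path)) {
        a <- read_volume(config$atlas_path)
        array(as.integer(round(a)), dim = dim(a))
      } else NULL
      att <- if (!is.null(config$att_path)) {
        normalize_time_units(read_volume(config$att_path), config$att_units)
      } else NULL
      list(label = ser$label, control = ser$control, brain_mask = brain,
           atlas = atlas, att = att, times = ser$times,
           voxel_dims = ser$voxel_dims, reference = ser$reference)
    }
  })

  iso <- stage("vessel isolation", isolate_vessels(
    inputs$label, inputs$control, inputs$brain_mask, inputs$times,
    voxel_dims = inputs$voxel_dims, params = config$isolation))
  log_stage(verbose, "vessel mask: %d voxels", sum(iso$mask$mask))

  map <- stage("breakpoint fitting",
               fit_map(iso$series, iso$mask, config$fit,
                       noise_reference = iso$raw_series))
  log_stage(verbose, "fit tally: %s",
            paste(names(map$tally), as.integer(map$tally), sep = "=",
                  collapse = " "))

  projection <- NULL
  if (!is.null(inputs$atlas)) {
    projection <- stage("atlas projection",
                        project_to_regions(map, inputs$atlas,
                                           min_voxels = config$min_voxels))
    if (!is.null(inputs$att)) {
      projection$table <- add_regional_mean(projection$table, inputs$atlas,
                                            inputs$att, "mean_att_ms")
    }
  }

  profile <- stage("slice statistics",
                   slice_profile(map, slice_thickness = inputs$voxel_dims[3],
                                 group_size = config$group_size))
  regression <- if (nrow(profile) >= 3) fit_distance_regression(profile) else NULL
  mtot <- matt_total(map)

  outputs <- character(0)
  if (write_outputs) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    od <- function(f) file.path(config$output_dir, f)
    ref <- inputs$reference
    vdim <- inputs$voxel_dims
    wv <- function(vol, f) { write_volume(vol, od(f), reference = ref,
                                          voxel_dims = vdim); od(f) }
    outputs <- c(outputs, wv(iso$mask$mask, "vessel_mask.nii.gz"))
    outputs <- c(outputs, wv(map$matt, "matt_ms.nii.gz"))
    outputs <- c(outputs, wv(map$amplitude, "amplitude.nii.gz"))
    outputs <- c(outputs, wv(map$quality, "r2.nii.gz"))
    outputs <- c(outputs, wv(map$status, "fit_status.nii.gz"))
    if (!is.null(projection)) {
      outputs <- c(outputs, wv(projection$filled, "matt_regional_ms.nii.gz"))
      write_regional_table(projection$table, od("regional_table.csv"))
      outputs <- c(outputs, od("regional_table.csv"))
    }
    write.csv(as.data.frame(profile), od("slice_profile.csv"),
              row.names = FALSE)
    outputs <- c(outputs, od("slice_profile.csv"))
    yaml::write_yaml(iso$mask$provenance, od("mask_provenance.yaml"))
    outputs <- c(outputs, od("mask_provenance.yaml"))
    summary_list <- list(
      matt_tot_ms = mtot,
      n_mask_voxels = sum(iso$mask$mask),
      n_fitted_voxels = sum(is.finite(map$matt)),
      fit_tally = as.list(setNames(as.integer(map$tally), names(map$tally))),
      noise_floor = map$noise_floor,
      slope_ms_per_mm = if (!is.null(regression)) regression$slope else NA,
      intercept_ms = if (!is.null(regression)) regression$intercept else NA,
      adj_r2 = if (!is.null(regression)) regression$adj_r2 else NA,
      seed = config$seed, synthetic = synthetic)
    jsonlite::write_json(summary_list, od("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    outputs <- c(outputs, od("summary.json"))
    manifest <- data.frame(file = basename(outputs),
                           md5 = unname(tools::md5sum(outputs)))
    jsonlite::write_json(manifest, od("manifest.json"), pretty = TRUE)
    outputs <- c(outputs, od("manifest.json"))
  }
  log_stage(verbose, "pipeline complete in %.1f s",
            as.numeric(difftime(Sys.time(), t0, units = "secs")))

  invisible(list(mask = iso$mask, series = iso$series, map = map,
                 projection = projection, profile = profile,
                 regression = regression, matt_tot = mtot,
                 atlas = inputs$atlas, att = inputs$att, truth = inputs$truth,
                 brain_mask = inputs$brain_mask,
                 outputs = outputs, config = config))
}

#' Compare two pipeline runs (pre/post challenge)
#'
#' Computes regional difference tables from two result bundles on a shared
#' atlas, both uncorrected and after restriction to the common vessel-voxel
#' set of the pre-challenge analysis (so differences are not driven by
#' newly visible distal vessels).
#'
#' @param pre,post Result bundles from [run_pipeline()] sharing a grid and
#'   atlas.
#' @param min_voxels Minimum defined voxels per region.
#' @return List with `delta` (uncorrected table), `delta_common`
#'   (common-mask table), `slope_reduction` (ms/mm) and the two common-mask
#'   restricted maps.
#' @export
compare_runs <- function(pre, post, min_voxels = 5) {
  if (is.null(pre$atlas) || !identical(dim(pre$atlas), dim(post$map$matt))) {
    stop("runs must share an atlas on a common grid", call. = FALSE)
  }
  atlas <- pre$atlas
  tab_pre <- project_to_regions(pre$map, atlas, min_voxels)$table
  tab_post <- project_to_regions(post$map, atlas, min_voxels)$table
  delta <- regional_delta(tab_pre, tab_post)
  cm <- apply_common_mask(pre$map, post$map)
  tab_pre_c <- project_to_regions(cm$pre, atlas, min_voxels)$table
  tab_post_c <- project_to_regions(cm$post, atlas, min_voxels)$table
  delta_common <- regional_delta(tab_pre_c, tab_post_c)
  slope_red <- if (!is.null(pre$regression) && !is.null(post$regression)) {
    slope_difference(pre$regression, post$regression)
  } else NA_real_
  list(delta = delta, delta_common = delta_common,
       slope_reduction = slope_red, pre_common = cm$pre, post_common = cm$post)
}
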