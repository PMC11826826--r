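# Shared synthetic fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small noiseless tree + series for unit tests
small_noiseless_sim <- function() {
  cached("small_noiseless", {
    cfg <- sim_config(shape = c(32, 32, 32), gradient = 5, b0 = 500,
                      noise_sigma = 0, blob_count = 0, n_trunks = 2,
                      seed = 11)
    truth <- generate_vessel_tree(cfg)
    sim <- simulate_inflow_series(truth, cfg)
    list(cfg = cfg, truth = truth, sim = sim)
  })
}

# full end-to-end pipeline run at a given caudal-cranial gradient: 64^3
# volume, uniform per-voxel SNR 10 (m = 10, noise sd 1), blob artifacts,
# component-size threshold tuned (as per dataset) to remove artifact rims,
# 3-slice profile grouping as in the published slice curves
e2e_run <- function(gradient, seed = 101) {
  key <- sprintf("e2e_g%.2f_s%d", gradient, seed)
  cached(key, {
    cfg <- pipeline_config(
      sim = sim_config(shape = c(64, 64, 64), gradient = gradient, b0 = 500,
                       m0 = 10, m_taper = 0, noise_sigma = 1, blob_count = 3,
                       n_trunks = 4, seed = seed),
      isolation = isolation_params(min_size = 200),
      atlas_blocks = c(4, 4, 2),
      group_size = 3,
      seed = seed)
    run_pipeline(cfg, write_outputs = FALSE, verbose = FALSE)
  })
}

# a straight synthetic tube of gaussian cross-section along z
tube_volume <- function(shape = c(32, 32, 32), sd_px = 1.5, center = NULL) {
  if (is.null(center)) center <- shape[1:2] / 2
  xy <- outer((seq_len(shape[1]) - center[1])^2,
              (seq_len(shape[2]) - center[2])^2, "+")
  slice <- exp(-xy / (2 * sd_px^2))
  array(rep(slice, shape[3]), dim = shape)
}
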