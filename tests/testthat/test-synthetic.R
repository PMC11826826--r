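test_that("vessel tree generation is seeded-deterministic and linear in path", {
  cfg <- sim_config(shape = c(24, 24, 24), gradient = 5, b0 = 500, seed = 3)
  t1 <- generate_vessel_tree(cfg)
  t2 <- generate_vessel_tree(cfg)
  expect_identical(t1$voxels, t2$voxels)

  # linear construction: b = b0 + gradient * path
  expect_equal(t1$voxels$true_b, 500 + 5 * t1$voxels$path_distance)
  # a voxel at 100 mm path with gradient 5 and b0 500 would sit at 1000 ms
  expect_equal(500 + 5 * 100, 1000)

  # all voxels inside the stated shape, positive parameters
  v <- t1$voxels
  expect_true(all(v$x >= 1 & v$x <= 24 & v$y >= 1 & v$y <= 24 &
                    v$z >= 1 & v$z <= 24))
  expect_true(all(v$true_m > 0 & v$true_h > 0 & v$true_b >= 0))

  # zero gradient collapses every breakpoint to b0
  t0 <- generate_vessel_tree(sim_config(shape = c(24, 24, 24), gradient = 0,
                                        b0 = 700, seed = 3))
  expect_true(all(t0$voxels$true_b == 700))
})

test_that("breakpoints are monotone along branches and across slices", {
  tr <- small_noiseless_sim()$truth
  v <- tr$voxels
  for (br in unique(v$branch)) {
    vb <- v[v$branch == br, ]
    vb <- vb[order(vb$z), ]
    expect_true(all(diff(vb$true_b) >= 0))
  }
  slice_means <- tapply(v$true_b, v$z, mean)
  expect_true(all(diff(slice_means) > -1e-9))
})

test_that("tree generation rejects undersized volumes", {
  expect_error(generate_vessel_tree(sim_config(shape = c(8, 24, 24))),
               "dimension 1")
})

test_that("simulated series inverts exactly under subtraction and models the signal", {
  fx <- small_noiseless_sim()
  sim <- fx$sim
  s <- pairwise_subtract(sim$label, sim$control, fx$cfg$times)
  expect_equal(s$data, sim$delta_true, tolerance = 1e-12)

  # noiseless forward values at a vessel voxel follow the saturation model
  v1 <- fx$truth$voxels[1, ]
  curve <- sim$delta_true[v1$x, v1$y, v1$z, ]
  expect_equal(curve,
               piecewise_saturation(fx$cfg$times, v1$true_b, v1$true_m,
                                    v1$true_h, variant = fx$cfg$variant))
  # the signal is zero before the breakpoint
  expect_true(all(curve[fx$cfg$times <= v1$true_b] == 0))

  # seeded determinism
  sim2 <- simulate_inflow_series(fx$truth, fx$cfg)
  expect_identical(sim$label, sim2$label)
})

test_that("background noise in the difference images is zero-mean", {
  cfg <- sim_config(shape = c(32, 32, 32), noise_sigma = 1, blob_count = 0,
                    n_trunks = 1, seed = 21)
  truth <- generate_vessel_tree(cfg)
  sim <- simulate_inflow_series(truth, cfg)
  delta <- sim$control - sim$label
  vessel <- array(FALSE, dim = cfg$shape)
  vessel[cbind(truth$voxels$x, truth$voxels$y, truth$voxels$z)] <- TRUE
  bg <- sim$brain_mask & !vessel
  vals <- delta[, , , 1][bg]
  vals <- vals[seq_len(min(10000, length(vals)))]
  # CLT bound: |mean| < 3 * sigma / sqrt(n) = 0.03 < 0.05
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("block atlas partitions the grid into the requested regions", {
  a <- generate_block_atlas(c(16, 16, 16), c(2, 2, 2))
  expect_identical(sort(unique(as.vector(a))), 1:8)
  expect_true(all(a >= 1))                      # every voxel has one label

  a1 <- generate_block_atlas(c(10, 12, 14), c(1, 1, 1))
  expect_true(all(a1 == 1L))

  # contiguity: each region is one rectangular block
  a2 <- generate_block_atlas(c(8, 8, 8), c(2, 1, 1))
  expect_identical(unique(as.vector(a2[1:4, , ])), 1L)
  expect_identical(unique(as.vector(a2[5:8, , ])), 2L)

  expect_error(generate_block_atlas(c(8, 8, 8), c(9, 1, 1)), "axis 1")
})

test_that("tissue transit time map lags the feeding vessel by the tissue delay", {
  fx <- small_noiseless_sim()
  tr <- fx$truth
  att0 <- simulate_tissue_att(tr, tissue_delay = 0, noise_sigma = 0, seed = 4)
  v <- tr$voxels
  at_vessels <- att0[cbind(v$x, v$y, v$z)]
  expect_equal(at_vessels, v$true_b, tolerance = 1e-12)

  att600 <- simulate_tissue_att(tr, tissue_delay = 600, noise_sigma = 0, seed = 4)
  expect_equal(att600 - att0, array(600, dim = dim(att0)), tolerance = 1e-12)

  # regional means of a noiseless map correlate perfectly with the
  # underlying breakpoints (affine relation)
  atlas <- generate_block_atlas(tr$shape, c(2, 2, 2))
  m_att <- tapply(att600, atlas, mean)
  m_b <- tapply(att0, atlas, mean)
  expect_equal(unname(cor(m_att, m_b)), 1, tolerance = 1e-12)

  expect_error(simulate_tissue_att(
    structure(list(voxels = tr$voxels[0, ], shape = tr$shape,
                   voxel_dims = tr$voxel_dims), class = "vessel_truth")),
    "empty")
})
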