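make_map_array <- function(shape, coords, values) {
  m <- array(NA_real_, dim = shape)
  m[coords] <- values
  m
}

test_that("regional projection averages defined voxels and fills regions", {
  shape <- c(8, 8, 4)
  atlas <- generate_block_atlas(shape, c(2, 1, 1))
  m <- make_map_array(shape, rbind(c(1, 1, 1), c(2, 1, 1)), c(1000, 2000))
  pr <- project_to_regions(m, atlas, min_voxels = 1)
  r1 <- pr$table[pr$table$region_label == 1, ]
  expect_equal(r1$mean_matt_ms, 1500)
  expect_equal(r1$n_vessel_voxels, 2L)
  expect_true(all(pr$filled[atlas == 1] == 1500))

  # a region without defined voxels stays undefined
  r2 <- pr$table[pr$table$region_label == 2, ]
  expect_true(is.na(r2$mean_matt_ms))
  expect_true(all(is.na(pr$filled[atlas == 2])))

  # min_voxels gates sparse regions
  pr5 <- project_to_regions(m, atlas, min_voxels = 5)
  expect_true(all(is.na(pr5$table$mean_matt_ms)))

  expect_error(project_to_regions(m, atlas[, , 1:2]), "grids differ")
})

test_that("projection conserves the global mean and is idempotent", {
  set.seed(71)
  shape <- c(16, 16, 8)
  atlas <- generate_block_atlas(shape, c(4, 4, 2))
  m <- array(NA_real_, dim = shape)
  sel <- sample(prod(shape), 400)
  m[sel] <- runif(400, 500, 2000)
  pr <- project_to_regions(m, atlas, min_voxels = 1)
  tab <- pr$table
  weighted <- sum(tab$mean_matt_ms * tab$n_vessel_voxels, na.rm = TRUE) /
    sum(tab$n_vessel_voxels[!is.na(tab$mean_matt_ms)])
  expect_equal(weighted, mean(m[is.finite(m) & atlas > 0]), tolerance = 1e-12)

  # projecting the filled map reproduces the same regional means
  pr2 <- project_to_regions(pr$filled, atlas, min_voxels = 1)
  expect_equal(pr2$table$mean_matt_ms, tab$mean_matt_ms, tolerance = 1e-12)
})

test_that("regional deltas difference post minus pre with NA propagation", {
  shape <- c(8, 8, 4)
  atlas <- generate_block_atlas(shape, c(2, 2, 1))
  m_pre <- array(NA_real_, shape); m_post <- array(NA_real_, shape)
  m_pre[1:2, 1, 1] <- 1600; m_post[1:2, 1, 1] <- 1400   # region 1
  m_pre[5, 1, 1] <- 1000                                 # region 2: pre only
  t_pre <- project_to_regions(m_pre, atlas, min_voxels = 1)$table
  t_post <- project_to_regions(m_post, atlas, min_voxels = 1)$table

  d <- regional_delta(t_pre, t_post)
  expect_equal(d$delta[d$region_label == 1], -200)
  expect_true(is.na(d$delta[d$region_label == 2]))

  d0 <- regional_delta(t_pre, t_pre)
  expect_true(all(d0$delta[!is.na(d0$delta)] == 0))

  t_bad <- t_post[t_post$region_label != 4, ]
  expect_error(regional_delta(t_pre, t_bad), "label sets differ")
})

test_that("the common vessel mask removes voxels newly visible post-challenge", {
  fx <- small_noiseless_sim()
  cfg <- fx$cfg
  sim <- fx$sim
  series <- pairwise_subtract(sim$label, sim$control, cfg$times,
                              brain_mask = sim$brain_mask)
  v <- fx$truth$voxels
  mask_pre <- array(FALSE, cfg$shape)
  ord <- order(v$true_b)
  keep_pre <- ord[seq_len(floor(nrow(v) * 0.7))]   # distal voxels invisible pre
  mask_pre[cbind(v$x[keep_pre], v$y[keep_pre], v$z[keep_pre])] <- TRUE
  mask_post <- array(FALSE, cfg$shape)
  mask_post[cbind(v$x, v$y, v$z)] <- TRUE

  map_pre <- fit_map(series, mask_pre, fit_options(variant = "continuous"))
  map_post <- fit_map(series, mask_post, fit_options(variant = "continuous"))

  cm <- apply_common_mask(map_pre, map_post)
  expect_identical(is.finite(cm$post$matt), is.finite(map_pre$matt))

  # identical defined sets pass through unchanged
  cm2 <- apply_common_mask(map_pre, map_pre)
  expect_equal(cm2$pre$matt, map_pre$matt)

  # regions gaining distal (late-arriving) voxels post-challenge show a
  # spurious positive delta that the common mask removes
  atlas <- generate_block_atlas(cfg$shape, c(2, 2, 2))
  t_pre <- project_to_regions(map_pre, atlas, min_voxels = 1)$table
  t_post <- project_to_regions(map_post, atlas, min_voxels = 1)$table
  d_raw <- regional_delta(t_pre, t_post)
  t_pre_c <- project_to_regions(cm$pre, atlas, min_voxels = 1)$table
  t_post_c <- project_to_regions(cm$post, atlas, min_voxels = 1)$table
  d_c <- regional_delta(t_pre_c, t_post_c)
  both <- !is.na(d_raw$delta) & !is.na(d_c$delta)
  expect_true(all(d_c$delta[both] <= d_raw$delta[both] + 1e-9))
  expect_true(all(abs(d_c$delta[both]) < 1e-6))
})

test_that("regional means of auxiliary maps join the table", {
  shape <- c(8, 8, 4)
  atlas <- generate_block_atlas(shape, c(2, 1, 1))
  m <- make_map_array(shape, rbind(c(1, 1, 1)), 1000)
  tab <- project_to_regions(m, atlas, min_voxels = 1)$table
  aux <- array(seq_len(prod(shape)), shape)
  tab <- add_regional_mean(tab, atlas, aux, "mean_att_ms")
  expect_equal(tab$mean_att_ms[tab$region_label == 1], mean(aux[atlas == 1]))
})
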