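times8 <- default_label_durations()

test_that("the saturation model has the stated limits and branch behaviour", {
  # zero before (and at) the breakpoint
  expect_equal(piecewise_saturation(800, b = 800, m = 10, h = 400), 0)
  expect_equal(piecewise_saturation(100, b = 800, m = 10, h = 400), 0)
  # literal branch: half maximum at t = h when b = 0
  expect_equal(piecewise_saturation(400, b = 0, m = 10, h = 400), 5)
  # approaches the saturation level at late times
  expect_equal(piecewise_saturation(1e9, b = 0, m = 10, h = 400), 10,
               tolerance = 1e-6)
  # continuous branch is shifted: half maximum at t = b + h
  expect_equal(piecewise_saturation(1200, b = 800, m = 10, h = 400,
                                    variant = "continuous"), 5)
  expect_error(piecewise_saturation(100, 0, 10, -1), "`h`")
})

test_that("single-voxel fits recover noiseless parameters and flag flat curves", {
  y <- piecewise_saturation(times8, 800, 10, 400)
  f <- fit_voxel(times8, y)
  expect_equal(f$status, "ok")
  expect_lt(abs(f$b - 800), 1)
  expect_equal(f$m, 10, tolerance = 1e-3)
  expect_equal(f$h, 400, tolerance = 1)
  expect_gte(f$r2, 0.999)

  yc <- piecewise_saturation(times8, 837.5, 10, 400, variant = "continuous")
  fc <- fit_voxel(times8, yc, fit_options(variant = "continuous"))
  expect_lt(abs(fc$b - 837.5), 1)

  f0 <- fit_voxel(times8, rep(0, 8))
  expect_equal(f0$status, "below_noise")
  expect_true(is.na(f0$b))

  expect_error(fit_voxel(c(100, 200, 400), c(0, 0, 1)), "at least 4")
  expect_error(fit_voxel(times8, c(rep(0, 7), NaN)), "non-finite")
})

test_that("a curve first visible at 1200 ms brackets the breakpoint with the oracle", {
  y <- piecewise_saturation(times8, 900, 10, 400)   # literal, zeros up to 800
  expect_true(all(y[times8 <= 800] == 0) && y[times8 == 1200] > 0)
  f <- fit_voxel(times8, y)
  o <- oracle_fit_b(times8, y, "literal")
  expect_lt(abs(f$b - o$b), 1)
  expect_gte(f$b, 800)
  expect_lte(f$b, 1200)
})

test_that("the production fitter matches the exhaustive 1 ms oracle", {
  set.seed(41)
  for (variant in c("literal", "continuous")) {
    for (i in 1:10) {
      b <- runif(1, 0, 1000); m <- runif(1, 5, 20); h <- runif(1, 100, 800)
      y <- piecewise_saturation(times8, b, m, h, variant = variant)
      f <- fit_voxel(times8, y, fit_options(variant = variant))
      o <- oracle_fit_b(times8, y, variant)
      expect_lt(abs(f$b - o$b), 1)
    }
  }
})

test_that("fits are invariant to curve scaling and equivariant to time shifts", {
  set.seed(43)
  for (i in 1:5) {
    b <- runif(1, 200, 1000); m <- runif(1, 5, 20); h <- runif(1, 100, 800)
    y <- piecewise_saturation(times8, b, m, h, variant = "continuous") +
      rnorm(8, 0, 0.2)
    y <- pmax(y, 0)
    f1 <- fit_voxel(times8, y, fit_options(variant = "continuous"))
    fk <- fit_voxel(times8, 3 * y, fit_options(variant = "continuous"))
    expect_equal(fk$b, f1$b, tolerance = 0.5)
    expect_equal(fk$h, f1$h, tolerance = 0.01 * f1$h + 0.5)
    expect_equal(fk$m, 3 * f1$m, tolerance = 1e-2)

    # shifting all times and the breakpoint jointly leaves the continuous
    # model's values unchanged
    delta <- 300
    v1 <- piecewise_saturation(times8, b, m, h, variant = "continuous")
    v2 <- piecewise_saturation(times8 + delta, b + delta, m, h,
                               variant = "continuous")
    expect_equal(v1, v2, tolerance = 1e-12)
  }
})

test_that("map fitting recovers ground truth on the vessel tree", {
  fx <- small_noiseless_sim()
  sim <- fx$sim
  series <- pairwise_subtract(sim$label, sim$control, fx$cfg$times,
                              brain_mask = sim$brain_mask)
  v <- fx$truth$voxels
  mask <- array(FALSE, dim = fx$cfg$shape)
  mask[cbind(v$x, v$y, v$z)] <- TRUE
  map <- fit_map(series, mask, fit_options(variant = "continuous"))
  fitted <- map$matt[cbind(v$x, v$y, v$z)]
  expect_true(all(is.finite(fitted)))
  expect_lt(max(abs(fitted - v$true_b)), 1)

  # matt_total equals the largest surviving true breakpoint
  expect_equal(matt_total(map), max(v$true_b), tolerance = 1)

  # single-voxel mask yields a single defined voxel
  m1 <- array(FALSE, dim = fx$cfg$shape)
  m1[v$x[1], v$y[1], v$z[1]] <- TRUE
  map1 <- fit_map(series, m1, fit_options(variant = "continuous"))
  expect_equal(sum(is.finite(map1$matt)), 1)

  expect_error(fit_map(series, array(FALSE, dim = fx$cfg$shape)), "empty")
})

test_that("matt_total summarizes defined voxels", {
  fake <- structure(list(matt = array(c(1000, 2000, NA, NA), c(2, 2, 1))),
                    class = "matt_map")
  expect_equal(matt_total(fake), 2000)
  expect_equal(matt_total(fake, q = 50), 1500)
  fake$matt[] <- NA
  expect_error(matt_total(fake), "no defined")
})

test_that("slice-mean fitted breakpoints rise monotonically at moderate noise", {
  cfg <- sim_config(shape = c(48, 48, 48), gradient = 8, b0 = 500, m0 = 10,
                    noise_sigma = 1, blob_count = 0, n_trunks = 3, seed = 55)
  truth <- generate_vessel_tree(cfg)
  sim <- simulate_inflow_series(truth, cfg)
  series <- pairwise_subtract(sim$label, sim$control, cfg$times,
                              brain_mask = sim$brain_mask)
  v <- truth$voxels
  mask <- array(FALSE, dim = cfg$shape)
  mask[cbind(v$x, v$y, v$z)] <- TRUE
  smoothed <- guided_bilateral_smooth(series, mask)
  map <- fit_map(smoothed, mask,
                 fit_options(variant = "continuous", noise_floor = "auto"),
                 noise_reference = series)
  prof <- slice_profile(map, slice_thickness = 1)
  rho <- cor(prof$distance, prof$mean_matt, method = "spearman")
  expect_gt(rho, 0.9)
})
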