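test_that("direction sampling honours degenerate dispersion and the sign rule", {
  ph <- column_phantom(fibre_cols = list(c(5, 5)))
  at <- c(4, 4, 8)                      # world mm inside the fibre column
  d <- sample_direction(ph$field, at)
  expect_equal(as.numeric(d), c(0, 0, 1))
  d2 <- sample_direction(ph$field, at, prev_dir = c(0, 0, -1))
  expect_equal(as.numeric(d2), c(0, 0, -1))
  # fibre-free voxel inside the mask returns NULL (dead end)
  expect_null(sample_direction(ph$field, c(4, 4, 0)))
})

test_that("fibre selection frequencies match the mixture weights", {
  g <- iso_grid(c(3, 3, 3))
  dir1 <- array(0, c(3, 3, 3, 3)); dir2 <- array(0, c(3, 3, 3, 3))
  dir1[2, 2, 2, 3] <- 1                  # +z
  dir2[2, 2, 2, 1] <- 1                  # +x
  f <- orientation_field(g, dir1, dir2, w1 = array(0.7, c(3, 3, 3)))
  n <- 1e5
  draws <- sample_direction(f, c(1, 1, 1), n = n, rng_seed = 99)
  p_hat <- mean(draws[, 3] == 1)
  expect_lt(abs(p_hat - 0.7), 3 * sqrt(0.7 * 0.3 / n))
})

test_that("dispersion draws concentrate around the fibre as kappa grows", {
  g <- iso_grid(c(3, 3, 3))
  dir1 <- array(0, c(3, 3, 3, 3)); dir1[, , , 3] <- 1
  for (kap in c(20, 200)) {
    f <- orientation_field(g, dir1, kappa = kap)
    draws <- sample_direction(f, c(1, 1, 1), n = 2000, rng_seed = 5)
    expect_true(all(abs(sqrt(rowSums(draws^2)) - 1) < 1e-9))
    expect_gt(mean(draws[, 3]), 1 - 2 / kap)    # E[cos] ~ 1 - 1/kappa
  }
})

test_that("streamlines in a straight tube reach the terminus with the right length", {
  ph <- column_phantom(shape = c(8, 8, 30), fibre_cols = list(c(4, 4)))
  seed_pt <- c(3, 3, 1)                  # bottom of the column
  params <- tracking_params(step_mm = 0.5, rng_seed = 2)
  sl <- propagate_streamline(seed_pt, ph$field, ph$terminus, params,
                             init_sign = 1L)
  expect_equal(sl$termination_reason, "terminus")
  len <- sum(sqrt(rowSums(diff(sl$points)^2)))
  expect_lt(abs(len - (28 - 1)), 2 * params$step_mm + 1e-9)
})

test_that("dead ends, mask exits and the step cap are reported", {
  ph <- column_phantom(shape = c(8, 8, 30), fibre_cols = list(c(4, 4)),
                       gap = list(c(4, 4, 15)))
  params <- tracking_params(step_mm = 0.5, rng_seed = 2)
  sl <- propagate_streamline(c(3, 3, 1), ph$field, ph$terminus, params,
                             init_sign = 1L)
  expect_equal(sl$termination_reason, "no_fiber")
  sl_down <- propagate_streamline(c(3, 3, 1), ph$field, ph$terminus, params,
                                  init_sign = -1L)
  expect_equal(sl_down$termination_reason, "no_fiber")  # below-slab voxel

  capped <- tracking_params(step_mm = 0.5, max_steps = 3, rng_seed = 2)
  sl3 <- propagate_streamline(c(3, 3, 1), ph$field, ph$terminus, capped,
                              init_sign = 1L)
  expect_equal(sl3$termination_reason, "max_steps")
  expect_equal(nrow(sl3$points), 4)       # seed + exactly 3 steps
  expect_error(propagate_streamline(c(0, 0, 10), ph$field, ph$terminus,
                                    params), "outside")
})

test_that("hit fractions equal voxel-graph reachability for kappa = Inf fields", {
  ph <- column_phantom(shape = c(10, 10, 24),
                       fibre_cols = list(c(3, 3), c(5, 5), c(7, 7), c(5, 8)),
                       gap = list(c(5, 5, 12)))
  params <- tracking_params(samples_per_seed_voxel = 5, jitter = FALSE,
                            bidirectional = TRUE, rng_seed = 31)
  hm <- seed_to_terminus_fractions(ph$field, ph$seed, ph$terminus, params)
  oracle <- reachability_oracle(ph$field, ph$seed, ph$terminus)
  expect_true(all(hm$data %in% c(0, 1)))
  expect_identical(hm$data, oracle)
  expect_equal(hm$data[5, 5, 2], 0)       # interrupted column never hits
  expect_equal(hm$data[3, 3, 2], 1)
})

test_that("a 50/50 fork yields a hit fraction near one half", {
  shape <- c(9, 9, 12)
  g <- iso_grid(shape)
  dir1 <- array(0, c(shape, 3)); dir2 <- array(0, c(shape, 3))
  tmask <- array(0, shape)
  dir1[5, 5, 2:5, 3] <- 1                 # approach column
  dir1[5, 5, 6, 3] <- 1; dir2[5, 5, 6, 1] <- 1   # the fork voxel
  dir1[5, 5, 7:10, 3] <- 1                # upward branch to terminus
  tmask[5, 5, ] <- 1
  # lateral branch: fibre-free corridor, streamline dies there
  tmask[6:9, 5, 6] <- 1
  seed <- array(0, shape); seed[5, 5, 2] <- 1
  term <- array(0, shape); term[5, 5, 11] <- 1
  tmask <- pmax(tmask, term)
  f <- orientation_field(g, dir1, dir2, w1 = array(0.5, shape),
                         tracking_mask = mask3d(tmask, g$affine))
  n <- 1000
  params <- tracking_params(step_mm = 1, samples_per_seed_voxel = n,
                            jitter = FALSE, rng_seed = 17,
                            bidirectional = TRUE)
  hm <- seed_to_terminus_fractions(f, mask3d(seed, g$affine),
                                   mask3d(term, g$affine), params)
  expect_lt(abs(hm$data[5, 5, 2] - 0.5), 3 * sqrt(0.25 / n))
})

test_that("fractions lie in [0,1], are zero off the seed, and repeat bit-identically", {
  ph <- column_phantom(fibre_cols = list(c(3, 3), c(6, 6)))
  params <- tracking_params(samples_per_seed_voxel = 25, rng_seed = 8,
                            bidirectional = TRUE)
  h1 <- seed_to_terminus_fractions(ph$field, ph$seed, ph$terminus, params)
  h2 <- seed_to_terminus_fractions(ph$field, ph$seed, ph$terminus, params)
  expect_identical(h1$data, h2$data)
  expect_true(all(h1$data >= 0 & h1$data <= 1))
  expect_true(all(h1$data[ph$seed$data == 0] == 0))
})

test_that("growing the terminus never lowers a hit fraction (common random numbers)", {
  spec <- phantom_spec(kappa = 40)
  ph <- make_subject_phantom(spec, deform = FALSE)
  params <- tracking_params(samples_per_seed_voxel = 10, rng_seed = 13,
                            bidirectional = TRUE)
  small <- ph$terminus
  grown_data <- small$data
  grown_data[, , dim(grown_data)[3] - 6] <- 1   # extra slab joins the terminus
  grown <- mask3d(pmax(grown_data, small$data), small$affine)
  h_small <- seed_to_terminus_fractions(ph$field, ph$vim, small, params)
  h_grown <- seed_to_terminus_fractions(ph$field, ph$vim, grown, params)
  expect_true(all(h_grown$data >= h_small$data))
})

test_that("degenerate seed/terminus configurations are rejected", {
  ph <- column_phantom(fibre_cols = list(c(5, 5)))
  empty <- mask3d(array(0, ph$grid$shape), ph$grid$affine)
  expect_error(seed_to_terminus_fractions(ph$field, empty, ph$terminus,
                                          tracking_params()), "empty")
  expect_error(seed_to_terminus_fractions(ph$field, ph$seed, ph$seed,
                                          tracking_params()), "overlap")
})
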