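test_that("voxelwise median handles odd, even and identical stacks", {
  g <- iso_grid(c(2, 2, 2))
  mk <- function(x) volume3d(array(x, c(2, 2, 2)), g$affine)
  odd <- median_combine(list(mk(0.1), mk(0.5), mk(0.9)))
  expect_equal(odd$data[1, 1, 1], 0.5)
  even <- median_combine(list(mk(0.2), mk(0.4)))
  expect_equal(even$data[2, 2, 2], 0.3)          # midpoint convention
  same <- median_combine(list(mk(0.7), mk(0.7), mk(0.7)))
  expect_equal(same$data, mk(0.7)$data)
  expect_error(median_combine(list()), "no maps")
  g2 <- iso_grid(c(2, 2, 2), origin = c(1, 0, 0))
  expect_error(median_combine(list(mk(1), volume3d(array(1, c(2, 2, 2)),
                                                   g2$affine))), "mismatch")
})

test_that("median combination is monotone", {
  g <- iso_grid(c(4, 4, 4))
  set.seed(6)
  lo <- replicate(5, volume3d(array(runif(64), c(4, 4, 4)), g$affine),
                  simplify = FALSE)
  hi <- lapply(lo, function(v) volume3d(v$data + runif(64, 0, 0.5), g$affine))
  expect_true(all(median_combine(hi)$data >= median_combine(lo)$data))
})

test_that("max normalization yields max exactly 1 and is scale invariant", {
  g <- iso_grid(c(3, 3, 3))
  a <- array(runif(27, 0, 0.25), c(3, 3, 3)); a[2, 2, 2] <- 0.25
  v <- volume3d(a, g$affine)
  n1 <- max_normalize(v)
  expect_equal(max(n1$data), 1)
  expect_equal(n1$data[2, 2, 2], 1)
  expect_equal(attr(n1, "pre_norm_max"), 0.25)
  expect_equal(max_normalize(n1)$data, n1$data)              # idempotent
  expect_equal(max_normalize(volume3d(a * 7.3, g$affine))$data, n1$data)
  expect_error(max_normalize(volume3d(array(0, c(3, 3, 3)), g$affine)),
               "undefined")
})

test_that("warping a delta hotspot back to template inverts the subject shift", {
  g <- iso_grid(c(11, 11, 11))
  a <- array(0, c(11, 11, 11)); a[6, 6, 6] <- 1
  map <- volume3d(a, g$affine)
  s <- subject_hotspot(map, rigid_transform(diag(3), c(2, 0, 0)), "s1")
  w <- warp_hotspot_to_template(s, g)
  expect_equal(w$data[4, 6, 6], 1)       # peak moved -2 mm in template space
  expect_equal(sum(w$data), 1)
  s_id <- subject_hotspot(map, identity_transform(), "s2")
  expect_identical(warp_hotspot_to_template(s_id, g)$data, map$data)
})

test_that("warping matches a fine-grid brute-force resampling oracle", {
  g <- iso_grid(c(12, 12, 12), res = 2)
  v <- smooth_volume(g)
  xf <- affine_transform(matrix(c(1.03, 0.02, 0, 0.8,
                                  0, 0.98, -0.01, -0.4,
                                  0.01, 0, 1.01, 0.3,
                                  0, 0, 0, 1), 4, 4, byrow = TRUE))
  s <- subject_hotspot(v, xf, "s")
  w <- warp_hotspot_to_template(s, g)
  # oracle: explicit per-voxel loop, affine-map each template centre and
  # trilinearly interpolate by hand
  idx <- ntatlas:::all_voxel_indices(g$shape)
  pts <- ntatlas:::voxel_to_world(idx, g$affine)
  mapped <- cbind(pts, 1) %*% t(xf$matrix)
  vox <- cbind(mapped[, 1:3], 1) %*% t(solve(g$affine))
  oracle <- vapply(seq_len(nrow(vox)), function(r) {
    p <- vox[r, 1:3]; i0 <- floor(p); f <- p - i0; acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      c_idx <- i0 + c(dx, dy, dz)
      if (all(c_idx >= 0 & c_idx <= g$shape - 1)) {
        wgt <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
        acc <- acc + wgt * v$data[matrix(c_idx + 1, ncol = 3)]
      }
    }
    acc
  }, 0)
  expect_equal(as.numeric(w$data), oracle, tolerance = 1e-12)
})

test_that("build_nta composes warp, median and normalization; order-invariant", {
  g <- iso_grid(c(10, 10, 10))
  set.seed(9)
  subs <- lapply(1:5, function(i) {
    a <- array(runif(1000, 0, 0.6), c(10, 10, 10))
    subject_hotspot(volume3d(a, g$affine),
                    rigid_transform(diag(3), round(runif(3, -2, 2))),
                    sprintf("s%d", i))
  })
  nta <- build_nta(subs, g)
  # step-by-step oracle: warp each, stack, median, divide by max
  warped <- vapply(subs, function(s)
    as.numeric(warp_hotspot_to_template(s, g)$data), numeric(1000))
  med <- apply(warped, 1, median)
  expect_equal(as.numeric(nta$data), med / max(med), tolerance = 1e-12)
  expect_equal(max(nta$data), 1)
  expect_equal(attr(nta, "n_subjects"), 5)

  shuffled <- build_nta(subs[c(3, 1, 5, 2, 4)], g)
  expect_identical(shuffled$data, nta$data)

  scaled <- lapply(subs, function(s) {
    s$map <- volume3d(s$map$data * 4.2, s$map$affine); s
  })
  expect_equal(build_nta(scaled, g)$data, nta$data, tolerance = 1e-12)

  sid <- subs[[1]]; sid$template_to_subject <- identity_transform()
  one <- build_nta(list(sid), g)
  expect_equal(one$data, max_normalize(sid$map)$data)
  expect_identical(build_nta(list(sid, sid, sid), g)$data, one$data)
})

test_that("round-tripped subject maps leave the atlas within the interpolation bound", {
  g <- iso_grid(c(12, 12, 12), res = 2)
  set.seed(15)
  subs <- lapply(1:3, function(i) {
    subject_hotspot(smooth_volume(g), identity_transform(),
                    sprintf("s%d", i))
  })
  nta0 <- build_nta(subs, g)
  xf <- rigid_transform(diag(3), c(0.6, -0.9, 0.3))
  rt <- lapply(subs, function(s) {
    fwd <- resample(s$map, xf, g)
    s$map <- resample(fwd, invert_transform(xf), g)
    s
  })
  nta1 <- build_nta(rt, g)
  interior <- array(FALSE, g$shape); interior[4:9, 4:9, 4:9] <- TRUE
  expect_lt(max(abs(nta1$data[interior] - nta0$data[interior])), 0.05)
})

test_that("medial apex picks the most medial hot voxel with anterior/superior tie-breaks", {
  g <- iso_grid(c(21, 21, 21), origin = c(0, -10, -10))
  a <- array(0, c(21, 21, 21))
  a[15, 11, 11] <- 1                    # x = 14
  a[17, 11, 11] <- 1                    # x = 16: lateral, loses
  nta <- max_normalize(volume3d(a, g$affine))
  expect_equal(medial_apex(nta)$point, c(14, 0, 0))

  a[15, 11, 11] <- 0; a[17, 11, 11] <- 0
  a[13, 11, 11] <- 1
  nta1 <- max_normalize(volume3d(a, g$affine))
  expect_equal(medial_apex(nta1)$point, c(12, 0, 0))   # single hot voxel

  # ties on |x|: anterior (larger y) wins, then superior (larger z)
  b <- array(0, c(21, 21, 21))
  b[15, 11, 11] <- 1; b[15, 14, 11] <- 1; b[15, 14, 15] <- 1
  ntab <- max_normalize(volume3d(b, g$affine))
  expect_equal(medial_apex(ntab)$point, c(14, 3, 4))
})

test_that("medial apex agrees with a brute-force scan on an ellipsoidal hotspot", {
  g <- iso_grid(c(24, 24, 24), origin = c(2, -12, -12))
  idx <- ntatlas:::all_voxel_indices(g$shape)
  pts <- ntatlas:::voxel_to_world(idx, g$affine)
  val <- exp(-(((pts[, 1] - 15) / 4)^2 + ((pts[, 2] + 2) / 6)^2 +
                 ((pts[, 3] - 1) / 3)^2))
  nta <- max_normalize(volume3d(array(val, g$shape), g$affine))
  hf <- 0.8
  res <- medial_apex(nta, hot_fraction = hf, ac = c(0, 10, 0),
                     pc = c(0, -14, 0))
  hot <- which(nta$data >= hf * max(nta$data))
  cand <- pts[hot, , drop = FALSE]
  ord <- order(abs(cand[, 1]), -cand[, 2], -cand[, 3])
  expect_equal(res$point, cand[ord[1], ])
  expect_equal(res$acpc_offsets$lateral_mm, res$point[1])
  expect_equal(res$acpc_offsets$superior_mm, res$point[3])
  expect_error(medial_apex(max_normalize(volume3d(array(c(rep(0, 26), 1),
                                                        c(3, 3, 3)),
                                                  diag(4))),
                           hot_fraction = 0), "hot_fraction")
})
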