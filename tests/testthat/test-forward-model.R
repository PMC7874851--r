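test_that("rdDiffusion matches hand-derived closed-form values", {
  # mu_a = 0, planar illumination: all light eventually re-emerges
  expect_equal(rdDiffusion(0, 1.0, 0), 1.0)
  expect_equal(rdDiffusion(0, 3.7, 0), 1.0)
  # independently recomputed closed-form values at (0.02, 1.4), n = 1.4
  expect_equal(rdDiffusion(0.02, 1.4, 0), 0.566, tolerance = 1e-3)
  expect_equal(rdDiffusion(0.02, 1.4, 0.2), 0.174, tolerance = 1e-3)
  # frozen regression values at full precision
  expect_equal(rdDiffusion(0.02, 1.4, 0), 0.5657747064, tolerance = 1e-9)
  expect_equal(rdDiffusion(0.02, 1.4, 0.2), 0.1740013141, tolerance = 1e-9)
})

test_that("rdDiffusion validates its inputs", {
  expect_error(rdDiffusion(NA, 1.4, 0), "finite")
  expect_error(rdDiffusion(0.02, Inf, 0), "finite")
  expect_error(rdDiffusion(-0.1, 1.4, 0), "muA")
  expect_error(rdDiffusion(0.02, 0, 0), "muSp")
  expect_error(rdDiffusion(0.02, 1.4, -0.1), "fx")
})

test_that("buildLUT has the paper geometry and equals rdDiffusion at nodes", {
  lut <- sharedLUT()
  expect_identical(length(lut@muaAxis), 768L)
  expect_identical(length(lut@muspAxis), 768L)
  expect_equal(range(lut@muaAxis), c(0, 3))
  expect_equal(range(lut@muspAxis), c(0.01, 4))
  expect_identical(dim(lut@values), c(5L, 768L, 768L))
  # spot-check bit-for-bit equality with the scalar forward model
  idx <- cbind(fx = c(1L, 3L, 5L), i = c(1L, 400L, 768L),
               j = c(10L, 200L, 768L))
  for (r in seq_len(nrow(idx))) {
    expect_identical(
      lut@values[idx[r, 1], idx[r, 2], idx[r, 3]],
      rdDiffusion(lut@muaAxis[idx[r, 2]], lut@muspAxis[idx[r, 3]],
                  lut@fx[idx[r, 1]]))
  }
  expect_error(buildLUT(fx = numeric()), "non-empty")
})

test_that("LUT values are monotone over every node", {
  lut <- sharedLUT()
  v <- lut@values
  expect_true(all(v > 0) && all(v <= 1 + 1e-12))
  # strictly decreasing in muA at every (fx, muSp) in the diffusion-valid
  # scattering range; at muSp below ~0.6 with fx > 0 the closed form is
  # genuinely non-monotone (low-albedo region outside the model's validity)
  hi <- lut@muspAxis >= 0.6
  expect_true(all(apply(v[, , hi], c(1, 3), function(col) all(diff(col) < 0))))
  # the documented low-albedo exception really exists
  expect_true(any(diff(v[3, , 1]) > 0))
  # strictly increasing in muSp at every fx > 0 (and every muA)
  for (k in 2:5)
    expect_true(all(v[k, , -1] - v[k, , -768] > 0))
  # strictly decreasing in fx at every node (fx grid is increasing)
  expect_true(all(v[-1, , ] - v[-5, , ] < 0))
  # fx = 0 limit: mu_a -> 0 gives Rd -> 1
  expect_equal(max(abs(v[1, 1, ] - 1)), 0)
})

test_that("penetrationDepth matches the stated formula and is monotone", {
  expect_equal(penetrationDepth(0.02, 1.4, 0), 3.43, tolerance = 1e-2)
  expect_equal(penetrationDepth(0.02, 1.4, 0.2), 0.775, tolerance = 1e-3)
  expect_equal(penetrationDepth(0.02, 1.4, 0), 3.425943549, tolerance = 1e-9)
  # limiting behavior: muSp -> large drives the depth to 0
  expect_lt(penetrationDepth(0.02, 1e6, 0), 1e-2)
  # strictly decreasing in each argument (property sweep)
  mua <- seq(0.01, 1, length.out = 25)
  expect_true(all(diff(penetrationDepth(mua, 1.4, 0.1)) < 0))
  musp <- seq(0.2, 4, length.out = 25)
  expect_true(all(diff(penetrationDepth(0.05, musp, 0.1)) < 0))
  fx <- seq(0, 0.2, length.out = 25)
  expect_true(all(diff(penetrationDepth(0.05, 1.4, fx)) < 0))
  expect_error(penetrationDepth(0, 1.4, 0), "undefined")
})

test_that("lutInterp reproduces node values and rejects outside points", {
  lut <- sharedLUT()
  expect_equal(lutInterp(lut, 2, lut@muaAxis[10], lut@muspAxis[20]),
               lut@values[2, 10, 20])
  # interpolation error against the true model is small off-node
  expect_equal(lutInterp(lut, 1, 0.513, 1.77), rdDiffusion(0.513, 1.77, 0),
               tolerance = 1e-5)
  expect_true(is.na(lutInterp(lut, 1, -0.1, 1)))
  expect_true(is.na(lutInterp(lut, 1, 0.5, 4.5)))
})

test_that("LUT binary container round-trips exactly", {
  lut <- buildLUT(fx = c(0, 0.1), nMua = 32L, nMusp = 24L)
  path <- tempfile(fileext = ".lut")
  on.exit(unlink(path))
  writeLUT(lut, path)
  back <- readLUT(path)
  expect_identical(back@values, lut@values)
  expect_identical(back@muaAxis, lut@muaAxis)
  expect_identical(back@muspAxis, lut@muspAxis)
  expect_identical(back@fx, lut@fx)
  expect_identical(back@constants@g, lut@constants@g)
  expect_identical(back@constants@n, lut@constants@n)
  # not a LUT container
  bad <- tempfile()
  writeLines("nope", bad)
  on.exit(unlink(bad), add = TRUE)
  expect_error(readLUT(bad), "not a LUT container")
})

test_that("OpticalPropertyPair and MediumConstants enforce invariants", {
  expect_error(opticalPropertyPair(-0.1, 1), "muA")
  expect_error(opticalPropertyPair(0.1, 0), "muSp")
  p <- opticalPropertyPair(0.5, 2)
  expect_equal(muA(p), 0.5)
  expect_equal(muSp(p), 2)
  expect_error(mediumConstants(g = 1), "anisotropy")
  expect_error(mediumConstants(n = 0.9), "refractive")
})
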