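test_that("three-phase demodulation matches closed-form examples", {
  # I_k = 1 + cos(phi_k): triplet (2, 0.5, 0.5) -> B = 1, A = 1
  m <- demodulate(tripletStack(2, 0.5, 0.5))
  expect_equal(m@ac[1, 1, 1, 1], 1.0, tolerance = 1e-12)
  expect_equal(m@dc[1, 1, 1, 1], 1.0, tolerance = 1e-12)
  # constant triplet: no modulation
  m0 <- demodulate(tripletStack(3, 3, 3))
  expect_equal(m0@ac[1, 1, 1, 1], 0)
  expect_equal(m0@dc[1, 1, 1, 1], 3)
})

test_that("demodulation is exact for pure sinusoids at any phase offset", {
  phases <- c(0, 2 * pi / 3, 4 * pi / 3)
  set.seed(7)
  for (rep in 1:50) {
    theta <- runif(1, 0, 2 * pi)
    A <- runif(1, 1, 3); B <- runif(1, 0, A) # keep intensities >= 0
    ik <- A + B * cos(phases + theta)
    m <- demodulate(tripletStack(ik[1], ik[2], ik[3]))
    expect_equal(m@ac[1, 1, 1, 1], B, tolerance = 1e-12)
    expect_equal(m@dc[1, 1, 1, 1], A, tolerance = 1e-12)
  }
})

test_that("demodulation accepts only the standard three-phase set", {
  dat <- array(1, dim = c(2, 2, 1, 1, 3))
  bad <- new("AcquisitionStack", data = dat, wavelengths = 500, fx = 0.1,
             phases = c(0, pi / 2, pi), pixelPitch = 0.25, seed = NA_real_,
             meta = list())
  expect_error(demodulate(bad), "three-phase")
  # phase order does not matter: a permuted stack demodulates identically
  st <- renderAcquisition(list(list(tissueModel(Inf, 0.02, 1.4))),
                          wavelengths = 500, fx = c(0, 0.1),
                          imageSize = 4L, noiseLevel = 0, seed = 1)
  perm <- new("AcquisitionStack", data = st@data[, , , , c(2, 3, 1),
                                                 drop = FALSE],
              wavelengths = st@wavelengths, fx = st@fx,
              phases = st@phases[c(2, 3, 1)], pixelPitch = st@pixelPitch,
              seed = st@seed, meta = st@meta)
  expect_equal(demodulate(perm)@ac, demodulate(st)@ac, tolerance = 1e-12)
})

test_that("noiseless uniform renders demodulate to constant amplitudes", {
  st <- renderAcquisition(list(list(tissueModel(Inf, 0.02, 1.4))),
                          wavelengths = 500, fx = defaultFrequencies(),
                          imageSize = 8L, noiseLevel = 0, seed = 1)
  m <- demodulate(st)
  for (jf in 2:5) {
    vals <- m@ac[, , 1, jf]
    expect_lt(diff(range(vals)), 1e-12)
  }
  # fx = 0: all three phase frames are identical (planar illumination)
  expect_identical(st@data[, , 1, 1, 1], st@data[, , 1, 1, 2])
  expect_identical(st@data[, , 1, 1, 1], st@data[, , 1, 1, 3])
})

test_that("calibration is the identity on the reference itself", {
  pred <- matrix(c(0.4, 0.3), 1, 2) # [wavelength, fx]
  ref <- uniformModulation(ac = 0.25, dc = 0.5)
  rs <- calibrate(ref, ref, pred)
  expect_equal(max(abs(rs@rd[, , 1, 1] - pred[1, 1])), 0)
  expect_equal(max(abs(rs@rd[, , 1, 2] - pred[1, 2])), 0)
  expect_true(all(rs@valid))
})

test_that("calibration is linear and scale-invariant", {
  pred <- matrix(c(0.4, 0.3), 1, 2)
  ref <- uniformModulation(ac = 0.25, dc = 0.5)
  samp <- uniformModulation(ac = 0.25 * 1.5, dc = 0.5 * 1.5)
  rs <- calibrate(samp, ref, pred)
  expect_equal(max(abs(rs@rd[, , 1, 1] - 1.5 * pred[1, 1])), 0)
  expect_equal(max(abs(rs@rd[, , 1, 2] - 1.5 * pred[1, 2])), 0)
  # multiplying both stacks by any positive constant changes nothing
  for (c0 in c(0.2, 7)) {
    refC <- uniformModulation(ac = 0.25 * c0, dc = 0.5 * c0)
    sampC <- uniformModulation(ac = 0.375 * c0, dc = 0.75 * c0)
    rsC <- calibrate(sampC, refC, pred)
    expect_equal(rsC@rd, rs@rd, tolerance = 1e-12)
  }
})

test_that("calibration flags bad pixels instead of dividing or clipping", {
  pred <- matrix(c(0.4, 0.3), 1, 2)
  ref <- uniformModulation(ac = 0.25, dc = 0.5)
  ref@ac[2, 2, 1, 2] <- 0      # dead reference pixel on an AC channel
  ref@dc[1, 3, 1, 1] <- 0      # dead reference pixel on the planar channel
  samp <- uniformModulation(ac = 0.25, dc = 0.5)
  samp@ac[3, 3, 1, 2] <- 2.5   # implausibly bright: Rd > 1 after ratio
  rs <- calibrate(samp, ref, pred)
  expect_false(rs@valid[2, 2, 1, 2])
  expect_false(rs@valid[1, 3, 1, 1])
  expect_false(rs@valid[3, 3, 1, 2])
  # the Rd > 1 value is carried, not clipped
  expect_gt(rs@rd[3, 3, 1, 2], 1)
  # everything else is untouched
  expect_true(rs@valid[1, 1, 1, 1] && rs@valid[4, 4, 1, 2])
})

test_that("rendered tissue calibrated against a rendered phantom recovers
           the tissue's forward reflectance", {
  fx <- defaultFrequencies()
  tm <- tissueModel(Inf, 0.05, 1.7)
  st <- renderAcquisition(list(list(tm)), wavelengths = 659, fx = fx,
                          imageSize = 6L, noiseLevel = 0, seed = 1)
  ph <- renderPhantom(defaultPhantom(659), fx = fx, imageSize = 6L,
                      noiseLevel = 0, seed = 2)
  rs <- calibrate(demodulate(st), demodulate(ph$stack), ph$predictedRd)
  want <- rdDiffusion(0.05, 1.7, fx)
  for (jf in seq_along(fx))
    expect_equal(max(abs(rs@rd[, , 1, jf] - want[jf])), 0, tolerance = 1e-12)
})
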