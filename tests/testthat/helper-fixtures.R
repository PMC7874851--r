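# Shared, lazily built fixtures.  The full default LUT takes a fraction of a
# second to build but is used by many tests; build it once per run.
sharedLUT <- local({
  lut <- NULL
  function() {
    if (is.null(lut)) lut <<- buildLUT()
    lut
  }
})

# A 1 x 1 px acquisition stack holding one phase triplet, for demodulation
# unit tests.
tripletStack <- function(i1, i2, i3, fx = 0.1) {
  dat <- array(c(i1, i2, i3), dim = c(1, 1, 1, 1, 3))
  new("AcquisitionStack", data = dat, wavelengths = 500, fx = fx,
      phases = c(0, 2 * pi / 3, 4 * pi / 3), pixelPitch = 0.25,
      seed = NA_real_, meta = list())
}

# A uniform ModulationStack with the given AC and DC amplitudes.
uniformModulation <- function(ac, dc, ny = 4, nx = 4, wavelengths = 500,
                              fx = c(0, 0.1)) {
  a <- array(0, dim = c(ny, nx, length(wavelengths), length(fx)))
  d <- a
  for (iw in seq_along(wavelengths)) for (jf in seq_along(fx)) {
    a[, , iw, jf] <- ac
    d[, , iw, jf] <- dc
  }
  new("ModulationStack", ac = a, dc = d,
      wavelengths = as.numeric(wavelengths), fx = as.numeric(fx))
}

# An OpticalPropertyMap with constant values and a given validity mask.
constantMap <- function(muSp, muA = 0.02, valid = NULL, side = 40L,
                        wavelength = 851) {
  v <- if (is.null(valid)) matrix(TRUE, side, side) else valid
  mk <- function(x) array(x, dim = c(side, side, 1))
  new("OpticalPropertyMap", muA = mk(muA), muSp = mk(muSp),
      residual = mk(0), valid = array(v, dim = c(side, side, 1)),
      reason = array(ifelse(v, 0L, 1L), dim = c(side, side, 1)),
      wavelengths = wavelength)
}
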