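#' @include AllClasses.R
NULL

# Effective internal-reflection parameter A for a refractive-index mismatch n,
# via the standard empirical polynomial for the effective reflection
# coefficient r_eff(n).
.reflectionParameterA <- function(n) {
  reff <- 0.0636 * n + 0.668 + 0.710 / n - 1.440 / n^2
  (1 - reff) / (2 * (1 + reff))
}

#' Diffuse reflectance of a homogeneous semi-infinite medium in the spatial
#' frequency domain
#'
#' Standard diffusion-approximation closed form for the demodulated diffuse
#' reflectance under sinusoidal illumination at spatial frequency \code{fx}:
#' with \eqn{\mu_{tr} = \mu_a + \mu_s'}, \eqn{a' = \mu_s'/\mu_{tr}} and
#' \eqn{\mu_{eff}'(f_x) = \sqrt{3\mu_a\mu_{tr} + (2\pi f_x)^2}},
#' \deqn{R_d = \frac{3Aa'}{(\mu_{eff}'/\mu_{tr} + 1)(\mu_{eff}'/\mu_{tr} + 3A)}}
#' where A is the internal-reflection parameter derived from the refractive
#' index.  Vectorized over all arguments.
#'
#' @param muA absorption coefficient(s), mm^-1 (>= 0)
#' @param muSp reduced scattering coefficient(s), mm^-1 (> 0)
#' @param fx spatial frequency(ies), mm^-1 (>= 0)
#' @param constants a \code{MediumConstants} (only \code{n} enters)
#' @return diffuse reflectance in (0, 1]
#' @examples
#' rdDiffusion(0.02, 1.4, fx = 0)    # ~0.566
#' rdDiffusion(0.02, 1.4, fx = 0.2)  # ~0.174
#' @export
rdDiffusion <- function(muA, muSp, fx, constants = mediumConstants()) {
  if (any(!is.finite(muA)) || any(!is.finite(muSp)) || any(!is.finite(fx)))
    stop("rdDiffusion: non-finite input (muA, muSp and fx must be finite)")
  if (any(muA < 0)) stop("rdDiffusion: muA must be >= 0")
  if (any(muSp <= 0)) stop("rdDiffusion: muSp must be > 0")
  if (any(fx < 0)) stop("rdDiffusion: fx must be >= 0")
  A <- .reflectionParameterA(constants@n)
  mutr <- muA + muSp
  ap <- muSp / mutr
  ratio <- sqrt(3 * muA * mutr + (2 * pi * fx)^2) / mutr
  3 * A * ap / ((ratio + 1) * (ratio + 3 * A))
}

#' Build the forward-model reflectance lookup table
#'
#' Tabulates \code{\link{rdDiffusion}} on a linearly spaced (muA, muSp) grid
#' at each requested spatial frequency.  The default geometry is the 768 x
#' 768 grid over 0 <= muA <= 3 mm^-1 and 0.01 <= muSp <= 4 mm^-1.
#'
#' @param fx spatial frequencies, mm^-1 (non-empty)
#' @param constants a \code{MediumConstants}
#' @param muaRange,muspRange axis ranges, mm^-1
#' @param nMua,nMusp nodes per axis
#' @return a \code{\link{ReflectanceLUT-class}} object
#' @export
buildLUT <- function(fx = defaultFrequencies(), constants = mediumConstants(),
                     muaRange = c(0, 3), muspRange = c(0.01, 4),
                     nMua = 768L, nMusp = 768L) {
  if (length(fx) < 1L) stop("buildLUT: fx list must be non-empty")
  muaAxis <- seq(muaRange[1], muaRange[2], length.out = nMua)
  muspAxis <- seq(muspRange[1], muspRange[2], length.out = nMusp)
  vals <- array(NA_real_, dim = c(length(fx), nMua, nMusp))
  for (k in seq_along(fx)) {
    g <- expand.grid(muA = muaAxis, muSp = muspAxis)
    vals[k, , ] <- rdDiffusion(g$muA, g$muSp, fx[k], constants)
  }
  new("ReflectanceLUT", muaAxis = muaAxis, muspAxis = muspAxis,
      fx = as.numeric(fx), values = vals, constants = constants)
}

#' The instrument's default spatial frequencies
#'
#' Five evenly spaced spatial frequencies between 0 and 0.2 mm^-1.
#' @return numeric vector, mm^-1
#' @export
defaultFrequencies <- function() seq(0, 0.2, length.out = 5)

#' The instrument's default wavelengths
#'
#' The eight LED center wavelengths, nm.
#' @return numeric vector, nm
#' @export
defaultWavelengths <- function() c(471, 526, 591, 621, 659, 691, 731, 851)

#' Light penetration depth under the diffusion approximation
#'
#' Characteristic 1/e interrogation depth for a homogeneous medium probed at
#' spatial frequency \code{fx}:
#' \deqn{\delta = 1 / \sqrt{3\mu_a(\mu_a + \mu_s') + (2\pi f_x)^2}}
#' Strictly decreasing in each of muA, muSp and fx.
#'
#' @inheritParams rdDiffusion
#' @return penetration depth, mm
#' @examples
#' penetrationDepth(0.02, 1.4, fx = 0)    # ~3.43 mm
#' penetrationDepth(0.02, 1.4, fx = 0.2)  # ~0.775 mm
#' @export
penetrationDepth <- function(muA, muSp, fx) {
  if (any(!is.finite(muA)) || any(!is.finite(muSp)) || any(!is.finite(fx)))
    stop("penetrationDepth: non-finite input")
  if (any(muA < 0) || any(muSp <= 0) || any(fx < 0))
    stop("penetrationDepth: require muA >= 0, muSp > 0, fx >= 0")
  denom2 <- 3 * muA * (muA + muSp) + (2 * pi * fx)^2
  if (any(denom2 <= 0))
    stop("penetrationDepth: undefined for muA = 0 with fx = 0")
  1 / sqrt(denom2)
}

#' Interpolate LUT reflectance at arbitrary (muA, muSp) points
#'
#' Bilinear interpolation of the tabulated Rd at one spatial-frequency plane.
#' Vectorized over points; points outside the grid return NA.
#'
#' @param lut a \code{ReflectanceLUT}
#' @param fxIndex which frequency plane (integer index into \code{lut@fx})
#' @param muA,muSp query coordinates, mm^-1
#' @return interpolated Rd (NA outside the grid)
#' @export
lutInterp <- function(lut, fxIndex, muA, muSp) {
  ax <- lut@muaAxis; ay <- lut@muspAxis
  nx <- length(ax); ny <- length(ay)
  ix <- findInterval(muA, ax, rightmost.closed = TRUE)
  iy <- findInterval(muSp, ay, rightmost.closed = TRUE)
  ok <- ix >= 1L & ix < nx & iy >= 1L & iy < ny &
    muA >= ax[1] & muA <= ax[nx] & muSp >= ay[1] & muSp <= ay[ny]
  out <- rep(NA_real_, length(muA))
  if (!any(ok)) return(out)
  ixo <- ix[ok]; iyo <- iy[ok]
  tx <- (muA[ok] - ax[ixo]) / (ax[ixo + 1L] - ax[ixo])
  ty <- (muSp[ok] - ay[iyo]) / (ay[iyo + 1L] - ay[iyo])
  pl <- lut@values[fxIndex, , ]
  v00 <- pl[cbind(ixo, iyo)];      v10 <- pl[cbind(ixo + 1L, iyo)]
  v01 <- pl[cbind(ixo, iyo + 1L)]; v11 <- pl[cbind(ixo + 1L, iyo + 1L)]
  out[ok] <- (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
  out
}

#' Serialize a reflectance LUT to a single binary container
#'
#' Little-endian doubles with a short header; \code{readLUT} round-trips
#' exactly.
#'
#' @param lut a \code{ReflectanceLUT}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeLUT <- function(lut, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("SFDLUT01"), con)
  writeBin(as.integer(c(length(lut@fx), length(lut@muaAxis),
                        length(lut@muspAxis))), con, size = 4L,
           endian = "little")
  writeBin(c(lut@constants@g, lut@constants@n), con, endian = "little")
  writeBin(lut@fx, con, endian = "little")
  writeBin(lut@muaAxis, con, endian = "little")
  writeBin(lut@muspAxis, con, endian = "little")
  writeBin(as.vector(lut@values), con, endian = "little")
  invisible(path)
}

#' @rdname writeLUT
#' @export
readLUT <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (magic != "SFDLUT01") stop("readLUT: not a LUT container: ", path)
  dims <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  gn <- readBin(con, "numeric", 2L, endian = "little")
  fx <- readBin(con, "numeric", dims[1], endian = "little")
  muaAxis <- readBin(con, "numeric", dims[2], endian = "little")
  muspAxis <- readBin(con, "numeric", dims[3], endian = "little")
  vals <- readBin(con, "numeric", prod(dims), endian = "little")
  new("ReflectanceLUT", muaAxis = muaAxis, muspAxis = muspAxis, fx = fx,
      values = array(vals, dim = dims),
      constants = mediumConstants(g = gn[1], n = gn[2]))
}
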