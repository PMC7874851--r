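#' @include AllClasses.R tissue-model.R monte-carlo.R cohort.R
NULL

#' Effective reflectance of a tissue column
#'
#' Dispatches between the fast depth-weighted diffusion path (default, used
#' for full-cohort rendering) and the Monte Carlo oracle (small scenes,
#' validation).
#'
#' @param model a \code{TissueModel}
#' @param fx spatial frequencies, mm^-1
#' @param method "twolayer" (depth-weighted diffusion collapse) or "mc"
#' @param nPhotons,seed Monte Carlo controls (method = "mc")
#' @return Rd(fx)
#' @export
tissueRd <- function(model, fx = defaultFrequencies(),
                     method = c("twolayer", "mc"), nPhotons = 1e5, seed = 1) {
  method <- match.arg(method)
  if (method == "twolayer") effectiveRd(model, fx)
  else mcReflectance(model, fx, nPhotons = nPhotons, seed = seed)
}

# core renderer: rd is [ny, nx, nwl, nfx]; sinusoidal patterns along columns
.renderFromRd <- function(rd, wavelengths, fx, phases, pixelPitch, i0,
                          noiseLevel, seed, meta = list()) {
  d <- dim(rd)
  ny <- d[1]; nx <- d[2]
  if (length(phases) < 3L)
    stop("renderAcquisition: at least 3 phases are required for demodulation")
  x <- (seq_len(nx) - 0.5) * pixelPitch
  dat <- array(0, dim = c(ny, nx, d[3], d[4], length(phases)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (iw in seq_len(d[3])) for (jf in seq_len(d[4])) {
    for (kp in seq_along(phases)) {
      # planar (fx = 0) projection carries no phase: all frames see the same
      # uniform illumination at the sinusoidal patterns' mean level
      illum <- if (fx[jf] == 0) rep(i0 / 2, nx)
      else (i0 / 2) * (1 + cos(2 * pi * fx[jf] * x + phases[kp]))
      sig <- rd[, , iw, jf] * matrix(illum, ny, nx, byrow = TRUE)
      if (noiseLevel > 0) {
        dc <- rd[, , iw, jf] * (i0 / 2)
        sig <- sig + stats::rnorm(ny * nx, 0, 1) * (noiseLevel * dc)
      }
      dat[, , iw, jf, kp] <- pmax(sig, 0)
    }
  }
  new("AcquisitionStack", data = dat, wavelengths = as.numeric(wavelengths),
      fx = as.numeric(fx), phases = as.numeric(phases),
      pixelPitch = pixelPitch, seed = as.numeric(seed),
      meta = c(meta, list(i0 = i0, noiseLevel = noiseLevel)))
}

#' Render a patterned-illumination acquisition stack
#'
#' Projects sinusoidal patterns \eqn{I(x) = (I_0/2)[1 + \cos(2\pi f_x x +
#' \phi)]} onto a scene and records the reflected intensity per pixel,
#' wavelength, frequency and phase, with signal-proportional Gaussian noise
#' (shot-noise approximation, SD = \code{noiseLevel} times the local DC
#' signal).  The scene is a per-pixel map of tissue columns: a list of
#' \code{TissueModel}s per wavelength plus an integer region map assigning
#' each pixel to one column.  A scalar region map renders a uniform scene.
#'
#' @param models list over wavelengths; each element is a list of
#'   \code{TissueModel}s (one per region)
#' @param regionMap integer matrix [ny, nx] of region indices, or NULL for a
#'   uniform single-region scene
#' @param wavelengths nm (same length as \code{models})
#' @param fx spatial frequencies, mm^-1
#' @param phases projection phases, radians (>= 3)
#' @param imageSize image side in pixels (used when regionMap is NULL)
#' @param pixelPitch mm per pixel
#' @param i0 peak illumination intensity (arbitrary units)
#' @param noiseLevel noise SD as a fraction of the local DC signal
#' @param seed RNG seed for the noise
#' @param method forward model for each tissue column, see
#'   \code{\link{tissueRd}}
#' @param nPhotons Monte Carlo photons per distinct column (method = "mc")
#' @return an \code{\link{AcquisitionStack-class}}
#' @export
renderAcquisition <- function(models, regionMap = NULL,
                              wavelengths = defaultWavelengths(),
                              fx = defaultFrequencies(),
                              phases = c(0, 2 * pi / 3, 4 * pi / 3),
                              imageSize = 48L, pixelPitch = 0.25, i0 = 1,
                              noiseLevel = 0.01, seed = 1,
                              method = c("twolayer", "mc"), nPhotons = 1e5) {
  method <- match.arg(method)
  if (length(models) != length(wavelengths))
    stop("renderAcquisition: one model list per wavelength required")
  if (is.null(regionMap))
    regionMap <- matrix(1L, imageSize, imageSize)
  ny <- nrow(regionMap); nx <- ncol(regionMap)
  rd <- array(0, dim = c(ny, nx, length(wavelengths), length(fx)))
  for (iw in seq_along(wavelengths)) {
    regs <- models[[iw]]
    if (!is.list(regs)) regs <- list(regs)
    # one forward evaluation per distinct tissue column, broadcast to pixels
    rdReg <- lapply(seq_along(regs), function(r)
      tissueRd(regs[[r]], fx, method = method, nPhotons = nPhotons,
               seed = seed + 7L * r + 101L * iw))
    for (jf in seq_along(fx)) {
      vals <- vapply(rdReg, `[[`, numeric(1), jf)
      rd[, , iw, jf] <- matrix(vals[regionMap], ny, nx)
    }
  }
  .renderFromRd(rd, wavelengths, fx, phases, pixelPitch, i0, noiseLevel,
                seed)
}

#' Render the calibration phantom
#'
#' Renders an optically homogeneous reference phantom of known optical
#' properties through the same geometry as the tissue scenes and returns
#' both the acquisition stack and the forward-model-predicted diffuse
#' reflectance table that calibration requires.
#'
#' @param properties data.frame with columns wavelength, mua, musp (mm^-1)
#' @inheritParams renderAcquisition
#' @param constants \code{MediumConstants} for the forward prediction
#' @return list with elements \code{stack} (an \code{AcquisitionStack}) and
#'   \code{predictedRd} (matrix [wavelength, fx])
#' @export
renderPhantom <- function(properties = defaultPhantom(),
                          fx = defaultFrequencies(),
                          phases = c(0, 2 * pi / 3, 4 * pi / 3),
                          imageSize = 48L, pixelPitch = 0.25, i0 = 1,
                          noiseLevel = 0, seed = 2,
                          constants = mediumConstants()) {
  wl <- properties$wavelength
  pred <- t(vapply(seq_along(wl), function(i)
    rdDiffusion(properties$mua[i], properties$musp[i], fx, constants),
    numeric(length(fx))))
  dimnames(pred) <- list(as.character(wl), as.character(fx))
  rd <- array(0, dim = c(imageSize, imageSize, length(wl), length(fx)))
  for (i in seq_along(wl)) for (j in seq_along(fx))
    rd[, , i, j] <- pred[i, j]
  stack <- .renderFromRd(rd, wl, fx, phases, pixelPitch, i0, noiseLevel,
                         seed, meta = list(role = "phantom"))
  list(stack = stack, predictedRd = pred)
}

#' Default calibration phantom optical properties
#'
#' A homogeneous silicone-like reference: flat low absorption and a gentle
#' scattering power law near 1 mm^-1.
#'
#' @param wavelengths nm
#' @return data.frame with wavelength, mua, musp
#' @export
defaultPhantom <- function(wavelengths = defaultWavelengths()) {
  data.frame(wavelength = wavelengths,
             mua = rep(0.02, length(wavelengths)),
             musp = 1.1 * (wavelengths / 660)^(-0.6))
}

#' Render one subject-location acquisition stack
#'
#' Materializes the acquisition stack for a cohort subject at one location,
#' using the cohort spec's geometry, noise level and a seed derived
#' deterministically from the spec seed, subject and location.
#'
#' @param cohort a \code{SyntheticCohort}
#' @param subject subject index (1-based)
#' @param location location name
#' @param method forward model, see \code{\link{tissueRd}}
#' @param library a \code{ChromophoreLibrary}
#' @param nPhotons Monte Carlo photons (method = "mc")
#' @return an \code{AcquisitionStack}
#' @export
renderSubjectLocation <- function(cohort, subject, location,
                                  method = c("twolayer", "mc"),
                                  library = chromophoreLibrary(),
                                  nPhotons = 1e5) {
  method <- match.arg(method)
  spec <- cohort@spec
  if (!location %in% spec@locations) stop("unknown location: ", location)
  ph <- cohort@phenotypes[[subject]]
  models <- lapply(spec@wavelengths, function(wl)
    skinModelFromPhenotype(ph, location, wl, targetMean = spec@targetMean,
                           scatterExponent = spec@scatterExponent,
                           library = library))
  seed <- spec@seed * 1009 + subject * 131 +
    match(location, spec@locations) * 17
  renderAcquisition(models, regionMap = NULL,
                    wavelengths = spec@wavelengths, fx = spec@fx,
                    phases = spec@phases, imageSize = spec@imageSize,
                    pixelPitch = spec@pixelPitch, noiseLevel = spec@noiseLevel,
                    seed = seed %% .Machine$integer.max,
                    method = method, nPhotons = nPhotons)
}
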