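#' @include AllClasses.R chromophores.R
NULL

# palm override: melanocyte activity is strongly suppressed on palmar skin,
# so the effective melanin fraction there is 10% of the subject's value
.PALM_MELANIN_FACTOR <- 0.1

#' Construct a subject phenotype
#'
#' @param id subject identifier
#' @param fitzpatrick Fitzpatrick type, "I".."VI"
#' @param melaninFraction epidermal melanin volume fraction; default from
#'   \code{\link{fitzpatrickMelanin}}
#' @param epidermalThickness mm (typical 0.10-0.15)
#' @param locationScale named per-location multipliers on the cohort target
#'   dermal musp at 851 nm
#' @return a \code{\link{SubjectPhenotype-class}}
#' @export
subjectPhenotype <- function(id, fitzpatrick,
                             melaninFraction = fitzpatrickMelanin(fitzpatrick),
                             epidermalThickness = 0.125,
                             locationScale = numeric()) {
  new("SubjectPhenotype", id = as.character(id), fitzpatrick = fitzpatrick,
      melaninFraction = melaninFraction,
      epidermalThickness = epidermalThickness,
      locationScale = locationScale)
}

#' Two-layer skin model for a phenotype at one location and wavelength
#'
#' Builds the generator's layered tissue description: a melanized epidermis
#' of the phenotype's thickness over a semi-infinite dermis.  Dermal reduced
#' scattering follows the shared power law
#' \eqn{\mu_s'(\lambda) = a (\lambda/851)^{-b}}, anchored at 851 nm to the
#' cohort's per-location target mean times the subject's location scale
#' factor.  Epidermal scattering is set equal to dermal scattering, so
#' melanin absorption is the only epidermis/dermis contrast; with zero
#' melanin the epidermis is optically matched to the dermis.  On the palm
#' the effective melanin fraction is reduced to 10% of the subject's value.
#'
#' @param phenotype a \code{SubjectPhenotype}
#' @param location location name (must appear in \code{targetMean} and in
#'   the phenotype's \code{locationScale})
#' @param wavelength nm
#' @param targetMean named per-location target dermal musp at 851 nm, mm^-1
#' @param scatterExponent power-law exponent b
#' @param library a \code{ChromophoreLibrary}
#' @return a \code{\link{TissueModel-class}} with two layers
#' @export
skinModelFromPhenotype <- function(phenotype, location, wavelength,
                                   targetMean = defaultLocationTargets()$mean,
                                   scatterExponent = 1.3,
                                   library = chromophoreLibrary()) {
  if (!location %in% names(targetMean))
    stop("unknown location: ", location)
  if (wavelength < 471 || wavelength > 851)
    stop("wavelength outside the generator band (471-851 nm)")
  scale <- if (location %in% names(phenotype@locationScale))
    phenotype@locationScale[[location]] else 1
  muspDerm <- targetMean[[location]] * scale *
    (wavelength / 851)^(-scatterExponent)
  muaDerm <- dermisBaselineMua(wavelength, library)
  mel <- phenotype@melaninFraction
  if (location == "palm") mel <- mel * .PALM_MELANIN_FACTOR
  muaEpi <- muaDerm + mel * melaninMua(wavelength, library)
  tissueModel(thickness = c(phenotype@epidermalThickness, Inf),
              mua = c(muaEpi, muaDerm),
              musp = c(muspDerm, muspDerm))
}

#' Per-location target dermal reduced scattering at 851 nm
#'
#' Generator anchors: intersubject mean and SD of dermal musp at 851 nm for
#' each of the ten anatomic locations, mm^-1.
#'
#' @return list with named numeric vectors \code{mean} and \code{sd}
#' @export
defaultLocationTargets <- function() {
  loc <- c("forehead", "cheek", "ventral forearm", "palm", "back",
           "upper arm", "dorsal forearm", "neck", "shin", "chest")
  m <- c(1.65, 1.53, 1.46, 1.45, 1.42, 1.41, 1.38, 1.31, 1.30, 1.28)
  s <- c(0.174, 0.173, 0.115, 0.0813, 0.154, 0.120, 0.120, 0.117,
         0.141, 0.141)
  names(m) <- loc; names(s) <- loc
  list(mean = m, sd = s)
}

#' Effective homogeneous reflectance of a layered model (fast path)
#'
#' Depth-weighted diffusion approximation used to render large scenes: at
#' each spatial frequency the layered absorption and scattering are
#' collapsed to effective homogeneous values using exponential interrogation
#' weights \eqn{w(z) \propto e^{-2z/\delta(f_x)}}, where the probing depth
#' \eqn{\delta(f_x)} is computed from the terminal (dermal) layer, and the
#' homogeneous closed form is evaluated on the collapsed coefficients.
#' Because \eqn{\delta} shrinks with fx, superficial layers weigh more at
#' high frequency — the mechanism by which epidermal melanin depresses the
#' apparent reduced scattering of a homogeneous fit.  For a single-layer
#' model this reduces exactly to \code{\link{rdDiffusion}}.
#'
#' @param model a \code{TissueModel}
#' @param fx spatial frequencies, mm^-1
#' @param constants \code{MediumConstants} for the homogeneous evaluation
#' @return Rd(fx), named numeric vector
#' @export
effectiveRd <- function(model, fx = defaultFrequencies(),
                        constants = mediumConstants()) {
  L <- model@layers
  nl <- nrow(L)
  zb <- c(0, cumsum(L$thickness))
  term <- nl
  out <- vapply(fx, function(f) {
    delta <- penetrationDepth(max(L$mua[term], 1e-6), L$musp[term], f)
    # layer weights: integral of (2/delta) exp(-2z/delta) over the layer
    w <- exp(-2 * zb[-length(zb)] / delta) - exp(-2 * zb[-1] / delta)
    w[nl] <- w[nl] + exp(-2 * zb[length(zb)] / delta) # tail into last layer
    muaEff <- sum(w * L$mua)
    muspEff <- sum(w * L$musp)
    rdDiffusion(muaEff, muspEff, f, constants)
  }, numeric(1))
  names(out) <- as.character(fx)
  out
}
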