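#' @import methods
NULL

#' Absorption / reduced-scattering pair
#'
#' Holds an absorption coefficient and a reduced scattering coefficient at a
#' single wavelength, the target quantity of the lookup-table inversion.
#' Both are expressed in mm^-1.
#'
#' @slot muA absorption coefficient, mm^-1 (>= 0)
#' @slot muSp reduced scattering coefficient, mm^-1 (> 0)
#' @exportClass OpticalPropertyPair
setClass("OpticalPropertyPair",
  representation(muA = "numeric", muSp = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@muA) != 1L || !is.finite(object@muA) || object@muA < 0)
      msg <- c(msg, "muA must be a single finite value >= 0")
    if (length(object@muSp) != 1L || !is.finite(object@muSp) || object@muSp <= 0)
      msg <- c(msg, "muSp must be a single finite value > 0")
    if (is.null(msg)) TRUE else msg
  })

#' @param muA absorption coefficient, mm^-1
#' @param muSp reduced scattering coefficient, mm^-1
#' @return an \code{OpticalPropertyPair}
#' @rdname OpticalPropertyPair-class
#' @export
opticalPropertyPair <- function(muA, muSp) {
  new("OpticalPropertyPair", muA = as.numeric(muA), muSp = as.numeric(muSp))
}

#' Fixed constants of the turbid medium
#'
#' Scattering anisotropy and internal refractive index, held fixed across the
#' whole inversion (g = 0.8, n = 1.4 by default, the conventional values for
#' skin in the visible/near-infrared).
#'
#' @slot g scattering anisotropy, dimensionless, 0 <= g < 1
#' @slot n refractive index, dimensionless, > 1
#' @exportClass MediumConstants
setClass("MediumConstants",
  representation(g = "numeric", n = "numeric"),
  prototype(g = 0.8, n = 1.4),
  validity = function(object) {
    msg <- NULL
    if (!is.finite(object@g) || object@g < 0 || object@g >= 1)
      msg <- c(msg, "anisotropy g must satisfy 0 <= g < 1")
    if (!is.finite(object@n) || object@n <= 1)
      msg <- c(msg, "refractive index n must be > 1")
    if (is.null(msg)) TRUE else msg
  })

#' @param g scattering anisotropy
#' @param n refractive index
#' @rdname MediumConstants-class
#' @export
mediumConstants <- function(g = 0.8, n = 1.4) {
  new("MediumConstants", g = as.numeric(g), n = as.numeric(n))
}

#' Forward-model reflectance lookup table
#'
#' Diffuse reflectance Rd tabulated on a (muA, muSp) grid at each measured
#' spatial frequency.  The default grid is 768 x 768 nodes, linearly spaced
#' over 0 <= muA <= 3 mm^-1 and 0.01 <= muSp <= 4 mm^-1.
#'
#' @slot muaAxis monotone increasing grid of absorption nodes, mm^-1
#' @slot muspAxis monotone increasing grid of reduced-scattering nodes, mm^-1
#' @slot fx spatial frequencies, mm^-1
#' @slot values numeric array [fx, mua-node, musp-node], Rd in (0, 1]
#' @slot constants the \code{MediumConstants} the table was built with
#' @exportClass ReflectanceLUT
setClass("ReflectanceLUT",
  representation(muaAxis = "numeric", muspAxis = "numeric", fx = "numeric",
                 values = "array", constants = "MediumConstants"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@values)
    if (length(d) != 3L ||
        d[1] != length(object@fx) ||
        d[2] != length(object@muaAxis) ||
        d[3] != length(object@muspAxis))
      msg <- c(msg, "values must be an [fx, mua, musp] array matching the axes")
    if (is.unsorted(object@muaAxis, strictly = TRUE) ||
        is.unsorted(object@muspAxis, strictly = TRUE))
      msg <- c(msg, "axes must be strictly increasing")
    if (any(object@values <= 0) || any(object@values > 1 + 1e-12))
      msg <- c(msg, "Rd values must lie in (0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' Layered tissue model
#'
#' Plane-parallel slab description of skin: ordered layers from the surface
#' down, the last layer semi-infinite.  Optical coefficients are per-layer at
#' a single wavelength.
#'
#' @slot layers data.frame with columns thickness (mm, last row Inf),
#'   mua (mm^-1), musp (mm^-1), g, n
#' @exportClass TissueModel
setClass("TissueModel",
  representation(layers = "data.frame"),
  validity = function(object) {
    L <- object@layers
    need <- c("thickness", "mua", "musp", "g", "n")
    if (!all(need %in% names(L)))
      return(paste("layers must have columns", paste(need, collapse = ", ")))
    if (nrow(L) < 1L) return("at least one layer is required")
    th <- L$thickness
    if (any(th[-nrow(L)] <= 0) || any(!is.finite(th[-nrow(L)])))
      return("non-terminal layer thicknesses must be finite and > 0")
    if (is.finite(th[nrow(L)]) && th[nrow(L)] <= 0)
      return("terminal layer thickness must be > 0 (or Inf)")
    if (any(L$mua < 0) || any(L$musp <= 0)) return("mua >= 0 and musp > 0 required")
    TRUE
  })

#' @param thickness layer thicknesses, mm (use Inf for the terminal layer)
#' @param mua per-layer absorption coefficients, mm^-1
#' @param musp per-layer reduced scattering coefficients, mm^-1
#' @param g per-layer anisotropy (recycled)
#' @param n per-layer refractive index (recycled)
#' @rdname TissueModel-class
#' @export
tissueModel <- function(thickness, mua, musp, g = 0.8, n = 1.4) {
  k <- max(length(thickness), length(mua), length(musp))
  new("TissueModel", layers = data.frame(
    thickness = rep_len(as.numeric(thickness), k),
    mua = rep_len(as.numeric(mua), k),
    musp = rep_len(as.numeric(musp), k),
    g = rep_len(as.numeric(g), k),
    n = rep_len(as.numeric(n), k)))
}

#' Spatially resolved diffuse reflectance from the Monte Carlo oracle
#'
#' @slot binEdges radial bin edges, mm (length nbins + 1)
#' @slot values diffuse reflectance per unit area in each annular bin, mm^-2
#' @slot totalDiffuse total diffuse reflectance (fraction of incident power)
#' @slot specular specular reflection fraction at the top interface
#' @slot overflow escaping weight fraction beyond the last bin edge
#' @slot nPhotons number of photons launched
#' @slot seed RNG seed used
#' @exportClass RadialReflectanceProfile
setClass("RadialReflectanceProfile",
  representation(binEdges = "numeric", values = "numeric",
                 totalDiffuse = "numeric", specular = "numeric",
                 overflow = "numeric", nPhotons = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@binEdges) != length(object@values) + 1L)
      msg <- c(msg, "binEdges must be one longer than values")
    if (any(object@values < 0)) msg <- c(msg, "bin values must be >= 0")
    if (object@totalDiffuse < 0 || object@totalDiffuse > 1)
      msg <- c(msg, "totalDiffuse must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' Raw patterned-illumination acquisition stack
#'
#' Camera frames indexed by wavelength, projected spatial frequency and phase
#' offset, together with the geometry needed to interpret them.  Pixel values
#' are linear detector intensities (arbitrary units, >= 0).
#'
#' @slot data numeric array [row, col, wavelength, fx, phase]
#' @slot wavelengths nm
#' @slot fx projected spatial frequencies, mm^-1
#' @slot phases phase offsets, radians
#' @slot pixelPitch mm per pixel
#' @slot seed RNG seed used for rendering noise (NA for measured data)
#' @slot meta free-form acquisition metadata
#' @exportClass AcquisitionStack
setClass("AcquisitionStack",
  representation(data = "array", wavelengths = "numeric", fx = "numeric",
                 phases = "numeric", pixelPitch = "numeric", seed = "numeric",
                 meta = "list"),
  validity = function(object) {
    d <- dim(object@data)
    msg <- NULL
    if (length(d) != 5L)
      msg <- c(msg, "data must be a 5-d array [row, col, wavelength, fx, phase]")
    else if (d[3] != length(object@wavelengths) || d[4] != length(object@fx) ||
             d[5] != length(object@phases))
      msg <- c(msg, "array extent must match wavelengths/fx/phases (no missing combinations)")
    if (any(object@data < 0)) msg <- c(msg, "intensities must be >= 0")
    if (object@pixelPitch <= 0) msg <- c(msg, "pixelPitch must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Demodulated modulation amplitudes
#'
#' AC and DC modulation amplitude images per (wavelength, frequency) channel,
#' the intermediate between a raw stack and calibrated reflectance.
#'
#' @slot ac AC amplitude array [row, col, wavelength, fx]
#' @slot dc DC amplitude array [row, col, wavelength, fx]
#' @slot wavelengths nm
#' @slot fx mm^-1
#' @exportClass ModulationStack
setClass("ModulationStack",
  representation(ac = "array", dc = "array", wavelengths = "numeric",
                 fx = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@ac), dim(object@dc)))
      return("ac and dc must have identical dimensions")
    if (any(object@ac < -1e-12) || any(object@dc < -1e-12))
      return("amplitudes must be >= 0")
    TRUE
  })

#' Calibrated diffuse reflectance maps
#'
#' Per-pixel diffuse reflectance per (wavelength, frequency) channel after
#' phantom calibration, with a validity mask.  Values above 1 are flagged
#' invalid rather than clipped.
#'
#' @slot rd reflectance array [row, col, wavelength, fx]
#' @slot valid logical array of the same shape
#' @slot wavelengths nm
#' @slot fx mm^-1
#' @exportClass ReflectanceStack
setClass("ReflectanceStack",
  representation(rd = "array", valid = "array", wavelengths = "numeric",
                 fx = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@rd), dim(object@valid)))
      return("rd and valid must have identical dimensions")
    if (any(object@rd[object@valid] < 0)) return("valid reflectance must be >= 0")
    TRUE
  })

#' Recovered per-pixel optical property maps
#'
#' @slot muA absorption maps [row, col, wavelength], mm^-1
#' @slot muSp reduced scattering maps [row, col, wavelength], mm^-1
#' @slot residual root-mean-square Rd misfit per pixel
#' @slot valid logical array; FALSE where inversion was not trusted
#' @slot reason integer codes: 0 ok, 1 out-of-range, 2 bad-calibration
#' @slot wavelengths nm
#' @exportClass OpticalPropertyMap
setClass("OpticalPropertyMap",
  representation(muA = "array", muSp = "array", residual = "array",
                 valid = "array", reason = "array", wavelengths = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@muA), dim(object@muSp)))
      return("muA and muSp must share dimensions")
    if (!identical(dim(object@muA), dim(object@valid)))
      return("valid mask must share dimensions with the maps")
    TRUE
  })

#' Synthetic subject phenotype
#'
#' @slot id subject identifier
#' @slot fitzpatrick one of "I".."VI"
#' @slot melaninFraction epidermal melanin volume fraction, in [0, 0.5]
#' @slot epidermalThickness mm, in [0.05, 0.3]
#' @slot locationScale named multipliers on each location's target dermal
#'   musp at 851 nm (the subject's draw from the intersubject distribution)
#' @exportClass SubjectPhenotype
setClass("SubjectPhenotype",
  representation(id = "character", fitzpatrick = "character",
                 melaninFraction = "numeric", epidermalThickness = "numeric",
                 locationScale = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@fitzpatrick %in% c("I", "II", "III", "IV", "V", "VI"))
      msg <- c(msg, "fitzpatrick must be one of I..VI")
    if (object@melaninFraction < 0 || object@melaninFraction > 0.5)
      msg <- c(msg, "melaninFraction must lie in [0, 0.5]")
    if (object@epidermalThickness < 0.05 || object@epidermalThickness > 0.3)
      msg <- c(msg, "epidermalThickness must lie in [0.05, 0.3] mm")
    if (is.null(msg)) TRUE else msg
  })

#' Chromophore spectral library for the skin generator
#'
#' Melanin absorption follows a power law in wavelength (strictly decreasing
#' over the instrument band); baseline dermal absorption is tabulated at the
#' instrument wavelengths and interpolated in between.
#'
#' @slot melaninScale melanin absorption of pure melanin at the reference
#'   wavelength, mm^-1
#' @slot melaninExponent power-law exponent (negative)
#' @slot melaninRefWavelength reference wavelength, nm
#' @slot dermisWavelengths nm, for the baseline absorption table
#' @slot dermisMua baseline dermal absorption at those wavelengths, mm^-1
#' @exportClass ChromophoreLibrary
setClass("ChromophoreLibrary",
  representation(melaninScale = "numeric", melaninExponent = "numeric",
                 melaninRefWavelength = "numeric",
                 dermisWavelengths = "numeric", dermisMua = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@melaninExponent >= 0)
      msg <- c(msg, "melaninExponent must be negative (extinction decreasing)")
    if (length(object@dermisWavelengths) != length(object@dermisMua))
      msg <- c(msg, "dermis table lengths differ")
    if (any(object@dermisMua < 0)) msg <- c(msg, "dermal mua must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' Cohort design specification
#'
#' Defaults reproduce the study design the package emulates: 15 subjects
#' spanning Fitzpatrick I-VI, 10 anatomic locations with per-location target
#' dermal musp mean/SD at 851 nm, 8 wavelengths, 5 spatial frequencies
#' between 0 and 0.2 mm^-1, 3 phases.
#'
#' @slot nSubjects number of subjects
#' @slot locations anatomic location names
#' @slot targetMean named per-location dermal musp mean at 851 nm, mm^-1
#' @slot targetSD named per-location intersubject SD at 851 nm, mm^-1
#' @slot wavelengths nm
#' @slot fx spatial frequencies, mm^-1
#' @slot phases radians
#' @slot fitzpatrick Fitzpatrick type assigned to each subject
#' @slot scatterExponent shared scattering power-law exponent b in
#'   musp(lambda) = a * (lambda/851)^(-b)
#' @slot imageSize rendered image side, pixels
#' @slot pixelPitch mm per pixel
#' @slot noiseLevel noise SD as a fraction of the DC illumination level
#' @slot seed base RNG seed
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(nSubjects = "integer", locations = "character",
                 targetMean = "numeric", targetSD = "numeric",
                 wavelengths = "numeric", fx = "numeric", phases = "numeric",
                 fitzpatrick = "character", scatterExponent = "numeric",
                 imageSize = "integer", pixelPitch = "numeric",
                 noiseLevel = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
    if (!all(object@locations %in% names(object@targetMean)) ||
        !all(object@locations %in% names(object@targetSD)))
      msg <- c(msg, "every location needs a target mean and SD")
    if (length(object@fitzpatrick) != object@nSubjects)
      msg <- c(msg, "fitzpatrick must assign one type per subject")
    if (length(object@phases) < 3L) msg <- c(msg, "at least 3 phases required")
    if (is.null(msg)) TRUE else msg
  })

#' A generated synthetic cohort
#'
#' @slot spec the \code{CohortSpec} used
#' @slot phenotypes list of \code{SubjectPhenotype}
#' @slot truth data.frame of ground-truth tissue parameters, one row per
#'   (subject, location, wavelength)
#' @slot stacks nested list stacks[[subject]][[location]] of
#'   \code{AcquisitionStack} (empty when rendering was deferred)
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  representation(spec = "CohortSpec", phenotypes = "list",
                 truth = "data.frame", stacks = "list"))

#' One-way ANOVA decomposition
#'
#' @slot table data.frame with rows Columns (between-group), Error (within),
#'   Total, and columns ss, df, ms, F, p
#' @exportClass AnovaResult
setClass("AnovaResult",
  representation(table = "data.frame"),
  validity = function(object) {
    tb <- object@table
    if (!all(c("ss", "df") %in% names(tb)) || nrow(tb) != 3L)
      return("table must have 3 rows and ss/df columns")
    if (abs(tb$ss[3] - tb$ss[1] - tb$ss[2]) > 1e-8 * max(tb$ss[3], 1))
      return("sums of squares must add: total = between + within")
    if (tb$df[3] != tb$df[1] + tb$df[2])
      return("degrees of freedom must add: total = between + within")
    TRUE
  })

#' Tukey honest-significant-difference matrix
#'
#' @slot p symmetric matrix of pairwise p-values (diagonal NA)
#' @slot significant logical matrix, p < alpha
#' @slot alpha significance level
#' @exportClass TukeyMatrix
setClass("TukeyMatrix",
  representation(p = "matrix", significant = "matrix", alpha = "numeric"),
  validity = function(object) {
    msg <- NULL
    off <- object@p[row(object@p) != col(object@p)]
    if (any(off < 0 | off > 1, na.rm = TRUE))
      msg <- c(msg, "p-values must lie in [0, 1]")
    if (!isTRUE(all.equal(object@p, t(object@p))))
      msg <- c(msg, "p matrix must be symmetric")
    flg <- object@p < object@alpha
    if (!identical(flg[row(flg) != col(flg)],
                   object@significant[row(flg) != col(flg)]))
      msg <- c(msg, "significance flags must equal p < alpha")
    if (is.null(msg)) TRUE else msg
  })
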