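#' @include AllClasses.R tissue-model.R
NULL

#' Construct a cohort design specification
#'
#' Defaults reproduce the emulated study design: 15 subjects distributed
#' across Fitzpatrick types I-VI, ten anatomic locations with target dermal
#' reduced-scattering mean/SD at 851 nm, eight wavelengths, five spatial
#' frequencies between 0 and 0.2 mm^-1 and three projection phases.  The
#' default pixel pitch of 0.25 mm makes a 40 x 40 pixel region of interest
#' about 1 cm^2.
#'
#' @param nSubjects number of subjects
#' @param locations anatomic locations
#' @param targetMean,targetSD named per-location dermal musp mean and
#'   intersubject SD at 851 nm, mm^-1
#' @param wavelengths nm
#' @param fx spatial frequencies, mm^-1
#' @param phases radians
#' @param fitzpatrick per-subject Fitzpatrick types; the default spreads
#'   \code{nSubjects} as evenly as possible over I-VI
#' @param scatterExponent shared scattering power-law exponent
#' @param imageSize rendered image side, pixels
#' @param pixelPitch mm per pixel
#' @param noiseLevel Gaussian noise SD as a fraction of the local DC signal
#' @param seed base RNG seed
#' @return a \code{\link{CohortSpec-class}}
#' @export
cohortSpec <- function(nSubjects = 15L,
                       locations = names(defaultLocationTargets()$mean),
                       targetMean = defaultLocationTargets()$mean,
                       targetSD = defaultLocationTargets()$sd,
                       wavelengths = defaultWavelengths(),
                       fx = defaultFrequencies(),
                       phases = c(0, 2 * pi / 3, 4 * pi / 3),
                       fitzpatrick = NULL,
                       scatterExponent = 1.3,
                       imageSize = 48L, pixelPitch = 0.25,
                       noiseLevel = 0.01, seed = 1L) {
  nSubjects <- as.integer(nSubjects)
  if (is.na(nSubjects) || nSubjects < 1L)
    stop("cohortSpec: nSubjects must be a positive integer")
  if (is.null(fitzpatrick)) {
    types <- c("I", "II", "III", "IV", "V", "VI")
    fitzpatrick <- rep(types, length.out = nSubjects)
    fitzpatrick <- fitzpatrick[order(match(fitzpatrick, types))]
  }
  new("CohortSpec", nSubjects = nSubjects, locations = locations,
      targetMean = targetMean, targetSD = targetSD,
      wavelengths = as.numeric(wavelengths), fx = as.numeric(fx),
      phases = as.numeric(phases), fitzpatrick = fitzpatrick,
      scatterExponent = scatterExponent, imageSize = as.integer(imageSize),
      pixelPitch = pixelPitch, noiseLevel = noiseLevel,
      seed = as.numeric(seed))
}

#' Generate a synthetic cohort
#'
#' Draws one phenotype per subject (Fitzpatrick-tiered epidermal melanin
#' fraction, epidermal thickness uniform in 0.10-0.15 mm, per-location
#' dermal musp at 851 nm Gaussian around the location target mean with the
#' target intersubject SD) and tabulates the ground-truth layered tissue
#' parameters for every (subject, location, wavelength).  Acquisition-stack
#' rendering is deferred by default (stacks for a full-size cohort are
#' large); use \code{render = TRUE} or \code{\link{renderSubjectLocation}}
#' to materialize images.  Fully reproducible from \code{spec@seed}.
#'
#' @param spec a \code{\link{CohortSpec-class}}
#' @param render render all acquisition stacks now (memory-heavy for large
#'   image sizes)
#' @param library a \code{ChromophoreLibrary}
#' @return a \code{\link{SyntheticCohort-class}}
#' @export
synthesizeCohort <- function(spec = cohortSpec(), render = FALSE,
                             library = chromophoreLibrary()) {
  stopifnot(is(spec, "CohortSpec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec@seed)
  phenos <- vector("list", spec@nSubjects)
  for (i in seq_len(spec@nSubjects)) {
    fp <- spec@fitzpatrick[i]
    scale <- stats::rnorm(length(spec@locations), 1,
                          spec@targetSD[spec@locations] /
                            spec@targetMean[spec@locations])
    scale <- pmax(scale, 0.2) # dermal scattering cannot vanish
    names(scale) <- spec@locations
    phenos[[i]] <- subjectPhenotype(
      id = sprintf("S%02d", i), fitzpatrick = fp,
      melaninFraction = fitzpatrickMelanin(fp),
      epidermalThickness = stats::runif(1, 0.10, 0.15),
      locationScale = scale)
  }
  grid <- expand.grid(subject = seq_len(spec@nSubjects),
                      location = spec@locations,
                      wavelength = spec@wavelengths,
                      stringsAsFactors = FALSE)
  truth <- do.call(rbind, lapply(seq_len(nrow(grid)), function(r) {
    i <- grid$subject[r]; loc <- grid$location[r]; wl <- grid$wavelength[r]
    ph <- phenos[[i]]
    tm <- skinModelFromPhenotype(ph, loc, wl, targetMean = spec@targetMean,
                                 scatterExponent = spec@scatterExponent,
                                 library = library)
    data.frame(subject = ph@id, fitzpatrick = ph@fitzpatrick, location = loc,
               wavelength = wl,
               melaninFraction = ph@melaninFraction,
               epidermalThickness = ph@epidermalThickness,
               muaEpidermis = tm@layers$mua[1],
               muaDermis = tm@layers$mua[2],
               muspDermis = tm@layers$musp[2],
               musp851 = spec@targetMean[[loc]] * ph@locationScale[[loc]],
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  co <- new("SyntheticCohort", spec = spec, phenotypes = phenos,
            truth = truth, stacks = list())
  if (render) {
    co@stacks <- lapply(seq_len(spec@nSubjects), function(i) {
      st <- lapply(spec@locations, function(loc)
        renderSubjectLocation(co, i, loc, library = library))
      names(st) <- spec@locations
      st
    })
  }
  co
}

#' Ground-truth table accessor
#' @param cohort a \code{SyntheticCohort}
#' @return data.frame of per-(subject, location, wavelength) tissue truth
#' @export
cohortTruth <- function(cohort) cohort@truth
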