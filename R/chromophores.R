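#' @include AllClasses.R
NULL

#' Default chromophore spectral library
#'
#' Melanin absorption is modelled as a power law,
#' \eqn{\mu_{a,mel}(\lambda) = s (\lambda / \lambda_0)^{p}}, anchored at
#' s = 51.9 mm^-1 at 500 nm (interior-of-melanosome scale) and multiplied by
#' the epidermal melanin volume fraction to give the melanin contribution to
#' epidermal absorption.  The default exponent p = -8 is an effective,
#' generator-level slope: it keeps the visible-band melanin contrast strong
#' while making the 851-nm contrast negligible, which is what in vivo
#' retrievals across skin types show at that wavelength; shallower in vitro
#' slopes (around -3) leave enough near-infrared melanin absorption in a
#' uniformly melanized 0.1-0.15 mm epidermis to depress apparent reduced
#' scattering by tens of percent there, which the emulated instrument does
#' not observe.  The law is strictly decreasing across the instrument
#' band.  Baseline dermal absorption is a small tabulated spectrum carrying
#' the residual blood/water background of bloodless-to-lightly-perfused
#' dermis, interpolated linearly between the instrument wavelengths.
#'
#' @return a \code{\link{ChromophoreLibrary-class}}
#' @export
chromophoreLibrary <- function() {
  new("ChromophoreLibrary",
      melaninScale = 51.9, melaninExponent = -8, melaninRefWavelength = 500,
      dermisWavelengths = c(471, 526, 591, 621, 659, 691, 731, 851),
      dermisMua = c(0.060, 0.070, 0.045, 0.030, 0.022, 0.018, 0.016, 0.012))
}

#' Melanin absorption coefficient of pure melanin
#'
#' @param library a \code{ChromophoreLibrary}
#' @param wavelength nm (vectorized)
#' @return mm^-1
#' @export
melaninMua <- function(wavelength, library = chromophoreLibrary()) {
  library@melaninScale *
    (wavelength / library@melaninRefWavelength)^library@melaninExponent
}

#' Baseline dermal absorption coefficient
#'
#' Linear interpolation of the library's dermis table; constant extrapolation
#' outside the tabulated band.
#'
#' @inheritParams melaninMua
#' @return mm^-1
#' @export
dermisBaselineMua <- function(wavelength, library = chromophoreLibrary()) {
  stats::approx(library@dermisWavelengths, library@dermisMua,
                xout = wavelength, rule = 2)$y
}

#' Default epidermal melanin volume fraction per Fitzpatrick type
#'
#' Tiered generator defaults spanning lightly pigmented (I, II) through
#' darkly pigmented (V, VI) skin.  All values are configurable per subject.
#'
#' @param fitzpatrick character vector of types "I".."VI"
#' @return melanin volume fraction(s) in [0, 0.5]
#' @export
fitzpatrickMelanin <- function(fitzpatrick) {
  tiers <- c(I = 0.01, II = 0.02, III = 0.04, IV = 0.06, V = 0.09, VI = 0.12)
  bad <- !fitzpatrick %in% names(tiers)
  if (any(bad)) stop("unknown Fitzpatrick type: ",
                     paste(unique(fitzpatrick[bad]), collapse = ", "))
  unname(tiers[fitzpatrick])
}
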