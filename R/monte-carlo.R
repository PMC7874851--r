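#' @include AllClasses.R forward-model.R
NULL

#' Monte Carlo photon transport through a layered tissue model
#'
#' MCML-style random walk through plane-parallel layers: Henyey-Greenstein
#' scattering at anisotropy g, Fresnel reflection/refraction at every
#' refractive-index mismatch, implicit-capture absorption weighting and
#' Russian roulette.  The scattering coefficient of each layer is recovered
#' from the reduced coefficient by similarity, mus = musp / (1 - g).
#' Diffuse reflectance escaping the top surface is binned radially around
#' the pencil-beam entry point.  Fully reproducible for a fixed seed.
#'
#' @param model a \code{\link{TissueModel-class}} (terminal layer
#'   semi-infinite)
#' @param nPhotons number of photons (>= 1e4)
#' @param seed RNG seed (integer)
#' @param dr radial bin width, mm
#' @param nr number of radial bins
#' @param nAmbient refractive index of the ambient medium
#' @return a \code{\link{RadialReflectanceProfile-class}}
#' @export
mcLayeredRadial <- function(model, nPhotons = 1e5, seed = 1, dr = 0.05,
                            nr = 400L, nAmbient = 1.0) {
  stopifnot(is(model, "TissueModel"))
  L <- model@layers
  if (nrow(L) < 1L) stop("mcLayeredRadial: zero layers")
  if (nPhotons < 1e4) stop("mcLayeredRadial: nPhotons must be >= 1e4")
  if (is.finite(L$thickness[nrow(L)]))
    warning("terminal layer is finite; transmitted photons will be lost")
  mus <- L$musp / (1 - L$g)
  res <- .mc_layered_cpp(L$thickness, L$mua, mus, L$g, L$n, nAmbient,
                         as.integer(nPhotons), dr, as.integer(nr),
                         as.numeric(seed))
  edges <- seq(0, nr * dr, by = dr)
  area <- pi * diff(edges^2)
  new("RadialReflectanceProfile",
      binEdges = edges,
      values = res$bin_weights / (nPhotons * area),
      totalDiffuse = res$total_diffuse,
      specular = res$specular,
      overflow = res$overflow / nPhotons,
      nPhotons = as.numeric(nPhotons), seed = as.numeric(seed))
}

#' Project a radial reflectance profile into the spatial frequency domain
#'
#' Zeroth-order Hankel transform of the spatially resolved reflectance,
#' \deqn{R_d(f_x) = 2\pi \int_0^\infty R(\rho) J_0(2\pi f_x \rho)\,\rho\,d\rho,}
#' evaluated by the midpoint rule on the profile's radial bins.  At fx = 0
#' this is the total diffuse reflectance captured by the bins.
#'
#' @param profile a \code{RadialReflectanceProfile}
#' @param fx spatial frequencies, mm^-1
#' @return named numeric vector of Rd(fx), in the order given; carries a
#'   \code{"truncated"} attribute (with a warning) when more than 1\% of the
#'   escaping weight fell beyond the last bin
#' @export
hankelToSFD <- function(profile, fx = defaultFrequencies()) {
  stopifnot(is(profile, "RadialReflectanceProfile"))
  edges <- profile@binEdges
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  w <- diff(edges)
  truncated <- FALSE
  if (profile@totalDiffuse > 0 &&
      profile@overflow / profile@totalDiffuse >= 0.01) {
    warning("hankelToSFD: profile truncated (tail mass >= 1% of diffuse ",
            "reflectance); Rd underestimated")
    truncated <- TRUE
  }
  out <- vapply(fx, function(f) {
    2 * pi * sum(profile@values * besselJ(2 * pi * f * mid, 0) * mid * w)
  }, numeric(1))
  names(out) <- as.character(fx)
  attr(out, "truncated") <- truncated
  out
}

#' Effective homogeneous reflectance of a layered model via Monte Carlo
#'
#' Convenience wrapper: runs the Monte Carlo oracle on a layered model and
#' projects the radial profile to the requested spatial frequencies.
#'
#' @inheritParams mcLayeredRadial
#' @param fx spatial frequencies, mm^-1
#' @return Rd(fx), named numeric vector
#' @export
mcReflectance <- function(model, fx = defaultFrequencies(), nPhotons = 1e5,
                          seed = 1, dr = 0.05, nr = 400L) {
  prof <- mcLayeredRadial(model, nPhotons = nPhotons, seed = seed, dr = dr,
                          nr = nr)
  hankelToSFD(prof, fx)
}
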