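#' @include AllClasses.R
NULL

# default three-phase set; demodulation in v1 is specific to it
.DEFAULT_PHASES <- c(0, 2 * pi / 3, 4 * pi / 3)

#' Three-phase demodulation of an acquisition stack
#'
#' Recovers the AC and DC modulation amplitudes per (wavelength, frequency)
#' channel from the three phase-shifted frames:
#' \deqn{M_{AC} = \frac{\sqrt 2}{3}\sqrt{(I_1-I_2)^2 + (I_2-I_3)^2 +
#' (I_3-I_1)^2}, \qquad M_{DC} = (I_1 + I_2 + I_3)/3.}
#' For ideal frames \eqn{I_k = A + B\cos(\phi_k + \theta)} this returns B
#' and A exactly, for any phase offset theta.  Only the standard phase set
#' {0, 2pi/3, 4pi/3} is accepted.
#'
#' @param stack an \code{\link{AcquisitionStack-class}}
#' @return a \code{\link{ModulationStack-class}}
#' @export
demodulate <- function(stack) {
  stopifnot(is(stack, "AcquisitionStack"))
  ph <- sort(stack@phases %% (2 * pi))
  if (length(ph) != 3L || any(abs(ph - .DEFAULT_PHASES) > 1e-9))
    stop("demodulate: only the three-phase set {0, 2pi/3, 4pi/3} is supported")
  ord <- order(stack@phases %% (2 * pi))
  d <- dim(stack@data)
  i1 <- stack@data[, , , , ord[1], drop = FALSE]
  i2 <- stack@data[, , , , ord[2], drop = FALSE]
  i3 <- stack@data[, , , , ord[3], drop = FALSE]
  ac <- sqrt(2) / 3 * sqrt((i1 - i2)^2 + (i2 - i3)^2 + (i3 - i1)^2)
  dc <- (i1 + i2 + i3) / 3
  dim(ac) <- d[1:4]; dim(dc) <- d[1:4]
  new("ModulationStack", ac = ac, dc = dc, wavelengths = stack@wavelengths,
      fx = stack@fx)
}

#' Calibrate modulation amplitudes against the reference phantom
#'
#' Converts sample modulation amplitudes into calibrated diffuse reflectance
#' by ratioing against the reference phantom measured under the same
#' geometry and multiplying by the phantom's forward-model-predicted
#' reflectance: \eqn{R_d = (M_{sample}/M_{ref}) \times R_{d,ref}^{pred}}.
#' The fx = 0 channel carries no AC modulation under planar illumination, so
#' the DC amplitudes are ratioed there.  Pixels where the reference
#' amplitude falls below \code{eps}, or where the calibrated value exceeds
#' 1, are flagged invalid rather than divided/clipped.
#'
#' @param sample a \code{ModulationStack} of the sample
#' @param reference a \code{ModulationStack} of the phantom
#' @param referencePredictedRd matrix [wavelength, fx] of predicted phantom
#'   reflectance (as returned by \code{\link{renderPhantom}})
#' @param eps reference-amplitude floor
#' @return a \code{\link{ReflectanceStack-class}}
#' @export
calibrate <- function(sample, reference, referencePredictedRd, eps = 1e-9) {
  stopifnot(is(sample, "ModulationStack"), is(reference, "ModulationStack"))
  if (!isTRUE(all.equal(sample@wavelengths, reference@wavelengths)) ||
      !isTRUE(all.equal(sample@fx, reference@fx)))
    stop("calibrate: sample and reference must share wavelengths and fx")
  if (!identical(dim(sample@ac), dim(reference@ac)))
    stop("calibrate: sample and reference must share geometry")
  d <- dim(sample@ac)
  if (nrow(referencePredictedRd) != d[3] || ncol(referencePredictedRd) != d[4])
    stop("calibrate: predicted Rd table must be [wavelength, fx]")
  rd <- array(NA_real_, dim = d)
  valid <- array(FALSE, dim = d)
  for (iw in seq_len(d[3])) for (jf in seq_len(d[4])) {
    planar <- sample@fx[jf] == 0
    ms <- if (planar) sample@dc[, , iw, jf] else sample@ac[, , iw, jf]
    mr <- if (planar) reference@dc[, , iw, jf] else reference@ac[, , iw, jf]
    ok <- mr > eps
    v <- matrix(NA_real_, d[1], d[2])
    v[ok] <- ms[ok] / mr[ok] * referencePredictedRd[iw, jf]
    rd[, , iw, jf] <- ifelse(is.na(v), 0, v)
    valid[, , iw, jf] <- ok & !is.na(v) & v <= 1
  }
  new("ReflectanceStack", rd = rd, valid = valid,
      wavelengths = sample@wavelengths, fx = sample@fx)
}
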