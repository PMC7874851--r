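#' @include AllClasses.R
NULL

.STACK_FORMAT_VERSION <- 1L

# absolute storage resolution of the 32-bit TIFF container on [0, scale]:
# writing rounds to the 2^32 - 1 grid and reading divides by 2^32
.STACK_RESOLUTION <- 2^-31

#' Write / read an acquisition stack (multi-page TIFF + JSON sidecar)
#'
#' Pixel data are stored as one 32-bit greyscale TIFF page per (wavelength,
#' fx, phase) frame, wavelength-major; acquisition metadata (wavelengths,
#' frequencies, phases, pixel pitch, seed, normalization scale, format
#' version) go to a JSON sidecar next to the TIFF (same path with extension
#' ".json").  The TIFF container stores unit-range samples quantized to 32
#' bits, so intensities are normalized by their maximum before writing and
#' rescaled on read; the stored representation resolves absolute
#' differences down to \code{max(data) * 2^-31}, and
#' \code{readStack(writeStack(x))} reproduces the pixel data to that
#' resolution.  Pixel values must be finite and non-negative.
#'
#' @param stack an \code{\link{AcquisitionStack-class}}
#' @param path output TIFF path
#' @return \code{path}, invisibly
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "AcquisitionStack"))
  if (any(!is.finite(stack@data)) || any(stack@data < 0))
    stop("writeStack: pixel data must be finite and non-negative")
  d <- dim(stack@data)
  scale <- max(stack@data)
  if (scale <= 0) scale <- 1
  pages <- vector("list", d[3] * d[4] * d[5])
  k <- 0L
  for (iw in seq_len(d[3])) for (jf in seq_len(d[4]))
    for (kp in seq_len(d[5])) {
      k <- k + 1L
      pages[[k]] <- stack@data[, , iw, jf, kp] / scale
    }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(format_version = .STACK_FORMAT_VERSION,
                  wavelengths = stack@wavelengths, fx = stack@fx,
                  phases = stack@phases, pixel_pitch = stack@pixelPitch,
                  seed = stack@seed, scale = scale, shape = d,
                  meta = stack@meta)
  jsonlite::write_json(sidecar, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path),
                                      ".json")

#' @rdname writeStack
#' @return \code{readStack}: the reconstructed \code{AcquisitionStack}
#' @export
readStack <- function(path) {
  side <- .sidecarPath(path)
  if (!file.exists(side))
    stop("readStack: missing JSON sidecar ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$format_version) ||
      meta$format_version != .STACK_FORMAT_VERSION)
    stop("readStack: sidecar format version ",
         if (is.null(meta$format_version)) "missing" else meta$format_version,
         " (this reader supports version ", .STACK_FORMAT_VERSION, ")")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  nexp <- length(meta$wavelengths) * length(meta$fx) * length(meta$phases)
  if (length(pages) != nexp)
    stop("readStack: ", length(pages), " TIFF pages but sidecar describes ",
         nexp, " (wavelengths x fx x phases)")
  d <- c(dim(pages[[1]]), length(meta$wavelengths), length(meta$fx),
         length(meta$phases))
  scale <- if (is.null(meta$scale)) 1 else meta$scale
  dat <- array(0, dim = d)
  k <- 0L
  for (iw in seq_len(d[3])) for (jf in seq_len(d[4]))
    for (kp in seq_len(d[5])) {
      k <- k + 1L
      dat[, , iw, jf, kp] <- pages[[k]] * scale
    }
  new("AcquisitionStack", data = dat, wavelengths = meta$wavelengths,
      fx = meta$fx, phases = meta$phases, pixelPitch = meta$pixel_pitch,
      seed = if (is.null(meta$seed)) NA_real_ else meta$seed,
      meta = if (is.null(meta$meta)) list() else as.list(meta$meta))
}
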