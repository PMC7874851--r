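#' @include AllClasses.R
NULL

#' @export
setGeneric("muA", function(x, ...) standardGeneric("muA"))
#' @export
setGeneric("muSp", function(x, ...) standardGeneric("muSp"))
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
#' @export
setGeneric("spatialFrequencies", function(x) standardGeneric("spatialFrequencies"))
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @export
setGeneric("anovaTable", function(x) standardGeneric("anovaTable"))

#' @describeIn OpticalPropertyPair-class absorption coefficient accessor
#' @param x object
#' @param ... unused
#' @export
setMethod("muA", "OpticalPropertyPair", function(x, ...) x@muA)
#' @describeIn OpticalPropertyPair-class reduced scattering accessor
#' @export
setMethod("muSp", "OpticalPropertyPair", function(x, ...) x@muSp)

#' @describeIn OpticalPropertyMap-class absorption map accessor
#' @param x object
#' @param ... unused
#' @export
setMethod("muA", "OpticalPropertyMap", function(x, ...) x@muA)
#' @describeIn OpticalPropertyMap-class reduced scattering map accessor
#' @export
setMethod("muSp", "OpticalPropertyMap", function(x, ...) x@muSp)
#' @describeIn OpticalPropertyMap-class validity mask accessor
#' @export
setMethod("validMask", "OpticalPropertyMap", function(x) x@valid)
#' @describeIn OpticalPropertyMap-class wavelength accessor
#' @export
setMethod("wavelengths", "OpticalPropertyMap", function(x) x@wavelengths)

#' @describeIn AcquisitionStack-class wavelength accessor
#' @export
setMethod("wavelengths", "AcquisitionStack", function(x) x@wavelengths)
#' @describeIn AcquisitionStack-class spatial frequency accessor
#' @export
setMethod("spatialFrequencies", "AcquisitionStack", function(x) x@fx)
#' @describeIn ReflectanceStack-class wavelength accessor
#' @export
setMethod("wavelengths", "ReflectanceStack", function(x) x@wavelengths)
#' @describeIn ReflectanceStack-class spatial frequency accessor
#' @export
setMethod("spatialFrequencies", "ReflectanceStack", function(x) x@fx)
#' @describeIn ReflectanceStack-class validity mask accessor
#' @export
setMethod("validMask", "ReflectanceStack", function(x) x@valid)
#' @describeIn ReflectanceLUT-class spatial frequency accessor
#' @export
setMethod("spatialFrequencies", "ReflectanceLUT", function(x) x@fx)

#' @describeIn AnovaResult-class the decomposition as a data.frame
#' @param x object
#' @export
setMethod("anovaTable", "AnovaResult", function(x) x@table)

setMethod("show", "OpticalPropertyPair", function(object) {
  cat(sprintf("OpticalPropertyPair: muA = %.4g mm^-1, muSp = %.4g mm^-1\n",
              object@muA, object@muSp))
})

setMethod("show", "ReflectanceLUT", function(object) {
  cat(sprintf(
    "ReflectanceLUT: %d x %d nodes, muA [%.3g, %.3g], muSp [%.3g, %.3g] mm^-1\n",
    length(object@muaAxis), length(object@muspAxis),
    min(object@muaAxis), max(object@muaAxis),
    min(object@muspAxis), max(object@muspAxis)))
  cat(sprintf("  fx: %s mm^-1 | g = %.2f, n = %.2f\n",
              paste(signif(object@fx, 3), collapse = ", "),
              object@constants@g, object@constants@n))
})

setMethod("show", "TissueModel", function(object) {
  cat(sprintf("TissueModel with %d layer(s):\n", nrow(object@layers)))
  print(object@layers, row.names = FALSE)
})

setMethod("show", "AcquisitionStack", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "AcquisitionStack: %d x %d px, %d wavelengths x %d frequencies x %d phases\n",
    d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  pixel pitch %.3g mm, field of view %.1f x %.1f mm\n",
              object@pixelPitch, d[1] * object@pixelPitch,
              d[2] * object@pixelPitch))
})

setMethod("show", "OpticalPropertyMap", function(object) {
  d <- dim(object@muA)
  cat(sprintf("OpticalPropertyMap: %d x %d px at %d wavelength(s); %.1f%% valid\n",
              d[1], d[2], d[3], 100 * mean(object@valid)))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d subjects x %d locations x %d wavelengths\n",
              object@spec@nSubjects, length(object@spec@locations),
              length(object@spec@wavelengths)))
  cat(sprintf("  Fitzpatrick: %s\n",
              paste(object@spec@fitzpatrick, collapse = " ")))
  cat(sprintf("  rendered stacks: %s\n",
              if (length(object@stacks)) "yes" else "deferred"))
})

setMethod("show", "AnovaResult", function(object) {
  cat("One-way ANOVA\n")
  tb <- object@table
  tb$ss <- signif(tb$ss, 4); tb$ms <- signif(tb$ms, 4)
  tb$F <- signif(tb$F, 4); tb$p <- signif(tb$p, 3)
  print(tb)
})

setMethod("show", "TukeyMatrix", function(object) {
  cat(sprintf("Tukey HSD pairwise p-values (alpha = %g):\n", object@alpha))
  p <- signif(object@p, 2)
  p[object@significant & !is.na(object@p)] <-
    paste0(p[object@significant & !is.na(object@p)], "*")
  print(p, quote = FALSE, na.print = "-")
})
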