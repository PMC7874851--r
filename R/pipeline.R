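#' @include AllClasses.R cohort.R render.R demodulate.R invert.R
#' @include cohort-stats.R io.R
NULL

.stageLog <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s | %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates simulate -> render -> demodulate -> calibrate -> invert ->
#' aggregate -> cohort statistics, persisting each stage's tabular outputs
#' as CSV under \code{outDir}.  Deterministic for a fixed spec seed.  The
#' \code{stages} argument allows a stats-only rerun from a persisted cohort
#' table without re-rendering.
#'
#' @param spec a \code{\link{CohortSpec-class}}
#' @param outDir output directory (created if needed)
#' @param lut a \code{\link{ReflectanceLUT-class}}; built at the spec's
#'   frequencies with the default 768 x 768 grid when NULL
#' @param stages subset of c("simulate", "process", "stats"); "process"
#'   implies "simulate", and "stats" reuses a persisted cohort table when
#'   "process" is skipped
#' @param roi a \code{\link{roiSpec}}; default is a centered square of up to
#'   40 px
#' @param statsWavelength wavelength for the ANOVA/Tukey stage, nm
#' @param method forward model for rendering, see \code{\link{tissueRd}}
#' @param alpha Tukey significance level
#' @return list with truth, cohort table, per-wavelength summaries, CV
#'   table, and the ANOVA/Tukey results at \code{statsWavelength}
#' @export
runPipeline <- function(spec = cohortSpec(), outDir, lut = NULL,
                        stages = c("simulate", "process", "stats"),
                        roi = NULL, statsWavelength = 851,
                        method = "twolayer", alpha = 0.05) {
  stages <- match.arg(stages, c("simulate", "process", "stats"),
                      several.ok = TRUE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tablePath <- file.path(outDir, "cohort_table.csv")
  out <- list()

  if (any(c("simulate", "process") %in% stages)) {
    .stageLog("simulate", "cohort: %d subjects x %d locations, seed %d",
              spec@nSubjects, length(spec@locations), spec@seed)
    cohort <- synthesizeCohort(spec)
    utils::write.csv(cohort@truth, file.path(outDir, "ground_truth.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(nSubjects = spec@nSubjects, locations = spec@locations,
           wavelengths = spec@wavelengths, fx = spec@fx,
           phases = spec@phases, imageSize = spec@imageSize,
           pixelPitch = spec@pixelPitch, noiseLevel = spec@noiseLevel,
           scatterExponent = spec@scatterExponent,
           fitzpatrick = spec@fitzpatrick, seed = spec@seed),
      file.path(outDir, "config.json"), auto_unbox = TRUE, digits = NA)
    out$cohort <- cohort
  }

  if ("process" %in% stages) {
    if (is.null(lut)) {
      .stageLog("process", "building %d x %d LUT", 768L, 768L)
      lut <- buildLUT(spec@fx)
    }
    if (is.null(roi)) {
      side <- min(40L, spec@imageSize)
      off <- (spec@imageSize - side) %/% 2L + 1L
      roi <- roiSpec(off, off, side, side)
    }
    ph <- renderPhantom(defaultPhantom(spec@wavelengths), fx = spec@fx,
                        phases = spec@phases, imageSize = spec@imageSize,
                        pixelPitch = spec@pixelPitch, noiseLevel = 0,
                        seed = spec@seed + 1)
    refMod <- demodulate(ph$stack)
    rows <- list()
    for (i in seq_len(spec@nSubjects)) {
      for (loc in spec@locations) {
        stack <- renderSubjectLocation(out$cohort, i, loc, method = method)
        rs <- calibrate(demodulate(stack), refMod, ph$predictedRd)
        opm <- invertMap(rs, lut)
        agg <- extractROI(opm, roi)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = out$cohort@phenotypes[[i]]@id,
          fitzpatrick = out$cohort@phenotypes[[i]]@fitzpatrick,
          location = loc, wavelength = agg$wavelength,
          muSp = agg$meanMuSp, muSpSdIntra = agg$sdMuSp,
          muA = agg$meanMuA, muASdIntra = agg$sdMuA,
          nValid = agg$nValid, stringsAsFactors = FALSE)
      }
      .stageLog("process", "subject %d/%d done", i, spec@nSubjects)
    }
    table <- do.call(rbind, rows)
    utils::write.csv(table, tablePath, row.names = FALSE)
    out$table <- table
  } else if ("stats" %in% stages) {
    if (!file.exists(tablePath))
      stop("runPipeline: stats-only rerun needs a persisted cohort table at ",
           tablePath)
    .stageLog("stats", "reusing persisted cohort table %s", tablePath)
    out$table <- utils::read.csv(tablePath, stringsAsFactors = FALSE)
  }

  if ("stats" %in% stages) {
    tb <- out$table
    summaries <- lapply(spec@wavelengths, function(wl)
      cbind(wavelength = wl,
            coefficientOfVariation(cohortSummary(tb, wl))))
    cv <- do.call(rbind, summaries)
    utils::write.csv(cv, file.path(outDir, "summary_cv.csv"),
                     row.names = FALSE)
    sw <- cohortSummary(tb, statsWavelength)
    groups <- split(tb$muSp[tb$wavelength == statsWavelength],
                    tb$location[tb$wavelength == statsWavelength])
    an <- oneWayAnova(groups)
    tk <- tukeyHsd(stats::setNames(sw$mean, sw$location),
                   anovaTable(an)$ms[2], anovaTable(an)$df[2],
                   as.integer(round(mean(sw$n))), alpha = alpha)
    utils::write.csv(anovaTable(an),
                     file.path(outDir,
                               sprintf("anova_%g.csv", statsWavelength)),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(tk@p),
                     file.path(outDir,
                               sprintf("tukey_%g.csv", statsWavelength)),
                     row.names = TRUE)
    out$cv <- cv
    out$anova <- an
    out$tukey <- tk
    .stageLog("stats", "ANOVA F = %.3g at %g nm", anovaTable(an)$F[1],
              statsWavelength)
  }
  out
}
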