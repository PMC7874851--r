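#' @include AllClasses.R cohort-stats.R
NULL

#' Bundled reference-cohort summary tables
#'
#' The package ships the printed intersubject summary of a 15-subject,
#' ten-location skin survey at 851 nm: per-location mean and sample SD of
#' the reduced scattering coefficient, the one-way ANOVA decomposition
#' across locations, and the Tukey HSD pairwise p-values.  These serve as
#' the generator's anchor targets and as the input for the
#' summary-statistics reconstruction (\code{\link{reproduceTables}}).
#'
#' @return \code{referenceCohortSummary}: data.frame with location, mean,
#'   sd (mm^-1, 851 nm)
#' @export
referenceCohortSummary <- function() {
  utils::read.csv(system.file("extdata", "refcohort_musp851.csv",
                              package = "sfdiskin"),
                  stringsAsFactors = FALSE)
}

#' @rdname referenceCohortSummary
#' @return \code{referenceAnova}: data.frame with the printed ANOVA rows
#'   (p column as printed, censored values as "<0.001")
#' @export
referenceAnova <- function() {
  utils::read.csv(system.file("extdata", "refcohort_anova851.csv",
                              package = "sfdiskin"),
                  stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = c(source = "character", ss = "numeric",
                                 df = "integer", ms = "numeric",
                                 F = "numeric", p = "character"))
}

#' @rdname referenceCohortSummary
#' @return \code{referenceTukey}: long-format data.frame of printed pairwise
#'   p-values with censoring ("<0.001" stored as 0.001 with
#'   \code{censored = TRUE}) and the printed significance flags
#' @export
referenceTukey <- function() {
  utils::read.csv(system.file("extdata", "refcohort_tukey851.csv",
                              package = "sfdiskin"),
                  stringsAsFactors = FALSE)
}

#' Reconstruct the ANOVA and Tukey tables from the printed summaries
#'
#' Feeds the bundled per-location (mean, SD) pairs with n = 15 into
#' \code{\link{anovaFromSummary}} and \code{\link{tukeyHsd}}, reproducing
#' the published location-comparison statistics from summary data alone.
#'
#' @param n per-location subject count
#' @param alpha significance level for the Tukey flags
#' @return list with \code{summary} (the input table), \code{anova} (an
#'   \code{AnovaResult}), \code{tukey} (a \code{TukeyMatrix})
#' @export
reproduceTables <- function(n = 15L, alpha = 0.05) {
  ref <- referenceCohortSummary()
  an <- anovaFromSummary(ref$mean, ref$sd, rep(n, nrow(ref)))
  means <- stats::setNames(ref$mean, ref$location)
  mse <- anovaTable(an)$ms[2]
  dfe <- anovaTable(an)$df[2]
  tk <- tukeyHsd(means, mse, dfe, n, alpha = alpha)
  list(summary = ref, anova = an, tukey = tk)
}
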