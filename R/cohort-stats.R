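#' @include AllClasses.R
NULL

#' Region-of-interest specification
#'
#' Top-left pixel and size of the square analysis region; the default 40 x
#' 40 pixels is about 1 cm^2 at the default 0.25 mm pixel pitch.
#'
#' @param row,col top-left pixel (1-based)
#' @param width,height extent in pixels
#' @return a list with class \code{"RoiSpec"}
#' @export
roiSpec <- function(row = 1L, col = 1L, width = 40L, height = 40L) {
  structure(list(row = as.integer(row), col = as.integer(col),
                 width = as.integer(width), height = as.integer(height)),
            class = "RoiSpec")
}

#' Aggregate an optical property map over a region of interest
#'
#' Intrasubject averaging: mean and SD of the recovered muSp and muA over
#' the ROI's valid pixels, per wavelength.  Rejected when the ROI leaves the
#' map or fewer than half its pixels are valid.
#'
#' @param map an \code{\link{OpticalPropertyMap-class}}
#' @param roi a \code{\link{roiSpec}}
#' @param minValidFraction reject below this valid-pixel fraction
#' @return data.frame with one row per wavelength: meanMuSp, sdMuSp,
#'   meanMuA, sdMuA, nValid
#' @export
extractROI <- function(map, roi = roiSpec(), minValidFraction = 0.5) {
  stopifnot(is(map, "OpticalPropertyMap"), inherits(roi, "RoiSpec"))
  d <- dim(map@muA)
  rows <- roi$row:(roi$row + roi$height - 1L)
  cols <- roi$col:(roi$col + roi$width - 1L)
  if (roi$row < 1L || roi$col < 1L || max(rows) > d[1] || max(cols) > d[2])
    stop("extractROI: ROI extends outside the map (",
         d[1], " x ", d[2], " px)")
  out <- lapply(seq_len(d[3]), function(iw) {
    v <- map@valid[rows, cols, iw]
    if (mean(v) < minValidFraction)
      stop("extractROI: only ", round(100 * mean(v)), "% of ROI pixels are ",
           "valid at wavelength index ", iw,
           " (needed ", 100 * minValidFraction, "%)")
    ms <- map@muSp[rows, cols, iw][v]
    ma <- map@muA[rows, cols, iw][v]
    data.frame(wavelength = map@wavelengths[iw],
               meanMuSp = mean(ms), sdMuSp = stats::sd(ms),
               meanMuA = mean(ma), sdMuA = stats::sd(ma),
               nValid = sum(v))
  })
  do.call(rbind, out)
}

#' Intersubject summary per location at one wavelength
#'
#' Computes the intersubject mean and sample SD (n - 1 denominator) of the
#' intrasubject ROI averages, per location.  Groups with a single subject
#' are flagged (SD undefined).
#'
#' @param table cohort table: data.frame with columns subject, location,
#'   wavelength and muSp (intrasubject ROI mean)
#' @param wavelength which wavelength to summarize, nm
#' @param value column to summarize (default "muSp")
#' @return data.frame with location, mean, sd, n, flagged
#' @export
cohortSummary <- function(table, wavelength, value = "muSp") {
  sub <- table[table$wavelength == wavelength, , drop = FALSE]
  if (nrow(sub) == 0L) stop("cohortSummary: no rows at wavelength ",
                            wavelength)
  sp <- split(sub[[value]], sub$location)
  out <- data.frame(
    location = names(sp),
    mean = vapply(sp, mean, numeric(1)),
    sd = vapply(sp, function(x) if (length(x) >= 2L) stats::sd(x)
                else NA_real_, numeric(1)),
    n = vapply(sp, length, integer(1)),
    stringsAsFactors = FALSE)
  out$flagged <- out$n < 2L
  rownames(out) <- NULL
  out
}

#' Intersubject coefficient of variation
#'
#' CV = SD / mean, dimensionless.  Accepts either a summary data.frame (as
#' returned by \code{\link{cohortSummary}}) or raw mean/sd vectors.
#'
#' @param mean intersubject means (or a summary data.frame)
#' @param sd intersubject SDs (ignored when \code{mean} is a data.frame)
#' @return numeric CV (with a cv column added when given a data.frame)
#' @export
coefficientOfVariation <- function(mean, sd = NULL) {
  if (is.data.frame(mean)) {
    df <- mean
    df$cv <- coefficientOfVariation(df$mean, df$sd)
    return(df)
  }
  if (any(!is.finite(mean)) || any(mean <= 0))
    stop("coefficientOfVariation: means must be finite and > 0")
  sd / mean
}

#' One-way analysis of variance on raw groups
#'
#' Standard one-way fixed-effects ANOVA (fit via \code{stats::aov}),
#' returning the between ("Columns"), within ("Error") and total
#' decomposition with the F ratio and its p-value.
#'
#' @param groups named list of numeric vectors, one per group
#' @return an \code{\link{AnovaResult-class}}
#' @export
oneWayAnova <- function(groups) {
  if (length(groups) < 2L) stop("oneWayAnova: at least 2 groups required")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("oneWayAnova: every group needs n >= 2")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), vapply(groups, length, integer(1)))))
  fit <- stats::aov(y ~ g, data = df)
  sm <- summary(fit)[[1]]
  ssb <- sm[1, "Sum Sq"]; ssw <- sm[2, "Sum Sq"]
  dfb <- sm[1, "Df"]; dfw <- sm[2, "Df"]
  .anovaResult(ssb, ssw, dfb, dfw)
}

.anovaResult <- function(ssb, ssw, dfb, dfw) {
  msb <- ssb / dfb; msw <- ssw / dfw
  f <- msb / msw
  p <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
  new("AnovaResult", table = data.frame(
    source = c("Columns", "Error", "Total"),
    ss = c(ssb, ssw, ssb + ssw),
    df = c(dfb, dfw, dfb + dfw),
    ms = c(msb, msw, NA),
    F = c(f, NA, NA),
    p = c(p, NA, NA),
    stringsAsFactors = FALSE))
}

#' One-way ANOVA reconstructed from printed summary statistics
#'
#' Rebuilds the full decomposition from per-group means, sample SDs and
#' sizes alone: \eqn{SS_{within} = \sum_i (n_i - 1) s_i^2},
#' \eqn{SS_{between} = \sum_i n_i (\bar x_i - \bar x)^2} with the grand mean
#' weighted by group size.  Identical to \code{\link{oneWayAnova}} applied
#' to any raw data having exactly those summaries.
#'
#' @param means per-group means
#' @param sds per-group sample SDs (n - 1 denominator)
#' @param ns per-group sizes (>= 2)
#' @return an \code{\link{AnovaResult-class}}
#' @export
anovaFromSummary <- function(means, sds, ns) {
  k <- length(means)
  if (length(sds) != k || length(ns) != k)
    stop("anovaFromSummary: means, sds and ns must have equal length")
  if (any(ns < 2L)) stop("anovaFromSummary: every group needs n >= 2")
  grand <- sum(ns * means) / sum(ns)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  .anovaResult(ssb, ssw, k - 1L, sum(ns) - k)
}

#' Tukey honest-significant-difference test from summary statistics
#'
#' All-pairs comparisons for balanced groups via the studentized range
#' distribution: for groups i, j the statistic is
#' \eqn{q = |\bar x_i - \bar x_j| / \sqrt{MSE/n}} and the p-value is the
#' upper tail of the studentized range with (k, dfError).
#'
#' @param means named per-group means
#' @param mse error (within-group) mean square
#' @param dfError error degrees of freedom
#' @param n common per-group size (balanced design)
#' @param alpha significance level for the flags
#' @return a \code{\link{TukeyMatrix-class}}
#' @export
tukeyHsd <- function(means, mse, dfError, n, alpha = 0.05) {
  k <- length(means)
  if (k < 2L) stop("tukeyHsd: at least 2 groups required")
  if (mse <= 0) stop("tukeyHsd: mse must be > 0")
  if (is.null(names(means))) names(means) <- paste0("g", seq_len(k))
  se <- sqrt(mse / n)
  q <- abs(outer(means, means, `-`)) / se
  p <- matrix(stats::ptukey(q, nmeans = k, df = dfError,
                            lower.tail = FALSE), k, k,
              dimnames = list(names(means), names(means)))
  diag(p) <- NA_real_
  sig <- p < alpha
  diag(sig) <- FALSE
  new("TukeyMatrix", p = p, significant = sig, alpha = alpha)
}
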