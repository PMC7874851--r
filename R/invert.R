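#' @include AllClasses.R forward-model.R
NULL

# reason codes for invalid pixels
.REASON_OK <- 0L
.REASON_OUT_OF_RANGE <- 1L
.REASON_BAD_CALIBRATION <- 2L

# Vectorized least-squares LUT inversion.
# rdMat: [npixel, nfx] measured reflectance, one row per pixel.
# Coarse search on a decimated node grid (every `decimate`-th node) followed
# by deterministic Levenberg-damped Gauss-Newton descent on the bilinearly
# interpolated table until the parameter update falls below `tol`.  Plain
# pattern search stalls in the narrow diagonal misfit valley at high muA /
# low muSp; Gauss-Newton follows the valley.  Ties in the coarse search
# break toward lower muA (which.min on a muA-major layout).
.invertCore <- function(rdMat, lut, decimate = 8L, tol = 1e-4,
                        chunk = 4096L, maxit = 100L) {
  nfx <- length(lut@fx)
  stopifnot(ncol(rdMat) == nfx)
  np <- nrow(rdMat)
  si <- seq(1L, length(lut@muaAxis), by = decimate)
  sj <- seq(1L, length(lut@muspAxis), by = decimate)
  # coarse node table: [node, fx], muA-major within each musp block
  coarse <- matrix(0, length(si) * length(sj), nfx)
  for (k in seq_len(nfx))
    coarse[, k] <- as.vector(lut@values[k, si, sj])
  nodeMua <- rep(lut@muaAxis[si], times = length(sj))
  nodeMusp <- rep(lut@muspAxis[sj], each = length(si))
  nodeSq <- rowSums(coarse^2)

  outA <- numeric(np); outS <- numeric(np); outR <- numeric(np)

  # hoist the per-frequency planes once; repeated slicing of the 3-d value
  # array inside the descent loop dominates runtime otherwise
  planes <- lapply(seq_len(nfx), function(k) lut@values[k, , ])
  ax <- lut@muaAxis; ay <- lut@muspAxis
  nA <- length(ax); nS <- length(ay)
  daCell <- diff(ax)[1]; dsCell <- diff(ay)[1]
  valGrad <- function(pl, a, s) {
    # value and gradient of the bilinear patch containing (a, s)
    ix <- pmin(pmax(findInterval(a, ax, rightmost.closed = TRUE), 1L), nA - 1L)
    iy <- pmin(pmax(findInterval(s, ay, rightmost.closed = TRUE), 1L), nS - 1L)
    tx <- (a - ax[ix]) / daCell; ty <- (s - ay[iy]) / dsCell
    p00 <- pl[cbind(ix, iy)]; p10 <- pl[cbind(ix + 1L, iy)]
    p01 <- pl[cbind(ix, iy + 1L)]; p11 <- pl[cbind(ix + 1L, iy + 1L)]
    list(v = (1 - tx) * (1 - ty) * p00 + tx * (1 - ty) * p10 +
           (1 - tx) * ty * p01 + tx * ty * p11,
         ga = (-(1 - ty) * p00 + (1 - ty) * p10 - ty * p01 + ty * p11) /
           daCell,
         gs = (-(1 - tx) * p00 - tx * p10 + (1 - tx) * p01 + tx * p11) /
           dsCell)
  }

  for (start in seq(1L, np, by = chunk)) {
    idx <- start:min(start + chunk - 1L, np)
    rdMatChunk <- rdMat[idx, , drop = FALSE]
    m <- length(idx)
    sseAt <- function(a, s) {
      tot <- numeric(m)
      for (k in seq_len(nfx))
        tot <- tot + (valGrad(planes[[k]], a, s)$v - rdMatChunk[, k])^2
      tot
    }
    # SSE to every coarse node via |rd|^2 - 2 rd.v + |v|^2
    cross <- rdMatChunk %*% t(coarse)
    sse <- sweep(-2 * cross, 2, nodeSq, `+`) # + |rd|^2 omitted (constant/pixel)
    best <- max.col(-sse, ties.method = "first") # first index = lowest muA
    a <- nodeMua[best]; s <- nodeMusp[best]
    cur <- sseAt(a, s)
    lam <- rep(1e-3, m)
    for (it in seq_len(maxit)) {
      Saa <- numeric(m); Sas <- numeric(m); Sss <- numeric(m)
      ba <- numeric(m); bs <- numeric(m)
      for (k in seq_len(nfx)) {
        vg <- valGrad(planes[[k]], a, s)
        r <- vg$v - rdMatChunk[, k]
        Saa <- Saa + vg$ga^2; Sas <- Sas + vg$ga * vg$gs
        Sss <- Sss + vg$gs^2
        ba <- ba - vg$ga * r; bs <- bs - vg$gs * r
      }
      done <- rep(FALSE, m)
      stepA <- numeric(m); stepS <- numeric(m)
      for (tries in 1:8) {
        A11 <- Saa * (1 + lam); A22 <- Sss * (1 + lam)
        det <- A11 * A22 - Sas^2
        det[det <= 0] <- NA_real_  # degenerate normal matrix: no move
        dA <- (A22 * ba - Sas * bs) / det
        dS <- (-Sas * ba + A11 * bs) / det
        dA[is.na(dA)] <- 0; dS[is.na(dS)] <- 0
        # keep updates local to the interpolation neighborhood
        dA <- pmin(pmax(dA, -20 * daCell), 20 * daCell)
        dS <- pmin(pmax(dS, -20 * dsCell), 20 * dsCell)
        ca <- pmin(pmax(a + dA, ax[1]), ax[nA])
        cs <- pmin(pmax(s + dS, ay[1]), ay[nS])
        v <- sseAt(ca, cs)
        acc <- !done & v <= cur
        a[acc] <- ca[acc]; s[acc] <- cs[acc]; cur[acc] <- v[acc]
        stepA[acc] <- abs(dA[acc]); stepS[acc] <- abs(dS[acc])
        lam[acc] <- pmax(lam[acc] / 4, 1e-8)
        done <- done | acc
        lam[!done] <- lam[!done] * 10
        if (all(done)) break
      }
      if (max(stepA) < tol && max(stepS) < tol) break
    }
    outA[idx] <- a; outS[idx] <- s
    outR[idx] <- sqrt(cur / nfx)
  }
  list(muA = outA, muSp = outS, rmse = outR)
}

# a fit is distrusted when its misfit is large or it is pinned to the
# non-physical edges of the table (musp floor/ceiling, mua ceiling)
.outOfRange <- function(muA, muSp, rmse, lut, rmseTol = 0.01) {
  limA <- range(lut@muaAxis); limS <- range(lut@muspAxis)
  gA <- diff(lut@muaAxis)[1]; gS <- diff(lut@muspAxis)[1]
  rmse > rmseTol |
    muSp <= limS[1] + gS / 2 | muSp >= limS[2] - gS / 2 |
    muA >= limA[2] - gA / 2
}

#' Invert a single reflectance vector to optical properties
#'
#' Least-squares fit of the measured diffuse reflectance over all measured
#' spatial frequencies against the lookup table:
#' \eqn{\arg\min_{\mu_a, \mu_s'} \sum_{f_x} [R_d^{meas}(f_x) -
#' R_d^{LUT}(f_x; \mu_a, \mu_s')]^2}, all frequencies equally weighted.  A
#' coarse grid search is refined by deterministic descent on the bilinearly
#' interpolated table until the parameter update falls below \code{tol};
#' there is no random initialization.  Measurements the table cannot attain
#' (misfit beyond \code{rmseTol}, or fits pinned to the table edges) are
#' flagged out-of-range.
#'
#' @param rd measured Rd at each of the LUT's frequencies (same order)
#' @param lut a \code{\link{ReflectanceLUT-class}}
#' @param fxSubset optional integer indices restricting the fit to a subset
#'   of the LUT's frequencies
#' @param tol descent termination step, mm^-1
#' @param rmseTol root-mean-square misfit above which the result is flagged
#' @return list with \code{pair} (an \code{OpticalPropertyPair}),
#'   \code{residual} (RMS misfit), \code{valid}, \code{reason}
#' @export
invertPixel <- function(rd, lut, fxSubset = NULL, tol = 1e-4,
                        rmseTol = 0.01) {
  if (length(rd) != length(lut@fx))
    stop("invertPixel: rd must supply one value per LUT frequency")
  if (any(!is.finite(rd))) stop("invertPixel: rd must be finite")
  use <- if (is.null(fxSubset)) seq_along(lut@fx) else as.integer(fxSubset)
  if (length(use) < 2L) stop("invertPixel: at least 2 frequencies required")
  slut <- if (length(use) == length(lut@fx)) lut else
    new("ReflectanceLUT", muaAxis = lut@muaAxis, muspAxis = lut@muspAxis,
        fx = lut@fx[use], values = lut@values[use, , , drop = FALSE],
        constants = lut@constants)
  res <- .invertCore(matrix(rd[use], nrow = 1), slut, tol = tol)
  oor <- .outOfRange(res$muA, res$muSp, res$rmse, slut, rmseTol)
  list(pair = opticalPropertyPair(res$muA, res$muSp),
       residual = res$rmse,
       valid = !oor,
       reason = if (oor) .REASON_OUT_OF_RANGE else .REASON_OK)
}

#' Invert calibrated reflectance maps to optical property maps
#'
#' Applies the \code{\link{invertPixel}} fit to every pixel of a calibrated
#' reflectance stack, one wavelength at a time, honoring the validity mask:
#' pixels with any invalid frequency channel are marked bad-calibration and
#' not fit.  Results are pixelwise identical to independent
#' \code{invertPixel} calls.
#'
#' @param maps a \code{\link{ReflectanceStack-class}}
#' @param lut a \code{\link{ReflectanceLUT-class}} (frequencies must match)
#' @param fxSubset optional frequency subset (indices into the LUT's fx)
#' @param tol,rmseTol see \code{\link{invertPixel}}
#' @return an \code{\link{OpticalPropertyMap-class}}
#' @export
invertMap <- function(maps, lut, fxSubset = NULL, tol = 1e-4,
                      rmseTol = 0.01) {
  stopifnot(is(maps, "ReflectanceStack"))
  if (!isTRUE(all.equal(maps@fx, lut@fx)))
    stop("invertMap: reflectance stack is missing LUT frequency channels")
  use <- if (is.null(fxSubset)) seq_along(lut@fx) else as.integer(fxSubset)
  slut <- if (length(use) == length(lut@fx)) lut else
    new("ReflectanceLUT", muaAxis = lut@muaAxis, muspAxis = lut@muspAxis,
        fx = lut@fx[use], values = lut@values[use, , , drop = FALSE],
        constants = lut@constants)
  d <- dim(maps@rd)
  nwl <- d[3]
  muA <- array(NA_real_, d[c(1, 2, 3)])
  muSp <- array(NA_real_, d[c(1, 2, 3)])
  resid <- array(NA_real_, d[c(1, 2, 3)])
  valid <- array(FALSE, d[c(1, 2, 3)])
  reason <- array(.REASON_BAD_CALIBRATION, d[c(1, 2, 3)])
  for (iw in seq_len(nwl)) {
    okpix <- apply(maps@valid[, , iw, use, drop = FALSE], c(1, 2), all)
    if (!any(okpix)) next
    rdMat <- matrix(maps@rd[, , iw, use], nrow = d[1] * d[2])[okpix, ,
                                                              drop = FALSE]
    res <- .invertCore(rdMat, slut, tol = tol)
    oor <- .outOfRange(res$muA, res$muSp, res$rmse, slut, rmseTol)
    a <- matrix(NA_real_, d[1], d[2]); s <- a; r <- a
    v <- matrix(FALSE, d[1], d[2]); rc <- matrix(.REASON_BAD_CALIBRATION,
                                                 d[1], d[2])
    a[okpix] <- res$muA; s[okpix] <- res$muSp; r[okpix] <- res$rmse
    v[okpix] <- !oor
    rc[okpix] <- ifelse(oor, .REASON_OUT_OF_RANGE, .REASON_OK)
    muA[, , iw] <- a; muSp[, , iw] <- s; resid[, , iw] <- r
    valid[, , iw] <- v; reason[, , iw] <- rc
  }
  new("OpticalPropertyMap", muA = muA, muSp = muSp, residual = resid,
      valid = valid, reason = reason, wavelengths = maps@wavelengths)
}
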