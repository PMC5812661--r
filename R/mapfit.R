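#' Voxel-wise quantification of parametric maps
#'
#' Nonlinear least-squares T1/T2 mapping (Levenberg-Marquardt), closed-form
#' ADC and MTR maps, background-noise estimation and Rician bias
#' correction.
#'
#' @name mapfit
NULL

.frame3d <- function(series, i) {
  arr <- series@imageData[, , , i, drop = FALSE]
  dim(arr) <- dim(arr)[1:3]
  arr
}

.newParameterMap <- function(parameter, values, units, mask, provenance = list()) {
  vals <- values
  vals[!mask] <- NA_real_
  bad <- mask & !is.finite(vals)
  if (any(bad)) {
    mask[bad] <- FALSE
    vals[bad] <- NA_real_
  }
  new("ParameterMap", parameter = parameter, values = vals, units = units,
      mask = mask, provenance = provenance)
}

#' Estimate the background noise level of a magnitude series
#'
#' In a signal-free background region the magnitude image is Rayleigh
#' distributed with mean \eqn{\sigma \sqrt{\pi/2}}; the Gaussian channel
#' noise sigma is therefore estimated as the mean background magnitude
#' divided by \eqn{\sqrt{\pi/2}}.
#'
#' @param series an [AcquisitionSeries-class]
#' @param backgroundRoi n x 2 polygon vertex matrix (voxel coordinates) of
#'   a region outside the body, by default the upper-left corner rectangle
#'   from [defaultBackgroundRoi()]
#' @param slice slice index on which the polygon is defined
#' @param foregroundMask optional logical mask of the object; overlap of
#'   the background polygon with it triggers a warning (estimation
#'   proceeds)
#' @return estimated sigma (signal units)
#' @export
estimateBackgroundNoise <- function(series, backgroundRoi = NULL, slice = 1L,
                                    foregroundMask = NULL) {
  stopifnot(is(series, "AcquisitionSeries"))
  d <- dim(series@imageData)
  if (is.null(backgroundRoi))
    backgroundRoi <- defaultBackgroundRoi(d[1:2])
  sel <- rasterizePolygon(backgroundRoi, d[1:2])
  if (!any(sel)) stop("background polygon rasterizes to zero voxels")
  if (!is.null(foregroundMask)) {
    fg <- if (length(dim(foregroundMask)) == 3L)
      foregroundMask[, , slice] else foregroundMask
    if (any(sel & fg))
      warning("background polygon overlaps the foreground mask; proceeding")
  }
  vals <- apply(series@imageData[, , slice, , drop = FALSE], 4,
                function(fr) fr[sel])
  mean(vals) / sqrt(pi / 2)
}

#' Correct Rician noise bias by squared subtraction
#'
#' Corrected magnitude \eqn{\sqrt{\max(S^2 - N^2, 0)}}: the background
#' noise level is subtracted in quadrature from the measured magnitude,
#' clamped at zero when the signal falls below the noise level.
#'
#' @param S measured magnitude signal(s), >= 0
#' @param N noise level (signal units), >= 0
#' @return corrected signal(s)
#' @examples
#' correctRicianBias(5, 3)  # 4
#' @export
correctRicianBias <- function(S, N) {
  if (any(S < 0)) stop("S must be non-negative")
  if (any(N < 0)) stop("N must be non-negative")
  sqrt(pmax(S^2 - N^2, 0))
}

.emptyFitArrays <- function(spatial) {
  list(rss = array(NA_real_, spatial),
       iterations = array(NA_real_, spatial),
       converged = array(NA, spatial))
}

#' Fit a T1 map from an inversion-recovery trueFISP series
#'
#' Per-voxel Levenberg-Marquardt fit of the magnitude inversion-recovery
#' model \eqn{|S_0 (1 - INV\, e^{-TI/T_1^*})|} (exported magnitude data
#' lose the sign of the recovery curve), followed by the apparent-time
#' correction [t1FromApparent()]. Starting values are derived from the
#' data: the TI of the minimum magnitude approximates the zero crossing
#' \eqn{T_1^* \ln 2} (with INV start 2), and the last-TI signal starts S0.
#'
#' Voxels are masked when the fit does not converge, `INV <= 1`, or T1
#' falls outside (1, 10000) ms (plausibility gate an order of magnitude
#' beyond liver values, rejecting only fit failures).
#'
#' @param series [AcquisitionSeries-class] with contrast `ir_truefisp`
#' @param mask logical array of voxels to fit (default: all)
#' @param alpha flip angle in degrees (default: from the series metadata)
#' @param maxIterations,tolerance Levenberg-Marquardt control
#' @return a [MapFitResult-class] with maps S0, INV, T1_star, T1
#' @export
fitT1Map <- function(series, mask = NULL, alpha = NULL,
                     maxIterations = 200L, tolerance = 1e-8) {
  stopifnot(is(series, "AcquisitionSeries"))
  if (contrastKind(series) != "ir_truefisp")
    stop("fitT1Map requires an ir_truefisp series")
  ti <- variableValues(series)
  if (length(ti) < 4L)
    stop("at least 4 inversion times are required for a 3-parameter fit")
  if (is.null(alpha)) alpha <- series@meta@flipAngle
  dat <- series@imageData
  spatial <- dim(dat)[1:3]
  if (is.null(mask)) mask <- array(TRUE, spatial)
  if (!any(mask)) stop("mask is empty")

  diag <- .emptyFitArrays(spatial)
  s0 <- inv <- t1s <- array(NA_real_, spatial)
  nTI <- length(ti)
  flat <- matrix(dat, ncol = nTI)
  idx <- which(mask)

  model <- function(p, ti) abs(p[1] * (1 - p[2] * exp(-ti / p[3])))
  resid <- function(p, ti, y) y - model(p, ti)

  for (i in idx) {
    y <- flat[i, ]
    if (all(y == 0) || !all(is.finite(y))) {
      diag$converged[i] <- FALSE
      next
    }
    tiMin <- ti[which.min(y)]
    start <- c(S0 = max(y[nTI], max(y) / 2, 1e-6),
               INV = 2,
               T1star = max(tiMin / log(2), ti[2]))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid, ti = ti, y = y,
                         lower = c(0, 0, 1e-3),
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxIterations, ftol = tolerance,
                           ptol = tolerance)),
      error = function(e) NULL)
    if (is.null(fit)) {
      diag$converged[i] <- FALSE
      next
    }
    p <- fit$par
    diag$rss[i] <- fit$deviance
    diag$iterations[i] <- fit$niter
    conv <- fit$info %in% 1:4
    t1 <- as.numeric(t1FromApparent(p[3], p[2], alpha))
    ok <- conv && p[2] > 1 && is.finite(t1) && t1 > 1 && t1 < 10000
    diag$converged[i] <- ok
    if (ok) {
      s0[i] <- p[1]; inv[i] <- p[2]; t1s[i] <- p[3]
    }
  }
  okMask <- mask & !is.na(diag$converged) & diag$converged
  t1map <- array(NA_real_, spatial)
  t1map[okMask] <- as.numeric(
    t1FromApparent(t1s[okMask], inv[okMask], alpha))
  prov <- list(contrast = "ir_truefisp", alpha = alpha, n_ti = nTI)
  new("MapFitResult",
      maps = list(
        S0 = .newParameterMap("S0", s0, "a.u.", okMask, prov),
        INV = .newParameterMap("INV", inv, "ratio", okMask, prov),
        T1_star = .newParameterMap("T1_star", t1s, "ms", okMask, prov),
        T1 = .newParameterMap("T1", t1map, "ms", okMask, prov)),
      rss = diag$rss, iterations = diag$iterations,
      converged = diag$converged)
}

#' Fit a T2 map from a multi-echo series
#'
#' Per-voxel Levenberg-Marquardt fit of
#' \eqn{S(TE) = S_0 e^{-TE/T_2} + N}. The fit is seeded deterministically
#' by a log-linear regression of the signal after subtracting the minimum
#' sample as the noise-floor start N0, which is already exact for
#' noiseless data with N = 0. Voxels with T2 outside (1, 500) ms or
#' without convergence are masked.
#'
#' @param series [AcquisitionSeries-class] with contrast `multi_echo`
#' @inheritParams fitT1Map
#' @return a [MapFitResult-class] with maps S0, T2, N
#' @export
fitT2Map <- function(series, mask = NULL,
                     maxIterations = 200L, tolerance = 1e-8) {
  stopifnot(is(series, "AcquisitionSeries"))
  if (contrastKind(series) != "multi_echo")
    stop("fitT2Map requires a multi_echo series")
  te <- variableValues(series)
  if (length(te) < 4L)
    stop("at least 4 echo times are required for a 3-parameter fit")
  dat <- series@imageData
  spatial <- dim(dat)[1:3]
  if (is.null(mask)) mask <- array(TRUE, spatial)
  if (!any(mask)) stop("mask is empty")

  diag <- .emptyFitArrays(spatial)
  s0 <- t2 <- nfl <- array(NA_real_, spatial)
  nTE <- length(te)
  flat <- matrix(dat, ncol = nTE)
  idx <- which(mask)

  resid <- function(p, te, y) y - (p[1] * exp(-te / p[2]) + p[3])

  for (i in idx) {
    y <- flat[i, ]
    if (all(y == 0) || !all(is.finite(y))) {
      diag$converged[i] <- FALSE
      next
    }
    n0 <- min(y)
    ys <- y - n0
    pos <- ys > 0
    if (sum(pos) >= 2L) {
      cf <- stats::lsfit(te[pos], log(ys[pos]))$coefficients
      t20 <- if (is.finite(cf[2]) && cf[2] < 0) -1 / cf[2] else diff(range(te))
      s00 <- exp(cf[1])
    } else {
      t20 <- diff(range(te)) / 2
      s00 <- max(y)
    }
    t20 <- min(max(t20, 1), 500)
    start <- c(S0 = max(s00, 1e-6), T2 = t20, N = n0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid, te = te, y = y,
                         lower = c(0, 1e-3, 0),
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxIterations, ftol = tolerance,
                           ptol = tolerance)),
      error = function(e) NULL)
    if (is.null(fit)) {
      diag$converged[i] <- FALSE
      next
    }
    p <- fit$par
    diag$rss[i] <- fit$deviance
    diag$iterations[i] <- fit$niter
    ok <- fit$info %in% 1:4 && p[2] > 1 && p[2] < 500
    diag$converged[i] <- ok
    if (ok) {
      s0[i] <- p[1]; t2[i] <- p[2]; nfl[i] <- p[3]
    }
  }
  okMask <- mask & !is.na(diag$converged) & diag$converged
  prov <- list(contrast = "multi_echo", n_te = nTE)
  new("MapFitResult",
      maps = list(
        S0 = .newParameterMap("S0", s0, "a.u.", okMask, prov),
        T2 = .newParameterMap("T2", t2, "ms", okMask, prov),
        N = .newParameterMap("N", nfl, "a.u.", okMask, prov)),
      rss = diag$rss, iterations = diag$iterations,
      converged = diag$converged)
}

#' Compute an ADC map from a two-point diffusion series
#'
#' \eqn{ADC = \frac{1}{b} \ln(S(b_0)/S(b))} per voxel. Voxels with
#' non-positive signal in either image, or attenuation ratio above 1
#' (negative ADC), are masked. When `noise > 0`, both images are first
#' corrected with [correctRicianBias()] — the diffusion-weighted image is
#' the lowest-SNR acquisition of the protocol, where the Rician floor
#' otherwise biases ADC downward.
#'
#' @param b0Image magnitude image at b = 0 (matrix or 3D array)
#' @param bImage magnitude image at the non-zero b-value
#' @param b diffusion weighting (s/mm^2), > 0
#' @param mask optional logical array
#' @param noise background noise level passed to [correctRicianBias()]
#'   (0 disables the correction)
#' @return a [ParameterMap-class] of ADC in mm^2/s
#' @export
computeAdcMap <- function(b0Image, bImage, b, mask = NULL, noise = 0) {
  if (!identical(dim(b0Image), dim(bImage)))
    stop("b0Image and bImage must have identical shapes")
  if (length(b) != 1L || b <= 0) stop("b must be a positive scalar")
  if (noise > 0) {
    b0Image <- correctRicianBias(b0Image, noise)
    bImage <- correctRicianBias(bImage, noise)
  }
  if (is.null(mask)) mask <- array(TRUE, dim(b0Image))
  ok <- mask & b0Image > 0 & bImage > 0 & bImage <= b0Image
  adc <- array(NA_real_, dim(b0Image))
  adc[ok] <- log(b0Image[ok] / bImage[ok]) / b
  .newParameterMap("ADC", adc, "mm^2/s", ok,
                   list(contrast = "dwi", b = b, noise = noise))
}

#' Compute an MTR map from an MT off/on image pair
#'
#' \eqn{MTR = (M_0 - M_{sat}) / M_0} per voxel, reported in percent.
#' Voxels with non-positive reference signal or MTR outside [-10, 100]
#' percent are masked.
#'
#' @param m0Image magnitude image without MT prepulse
#' @param msatImage magnitude image with MT prepulse
#' @param mask optional logical array
#' @return a [ParameterMap-class] of MTR in percent
#' @export
computeMtrMap <- function(m0Image, msatImage, mask = NULL) {
  if (!identical(dim(m0Image), dim(msatImage)))
    stop("m0Image and msatImage must have identical shapes")
  if (is.null(mask)) mask <- array(TRUE, dim(m0Image))
  ok <- mask & m0Image > 0
  mtr <- array(NA_real_, dim(m0Image))
  mtr[ok] <- 100 * (m0Image[ok] - msatImage[ok]) / m0Image[ok]
  ok <- ok & !is.na(mtr) & mtr >= -10 & mtr <= 100
  mtr[!ok] <- NA_real_
  .newParameterMap("MTR", mtr, "percent", ok, list(contrast = "mt_flash"))
}

#' Fit/compute the parameter maps appropriate for a series
#'
#' Dispatches on the contrast of the series: Levenberg-Marquardt T1 or T2
#' fitting, or the closed-form ADC / MTR maps. For `dwi`, the Rician bias
#' correction is applied with the supplied `noise` level (estimated from a
#' background ROI with [estimateBackgroundNoise()] upstream).
#'
#' @param series an [AcquisitionSeries-class]
#' @param mask optional logical array restricting the fit
#' @param noise background noise level for the DWI bias correction
#' @param ... passed to the contrast-specific fitter
#' @return a [MapFitResult-class] (T1/T2) or [ParameterMap-class] (ADC/MTR)
#' @export
fitParameterMaps <- function(series, mask = NULL, noise = 0, ...) {
  switch(contrastKind(series),
    ir_truefisp = fitT1Map(series, mask = mask, ...),
    multi_echo = fitT2Map(series, mask = mask, ...),
    dwi = {
      v <- variableValues(series)
      computeAdcMap(.frame3d(series, which(v == 0)),
                    .frame3d(series, which(v > 0)),
                    b = v[v > 0], mask = mask, noise = noise)
    },
    mt_flash = {
      v <- variableValues(series)
      computeMtrMap(.frame3d(series, which(v == 0)),
                    .frame3d(series, which(v == 1)),
                    mask = mask)
    },
    stop("unsupported contrast: ", contrastKind(series))
  )
}
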