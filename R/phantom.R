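#' Digital liver phantom
#'
#' Simple, fully parameterized liver geometry: an ellipse (2D) or
#' ellipsoid (3D) of parenchyma with embedded vessel tubes, carrying one
#' complete set of relaxation/diffusion/MT parameters per tissue. The
#' geometry is deliberately schematic — no registration is ever performed
#' on it; its job is to exercise every quantification stage with known
#' ground truth (including the vessel-avoidance rule of the ROI placer).
#'
#' @name phantom
NULL

#' Default tissue parameters
#'
#' Liver parenchyma defaults correspond to healthy baseline values of
#' C57BL/6 mouse liver at 4.7 T (T1 ~ 1000 ms, T2 ~ 30 ms,
#' ADC ~ 1.5e-3 mm^2/s, MTR ~ 66 percent); the vessel tissue mimics slowly
#' flowing blood (long T1/T2, high ADC, low MTR) so that vessel voxels are
#' clearly distinct from parenchyma in every contrast.
#'
#' @param T1,T2 relaxation times (ms)
#' @param ADC apparent diffusion coefficient (mm^2/s)
#' @param MTR magnetization transfer ratio (fraction in [0, 1))
#' @param S0,M0 equilibrium signal amplitudes (a.u.)
#' @param INV inversion ratio of the IR-trueFISP preparation (> 1)
#' @param N noise floor of the multi-echo model (a.u.)
#' @return named list of tissue parameters
#' @export
tissueTruth <- function(T1 = 997, T2 = 29.9, ADC = 1.54e-3, MTR = 0.685,
                        S0 = 1000, M0 = 1000, INV = 1.95, N = 0) {
  stopifnot(T1 > 0, T2 > 0, ADC >= 0, MTR >= 0, MTR < 1,
            S0 >= 0, M0 >= 0, INV > 1, N >= 0)
  list(S0 = S0, INV = INV, T1 = T1, T2 = T2, N = N,
       ADC = ADC, MTR = MTR, M0 = M0)
}

#' @rdname tissueTruth
#' @export
vesselTruth <- function() {
  tissueTruth(T1 = 1900, T2 = 150, ADC = 3.0e-3, MTR = 0.10,
              S0 = 1200, M0 = 1200)
}

#' Build a digital liver phantom
#'
#' Places an ellipse/ellipsoid of liver tissue at the grid centre and
#' carves vessel tubes (through-plane cylinders) into it at seeded
#' positions. If `targetVolume` is given, the liver is voxelized by
#' ranking voxels by their ellipsoidal norm and keeping exactly
#' `round(targetVolume / voxelVolume)` of them, so the voxel-counted
#' volume matches the requested volume to within one voxel volume.
#'
#' @param dim grid size: length 2 (single slice) or 3
#' @param voxelSize in-plane voxel size in mm (length 2)
#' @param sliceThickness slice thickness in mm
#' @param liverAxes semi-axes of the liver in voxels (length = length(dim));
#'   default 0.36 of the grid
#' @param targetVolume optional liver volume in mm^3 overriding `liverAxes`
#'   scaling (shape ratios are kept)
#' @param nVessels number of vessel tubes
#' @param vesselRadius vessel radius in voxels
#' @param parenchyma,vessel tissue parameter lists ([tissueTruth()])
#' @param sigma default Rician noise level attached to the phantom
#' @param seed integer seed for vessel placement (deterministic geometry)
#' @return a [LiverPhantom-class]
#' @examples
#' ph <- buildPhantom(dim = c(28, 28), seed = 7)
#' sum(liverMask(ph))
#' @export
buildPhantom <- function(dim = c(28, 28), voxelSize = c(0.234, 0.234),
                         sliceThickness = 1.5, liverAxes = NULL,
                         targetVolume = NULL, nVessels = 2L,
                         vesselRadius = 1.3,
                         parenchyma = tissueTruth(), vessel = vesselTruth(),
                         sigma = 0, seed = 1L) {
  is3d <- length(dim) == 3L
  if (!is3d && length(dim) != 2L) stop("dim must have length 2 or 3")
  if (is.null(liverAxes)) liverAxes <- dim * 0.36
  if (any(liverAxes <= 0)) stop("degenerate geometry: liver volume is 0")
  full <- if (is3d) dim else c(dim, 1L)
  ctr <- (full[1:length(dim)] + 1) / 2
  voxVol <- prod(voxelSize) * sliceThickness

  ix <- seq_len(full[1]); iy <- seq_len(full[2]); iz <- seq_len(full[3])
  gx <- array(rep(ix, times = full[2] * full[3]), full)
  gy <- array(rep(rep(iy, each = full[1]), times = full[3]), full)
  gz <- array(rep(iz, each = full[1] * full[2]), full)

  nrm2 <- ((gx - ctr[1]) / liverAxes[1])^2 + ((gy - ctr[2]) / liverAxes[2])^2
  if (is3d) nrm2 <- nrm2 + ((gz - (full[3] + 1) / 2) / liverAxes[3])^2

  if (!is.null(targetVolume)) {
    if (targetVolume <= 0) stop("degenerate geometry: liver volume is 0")
    nWant <- max(1L, round(targetVolume / voxVol))
    if (nWant > length(nrm2))
      stop("targetVolume exceeds the grid capacity")
    thr <- sort(as.vector(nrm2), partial = nWant)[nWant]
    liver <- nrm2 <= thr
    # resolve ties at the threshold deterministically by index order
    if (sum(liver) > nWant) {
      extra <- which(liver & nrm2 == thr)
      liver[extra[seq_len(sum(liver) - nWant)]] <- FALSE
    }
  } else {
    liver <- nrm2 <= 1
  }
  if (!any(liver)) stop("degenerate geometry: liver volume is 0")

  labels <- array(0L, full)
  labels[liver] <- 1L

  if (nVessels > 0L) {
    centers <- .withSeed(seed, {
      matrix(c(stats::runif(nVessels, -0.45, 0.45) * liverAxes[1] + ctr[1],
               stats::runif(nVessels, -0.45, 0.45) * liverAxes[2] + ctr[2]),
             ncol = 2)
    })
    for (v in seq_len(nVessels)) {
      tube <- (gx - centers[v, 1])^2 + (gy - centers[v, 2])^2 <=
        vesselRadius^2
      labels[tube & labels == 1L] <- 2L
    }
  }

  new("LiverPhantom", labels = labels,
      truth = list(parenchyma = parenchyma, vessel = vessel),
      voxelSize = voxelSize, sliceThickness = sliceThickness,
      sigma = sigma, seed = as.integer(seed))
}

#' Ground-truth parameter map of a phantom
#'
#' @param phantom a [LiverPhantom-class]
#' @param parameter one of `"T1"`, `"T2"`, `"ADC"`, `"MTR"`, `"S0"`,
#'   `"INV"`, `"N"`, `"M0"`
#' @return a [ParameterMap-class] with values on liver voxels (MTR in
#'   percent, matching the fitted maps)
#' @export
groundTruthMap <- function(phantom, parameter) {
  stopifnot(is(phantom, "LiverPhantom"))
  units <- switch(parameter, T1 = , T2 = "ms", ADC = "mm^2/s",
                  MTR = "percent", INV = "ratio", "a.u.")
  lut <- c(NA_real_,
           phantom@truth$parenchyma[[parameter]],
           phantom@truth$vessel[[parameter]])
  if (parameter == "MTR") lut <- lut * 100
  vals <- array(lut[phantom@labels + 1L], dim(phantom@labels))
  .newParameterMap(parameter, vals, units, phantom@labels > 0L,
                   list(source = "phantom ground truth"))
}

#' Simulate a magnitude acquisition series from a phantom
#'
#' Applies the forward signal model matching the contrast of `meta` to
#' every voxel (background voxels emit no signal), then applies Rician
#' magnitude noise at the effective level `sigma / sqrt(averages)` —
#' signal averages are combined before magnitude reconstruction, so
#' averaging reduces the channel noise by sqrt(averages).
#'
#' @param phantom a [LiverPhantom-class]
#' @param meta a [SequenceMeta-class]; defaults from [protocolMeta()]
#' @param sigma Rician channel noise per single average (default: the
#'   phantom's `sigma`)
#' @param seed integer seed for the noise draw
#' @return an [AcquisitionSeries-class]
#' @export
simulateAcquisitions <- function(phantom, meta, sigma = NULL, seed = 1L) {
  stopifnot(is(phantom, "LiverPhantom"), is(meta, "SequenceMeta"))
  if (is.null(sigma)) sigma <- phantom@sigma
  labels <- phantom@labels
  full <- dim(labels)
  v <- meta@variableValues
  nFrames <- length(v)

  par <- function(name) {
    lut <- c(0, phantom@truth$parenchyma[[name]],
             phantom@truth$vessel[[name]])
    if (any(is.na(lut[unique(labels) + 1L])))
      stop("phantom truth lacks parameter '", name,
           "' required by contrast ", meta@contrast)
    array(lut[labels + 1L], full)
  }

  ideal <- array(0, c(full, nFrames))
  kind <- meta@contrast
  if (kind == "ir_truefisp") {
    T1 <- par("T1"); INV <- par("INV"); S0 <- par("S0")
    t1s <- array(0, full)
    inside <- labels > 0L
    t1s[inside] <- t1StarFromT1(T1[inside], INV[inside], meta@flipAngle)
    for (f in seq_len(nFrames)) {
      fr <- array(0, full)
      fr[inside] <- irTruefispSignal(S0[inside], INV[inside],
                                     t1s[inside], v[f])
      ideal[, , , f] <- fr
    }
  } else if (kind == "multi_echo") {
    T2 <- par("T2"); S0 <- par("S0"); N <- par("N")
    inside <- labels > 0L
    for (f in seq_len(nFrames)) {
      fr <- array(0, full)
      fr[inside] <- multiEchoSignal(S0[inside], T2[inside], N[inside], v[f])
      ideal[, , , f] <- fr
    }
  } else if (kind == "dwi") {
    ADC <- par("ADC"); S0 <- par("S0")
    inside <- labels > 0L
    for (f in seq_len(nFrames)) {
      fr <- array(0, full)
      fr[inside] <- dwiSignal(S0[inside], ADC[inside], v[f])
      ideal[, , , f] <- fr
    }
  } else if (kind == "mt_flash") {
    MTR <- par("MTR"); M0 <- par("M0")
    inside <- labels > 0L
    for (f in seq_len(nFrames)) {
      fr <- array(0, full)
      pair <- mtSignalPair(M0[inside], MTR[inside])
      fr[inside] <- if (v[f] == 0) pair$off else pair$on
      ideal[, , , f] <- fr
    }
  } else stop("unsupported contrast: ", kind)

  sigmaEff <- sigma / sqrt(meta@averages)
  noisy <- addRicianNoise(ideal, sigmaEff, seed = seed)
  dim(noisy) <- c(full, nFrames)
  new("AcquisitionSeries", imageData = noisy, meta = meta)
}
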