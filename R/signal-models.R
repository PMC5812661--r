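#' Forward signal models for the four quantitative contrasts
#'
#' These closed-form signal equations are shared by the phantom simulator
#' and the voxel-wise fitters, so that simulation and quantification are
#' exact inverses in the noiseless case.
#'
#' @name signal-models
NULL

#' Inversion-recovery trueFISP signal
#'
#' Ideal (signed) signal of a segmented inversion-recovery trueFISP
#' readout, \eqn{S(TI) = S_0 (1 - INV \, e^{-TI/T_1^*})}, where `INV` is
#' the ratio between the initial (inverted) and steady-state signal and
#' `T1star` the apparent relaxation time of the driven recovery. The value
#' is negative for TI below the zero crossing \eqn{T_1^* \ln(INV)};
#' magnitude is applied only at the noise stage.
#'
#' @param S0 steady-state signal (arbitrary units), >= 0
#' @param INV inversion ratio (dimensionless, > 1 for inverting preparations)
#' @param T1star apparent relaxation time (ms), > 0
#' @param TI inversion time(s) (ms), >= 0
#' @return numeric vector of ideal signals
#' @examples
#' irTruefispSignal(1000, 2, 500, c(0, 500 * log(2), 1e7))
#' @export
irTruefispSignal <- function(S0, INV, T1star, TI) {
  if (any(T1star <= 0)) stop("T1star must be positive")
  if (any(TI < 0)) stop("TI must be non-negative")
  S0 * (1 - INV * exp(-TI / T1star))
}

#' Convert apparent T1* to T1
#'
#' Corrects the apparent relaxation time of the inversion-recovery
#' trueFISP experiment to the longitudinal relaxation time via
#' \eqn{T_1 = T_1^* \cos(\alpha/2) (INV - 1)} (effective-flip-angle
#' convention of balanced steady-state readouts).
#'
#' Voxels with `INV <= 1` are physically degenerate; in batch use they are
#' masked, so this function returns the algebraic value with a `valid`
#' attribute instead of raising.
#'
#' @param T1star apparent relaxation time (ms), > 0
#' @param INV inversion ratio
#' @param alpha flip angle in degrees
#' @return T1 in ms, with attribute `valid` (logical, `INV > 1`)
#' @examples
#' t1FromApparent(800, 2, 0)      # 800
#' t1FromApparent(800, 2.438, 60) # ~996.1
#' @export
t1FromApparent <- function(T1star, INV, alpha) {
  if (any(T1star <= 0)) stop("T1star must be positive")
  t1 <- T1star * cos(alpha * pi / 360) * (INV - 1)
  structure(t1, valid = INV > 1)
}

#' Invert the T1* correction (simulation helper)
#'
#' Given a target T1, inversion ratio and flip angle, returns the apparent
#' T1* that [t1FromApparent()] maps back to T1.
#'
#' @inheritParams t1FromApparent
#' @param T1 longitudinal relaxation time (ms)
#' @return T1* in ms
#' @export
t1StarFromT1 <- function(T1, INV, alpha) {
  if (any(INV <= 1)) stop("INV must exceed 1 to invert the correction")
  T1 / (cos(alpha * pi / 360) * (INV - 1))
}

#' Multi-echo spin-echo signal with noise floor
#'
#' \eqn{S(TE) = S_0 e^{-TE/T_2} + N}, the mono-exponential echo decay with
#' an additive noise-floor term `N`.
#'
#' @param S0 signal at TE = 0 above the floor, >= 0
#' @param T2 transverse relaxation time (ms), > 0
#' @param N noise floor (signal units), >= 0
#' @param TE echo time(s) (ms), >= 0
#' @return numeric vector of signals
#' @export
multiEchoSignal <- function(S0, T2, N, TE) {
  if (any(T2 <= 0)) stop("T2 must be positive")
  if (any(N < 0)) stop("N must be non-negative")
  if (any(TE < 0)) stop("TE must be non-negative")
  S0 * exp(-TE / T2) + N
}

#' Diffusion-weighted signal
#'
#' \eqn{S(b) = S_0 e^{-b \cdot ADC}} — mono-exponential attenuation between
#' the unweighted and the diffusion-weighted acquisition.
#'
#' @param S0 signal at b = 0
#' @param adc apparent diffusion coefficient (mm^2/s), >= 0
#' @param b diffusion weighting (s/mm^2), >= 0
#' @return numeric vector of signals
#' @export
dwiSignal <- function(S0, adc, b) {
  if (any(adc < 0)) stop("adc must be non-negative")
  if (any(b < 0)) stop("b must be non-negative")
  S0 * exp(-b * adc)
}

#' Magnetization-transfer signal pair
#'
#' Forward model of the MTR experiment: the reference scan without MT
#' prepulse gives `M0`, the saturated scan gives `M0 * (1 - mtr)`.
#' [mtrFromPair()] applied to the pair returns `mtr` exactly.
#'
#' @param M0 signal without MT prepulse, >= 0
#' @param mtr magnetization transfer ratio as a fraction in [0, 1)
#' @return list with elements `off` and `on`
#' @export
mtSignalPair <- function(M0, mtr) {
  if (any(M0 < 0)) stop("M0 must be non-negative")
  if (any(mtr < 0 | mtr >= 1)) stop("mtr must lie in [0, 1)")
  list(off = M0, on = M0 * (1 - mtr))
}

#' Magnetization transfer ratio from an off/on signal pair
#'
#' \eqn{MTR = (M_0 - M_{sat}) / M_0}, returned as a fraction.
#'
#' @param off signal without MT prepulse
#' @param on signal with MT prepulse
#' @return MTR fraction
#' @export
mtrFromPair <- function(off, on) {
  (off - on) / off
}

#' Add Rician noise to ideal signals
#'
#' Magnitude-image noise: the ideal signal is placed on the real channel,
#' independent zero-mean Gaussian noise of standard deviation `sigma` is
#' added to the real and imaginary channels, and the magnitude is taken.
#' With `sigma = 0` the output is `abs(signal)`. Deterministic given
#' `seed`; the caller's RNG state is left untouched when a seed is given.
#'
#' @param signal numeric array/vector of ideal (possibly signed) signals
#' @param sigma Gaussian channel noise SD (signal units), >= 0
#' @param seed optional integer seed
#' @return array of magnitude signals, same shape as `signal`
#' @export
addRicianNoise <- function(signal, sigma, seed = NULL) {
  if (length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("sigma must be a single non-negative number")
  if (sigma == 0) {
    out <- abs(signal)
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit({
        if (is.null(old)) {
          if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
      })
      set.seed(as.integer(seed))
    }
    n <- length(signal)
    re <- signal + stats::rnorm(n, 0, sigma)
    im <- stats::rnorm(n, 0, sigma)
    out <- sqrt(re * re + im * im)
  }
  if (!is.null(dim(signal))) dim(out) <- dim(signal)
  out
}

#' Protocol metadata for the four default acquisitions
#'
#' Returns the [SequenceMeta-class] of the small-animal 4.7 T liver
#' protocol emulated by the simulator: a segmented IR-trueFISP T1 series
#' (60 inversion times, TI_i = 90 + (i-1) * 144 ms, flip angle 60 deg,
#' 4 averages), a five-echo RARE T2 series (TE = 11..99 ms in 22 ms steps,
#' longest TR 4000 ms, 2 averages), a two-point diffusion series
#' (b = 0 and 800 s/mm^2, 8 averages) and an MT-FLASH off/on pair
#' (flip angle 12 deg, 8 averages). In-plane voxels are
#' 0.234 x 0.234 mm with 1.5 mm slices.
#'
#' @param contrast one of `"ir_truefisp"`, `"multi_echo"`, `"dwi"`,
#'   `"mt_flash"`
#' @return a [SequenceMeta-class] object
#' @examples
#' protocolMeta("ir_truefisp")
#' @export
protocolMeta <- function(contrast = c("ir_truefisp", "multi_echo",
                                      "dwi", "mt_flash")) {
  contrast <- match.arg(contrast)
  vox <- c(0.234, 0.234)
  thk <- 1.5
  switch(contrast,
    ir_truefisp = new("SequenceMeta", contrast = "ir_truefisp",
      flipAngle = 60, tr = 4.5, variableName = "TI",
      variableValues = 90 + (0:59) * 144, averages = 4,
      voxelSize = vox, sliceThickness = thk),
    multi_echo = new("SequenceMeta", contrast = "multi_echo",
      flipAngle = 90, tr = 4000, variableName = "TE",
      variableValues = c(11, 33, 55, 77, 99), averages = 2,
      voxelSize = vox, sliceThickness = thk),
    dwi = new("SequenceMeta", contrast = "dwi",
      flipAngle = 90, tr = 3000, variableName = "b",
      variableValues = c(0, 800), averages = 8,
      voxelSize = vox, sliceThickness = thk),
    mt_flash = new("SequenceMeta", contrast = "mt_flash",
      flipAngle = 12, tr = 18.4, variableName = "mt",
      variableValues = c(0, 1), averages = 8,
      voxelSize = vox, sliceThickness = thk)
  )
}
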