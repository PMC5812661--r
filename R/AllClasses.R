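#' @import methods
NULL

.CONTRASTS <- c("ir_truefisp", "multi_echo", "dwi", "mt_flash")

#' SequenceMeta: acquisition metadata for one MR series
#'
#' Describes a stack of magnitude images acquired while one acquisition
#' variable changes: inversion time (TI) for inversion-recovery trueFISP T1
#' mapping, echo time (TE) for multi-echo T2 mapping, b-value for
#' diffusion weighting, or the MT-prepulse state (off/on) for magnetization
#' transfer imaging.
#'
#' @slot contrast one of `"ir_truefisp"`, `"multi_echo"`, `"dwi"`, `"mt_flash"`
#' @slot flipAngle excitation flip angle in degrees, in (0, 180)
#' @slot tr repetition time in ms
#' @slot variableName name of the varying quantity (`"TI"`, `"TE"`, `"b"`,
#'   `"mt"`); for `"mt"` the values are 0 (prepulse off) and 1 (on)
#' @slot variableValues numeric values of the varying quantity (ms for
#'   TI/TE, s/mm^2 for b)
#' @slot averages number of signal averages; noise is simulated at
#'   sigma/sqrt(averages), i.e. complex averaging before magnitude
#' @slot voxelSize in-plane voxel size in mm (length 2)
#' @slot sliceThickness slice thickness in mm
#' @export
setClass("SequenceMeta",
  representation(
    contrast = "character",
    flipAngle = "numeric",
    tr = "numeric",
    variableName = "character",
    variableValues = "numeric",
    averages = "numeric",
    voxelSize = "numeric",
    sliceThickness = "numeric"
  )
)

setValidity("SequenceMeta", function(object) {
  msg <- character()
  if (length(object@contrast) != 1L || !object@contrast %in% .CONTRASTS)
    msg <- c(msg, sprintf("contrast must be one of %s",
                          paste(.CONTRASTS, collapse = ", ")))
  if (length(object@flipAngle) != 1L || object@flipAngle <= 0 ||
      object@flipAngle >= 180)
    msg <- c(msg, "flipAngle must lie in (0, 180) degrees")
  if (length(object@tr) != 1L || object@tr <= 0)
    msg <- c(msg, "tr must be a positive scalar (ms)")
  v <- object@variableValues
  if (length(object@contrast) == 1L && object@contrast %in% .CONTRASTS) {
    if (object@contrast %in% c("ir_truefisp", "multi_echo")) {
      if (length(v) < 2L || any(v <= 0) || any(diff(v) <= 0))
        msg <- c(msg, "TI/TE values must be positive and strictly increasing")
    } else if (object@contrast == "dwi") {
      if (length(v) != 2L || sum(v == 0) != 1L || sum(v > 0) != 1L)
        msg <- c(msg, "dwi requires exactly one b = 0 and one b > 0")
    } else if (object@contrast == "mt_flash") {
      if (!identical(sort(v), c(0, 1)))
        msg <- c(msg, "mt_flash requires exactly the two states off (0) and on (1)")
    }
  }
  if (length(object@averages) != 1L || object@averages < 1)
    msg <- c(msg, "averages must be >= 1")
  if (length(object@voxelSize) != 2L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be two positive lengths (mm)")
  if (length(object@sliceThickness) != 1L || object@sliceThickness <= 0)
    msg <- c(msg, "sliceThickness must be positive (mm)")
  if (length(msg)) msg else TRUE
})

#' AcquisitionSeries: a stack of magnitude images over one acquisition variable
#'
#' The image data are stored as a 4D array (x, y, z, frame) whose last
#' dimension matches `variableValues(meta)`; 2D acquisitions use a singleton
#' z dimension.
#'
#' @slot imageData 4D numeric array (x, y, z, frame)
#' @slot meta a [SequenceMeta-class] object
#' @export
setClass("AcquisitionSeries",
  representation(imageData = "array", meta = "SequenceMeta")
)

setValidity("AcquisitionSeries", function(object) {
  d <- dim(object@imageData)
  if (length(d) != 4L)
    return("imageData must be a 4D array (x, y, z, frame)")
  if (d[4L] != length(object@meta@variableValues))
    return("number of frames must equal length(variableValues(meta))")
  TRUE
})

#' ParameterMap: a per-voxel quantitative parameter map
#'
#' Holds one fitted or computed parameter (T1, T2, ADC, MTR or a fit
#' by-product) on the spatial grid of its source series, together with a
#' validity mask. Voxels outside the mask carry `NA` as an explicit
#' sentinel; unmasked voxels are guaranteed finite.
#'
#' @slot parameter one of T1, T2, ADC, MTR, S0, INV, T1_star, N
#' @slot values numeric array (2D or 3D); `NA` where masked out
#' @slot units unit string (ms, mm^2/s, percent, a.u.)
#' @slot mask logical array, same shape as `values`
#' @slot provenance list: source series contrast, fit settings
#' @export
setClass("ParameterMap",
  representation(
    parameter = "character",
    values = "array",
    units = "character",
    mask = "array",
    provenance = "list"
  ),
  prototype(provenance = list())
)

setValidity("ParameterMap", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@mask)))
    msg <- c(msg, "values and mask must have identical dimensions")
  if (length(object@units) != 1L || !nzchar(object@units))
    msg <- c(msg, "units must always be set")
  if (any(is.na(object@values[object@mask])))
    msg <- c(msg, "unmasked voxels must carry finite values (no NA/NaN leaks)")
  if (any(!is.na(object@values[!object@mask])))
    msg <- c(msg, "masked-out voxels must carry the NA sentinel")
  if (length(msg)) msg else TRUE
})

#' MapFitResult: parameter maps plus per-voxel fit diagnostics
#'
#' @slot maps named list of [ParameterMap-class] objects
#' @slot rss per-voxel residual sum of squares (NA outside the fit mask)
#' @slot iterations per-voxel iteration counts
#' @slot converged per-voxel convergence flags; a non-converged voxel is
#'   masked in every map in `maps`
#' @export
setClass("MapFitResult",
  representation(
    maps = "list",
    rss = "array",
    iterations = "array",
    converged = "array"
  )
)

#' LiverPhantom: digital liver slice/volume with known tissue parameters
#'
#' A label image (0 = background, 1 = liver parenchyma, 2 = intrahepatic
#' vessel) plus one complete set of tissue parameters per non-background
#' label, used to simulate acquisitions and to score parameter recovery.
#'
#' @slot labels integer array (2D or 3D)
#' @slot truth named list (`parenchyma`, `vessel`) of tissue parameter
#'   lists with elements S0, INV, T1, T2, N, ADC, MTR, M0
#' @slot voxelSize in-plane voxel size (mm, length 2)
#' @slot sliceThickness slice thickness (mm)
#' @slot sigma default Rician noise level (signal units)
#' @slot seed integer seed the geometry was generated from
#' @export
setClass("LiverPhantom",
  representation(
    labels = "array",
    truth = "list",
    voxelSize = "numeric",
    sliceThickness = "numeric",
    sigma = "numeric",
    seed = "integer"
  )
)

setValidity("LiverPhantom", function(object) {
  msg <- character()
  if (!all(object@labels %in% 0:2))
    msg <- c(msg, "labels must partition the grid into 0/1/2")
  if (sum(object@labels > 0L) == 0L)
    msg <- c(msg, "degenerate geometry: liver volume is zero")
  needed <- c("S0", "INV", "T1", "T2", "N", "ADC", "MTR", "M0")
  for (tis in intersect(c("parenchyma", "vessel"), names(object@truth))) {
    miss <- setdiff(needed, names(object@truth[[tis]]))
    if (length(miss))
      msg <- c(msg, sprintf("truth for '%s' lacks: %s", tis,
                            paste(miss, collapse = ", ")))
  }
  if (length(object@sigma) != 1L || object@sigma < 0)
    msg <- c(msg, "sigma must be a non-negative scalar")
  if (length(msg)) msg else TRUE
})

#' ROISet: named parenchymal polygons plus one background polygon
#'
#' Polygons are vertex matrices (n x 2, columns x = column index, y = row
#' index, voxel-centre coordinates) on one slice. The parenchymal ROIs are
#' meant to lie inside the liver avoiding large vessels; the background
#' polygon lies outside the body and feeds noise estimation.
#'
#' @slot rois named list of vertex matrices (parenchymal ROIs)
#' @slot background vertex matrix of the background-noise polygon
#' @slot slice slice index the polygons live on
#' @slot source identifier of the map/series the ROIs were defined on
#' @export
setClass("ROISet",
  representation(
    rois = "list",
    background = "matrix",
    slice = "integer",
    source = "character"
  ),
  prototype(slice = 1L, source = "")
)

setValidity("ROISet", function(object) {
  msg <- character()
  ok <- function(p) is.matrix(p) && ncol(p) == 2L && nrow(p) >= 3L
  if (!all(vapply(object@rois, ok, logical(1))))
    msg <- c(msg, "each ROI must be an n x 2 vertex matrix with n >= 3")
  if (!ok(object@background))
    msg <- c(msg, "background must be an n x 2 vertex matrix with n >= 3")
  if (length(msg)) msg else TRUE
})
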