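#' NIfTI series and map IO with JSON sidecars
#'
#' NIfTI is the canonical image format of the pipeline. Acquisition
#' metadata and units, which NIfTI headers cannot carry, travel in a JSON
#' sidecar next to each image (keys: contrast, flip_angle_deg, tr_ms,
#' variable_name, variable_values, averages, voxel_size_mm,
#' slice_thickness_mm).
#'
#' @name io-nifti
NULL

.sidecarPath <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write an acquisition series to NIfTI + JSON sidecar
#'
#' @param series an [AcquisitionSeries-class]
#' @param path output path ending in `.nii` or `.nii.gz`
#' @return `path`, invisibly
#' @export
writeAcquisitionSeries <- function(series, path) {
  stopifnot(is(series, "AcquisitionSeries"))
  m <- series@meta
  pix <- c(m@voxelSize, m@sliceThickness)
  img <- RNifti::asNifti(series@imageData, pixdim = pix)
  RNifti::writeNifti(img, path)
  side <- list(contrast = m@contrast, flip_angle_deg = m@flipAngle,
               tr_ms = m@tr, variable_name = m@variableName,
               variable_values = m@variableValues, averages = m@averages,
               voxel_size_mm = m@voxelSize,
               slice_thickness_mm = m@sliceThickness)
  jsonlite::write_json(side, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an acquisition series from NIfTI + JSON sidecar
#'
#' @param path path to the `.nii`/`.nii.gz` image (sidecar found by
#'   extension swap)
#' @return an [AcquisitionSeries-class]
#' @export
readAcquisitionSeries <- function(path) {
  side <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  dat <- array(as.numeric(RNifti::readNifti(path)),
               dim(RNifti::readNifti(path)))
  if (length(dim(dat)) == 3L) dim(dat) <- c(dim(dat)[1:2], 1L, dim(dat)[3])
  meta <- new("SequenceMeta", contrast = side$contrast,
              flipAngle = side$flip_angle_deg, tr = side$tr_ms,
              variableName = side$variable_name,
              variableValues = as.numeric(side$variable_values),
              averages = side$averages,
              voxelSize = as.numeric(side$voxel_size_mm),
              sliceThickness = side$slice_thickness_mm)
  new("AcquisitionSeries", imageData = dat, meta = meta)
}

#' Write a parameter map to NIfTI + JSON sidecar
#'
#' Masked voxels are written as NaN (the NIfTI sentinel for invalid
#' voxels); the mask itself travels in the sidecar-adjacent `_mask` image.
#'
#' @param map a [ParameterMap-class]
#' @param path output path ending in `.nii` or `.nii.gz`
#' @param voxelSize,sliceThickness geometry recorded in the header (mm)
#' @return `path`, invisibly
#' @export
writeParameterMap <- function(map, path, voxelSize = c(1, 1),
                              sliceThickness = 1) {
  stopifnot(is(map, "ParameterMap"))
  vals <- map@values
  vals[!map@mask] <- NaN
  img <- RNifti::asNifti(vals, pixdim = c(voxelSize, sliceThickness))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(parameter = map@parameter, units = map@units,
         provenance = map@provenance),
    .sidecarPath(path), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a parameter map written by [writeParameterMap()]
#'
#' @param path path to the `.nii`/`.nii.gz` map
#' @return a [ParameterMap-class]
#' @export
readParameterMap <- function(path) {
  side <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img))
  mask <- is.finite(vals)
  vals[!mask] <- NA_real_
  .newParameterMap(side$parameter, vals, side$units, mask,
                   as.list(side$provenance))
}

#' Write an ROI set as JSON
#'
#' @param rois an [ROISet-class]
#' @param path output `.json` path
#' @return `path`, invisibly
#' @export
writeRoiSet <- function(rois, path) {
  stopifnot(is(rois, "ROISet"))
  jsonlite::write_json(
    list(slice = rois@slice, source = rois@source,
         rois = lapply(rois@rois, function(p)
           list(x = p[, 1], y = p[, 2])),
         background = list(x = rois@background[, 1],
                           y = rois@background[, 2])),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an ROI set written by [writeRoiSet()]
#'
#' @param path `.json` path
#' @return an [ROISet-class]
#' @export
readRoiSet <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ROISet",
      rois = lapply(j$rois, function(p) cbind(x = p$x, y = p$y)),
      background = cbind(x = j$background$x, y = j$background$y),
      slice = as.integer(j$slice), source = j$source)
}
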