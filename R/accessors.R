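#' @describeIn SequenceMeta-class contrast kind of the series
#' @export
setMethod("contrastKind", "SequenceMeta", function(object) object@contrast)

#' @describeIn SequenceMeta-class values of the varying acquisition variable
#' @export
setMethod("variableValues", "SequenceMeta", function(object) object@variableValues)

#' @describeIn AcquisitionSeries-class contrast kind of the series
#' @export
setMethod("contrastKind", "AcquisitionSeries",
          function(object) object@meta@contrast)

#' @describeIn AcquisitionSeries-class the 4D image array
#' @export
setMethod("imageData", "AcquisitionSeries", function(object) object@imageData)

#' @describeIn AcquisitionSeries-class acquisition metadata
#' @export
setMethod("seriesMeta", "AcquisitionSeries", function(object) object@meta)

#' @describeIn AcquisitionSeries-class variable values of the series
#' @export
setMethod("variableValues", "AcquisitionSeries",
          function(object) object@meta@variableValues)

#' @describeIn ParameterMap-class numeric value grid (NA where masked)
#' @export
setMethod("mapValues", "ParameterMap", function(object) object@values)

#' @describeIn ParameterMap-class logical validity mask
#' @export
setMethod("mapMask", "ParameterMap", function(object) object@mask)

#' @describeIn ParameterMap-class unit string
#' @export
setMethod("mapUnits", "ParameterMap", function(object) object@units)

#' @describeIn ParameterMap-class parameter name
#' @export
setMethod("mapParameter", "ParameterMap", function(object) object@parameter)

#' @describeIn MapFitResult-class named list of ParameterMap objects
#' @export
setMethod("parameterMaps", "MapFitResult", function(object) object@maps)

#' @describeIn MapFitResult-class per-voxel diagnostics (rss, iterations,
#'   converged)
#' @export
setMethod("fitDiagnostics", "MapFitResult", function(object)
  list(rss = object@rss, iterations = object@iterations,
       converged = object@converged))

#' @describeIn LiverPhantom-class integer label array
#' @export
setMethod("phantomLabels", "LiverPhantom", function(object) object@labels)

#' @describeIn LiverPhantom-class per-tissue parameter truth
#' @export
setMethod("phantomTruth", "LiverPhantom", function(object) object@truth)

#' @describeIn LiverPhantom-class logical mask of the whole liver
#'   (parenchyma plus vessels)
#' @export
setMethod("liverMask", "LiverPhantom", function(object) object@labels > 0L)

#' @describeIn LiverPhantom-class logical mask of intrahepatic vessels
#' @export
setMethod("vesselMask", "LiverPhantom", function(object) object@labels == 2L)

setMethod("show", "SequenceMeta", function(object) {
  cat(sprintf("SequenceMeta: %s | alpha=%g deg, TR=%g ms, AVG=%g\n",
              object@contrast, object@flipAngle, object@tr, object@averages))
  v <- object@variableValues
  cat(sprintf("  %s: %s%s\n", object@variableName,
              paste(utils::head(v, 6), collapse = ", "),
              if (length(v) > 6) sprintf(", ... (%d values)", length(v)) else ""))
  cat(sprintf("  voxel %g x %g mm, slice %g mm\n",
              object@voxelSize[1], object@voxelSize[2], object@sliceThickness))
})

setMethod("show", "AcquisitionSeries", function(object) {
  d <- dim(object@imageData)
  cat(sprintf("AcquisitionSeries [%s]: %d x %d x %d voxels, %d frames\n",
              object@meta@contrast, d[1], d[2], d[3], d[4]))
  show(object@meta)
})

setMethod("show", "ParameterMap", function(object) {
  v <- object@values[object@mask]
  cat(sprintf("ParameterMap '%s' [%s]: %s grid, %d/%d voxels valid\n",
              object@parameter, object@units,
              paste(dim(object@values), collapse = " x "),
              sum(object@mask), length(object@mask)))
  if (length(v))
    cat(sprintf("  range %.4g .. %.4g, median %.4g\n",
                min(v), max(v), stats::median(v)))
})

setMethod("show", "MapFitResult", function(object) {
  cat(sprintf("MapFitResult: maps {%s}; %d/%d voxels converged\n",
              paste(names(object@maps), collapse = ", "),
              sum(object@converged, na.rm = TRUE),
              sum(!is.na(object@converged))))
})

setMethod("show", "LiverPhantom", function(object) {
  cat(sprintf("LiverPhantom: %s grid, %d liver voxels (%d vessel), sigma=%g\n",
              paste(dim(object@labels), collapse = " x "),
              sum(object@labels > 0L), sum(object@labels == 2L), object@sigma))
})

setMethod("show", "ROISet", function(object) {
  cat(sprintf("ROISet on slice %d: %s + background (%d vertices)\n",
              object@slice, paste(names(object@rois), collapse = ", "),
              nrow(object@background)))
})
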