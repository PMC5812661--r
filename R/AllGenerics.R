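#' @rdname SequenceMeta-class
#' @param object,x an object
#' @export
setGeneric("contrastKind", function(object) standardGeneric("contrastKind"))

#' @rdname SequenceMeta-class
#' @export
setGeneric("variableValues", function(object) standardGeneric("variableValues"))

#' @rdname AcquisitionSeries-class
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))

#' @rdname AcquisitionSeries-class
#' @export
setGeneric("seriesMeta", function(object) standardGeneric("seriesMeta"))

#' @rdname ParameterMap-class
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))

#' @rdname ParameterMap-class
#' @export
setGeneric("mapMask", function(object) standardGeneric("mapMask"))

#' @rdname ParameterMap-class
#' @export
setGeneric("mapUnits", function(object) standardGeneric("mapUnits"))

#' @rdname ParameterMap-class
#' @export
setGeneric("mapParameter", function(object) standardGeneric("mapParameter"))

#' @rdname MapFitResult-class
#' @export
setGeneric("parameterMaps", function(object) standardGeneric("parameterMaps"))

#' @rdname MapFitResult-class
#' @export
setGeneric("fitDiagnostics", function(object) standardGeneric("fitDiagnostics"))

#' @rdname LiverPhantom-class
#' @export
setGeneric("phantomLabels", function(object) standardGeneric("phantomLabels"))

#' @rdname LiverPhantom-class
#' @export
setGeneric("phantomTruth", function(object) standardGeneric("phantomTruth"))

#' @rdname LiverPhantom-class
#' @export
setGeneric("liverMask", function(object) standardGeneric("liverMask"))

#' @rdname LiverPhantom-class
#' @export
setGeneric("vesselMask", function(object) standardGeneric("vesselMask"))
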