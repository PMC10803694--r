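#' @include AllClasses.R
NULL

#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @export
setGeneric("mapStage", function(x) standardGeneric("mapStage"))
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @export
setGeneric("fieldVectors", function(x) standardGeneric("fieldVectors"))
#' @export
setGeneric("landmarkPoints", function(x) standardGeneric("landmarkPoints"))
#' @export
setGeneric("trueDisplacement", function(model, points)
  standardGeneric("trueDisplacement"))
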