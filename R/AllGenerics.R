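#' @rdname CalciumMovie-class
#' @param object,x a \linkS4class{CalciumMovie}, \linkS4class{TrialTensor} or
#'   \linkS4class{ResponseSet}
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname CalciumMovie-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname CalciumMovie-class
#' @export
setGeneric("movieData", function(x) standardGeneric("movieData"))

#' @rdname CalciumMovie-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname RegionSet-class
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname RegionSet-class
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @rdname RegionSet-class
#' @export
setGeneric("regionWeights", function(x, id) standardGeneric("regionWeights"))

#' @rdname RegionSet-class
#' @export
setGeneric("mergeHistory", function(x) standardGeneric("mergeHistory"))

#' @rdname TrialTensor-class
#' @export
setGeneric("stimuli", function(x) standardGeneric("stimuli"))

#' @rdname TrialTensor-class
#' @export
setGeneric("trialLayout", function(x) standardGeneric("trialLayout"))

#' @rdname ResponseSet-class
#' @export
setGeneric("responseMatrix", function(x) standardGeneric("responseMatrix"))

#' @rdname ResponseSet-class
#' @export
setGeneric("odorant", function(x) standardGeneric("odorant"))

#' @rdname ResponseSet-class
#' @export
setGeneric("dilution", function(x) standardGeneric("dilution"))

#' @rdname ResponseSet-class
#' @export
setGeneric("trialIndex", function(x) standardGeneric("trialIndex"))

#' @rdname GroundTruth-class
#' @export
setGeneric("cellCategory", function(x) standardGeneric("cellCategory"))

#' @rdname GroundTruth-class
#' @export
setGeneric("trueMeans", function(x) standardGeneric("trueMeans"))

#' @rdname GroundTruth-class
#' @export
setGeneric("cellMasks", function(x) standardGeneric("cellMasks"))

#' @rdname GroundTruth-class
#' @export
setGeneric("cellCenters", function(x) standardGeneric("cellCenters"))
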