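# Accessor and show methods for the S4 containers.

#' @rdname CalciumMovie-class
#' @export
setMethod("frameRate", "CalciumMovie", function(x) x@frameRate)

#' @rdname CalciumMovie-class
#' @export
setMethod("pixelSize", "CalciumMovie", function(x) x@pixelSize)

#' @rdname CalciumMovie-class
#' @export
setMethod("movieData", "CalciumMovie", function(x) x@data)

#' @rdname CalciumMovie-class
#' @export
setMethod("nFrames", "CalciumMovie", function(x) dim(x@data)[3])

#' @rdname CalciumMovie-class
#' @export
setMethod("dim", "CalciumMovie", function(x) dim(x@data))

setMethod("show", "CalciumMovie", function(object) {
  d <- dim(object@data)
  cat(sprintf("CalciumMovie: %d x %d pixels, %d frames @ %.3g Hz (%.3g um/px)\n",
              d[1], d[2], d[3], object@frameRate, object@pixelSize))
})

#' Construct a CalciumMovie
#'
#' @param data rows x cols x frames numeric array.
#' @param frameRate frames per second.
#' @param pixelSize micrometres per pixel.
#' @return a \linkS4class{CalciumMovie}
#' @export
CalciumMovie <- function(data, frameRate, pixelSize = 1) {
  new("CalciumMovie", data = data, frameRate = frameRate, pixelSize = pixelSize)
}

#' @rdname RegionSet-class
#' @param x,object a \linkS4class{RegionSet}
#' @param id region id (integer or string)
#' @export
setMethod("regionLabels", "RegionSet", function(x) x@labels)

#' @rdname RegionSet-class
#' @export
setMethod("regionIds", "RegionSet", function(x) as.integer(names(x@weights)))

#' @rdname RegionSet-class
#' @export
setMethod("regionWeights", "RegionSet", function(x, id) x@weights[[as.character(id)]])

#' @rdname RegionSet-class
#' @export
setMethod("mergeHistory", "RegionSet", function(x) x@mergeHistory)

#' @rdname RegionSet-class
#' @export
setMethod("length", "RegionSet", function(x) length(x@weights))

setMethod("show", "RegionSet", function(object) {
  cat(sprintf("RegionSet: %d regions on a %d x %d field (%d merges recorded)\n",
              length(object@weights), nrow(object@labels), ncol(object@labels),
              nrow(object@mergeHistory)))
})

#' @rdname TrialTensor-class
#' @param x,object a \linkS4class{TrialTensor}
#' @export
setMethod("stimuli", "TrialTensor", function(x) x@stimuli)

#' @rdname TrialTensor-class
#' @export
setMethod("trialLayout", "TrialTensor", function(x) x@layout)

#' @rdname TrialTensor-class
#' @export
setMethod("frameRate", "TrialTensor", function(x) x@frameRate)

#' @rdname TrialTensor-class
#' @export
setMethod("dim", "TrialTensor", function(x) dim(x@data))

setMethod("show", "TrialTensor", function(object) {
  d <- dim(object@data)
  cat(sprintf("TrialTensor (%s): %d cells x %d stimuli x %d trials x %d frames @ %.3g Hz\n",
              object@signal, d[1], d[2], d[3], d[4], object@frameRate))
})

#' Construct a ResponseSet
#'
#' @param responses cells x trials numeric matrix of scalar responses.
#' @param odorant,dilution,trial per-column stimulus metadata.
#' @return a \linkS4class{ResponseSet}
#' @export
ResponseSet <- function(responses, odorant, dilution, trial) {
  responses <- as.matrix(responses)
  if (is.null(rownames(responses)))
    rownames(responses) <- sprintf("cell_%d", seq_len(nrow(responses)))
  cd <- S4Vectors::DataFrame(odorant = odorant, dilution = dilution, trial = trial)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(response = responses), colData = cd)
  new("ResponseSet", se)
}

#' @rdname ResponseSet-class
#' @param x,object a \linkS4class{ResponseSet}
#' @export
setMethod("responseMatrix", "ResponseSet", function(x)
  SummarizedExperiment::assay(x, "response"))

#' @rdname ResponseSet-class
#' @export
setMethod("odorant", "ResponseSet", function(x)
  as.character(SummarizedExperiment::colData(x)$odorant))

#' @rdname ResponseSet-class
#' @export
setMethod("dilution", "ResponseSet", function(x)
  SummarizedExperiment::colData(x)$dilution)

#' @rdname ResponseSet-class
#' @export
setMethod("trialIndex", "ResponseSet", function(x)
  SummarizedExperiment::colData(x)$trial)

setMethod("show", "ResponseSet", function(object) {
  cat(sprintf("ResponseSet: %d cells x %d trials (%d odorants x %d dilutions)\n",
              nrow(object), ncol(object), length(unique(odorant(object))),
              length(unique(dilution(object)))))
})

#' @rdname GroundTruth-class
#' @param x,object a \linkS4class{GroundTruth}
#' @export
setMethod("cellCategory", "GroundTruth", function(x) x@category)

#' @rdname GroundTruth-class
#' @export
setMethod("trueMeans", "GroundTruth", function(x) x@trueMeans)

#' @rdname GroundTruth-class
#' @export
setMethod("cellMasks", "GroundTruth", function(x) x@masks)

#' @rdname GroundTruth-class
#' @export
setMethod("cellCenters", "GroundTruth", function(x) x@centers)

#' @rdname GroundTruth-class
#' @export
setMethod("stimuli", "GroundTruth", function(x) x@stimuli)

#' @rdname GroundTruth-class
#' @export
setMethod("length", "GroundTruth", function(x) length(x@category))

setMethod("show", "GroundTruth", function(object) {
  tab <- table(object@category)
  cat(sprintf("GroundTruth: %d cells, %d stimuli\n categories: %s\n",
              length(object@category), nrow(object@stimuli),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})
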