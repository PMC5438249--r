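#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor median sd quantile rnorm runif rbinom pf prcomp predict
#'   hclust as.dist dist approx fft mvfft setNames aggregate sd var
#' @importFrom utils head read.csv write.csv
NULL

#' Simulation configuration
#'
#' Holds every parameter of the synthetic two-photon experiment: field
#' geometry, trial layout, stimulus panel, cell-category proportions, response
#' amplitude distribution, indicator kernel and nuisance (noise, neuropil,
#' drift) settings.  Construct with [simConfig()].
#'
#' @slot fieldSize integer of length 2, movie rows and columns (pixels).
#' @slot pixelSize micrometres per pixel.
#' @slot frameRate acquisition rate in Hz.
#' @slot nCells number of cells to plant.
#' @slot cellRadius soma radius in micrometres.
#' @slot trialLayout named numeric `c(pre, odor, post)` in seconds; the
#'   default 8/2/20 s gives the 30 s trial used throughout.
#' @slot nTrialsPerStimulus trials per stimulus (default 4).
#' @slot stimulusSet data.frame with columns `odorant`, `dilution`.
#' @slot fractionActivated,fractionSuppressed,fractionInvariant,fractionMixed
#'   cell-category proportions of the whole population; `fractionInvariant`
#'   (identity-only cells) and `fractionMixed` are carved out of
#'   `fractionActivated`.
#' @slot fractionBroad proportion of activated cells that are broadly tuned.
#' @slot responseAmplitudeMean,responseAmplitudeSd mean and SD of the per
#'   cell-stimulus response amplitude (deconvolved dF/F units).
#' @slot trialNoiseSd i.i.d. Gaussian trial-to-trial noise (dF/F units).
#' @slot pRespond probability that a responsive cell-stimulus pair emits its
#'   transient on any given trial.
#' @slot amplitudeJitterSd relative per-trial jitter of the event amplitude.
#' @slot kernelTau indicator decay constant in seconds (2 s, GCaMP6s-like).
#' @slot neuropilAmplitude amplitude of the shared neuropil signal (dF/F).
#' @slot driftPeriod period of the slow sinusoidal drift (s).
#' @slot movieNoiseSd pixel noise SD of simulated movies, fluorescence a.u.
#' @slot baselineF baseline fluorescence of a cell, a.u.
#' @slot seed master seed; all sub-draws are derived from it.
#' @export
setClass("SimConfig", representation(
  fieldSize = "integer", pixelSize = "numeric", frameRate = "numeric",
  nCells = "integer", cellRadius = "numeric", trialLayout = "numeric",
  nTrialsPerStimulus = "integer", stimulusSet = "data.frame",
  fractionActivated = "numeric", fractionSuppressed = "numeric",
  fractionInvariant = "numeric", fractionMixed = "numeric",
  fractionBroad = "numeric",
  responseAmplitudeMean = "numeric", responseAmplitudeSd = "numeric",
  trialNoiseSd = "numeric", pRespond = "numeric", amplitudeJitterSd = "numeric",
  kernelTau = "numeric", neuropilAmplitude = "numeric", driftPeriod = "numeric",
  movieNoiseSd = "numeric", baselineF = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  pr <- c(object@fractionActivated, object@fractionSuppressed,
          object@fractionInvariant, object@fractionMixed, object@fractionBroad)
  if (any(pr < 0 | pr > 1)) msg <- c(msg, "proportions must lie in [0, 1]")
  if (object@fractionActivated + object@fractionSuppressed > 1)
    msg <- c(msg, "fractionActivated + fractionSuppressed must be <= 1")
  if (object@fractionInvariant + object@fractionMixed > object@fractionActivated + 1e-9)
    msg <- c(msg, "fractionInvariant + fractionMixed must not exceed fractionActivated")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be positive")
  if (any(object@trialLayout <= 0)) msg <- c(msg, "all trial durations must be positive")
  if (object@kernelTau <= 0) msg <- c(msg, "kernelTau must be positive")
  if (nrow(object@stimulusSet) < 1) msg <- c(msg, "stimulusSet must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Per-cell ground truth of a simulated dataset
#'
#' @slot category character vector, one of `"null"`, `"identity_only"`,
#'   `"concentration_modulated"`, `"mixed"`, `"broadly_tuned"`, `"suppressed"`.
#' @slot trueMeans cells x stimuli matrix of noise-free expected responses.
#' @slot stimuli data.frame (`odorant`, `dilution`), one row per stimulus.
#' @slot centers cells x 2 matrix of sub-pixel (row, col) centres, 0 rows when
#'   no movie was generated.
#' @slot masks list of integer vectors of linear pixel indices (disjoint).
#' @slot events data.frame of planted transients (`cell`, `stimulus`, `trial`,
#'   `onset_s`, `amplitude`); 0 rows for table-only simulations.
#' @export
setClass("GroundTruth", representation(
  category = "character", trueMeans = "matrix", stimuli = "data.frame",
  centers = "matrix", masks = "list", events = "data.frame"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (nrow(object@trueMeans) != length(object@category))
    msg <- c(msg, "trueMeans rows must match category length")
  if (ncol(object@trueMeans) != nrow(object@stimuli))
    msg <- c(msg, "trueMeans columns must match stimuli rows")
  if (length(object@masks) > 1L) {
    all_px <- unlist(object@masks)
    if (anyDuplicated(all_px)) msg <- c(msg, "cell masks must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' A calcium imaging movie
#'
#' Thin container around a 3-D intensity array (rows x cols x frames) with
#' acquisition metadata.
#'
#' @slot data numeric array, rows x cols x frames.
#' @slot frameRate frames per second.
#' @slot pixelSize micrometres per pixel.
#' @export
setClass("CalciumMovie", representation(
  data = "array", frameRate = "numeric", pixelSize = "numeric"))

setValidity("CalciumMovie", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L) msg <- c(msg, "data must be a 3-D array")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be positive")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  if (length(msg)) msg else TRUE
})

#' Segmented regions of a movie
#'
#' Output of the correlation-clustering segmentation: a label image, per-region
#' pixel weights and the greedy merge history.
#'
#' @slot labels integer matrix (rows x cols); 0 marks unassigned/neuropil
#'   pixels, positive values are region ids.
#' @slot weights named list (by region id) of data.frames with columns
#'   `row`, `col`, `weight`; weights are defined exactly on the region pixels
#'   and sum to 1 within a region.
#' @slot mergeHistory data.frame (`step`, `region_a`, `region_b`, `new_region`,
#'   `correlation`) in greedy merge order.
#' @export
setClass("RegionSet", representation(
  labels = "matrix", weights = "list", mergeHistory = "data.frame"))

setValidity("RegionSet", function(object) {
  msg <- character()
  cc <- object@mergeHistory$correlation
  if (length(cc) && any(is.finite(cc) & (cc < -1 - 1e-9 | cc > 1 + 1e-9)))
    msg <- c(msg, "merge correlations must lie in [-1, 1]")
  ids <- names(object@weights)
  if (length(ids) && !all(as.integer(ids) %in% object@labels))
    msg <- c(msg, "weight maps must refer to regions present in the label image")
  if (length(msg)) msg else TRUE
})

#' Trial-aligned traces
#'
#' Per-cell traces organised by (cell, stimulus, trial, frame) together with
#' stimulus metadata and the trial layout.
#'
#' @slot data 4-D numeric array: cells x stimuli x trials x frames.
#' @slot stimuli data.frame (`odorant`, `dilution`), one row per stimulus.
#' @slot layout named numeric `c(pre, odor, post)` in seconds.
#' @slot frameRate Hz.
#' @slot signal `"dff"` or `"rate"` (deconvolved).
#' @export
setClass("TrialTensor", representation(
  data = "array", stimuli = "data.frame", layout = "numeric",
  frameRate = "numeric", signal = "character"))

setValidity("TrialTensor", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 4L) msg <- c(msg, "data must be 4-D")
  if (dim(object@data)[2] != nrow(object@stimuli))
    msg <- c(msg, "stimulus dimension must match stimuli table")
  nf <- round(sum(object@layout) * object@frameRate)
  if (dim(object@data)[4] != nf)
    msg <- c(msg, sprintf("frame dimension (%d) must equal layout duration x frameRate (%d)",
                          dim(object@data)[4], nf))
  if (!object@signal %in% c("dff", "rate")) msg <- c(msg, "signal must be 'dff' or 'rate'")
  if (length(msg)) msg else TRUE
})

#' Per-trial population responses
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose single `response` assay holds one scalar response per cell (row) and
#' trial (column) -- the mean deconvolved dF/F over the post-onset response
#' window -- with `odorant`, `dilution` and `trial` in the column data.
#'
#' @export
setClass("ResponseSet", contains = "SummarizedExperiment")

setValidity("ResponseSet", function(object) {
  msg <- character()
  if (!"response" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'response' is required")
  need <- c("odorant", "dilution", "trial")
  if (!all(need %in% colnames(SummarizedExperiment::colData(object))))
    msg <- c(msg, "colData must contain odorant, dilution and trial")
  if (length(msg)) msg else TRUE
})
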