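# Shared fixtures, all generated in code.

# 3 odorants x 3 dilutions x 4 trials factor layout (36 observations)
fullDesign <- function() {
  stim <- concentrationSeries()
  list(od = rep(stim$odorant, each = 4),
       cc = rep(stim$dilution, each = 4),
       tr = rep(1:4, times = nrow(stim)))
}

# ResponseSet from a cells x 9 matrix of per-stimulus means, plus noise
responseSetFromMeans <- function(means, noiseSd = 0, nTrials = 4, seed = 1) {
  stim <- concentrationSeries()
  cols <- rep(seq_len(nrow(stim)), each = nTrials)
  m <- means[, cols, drop = FALSE]
  if (noiseSd > 0) {
    set.seed(seed)
    m <- m + matrix(rnorm(length(m), 0, noiseSd), nrow(m), ncol(m))
  }
  ResponseSet(m, odorant = stim$odorant[cols], dilution = stim$dilution[cols],
              trial = rep(seq_len(nTrials), nrow(stim)))
}

# a small all-responsive movie configuration used by the segmentation tests
segTestConfig <- function(fieldSize = c(64, 64), nCells = 30, seed = 7) {
  simConfig(fieldSize = fieldSize, nCells = nCells, frameRate = 5,
            cellRadius = 5, pixelSize = 1.4,
            stimulusSet = stimulusPanel(8), nTrialsPerStimulus = 4,
            fractionActivated = 1, fractionSuppressed = 0, fractionBroad = 0,
            fractionInvariant = 0, fractionMixed = 0,
            pRespond = 1, trialNoiseSd = 0.03, seed = seed)
}

segTestParams <- function() {
  segmentationParams(binSeconds = 4, highpassSeconds = 60,
                     minSize = 10, maxSize = 120)
}

# deterministic dF/F trial trace: quiet baseline with known SD, optional
# response plateau of `plateauFrames` frames at `level` starting at onset
trialDff <- function(level = 0, plateauFrames = 0, frameRate = 15,
                     baseSd = 0.01, nFrames = 30 * frameRate) {
  onset <- 8 * frameRate + 1
  x <- numeric(nFrames)
  x[seq_len(onset - 1)] <- rep(c(baseSd, -baseSd), length.out = onset - 1)
  if (plateauFrames > 0) x[onset:(onset + plateauFrames - 1)] <- level
  x
}
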