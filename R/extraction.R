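# Signal extraction: subpixel frame registration, weighted trace extraction,
# neuropil correction, dF/F, linear temporal deconvolution and run-length
# response detection with ROC-based threshold calibration.

#' Detection parameters
#'
#' Run-length response detection: a trial is flagged activated (suppressed)
#' if dF/F reaches and remains above +k SD (below -k SD) of its baseline for
#' at least `runActivation` (`runSuppression`) consecutive frames, with the
#' run starting inside the 4 s window after odor onset.  Run lengths were
#' calibrated at 15 Hz (`referenceRate`) and are rescaled proportionally for
#' other frame rates.
#'
#' @param k threshold in baseline-SD units (default 2).
#' @param runActivation,runSuppression required run lengths in frames at the
#'   reference rate (defaults 21 and 19).
#' @param windowS response window after odor onset, seconds.
#' @param referenceRate frame rate at which the run lengths apply, Hz.
#' @return list of class `DetectionParams`
#' @export
detectionParams <- function(k = 2, runActivation = 21, runSuppression = 19,
                            windowS = 4, referenceRate = 15) {
  if (k <= 0) stopf("k must be positive")
  if (runActivation < 1 || runSuppression < 1) stopf("run lengths must be >= 1")
  structure(list(k = k, runActivation = runActivation,
                 runSuppression = runSuppression, windowS = windowS,
                 referenceRate = referenceRate), class = "DetectionParams")
}

# ---- registration -----------------------------------------------------------

# Upsampled portion of the inverse DFT of `x` by matrix multiply
# (Guizar-Sicairos style local refinement).
dftUpsample <- function(x, nor, noc, usfac, roff, coff) {
  nr <- nrow(x); nc <- ncol(x)
  kernc <- exp((2i * pi / (nc * usfac)) *
               outer(ifftShiftIdx(nc), seq(0, noc - 1) - coff))
  kernr <- exp((2i * pi / (nr * usfac)) *
               outer(seq(0, nor - 1) - roff, ifftShiftIdx(nr)))
  kernr %*% x %*% kernc
}

ifftShiftIdx <- function(n) {
  i <- seq(0, n - 1)
  i[i >= ceiling(n / 2)] <- i[i >= ceiling(n / 2)] - n
  i
}

# Estimate the (dy, dx) shift of frame relative to ref via phase correlation
# with optional subpixel refinement.
estimateShift <- function(refF, frameF, usfac = 10) {
  nr <- nrow(refF); nc <- ncol(refF)
  CP <- Conj(refF) * frameF
  cc <- Mod(fft(CP, inverse = TRUE))
  peak <- arrayInd(which.max(cc), dim(cc))
  dy <- peak[1] - 1
  dx <- peak[2] - 1
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  if (usfac > 1) {
    # refine in a 1.5-pixel neighborhood at resolution 1/usfac
    nloc <- ceiling(usfac * 1.5)
    dftshift <- floor(nloc / 2)
    roff <- dftshift - dy * usfac
    coff <- dftshift - dx * usfac
    ccu <- Mod(dftUpsample(CP, nloc, nloc, usfac, roff, coff))
    pk <- arrayInd(which.max(ccu), dim(ccu))
    dy <- dy + (pk[1] - 1 - dftshift) / usfac
    dx <- dx + (pk[2] - 1 - dftshift) / usfac
  }
  c(dy = dy, dx = dx)
}

applyShift <- function(frame, dy, dx) {
  nr <- nrow(frame); nc <- ncol(frame)
  ky <- ifftShiftIdx(nr); kx <- ifftShiftIdx(nc)
  ph <- exp(2i * pi * (outer(ky, rep(1, nc)) * dy / nr +
                       outer(rep(1, nr), kx) * dx / nc))
  Re(fft(fft(frame) * ph, inverse = TRUE)) / (nr * nc)
}

#' Subpixel motion correction
#'
#' Rigid translational registration by discrete Fourier phase correlation:
#' every frame is aligned to the mean of the first (up to) 100 frames, with
#' subpixel resolution obtained by locally upsampling the cross-correlation
#' by `usfac`.
#'
#' @param movie a \linkS4class{CalciumMovie}
#' @param usfac upsampling factor (shift resolution 1/usfac pixels)
#' @param refFrames number of initial frames averaged into the reference
#' @return list with `movie` (registered \linkS4class{CalciumMovie}) and
#'   `shifts` (frames x 2 matrix of (dy, dx) in pixels)
#' @export
registerFrames <- function(movie, usfac = 10, refFrames = 100) {
  d <- dim(movie)
  if (d[3] < 2) stopf("need at least 2 frames")
  ref <- apply(movie@data[, , seq_len(min(refFrames, d[3])), drop = FALSE],
               c(1, 2), mean)
  refF <- fft(ref)
  shifts <- matrix(0, d[3], 2, dimnames = list(NULL, c("dy", "dx")))
  out <- movie@data
  for (t in seq_len(d[3])) {
    fr <- movie@data[, , t]
    if (all(fr == 0)) {
      warnf("frame %d is all zero; shift set to (0, 0)", t)
      next
    }
    s <- estimateShift(refF, fft(fr), usfac = usfac)
    shifts[t, ] <- s
    if (any(s != 0)) out[, , t] <- applyShift(fr, s[1], s[2])
  }
  list(movie = CalciumMovie(out, frameRate(movie), pixelSize(movie)),
       shifts = shifts)
}

# ---- trace extraction -------------------------------------------------------

#' Extract weighted fluorescence traces
#'
#' The fluorescence of each region is the weighted average of its pixel time
#' courses, `F(t) = sum_i w_i x_i(t) / sum_i w_i`.
#'
#' @param movie a \linkS4class{CalciumMovie}
#' @param regions a \linkS4class{RegionSet} with weight maps
#' @return matrix, regions x frames; row names are region ids
#' @export
extractTraces <- function(movie, regions) {
  d <- dim(movie)
  M <- matrix(movie@data, d[1] * d[2], d[3])
  ids <- regionIds(regions)
  out <- matrix(0, length(ids), d[3], dimnames = list(as.character(ids), NULL))
  for (k in seq_along(ids)) {
    wdf <- regionWeights(regions, ids[k])
    px <- pixelIndex(wdf$row, wdf$col, d[1])
    sw <- sum(wdf$weight)
    if (abs(sw) < 1e-15) stopf("region %s has all-zero weights", ids[k])
    out[k, ] <- as.vector(crossprod(M[px, , drop = FALSE], wdf$weight)) / sw
  }
  out
}

#' Neuropil correction
#'
#' Estimates the neuropil signal around a region as the plain average of all
#' pixels within `radiusUm` of the region centre, excluding the pixels of
#' every segmented region, and subtracts `r` times it:
#' `F_true(t) = F_measured(t) - r * F_neuropil(t)`.
#'
#' @param trace the region's measured fluorescence (vector over frames)
#' @param movie the registered \linkS4class{CalciumMovie}
#' @param regions the full \linkS4class{RegionSet}
#' @param id id of the region the trace belongs to
#' @param radiusUm neuropil disk radius in micrometres (default 20)
#' @param r contamination ratio (default 0.5)
#' @return corrected trace; if the disk contains no free pixels the trace is
#'   returned unchanged with a warning
#' @export
neuropilCorrect <- function(trace, movie, regions, id, radiusUm = 20, r = 0.5) {
  if (r == 0) return(trace)
  d <- dim(movie)
  wdf <- regionWeights(regions, id)
  ctr <- c(sum(wdf$row * wdf$weight), sum(wdf$col * wdf$weight)) / sum(wdf$weight)
  rows <- matrix(seq_len(d[1]), d[1], d[2])
  cols <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  dPix <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
  disk <- dPix <= radiusUm / pixelSize(movie)
  disk[regionLabels(regions) > 0L] <- FALSE
  if (!any(disk)) {
    warnf("neuropil disk of region %s fully covered by ROIs; correction skipped", id)
    return(trace)
  }
  M <- matrix(movie@data, d[1] * d[2], d[3])
  fnp <- colMeans(M[which(disk), , drop = FALSE])
  trace - r * fnp
}

#' Upsample a trace by linear interpolation
#'
#' Used to bring raw traces acquired at different rates onto the highest
#' sampling rate of an experiment before pooling.
#'
#' @param x trace (vector over frames)
#' @param fromRate,toRate sampling rates in Hz
#' @return trace resampled at `toRate`, covering the same time span
#' @export
upsampleTrace <- function(x, fromRate, toRate) {
  if (toRate == fromRate) return(x)
  t0 <- (seq_along(x) - 1) / fromRate
  t1 <- seq(0, t0[length(t0)], by = 1 / toRate)
  approx(t0, x, xout = t1, rule = 2)$y
}

# ---- dF/F, deconvolution, detection ----------------------------------------

#' Per-trial dF/F
#'
#' `dff(t) = (F(t) - F0)/F0` with `F0` the median fluorescence between
#' seconds 4 and 8 of the pre-stimulus baseline.
#'
#' @param trace fluorescence of one trial (vector over frames)
#' @param frameRate Hz
#' @param layout named `c(pre, odor, post)` seconds; `pre` must be >= 8 s... at
#'   least the 4--8 s baseline segment must exist
#' @return dF/F vector, or all-`NA` (invalid trial) when `F0 <= 0`
#' @export
computeDff <- function(trace, frameRate, layout = c(pre = 8, odor = 2, post = 20)) {
  if (layout[["pre"]] < 8) stopf("pre-stimulus period must be at least 8 s")
  i0 <- floor(4 * frameRate) + 1L
  i1 <- floor(8 * frameRate)
  F0 <- median(trace[i0:i1])
  if (!is.finite(F0) || F0 <= 0) return(rep(NA_real_, length(trace)))
  (trace - F0) / F0
}

#' Linear temporal deconvolution
#'
#' Inverts the indicator's exponential kernel: `r(t) = f'(t) + f(t)/tau`,
#' with the derivative taken as a forward difference times the frame rate,
#' then low-pass filters with a zero-phase four-pole Butterworth filter
#' (cutoff `cutoffHz`).  For `filter = FALSE` the raw deconvolved signal is
#' returned, which recovers an impulse train convolved with
#' `exp(-t/tau)` up to discretisation error.
#'
#' @param f dF/F trace (vector)
#' @param tau decay constant, s (2 s for GCaMP6s)
#' @param frameRate Hz
#' @param cutoffHz Butterworth cutoff (default 2.5 Hz)
#' @param order filter order (default 4)
#' @param filter apply the low-pass (default TRUE)
#' @return deconvolved trace
#' @export
deconvolve <- function(f, tau, frameRate, cutoffHz = 2.5, order = 4,
                       filter = TRUE) {
  if (tau <= 0) stopf("tau must be positive")
  n <- length(f)
  fp <- c(diff(f), 0) * frameRate
  r <- fp + f / tau
  if (!filter) return(r)
  if (frameRate <= 2 * cutoffHz)
    stopf("frameRate must exceed twice the filter cutoff")
  bf <- signal::butter(order, cutoffHz / (frameRate / 2), type = "low")
  as.numeric(signal::filtfilt(bf, r))
}

#' Classify one trial as activated, suppressed or unresponsive
#'
#' @param dff one trial's dF/F trace
#' @param frameRate Hz
#' @param layout named `c(pre, odor, post)` seconds
#' @param params see [detectionParams()]
#' @return `"act"`, `"sup"` or `"none"`
#' @export
classifyTrialResponse <- function(dff, frameRate,
                                  layout = c(pre = 8, odor = 2, post = 20),
                                  params = detectionParams()) {
  if (anyNA(dff)) return(NA_character_)
  onset <- round(layout[["pre"]] * frameRate) + 1L
  winFrames <- round(params$windowS * frameRate)
  scaleRun <- frameRate / params$referenceRate
  runAct <- max(1L, round(params$runActivation * scaleRun))
  runSup <- max(1L, round(params$runSuppression * scaleRun))
  if (winFrames < 1) stopf("response window shorter than one frame")
  base <- dff[seq_len(onset - 1L)]
  thr <- params$k * sd(base)
  lastAct <- min(length(dff), onset + winFrames + runAct - 1L)
  lastSup <- min(length(dff), onset + winFrames + runSup - 1L)
  segAct <- dff[onset:lastAct]
  segSup <- dff[onset:lastSup]
  if (length(segAct) < runAct && length(segSup) < runSup)
    stopf("response window shorter than the required run")
  if (runStartsWithin(segAct > thr, runAct, winFrames)) return("act")
  if (runStartsWithin(segSup < -thr, runSup, winFrames)) return("sup")
  "none"
}

#' Detect responses across a trial tensor
#'
#' Applies [classifyTrialResponse()] to every (cell, stimulus, trial).
#'
#' @param tensor a \linkS4class{TrialTensor} carrying dF/F
#' @param params see [detectionParams()]
#' @return data.frame with columns `cell`, `odorant`, `dilution`, `trial`,
#'   `flag`
#' @export
detectResponses <- function(tensor, params = detectionParams()) {
  if (tensor@signal != "dff")
    warnf("detection is defined on dF/F; tensor carries '%s'", tensor@signal)
  d <- dim(tensor@data)
  st <- stimuli(tensor)
  res <- expand.grid(trial = seq_len(d[3]), stimulus = seq_len(d[2]),
                     cell = seq_len(d[1]), KEEP.OUT.ATTRS = FALSE)
  flag <- character(nrow(res))
  for (k in seq_len(nrow(res)))
    flag[k] <- classifyTrialResponse(
      tensor@data[res$cell[k], res$stimulus[k], res$trial[k], ],
      frameRate(tensor), trialLayout(tensor), params)
  data.frame(cell = res$cell, odorant = st$odorant[res$stimulus],
             dilution = st$dilution[res$stimulus], trial = res$trial,
             flag = flag, stringsAsFactors = FALSE)
}

#' ROC calibration of the detection threshold
#'
#' Evaluates a grid of `(k, run)` candidates on labelled trials -- planted
#' responses as positives and blank (no-stimulus) trials for the
#' false-positive rate -- and returns the grid point maximising Youden's J
#' (sensitivity + specificity - 1), with its accuracy and true-positive rate.
#'
#' @param positives list of dF/F trial traces containing a planted response
#' @param blanks list of blank dF/F trial traces
#' @param frameRate Hz
#' @param layout trial layout
#' @param kGrid,runGrid candidate thresholds (SD units) and run lengths
#' @param mode `"act"` (default) or `"sup"`
#' @return list: `k`, `run`, `J`, `ACC`, `TPR`, `FPR`, and the full `grid`
#' @export
calibrateThresholdRoc <- function(positives, blanks, frameRate,
                                  layout = c(pre = 8, odor = 2, post = 20),
                                  kGrid = c(1, 1.5, 2, 2.5, 3),
                                  runGrid = c(11, 15, 19, 21, 25),
                                  mode = "act") {
  if (!length(blanks)) stopf("blank trials are required to estimate the FPR")
  grid <- expand.grid(k = kGrid, run = runGrid, KEEP.OUT.ATTRS = FALSE)
  grid$TPR <- grid$FPR <- grid$ACC <- grid$J <- NA_real_
  for (g in seq_len(nrow(grid))) {
    p <- detectionParams(k = grid$k[g], runActivation = grid$run[g],
                         runSuppression = grid$run[g],
                         referenceRate = frameRate)
    hit <- vapply(positives, function(x)
      classifyTrialResponse(x, frameRate, layout, p) == mode, logical(1))
    fa <- vapply(blanks, function(x)
      classifyTrialResponse(x, frameRate, layout, p) == mode, logical(1))
    tpr <- mean(hit); fpr <- mean(fa)
    grid$TPR[g] <- tpr; grid$FPR[g] <- fpr
    grid$ACC[g] <- (sum(hit) + sum(!fa)) / (length(hit) + length(fa))
    grid$J[g] <- tpr - fpr
  }
  best <- which.max(grid$J)
  list(k = grid$k[best], run = grid$run[best], J = grid$J[best],
       ACC = grid$ACC[best], TPR = grid$TPR[best], FPR = grid$FPR[best],
       grid = grid)
}

# ---- movie -> trial tensor --------------------------------------------------

#' Build a dF/F trial tensor from a movie and its regions
#'
#' Extracts weighted traces, optionally neuropil-corrects them, splits them
#' into trials following the presentation schedule and computes per-trial
#' dF/F.
#'
#' @param movie registered \linkS4class{CalciumMovie}
#' @param regions \linkS4class{RegionSet} with weights
#' @param schedule presentation schedule as returned by [generateMovie()]
#'   (`stimulus`, `trial`, `startFrame`)
#' @param stimuli data.frame (`odorant`, `dilution`) indexed by
#'   `schedule$stimulus`
#' @param layout trial layout, seconds
#' @param neuropil apply neuropil correction (default TRUE)
#' @param r neuropil contamination ratio
#' @return \linkS4class{TrialTensor} with signal `"dff"`
#' @export
extractTrialTensor <- function(movie, regions, schedule, stimuli,
                               layout = c(pre = 8, odor = 2, post = 20),
                               neuropil = TRUE, r = 0.5) {
  traces <- extractTraces(movie, regions)
  ids <- regionIds(regions)
  if (neuropil)
    for (k in seq_along(ids))
      traces[k, ] <- neuropilCorrect(traces[k, ], movie, regions, ids[k], r = r)
  fr <- frameRate(movie)
  fpt <- round(sum(layout) * fr)
  nStim <- nrow(stimuli)
  nTrial <- max(schedule$trial)
  arr <- array(NA_real_, c(nrow(traces), nStim, nTrial, fpt))
  for (p in seq_len(nrow(schedule))) {
    fidx <- schedule$startFrame[p]:(schedule$startFrame[p] + fpt - 1L)
    for (k in seq_len(nrow(traces)))
      arr[k, schedule$stimulus[p], schedule$trial[p], ] <-
        computeDff(traces[k, fidx], fr, layout)
  }
  new("TrialTensor", data = arr, stimuli = stimuli,
      layout = setNames(as.numeric(layout), c("pre", "odor", "post")),
      frameRate = fr, signal = "dff")
}

#' Deconvolve a dF/F trial tensor
#'
#' @param tensor \linkS4class{TrialTensor} with signal `"dff"`
#' @param tau decay constant, s
#' @param ... passed to [deconvolve()]
#' @return \linkS4class{TrialTensor} with signal `"rate"`
#' @export
deconvolveTensor <- function(tensor, tau = 2, ...) {
  d <- dim(tensor@data)
  out <- tensor@data
  for (i in seq_len(d[1])) for (s in seq_len(d[2])) for (tr in seq_len(d[3])) {
    x <- tensor@data[i, s, tr, ]
    if (!anyNA(x)) out[i, s, tr, ] <- deconvolve(x, tau, frameRate(tensor), ...)
  }
  initialize(tensor, data = out, signal = "rate")
}
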