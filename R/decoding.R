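# Linear decoding of stimulus identity from population vectors:
# leave-one-out cross-validation, time-resolved decoding, train-at-timepoint
# generalization, and the 7-group concentration-generalization task.

# Fit a linear decoder on training vectors and predict test vectors.
# method "lda": LDA on the principal components capturing `varFrac` of the
# training variance (basis refitted per training fold, never on test data);
# method "svm": one-vs-all linear-kernel SVMs with unit cost, class decided
# by the largest decision value.  Ties break toward the lowest class index.
fitPredict <- function(Xtr, ytr, Xte, method = c("lda", "svm"),
                       varFrac = 0.95) {
  method <- match.arg(method)
  ytr <- factor(ytr)
  lev <- levels(ytr)
  if (is.null(dim(Xte))) Xte <- matrix(Xte, nrow = 1)
  if (method == "lda") {
    pc <- prcomp(Xtr, center = TRUE, scale. = FALSE)
    if (sum(pc$sdev > 1e-10) == 0)            # degenerate: no variance at all
      return(rep(lev[1], nrow(Xte)))
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    k <- which(cumsum(ve) >= varFrac - 1e-12)[1]
    if (is.na(k)) k <- sum(pc$sdev > 1e-10)
    # cap the retained components so the pooled within-class covariance
    # stays well conditioned (few trials per class); LDA only uses
    # nClasses - 1 discriminant directions in any case
    k <- min(k, nrow(Xtr) - length(lev), sum(pc$sdev > 1e-10),
             max(length(lev) - 1L, floor(nrow(Xtr) / 4)))
    k <- max(k, 1L)
    Str <- pc$x[, seq_len(k), drop = FALSE]
    Ste <- scale(Xte, center = pc$center, scale = FALSE) %*%
      pc$rotation[, seq_len(k), drop = FALSE]
    fit <- suppressWarnings(MASS::lda(Str, grouping = ytr,
                                      prior = rep(1 / length(lev), length(lev))))
    post <- predict(fit, Ste)$posterior
    post <- post[, lev, drop = FALSE]
    pred <- lev[apply(post, 1, which.max)]   # which.max -> lowest index on ties
  } else {
    scores <- matrix(NA_real_, nrow(Xte), length(lev))
    for (j in seq_along(lev)) {
      yy <- factor(ifelse(ytr == lev[j], "pos", "neg"), levels = c("neg", "pos"))
      fit <- e1071::svm(Xtr, yy, kernel = "linear", cost = 1, scale = FALSE)
      dv <- attr(predict(fit, Xte, decision.values = TRUE), "decision.values")
      # orient so that larger means more "pos"
      sgn <- if (grepl("^pos", colnames(dv)[1])) 1 else -1
      scores[, j] <- sgn * dv[, 1]
    }
    pred <- lev[apply(scores, 1, which.max)]
  }
  pred
}

decodingResult <- function(truth, pred, chance) {
  lev <- sort(unique(c(truth, pred)))
  confusion <- table(factor(truth, lev), factor(pred, lev))
  structure(list(confusion = confusion,
                 accuracy = 100 * mean(truth == pred),
                 chance = chance,
                 predictions = data.frame(truth = truth, predicted = pred)),
            class = "DecodingResult")
}

#' @export
print.DecodingResult <- function(x, ...) {
  cat(sprintf("DecodingResult: accuracy %.1f%% (chance %.1f%%), %d trials\n",
              x$accuracy, x$chance, nrow(x$predictions)))
  invisible(x)
}

#' Leave-one-out linear classification
#'
#' Predicts the label of every trial from a model fitted on all other trials
#' (the assessed trial is excluded from training).  Methods: `"lda"`, linear
#' discriminant analysis on the principal components capturing 95% of the
#' training-fold variance, or `"svm"`, one-vs-all linear support vector
#' machines.
#'
#' @param X trials x features matrix of population vectors
#' @param labels per-trial stimulus labels
#' @param method `"lda"` (default) or `"svm"`
#' @param varFrac variance fraction retained by the PCA step (LDA only)
#' @return a `DecodingResult` list: `confusion`, `accuracy` (%), `chance`
#'   (%), `predictions`
#' @export
classifyLoo <- function(X, labels, method = "lda", varFrac = 0.95) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) stopf("need at least 2 classes")
  if (any(tab < 2)) stopf("every class needs >= 2 trials for leave-one-out")
  pred <- character(nrow(X))
  for (i in seq_len(nrow(X)))
    pred[i] <- fitPredict(X[-i, , drop = FALSE], labels[-i],
                          X[i, , drop = FALSE], method, varFrac)
  decodingResult(labels, pred, 100 / length(tab))
}

# mean signal in a frame window for every (stimulus, trial) -> trials x cells
windowVectors <- function(tensor, frames) {
  d <- dim(tensor@data)
  X <- matrix(NA_real_, d[2] * d[3], d[1])
  labs <- character(d[2] * d[3])
  st <- stimuli(tensor)
  k <- 0L
  for (s in seq_len(d[2])) for (tr in seq_len(d[3])) {
    k <- k + 1L
    block <- tensor@data[, s, tr, frames, drop = FALSE]
    X[k, ] <- rowMeans(matrix(block, d[1]))
    labs[k] <- paste0(st$odorant[s], "@", st$dilution[s])
  }
  list(X = X, labels = labs)
}

#' Time-resolved decoding accuracy
#'
#' Accumulates the signal over a sliding window of `windowFrames` frames and
#' reports leave-one-out accuracy at each window position.
#'
#' @param tensor a \linkS4class{TrialTensor}
#' @param windowFrames sliding window length in frames (default 5, ~333 ms
#'   at 15 Hz)
#' @param step window step in frames
#' @param method,varFrac passed to [classifyLoo()]
#' @return data.frame: `timeS` (window centre relative to odor onset),
#'   `accuracy`, `chance`
#' @export
timeResolvedDecoding <- function(tensor, windowFrames = 5, step = windowFrames,
                                 method = "lda", varFrac = 0.95) {
  d <- dim(tensor@data)
  if (windowFrames > d[4]) stopf("window longer than the trace")
  fr <- frameRate(tensor)
  onset <- round(trialLayout(tensor)[["pre"]] * fr) + 1L
  starts <- seq(1L, d[4] - windowFrames + 1L, by = step)
  acc <- numeric(length(starts))
  chance <- NA_real_
  for (k in seq_along(starts)) {
    wv <- windowVectors(tensor, starts[k]:(starts[k] + windowFrames - 1L))
    res <- classifyLoo(wv$X, wv$labels, method, varFrac)
    acc[k] <- res$accuracy; chance <- res$chance
  }
  data.frame(timeS = (starts + (windowFrames - 1) / 2 - onset) / fr,
             accuracy = acc, chance = chance)
}

#' Generalization over time from fixed training timepoints
#'
#' For each training time, fits the decoder on the window at that time and
#' evaluates it at every test time, using leave-one-out folds so that the
#' tested trial never enters training at any timepoint.
#'
#' @param tensor a \linkS4class{TrialTensor}
#' @param tTrainS training times in seconds after odor onset
#' @param windowFrames window length in frames
#' @param step test-window step in frames
#' @param method,varFrac passed to the decoder
#' @return data.frame: `tTrainS`, `tTestS`, `accuracy`, `chance`
#' @export
trainAtTimepoint <- function(tensor, tTrainS = c(0.27, 1, 3), windowFrames = 5,
                             step = windowFrames, method = "lda",
                             varFrac = 0.95) {
  d <- dim(tensor@data)
  fr <- frameRate(tensor)
  onset <- round(trialLayout(tensor)[["pre"]] * fr) + 1L
  starts <- seq(1L, d[4] - windowFrames + 1L, by = step)
  nTrials <- d[2] * d[3]
  out <- list()
  for (tt in tTrainS) {
    trainStart <- onset + round(tt * fr)
    if (trainStart + windowFrames - 1L > d[4]) stopf("training time outside trace")
    wvTrain <- windowVectors(tensor, trainStart:(trainStart + windowFrames - 1L))
    testX <- lapply(starts, function(s0)
      windowVectors(tensor, s0:(s0 + windowFrames - 1L))$X)
    correct <- matrix(FALSE, nTrials, length(starts))
    for (i in seq_len(nTrials)) {
      for (k in seq_along(starts)) {
        pred <- fitPredict(wvTrain$X[-i, , drop = FALSE], wvTrain$labels[-i],
                           testX[[k]][i, , drop = FALSE], method, varFrac)
        correct[i, k] <- pred == wvTrain$labels[i]
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      tTrainS = tt,
      tTestS = (starts + (windowFrames - 1) / 2 - onset) / fr,
      accuracy = 100 * colMeans(correct),
      chance = 100 / length(unique(wvTrain$labels)))
  }
  do.call(rbind, out)
}

#' Concentration-generalization decoding (7 stimulus groups)
#'
#' For each test trial of odorant `o` at dilution `d`, the classifier is
#' trained on `o` at the single most distant dilution only (for the middle
#' dilution, the lowest), plus the other two odorants at all three dilutions
#' -- seven training groups in total.  A prediction is correct when the trial
#' is assigned to `o`'s group; chance is 1/7.
#'
#' @param rs a \linkS4class{ResponseSet} covering exactly 3 odorants x 3
#'   dilutions
#' @param cells optional subset of cell indices (e.g. the
#'   concentration-invariant subset)
#' @param method,varFrac passed to the decoder
#' @return a `DecodingResult`; `predictions` additionally records the tested
#'   odorant and dilution
#' @export
concentrationGeneralization <- function(rs, cells = NULL, method = "lda",
                                        varFrac = 0.95) {
  od <- odorant(rs); dil <- dilution(rs)
  odors <- sort(unique(od)); dils <- sort(unique(dil))
  if (length(odors) != 3 || length(dils) != 3)
    stopf("the generalization task requires exactly 3 odorants x 3 dilutions")
  m <- responseMatrix(rs)
  if (!is.null(cells)) {
    if (!length(cells)) stopf("empty cell subset")
    m <- m[cells, , drop = FALSE]
  }
  X <- t(m)
  rk <- match(dil, dils)
  mostDistant <- c(3L, 1L, 1L)               # per tested dilution rank
  truth <- pred <- character(ncol(m) * 0)
  testOd <- character(0); testDil <- numeric(0)
  for (i in seq_len(nrow(X))) {
    o <- od[i]; dstar <- mostDistant[rk[i]]
    trainIdx <- which((od == o & rk == dstar) | od != o)
    grp <- ifelse(od[trainIdx] == o, paste0("id:", o),
                  paste0(od[trainIdx], "@", rk[trainIdx]))
    if (length(unique(grp)) != 7L)
      stopf("expected 7 training groups, got %d", length(unique(grp)))
    p <- fitPredict(X[trainIdx, , drop = FALSE], grp,
                    X[i, , drop = FALSE], method, varFrac)
    truth <- c(truth, paste0("id:", o)); pred <- c(pred, p)
    testOd <- c(testOd, o); testDil <- c(testDil, dil[i])
  }
  res <- decodingResult(truth, pred, 100 / 7)
  res$predictions$odorant <- testOd
  res$predictions$dilution <- testDil
  res
}
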