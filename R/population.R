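# Population-vector statistics: single-trial population vectors, trial
# correlation matrices and their stimulus-structured summaries, lifetime
# sparseness, responsive fractions, tuning filters, PCA and hierarchical
# ordering.

#' Build single-trial population vectors
#'
#' Averages each cell's (deconvolved) signal over the `windowS` seconds
#' following odor onset, yielding one population vector per trial.
#'
#' @param tensor a \linkS4class{TrialTensor}
#' @param windowS integration window after odor onset, seconds (default 4)
#' @return a \linkS4class{ResponseSet}
#' @export
buildPopulationVectors <- function(tensor, windowS = 4) {
  d <- dim(tensor@data)
  fr <- frameRate(tensor)
  onset <- round(trialLayout(tensor)[["pre"]] * fr) + 1L
  win <- onset:(onset + round(windowS * fr) - 1L)
  if (max(win) > d[4]) stopf("response window extends past the trial")
  st <- stimuli(tensor)
  resp <- matrix(NA_real_, d[1], d[2] * d[3])
  odor <- character(d[2] * d[3]); dil <- numeric(d[2] * d[3]); tri <- integer(d[2] * d[3])
  col <- 0L
  for (s in seq_len(d[2])) for (tr in seq_len(d[3])) {
    col <- col + 1L
    block <- tensor@data[, s, tr, win, drop = FALSE]
    resp[, col] <- rowMeans(matrix(block, d[1]))
    odor[col] <- st$odorant[s]; dil[col] <- st$dilution[s]; tri[col] <- tr
  }
  if (anyNA(resp)) {
    bad <- which(apply(resp, 2, anyNA))
    stopf("missing trials: columns %s", paste(head(bad, 10), collapse = ", "))
  }
  ResponseSet(resp, odorant = odor, dilution = dil, trial = tri)
}

#' Pairwise trial correlation matrix
#'
#' Pearson correlations between every pair of single-trial population
#' vectors.  Zero-variance vectors yield `NA` entries.
#'
#' @param x a \linkS4class{ResponseSet} or cells x trials matrix
#' @return symmetric trials x trials correlation matrix
#' @export
correlationMatrix <- function(x) {
  m <- if (is(x, "ResponseSet")) responseMatrix(x) else as.matrix(x)
  if (nrow(m) < 2) stopf("need at least 2 cells")
  v <- apply(m, 2, var)
  C <- suppressWarnings(cor(m))
  C[v < 1e-24, ] <- NA; C[, v < 1e-24] <- NA
  diag(C)[v >= 1e-24] <- 1
  C
}

#' Stimulus-structured correlation summary
#'
#' Mean off-diagonal correlations grouped by the relation between the two
#' trials: same odorant and dilution (intra-stimulus), same odorant at
#' different dilutions (split by dilution-rank pair), and different odorants.
#'
#' @param C trial correlation matrix
#' @param odorant,dilution per-trial metadata aligned with `C`
#' @return data.frame with columns `group`, `meanCor`, `nPairs`
#' @export
summarizeCorrelations <- function(C, odorant, dilution) {
  n <- ncol(C)
  if (length(odorant) != n || length(dilution) != n)
    stopf("metadata must match the matrix dimension")
  dils <- sort(unique(dilution))
  rk <- match(dilution, dils)
  iu <- which(upper.tri(C), arr.ind = TRUE)
  i <- iu[, 1]; j <- iu[, 2]
  cc <- C[iu]
  sameOd <- odorant[i] == odorant[j]
  sameDil <- rk[i] == rk[j]
  pairRank <- paste(pmin(rk[i], rk[j]), pmax(rk[i], rk[j]), sep = "-")
  grp <- ifelse(!sameOd, "inter_odorant",
         ifelse(sameDil, "intra_stimulus", paste0("intra_odorant_", pairRank)))
  agg <- aggregate(cc, list(group = grp), function(z) mean(z, na.rm = TRUE))
  cnt <- aggregate(cc, list(group = grp), length)
  lev <- c("intra_stimulus",
           paste0("intra_odorant_", c("1-2", "1-3", "2-3")), "inter_odorant")
  out <- data.frame(group = lev,
                    meanCor = agg$x[match(lev, agg$group)],
                    nPairs = cnt$x[match(lev, cnt$group)])
  out$nPairs[is.na(out$nPairs)] <- 0L
  out
}

#' Lifetime sparseness
#'
#' `Sl = (1 - ((sum r_j / N)^2 / (sum r_j^2 / N))) / (1 - 1/N)` over a cell's
#' mean responses to the `N` stimuli of a panel: 0 for responses uniformly
#' distributed across odors, 1 for a cell highly selective for one odor.
#' Negative responses are clipped to 0 first (the statistic is only bounded
#' by 1 for non-negative inputs); an all-zero profile returns 0.
#'
#' @param r vector of a cell's mean responses to each stimulus
#' @return sparseness in `[0, 1]`
#' @export
lifetimeSparseness <- function(r) {
  N <- length(r)
  if (N < 2) stopf("need at least 2 stimuli")
  r <- pmax(r, 0)
  s2 <- sum(r^2)
  if (s2 <= 0) return(0)
  (1 - (sum(r) / N)^2 / (s2 / N)) / (1 - 1 / N)
}

#' Per-cell lifetime sparseness table
#'
#' Computes per-odorant trial means (optionally at one dilution) and applies
#' [lifetimeSparseness()] to each cell.
#'
#' @param rs a \linkS4class{ResponseSet}
#' @param atDilution optional single dilution to restrict to; by default all
#'   stimuli (odorant x dilution combinations) are treated as the panel
#' @return numeric vector of per-cell sparseness values
#' @export
sparsenessByCell <- function(rs, atDilution = NULL) {
  m <- responseMatrix(rs)
  od <- odorant(rs); dil <- dilution(rs)
  if (!is.null(atDilution)) {
    keep <- dil == atDilution
    if (!any(keep)) stopf("no trials at dilution %g", atDilution)
    m <- m[, keep, drop = FALSE]; od <- od[keep]; dil <- dil[keep]
    key <- od
  } else key <- paste(od, dil)
  means <- t(rowsum(t(m), key) / as.vector(table(key)[sort(unique(key))]))
  apply(means, 1, lifetimeSparseness)
}

#' Percentage of responsive cells per stimulus
#'
#' The percent of responding neurons to each stimulus is the average over
#' trials of the fraction of flagged cells, separately for activation and
#' suppression.
#'
#' @param flags data.frame from [detectResponses()]
#' @param nCells total cell count (defaults to the number of distinct cells
#'   in `flags`)
#' @return data.frame: `odorant`, `dilution`, `pctActivated`, `pctSuppressed`
#' @export
responsiveFractions <- function(flags, nCells = length(unique(flags$cell))) {
  key <- paste(flags$odorant, flags$dilution, sep = "@")
  out <- do.call(rbind, lapply(split(flags, key), function(df) {
    perTrial <- split(df, df$trial)
    act <- mean(vapply(perTrial, function(d) sum(d$flag == "act"), 0)) / nCells
    sup <- mean(vapply(perTrial, function(d) sum(d$flag == "sup"), 0)) / nCells
    data.frame(odorant = df$odorant[1], dilution = df$dilution[1],
               pctActivated = 100 * act, pctSuppressed = 100 * sup)
  }))
  rownames(out) <- NULL
  out[order(out$odorant, out$dilution), ]
}

#' Reliability filter and odor preference
#'
#' Keeps cell-stimulus pairs flagged on at least `minTrials` of the trials
#' (2 of 4 by default); a cell's preferred odorant is the kept stimulus with
#' the strongest mean response.
#'
#' @param flags data.frame from [detectResponses()]
#' @param rs \linkS4class{ResponseSet} with the matching responses
#' @param minTrials minimum number of flagged trials (default 2)
#' @param mode flag type to count (default `"act"`)
#' @return list: `kept` (data.frame cell/odorant/dilution/nFlagged) and
#'   `preferred` (data.frame cell/odorant/meanResponse)
#' @export
tuningFilter <- function(flags, rs, minTrials = 2, mode = "act") {
  agg <- aggregate(list(nFlagged = flags$flag == mode),
                   list(cell = flags$cell, odorant = flags$odorant,
                        dilution = flags$dilution), sum)
  kept <- agg[agg$nFlagged >= minTrials, ]
  rownames(kept) <- NULL
  if (!nrow(kept))
    return(list(kept = kept, preferred = data.frame(cell = integer(0),
                                                    odorant = character(0),
                                                    meanResponse = numeric(0))))
  m <- responseMatrix(rs)
  od <- odorant(rs); dil <- dilution(rs)
  kept$meanResponse <- vapply(seq_len(nrow(kept)), function(k) {
    cols <- od == kept$odorant[k] & dil == kept$dilution[k]
    mean(m[kept$cell[k], cols])
  }, 0)
  pref <- do.call(rbind, lapply(split(kept, kept$cell), function(df) {
    best <- which.max(df$meanResponse)
    data.frame(cell = df$cell[1], odorant = df$odorant[best],
               meanResponse = df$meanResponse[best])
  }))
  rownames(pref) <- NULL
  list(kept = kept, preferred = pref)
}

#' PCA projection of trial vectors
#'
#' Centred principal component analysis of the single-trial population
#' vectors.
#'
#' @param rs \linkS4class{ResponseSet} (or trials-in-columns matrix)
#' @param nComponents number of components to return (default 3)
#' @return list: `coords` (trials x nComponents), `varianceExplained`
#'   (fraction per returned component) and `fullSpectrum`
#' @export
pcaProject <- function(rs, nComponents = 3) {
  m <- if (is(rs, "ResponseSet")) responseMatrix(rs) else as.matrix(rs)
  X <- t(m)                                  # trials x cells
  if (nrow(X) < nComponents)
    stopf("fewer trials (%d) than requested components (%d)", nrow(X), nComponents)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(nComponents, ncol(pc$x))
  list(coords = pc$x[, seq_len(k), drop = FALSE],
       varianceExplained = ve[seq_len(k)], fullSpectrum = ve)
}

#' Leaf order from hierarchical clustering
#'
#' Agglomerative clustering (average linkage on correlation distance
#' `1 - r`) of the rows of a matrix; returns the dendrogram leaf order used
#' to sort cells or trials for display.
#'
#' @param m numeric matrix (rows are the items to order)
#' @return integer permutation of the row indices
#' @export
hierarchicalSort <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) return(seq_len(nrow(m)))
  C <- suppressWarnings(cor(t(m)))
  C[!is.finite(C)] <- 0
  hclust(as.dist(1 - C), method = "average")$order
}
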