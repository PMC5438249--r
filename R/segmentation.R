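# Automated cell segmentation: greedy agglomerative clustering of neighboring
# pixels by signal correlation, iterative pixel-weight estimation and
# size/shape/border-based region selection.

#' Segmentation parameters
#'
#' @param stopIter number of greedy merges to perform.  `NULL` scales the
#'   reference value of 25,000 (for a 256 x 256 field) proportionally with
#'   pixel count.
#' @param binSeconds temporal bin width used for clustering (s).
#' @param highpassSeconds cutoff period of the slow-drift high-pass (s).
#' @param minSize,maxSize retained region size range (pixels).
#' @param maxDisp dispersion threshold; round regions fall well below it,
#'   elongated ones above (typical 0.5).
#' @param maxBorder maximum ratio of mean border-pixel weight to mean region
#'   weight (typical 0.9).
#' @param weightIterations iterations of the pixel-weight update (typical 3).
#' @return list of class `SegmentationParams`
#' @export
segmentationParams <- function(stopIter = NULL, binSeconds = 30,
                               highpassSeconds = 100, minSize = 8,
                               maxSize = 200, maxDisp = 0.5, maxBorder = 0.9,
                               weightIterations = 3) {
  if (minSize <= 0 || maxSize <= minSize) stopf("need 0 < minSize < maxSize")
  if (maxDisp <= 0) stopf("maxDisp must be positive")
  if (maxBorder <= 0 || maxBorder > 1) stopf("maxBorder must be in (0, 1]")
  structure(list(stopIter = stopIter, binSeconds = binSeconds,
                 highpassSeconds = highpassSeconds, minSize = minSize,
                 maxSize = maxSize, maxDisp = maxDisp, maxBorder = maxBorder,
                 weightIterations = weightIterations),
            class = "SegmentationParams")
}

defaultStopIter <- function(npix) as.integer(round(25000 * npix / (256 * 256)))

#' Preprocess a movie for correlation clustering
#'
#' Temporally bins each pixel time course, removes slow global drifts with a
#' moving-average high-pass (cutoff period `highpassSeconds`), and subtracts
#' each pixel's projection onto the average signal over all pixels.  After
#' preprocessing every pixel is exactly orthogonal to that average signal.
#'
#' @param movie a \linkS4class{CalciumMovie}
#' @param params see [segmentationParams()]
#' @return numeric matrix, time bins x pixels (column-major pixel order)
#' @export
preprocessForClustering <- function(movie, params = segmentationParams()) {
  d <- dim(movie)
  durS <- d[3] / frameRate(movie)
  if (durS < params$binSeconds) stopf("movie shorter than one temporal bin")
  if (durS < 2 * params$highpassSeconds)
    warnf("movie duration (%.0f s) below twice the high-pass period; drift removal will be weak", durS)
  framesPerBin <- max(1L, round(params$binSeconds * frameRate(movie)))
  nBins <- d[3] %/% framesPerBin
  npix <- d[1] * d[2]
  M <- matrix(movie@data, npix, d[3])
  binIdx <- rep(seq_len(nBins), each = framesPerBin)
  B <- t(rowsum(t(M[, seq_len(nBins * framesPerBin), drop = FALSE]), binIdx) / framesPerBin)
  X <- t(B)                                   # bins x pixels

  # moving-average high-pass with the cutoff period expressed in bins
  w <- max(1L, round(params$highpassSeconds / params$binSeconds))
  if (w > 1L && nrow(X) > 1L) {
    kernel <- rep(1 / w, w)
    slow <- apply(X, 2, function(x)
      as.numeric(stats::filter(x, kernel, sides = 2)))
    # fill filter edges with the nearest computed value
    slow <- apply(slow, 2, function(x) {
      ok <- which(!is.na(x))
      if (!length(ok)) return(rep(mean(x, na.rm = TRUE), length(x)))
      x[seq_len(ok[1] - 1)] <- x[ok[1]]
      x[seq((ok[length(ok)] + 1), length.out = length(x) - ok[length(ok)])] <- x[ok[length(ok)]]
      x
    })
    X <- X - slow
  }
  X <- sweep(X, 2, colMeans(X))               # exact DC removal

  g <- rowMeans(X)                            # global mean signal
  gg <- sum(g * g)
  if (gg > 1e-12) {
    proj <- crossprod(X, g) / gg              # npix coefficients
    X <- X - outer(g, as.vector(proj))
  }
  X
}

#' Greedy correlation clustering of pixels into regions
#'
#' At each step the pair of 4-connected neighboring regions with the highest
#' Pearson correlation between their signals is merged; the merged region's
#' signal is the average of the two constituent signals and correlations with
#' its neighbors are recomputed exactly.  Exactly `stopIter` merges are
#' performed.  Correlation ties are broken toward the pair with the lowest
#' (row, col) lexicographic pixel; zero-variance signals get correlation
#' `-Inf` so they merge last.
#'
#' @param signals bins x pixels matrix from [preprocessForClustering()]
#' @param dims `c(rows, cols)` of the field
#' @param params see [segmentationParams()]; `stopIter` may also be given
#'   directly
#' @param stopIter override for the number of merges
#' @return a \linkS4class{RegionSet} (labels only; weights are added by
#'   [computeRegionWeights()] / [segmentMovie()])
#' @export
clusterPixels <- function(signals, dims, params = segmentationParams(),
                          stopIter = NULL) {
  nr <- dims[1]; nc <- dims[2]; npix <- nr * nc
  if (ncol(signals) != npix) stopf("signals has %d columns but field has %d pixels",
                                   ncol(signals), npix)
  if (npix < 2) stopf("need at least 2 pixels")
  I <- if (!is.null(stopIter)) stopIter else
    if (!is.null(params$stopIter)) params$stopIter else defaultStopIter(npix)
  if (I >= npix) stopf("stopIter (%d) must be below the pixel count (%d)", I, npix)
  if (I < 1) stopf("stopIter must be at least 1")

  maxRegions <- npix + I
  sig <- matrix(0, nrow(signals), maxRegions)
  sig[, seq_len(npix)] <- signals
  sdv <- numeric(maxRegions)
  sdv[seq_len(npix)] <- apply(signals, 2, sd)
  active <- c(rep(TRUE, npix), rep(FALSE, I))
  members <- vector("list", maxRegions)
  members[seq_len(npix)] <- as.list(seq_len(npix))
  rowOf <- rep(seq_len(nr), nc); colOf <- rep(seq_len(nc), each = nr)
  minKey <- numeric(maxRegions)
  minKey[seq_len(npix)] <- lexKey(rowOf, colOf, nc)

  adj <- vector("list", maxRegions)
  edgeIdx <- vector("list", maxRegions)

  # initial 4-neighborhood edges (right and down)
  p <- seq_len(npix)
  right <- p[colOf < nc]; down <- p[rowOf < nr]
  ea0 <- c(right, down); eb0 <- c(right + nr, down + 1L)
  nE0 <- length(ea0)
  cap <- nE0 + 6L * I + 16L
  ea <- integer(cap); eb <- integer(cap); ecor <- rep(-Inf, cap)
  ea[seq_len(nE0)] <- ea0; eb[seq_len(nE0)] <- eb0

  corPair <- function(i, j) {
    if (sdv[i] < 1e-14 || sdv[j] < 1e-14) return(-Inf)
    v <- cor(sig[, i], sig[, j])
    if (is.na(v)) -Inf else v
  }
  cc0 <- rep(-Inf, nE0)
  ok <- sdv[ea0] >= 1e-14 & sdv[eb0] >= 1e-14
  if (any(ok)) {
    # vectorized initial correlations
    Z <- scale(signals)
    Z[, !is.finite(colSums(Z))] <- 0
    cc <- colSums(Z[, ea0[ok], drop = FALSE] * Z[, eb0[ok], drop = FALSE]) /
      (nrow(signals) - 1)
    cc0[ok] <- cc
  }
  ecor[seq_len(nE0)] <- cc0
  nE <- nE0
  for (k in seq_len(nE0)) {
    adj[[ea[k]]] <- c(adj[[ea[k]]], eb[k])
    adj[[eb[k]]] <- c(adj[[eb[k]]], ea[k])
    edgeIdx[[ea[k]]] <- c(edgeIdx[[ea[k]]], k)
    edgeIdx[[eb[k]]] <- c(edgeIdx[[eb[k]]], k)
  }

  hist_a <- integer(I); hist_b <- integer(I); hist_new <- integer(I)
  hist_cor <- numeric(I)

  for (step in seq_len(I)) {
    m <- max(ecor[seq_len(nE)])
    cand <- which(ecor[seq_len(nE)] == m)
    if (length(cand) > 1L) {
      k1 <- pmin(minKey[ea[cand]], minKey[eb[cand]])
      k2 <- pmax(minKey[ea[cand]], minKey[eb[cand]])
      cand <- cand[order(k1, k2)][1L]
    }
    a <- ea[cand]; b <- eb[cand]
    newId <- npix + step
    sig[, newId] <- (sig[, a] + sig[, b]) / 2
    sdv[newId] <- sd(sig[, newId])
    members[[newId]] <- c(members[[a]], members[[b]])
    minKey[newId] <- min(minKey[a], minKey[b])
    active[a] <- FALSE; active[b] <- FALSE; active[newId] <- TRUE
    ecor[edgeIdx[[a]]] <- -Inf
    ecor[edgeIdx[[b]]] <- -Inf
    nbrs <- unique(c(adj[[a]], adj[[b]]))
    nbrs <- nbrs[active[nbrs]]
    adj[[newId]] <- nbrs
    for (u in nbrs) {
      nE <- nE + 1L
      ea[nE] <- newId; eb[nE] <- u
      ecor[nE] <- corPair(newId, u)
      edgeIdx[[newId]] <- c(edgeIdx[[newId]], nE)
      edgeIdx[[u]] <- c(edgeIdx[[u]], nE)
      adj[[u]] <- c(adj[[u]], newId)
    }
    hist_a[step] <- a; hist_b[step] <- b; hist_new[step] <- newId
    hist_cor[step] <- if (is.finite(m)) m else NA_real_
    # free signal storage of dead regions lazily (memory only matters for
    # large fields; columns are overwritten anyway)
  }

  labels <- matrix(0L, nr, nc)
  act <- which(active)
  for (r in act) labels[members[[r]]] <- r
  mh <- data.frame(step = seq_len(I), region_a = hist_a, region_b = hist_b,
                   new_region = hist_new, correlation = hist_cor)
  new("RegionSet", labels = labels, weights = list(), mergeHistory = mh)
}

#' Estimate per-pixel weights of a region
#'
#' Weights quantify each pixel's share of the signal common to the region.
#' Starting from uniform weights 1/N, the region signal is formed as the
#' weighted combination of (temporally centred) pixel signals and each
#' pixel's weight is re-estimated as the least-squares loading of that pixel
#' on the region signal; the two steps are alternated `iterations` times
#' (rank-1 alternating least squares, converging to the dominant common
#' component).  Weights are normalised to sum to 1.
#'
#' @param pixelSignals frames x N matrix of the region's raw (full-rate)
#'   pixel time courses
#' @param iterations number of update iterations (default 3)
#' @return numeric vector of N weights summing to 1
#' @export
computeRegionWeights <- function(pixelSignals, iterations = 3) {
  X <- as.matrix(pixelSignals)
  N <- ncol(X)
  if (N < 1) stopf("region must contain at least one pixel")
  X <- sweep(X, 2, colMeans(X))
  w <- rep(1 / N, N)
  for (it in seq_len(iterations)) {
    xreg <- as.vector(X %*% w)
    denom <- sum(xreg^2)
    if (denom < 1e-24) return(rep(1 / N, N))
    w <- as.vector(crossprod(X, xreg)) / denom
    s <- sum(w)
    if (abs(s) > 1e-12) w <- w / s else w <- rep(1 / N, N)
  }
  w
}

# Full-rate pixel signals prepared for weight estimation: temporally centred
# with each pixel's projection onto the global mean signal removed, so that
# weights reflect each pixel's share of the cell's own signal rather than the
# shared neuropil component.
weightSignals <- function(movie) {
  d <- dim(movie)
  M <- matrix(movie@data, d[1] * d[2], d[3])
  M <- M - rowMeans(M)
  g <- colMeans(M)
  gg <- sum(g * g)
  if (gg > 1e-12) M <- M - (M %*% g) %*% matrix(g / gg, 1)
  M
}

regionGeometry <- function(pixels, nr) {
  row <- ((pixels - 1L) %% nr) + 1L
  col <- ((pixels - 1L) %/% nr) + 1L
  cbind(row = row, col = col)
}

#' Region dispersion
#'
#' Mean squared distance of the region's pixels to their centroid, divided by
#' the region size: small for round regions, large for elongated ones.
#'
#' @param pixels linear pixel indices
#' @param nr number of rows of the field
#' @return dispersion (dimensionless)
#' @export
regionDispersion <- function(pixels, nr) {
  g <- regionGeometry(pixels, nr)
  ctr <- colMeans(g)
  mean((g[, 1] - ctr[1])^2 + (g[, 2] - ctr[2])^2) / nrow(g)
}

# region pixels 4-adjacent to any out-of-region pixel (or the field edge)
borderPixels <- function(pixels, nr, nc) {
  inReg <- logical(nr * nc)
  inReg[pixels] <- TRUE
  g <- regionGeometry(pixels, nr)
  isBorder <- logical(length(pixels))
  for (k in seq_along(pixels)) {
    r <- g[k, 1]; c_ <- g[k, 2]
    nb <- c(if (r > 1) pixelIndex(r - 1L, c_, nr),
            if (r < nr) pixelIndex(r + 1L, c_, nr),
            if (c_ > 1) pixelIndex(r, c_ - 1L, nr),
            if (c_ < nc) pixelIndex(r, c_ + 1L, nr))
    isBorder[k] <- (r == 1 || r == nr || c_ == 1 || c_ == nc) || !all(inReg[nb])
  }
  isBorder
}

#' Select neuron-like regions
#'
#' Retains regions that satisfy all three criteria: size between `minSize`
#' and `maxSize` pixels, dispersion below `maxDisp` (round shape), and
#' border-to-overall mean weight ratio below `maxBorder` (pixel contributions
#' decaying toward the region border, as for somata but not neuropil
#' fragments).  Weights for the candidate regions are estimated from the raw
#' movie with [computeRegionWeights()].
#'
#' @param regions a \linkS4class{RegionSet} from [clusterPixels()]
#' @param movie the \linkS4class{CalciumMovie} (raw, full frame rate)
#' @param params see [segmentationParams()]
#' @param include,exclude optional region ids to force-keep or drop
#'   (replacing interactive curation)
#' @return a \linkS4class{RegionSet} with only the retained regions, their
#'   labels renumbered 1..K and weight maps filled in
#' @export
selectNeuronalRegions <- function(regions, movie, params = segmentationParams(),
                                  include = integer(0), exclude = integer(0)) {
  lab <- regionLabels(regions)
  nr <- nrow(lab); nc <- ncol(lab)
  d <- dim(movie)
  M <- weightSignals(movie)
  ids <- sort(unique(lab[lab > 0L]))
  keptIds <- integer(0)
  weights <- list()
  for (id in ids) {
    pixels <- which(lab == id)
    if (id %in% exclude) next
    forced <- id %in% include
    n <- length(pixels)
    if (!forced && (n < params$minSize || n > params$maxSize)) next
    if (!forced && regionDispersion(pixels, nr) >= params$maxDisp) next
    w <- computeRegionWeights(t(M[pixels, , drop = FALSE]),
                              iterations = params$weightIterations)
    if (!forced) {
      bp <- borderPixels(pixels, nr, nc)
      mw <- mean(w)
      if (any(bp) && mw > 1e-15 && mean(w[bp]) / mw >= params$maxBorder) next
    }
    keptIds <- c(keptIds, id)
    g <- regionGeometry(pixels, nr)
    weights[[length(weights) + 1L]] <-
      data.frame(row = g[, 1], col = g[, 2], weight = w)
  }
  newLab <- matrix(0L, nr, nc)
  for (k in seq_along(keptIds)) newLab[lab == keptIds[k]] <- k
  names(weights) <- as.character(seq_along(keptIds))
  new("RegionSet", labels = newLab, weights = weights,
      mergeHistory = mergeHistory(regions))
}

#' Full segmentation of a movie
#'
#' Convenience wrapper: [preprocessForClustering()], [clusterPixels()] and
#' [selectNeuronalRegions()] in sequence.
#'
#' @inheritParams selectNeuronalRegions
#' @param stopIter optional override of the merge count
#' @return a \linkS4class{RegionSet}
#' @export
segmentMovie <- function(movie, params = segmentationParams(), stopIter = NULL) {
  signals <- preprocessForClustering(movie, params)
  regions <- clusterPixels(signals, dim(movie)[1:2], params, stopIter = stopIter)
  selectNeuronalRegions(regions, movie, params)
}

#' Match segmented regions to ground-truth masks
#'
#' Greedy best-IoU (intersection over union) assignment of regions to planted
#' masks.
#'
#' @param regions a \linkS4class{RegionSet}
#' @param masks list of integer pixel-index vectors (ground truth)
#' @return data.frame with one row per mask: `mask`, `region` (0 if none
#'   overlaps) and `iou`
#' @export
matchRegionsToMasks <- function(regions, masks) {
  lab <- regionLabels(regions)
  ids <- sort(unique(lab[lab > 0L]))
  regionPix <- lapply(ids, function(id) which(lab == id))
  out <- data.frame(mask = seq_along(masks), region = 0L, iou = 0)
  for (mi in seq_along(masks)) {
    best <- 0; bestId <- 0L
    for (k in seq_along(ids)) {
      inter <- length(intersect(masks[[mi]], regionPix[[k]]))
      if (inter == 0) next
      iou <- inter / length(union(masks[[mi]], regionPix[[k]]))
      if (iou > best) { best <- iou; bestId <- ids[k] }
    }
    out$region[mi] <- bestId
    out$iou[mi] <- best
  }
  out
}
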