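# Spatial organisation: nearest neighbor index (NNI), label-shuffle
# permutation tests, simulated clustered maps and starter-cell ensemble
# decoding.

#' Construct a cell map
#'
#' @param x,y cell positions in micrometres
#' @param label functional class per cell (preferred odorant, invariance
#'   flag, ...)
#' @param bounds field bounds `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   range of the positions
#' @return data.frame of class `CellMap` with columns `cell`, `x`, `y`,
#'   `label` and a `bounds` attribute
#' @export
cellMap <- function(x, y, label, bounds = NULL) {
  if (is.null(bounds)) bounds <- c(min(x), max(x), min(y), max(y))
  out <- data.frame(cell = seq_along(x), x = x, y = y,
                    label = as.character(label), stringsAsFactors = FALSE)
  attr(out, "bounds") <- bounds
  class(out) <- c("CellMap", "data.frame")
  out
}

#' Random non-overlapping cell positions
#'
#' Jittered-grid positions for a population of somata: cells sit on a square
#' grid with spacing `2.5 * radiusUm` and are jittered by up to half a
#' radius, which keeps all pairs farther apart than a cell diameter.
#'
#' @param n number of cells
#' @param radiusUm soma radius in micrometres
#' @param seed RNG seed
#' @return n x 2 matrix of (x, y) positions in micrometres
#' @export
randomCellPositions <- function(n, radiusUm = 5, seed = 1) {
  side <- ceiling(sqrt(n))
  spacing <- 2.5 * radiusUm
  g <- expand.grid(gx = seq_len(side), gy = seq_len(side))
  withSeed(seed, {
    g <- g[sample.int(nrow(g), n), ]
    cbind(x = g$gx * spacing + runif(n, -radiusUm / 2, radiusUm / 2),
          y = g$gy * spacing + runif(n, -radiusUm / 2, radiusUm / 2))
  })
}

nniFromDistances <- function(D, idx) {
  if (length(idx) < 2) return(NA_real_)
  mean(rowMins(D[idx, idx, drop = FALSE]))
}

#' Nearest neighbor index of a cell class
#'
#' Mean Euclidean distance from each cell of class `class` to the nearest
#' other cell of the same class (micrometres).  Small values indicate
#' spatial clustering.  `NA` when the class has fewer than 2 members.
#'
#' @param map a `CellMap` (see [cellMap()])
#' @param class class label
#' @return NNI in micrometres
#' @export
nearestNeighborIndex <- function(map, class) {
  idx <- which(map$label == class)
  if (length(idx) < 2) return(NA_real_)
  D <- as.matrix(dist(cbind(map$x, map$y)))
  diag(D) <- Inf
  nniFromDistances(D, idx)
}

#' Label-shuffle permutation test of the NNI
#'
#' Compares the observed per-class NNIs (and a class-size-weighted pooled
#' NNI) against `nShuffles` maps with labels randomly permuted over the
#' fixed cell positions.  One-sided p-values toward clustering use the
#' add-one estimator `p = (#\{shuffled NNI <= observed\} + 1)/(n + 1)`.
#'
#' @param map a `CellMap`
#' @param nShuffles number of shuffled maps (default 1000)
#' @param seed RNG seed
#' @return list: `perClass` (data.frame class/n/nni/p) and `pooled`
#'   (observed pooled NNI and its p)
#' @export
nniShuffleTest <- function(map, nShuffles = 1000, seed = 1) {
  D <- as.matrix(dist(cbind(map$x, map$y)))
  diag(D) <- Inf
  classes <- sort(unique(map$label))
  sizes <- vapply(classes, function(cl) sum(map$label == cl), 0L)
  usable <- sizes >= 2
  obs <- vapply(classes, function(cl)
    nniFromDistances(D, which(map$label == cl)), 0)
  pooledObs <- weightedPooledNni(obs, sizes, usable)
  nullClass <- matrix(NA_real_, nShuffles, length(classes))
  nullPooled <- numeric(nShuffles)
  withSeed(seed, {
    n <- nrow(map)
    for (b in seq_len(nShuffles)) {
      lab <- map$label[sample.int(n)]
      v <- vapply(classes, function(cl)
        nniFromDistances(D, which(lab == cl)), 0)
      nullClass[b, ] <- v
      nullPooled[b] <- weightedPooledNni(v, sizes, usable)
    }
  })
  pClass <- vapply(seq_along(classes), function(j) {
    if (!usable[j]) return(NA_real_)
    (sum(nullClass[, j] <= obs[j], na.rm = TRUE) + 1) / (nShuffles + 1)
  }, 0)
  list(perClass = data.frame(class = classes, n = as.integer(sizes),
                             nni = obs, p = pClass),
       pooled = list(nni = pooledObs,
                     p = (sum(nullPooled <= pooledObs) + 1) / (nShuffles + 1)))
}

weightedPooledNni <- function(nni, sizes, usable) {
  if (!any(usable)) return(NA_real_)
  sum(nni[usable] * sizes[usable]) / sum(sizes[usable])
}

#' Simulate a spatially clustered map
#'
#' Simulates a population with subtle spatial inhomogeneity: the field is
#' divided into a 4x4 grid of equally sized sub-areas and each class is
#' allowed to occur in only 3 or 4 randomly chosen sub-areas; cells of the
#' class are placed uniformly inside its allowed sub-areas.  Class labels and
#' sizes are preserved, positions are re-drawn.
#'
#' @param map a `CellMap` (supplies labels, class sizes and field bounds)
#' @param nSubareas number of sub-areas (must be a square number; default 16)
#' @param areasPerClass sub-areas allowed per class (drawn from this set)
#' @param seed RNG seed
#' @return a `CellMap` with the same labels and new clustered positions
#' @export
simulateClusteredMap <- function(map, nSubareas = 16, areasPerClass = c(3, 4),
                                 seed = 1) {
  side <- sqrt(nSubareas)
  if (side != round(side)) stopf("nSubareas must be a square number")
  b <- attr(map, "bounds")
  if (b[2] <= b[1] || b[4] <= b[3]) stopf("degenerate field bounds")
  wx <- (b[2] - b[1]) / side; wy <- (b[4] - b[3]) / side
  classes <- unique(map$label)
  out <- map
  withSeed(seed, {
    for (cl in classes) {
      idx <- which(map$label == cl)
      k <- if (length(areasPerClass) > 1) sample(areasPerClass, 1) else areasPerClass
      allowed <- sample.int(nSubareas, min(k, nSubareas))
      a <- allowed[sample.int(length(allowed), length(idx), replace = TRUE)]
      ax <- (a - 1) %% side; ay <- (a - 1) %/% side
      out$x[idx] <- b[1] + (ax + runif(length(idx))) * wx
      out$y[idx] <- b[3] + (ay + runif(length(idx))) * wy
    }
  })
  out
}

#' Starter-cell ensemble decoding
#'
#' Defines every cell in turn as a starter, grows ensembles of the `k`
#' spatially nearest cells (starter included) for each requested size, and
#' reports the leave-one-out decoding accuracy of each ensemble.
#'
#' @param map a `CellMap` aligned with the rows of `rs`
#' @param rs a \linkS4class{ResponseSet}
#' @param sizes ensemble sizes
#' @param starters starter cells (defaults to all)
#' @param method,varFrac passed to [classifyLoo()]
#' @return matrix of accuracies, starters x sizes
#' @export
starterCellEnsembles <- function(map, rs, sizes, starters = seq_len(nrow(map)),
                                 method = "lda", varFrac = 0.95) {
  if (nrow(map) != nrow(rs)) stopf("map and responses must cover the same cells")
  if (any(sizes > nrow(map))) stopf("ensemble size exceeds the cell count")
  D <- as.matrix(dist(cbind(map$x, map$y)))
  m <- responseMatrix(rs)
  labs <- paste0(odorant(rs), "@", dilution(rs))
  out <- matrix(NA_real_, length(starters), length(sizes),
                dimnames = list(starters, sizes))
  for (si in seq_along(starters)) {
    ord <- order(D[starters[si], ])           # starter first (distance 0)
    for (ki in seq_along(sizes)) {
      ens <- ord[seq_len(sizes[ki])]
      out[si, ki] <- classifyLoo(t(m[ens, , drop = FALSE]), labs,
                                 method, varFrac)$accuracy
    }
  }
  out
}
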