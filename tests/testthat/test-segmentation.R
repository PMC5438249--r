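test_that("preprocessing removes DC, global sinusoids and the mean-signal projection", {
  # constant movie -> all-zero signals
  mv <- CalciumMovie(array(7, c(4, 4, 200)), frameRate = 1)
  p <- segmentationParams(binSeconds = 5, highpassSeconds = 50)
  sig <- suppressWarnings(preprocessForClustering(mv, p))
  expect_lt(max(abs(sig)), 1e-10)

  # identical global sinusoid in every pixel -> zero after projection removal
  s <- sin(2 * pi * seq_len(200) / 20)
  arr <- array(rep(s, each = 16), c(4, 4, 200))
  sig2 <- suppressWarnings(preprocessForClustering(CalciumMovie(arr, 1), p))
  expect_lt(max(abs(sig2)), 1e-10)

  # synthetic movie: residual projection onto the global mean signal is zero
  gm <- generateMovie(segTestConfig(fieldSize = c(32, 32), nCells = 8, seed = 7))
  sig3 <- preprocessForClustering(gm$movie, segTestParams())
  g <- rowMeans(sig3)
  expect_lt(max(abs(crossprod(sig3, g))), 1e-10)

  expect_error(preprocessForClustering(
    CalciumMovie(array(1, c(2, 2, 3)), frameRate = 1),
    segmentationParams(binSeconds = 10)), "bin")
})

test_that("greedy clustering merges the planted pairs of the toy movie first", {
  tm <- toyMovie()
  signals <- t(matrix(movieData(tm), 9, 6))     # frames x pixels
  # oracle: enumerate all 4-neighbor correlations and confirm the planted
  # pairs (pixels 1&4, 6&9 in column-major order) are the two top pairs
  nbr <- function(a, b) cor(signals[, a], signals[, b])
  pairs <- rbind(c(1, 4), c(4, 7), c(2, 5), c(5, 8), c(3, 6), c(6, 9),
                 c(1, 2), c(2, 3), c(4, 5), c(5, 6), c(7, 8), c(8, 9))
  cc <- apply(pairs, 1, function(p) nbr(p[1], p[2]))
  top2 <- pairs[order(-cc)[1:2], ]
  expect_setequal(c(t(top2)), c(1, 4, 6, 9))

  reg <- clusterPixels(signals, c(3, 3), stopIter = 4)
  mh <- mergeHistory(reg)
  expect_setequal(c(mh$region_a[1], mh$region_b[1]), c(1, 4))
  expect_setequal(c(mh$region_a[2], mh$region_b[2]), c(6, 9))
  expect_equal(mh$correlation[1:2], c(1, 1))
})

test_that("identical neighboring pixels merge first with correlation one", {
  set.seed(9)
  signals <- matrix(rnorm(10 * 6), 10, 6)
  signals[, 2] <- signals[, 1]                  # pixels (1,1) and (2,1)
  reg <- clusterPixels(signals, c(2, 3), stopIter = 1)
  mh <- mergeHistory(reg)
  expect_equal(sort(c(mh$region_a[1], mh$region_b[1])), c(1, 2))
  expect_equal(mh$correlation[1], 1)
})

test_that("clustering is deterministic and produces 4-connected regions", {
  gm <- generateMovie(segTestConfig(fieldSize = c(32, 32), nCells = 8, seed = 13))
  sig <- preprocessForClustering(gm$movie, segTestParams())
  r1 <- clusterPixels(sig, c(32, 32), stopIter = 900)
  r2 <- clusterPixels(sig, c(32, 32), stopIter = 900)
  expect_identical(regionLabels(r1), regionLabels(r2))

  lab <- regionLabels(r1)
  connected <- function(px, nr, nc) {
    if (length(px) == 1) return(TRUE)
    seen <- px[1]; frontier <- px[1]
    while (length(frontier)) {
      r <- ((frontier - 1) %% nr) + 1; c_ <- ((frontier - 1) %/% nr) + 1
      nb <- c(frontier[r > 1] - 1, frontier[r < nr] + 1,
              frontier[c_ > 1] - nr, frontier[c_ < nc] + nr)
      frontier <- setdiff(intersect(nb, px), seen)
      seen <- union(seen, frontier)
    }
    length(seen) == length(px)
  }
  ids <- setdiff(unique(as.vector(lab)), 0)
  bigIds <- ids[tabulate(match(lab, ids))[match(ids, ids)] > 1]
  set.seed(2)
  for (id in sample(bigIds, min(25, length(bigIds))))
    expect_true(connected(which(lab == id), 32, 32))
})

test_that("stop-iteration bounds are enforced", {
  sig <- matrix(rnorm(40), 10, 4)
  expect_error(clusterPixels(sig, c(2, 2), stopIter = 4), "stopIter")
  expect_error(clusterPixels(sig, c(2, 2), stopIter = 0), "stopIter")
})

test_that("region weights follow the per-iteration least-squares oracle", {
  set.seed(8)
  s <- rnorm(300)
  a <- c(0.2, 0.5, 1, 0.8, 0.3)
  X <- sapply(a, function(ai) ai * s + rnorm(300, 0, 0.05))
  w <- computeRegionWeights(X, iterations = 3)

  oracle <- function(X, iters) {
    X <- sweep(X, 2, colMeans(X))
    w <- rep(1 / ncol(X), ncol(X))
    for (i in seq_len(iters)) {
      xr <- X %*% w
      # independent normal-equations solve of each pixel's loading on xr
      w <- vapply(seq_len(ncol(X)), function(j)
        solve(crossprod(xr), crossprod(xr, X[, j]))[1, 1], 0)
      w <- w / sum(w)
    }
    w
  }
  expect_equal(w, oracle(X, 3), tolerance = 1e-12)
  # weights track the true per-pixel signal share
  expect_gt(cor(w, a), 0.99)

  expect_equal(computeRegionWeights(matrix(rnorm(50), ncol = 1)), 1)
  z <- rnorm(50)
  expect_equal(computeRegionWeights(cbind(z, z)), c(0.5, 0.5))
})

test_that("region selection applies the size, dispersion and border criteria", {
  # dispersion: a disk beats a line of equal area, which is rejected
  nr <- 21
  rows <- matrix(seq_len(nr), nr, nr); cols <- t(rows)
  disk <- which((rows - 11)^2 + (cols - 11)^2 <= 9)
  line <- which(rows == 1 & cols <= length(disk))
  dDisk <- regionDispersion(disk, nr)
  dLine <- regionDispersion(line, nr)
  expect_lt(dDisk, dLine)
  expect_lt(dDisk, 0.5)
  expect_gt(dLine, 0.5)

  # build a movie where region 1 is a single pixel (too small), region 2 a
  # disk with donut-profiled signal (kept), region 3 a disk with spatially
  # uniform signal (border ratio 1 -> rejected)
  set.seed(5)
  nFrames <- 120
  lab <- matrix(0L, nr, nr)
  lab[2, 2] <- 1L
  lab[disk] <- 2L
  disk2 <- which((rows - 11)^2 + (cols - 3 + 14)^2 <= 9)   # off-field guard
  arr <- array(rnorm(nr * nr * nFrames, 100, 1), c(nr, nr, nFrames))
  s <- rnorm(nFrames, 0, 5)
  d <- sqrt((rows - 11)^2 + (cols - 11)^2)
  prof <- exp(-(d / 2)^2)
  for (px in disk) arr[((px - 1) %% nr) + 1, ((px - 1) %/% nr) + 1, ] <-
    100 + prof[px] * s + rnorm(nFrames)
  mv <- CalciumMovie(arr, frameRate = 1)
  regions <- new("RegionSet", labels = lab, weights = list(),
                 mergeHistory = data.frame(step = integer(0),
                                           region_a = integer(0),
                                           region_b = integer(0),
                                           new_region = integer(0),
                                           correlation = numeric(0)))
  p <- segmentationParams(minSize = 3, maxSize = 100, maxDisp = 0.5,
                          maxBorder = 0.9)
  sel <- selectNeuronalRegions(regions, mv, p)
  expect_equal(length(sel), 1L)                # only the profiled disk
  w <- regionWeights(sel, regionIds(sel)[1])
  expect_equal(nrow(w), length(disk))

  # uniform signal share -> border ratio ~1 -> rejected at maxBorder 0.9
  arrU <- array(rnorm(nr * nr * nFrames, 100, 1), c(nr, nr, nFrames))
  for (px in disk) arrU[((px - 1) %% nr) + 1, ((px - 1) %/% nr) + 1, ] <-
    100 + s + rnorm(nFrames, 0, 0.1)
  selU <- selectNeuronalRegions(regions, CalciumMovie(arrU, 1), p)
  expect_equal(length(selU), 0L)
})

test_that("most planted cells are recovered as single regions at the merge plateau", {
  cfg <- segTestConfig(fieldSize = c(48, 48), nCells = 15, seed = 7)
  gm <- generateMovie(cfg)
  params <- segTestParams()
  sig <- preprocessForClustering(gm$movie, params)
  reg <- clusterPixels(sig, c(48, 48), params, stopIter = 48 * 48 - 120)
  sel <- selectNeuronalRegions(reg, gm$movie, params)
  mm <- matchRegionsToMasks(sel, cellMasks(gm$truth))
  expect_gte(mean(mm$iou >= 0.5), 0.85)
  # recovered regions are unique (one region per planted cell)
  hit <- mm$region[mm$iou >= 0.5]
  expect_equal(anyDuplicated(hit), 0)
})
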