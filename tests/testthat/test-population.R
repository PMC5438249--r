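test_that("population vectors are window means of the deconvolved signal", {
  cfg <- simConfig(nCells = 5, frameRate = 15, stimulusSet = stimulusPanel(2),
                   trialNoiseSd = 0.02, seed = 3)
  tt <- generateTrialTraces(cfg)
  rs <- buildPopulationVectors(tt$tensor, windowS = 4)
  expect_s4_class(rs, "ResponseSet")
  expect_equal(dim(responseMatrix(rs)), c(5L, 8L))
  # frame-mean oracle on one entry
  win <- (8 * 15 + 1):(12 * 15)
  expect_equal(unname(responseMatrix(rs)[3, 1]),
               mean(tt$tensor@data[3, 1, 1, win]))

  # constant signal in the window -> that constant; zero cell -> zeros
  arr <- array(0, c(2, 1, 2, 450))
  arr[1, 1, , ] <- 0.4
  tens <- new("TrialTensor", data = arr,
              stimuli = data.frame(odorant = "o", dilution = 1e-4),
              layout = c(pre = 8, odor = 2, post = 20), frameRate = 15,
              signal = "rate")
  rc <- responseMatrix(buildPopulationVectors(tens))
  expect_equal(unname(rc[1, ]), c(0.4, 0.4))
  expect_equal(unname(rc[2, ]), c(0, 0))
})

test_that("trial correlation matrices follow the Pearson formula", {
  set.seed(3)
  m <- matrix(rnorm(30), 10, 3)
  C <- correlationMatrix(m)
  for (i in 1:3) for (j in 1:3) {
    x <- m[, i]; y <- m[, j]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(C[i, j], r)
  }
  # duplicated trial and negated trial
  m2 <- cbind(m, m[, 1], -m[, 1])
  C2 <- correlationMatrix(m2)
  expect_equal(C2[1, 4], 1)
  expect_equal(C2[1, 5], -1)
  # zero-variance vector reported as missing
  C3 <- correlationMatrix(cbind(m, 0))
  expect_true(all(is.na(C3[, 4])))
  expect_error(correlationMatrix(matrix(1, 1, 3)), "2 cells")
})

test_that("correlation summaries group trials by stimulus relation", {
  means <- matrix(rnorm(20 * 9), 20, 9)
  rs <- responseSetFromMeans(means, noiseSd = 0)
  C <- correlationMatrix(rs)
  sm <- summarizeCorrelations(C, odorant(rs), dilution(rs))
  # identical trials within a stimulus -> intra-stimulus mean exactly 1
  expect_equal(sm$meanCor[sm$group == "intra_stimulus"], 1)
  expect_equal(sm$nPairs[sm$group == "intra_stimulus"], 9 * choose(4, 2))

  # block-structured construction: known within/between correlation levels
  set.seed(5)
  shared <- rnorm(400)
  perOdor <- replicate(3, rnorm(400))
  perStim <- matrix(0, 400, 9)
  stim <- concentrationSeries()
  for (s in 1:9) perStim[, s] <- shared + 2 * perOdor[, match(stim$odorant[s],
                                                             unique(stim$odorant))]
  rs2 <- responseSetFromMeans(perStim, noiseSd = 0.8, seed = 6)
  C2 <- correlationMatrix(rs2)
  sm2 <- summarizeCorrelations(C2, odorant(rs2), dilution(rs2))
  intra <- sm2$meanCor[sm2$group == "intra_stimulus"]
  sameOd <- sm2$meanCor[grepl("intra_odorant", sm2$group)]
  inter <- sm2$meanCor[sm2$group == "inter_odorant"]
  expect_equal(mean(sameOd), intra, tolerance = 0.02)
  expect_lt(inter, intra - 0.2)

  # a single odorant leaves the inter-odorant group empty
  one <- ResponseSet(matrix(rnorm(40), 10, 4), odorant = rep("a", 4),
                     dilution = rep(1e-4, 4), trial = 1:4)
  smo <- summarizeCorrelations(correlationMatrix(one), odorant(one), dilution(one))
  expect_true(is.na(smo$meanCor[smo$group == "inter_odorant"]))
})

test_that("lifetime sparseness matches its closed form and bounds", {
  expect_equal(lifetimeSparseness(rep(3, 13)), 0)
  expect_equal(lifetimeSparseness(c(5, rep(0, 12))), 1)
  expect_equal(lifetimeSparseness(c(1, 1, 0, 0)), 2 / 3)
  expect_equal(lifetimeSparseness(rep(0, 8)), 0)
  # invariant to positive scaling; negatives clipped before evaluation
  r <- c(0.5, 0.1, 0, 0.9, 0.2)
  expect_equal(lifetimeSparseness(r), lifetimeSparseness(17 * r))
  expect_equal(lifetimeSparseness(c(r, -0.4)), lifetimeSparseness(c(r, 0)))
  expect_error(lifetimeSparseness(1), "2 stimuli")
  # per-cell table path: one-hot odorant tuning at a fixed dilution
  means <- matrix(0, 2, 9)
  means[1, ] <- rep(c(1, 0, 0), each = 3)   # odorant 1 only, all dilutions
  means[2, ] <- 0.5
  rs <- responseSetFromMeans(means, noiseSd = 0)
  sl <- sparsenessByCell(rs, atDilution = 1e-4)
  expect_equal(unname(sl), c(1, 0))
  expect_length(sparsenessByCell(rs), 2)
})

test_that("responsive fractions average flagged cells over trials", {
  flags <- expand.grid(cell = 1:10, odorant = "a", dilution = 1e-4,
                       trial = 1:4, stringsAsFactors = FALSE)
  flags$flag <- "none"
  expect_equal(responsiveFractions(flags)$pctActivated, 0)
  flags$flag <- "act"
  expect_equal(responsiveFractions(flags)$pctActivated, 100)
  # one cell flagged on 2 of 4 trials, population of one
  f1 <- data.frame(cell = 1, odorant = "a", dilution = 1e-4, trial = 1:4,
                   flag = c("act", "act", "none", "none"))
  expect_equal(responsiveFractions(f1)$pctActivated, 50)
})

test_that("the 2-of-4 reliability filter selects cells and their preference", {
  flags <- rbind(
    data.frame(cell = 1, odorant = "A", dilution = 1e-4, trial = 1:4,
               flag = c("act", "none", "none", "none")),
    data.frame(cell = 2, odorant = "A", dilution = 1e-4, trial = 1:4,
               flag = c("act", "act", "none", "none")),
    data.frame(cell = 2, odorant = "B", dilution = 1e-4, trial = 1:4,
               flag = c("act", "act", "act", "none")))
  m <- matrix(0, 2, 8)
  m[2, 1:4] <- 0.2; m[2, 5:8] <- 0.5
  rs <- ResponseSet(m, odorant = rep(c("A", "B"), each = 4),
                    dilution = 1e-4, trial = rep(1:4, 2))
  tf <- tuningFilter(flags, rs)
  expect_false(1 %in% tf$kept$cell)           # 1-of-4 responder excluded
  expect_setequal(tf$kept$odorant[tf$kept$cell == 2], c("A", "B"))
  expect_equal(tf$preferred$odorant[tf$preferred$cell == 2], "B")
})

test_that("PCA projection reports variance and is rotation invariant", {
  set.seed(2)
  # 1-D embedded data: first component captures everything
  u <- rnorm(12)
  X <- outer(u, c(1, 2, -1))                  # trials x cells, rank 1
  p1 <- pcaProject(t(X), nComponents = 2)
  expect_equal(p1$varianceExplained[1], 1)

  m <- matrix(rnorm(50), 10, 5)               # trials x cells
  p <- pcaProject(t(m), nComponents = 5)
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  pR <- pcaProject(t(m %*% Q), nComponents = 5)
  expect_equal(p$fullSpectrum, pR$fullSpectrum, tolerance = 1e-9)
  # completeness: reconstruction from all components returns the input
  pc <- prcomp(m, center = TRUE)
  rec <- sweep(pc$x %*% t(pc$rotation), 2, -pc$center)
  expect_equal(rec, m, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pcaProject(t(m[1:2, ]), nComponents = 3), "components")
})

test_that("hierarchical sorting keeps similar rows together", {
  expect_equal(hierarchicalSort(matrix(1, 1, 4)), 1L)
  set.seed(4)
  a <- rnorm(20)
  m <- rbind(a + rnorm(20, 0, 0.01), rnorm(20), a + rnorm(20, 0, 0.01))
  ord <- hierarchicalSort(m)
  expect_equal(abs(which(ord == 1) - which(ord == 3)), 1)
  # two planted blocks remain contiguous
  b <- rnorm(20)
  blk <- rbind(t(replicate(4, a + rnorm(20, 0, 0.1))),
               t(replicate(4, b + rnorm(20, 0, 0.1))))
  ob <- hierarchicalSort(blk)
  pos1 <- sort(match(1:4, ob)); pos2 <- sort(match(5:8, ob))
  expect_true(all(diff(pos1) == 1))
  expect_true(all(diff(pos2) == 1))
})
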