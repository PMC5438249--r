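makeScene <- function(seed = 3) {
  set.seed(seed)
  base <- matrix(0, 48, 48)
  base[15:20, 22:28] <- 5; base[30:38, 10:14] <- 3
  base + matrix(runif(48 * 48), 48, 48) * 0.1
}

test_that("planted frame shifts are recovered and undone", {
  base <- makeScene()
  shiftInt <- function(m, dy, dx) {
    n <- nrow(m); p <- ncol(m)
    m[((seq_len(n) - 1 - dy) %% n) + 1, ((seq_len(p) - 1 - dx) %% p) + 1]
  }
  arr <- array(0, c(48, 48, 4))
  arr[, , 1] <- base
  arr[, , 2] <- shiftInt(base, 3, -2)
  arr[, , 3] <- shiftInt(base, -1, 4)
  arr[, , 4] <- base
  reg <- registerFrames(CalciumMovie(arr, 15), refFrames = 1)
  expect_equal(unname(reg$shifts[2, ]), c(3, -2))
  expect_equal(unname(reg$shifts[3, ]), c(-1, 4))
  expect_equal(unname(reg$shifts[c(1, 4), ]), matrix(0, 2, 2))
  for (t in 1:4)
    expect_lt(max(abs(movieData(reg$movie)[, , t] - base)), 1e-8)
})

test_that("subpixel shifts are recovered within a tenth of a pixel", {
  base <- makeScene(4)
  shifted <- pirinv:::applyShift(base, 0.5, -0.3)
  s <- pirinv:::estimateShift(fft(base), fft(shifted), usfac = 10)
  # applyShift displaces content by the negated arguments
  expect_lt(max(abs(s - c(-0.5, 0.3))), 0.1)
})

test_that("all-zero frames register with zero shift and a warning", {
  arr <- array(1, c(8, 8, 3)); arr[, , 2] <- 0
  expect_warning(reg <- registerFrames(CalciumMovie(arr, 1), refFrames = 1),
                 "zero")
  expect_equal(unname(reg$shifts[2, ]), c(0, 0))
})

test_that("trace extraction is the weighted pixel average", {
  set.seed(6)
  arr <- array(rnorm(5 * 5 * 40, 100, 3), c(5, 5, 40))
  mv <- CalciumMovie(arr, 10)
  mkRegion <- function(df) new("RegionSet",
    labels = {
      l <- matrix(0L, 5, 5)
      l[cbind(df$row, df$col)] <- 1L
      l
    },
    weights = list("1" = df),
    mergeHistory = data.frame())

  one <- mkRegion(data.frame(row = 2, col = 3, weight = 1))
  expect_equal(as.vector(extractTraces(mv, one)), arr[2, 3, ])

  unif <- mkRegion(data.frame(row = c(1, 1, 2), col = c(1, 2, 1),
                              weight = rep(1 / 3, 3)))
  expect_equal(as.vector(extractTraces(mv, unif)),
               colMeans(rbind(arr[1, 1, ], arr[1, 2, ], arr[2, 1, ])))

  bad <- mkRegion(data.frame(row = 1, col = 1, weight = 0))
  expect_error(extractTraces(mv, bad), "zero")
})

test_that("donut weights track the event kernel at least as well as a plain mean", {
  cfg <- simConfig(fieldSize = c(32, 32), nCells = 1, frameRate = 5,
                   cellRadius = 5, pixelSize = 1.4,
                   stimulusSet = stimulusPanel(1), nTrialsPerStimulus = 4,
                   fractionActivated = 1, fractionSuppressed = 0,
                   fractionBroad = 0, fractionInvariant = 0,
                   fractionMixed = 0, pRespond = 1, trialNoiseSd = 0,
                   neuropilAmplitude = 0, movieNoiseSd = 3, seed = 9)
  gm <- generateMovie(cfg)
  px <- cellMasks(gm$truth)[[1]]
  M <- matrix(movieData(gm$movie), 32 * 32, dim(gm$movie)[3])
  X <- t(M[px, ])
  w <- computeRegionWeights(X)
  truthTrace <- rep(0, dim(gm$movie)[3])
  ev <- gm$truth@events
  fr <- frameRate(gm$movie)
  for (k in seq_len(nrow(ev))) {
    f0 <- round(ev$onset_s[k] * fr) + 1
    idx <- f0:length(truthTrace)
    truthTrace[idx] <- truthTrace[idx] +
      ev$amplitude[k] * exp(-(seq_along(idx) - 1) / (fr * cfg@kernelTau))
  }
  weighted <- as.vector(X %*% w) / sum(w)
  plain <- rowMeans(X)
  expect_gte(cor(weighted, truthTrace) + 1e-10, cor(plain, truthTrace))
})

test_that("neuropil correction inverts the planted contamination", {
  set.seed(12)
  nr <- 31
  arr <- array(0, c(nr, nr, 60))
  bg <- 50 + 10 * sin(seq_len(60) / 4)
  cellSig <- 100 + c(rep(0, 20), 30 * exp(-(1:40) / 10))
  rows <- matrix(seq_len(nr), nr, nr); cols <- t(rows)
  cellPx <- which((rows - 16)^2 + (cols - 16)^2 <= 4)
  for (t in 1:60) {
    fr <- matrix(bg[t], nr, nr)
    fr[cellPx] <- cellSig[t] + 0.5 * bg[t]
    arr[, , t] <- fr
  }
  mv <- CalciumMovie(arr, 5, pixelSize = 2)
  lab <- matrix(0L, nr, nr); lab[cellPx] <- 1L
  g <- pirinv:::regionGeometry(cellPx, nr)
  regions <- new("RegionSet", labels = lab,
                 weights = list("1" = data.frame(row = g[, 1], col = g[, 2],
                                                 weight = rep(1 / length(cellPx),
                                                              length(cellPx)))),
                 mergeHistory = data.frame())
  tr <- as.vector(extractTraces(mv, regions))
  corr <- neuropilCorrect(tr, mv, regions, 1, radiusUm = 20, r = 0.5)
  expect_equal(corr, cellSig, tolerance = 1e-10)
  expect_identical(neuropilCorrect(tr, mv, regions, 1, r = 0), tr)
})

test_that("dF/F uses the 4-8 s baseline median", {
  fr <- 15
  x <- rep(80, 450)
  expect_equal(computeDff(x, fr), rep(0, 450))
  y <- x; y[150:200] <- 80 * 1.4
  expect_equal(max(computeDff(y, fr)), 0.4)
  # linear drift: F0 must equal the independent median of the 4-8 s frames
  z <- 100 + 0.05 * seq_len(450)
  F0 <- median(z[(4 * fr + 1):(8 * fr)])
  expect_equal(computeDff(z, fr), (z - F0) / F0)
  # non-positive baseline invalidates the trial
  expect_true(all(is.na(computeDff(rep(-1, 450), fr))))
})

test_that("deconvolution inverts the exponential kernel", {
  tau <- 2
  runFor <- function(fr) {
    t <- seq(0, 30 - 1 / fr, by = 1 / fr)
    f <- ifelse(t >= 8, 0.7 * exp(-(t - 8) / tau), 0)
    r <- deconvolve(f, tau, fr, filter = FALSE)
    peak <- which.max(r)
    list(r = r, peak = peak, area = sum(r) / fr,
         offPeak = max(abs(r[-c(peak - 1, peak, peak + 1)])))
  }
  r15 <- runFor(15)
  expect_equal(r15$peak, 8 * 15, tolerance = 0)   # forward difference: onset frame - 1
  expect_equal(r15$area, 0.7, tolerance = 0.05)
  # decay tail is an eigenfunction: residual O(1/frameRate), shrinking at 60 Hz
  r60 <- runFor(60)
  expect_lt(r60$offPeak, r15$offPeak / 2)
  expect_lt(r15$offPeak, 0.7 / (2 * tau^2) / 15 * 3)

  # constant trace deconvolves to c/tau
  cst <- deconvolve(rep(3, 300), tau, 15, filter = FALSE)
  expect_equal(cst[-300], rep(3 / tau, 299))

  expect_error(deconvolve(rep(0, 10), tau = -1, 15), "tau")
  expect_error(deconvolve(rep(0, 10), tau = 2, frameRate = 4), "cutoff")
})

test_that("an impulse train is recovered up to discretisation", {
  tau <- 2; fr <- 15
  n <- 450
  impulses <- rep(0, n); impulses[c(121, 241)] <- c(0.5, 0.3)
  kern <- exp(-(0:(n - 1)) / (fr * tau))
  f <- stats::convolve(impulses, rev(kern), type = "open")[seq_len(n)]
  r <- deconvolve(f, tau, fr, filter = FALSE)
  # peaks land one frame before each planted onset (forward difference)
  pk <- order(r, decreasing = TRUE)[1:2]
  expect_setequal(pk, c(120, 240))
  expect_equal(sum(r) / fr, sum(impulses) / fr * fr, tolerance = 0.1)
})

test_that("run-length response detection follows the 21/19-frame rule", {
  fr <- 15
  expect_equal(classifyTrialResponse(rep(0, 450), fr), "none")
  up25 <- trialDff(level = 0.05, plateauFrames = 25)
  expect_equal(classifyTrialResponse(up25, fr), "act")
  up15 <- trialDff(level = 0.05, plateauFrames = 15)
  expect_equal(classifyTrialResponse(up15, fr), "none")
  up20 <- trialDff(level = 0.05, plateauFrames = 20)
  expect_equal(classifyTrialResponse(up20, fr), "none")   # 20 < 21
  dn19 <- trialDff(level = -0.05, plateauFrames = 19)
  expect_equal(classifyTrialResponse(dn19, fr), "sup")    # 19 >= 19
  # run lengths rescale with the frame rate (30 Hz needs 42 frames)
  up30 <- trialDff(level = 0.05, plateauFrames = 41, frameRate = 30)
  expect_equal(classifyTrialResponse(up30, 30), "none")
  up42 <- trialDff(level = 0.05, plateauFrames = 42, frameRate = 30)
  expect_equal(classifyTrialResponse(up42, 30), "act")
})

test_that("noise-free detection flags exactly the planted trials", {
  cfg <- simConfig(nCells = 60, trialNoiseSd = 0, pRespond = 0.75,
                   amplitudeJitterSd = 0, stimulusSet = stimulusPanel(4),
                   seed = 2)
  tt <- generateTrialTraces(cfg)
  fl <- detectResponses(tt$tensor)
  st <- stimuli(tt$tensor)
  ev <- tt$truth@events
  tm <- trueMeans(tt$truth)
  evKey <- paste(ev$cell, ev$stimulus, ev$trial)
  flKey <- paste(fl$cell, match(paste(fl$odorant, fl$dilution),
                                paste(st$odorant, st$dilution)), fl$trial)
  plantedAct <- evKey[ev$amplitude > 0]
  expect_setequal(flKey[fl$flag == "act"], plantedAct)
  plantedSup <- evKey[tm[cbind(ev$cell, ev$stimulus)] < 0]
  expect_setequal(flKey[fl$flag == "sup"], plantedSup)
})

test_that("response flags are invariant to adding a constant to the fluorescence", {
  fr <- 15
  f <- 100 * (1 + trialDff(level = 0.08, plateauFrames = 25))
  flag1 <- classifyTrialResponse(computeDff(f, fr), fr)
  flag2 <- classifyTrialResponse(computeDff(f + 50, fr), fr)
  expect_equal(flag1, "act")
  expect_equal(flag1, flag2)
})

test_that("ROC calibration picks the best operating point", {
  fr <- 15
  set.seed(2)
  shape <- c(rep(0, 8 * fr), 0.4 * exp(-(0:(22 * fr - 1)) / (fr * 2)))
  pos <- replicate(40, shape + rnorm(450, 0, 0.05), simplify = FALSE)
  blank <- replicate(40, rnorm(450, 0, 0.05), simplify = FALSE)
  roc <- calibrateThresholdRoc(pos, blank, fr)
  expect_equal(roc$ACC, 1)
  expect_equal(roc$TPR, 1)
  # single candidate point is returned unchanged with its empirical rates
  one <- calibrateThresholdRoc(pos, blank, fr, kGrid = 2, runGrid = 21)
  expect_equal(one$k, 2); expect_equal(one$run, 21)
  expect_equal(nrow(one$grid), 1L)
  # randomized labels: best J stays near zero
  all <- c(pos, blank)
  set.seed(7)
  mix <- sample(length(all))
  rocNull <- calibrateThresholdRoc(all[mix[1:40]], all[mix[41:80]], fr)
  expect_lt(abs(rocNull$J), 0.25)
  expect_error(calibrateThresholdRoc(pos, list(), fr), "blank")
})

test_that("a movie round-trips through segmentation into trial dF/F", {
  cfg <- segTestConfig(fieldSize = c(32, 32), nCells = 6, seed = 15)
  gm <- generateMovie(cfg)
  params <- segTestParams()
  sig <- preprocessForClustering(gm$movie, params)
  reg <- clusterPixels(sig, c(32, 32), params, stopIter = 32 * 32 - 60)
  sel <- selectNeuronalRegions(reg, gm$movie, params)
  expect_gt(length(sel), 0)
  tt <- extractTrialTensor(gm$movie, sel, gm$schedule, stimuli(gm$truth),
                           layout = cfg@trialLayout)
  d <- dim(tt@data)
  expect_equal(d[2], nrow(stimuli(gm$truth)))
  expect_equal(d[4], round(30 * frameRate(gm$movie)))
  expect_false(anyNA(tt@data))
  # baseline dF/F hovers near zero
  expect_lt(abs(mean(tt@data[, , , 1:(8 * 5)])), 0.05)
})
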