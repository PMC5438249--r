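# Synthetic-data module: movies, trial traces and response tables with full
# ground truth, emulating the structure of a two-photon odor-panel experiment
# (30 s trials: 8 s baseline / 2 s odor / 20 s post, ~15 Hz, 4 trials per
# stimulus, ~20% activated and ~11% suppressed cells, ~10% identity-only
# concentration-invariant cells, GCaMP-like exponential kernel).

#' Stimulus panels
#'
#' `stimulusPanel()` builds the 13-odorant single-dilution test panel;
#' `concentrationSeries()` builds the 3 odorants x 3 log-spaced dilutions
#' (1:10,000, 1:1,000, 1:100 vol./vol.) panel.
#'
#' @param nOdorants number of odorants.
#' @param dilution,dilutions volumetric dilution(s).
#' @param odorants odorant names.
#' @return data.frame with columns `odorant` and `dilution`.
#' @export
stimulusPanel <- function(nOdorants = 13, dilution = 1e-4) {
  data.frame(odorant = sprintf("odor%02d", seq_len(nOdorants)),
             dilution = dilution, stringsAsFactors = FALSE)
}

#' @rdname stimulusPanel
#' @export
concentrationSeries <- function(odorants = c("acetophenone", "ethyl_acetate", "hexanone"),
                                dilutions = c(1e-4, 1e-3, 1e-2)) {
  out <- expand.grid(dilution = dilutions, odorant = odorants,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, c("odorant", "dilution")]
  rownames(out) <- NULL
  out
}

#' Build a simulation configuration
#'
#' Defaults are the study conditions emulated throughout the package: a 30 s
#' trial (8 s baseline, 2 s odor, 20 s post) at 15 Hz, 4 trials per stimulus,
#' 20% activated / 11% suppressed cells of which 10% of the population are
#' identity-only (concentration-invariant), a 2 s indicator decay constant,
#' and a 0.75 per-trial response probability.
#'
#' @param fieldSize movie size in pixels, `c(rows, cols)`.
#' @param pixelSize micrometres per pixel.
#' @param frameRate Hz.
#' @param nCells number of cells.
#' @param cellRadius soma radius, micrometres.
#' @param trialLayout seconds of `c(pre, odor, post)`.
#' @param nTrialsPerStimulus trials per stimulus.
#' @param stimulusSet data.frame (`odorant`, `dilution`); see [stimulusPanel()].
#' @param fractionActivated,fractionSuppressed,fractionInvariant,fractionMixed,
#'   fractionBroad cell-category proportions (invariant/mixed are subsets of
#'   activated; broad is a fraction of activated cells).
#' @param responseAmplitudeMean,responseAmplitudeSd response amplitude
#'   distribution, dF/F units.
#' @param trialNoiseSd i.i.d. Gaussian trial noise, dF/F units.
#' @param pRespond per-trial event probability for responsive pairs.
#' @param amplitudeJitterSd relative per-trial amplitude jitter.
#' @param kernelTau indicator decay constant, s.
#' @param neuropilAmplitude shared neuropil signal amplitude, dF/F units.
#' @param driftPeriod slow drift period, s.
#' @param movieNoiseSd movie pixel noise SD, a.u.
#' @param baselineF cell baseline fluorescence, a.u.
#' @param seed master seed.
#' @return a \linkS4class{SimConfig}
#' @export
simConfig <- function(fieldSize = c(64, 64), pixelSize = 1.4, frameRate = 15,
                      nCells = 300, cellRadius = 5,
                      trialLayout = c(pre = 8, odor = 2, post = 20),
                      nTrialsPerStimulus = 4,
                      stimulusSet = concentrationSeries(),
                      fractionActivated = 0.20, fractionSuppressed = 0.11,
                      fractionInvariant = 0.10, fractionMixed = NA,
                      fractionBroad = 0.085,
                      responseAmplitudeMean = 0.3, responseAmplitudeSd = 0.1,
                      trialNoiseSd = 0.05, pRespond = 0.75,
                      amplitudeJitterSd = 0.2,
                      kernelTau = 2, neuropilAmplitude = 0.1,
                      driftPeriod = 300, movieNoiseSd = 2, baselineF = 100,
                      seed = 1) {
  if (is.na(fractionMixed))
    fractionMixed <- max(0, (fractionActivated - fractionInvariant) / 2)
  new("SimConfig",
      fieldSize = as.integer(fieldSize), pixelSize = pixelSize,
      frameRate = frameRate, nCells = as.integer(nCells),
      cellRadius = cellRadius,
      trialLayout = setNames(as.numeric(trialLayout), c("pre", "odor", "post")),
      nTrialsPerStimulus = as.integer(nTrialsPerStimulus),
      stimulusSet = stimulusSet,
      fractionActivated = fractionActivated,
      fractionSuppressed = fractionSuppressed,
      fractionInvariant = fractionInvariant, fractionMixed = fractionMixed,
      fractionBroad = fractionBroad,
      responseAmplitudeMean = responseAmplitudeMean,
      responseAmplitudeSd = responseAmplitudeSd,
      trialNoiseSd = trialNoiseSd, pRespond = pRespond,
      amplitudeJitterSd = amplitudeJitterSd,
      kernelTau = kernelTau, neuropilAmplitude = neuropilAmplitude,
      driftPeriod = driftPeriod, movieNoiseSd = movieNoiseSd,
      baselineF = baselineF, seed = as.integer(seed))
}

# ---- category assignment and noise-free response means ----------------------

assignCategories <- function(config) {
  n <- config@nCells
  nAct <- round(config@fractionActivated * n)
  nSup <- round(config@fractionSuppressed * n)
  nBroad <- round(config@fractionBroad * nAct)
  nDil <- length(unique(config@stimulusSet$dilution))
  if (nDil > 1) {
    nInv <- round(config@fractionInvariant * n)
    nMix <- round(config@fractionMixed * n)
    nConc <- max(0L, nAct - nInv - nMix - nBroad)
    cats <- c(rep("identity_only", nInv), rep("mixed", nMix),
              rep("broadly_tuned", nBroad), rep("concentration_modulated", nConc))
  } else {
    cats <- c(rep("identity_only", nAct - nBroad), rep("broadly_tuned", nBroad))
  }
  cats <- c(cats, rep("suppressed", nSup))
  cats <- c(cats, rep("null", n - length(cats)))
  sample(cats)
}

drawAmplitude <- function(n, config, scale = 1) {
  pmax(0.05, rnorm(n, config@responseAmplitudeMean * scale,
                   config@responseAmplitudeSd * scale))
}

# Noise-free expected responses per cell x stimulus. Identity-only cells have
# per-odorant means that are exactly constant across dilutions; concentration-
# modulated cells scale monotonically with dilution; mixed cells get an
# independent amplitude per odorant-dilution pair (interaction).
makeTrueMeans <- function(config, categories) {
  stim <- config@stimulusSet
  n <- length(categories)
  odors <- unique(stim$odorant)
  dils <- sort(unique(stim$dilution))
  odIdx <- match(stim$odorant, odors)
  dilRank <- match(stim$dilution, dils)
  tm <- matrix(0, n, nrow(stim))
  pickOdors <- function(maxK) {
    k <- sample(seq_len(min(maxK, 3L)), 1, prob = c(0.6, 0.3, 0.1)[seq_len(min(maxK, 3L))])
    sample(seq_along(odors), k)
  }
  concGains <- c(0.4, 1.0, 1.6)
  for (i in seq_len(n)) {
    cat_i <- categories[i]
    if (cat_i == "null") next
    if (cat_i == "broadly_tuned") {
      # broad responders gain strength with concentration (population
      # sparseness decreases at higher concentrations)
      amp <- drawAmplitude(length(odors), config)
      g <- if (length(dils) > 1) concGains else 1
      tm[i, ] <- amp[odIdx] * g[pmin(dilRank, length(g))]
    } else if (cat_i == "identity_only") {
      sel <- pickOdors(length(odors))
      amp <- rep(0, length(odors)); amp[sel] <- drawAmplitude(length(sel), config)
      tm[i, ] <- amp[odIdx]                      # constant across dilutions
    } else if (cat_i == "concentration_modulated") {
      sel <- pickOdors(length(odors))
      amp <- rep(0, length(odors)); amp[sel] <- drawAmplitude(length(sel), config)
      g <- if (runif(1) < 0.5) concGains else rev(concGains)
      tm[i, ] <- amp[odIdx] * g[pmin(dilRank, length(g))]
    } else if (cat_i == "mixed") {
      # identity x concentration interaction: each responsive odorant gets
      # its own permutation of well-separated concentration gains
      sel <- pickOdors(length(odors))
      mixGains <- c(0.3, 1.0, 1.7)
      for (o in sel) {
        a <- drawAmplitude(1, config)
        g <- if (length(dils) > 1) sample(mixGains) else 1
        sCols <- which(odIdx == o)
        tm[i, sCols] <- a * g[pmin(dilRank[sCols], length(g))]
      }
    } else if (cat_i == "suppressed") {
      # suppression deepens with concentration
      sel <- sample(seq_along(odors), sample(1:2, 1))
      amp <- rep(0, length(odors)); amp[sel] <- -drawAmplitude(length(sel), config, 0.6)
      g <- if (length(dils) > 1) concGains else 1
      tm[i, ] <- amp[odIdx] * g[pmin(dilRank, length(g))]
    }
  }
  tm
}

#' Generate a per-trial response table with ground truth
#'
#' Draws cell categories and noise-free expected responses, then produces the
#' observed table as expected response plus i.i.d. Gaussian trial noise.
#' With `trialNoiseSd = 0` every trial equals its true mean exactly.
#'
#' @param config a \linkS4class{SimConfig}
#' @return list with elements `responses` (\linkS4class{ResponseSet}) and
#'   `truth` (\linkS4class{GroundTruth})
#' @export
generateResponseDataset <- function(config) {
  validObject(config)
  stim <- config@stimulusSet
  nT <- config@nTrialsPerStimulus
  withSeed(deriveSeed(config@seed, "response_dataset"), {
    categories <- assignCategories(config)
    tm <- makeTrueMeans(config, categories)
    nStim <- nrow(stim)
    stimCol <- rep(seq_len(nStim), each = nT)
    resp <- tm[, stimCol, drop = FALSE]
    if (config@trialNoiseSd > 0)
      resp <- resp + matrix(rnorm(length(resp), 0, config@trialNoiseSd),
                            nrow(resp), ncol(resp))
    rs <- ResponseSet(resp,
                      odorant = stim$odorant[stimCol],
                      dilution = stim$dilution[stimCol],
                      trial = rep(seq_len(nT), times = nStim))
    truth <- new("GroundTruth", category = categories, trueMeans = tm,
                 stimuli = stim, centers = matrix(numeric(0), 0, 2),
                 masks = list(),
                 events = data.frame(cell = integer(0), stimulus = integer(0),
                                     trial = integer(0), onset_s = numeric(0),
                                     amplitude = numeric(0)))
    list(responses = rs, truth = truth)
  })
}

# Response time course of one trial: zero baseline, exponential-decay
# transient locked to odor onset.
trialShape <- function(config) {
  fr <- config@frameRate
  nFrames <- round(sum(config@trialLayout) * fr)
  onset <- round(config@trialLayout[["pre"]] * fr) + 1L
  shape <- numeric(nFrames)
  t <- seq(0, by = 1 / fr, length.out = nFrames - onset + 1L)
  shape[onset:nFrames] <- exp(-t / config@kernelTau)
  list(shape = shape, onset = onset, nFrames = nFrames)
}

#' Generate trial-aligned dF/F traces with ground truth
#'
#' Each responsive cell-stimulus pair fires one onset-locked exponential
#' transient per trial with probability `pRespond`; its amplitude is drawn
#' once per cell-stimulus and jittered per trial.  Gaussian frame noise with
#' SD `trialNoiseSd` is added when nonzero.
#'
#' @param config a \linkS4class{SimConfig}
#' @return list with elements `tensor` (\linkS4class{TrialTensor}, signal
#'   `"dff"`) and `truth` (\linkS4class{GroundTruth})
#' @export
generateTrialTraces <- function(config) {
  validObject(config)
  stim <- config@stimulusSet
  nT <- config@nTrialsPerStimulus
  sh <- trialShape(config)
  withSeed(deriveSeed(config@seed, "trial_traces"), {
    categories <- assignCategories(config)
    tm <- makeTrueMeans(config, categories)
    n <- config@nCells; nStim <- nrow(stim)
    arr <- array(0, c(n, nStim, nT, sh$nFrames))
    ev <- vector("list", 2000L); nev <- 0L
    for (i in seq_len(n)) for (s in seq_len(nStim)) {
      a <- tm[i, s]
      if (a == 0) next
      for (tr in seq_len(nT)) {
        if (runif(1) > config@pRespond) next
        aTrial <- a * max(0, 1 + rnorm(1, 0, config@amplitudeJitterSd))
        arr[i, s, tr, ] <- aTrial * sh$shape
        nev <- nev + 1L
        if (nev > length(ev)) ev <- c(ev, vector("list", length(ev)))
        ev[[nev]] <- c(i, s, tr, config@trialLayout[["pre"]], aTrial)
      }
    }
    if (config@trialNoiseSd > 0)
      arr <- arr + array(rnorm(length(arr), 0, config@trialNoiseSd), dim(arr))
    evm <- if (nev) do.call(rbind, ev[seq_len(nev)]) else matrix(numeric(0), 0, 5)
    events <- data.frame(cell = as.integer(evm[, 1][seq_len(nev)]),
                         stimulus = as.integer(evm[, 2][seq_len(nev)]),
                         trial = as.integer(evm[, 3][seq_len(nev)]),
                         onset_s = evm[, 4][seq_len(nev)],
                         amplitude = evm[, 5][seq_len(nev)])
    tensor <- new("TrialTensor", data = arr, stimuli = stim,
                  layout = config@trialLayout, frameRate = config@frameRate,
                  signal = "dff")
    truth <- new("GroundTruth", category = categories, trueMeans = tm,
                 stimuli = stim, centers = matrix(numeric(0), 0, 2),
                 masks = list(), events = events)
    list(tensor = tensor, truth = truth)
  })
}

# ---- movie generation -------------------------------------------------------

# Annular ("donut") radial intensity profile mimicking nuclear-excluded GCaMP.
donutProfile <- function(r, radius) {
  ring <- 0.55 * radius
  width <- 0.25 * radius + 0.2
  0.15 + 0.85 * exp(-((r - ring)^2) / (2 * width^2))
}

placeCells <- function(config) {
  nr <- config@fieldSize[1]; nc <- config@fieldSize[2]
  rPix <- config@cellRadius / config@pixelSize
  margin <- rPix + 1
  if (2 * margin >= min(nr, nc))
    stopf("field too small for cells of radius %.1f pixels", rPix)
  centers <- matrix(NA_real_, config@nCells, 2)
  placed <- 0L; attempts <- 0L
  maxAttempts <- 500L * config@nCells
  while (placed < config@nCells) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stopf("could not place %d non-overlapping cells in a %d x %d field",
            config@nCells, nr, nc)
    cand <- c(runif(1, margin, nr - margin + 1), runif(1, margin, nc - margin + 1))
    if (placed > 0L) {
      d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
            (centers[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < (2 * rPix + 1)^2) next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  centers
}

# Smooth random spatial field in [lo, 1] from a low-order cosine basis.
smoothField <- function(nr, nc, lo = 0.4) {
  r <- seq_len(nr) / nr; c_ <- seq_len(nc) / nc
  f <- matrix(0, nr, nc)
  for (p in 0:2) for (q in 0:2) {
    if (p == 0 && q == 0) next
    f <- f + rnorm(1) * outer(cos(pi * p * r + runif(1, 0, 2 * pi)),
                              cos(pi * q * c_ + runif(1, 0, 2 * pi)))
  }
  rng <- range(f)
  if (diff(rng) < 1e-12) return(matrix(1, nr, nc))
  lo + (1 - lo) * (f - rng[1]) / diff(rng)
}

#' Generate a synthetic movie with planted cells
#'
#' Builds a rows x cols x frames fluorescence movie as the sum of planted
#' annular cells (baseline plus kernel-convolved onset-locked transients), a
#' smooth neuropil field carrying a shared slow signal, a sinusoidal drift and
#' Gaussian pixel noise.  The presentation schedule interleaves stimuli in
#' pseudo-random order (no stimulus twice in a row).
#'
#' @param config a \linkS4class{SimConfig}
#' @return list with `movie` (\linkS4class{CalciumMovie}), `truth`
#'   (\linkS4class{GroundTruth}, including disjoint masks and sub-pixel
#'   centres) and `schedule` (data.frame of presentations with start and
#'   onset frames)
#' @export
generateMovie <- function(config) {
  validObject(config)
  nr <- config@fieldSize[1]; nc <- config@fieldSize[2]
  npix <- nr * nc
  fr <- config@frameRate
  stim <- config@stimulusSet
  nT <- config@nTrialsPerStimulus
  framesPerTrial <- round(sum(config@trialLayout) * fr)
  nPres <- nrow(stim) * nT
  totFrames <- nPres * framesPerTrial
  withSeed(deriveSeed(config@seed, "movie"), {
    categories <- assignCategories(config)
    tm <- makeTrueMeans(config, categories)
    centers <- placeCells(config)
    rPix <- config@cellRadius / config@pixelSize

    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    masks <- vector("list", config@nCells)
    profiles <- vector("list", config@nCells)
    for (i in seq_len(config@nCells)) {
      d <- sqrt((rows - centers[i, 1])^2 + (cols - centers[i, 2])^2)
      idx <- which(d <= rPix)
      masks[[i]] <- idx
      profiles[[i]] <- donutProfile(d[idx], rPix)
    }

    # pseudo-random schedule: one permutation of the stimuli per round,
    # avoiding immediate repeats across round boundaries
    sched <- integer(0)
    for (round in seq_len(nT)) {
      perm <- sample(nrow(stim))
      if (length(sched) && nrow(stim) > 1 && perm[1] == sched[length(sched)])
        perm <- rev(perm)
      sched <- c(sched, perm)
    }
    schedule <- data.frame(
      presentation = seq_len(nPres), stimulus = sched,
      odorant = stim$odorant[sched], dilution = stim$dilution[sched],
      startFrame = (seq_len(nPres) - 1L) * framesPerTrial + 1L)
    schedule$onsetFrame <- schedule$startFrame + round(config@trialLayout[["pre"]] * fr)
    schedule$trial <- ave(schedule$stimulus, schedule$stimulus, FUN = seq_along)

    sh <- trialShape(config)
    # per-cell dF/F over the full movie + planted event log
    ev <- list(); k <- 0L
    dffAll <- matrix(0, config@nCells, totFrames)
    for (p in seq_len(nPres)) {
      s <- schedule$stimulus[p]
      fidx <- schedule$startFrame[p]:(schedule$startFrame[p] + framesPerTrial - 1L)
      for (i in seq_len(config@nCells)) {
        a <- tm[i, s]
        if (a == 0) next
        if (runif(1) > config@pRespond) next
        aTrial <- a * max(0, 1 + rnorm(1, 0, config@amplitudeJitterSd))
        dffAll[i, fidx] <- dffAll[i, fidx] + aTrial * sh$shape
        k <- k + 1L
        ev[[k]] <- data.frame(cell = i, stimulus = s,
                              trial = schedule$trial[p],
                              onset_s = (schedule$onsetFrame[p] - 1) / fr,
                              amplitude = aTrial)
      }
    }
    events <- if (k) do.call(rbind, ev) else
      data.frame(cell = integer(0), stimulus = integer(0), trial = integer(0),
                 onset_s = numeric(0), amplitude = numeric(0))

    # background: neuropil field x shared slow signal + drift + pixel noise
    M <- matrix(0.25 * config@baselineF, npix, totFrames)
    if (config@neuropilAmplitude > 0) {
      field <- smoothField(nr, nc)
      npSig <- as.numeric(stats::filter(rnorm(totFrames), 0.97, "recursive"))
      npSig <- npSig / max(sd(npSig), 1e-12)
      M <- M + (config@neuropilAmplitude * config@baselineF) * outer(as.vector(field), npSig)
    }
    if (config@driftPeriod > 0) {
      drift <- 0.02 * config@baselineF *
        sin(2 * pi * seq_len(totFrames) / (config@driftPeriod * fr))
      M <- M + matrix(drift, npix, totFrames, byrow = TRUE)
    }
    if (config@movieNoiseSd > 0)
      M <- M + matrix(rnorm(npix * totFrames, 0, config@movieNoiseSd), npix, totFrames)

    baseMul <- ifelse(categories == "suppressed", 1.3, 1)
    for (i in seq_len(config@nCells)) {
      Fcell <- config@baselineF * baseMul[i] * (1 + dffAll[i, ])
      M[masks[[i]], ] <- M[masks[[i]], ] + outer(profiles[[i]], Fcell)
    }
    M[M < 0] <- 0

    movie <- CalciumMovie(array(M, c(nr, nc, totFrames)), frameRate = fr,
                          pixelSize = config@pixelSize)
    truth <- new("GroundTruth", category = categories, trueMeans = tm,
                 stimuli = stim, centers = centers, masks = masks,
                 events = events)
    list(movie = movie, truth = truth, schedule = schedule)
  })
}
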