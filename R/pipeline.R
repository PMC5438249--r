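# End-to-end orchestration: reproducible runs over the synthetic study, with
# per-stage timing, JSON reporting and fixture generation.

#' Pipeline configuration
#'
#' @param sim a \linkS4class{SimConfig}; drives every simulated stage.
#' @param seg segmentation parameters ([segmentationParams()]).
#' @param det detection parameters ([detectionParams()]).
#' @param decodingMethod `"lda"` or `"svm"`.
#' @param alpha significance level of the per-cell ANOVA.
#' @param nBoot identity-shuffle bootstrap replicates.
#' @param nniShuffles shuffles of the spatial test.
#' @param runMovie also run the imaging stages (simulated movie,
#'   segmentation, mask recovery); slower, off by default.
#' @param movieSim optional smaller \linkS4class{SimConfig} for the movie
#'   stages.
#' @param outDir optional output directory for the report and tables.
#' @param seed master seed; each stochastic stage derives its own stream.
#' @return list of class `PipelineConfig`
#' @export
pipelineConfig <- function(sim = simConfig(), seg = segmentationParams(),
                           det = detectionParams(), decodingMethod = "lda",
                           alpha = 0.01, nBoot = 200, nniShuffles = 500,
                           runMovie = FALSE, movieSim = NULL, outDir = NULL,
                           seed = 1) {
  structure(list(sim = sim, seg = seg, det = det,
                 decodingMethod = decodingMethod, alpha = alpha,
                 nBoot = nBoot, nniShuffles = nniShuffles,
                 runMovie = runMovie, movieSim = movieSim, outDir = outDir,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

configHash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates the study (trial traces and, optionally, a movie), detects
#' responses, builds population vectors from the deconvolved traces, and
#' computes the population statistics, decoding accuracies, spatial NNI
#' tests and concentration-invariance statistics, logging per-stage timings.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()]
#' @param verbose print per-stage progress (default TRUE)
#' @return report list with one element per stage plus `provenance`; written
#'   to `report.json` under `outDir` when set
#' @export
runPipeline <- function(config = pipelineConfig(), verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  report <- list()
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    if (verbose) message(sprintf("[pirinv] stage %-12s ...", name))
    out <- tryCatch(force(expr), error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    out
  }
  sim <- config$sim
  sim@seed <- deriveSeed(config$seed, "pipeline_sim")

  tt <- stage("traces", generateTrialTraces(sim))
  flags <- stage("detect", detectResponses(tt$tensor, config$det))
  rate <- stage("deconvolve", deconvolveTensor(tt$tensor, tau = sim@kernelTau))
  rs <- stage("vectors", buildPopulationVectors(rate))

  report$responses <- list(
    nCells = nrow(rs), nTrials = ncol(rs),
    responsiveFractions = responsiveFractions(flags))

  report$population <- stage("population", {
    C <- correlationMatrix(rs)
    list(correlationSummary = summarizeCorrelations(C, odorant(rs), dilution(rs)),
         meanSparseness = mean(sparsenessByCell(rs)),
         pcaVariance3 = sum(pcaProject(rs, 3)$varianceExplained))
  })

  report$decoding <- stage("decoding", {
    res <- classifyLoo(t(responseMatrix(rs)),
                       paste0(odorant(rs), "@", dilution(rs)),
                       method = config$decodingMethod)
    out <- list(identityAccuracy = res$accuracy, chance = res$chance)
    if (length(unique(odorant(rs))) == 3 &&
        length(unique(dilution(rs))) == 3) {
      gen <- concentrationGeneralization(rs, method = config$decodingMethod)
      out$generalizationAccuracy <- gen$accuracy
      out$generalizationChance <- gen$chance
    }
    out
  })

  report$spatial <- stage("spatial", {
    pos <- randomCellPositions(nrow(rs), sim@cellRadius,
                               seed = deriveSeed(config$seed, "positions"))
    tf <- tuningFilter(flags, rs)
    lab <- rep("untuned", nrow(rs))
    lab[tf$preferred$cell] <- tf$preferred$odorant
    cm <- cellMap(pos[, 1], pos[, 2], lab)
    tuned <- cm[cm$label != "untuned", ]
    attr(tuned, "bounds") <- attr(cm, "bounds")
    if (length(unique(tuned$label)) >= 1 && nrow(tuned) >= 4) {
      nni <- nniShuffleTest(tuned, nShuffles = config$nniShuffles,
                            seed = deriveSeed(config$seed, "nni"))
      list(pooledNni = nni$pooled$nni, pooledP = nni$pooled$p,
           perClass = nni$perClass)
    } else list(pooledNni = NA, pooledP = NA)
  })

  if (length(unique(odorant(rs))) == 3 && length(unique(dilution(rs))) == 3) {
    report$invariance <- stage("invariance", {
      cl <- classifyPopulation(rs, alpha = config$alpha)
      bt <- bootstrapIdentityShuffle(rs, nBoot = config$nBoot,
                                     alpha = config$alpha,
                                     seed = deriveSeed(config$seed, "bootstrap"))
      list(fractions = as.list(cl$fractions),
           invariantFraction = cl$invariantFraction,
           invariantOfIdentitySig = cl$invariantOfIdentitySig,
           bootstrapP = bt$p,
           bootstrapNullMean = mean(bt$nullFractions))
    })
  }

  if (isTRUE(config$runMovie)) {
    report$imaging <- stage("imaging", {
      msim <- if (!is.null(config$movieSim)) config$movieSim else sim
      msim@seed <- deriveSeed(config$seed, "movie_stage")
      gm <- generateMovie(msim)
      regions <- segmentMovie(gm$movie, config$seg,
                              stopIter = prod(msim@fieldSize) - 16 * msim@nCells)
      match <- matchRegionsToMasks(regions, cellMasks(gm$truth))
      list(nRegions = length(regions),
           maskRecovery = mean(match$iou >= 0.5))
    })
  }

  report$provenance <- list(
    package = "pirinv",
    version = as.character(utils::packageVersion("pirinv")),
    rVersion = R.version.string,
    seed = config$seed,
    configHash = configHash(config),
    timingsS = as.list(timings))

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(reportToJson(report),
                         file.path(config$outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    writeResponseCsv(rs, file.path(config$outDir, "responses.csv"))
    writeFlagsCsv(flags, file.path(config$outDir, "flags.csv"))
  }
  invisible(report)
}

reportToJson <- function(x) {
  if (is.list(x)) lapply(x, reportToJson)
  else if (is.data.frame(x) || is.matrix(x)) as.data.frame(x)
  else x
}

#' Deterministic 3x3x6 toy movie
#'
#' A schematic movie with two planted two-pixel sources -- pixels (1,1) and
#' (1,2) share one signal, pixels (3,2) and (3,3) another -- over a weakly
#' structured background, used to exercise the clustering on a case where
#' every correlation can be enumerated by hand.
#'
#' @return a \linkS4class{CalciumMovie} (frame rate 1 Hz)
#' @export
toyMovie <- function() {
  sA <- c(0, 2, 0, 2, 0, 2)
  sB <- c(2, 0, 0, 2, 2, 0)
  bg <- list(c(1.0, 1.1, 0.9, 1.0, 1.2, 0.8),
             c(0.9, 1.0, 1.2, 0.8, 1.0, 1.1),
             c(1.1, 0.8, 1.0, 1.2, 0.9, 1.0),
             c(1.2, 1.0, 0.8, 1.1, 1.0, 0.9),
             c(0.8, 1.2, 1.1, 0.9, 1.0, 1.0))
  arr <- array(0, c(3, 3, 6))
  arr[1, 1, ] <- sA; arr[1, 2, ] <- sA
  arr[3, 2, ] <- sB; arr[3, 3, ] <- sB
  rest <- list(c(1, 3), c(2, 1), c(2, 2), c(2, 3), c(3, 1))
  for (k in seq_along(rest)) arr[rest[[k]][1], rest[[k]][2], ] <- bg[[k]]
  CalciumMovie(arr, frameRate = 1, pixelSize = 1)
}

#' Generate the fixture set used by examples and tests
#'
#' Writes the 3x3x6 toy movie, a small 64x64 demo movie, a 300-cell
#' concentration-series response table and a null-site (no planted effects)
#' table; regeneration with the same seed is bit-identical.
#'
#' @param dir output directory (created if needed)
#' @param seed master seed
#' @return named character vector of the written paths
#' @export
makeFixtures <- function(dir = tempfile("pirinv_fixtures"), seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()

  paths["toy_movie"] <- writeMovieTiff(
    CalciumMovie(toyMovie()@data * 1000, 1, 1),
    file.path(dir, "toy_movie_3x3x6.tif"))

  demoSim <- simConfig(fieldSize = c(64, 64), nCells = 20, frameRate = 5,
                       stimulusSet = stimulusPanel(nOdorants = 2),
                       nTrialsPerStimulus = 2, seed = deriveSeed(seed, "demo"))
  gm <- generateMovie(demoSim)
  paths["demo_movie"] <- writeMovieTiff(gm$movie, file.path(dir, "demo_movie_64x64.tif"))
  paths["demo_truth"] <- writeGroundTruthJson(gm$truth,
    file.path(dir, "demo_movie_truth.json"), fieldSize = demoSim@fieldSize)

  tbl <- generateResponseDataset(simConfig(nCells = 300,
                                           seed = deriveSeed(seed, "table")))
  paths["responses"] <- writeResponseCsv(tbl$responses,
                                         file.path(dir, "responses_300cells.csv"))

  nullTbl <- generateResponseDataset(simConfig(
    nCells = 300, fractionActivated = 0, fractionSuppressed = 0,
    fractionInvariant = 0, fractionMixed = 0, fractionBroad = 0,
    seed = deriveSeed(seed, "null")))
  paths["null_site"] <- writeResponseCsv(nullTbl$responses,
                                         file.path(dir, "null_site_300cells.csv"))
  paths
}
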