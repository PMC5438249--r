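# Plain-format input/output: multi-page 16-bit TIFF movies, CSV response
# tables and flags, JSON ground truth (masks run-length encoded).

#' Read and write movies as multi-page 16-bit TIFF
#'
#' Intensities are stored as 16-bit samples; `writeMovieTiff` scales by
#' 1/65535 as required by the TIFF writer and `readMovieTiff` undoes the
#' scaling, so round-tripped movies agree to integer precision.
#'
#' @param movie a \linkS4class{CalciumMovie}
#' @param path file path
#' @param frameRate,pixelSize metadata to attach on reading
#' @return `readMovieTiff` returns a \linkS4class{CalciumMovie};
#'   `writeMovieTiff` returns `path` invisibly
#' @export
writeMovieTiff <- function(movie, path) {
  d <- dim(movie)
  mx <- max(movie@data, 1e-9)
  if (mx > 65535) stopf("movie intensities exceed the 16-bit range")
  pages <- lapply(seq_len(d[3]), function(t)
    pmin(pmax(round(movie@data[, , t]), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname writeMovieTiff
#' @export
readMovieTiff <- function(path, frameRate, pixelSize = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- round(pages[[t]] * 65535)
  CalciumMovie(arr, frameRate = frameRate, pixelSize = pixelSize)
}

#' Read and write response tables as CSV
#'
#' Long format with columns `cell_id`, `odorant`, `dilution`, `trial`,
#' `response`.
#'
#' @param rs a \linkS4class{ResponseSet}
#' @param path file path
#' @return `readResponseCsv` returns a \linkS4class{ResponseSet}
#' @export
writeResponseCsv <- function(rs, path) {
  m <- responseMatrix(rs)
  long <- data.frame(
    cell_id = rep(rownames(m), times = ncol(m)),
    odorant = rep(odorant(rs), each = nrow(m)),
    dilution = rep(dilution(rs), each = nrow(m)),
    trial = rep(trialIndex(rs), each = nrow(m)),
    response = as.vector(m))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResponseCsv
#' @export
readResponseCsv <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  cells <- unique(long$cell_id)
  key <- paste(long$odorant, long$dilution, long$trial, sep = "@")
  cols <- unique(key)
  m <- matrix(NA_real_, length(cells), length(cols),
              dimnames = list(cells, NULL))
  m[cbind(match(long$cell_id, cells), match(key, cols))] <- long$response
  meta <- long[match(cols, key), c("odorant", "dilution", "trial")]
  ResponseSet(m, odorant = meta$odorant, dilution = meta$dilution,
              trial = meta$trial)
}

# run-length encode a sorted integer vector as a flat
# [start1, len1, start2, len2, ...] vector
rleEncode <- function(idx) {
  idx <- sort(idx)
  breaks <- c(TRUE, diff(idx) != 1L)
  starts <- idx[breaks]
  lens <- as.integer(diff(c(which(breaks), length(idx) + 1L)))
  as.integer(rbind(starts, lens))
}

rleDecode <- function(flat) {
  flat <- as.integer(flat)
  starts <- flat[seq(1, length(flat), by = 2)]
  lens <- flat[seq(2, length(flat), by = 2)]
  unlist(mapply(function(s, l) seq(s, length.out = l), starts, lens,
                SIMPLIFY = FALSE))
}

#' Write and read ground truth as JSON
#'
#' Masks are stored as run-length-encoded lists of 0-based row-major flat
#' pixel indices; centres as 0-based (row, col).
#'
#' @param truth a \linkS4class{GroundTruth}
#' @param path file path
#' @param fieldSize `c(rows, cols)`, required to encode masks
#' @return `readGroundTruthJson` returns a \linkS4class{GroundTruth}
#' @export
writeGroundTruthJson <- function(truth, path, fieldSize = NULL) {
  masks <- cellMasks(truth)
  enc <- NULL
  if (length(masks)) {
    if (is.null(fieldSize)) stopf("fieldSize is required to encode masks")
    nr <- fieldSize[1]; nc <- fieldSize[2]
    enc <- lapply(masks, function(px) {
      row0 <- ((px - 1L) %% nr)
      col0 <- ((px - 1L) %/% nr)
      rleEncode(row0 * nc + col0)             # 0-based row-major
    })
  }
  ctr <- cellCenters(truth)
  obj <- list(
    category = cellCategory(truth),
    stimuli = stimuli(truth),
    true_means = trueMeans(truth),
    centers_rc0 = if (nrow(ctr)) unname(ctr - 1) else NULL,
    field_size = fieldSize,
    masks_rle = enc,
    events = truth@events)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeGroundTruthJson
#' @export
readGroundTruthJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  masks <- list()
  if (!is.null(obj$masks_rle) && length(obj$masks_rle)) {
    nr <- obj$field_size[1]; nc <- obj$field_size[2]
    enc <- obj$masks_rle
    if (is.matrix(enc)) enc <- asplit(enc, 1)   # equal run counts collapse
    masks <- lapply(enc, function(flat) {
      flat <- rleDecode(flat)
      row0 <- flat %/% nc; col0 <- flat %% nc
      sort(pixelIndex(row0 + 1L, col0 + 1L, nr))
    })
  }
  ctr <- if (!is.null(obj$centers_rc0)) as.matrix(obj$centers_rc0) + 1 else
    matrix(numeric(0), 0, 2)
  ev <- if (!is.null(obj$events) && length(obj$events)) as.data.frame(obj$events) else
    data.frame(cell = integer(0), stimulus = integer(0), trial = integer(0),
               onset_s = numeric(0), amplitude = numeric(0))
  new("GroundTruth", category = obj$category,
      trueMeans = as.matrix(obj$true_means),
      stimuli = as.data.frame(obj$stimuli), centers = ctr, masks = masks,
      events = ev)
}

#' Write a segmentation to disk
#'
#' The label image goes to 16-bit TIFF, per-region weights to a sparse CSV
#' (`region_id`, `row`, `col`, `weight`) and the merge history to CSV.
#'
#' @param regions a \linkS4class{RegionSet}
#' @param labelPath,weightsPath,mergePath output file paths (any may be
#'   `NULL` to skip)
#' @return invisibly, the written paths
#' @export
writeRegions <- function(regions, labelPath = NULL, weightsPath = NULL,
                         mergePath = NULL) {
  written <- character(0)
  if (!is.null(labelPath)) {
    lab <- regionLabels(regions)
    if (max(lab) > 65535) stopf("more than 65535 regions cannot be stored in 16 bits")
    tiff::writeTIFF(lab / 65535, labelPath, bits.per.sample = 16L,
                    compression = "none")
    written <- c(written, labelPath)
  }
  if (!is.null(weightsPath)) {
    ids <- regionIds(regions)
    w <- do.call(rbind, lapply(ids, function(id)
      cbind(region_id = id, regionWeights(regions, id))))
    write.csv(w, weightsPath, row.names = FALSE)
    written <- c(written, weightsPath)
  }
  if (!is.null(mergePath)) {
    write.csv(mergeHistory(regions), mergePath, row.names = FALSE)
    written <- c(written, mergePath)
  }
  invisible(written)
}

#' Read a label image written by [writeRegions()]
#'
#' @param path TIFF path
#' @return integer label matrix
#' @export
readRegionLabelsTiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write a flags table as CSV
#'
#' @param flags data.frame from [detectResponses()]
#' @param path file path
#' @export
writeFlagsCsv <- function(flags, path) {
  write.csv(flags, path, row.names = FALSE)
  invisible(path)
}
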