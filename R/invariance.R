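# Concentration-invariance statistics: per-cell ANOVA with odorant identity,
# concentration and trial number as fixed effects, three-test classification
# of cells, identity-shuffle bootstrap of the invariant fraction, per-site
# significance and subsampled comparison.

# Orthonormal bases of the effect subspaces of the balanced complete
# odorant x concentration x trial design.  On a balanced design the effect
# subspaces are mutually orthogonal after centring, so the sums of squares
# from these projections coincide with type II sums of squares.
makeAnovaBasis <- function(od, cc, tr) {
  od <- factor(od); cc <- factor(cc); tr <- factor(tr)
  n <- length(od)
  if (nlevels(od) < 2 || nlevels(cc) < 2 || nlevels(tr) < 2)
    stopf("per-cell ANOVA requires at least two levels of each factor (balanced design)")
  tab <- table(od, cc, tr)
  if (any(tab != 1))
    stopf("per-cell ANOVA requires one observation per odorant x concentration x trial (full balanced design)")
  one <- matrix(1 / sqrt(n), n, 1)
  ortho <- function(M, prior) {
    R <- M - prior %*% crossprod(prior, M)
    q <- qr(R, tol = 1e-9)
    qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  }
  Qod <- ortho(stats::model.matrix(~ od - 1), one)
  Qcc <- ortho(stats::model.matrix(~ cc - 1), one)
  Qtr <- ortho(stats::model.matrix(~ tr - 1), one)
  Qint <- ortho(stats::model.matrix(~ od:cc - 1), cbind(one, Qod, Qcc))
  dfs <- c(identity = ncol(Qod), concentration = ncol(Qcc),
           interaction = ncol(Qint), trial = ncol(Qtr))
  list(Qod = Qod, Qcc = Qcc, Qtr = Qtr, Qint = Qint, dfs = dfs,
       dfRes = n - 1L - sum(dfs), n = n)
}

# Vectorised per-cell ANOVA: Y is observations x cells.
anovaPvalues <- function(Y, basis) {
  Yc <- sweep(Y, 2, colMeans(Y))
  ssTot <- colSums(Yc^2)
  ss <- function(Q) colSums((crossprod(Q, Yc))^2)
  ssOd <- ss(basis$Qod); ssCc <- ss(basis$Qcc)
  ssInt <- ss(basis$Qint); ssTr <- ss(basis$Qtr)
  ssRes <- pmax(ssTot - ssOd - ssCc - ssInt - ssTr, 0)
  msRes <- ssRes / basis$dfRes
  fp <- function(ssTerm, df) {
    f <- (ssTerm / df) / msRes
    p <- pf(f, df, basis$dfRes, lower.tail = FALSE)
    p[msRes < 1e-20] <- NA_real_
    p
  }
  data.frame(
    p_identity = fp(ssOd, basis$dfs["identity"]),
    p_concentration = fp(ssCc, basis$dfs["concentration"]),
    p_interaction = fp(ssInt, basis$dfs["interaction"]),
    p_trial = fp(ssTr, basis$dfs["trial"]))
}

categorize <- function(pI, pC, pX, alpha) {
  out <- character(length(pI))
  deg <- is.na(pI) | is.na(pC) | is.na(pX)
  sigI <- pI < alpha; sigC <- pC < alpha; sigX <- pX < alpha
  out[sigX] <- "mixed_interaction"
  out[!sigX & sigI & sigC] <- "identity_and_concentration"
  out[!sigX & sigI & !sigC] <- "concentration_invariant"
  out[!sigX & !sigI & sigC] <- "concentration_only"
  out[!sigX & !sigI & !sigC] <- "unmodulated"
  out[deg] <- "degenerate"
  out
}

#' Per-cell analysis of variance
#'
#' Fits the linear model with odorant identity, concentration and trial
#' number as fixed effects (identity x concentration interaction included,
#' type II sums of squares) to one cell's 3 x 3 x 4 response profile, and
#' classifies the cell from three tests at level `alpha`:
#' concentration-invariant cells are significantly modulated by odorant
#' identity (p < alpha) but neither by concentration (p > alpha) nor by the
#' identity x concentration interaction (p > alpha).
#'
#' @param y vector of responses, one per observation
#' @param od,cc,tr odorant, concentration and trial of each observation
#' @param alpha significance level (default 0.01)
#' @return list: `p_identity`, `p_concentration`, `p_interaction`,
#'   `p_trial`, `category`
#' @export
anovaCell <- function(y, od, cc, tr, alpha = 0.01) {
  basis <- makeAnovaBasis(od, cc, tr)
  p <- anovaPvalues(matrix(y, ncol = 1), basis)
  c(as.list(p), list(category = categorize(p$p_identity, p$p_concentration,
                                           p$p_interaction, alpha)))
}

#' Classify every cell of a response table
#'
#' Runs the per-cell ANOVA on all cells and summarises category fractions.
#' With `successive = TRUE` the figure-style two-step variant is used
#' (interaction-significant cells are excluded first, then the remaining
#' cells are tested for identity and concentration); the resulting
#' concentration-invariant set is identical to the canonical three-test
#' rule.
#'
#' @param rs a \linkS4class{ResponseSet} with 3 odorants x 3 dilutions x 4
#'   trials per cell
#' @param alpha significance level (default 0.01)
#' @param successive use the two-step variant (default FALSE)
#' @return list: `cells` (per-cell data.frame with p-values and category),
#'   `fractions` (named proportions over non-degenerate cells),
#'   `invariantFraction` (proportion of all non-degenerate cells),
#'   `invariantOfIdentitySig` (proportion among identity-significant cells),
#'   `nDegenerate`
#' @export
classifyPopulation <- function(rs, alpha = 0.01, successive = FALSE) {
  m <- responseMatrix(rs)
  basis <- makeAnovaBasis(odorant(rs), dilution(rs), trialIndex(rs))
  p <- anovaPvalues(t(m), basis)
  category <- categorize(p$p_identity, p$p_concentration, p$p_interaction, alpha)
  if (successive) {
    # step 1: drop mixed-selectivity (interaction) cells; step 2: three-way
    # split of the rest -- same labels by construction, kept as explicit path
    category2 <- rep("mixed_interaction", nrow(p))
    keep <- !(p$p_interaction < alpha) & !is.na(p$p_interaction)
    category2[keep] <- categorize(p$p_identity[keep], p$p_concentration[keep],
                                  rep(1, sum(keep)), alpha)
    category2[is.na(p$p_interaction)] <- "degenerate"
    category <- category2
  }
  cells <- data.frame(cell = seq_len(nrow(m)), p, category,
                      stringsAsFactors = FALSE)
  ok <- category != "degenerate"
  nOk <- sum(ok)
  lev <- c("concentration_invariant", "identity_and_concentration",
           "mixed_interaction", "concentration_only", "unmodulated")
  fractions <- vapply(lev, function(l) sum(category[ok] == l) / max(nOk, 1), 0)
  idSig <- ok & cells$p_identity < alpha
  list(cells = cells, fractions = fractions,
       invariantFraction = fractions[["concentration_invariant"]],
       invariantOfIdentitySig = if (any(idSig))
         sum(category[idSig] == "concentration_invariant") / sum(idSig) else NA_real_,
       nDegenerate = nrow(m) - nOk)
}

# One identity-shuffle surrogate: cell columns permuted independently within
# each stimulus block (rows of a block stay together, so the four trials of a
# cell-odorant-concentration triplet travel as a unit).
shuffleIdentityBlocks <- function(Y, blocks) {
  nCells <- ncol(Y)
  for (rIdx in blocks) Y[rIdx, ] <- Y[rIdx, sample.int(nCells)]
  Y
}

invariantFractionFast <- function(Y, basis, alpha) {
  p <- anovaPvalues(Y, basis)
  cat <- categorize(p$p_identity, p$p_concentration, p$p_interaction, alpha)
  ok <- cat != "degenerate"
  sum(cat[ok] == "concentration_invariant") / max(sum(ok), 1)
}

#' Identity-shuffle bootstrap of the invariant fraction
#'
#' Tests whether the observed fraction of concentration-invariant cells
#' could arise from a random coding scheme in which response magnitudes are
#' arbitrarily assigned per neuron and odorant-concentration pair: for each
#' surrogate dataset the cell identities are independently permuted within
#' each of the nine odorant-concentration blocks, keeping the four trials of
#' a cell-odorant-concentration triplet together, and the invariant fraction
#' is recomputed.
#'
#' @param rs a \linkS4class{ResponseSet}
#' @param nBoot bootstrap replicates (default 1000; at least 100)
#' @param alpha significance level of the per-cell tests
#' @param seed RNG seed
#' @return list: `observedFraction`, `nullFractions` (length `nBoot`), and
#'   `p = (#\{null >= observed\} + 1)/(nBoot + 1)`
#' @export
bootstrapIdentityShuffle <- function(rs, nBoot = 1000, alpha = 0.01, seed = 1) {
  if (nBoot < 100) stopf("nBoot must be at least 100")
  m <- responseMatrix(rs)
  Y <- t(m)                                   # observations x cells
  basis <- makeAnovaBasis(odorant(rs), dilution(rs), trialIndex(rs))
  blocks <- split(seq_len(nrow(Y)), paste(odorant(rs), dilution(rs), sep = "@"))
  obs <- invariantFractionFast(Y, basis, alpha)
  nullFr <- numeric(nBoot)
  nCells <- ncol(Y)
  withSeed(seed, {
    for (b in seq_len(nBoot))
      nullFr[b] <- invariantFractionFast(shuffleIdentityBlocks(Y, blocks),
                                         basis, alpha)
  })
  list(observedFraction = obs, nullFractions = nullFr,
       p = (sum(nullFr >= obs) + 1) / (nBoot + 1))
}

#' Per-site bootstrap significance of the invariant count
#'
#' A site is flagged significantly enriched in concentration-invariant cells
#' when its observed invariant count exceeds the 99th percentile of its own
#' identity-shuffle null distribution.
#'
#' @param sites list of \linkS4class{ResponseSet}s
#' @param nBoot bootstrap replicates per site
#' @param alpha per-cell significance level
#' @param seed master seed (per-site seeds derived from it)
#' @return data.frame: `site`, `nCells`, `observedCount`, `observedFraction`,
#'   `crit99`, `flagged`, `p`
#' @export
perSiteSignificance <- function(sites, nBoot = 1000, alpha = 0.01, seed = 1) {
  out <- lapply(seq_along(sites), function(si) {
    rs <- sites[[si]]
    n <- nrow(rs)
    bt <- bootstrapIdentityShuffle(rs, nBoot = nBoot, alpha = alpha,
                                   seed = deriveSeed(seed, paste0("site", si)))
    obsCount <- round(bt$observedFraction * n)
    nullCounts <- round(bt$nullFractions * n)
    crit <- quantile(nullCounts, 0.99, names = FALSE)
    data.frame(site = si, nCells = n, observedCount = obsCount,
               observedFraction = bt$observedFraction, crit99 = crit,
               flagged = obsCount > crit, p = bt$p)
  })
  do.call(rbind, out)
}

#' Invariant fraction under cell subsampling
#'
#' Distribution of the concentration-invariant fraction over random
#' subsamples of `nTarget` cells drawn without replacement, used to compare
#' populations of different sizes on equal footing.  Per-cell categories do
#' not depend on the other cells, so they are computed once and averaged
#' over the sampled cells of each iterate.
#'
#' @param rs a \linkS4class{ResponseSet}
#' @param nTarget subsample size
#' @param nIter number of subsamples (default 1000)
#' @param alpha per-cell significance level
#' @param seed RNG seed
#' @return list: `fractions` (length `nIter`), `fullFraction`, `nTarget`
#' @export
subsampleComparison <- function(rs, nTarget, nIter = 1000, alpha = 0.01,
                                seed = 1) {
  if (nTarget > nrow(rs)) stopf("nTarget exceeds the number of cells")
  cl <- classifyPopulation(rs, alpha = alpha)
  flag <- cl$cells$category == "concentration_invariant"
  deg <- cl$cells$category == "degenerate"
  fr <- withSeed(seed, vapply(seq_len(nIter), function(i) {
    idx <- sample.int(nrow(rs), nTarget)
    mean(flag[idx][!deg[idx]])
  }, 0))
  list(fractions = fr, fullFraction = cl$invariantFraction, nTarget = nTarget)
}
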