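# pirinv

Analysis of two-photon calcium imaging of odor-evoked cortical activity,
centred on one question: does a population of odor-coding neurons contain a
subpopulation whose responses encode odorant *identity* independently of
odorant *concentration*?

The package implements the complete computational chain from raw movies to
that answer, and a synthetic-data generator with full ground truth so every
stage can be validated without any recorded dataset:

1. **Simulation** — movies and trial-structured response tables emulating a
   standard odor-panel experiment: 30 s trials (8 s baseline, 2 s odor, 20 s
   post) at ~15 Hz, 4 trials per stimulus, 13 odorants at one dilution or 3
   odorants at 3 log-spaced dilutions, ~20% activated / ~11% suppressed
   cells, ~10% identity-only cells, GCaMP-like kernel with tau = 2 s,
   annular cell profiles, correlated neuropil and slow drift.
2. **Segmentation** — greedy agglomerative clustering of 4-connected pixels
   by signal correlation (merge the most correlated neighboring pair,
   average their signals, update, repeat for `I` steps), iterative
   pixel-weight estimation, and region selection by size, dispersion and
   border-weight ratio.
3. **Signal extraction** — subpixel DFT frame registration, weighted trace
   extraction, neuropil correction `F_true = F - 0.5 F_neuropil`, per-trial
   dF/F against the 4–8 s baseline median, linear deconvolution
   `r(t) = f'(t) + f(t)/tau` with zero-phase Butterworth smoothing, and
   run-length response detection (>= 2 SD of baseline for 21/19 consecutive
   frames) with an ROC harness for threshold calibration.
4. **Population coding** — single-trial population vectors (mean deconvolved
   dF/F over 4 s after onset), trial correlation matrices and their
   stimulus-structured summaries, lifetime sparseness
   `Sl = (1 - (sum r_j / N)^2 / (sum r_j^2 / N)) / (1 - 1/N)`,
   responsive fractions, 2-of-4 reliability tuning filters, PCA and
   hierarchical ordering.
5. **Decoding** — leave-one-out linear classification (LDA on principal
   components, or one-vs-all linear SVM), time-resolved decoding in sliding
   windows, train-at-timepoint generalization, and the 7-group
   concentration-generalization task in which the tested odorant is
   represented in training only by its most distant concentration
   (chance 1/7).
6. **Spatial analysis** — nearest neighbor index (mean distance from each
   cell of a class to its nearest same-class cell), 1000-fold label-shuffle
   permutation tests, simulated clustered maps (classes confined to 3–4 of
   16 sub-areas), and starter-cell ensemble decoding.
7. **Invariance statistics** — per-cell ANOVA with odorant identity,
   concentration, identity x concentration and trial number as fixed effects
   (type II sums of squares); a cell is *concentration-invariant* iff
   p_identity < 0.01, p_concentration > 0.01 and p_interaction > 0.01 (the
   product-of-tests argument bounds the false-positive rate of the
   intersection below 1%); an identity-shuffle bootstrap (cell labels
   permuted within each odorant-concentration block, trials kept together)
   tests the invariant fraction against a random-coding null; per-site 99%
   criteria and cell-subsampling comparisons round out the module.

## Worked example

```r
library(pirinv)

cfg <- simConfig(nCells = 3000, seed = 1)        # 3 odorants x 3 dilutions
gd  <- generateResponseDataset(cfg)

cl <- classifyPopulation(gd$responses, alpha = 0.01)
round(100 * cl$invariantFraction, 1)
#> [1] 11.7
mean(cellCategory(gd$truth) == "identity_only")  # planted fraction
#> [1] 0.1

bt <- bootstrapIdentityShuffle(gd$responses, nBoot = 200, seed = 2)
round(100 * mean(bt$nullFractions), 2); bt$p
#> [1] 1.33
#> [1] 0.004975124
```

The three-test ANOVA recovers the planted 10% of identity-only cells as an
11.7% invariant fraction (the excess comes from the <= 1% false-positive
rate on null cells and from weakly suppressed cells whose concentration
modulation is genuinely undetectable at this noise level), and the
identity-shuffle bootstrap rejects the random-coding explanation (null mean
~1.3%, p < 0.01).  Decoding the 13-odorant panel with the same generator
(`classifyLoo`) reaches 100% leave-one-out accuracy at 250 cells against a
7.7% chance level, and concentration-invariant subsets generalize across a
100-fold concentration change while concentration-modulated cells do not
(`concentrationGeneralization`).

A full end-to-end run (simulate, detect, deconvolve, decode, spatial and
invariance statistics, JSON report) is one call:

```r
report <- runPipeline(pipelineConfig(sim = simConfig(nCells = 300, seed = 1),
                                     outDir = "out"))
```

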