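---
title: "Models and methods behind pirinv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pirinv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirinv)
```

pirinv analyses two-photon calcium imaging of odor-evoked population
activity, from the raw movie to the detection of a concentration-invariant
subpopulation of odor-coding neurons.  This vignette documents the models,
the tunable parameters, the numerical choices, and what the synthetic-data
generator does and does not emulate — the working knowledge a user needs to
interpret results and a maintainer needs to modify the code.

## The signal model

A trial lasts 30 s: 8 s of pre-stimulus baseline, 2 s of odor, 20 s of
post-stimulus acquisition, sampled at ~15 Hz.  Fluorescence is converted to
dF/F per trial against `F0`, the *median* fluorescence between seconds 4
and 8 of the baseline (the median resists residual transients; the first
4 s are excluded as a guard against carry-over from the previous trial).
A trial whose `F0` is non-positive is marked invalid rather than silently
producing infinities.

The calcium indicator is modelled as a single-exponential kernel with decay
constant `tau` (2 s, GCaMP6s-like).  The firing-rate proxy inverts that
kernel linearly, `r(t) = f'(t) + f(t)/tau`, with the derivative taken as a
*forward* difference times the frame rate.  The forward difference is
deliberate: it concentrates the response to an onset at the frame before
the jump, so an impulse train convolved with the kernel deconvolves back to
(nearly) an impulse train, which the tests verify directly, and the
residual away from impulses shrinks as O(1/frame rate).  The deconvolved
trace is smoothed with a four-pole Butterworth low-pass at 2.5 Hz applied
forward-backward.  Zero-phase filtering matters because all downstream
statistics integrate fixed windows after odor onset; a causal filter would
delay energy out of the window.

Response detection is a run-length rule: a trial is *activated* when dF/F
reaches and remains above `k` times the baseline SD (default `k = 2`; the
SD is computed per trial over the full 8 s baseline) for at least 21
consecutive frames, *suppressed* below the mirrored negative threshold for
19 frames.  Runs must start inside the 4 s response window but may extend
past it.  The 21/19-frame constants are tied to 15 Hz sampling and are
rescaled proportionally at other frame rates.  `calibrateThresholdRoc()`
reproduces the calibration procedure — a grid of `(k, run)` candidates
scored by Youden's J against labelled positives and blank trials — but the
operating point shipped as default is the 2 SD / 21 / 19 rule itself.

## Segmentation

Cells are found from temporal structure, not contrast.  Pixel time courses
are binned (30 s bins by default; the tests use shorter bins on short
synthetic movies), slow global drifts are removed by subtracting a moving
average with a 100 s window (exact for constants, which the tests exploit),
and each pixel's projection onto the average signal over all pixels is
subtracted — after preprocessing every pixel is orthogonal to that global
signal to machine precision.  This projection step is what removes the
shared neuropil component that would otherwise dominate every correlation.

Clustering is greedy agglomeration: among all 4-connected neighboring
region pairs, merge the most correlated pair, set the merged signal to the
*average of the two region signals* (not a size-weighted mean), recompute
the merged region's correlations with its neighbors exactly, repeat for
`I` steps.  Numerical conventions:

* correlation ties break toward the pair containing the lowest
  (row, col)-lexicographic pixel, making the procedure deterministic;
* zero-variance signals get correlation `-Inf`, so silent pixels merge
  last instead of propagating `NaN`;
* `I` defaults to 25,000 for a 256 x 256 field and scales with pixel
  count.  The informative range of `I` is a plateau: somata (high mutual
  correlation) aggregate early, diffuse background late, and pushing `I`
  too far merges cells into the background.  On the 64 x 64 test movies
  the plateau spans roughly `npix - 20*nCells` to `npix - 10*nCells`; the
  tests stop at `npix - 16*nCells`.

Per-pixel weights quantify each pixel's share of the region's common
signal.  The update we run is rank-1 alternating least squares on the
temporally centred full-rate pixel matrix `X`: form the region signal
`x_reg = X w`, re-estimate each pixel's weight as the least-squares loading
of that pixel on `x_reg`, normalise to sum 1, repeat three times (the
iteration converges to the dominant common component, and three iterations
are ample).  A "combination-weight" variant — solving `X w = x_reg` for
`w` — is algebraically a fixed point whenever `X` has full column rank
(the solver just returns the current `w`), so it cannot produce the
non-uniform weight maps the border criterion needs; the loading form is
the one that does what weights are for.  Weights are estimated on
full-rate signals with the global-mean projection removed, for the same
reason as in clustering: otherwise the shared neuropil floor flattens all
loadings toward 1/N.

Candidate regions become cells if they pass three filters: size within
`[minSize, maxSize]` pixels; dispersion (mean squared distance to the
centroid divided by the region size) below `maxDisp = 0.5`, which accepts
disks (a disk's dispersion is 1/(2*pi) ~ 0.16 regardless of radius) and
rejects elongated fragments; and border ratio (mean weight of border
pixels over mean weight of all pixels) below `maxBorder = 0.9`, which
accepts regions whose contribution decays toward the edge, as somata do
and neuropil fragments do not.  Border pixels are region pixels 4-adjacent
to any out-of-region pixel or to the field edge.  Interactive curation is
replaced by `include`/`exclude` id lists.

## Extraction

Frames are registered by translational phase correlation against the mean
of the first 100 frames, with subpixel refinement by locally upsampling
the cross-correlation (default resolution 0.1 pixel).  Traces are weighted
pixel averages `sum(w_i x_i)/sum(w_i)`.  Neuropil correction subtracts
`r = 0.5` times the plain average of all pixels within 20 um of the region
centre, excluding every segmented region's pixels; if the disk is fully
covered by regions the correction is skipped with a warning rather than
inventing a neuropil estimate from nothing.

## Population statistics and decoding

Population vectors are per-trial means of the deconvolved signal over the
4 s after onset.  Trial similarity is Pearson correlation; summaries group
trial pairs by relation (same stimulus, same odorant at different
dilutions split by rank pair, different odorants), always excluding the
diagonal.  Lifetime sparseness uses per-odorant trial means with negative
responses clipped to zero first — with signed inputs the statistic can
exceed its nominal upper bound of 1, and clipping restores the 0 =
uniform, 1 = one-hot interpretation the tests pin down exactly.  A cell
with an all-zero profile is assigned sparseness 0 as the degenerate limit
of "uniformly distributed".  Population vectors for correlation analysis
remain signed; rectification is applied only inside the sparseness
statistic.

The default decoder is LDA on principal components, refitted within every
training fold so no test information leaks into the basis; a one-vs-all
linear SVM (unit cost) is available.  Components are retained up to 95% of
training variance but capped at `max(nClasses - 1, nTrials/4)`: with four
trials per stimulus the trailing components are almost pure noise, the
pooled within-class covariance becomes ill-conditioned, and an uncapped
decoder is both less accurate and biased below chance under label
permutation.  With the cap, permutation calibration sits at chance within
Monte-Carlo error (an acceptance-level test).  Class priors are uniform —
the designs are balanced by construction, and empirical priors would
penalise the left-out trial's class in every fold.  Score ties break
toward the lowest class index.

Leave-one-out is per trial: the assessed trial is excluded from all
fitting.  The concentration-generalization task tests each trial of
odorant `o` at dilution `d` against seven training groups: `o` represented
*only* by its most distant dilution (for the middle dilution, the lowest —
the asymmetry follows the protocol's worked rule), plus the other two
odorants at all three dilutions.  Chance is 1/7.

## Spatial statistics

The NNI of a class is the mean distance from each member to its nearest
other member (Euclidean, micrometres, the cell itself excluded); it is
undefined below two members.  The shuffle test permutes labels over fixed
positions and reports one-sided p-values toward clustering with the
add-one estimator `(#{null <= obs} + 1)/(n + 1)`, which cannot return 0
and is exactly 1 when the observed value exceeds every shuffle.  The
site-level statistic pools per-class NNIs by class-size weighting; classes
below two members are dropped from the pool.  Simulated clustered maps
redraw *positions*: each class is confined to 3 or 4 of 16 equal sub-areas
and its cells are placed uniformly inside them.  Re-labelling at fixed
positions cannot express this construction when the classes tile all
cells — no assignment exists with every class confined to 3 of 16 areas —
so position simulation is the implemented semantics.

## Per-cell ANOVA and the invariance call

Each cell's 36 responses (3 odorants x 3 concentrations x 4 trials, the
response being the mean deconvolved dF/F over the 4 s window) are fit with
odorant identity, concentration, their interaction, and trial number as
fixed effects.  Because the design is balanced and complete, the effect
subspaces are mutually orthogonal after centring and type I/II/III sums of
squares coincide; the implementation therefore computes each term's SS as
the squared norm of the response's projection onto a precomputed
orthonormal basis of that term's contrast subspace.  This makes the
procedure a handful of matrix products — 10,000 cells are classified in
well under a second — and the tests verify the p-values against an
independent type II model-comparison fit to machine precision.  The
balanced-design requirement is enforced, not assumed.

A cell is **concentration-invariant** iff the identity test is significant
(p < alpha, default 0.01) and neither the concentration nor the
interaction test is (both p > alpha).  Since the invariance call is the
intersection of one positive test at level alpha with two negations whose
false-positive contributions are bounded by 1, the false-positive rate of
the call is itself below alpha; the acceptance suite measures it on 10,000
null cells.  Cells with zero residual variance have undefined F statistics
and are reported as `degenerate`, excluded from fraction denominators.
The two-step variant (exclude interaction-significant cells first, then
test the remainder) is available and provably selects the same invariant
set.  Relaxing alpha enlarges the identity-significant set monotonically;
the invariant set itself is not nested in alpha because the negated tests
tighten, which is why only the monotonicity of the identity set is a
tested invariant.

The identity-shuffle bootstrap generates surrogates by permuting cell
indices independently within each of the nine odorant-concentration
blocks, keeping the four trials of a cell-stimulus pair together; each
block's marginal response distribution is exactly preserved (tested by
sorted-value equality).  The reported p is add-one, `(#{null >= obs} + 1)/
(n_boot + 1)`, with 1000 replicates by default (configurable; the tests
use 100-200).  A site is flagged enriched when its observed invariant
count exceeds the 99th percentile of its own null counts.  Subsampling
comparisons exploit that per-cell categories are independent across cells:
categories are computed once and subsample fractions are means over
sampled cells, numerically identical to re-running the ANOVA per
subsample.

## The synthetic-data generator

The generator is the package's study stand-in, with its defaults fixed as
the emulated conditions: 30 s trials (8/2/20 s) at 15 Hz, 4 trials per
stimulus, 13 odorants at 1:10,000 vol./vol. or 3 odorants x
{1:10,000, 1:1,000, 1:100}, 20% activated and 11% suppressed cells, 10%
identity-only (concentration-invariant) cells, a 2 s kernel, and a 0.75
per-trial response probability with per-trial amplitude jitter (SD 0.2 of
the amplitude) to emulate trial-to-trial variability.  Values the emulated
study does not pin down were chosen once as field-realistic and are free
parameters, not claims: response amplitudes N(0.3, 0.1) dF/F floored at
0.05, trial noise SD 0.05 dF/F, neuropil amplitude 0.1 dF/F on a smooth
random field with an AR(1) time course, 2% sinusoidal drift, pixel noise
SD 2 a.u. on a baseline of 100 a.u.  Category semantics define the ground
truth the statistics are scored against: identity-only cells have
per-odorant means exactly constant across dilutions; concentration-
modulated, broadly tuned and suppressed cells scale with concentration
(gains 0.4/1.0/1.6, suppression deepening at higher concentration, as the
activated/suppressed fractions themselves do); mixed cells get distinct
gain permutations per odorant, guaranteeing a real interaction rather
than an accidental one.  Cells are drawn as annular ("donut") profiles —
nuclear-excluded indicator — which is what makes the weight maps and the
border criterion non-trivial; masks are placed without overlap by
rejection sampling and error out when the field cannot hold them.

What the generator does **not** emulate: breathing-locked dynamics and
sniff modulation, odorant adaptation, indicator nonlinearity and
saturation, photobleaching beyond the sinusoidal drift, motion (the
registration tests plant their own shifts), and the heavy-tailed noise of
real photon counting.  Passing tests therefore demonstrate that the
implementation is faithful to the stated models and recovers planted
structure under realistic Gaussian-noise conditions — not that the
pipeline is robust to every artefact of real recordings.

## Problem sizes and reproducibility

All randomness flows from a single master seed through deterministically
derived per-component streams; every generator re-run with the same seed
is bit-identical, and the end-to-end pipeline report is too.  The test
suite exercises the pipeline at sizes chosen for desk-scale runtimes: 64 x
64 movies with 30 cells for segmentation recovery, 3000-cell response
tables for invariant-fraction recovery, 200 label permutations for decoder
calibration, 400 null maps (199 shuffles each) for NNI p-value uniformity,
and 10,000 null cells for the error-rate measurements.  The acceptance
script (`scripts/acceptance.R`) recomputes the analytic endpoints and
error rates from scratch at those sizes.

## Known limitations

* The per-cell ANOVA path requires the full balanced 3 x 3 x 4 design;
  unbalanced or incomplete designs are rejected rather than approximated.
* The greedy clustering is O(I x neighbors) in pure R; a 256 x 256 field
  at `I` = 25,000 is minutes, not seconds.
* The linear deconvolution is a derivative filter, not spike inference; at
  low SNR it amplifies noise, which the 2.5 Hz low-pass only partly
  offsets.
* `simulateClusteredMap` redraws positions, so it cannot preserve a real
  site's exact cell geometry while imposing clustering.
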