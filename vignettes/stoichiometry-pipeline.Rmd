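---
title: "Counting phosphatase subunits by photobleaching: models and methods"
author: "SiMPullCount"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting phosphatase subunits by photobleaching: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SiMPullCount)
```

## The measurement problem

Single-molecule pull-down (SiMPull) immobilizes intact protein complexes
from cell or animal lysate on an antibody-functionalized coverslip and
images them by TIRF microscopy. When a complex carries a single
fluorescently tagged bait (green channel) and a variable number of tagged
prey subunits (far-red channel), the number of discrete, irreversible
photobleaching steps in the far-red intensity trace estimates the number of
labeled prey copies in that one complex. `SiMPullCount` implements the full
analysis chain for this experiment — spot detection, bead-based channel
registration, colocalization, trace extraction and normalization, trace
classification, and replicate-aware statistics — alongside a synthetic-data
generator with known ground truth, so every stage can be validated without
any raw microscopy data.

The biological system the defaults emulate is an ASPP-family scaffold
(single green fluorophore per complex) binding a variable number of PP1
phosphatase catalytic subunits (HaloTag + far-red dye). The scientific
quantity of interest is the *multimeric fraction*: the share of analyzable
complexes whose far-red trace shows two or more photobleaching steps.

## The generative model

`simParams()` collects the acquisition settings:

* 1000 frames per channel at 20 frames/sec (`frames`, `frameInterval`),
  i.e. a 50 s continuous recording;
* exponential photobleaching with half-time 10 s for far-red (one fifth of
  the recording) and 5 s for green (one tenth), matching how laser powers
  are tuned in the real acquisition;
* per-fluorophore dye labeling with probability `labelingProb = 0.4`
  (HaloTag + Janelia Fluor dyes in lysate label roughly 40% of available
  tags), modeled as independent Bernoulli thinning;
* a true far-red copy-number distribution `copyNumberDist`.

Each fluorophore contributes a constant `stepHeight` (50 counts by default)
until its exponential bleach time; a trace is the survivor staircase plus a
`baseline` and i.i.d. Gaussian frame noise (`noiseSd`, default 10 counts =
`stepHeight / 5`).

The default copy-number distribution is a monomer/tetramer mixture whose
weight is solved (via the forward thinning model, `defaultCopyNumberDist()`)
so that after 40% labeling the expected multimeric fraction among
far-red-visible complexes is 0.39 — the wild-type value the pipeline is
designed to measure. Under these defaults roughly 40% of far-red traces are
rejected by the labeling rubric (mostly complexes with zero labeled dyes),
which matches the rejection rate observed in real labeled datasets, where
about 42% of traces are unusable.

What the generator deliberately does **not** model: dye blinking and other
photophysics, partial-frame bleaching, camera-specific noise (EMCCD excess
noise, read-noise structure), spatial drift, and uneven illumination.
Passing tests on synthetic data therefore demonstrates correctness of the
*analysis logic* under the stated noise model, not robustness to every
artifact of real recordings.

```{r sim-example}
set.seed(1)
p <- simParams(nBio = 2L, nTech = 2L, spotsPerField = 50L)
p
sim <- simulateExperiment(p)
sim$traces
```

## The step-counting rubric

Training labels in the original workflow come from humans scoring Z-scored
traces. `countStepsReference()` is a deterministic operationalization of the
written rubric, used both to label synthetic training data and as an
independent check on the classifiers:

* **Segmentation.** Recursive binary segmentation for mean shifts. A split
  is accepted when both plateaus last at least `minPlateau` frames and the
  plateau means differ by more than `stepThreshold` counts. "Sustained" is
  not quantified in the rubric; we fix `minPlateau = 5` frames (0.25 s at
  20 frames/sec) as the shortest dwell a scorer would accept. A second
  guard requires the mean difference to clear `minZ = 4.5` standard errors
  of the robustly estimated frame noise, which keeps a flat pure-noise
  trace at zero changepoints at the default noise level while leaving
  genuine steps (several-fold above frame noise) untouched.
* **Counting.** Plateaus are walked in time order; each sustained decrease
  greater than 25 counts is one photobleaching step. The first sustained
  *increase* stops counting early (a new molecule landed in the spot);
  steps counted up to that point stand.
* **Rejection.** A trace is rejected when no steps were counted, or when
  pooled within-plateau standard deviation exceeds half the step threshold
  — a step smaller than about two noise standard deviations is not visually
  discrete, which is how we operationalize "signal variability prevented
  visualization".
* **Binning.** Far-red: rejected / 1-step / 2-step / 3plus (three and more
  steps are pooled). Green: 1-step only when exactly one event was counted,
  rejected otherwise — the bait must be monomeric.

The thresholds act on raw camera counts; the rubric refuses Z-scored input.
The rubric is a stated operationalization of manual scoring, not a claim of
equivalence to any particular human annotator; traces with bleach events
closer than one plateau to each other or to the recording boundaries are
ambiguous for *any* scorer and are excluded when we measure rubric-vs-truth
agreement (which exceeds 95% at the default noise level).

## The CNN classifiers

At scale, classification is done by two small 1-D convolutional networks
operating on Z-scored traces of fixed length 1000: a 4-class far-red
network and a 2-class green network. The package implements the networks
natively (convolution, ReLU, max pooling, dense layers, softmax, weighted
cross-entropy, Adam) with the heavy loops in compiled code.

Protocol, mirrored from the original workflow:

* **Inverse class frequency weighting.** Losses are weighted by
  `w_c = N / (K n_c)`; the exact normalization is not fixed by the protocol
  description, and any positive rescaling is loss-equivalent, so we use the
  mean-weight-1 convention. The identity `sum(w_c n_c) = N` holds exactly.
* **Stratified 80/20 split** for validation during the architecture
  search, then **5-fold stratified cross-validation** on the finalists, and
  final training on 100% of the labeled data.
* **Architecture search.** `defaultArchGrid()` is a compact declarative
  grid (kernel 5/15/31 x filters 8/16 x one or two dense layers) standing
  in for a larger exploratory sweep; it is config-extensible.
* Optimizer settings (Adam, learning rate 1e-3, batch 128, fixed epoch
  budget, no early stopping) are package choices, all exposed in
  `trainConfig()`.

Determinism: a seed fixes initialization and batch order, so a training run
is reproducible on a fixed platform; bit-identical results across BLAS
builds are not promised, and cross-validation fold assignment is
deterministic per seed but tied to dataset row order. Splits are per-trace;
grouped (per-replicate) splitting can be emulated by subsetting, but the
protocol as described splits traces.

The published validation accuracies of the original trained networks (85.6
± 1.2% green, 73.2 ± 1.0% far-red) are properties of their hand-labeled
worm-lysate datasets, which are not deposited; they cannot be reproduced
from synthetic data and are not targets. What the package can and does
check is behavior with known answers: cross-validated accuracy at or above
0.95 on cleanly separable synthetic traces and collapse to the
majority-class frequency when labels are shuffled. For the shuffled-label
null we disable class weighting and use a short (2-epoch) budget: with
inverse-frequency weights the null model is pushed toward balanced
predictions and sits at mean class frequency rather than at the
majority-class frequency, and a long budget lets it overfit label noise,
either of which would obscure the chance-level comparison.

## Imaging front end

Rendered fields place each complex as a symmetric 2-D Gaussian PSF
(`psfSd`, default 1.2 px) whose per-frame peak amplitude follows the
noiseless survivor staircase; the far-red channel is offset by a pure
translation (`registrationShift`), and bead images contain common bright
points with the same offset. Detection finds smoothed local maxima above a
robust background threshold with sub-pixel centroid refinement. The
candidate cap follows the upstream acquisition convention
`floor(imgArea / 3e5)` — 17 spots for a 2304 x 2304 sensor — which is tied
to the full-sensor scale; synthetic tests on small fields pass an explicit
cap. Registration is translation-only (no evidence of rotation/scaling
correction in the source workflow) estimated from mutual-nearest-neighbor
bead matches, with a 1 px RMS residual guard so unrelated point sets raise
an error instead of returning a garbage shift. Colocalization pairs mutual
nearest neighbors within an inclusive 2 px registered distance, breaking
ties by smallest index; whether the original analysis used mutual NN or a
one-sided window is not documented, so mutual NN — the symmetric, more
conservative choice — is the default and the brute-force enumeration is the
test oracle.

## Quantification and statistics

Classified pairs are filtered to the analyzable subset (green `1-step` and
far-red not `rejected`). Per technical replicate, class percentages are
computed over analyzable traces; the multimeric percentage is
`2-step + 3plus`. Each biological replicate is the unweighted mean of its
technical replicates (matching the outlined-vs-small-dot presentation of
replicate plots; spot-count weighting would down-weight sparse chambers and
is available by operating on the count columns directly), and the
experiment summary is mean ± SEM over biological replicates. Pooling
technical replicates before averaging is the alternative order; the
replicate-mean order is primary throughout.

Group comparisons use a nested one-way ANOVA: the group mean square is
tested against the between-biological-replicate (within group) mean square,
so technical replicates do not pseudoreplicate the test. Tukey's adjustment
uses the studentized range on the same biological stratum. The
implementation is an explicit sums-of-squares decomposition, validated in
the tests against `aov()` with an `Error()` stratum and by null calibration
(uniform p-values) and power checks.

Labeling efficiency is summarized as mean ± SEM of per-replicate
colocalized fractions with the unstained control reported alongside — not
subtracted, since the reference workflow reports both without defining a
subtraction.

Because only ~40% of prey subunits carry dye, observed step counts
underestimate true copy numbers. `expectedObservedClasses()` gives the
forward binomial-thinning map from a true copy-number distribution to the
expected observed distribution, and `invertTrueDistribution()` inverts it
by non-negative least squares on the probability simplex (the forward
operator is lower-triangular with positive diagonal for `p > 0`, so exact
inputs invert exactly; `p = 0` is unidentifiable and raises an error).

```{r thinning}
obs <- expectedObservedClasses(c("1" = 0.6, "3" = 0.4), pLabel = 0.4)
round(obs, 4)
round(invertTrueDistribution(obs, pLabel = 0.4, maxCopies = 3), 4)
```

## Numerical choices and degenerate inputs

* Z-scoring uses the population (1/n) standard deviation over the full
  trace — fixed-length signals, identical convention at training and
  inference; no pre-bleach window is used because none is specified in the
  protocol. Zero-variance traces cannot be normalized and are classed
  `rejected`.
* The half-time fit is least squares on log survival counts with
  zero-count frames excluded and an error if the fitted decay rate is not
  positive.
* Empty technical replicates propagate as flagged rows with `NA`
  percentages and are dropped (with a warning) from the multimeric
  roll-up.
* Segmentation tie-breaks: the residual-sum-of-squares-minimizing split is
  taken; changepoints are reported as the first frame of the new plateau.

## Problem sizes used in the checks

The shipped tests and the acceptance script exercise the pipeline at sizes
chosen to be statistically meaningful for each claim: 2,000 traces for
rubric-vs-truth agreement, 8,000 traces for 5-fold cross-validation of the
far-red network, 6,000/3,000 rubric-labeled traces to train the far-red and
green networks used in quantification, and a full replicate structure of 10
biological x 7 technical replicates with 270 complexes per field (about 150
analyzable pairs per technical replicate) for the multimeric-fraction
recovery; detection-power simulations use 50 independent replicate-level
runs. These sizes are the package's validation design; the functions
themselves scale to arbitrarily larger experiments.

## Known limitations

* The synthetic noise model is additive Gaussian; real sCMOS/EMCCD noise,
  blinking and partial-frame bleaching are not emulated.
* Bleach times are independent per fluorophore; no photophysical coupling
  or FRET-like interactions.
* Registration is translation-only; drift over the 50 s recording is not
  modeled or corrected.
* The rubric is one deterministic reading of a manual protocol; human
  scorers may treat temporally overlapping steps differently.
* Classifier accuracy on real data depends on the realism of training
  traces; the shipped networks are demonstrations trained on synthetic
  data, not replacements for networks trained on annotated experimental
  traces.
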