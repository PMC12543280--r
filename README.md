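# SiMPullCount

Subunit-stoichiometry analysis for two-channel single-molecule pull-down
(SiMPull) photobleaching experiments, with a ground-truth synthetic-data
generator.

## The problem

In a SiMPull experiment, protein complexes are captured from lysate on an
antibody-functionalized coverslip and imaged by TIRF microscopy under
continuous excitation. A complex carrying one green-tagged bait and *k*
far-red-labeled prey subunits produces, at a single diffraction-limited
spot, a green intensity trace with one photobleaching step and a far-red
trace with up to *k* discrete steps. Counting those steps across thousands
of colocalized spots estimates the prey:bait stoichiometry — here, how many
PP1 phosphatase catalytic subunits an ASPP-family scaffold binds. The
quantity of interest is the **multimeric fraction**: among analyzable
complexes (green trace = exactly 1 step, far-red trace not rejected), the
percentage whose far-red trace shows ≥ 2 steps,

```
multimeric% = 100 · (n_2-step + n_3plus) / n_analyzable ,
```

computed per technical replicate, averaged per biological replicate, and
reported as mean ± SEM over biological replicates. Because dye labeling is
incomplete (p ≈ 0.4 per subunit), the observed step-count distribution is a
binomial thinning of the true copy-number distribution,

```
P(observe k) = Σ_n P(true n) · C(n,k) p^k (1−p)^(n−k) ,
```

so the measured stoichiometry is a lower bound; the package provides both
the forward map and its simplex-constrained inverse.

## What is in the package

* **Synthetic data** — `simParams()`, `simulateTrace()`,
  `simulateExperiment()`, `makeLabeledDataset()`, `renderField()`:
  exponential photobleaching traces (1000 frames at 20 frames/sec; far-red
  half-time 10 s, green 5 s), binomial dye-labeling at 40%, replicate
  structure (10 biological × 7 technical), and optional Gaussian-PSF image
  stacks with bead registration pairs.
* **Imaging front end** — `detectSpots()`, `estimateRegistration()`,
  `colocalizeSpots()`, `extractTrace()`: local-maximum spot detection with
  sub-pixel refinement and the `floor(imgArea/3e5)` candidate cap,
  translation registration from bead images, mutual-nearest-neighbor
  pairing within an inclusive 2 px registered distance.
* **Step-counting rubric** — `segmentPlateaus()`, `countStepsReference()`,
  `binClass()`: the deterministic reference labeler (sustained >25-count
  decreases, early stop on an increase, variability-based rejection; far-red
  classes rejected/1-step/2-step/3plus, green rejected/1-step).
* **CNN classifiers** — `cnnArchitecture()`, `trainClassifier()`,
  `crossValidate()`, `searchArchitectures()`, `classifyTraces()`: native
  1-D CNNs (conv → ReLU → max-pool → dense → softmax) with inverse class
  frequency weighting, stratified 80/20 splits and stratified 5-fold CV,
  compiled compute kernels, text-only model serialization.
* **Quantification & statistics** — `classifyPairs()`, `filterPairs()`,
  `classPercentages()`, `percentMultimeric()`, `nestedAnova()`,
  `labelingEfficiency()`, `expectedObservedClasses()`,
  `invertTrueDistribution()`: replicate roll-up and a nested one-way ANOVA
  (group tested against the biological-replicate stratum) with Tukey
  adjustment.

Central containers are Bioconductor-style S4: `TraceSet` (a
`SummarizedExperiment` of traces × frames with replicate metadata) and
`StepClassifier` (trained network + class map + provenance).

## Worked example

Simulate a wild-type-like experiment, train the two classifiers on
rubric-labeled synthetic traces, and quantify:

```r
library(SiMPullCount)

set.seed(1)
p <- simParams()                      # defaults: 0.39 multimeric after thinning
dsF <- makeLabeledDataset(p, nTraces = 6000)
farred <- trainClassifier(dsF, dsF$label,
                          cnnArchitecture(nClasses = 4),
                          trainConfig(epochs = 15))$model
dsG <- makeLabeledDataset(p, nTraces = 3000, channel = "green")
green <- trainClassifier(dsG, dsG$label,
                         cnnArchitecture(nClasses = 2),
                         trainConfig(epochs = 10))$model

sim <- simulateExperiment(simParams(spotsPerField = 270))
res <- quantifyPairs(classifyPairs(sim$traces, green, farred))
res$grandMean; res$sem
#> [1] 37.09568
#> [1] 0.3274869
```

The estimate sits within a few points of the generative 39% multimeric
fraction; the small downward bias comes from fluorophores whose bleach
falls outside the 50 s recording window. Per-replicate detail is in
`res$perTech` / `res$perBio`, and a two-condition comparison runs through
`nestedAnova(values, group, bio)`.

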