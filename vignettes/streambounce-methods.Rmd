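---
title: "Models and methods for stream-bounce disambiguation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for stream-bounce disambiguation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streambounce)
```

## The problem

Two small vertical bars move horizontally toward each other, cross at the
centre of the display, and continue. The physical stimulus is compatible
with two percepts: the bars *stream* through each other or *bounce* off
each other. A brief click at the moment of crossing biases observers toward
"bounce", and observers also tend to repeat their previous report. Because
the display is embedded in dynamic luminance noise whose exact values are
known on every trial, reverse correlation can recover the spatiotemporal
templates that drive each report, and a generative model of the decision
can be tested trial by trial.

`streambounce` implements that full chain: stimulus synthesis, motion-energy
extraction, classification images, a probit-linked linear integration model
of vision, audition and perceptual memory, and a synthetic observer that
closes the loop so every stage can be validated without human data.

## The display

A display is a 20 x 20 space-time luminance matrix: 20 frames at 60 Hz
(333 ms) by 20 vertical bars of 0.085 deg x 0.426 deg. Every cell carries
independent uniform noise on [14.6, 48.3] cd/m^2; the two signal bars add
(or, for dark bars, subtract) a 50 cd/m^2 increment along the two crossing
diagonals. Choices the sources leave open, fixed here once:

* **Noise distribution.** Only the bounds are stated; we use the uniform
  distribution on the closed interval (maximum entropy given bounds).
* **Background.** "Middle grey" is not quantified; we use the noise
  midpoint, 31.45 cd/m^2. It only matters for rendering the noiseless
  signal: in composed displays the increment is added to the noise, so the
  background cancels from every kernel.
* **Trajectory convention.** With an even number of columns the bars cannot
  occupy one shared column at the crossing; the rightward bar sits at
  column *t* on frame *t*, the leftward at column *21 - t*, so they swap
  sides between frames 10 and 11 and never co-occupy a cell. Where both
  trajectories touched the same cell the increments would add.
* **Composition.** The increment is added to the noise sample rather than
  replacing it, and no clipping is applied; all values stay physical at the
  default parameters.

## Motion energy

The visual front end is the classic opponent-energy model: even and odd
Gabor spatial filters, `E(x) = cos(2*pi*f*x) exp(-(x/sigma)^2)` and
`O(x) = sin(2*pi*f*x) exp(-(x/sigma)^2)` with `sigma = 0.5` deg and
`f = 1.1` cycles/deg, paired with slow and fast biphasic temporal filters
`R(t) = (kt)^n exp(-kt) [1/n! - beta (kt)^2/(n+2)!]` with `k = 100`,
`n = 9` (slow) and `6` (fast), `beta = 0.9`. The four separable responses
are combined into two direction-selective quadrature pairs, squared and
summed into rightward and leftward energy maps; their difference is the
opponent map. The scalar covariate fed to the decision model is the mean
absolute opponent energy of the display.

Numerical choices:

* **Sampling.** Filters share the stimulus resolution. The temporal grid is
  the frame times (causal, t = 0 at the first frame); the spatial grid has
  one tap per bar on an odd-length grid centred on zero, spanning the
  display's width. Convolution is zero-padded with "same"-size output,
  causal in time and centred in space. The odd centred spatial grid makes
  mirror symmetry exact: mirroring a display swaps the rightward and
  leftward maps to machine precision, a property the tests exercise.
* **Mean subtraction.** Filters are applied to the display minus its global
  mean, so energy reflects contrast rather than absolute luminance.
* **Onset transient.** Causal filters need a few frames to ramp up, so the
  first frames of every energy map are attenuated; energy that follows the
  crossing is likewise lagged by roughly the filters' time to peak (4-5
  frames). The profile extrema (`energy_peak`, `energy_dip`,
  `energy_drop`) are taken over the full profile, matching the plain
  max-minus-min definition of the drop. For a noiseless display the profile
  minimum therefore sits in the onset frames (near zero), while the
  crossing produces a clear *local* minimum a few frames after the
  geometric crossing, at about 9% of the profile peak with the stated
  filter parameters.
* **Normalization.** A divisive normalization step (opponent energy over
  the display's mean flicker energy plus a small epsilon) is implemented
  and switchable, but the default is the raw opponent energy. The reason is
  empirical and recorded in the tests: the drop in motion energy at the
  crossing grows linearly with the display's total energy — and hence with
  its contrast — only on the raw scale; whole-display divisive
  normalization cancels the contrast dependence entirely. Binned into five
  total-energy groups, the binned drop-versus-energy correlation is ~0.999
  raw. Per display the same correlation is ~0.7: single-display variation
  is dominated by the chance directional structure of the noise rather
  than by contrast, so the linear relation is a property of the binned
  means, which is also how the relation is displayed in the source
  analyses.

The *alternative model* replaces the temporal pair with a single Gaussian
profile (SD 40 ms, centred): one spatial quadrature pair, squared — a
contrast detector with no direction selectivity. It is exactly invariant to
left-right mirroring, and its median-split kernels differ measurably from
the energy model's (the acceptance suite quantifies this as cross-model vs
within-model replicate kernel correlations).

## Classification images

For each response class the per-cell mean luminance and the per-cell mean
squared deviation (MSE, a contrast-energy measure) are computed across
trials; the luminance kernel is the bounce-minus-stream difference of the
means, the contrast kernel the difference of the MSEs. Kernels are then
smoothed with the fixed 3 x 3 low-pass filter
`[0.49, 0.7, 0.49; 0.70, 1.0, 0.70; 0.49, 0.7, 0.49]` and range-scaled so
the maximum absolute value is 1.

Open choices, fixed here:

* **MSE reference.** Deviations are taken from each class's own per-cell
  mean (consistent with per-class templates); a switch allows the grand
  mean.
* **Order.** Difference first, then smoothing, then scaling; smoothing is
  linear, so the order only affects boundary cells.
* **Smoothing boundary.** Zero padding with "same" output (irrelevant up to
  scale after range-scaling); edge replication is available.
* **Permutation test.** Kernel similarity is Pearson correlation over
  flattened cells; significance comes from permuting the cells of the
  second (model-predicted) kernel, two-sided with add-one correction, with
  the p = 0.05 threshold reported as the 95th percentile of the absolute
  null correlations.

A practical note on statistical power: the luminance kernel is
high-signal-to-noise (replicate correlations above 0.99 at 20,000
deterministic-label displays), while the contrast kernel's stable component
is weak at that scale (replicate correlations around 0.2). This is why the
full-scale kernel-derivation procedure used 400,000 displays; the package's
desk-scale default of 20,000 (flag to run larger) resolves the luminance
kernel fully and the contrast kernel only coarsely. Tests therefore anchor
their strong assertions on the luminance kernel.

## The integration model

The decision variable is a weighted linear sum
`Z = omega0 + omega_me * E_v + omega_a * sound + omega_r * prev`, mapped to
a bounce probability by the probit link `p = Phi(Z)`. The coefficients mix
weights and scaling factors and are not constrained to sum to one; they are
estimated by maximum likelihood (`glm`, binomial family, probit link).
First-of-block trials are excluded from modeling, as their previous
response belongs to another block.

* **Covariate scale.** `E_v` enters raw by default; `standardize_energy`
  re-expresses `omega_me` per standard deviation of the energy
  distribution, which is the portable scale the synthetic observer uses.
* **Cross-validation.** 39 folds; where the table has block structure,
  whole blocks are assigned to folds round-robin (after first-trial
  removal a 40-trial block contributes 39 usable trials, which is what
  makes 39 a natural fold count); otherwise random equal-size folds under a
  fixed seed. Calibration uses 50 equal-count bins on Z with 99% binomial
  intervals around the predicted value.
* **Separation.** Quasi-complete separation aborts with an explicit error
  by default (a warning-only mode exists); no silent ridge penalty is
  applied.
* **Model comparison.** All seven nonempty predictor subsets plus the
  three-main-effects model with all pairwise interactions, compared by AIC.
* **Effect tests.** Pearson chi-squared on the 2 x 2 table, 1 df, no
  continuity correction, consistent with the large-sample usage.
* **Model-predicted kernels.** The fitted model's "responses" are sampled
  from Bernoulli(Phi(Z)) under a fixed seed, reproducing the response
  variability of a probabilistic observer; deterministic 0.5-thresholding
  is available.

## The synthetic observer

The generator runs the integration model forward: per trial a fresh noisy
display is drawn, its total motion energy computed and session-standardized,
and the report sampled from Bernoulli(Phi(Z)) using the previous simulated
report within the block. Sound alternates over 40-trial blocks; the first
trial of each block uses a fair-coin previous response and is flagged
excluded. The default generating coefficients
(`omega0 = -0.81, omega_me = 0.35, omega_a = 0.74, omega_r = 0.6`) were
calibrated analytically — a mean-field inversion of the probit link — to the
experiment's marginal statistics (about 27% bounce without sound, 61% with
sound, 43% overall, with strong sequential dependence); they were fixed
before any test was written and are not tuned.

What the generator emulates: the stimulus ensemble, the blocked sound
schedule, sequential dependence, and Bernoulli response variability. What
it does not emulate: lapses, fatigue, attention drift, left-right
anisotropies of real observers (empirical kernels are known to weight the
rightward direction and the pre-crossing epoch more), and cross-observer
heterogeneity beyond independent configurations. Passing tests therefore
demonstrate the correctness and identifiability of the analysis chain under
the model's own assumptions, not that real observers obey the model.

## The simulated polarity experiment

The second-experiment construction is reproduced at reduced scale: 20,000
noisy displays per polarity (the full-scale procedure used 400,000) are
median-split by total motion energy into pseudo-bounce/stream classes;
their luminance kernels (opposite in sign for light vs dark bars) are added
to or subtracted from fresh displays to build high- and low-energy variants
(HI/LO pairs share base displays, isolating the kernel's effect). The
kernel gain is not stated anywhere; the default is the signal increment
(50 cd/m^2 at the kernel peak), configurable. Ten simulated subjects, 32
trials per condition, respond through the integration model with a small
per-subject criterion jitter (SD 0.2) and no sound or memory terms (the
short task is modeled as memoryless); per-subject bounce probabilities are
z-scored across the four conditions before the 2 x 2 within-subject ANOVA.
A known count inconsistency in the described design (126 total trials vs
4 x 32 = 128) is noted and not resolved; the simulation uses 32 per
condition.

## Problem sizes

The test-suite and acceptance-script sizes were chosen as the package's own
desk-scale defaults: sessions of 2,080-10,400 trials (the experiments used
roughly 10,000 per observer), a 10,400-display energy pool with 100
replicate fits for parameter recovery, 5,000 displays for the drop-energy
relation, 20,000 displays per polarity for kernel derivation, and 20,000
permutation iterations where significance is reported. The acceptance
script analyzes a three-observer aggregate of 31,200 trials.

## Known limitations

* The crossing dip of the noiseless display bottoms out near 9% of the
  profile peak (not zero): with filters as coarse as the display (the Gabor
  envelope spans most of its width) the cancellation window is smeared.
* The deposited human datasets are not shipped; the printed aggregate
  statistics can be recomputed by placing the two MAT files under
  `inst/extdata/supplementary/` before installation (see
  `?reproduce_exp1`). Without them the corresponding acceptance check
  reports their absence.
* The MAT v5 codec covers uncompressed double-precision arrays — exactly
  the deposited layouts — and rejects everything else loudly.
* Reaction times are carried through the trial tables but never analyzed.
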