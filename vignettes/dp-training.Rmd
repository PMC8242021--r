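---
title: "Differentially private training: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentially private training: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpsgd)
```

This vignette is the package's own account of the science it
implements: the DP-SGD mechanism and its accounting, the assumptions
each component rests on, the parameters that matter, and the design
choices made where more than one defensible option existed.

## The mechanism

Differential privacy bounds how much any single training record can
change the distribution of everything the training run emits. DP-SGD
achieves an (ε, δ) guarantee by modifying the gradient computation of
ordinary minibatch SGD in three places:

1. the gradient of each sample's loss is computed *individually*
   (per-sample gradients $g_i$);
2. each $g_i$ is clipped to a fixed L2 bound:
   $\bar g_i = g_i \cdot \min(1,\, C/\lVert g_i\rVert_2)$, bounding the
   influence (sensitivity) of any one record on the aggregate;
3. isotropic Gaussian noise with per-coordinate standard deviation
   $\sigma C$ is added to the clipped sum, which is then divided by the
   batch size for the mean update. The effective noise on the update is
   thus $\sigma C / B$ per coordinate.

Any first-order optimiser may consume the result: the privacy guarantee
is already sealed before the optimiser sees the gradient, which is why
`opt_sgd()` and `opt_adam()` need no DP-specific logic.

### Per-sample gradients via weight-sharing replicas

`wrap_model(model, B)` creates B *views* of the model that alias one
shared parameter store (an R environment). Parameter memory is
allocated exactly once; a write through the base store is observable
through every replica. Because every compliant layer is per-sample pure
— its output for sample $i$ is a function of sample $i$ alone — the B
replica passes can be executed as a single batched dispatch, and the
backward pass simply refrains from summing parameter gradients over the
batch axis. The result is *exact*: the test suite holds the engine to
the definitional serial oracle (`serial_oracle()`, an independent
one-sample-at-a-time loop) to within 1e-5 on random dense, convolution,
batch-norm and group-norm architectures.

Parallelism here is a contract, not a mechanism: results are
independent of scheduling order, and a batched single-dispatch
execution satisfies the contract on one CPU exactly as a thread-pool
would on many.

### Model surgery

Batch normalisation with running statistics breaks both requirements of
the setting: it couples samples within a batch (per-sample purity
fails) and it accumulates a *non-private* summary of past batches in
its buffers. `scan_model()` flags such layers; `fix_model()` disables
the collection of running statistics so the layer computes with current
statistics in training and evaluation alike, keeping its learnable
affine parameters. In the per-sample execution regime "current
statistics" are single-sample (per-channel, spatial) statistics — the
batch-size-1 convention this package adopts deliberately, since
statistics-free batch-norm is otherwise undefined at batch size one;
this makes the repaired layer an instance-normalisation in effect and
restores exact per-sample purity. The alternative repair,
`strategy = "group_norm"`, substitutes group normalisation reusing the
same gamma/beta. Layers of unknown kind fail *closed*: surgery raises
rather than certifying a model it cannot analyse, because the privacy
guarantee outranks convenience.

### Secure noise

DP noise must be unpredictable to an adversary, so the default noise
source draws uniforms from the operating system's CSPRNG
(`/dev/urandom`) and transforms them with the Box–Muller map — chosen
over rejection samplers because it is exact and needs nothing but
uniforms. Secure mode rejects seeds outright instead of silently
downgrading. The seeded insecure mode exists for tests and examples and
is labelled as such everywhere it appears; `run_config()` refuses a
global seed while the secure RNG is on, and refuses the insecure source
unless explicitly opted into.

## Accounting

### Gaussian DP

A mechanism is μ-GDP when distinguishing any two neighbouring datasets
from its output is no easier than distinguishing $N(0,1)$ from
$N(\mu,1)$. Composition over T Poisson-subsampled Gaussian steps at
rate $q = B/n$ has the central-limit form

$$\mu = q\sqrt{T\,(e^{1/\sigma^2}-1)},$$

and uniform (shuffled fixed-size batch) subsampling the variant

$$\mu = q\sqrt{T}\sqrt{e^{1/\sigma^2}\Phi(1.5/\sigma) +
3\Phi(-0.5/\sigma) - 2}.$$

Conversion to (ε, δ) goes through the Gaussian trade-off dual
$\delta(\varepsilon;\mu) = \Phi(-\varepsilon/\mu+\mu/2) -
e^\varepsilon\Phi(-\varepsilon/\mu-\mu/2)$, inverted by bracketed
root-finding (bracket $[0, 10^4]$ with decade expansion, absolute
tolerance $10^{-9}$). The $e^\varepsilon\Phi(\cdot)$ product is
evaluated in log space; the naive product overflows to NaN for large ε
and would break the bracket.

### Rényi DP

For integer orders $\alpha \ge 2$ the Rényi divergence of one
Poisson-sampled Gaussian step has an exact binomial-sum form, evaluated
here in log space (log-sum-exp over `lchoose` terms) and composed
additively; conversion takes the minimising order of
$T\varepsilon(\alpha) + \log(1/\delta)/(\alpha-1)$ over 2..256. The
integer-order grid was chosen because the bound is exact there — no
numerical quadrature — and the grid comfortably brackets the optimum
for all schedules of interest (the reference schedules select orders 36
and 132). At $q = 1$ the bound collapses to the Gaussian-mechanism
value $\alpha/(2\sigma^2)$, which the tests assert to machine
precision, and small orders are held to an independent plain-arithmetic
oracle.

### Reference schedules

Two schedules serve as the package's reproduction anchors, with
$B = 32$ and $\delta = 10^{-5}$:

```{r}
classification <- training_schedule(4389, 32, epochs = 20, sigma = 3.0)
segmentation   <- training_schedule(5184, 32, epochs = 5, sigma = 5.0,
                                    clip_norm = 0.5)
audit(classification, "gdp-poisson")$epsilon
audit(segmentation, "gdp-poisson")$epsilon
audit(classification, "rdp")$epsilon
audit(segmentation, "rdp")$epsilon
```

GDP certifies a strictly smaller spend than RDP on both — the
"tighter accounting" property the GDP analysis is valued for. Step
counting is $T = E\lceil n/B\rceil$: one full traversal of the data per
epoch, deterministic. The sampler actually used during training
(shuffled-uniform or Poisson) is configurable and the accounting mode
is always reported next to ε, because the Poisson accountant analyses
the Poisson mechanism: empty Poisson batches are kept, become
noise-only steps, and are counted.

### The watchdog

`train_private()` accounts *prospectively*: before step $t+1$ it
evaluates the budget that step would reach and halts if it would exceed
`eps_budget`, so the budget is never overrun — the strict reading of
"interrupt when exhausted". `steps_within_budget()` inverts the
accountant analytically (bisection on the step count, using ε's
monotonicity in T); the tests require the training loop to halt at
exactly that step on several schedules.

## Data handling

Splits round the training share half-up (an 85/15 split of 5163 gives
4389/774) and are subject-disjoint whenever subject identifiers are
present, at the cost of hitting the quota only up to subject
granularity. Class weights are $1 - n_c/n$, assigning the minority
class the larger weight. The privacy unit is one image; occurrence
counting gives augmented presentations no discount — every appearance
of a record in a step counts, and the step count reported to the
accountant includes noise-only steps.

Under Poisson sampling the mean update divides by the *nominal* batch
size B (the expected batch size), not the realised one: the realised
size is itself data-dependent, and the accounting analyses the
fixed-rate mechanism.

## Synthetic fixtures

The generators produce phantoms with the statistical *shape* of the two
target tasks: class-imbalanced bright-opacity classification images
(default counts 1339/3824, mirroring the emulated case mix) and
star-convex "organ" blobs with exact binary masks for segmentation
(default 512 pairs — deliberately scaled down from the thousands of
slices of the emulated setting, since desk-scale training needs data
but privacy accounting needs only n). They are seeded and
byte-deterministic (8-bit quantisation happens once, before writing).
What they do *not* have: anatomical structure, scanner noise
characteristics, inter-reader label noise, or distribution shift — so a
passing end-to-end test demonstrates the *mechanism* (training under
clipping and noise still learns; budgets are certified correctly), not
clinical-grade utility on real radiographs.

Augmentation draws affine transforms (rotation, scaling, translation,
shearing for classification; rotation, translation, scaling, flipping
plus Gaussian image noise for segmentation) applied identically to
image and mask; masks are resampled nearest-neighbour so they stay
binary, images bilinearly. Default ranges (±15°, scale 0.9–1.1,
translation ±10%, shear ±10°, noise sd 0.02) are package defaults,
documented rather than inherited from anywhere.

## Numerical choices and degenerate inputs

- Clip factors use $\min(1, C/\max(\lVert g_i\rVert, 10^{-12}))$: zero
  gradients pass through without division failure; clipping is
  idempotent and global (one norm over the full flattened gradient per
  sample, matching the single-norm formulation of the algorithm).
- $\mu = 0$ is treated as the degenerate no-release mechanism
  (δ = 0, ε = 0); non-finite μ returns ε = ∞.
- δ values below double precision cannot be inverted and the tests do
  not pretend otherwise.
- The plateau scheduler halves the learning rate after validation loss
  fails to improve by a relative $10^{-3}$ for 2 consecutive epochs;
  the patience and factor follow the plateau-halving convention, the
  threshold is a documented package default.
- Weight initialisation is He-scaled from R's RNG at model
  construction; seed beforehand for reproducible weights.

## Problem sizes in the test suite

The suite runs on one CPU in well under the package's own patience:
engine-vs-oracle equivalence uses batches up to 16 on nets of a few
thousand parameters; noise calibration checks $10^5$ draws against
$\sigma C/B$ (within 2%); the end-to-end private smoke run trains a
~1000-parameter CNN on a 300-image 32×32 fixture for 5 epochs
(σ = 1, C = 1) and reaches held-out ROC-AUC above 0.8. Accounting tests
are analytic and run in milliseconds at the full reference sizes
(n = 4389 and 5184), which require no data.

## Known limitations

- Per-record (individual) accounting, heterogeneous σ schedules, and
  numerical f-DP composition beyond the CLT are out of scope; the CLT
  form is an approximation that is excellent at these q and T but is
  not an exact finite-sample bound.
- The integer-order RDP bound is an upper bound; other RDP variants
  (continuous orders, different subsampled-divergence bounds) can give
  slightly different numbers.
- The layer library is deliberately small (dense, conv2d stride 1,
  average pooling, batch/group norm, relu/sigmoid); it exists to give
  the engine a concrete, fully-tested substrate, not to compete with a
  deep-learning runtime.
- Secure noise is not hardened against floating-point representation
  attacks, and there is no GPU-resident CSPRNG.
- Subject-level privacy units are supported in the data handling
  (subject-disjoint splits) but the accountant counts image-level
  units.
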