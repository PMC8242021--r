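# dpsgd: differentially private training with per-sample gradients

Training a neural network on medical images leaks information about the
patients in the training set unless the training algorithm itself bounds
that leakage. `dpsgd` implements differentially private stochastic
gradient descent (DP-SGD) for image classification and segmentation in R,
for researchers who need formally certified privacy budgets alongside
their models:

1. **per-sample gradients** computed exactly, through weight-sharing
   model replicas — the minibatch is dispatched through B views of one
   parameter store, so replication costs no parameter memory;
2. **clipping** of each sample's gradient to an L2 norm bound C, then
   **calibrated Gaussian noising** of the aggregate with per-coordinate
   standard deviation σC;
3. **privacy accounting** under Gaussian Differential Privacy (GDP, the
   primary accountant) and Rényi Differential Privacy (RDP, for
   comparison), with a watchdog that interrupts training before the
   privacy budget ε is exceeded;
4. **model surgery** that detects layers incompatible with per-sample
   semantics (batch-norm running statistics) and repairs them;
5. **cryptographically secure noise** drawn from the OS entropy pool;
6. **privacy-aware data handling** (uniform and Poisson subsampling,
   occurrence counting, subject-disjoint splits) and **synthetic fixture
   generators** so everything is testable offline.

## The model

DP-SGD makes one optimiser step per minibatch:

    ḡᵢ = gᵢ · min(1, C / ‖gᵢ‖₂)                      (clip each sample)
    g̃  = ( Σᵢ ḡᵢ + 𝒩(0, σ²C² I) ) / B                (aggregate + noise)

Composed over T steps at sampling rate q = B/n, the GDP accountant
certifies (Poisson subsampling, CLT composition)

    μ = q · √( T · (e^{1/σ²} − 1) )

and converts μ to (ε, δ) through the Gaussian trade-off dual

    δ(ε; μ) = Φ(−ε/μ + μ/2) − e^ε · Φ(−ε/μ − μ/2),

inverted by root-finding for the smallest ε at a target δ. The RDP
accountant evaluates the exact integer-order bound for the
Poisson-sampled Gaussian mechanism,

    ε(α) = 1/(α−1) · log Σₖ C(α,k) (1−q)^{α−k} q^k e^{k(k−1)/(2σ²)},

composes additively over steps and takes
ε = min_α [ T·ε(α) + log(1/δ)/(α−1) ] over orders 2..256.

## Worked example

Certify the budget of a segmentation schedule (n = 5184 slices,
minibatch 32, 5 epochs, σ = 5.0, C = 0.5, δ = 1e-5):

```r
library(dpsgd)
sch <- training_schedule(n = 5184, batch_size = 32, epochs = 5,
                         sigma = 5.0, clip_norm = 0.5, delta = 1e-5)
audit(sch, "gdp-poisson")
#> privacy spent after 810 steps [gdp-poisson]:
#>   mu      = 0.0354907
#>   epsilon = 0.110041
#>   delta   = 1e-05
audit(sch, "rdp")
#> privacy spent after 810 steps [rdp]:
#>   epsilon = 0.173888
#>   delta   = 1e-05
#>   best RDP order = 132
```

The run would spend ε ≈ 0.11 (GDP): a strong guarantee — and the GDP
analysis is visibly tighter than the RDP bound of ε ≈ 0.17 for the same
mechanism.

Train a small CNN privately on a generated fixture (the insecure seeded
RNG is for reproducible examples only; real private runs keep the
default secure RNG, which refuses seeds):

```r
dir <- tempfile()
m <- generate_classification(dir, n_negative = 100, n_positive = 200,
                             size = 32, seed = 501)
train <- load_images(m, "train"); train$val <- load_images(m, "val")
set.seed(502)
model <- fix_model(tiny_cnn(32, channels = 4, with_batch_norm = TRUE))$model
sch2 <- training_schedule(n = dim(train$x)[1], batch_size = 32, epochs = 5,
                          sigma = 1.0, clip_norm = 1.0, delta = 1e-5)
cfg <- run_config("classification", model, sch2, optimiser = "sgd", lr = 0.5,
                  secure_rng = FALSE, insecure_ok = TRUE, seed = 503)
tr <- train_private(cfg, train)
tr
#> run trace: 40 steps, halt = completed, epsilon = 4.583
#>   validation metric = 0.9612
```

Forty noisy steps reach held-out ROC-AUC 0.96 at a spend of ε ≈ 4.6 on
this deliberately easy fixture; `tr$steps` holds the per-step loss, ε
and learning-rate log, and `tr$halt_reason` becomes `budget_exhausted`
when an `eps_budget` stops the run early.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/dpsgd.R audit --n 5184 --batch 32 --epochs 5 \
    --sigma 5.0 --clip 0.5 --delta 1e-5 --mode gdp-poisson
Rscript inst/cli/dpsgd.R generate-data --task segmentation --out data/ --seed 1
Rscript inst/cli/dpsgd.R train --config run.yaml
```

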