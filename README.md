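# enetcaem

Lightweight multi-scale attention networks for plant-disease image
classification in R.

Compact CNNs for field diagnosis of leaf and fruit diseases face three
recurring obstacles: lesions appear at widely varying scales, cluttered
backgrounds mimic disease features, and the datasets are small and
imbalanced. This package implements, end to end and without any external
deep-learning framework, a classifier built for that regime — a reduced
EfficientNetB0 backbone whose 13 inverted-bottleneck (MBConv) blocks carry
**multi-scale efficient channel attention** (parallel 1-D convolutions of
kernel size 3/5/7 over the pooled channel sequence, mean-fused, sigmoid
gated, followed by a light 7×7 spatial attention), a **channel context
module** in the middle stages (GAP → 1×1 bottleneck `C/r` → 1×1 restore →
sigmoid gate), a head of **light atrous spatial pyramid pooling** (3×3
dilated convolutions at rates 3/6/9 plus a 128-channel global branch,
concatenated directly), **learnable mixed pooling**
`y = λ·max + (1−λ)·avg` with trainable `λ ∈ [0,1]`, and **learnable
stochastic depth** on every residual (`p = σ(θ)·p_max`, per-block `θ`).
Training follows the matching recipe: Adam, batch 32, cosine-annealed
learning rate, label-smoothed cross-entropy.

Around the model sit the full pipeline stages: a seeded 8-transform
augmentation policy, resampling-based class balancing, stratified 8:1:1
splitting, per-class precision/recall/F1 metrics with stratified k-fold
cross-validation, exact parameter/MAC accounting, and a synthetic
lesion-image generator so everything is testable offline. All tensor
operations — grouped/dilated convolution (im2col + GEMM via
RcppArmadillo), batch norm, the attention blocks — implement their own
backward passes, verified against nested-loop oracles and finite
differences in the test suite.

## Worked example

Build both architectures and read off their complexity:

```r
library(enetcaem)
set.seed(1)
print(build_baseline_b0(num_classes = 8))
#> <caem_network: baseline_b0>
#>   MBConv blocks : 16
#>   classes       : 8
#>   parameters    : 4.02 M
#>   MACs @224x224 : 0.385 G
print(build_enet_caem())
#> <caem_network: enet_caem>
#>   MBConv blocks : 13
#>   classes       : 8
#>   parameters    : 6.55 M
#>   MACs @224x224 : 0.469 G
```

The parameter counts reproduce the reference figures (4.02 M baseline,
6.55 M full model) exactly; the MAC counts are pure
convolution/depthwise/linear multiply-accumulates at 224×224 (counters
that also bill normalisation and element-wise operations report ~0.41 G
for the baseline — see the methods vignette for the convention).

Train the desk-scale preset on synthetic lesions and evaluate:

```r
ds  <- generate_dataset(synth_spec(n_per_class = 50, image_size = 48, seed = 11))
sp  <- stratified_split(ds, c(0.8, 0.1, 0.1), seed = 11)
set.seed(123)
net <- build_enet_caem(enet_caem_mini_config())
fit <- train_network(net, sp$train, sp$val, train_config(epochs = 8, seed = 123))
summary(fit)
#> Fitted enet_caem (0.04 M parameters), 8 epochs
#>   best validation accuracy: 0.900 (epoch 5)
#>   final training loss:      0.8718
#>   mixed-pooling lambda:     0.496
#>   drop probabilities:       0.000 0.050 0.100
evaluate_model(fit, sp$test)$metrics
#> accuracy: 0.9250
#> ...
#> macro: P 0.9531  R 0.9250  F1 0.9176
```

The summary shows the two learnable regularisers doing their job: `λ`
has moved off its 0.5 initialisation and the per-block drop probabilities
sit on their 0→0.1 depth ramp. Training loss cannot reach 0 here — label
smoothing (ε = 0.1) imposes an entropy floor of about 0.60 for 8 classes.
With the default 30-epoch budget the validation accuracy on this separable
dataset reaches 1.0 (see `tests/testthat/test-acceptance.R`).

A thin CLI covers the same pipeline from a shell
(`inst/cli/enetcaem synth|augment|split|build|train|eval|cv`).

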