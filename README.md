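# loopcaps

Capsule networks for predicting YY1-mediated chromatin loops from paired
DNA sequences.

The transcription factor Yin Yang 1 (YY1) dimerizes to bridge enhancer and
promoter elements into chromatin loops; deleting or mutating YY1 binding
sites disrupts those contacts and the expression of the genes they serve.
Given two fixed-length anchor sequences, each centered on a YY1 motif
(506 bp in the published HCT116/K562 benchmark), `loopcaps` classifies
whether the pair forms a loop. It is aimed at regulatory-genomics groups who
want a trainable-from-scratch, fully tested R implementation of this
sequence-pair architecture — including its synthetic benchmark, evaluation
protocol and cross-cell-type transfer analysis — with no Python stack and no
downloads required.

## Model

Both anchors are one-hot encoded (`A=(1,0,0,0)`, ..., `T=(0,0,0,1)`) and
pass through one weight-shared encoder: three parallel 1-D convolutions
(kernels 3/5/7, 32 filters each, stride 2, ReLU), a fusion convolution
(kernel 5, 32 filters, stride 2), and a bidirectional GRU (32 units per
direction). The two feature maps are concatenated along the position axis
and fed to a convolutional primary-capsule layer (16 channels × 8
dimensions, kernel 9, stride 2, squash nonlinearity
*v* = (‖s‖²/(1+‖s‖²))·s/‖s‖) and a two-capsule digit layer coupled by
three rounds of dynamic routing-by-agreement
(c<sub>ij</sub> = softmax<sub>j</sub> b<sub>ij</sub>,
s<sub>j</sub> = Σ<sub>i</sub> c<sub>ij</sub> û<sub>j|i</sub>,
v<sub>j</sub> = squash(s<sub>j</sub>),
b<sub>ij</sub> += û<sub>j|i</sub>·v<sub>j</sub>). The digit-capsule lengths
‖v₀‖, ‖v₁‖ are the class evidence; training minimizes the margin loss

> L<sub>k</sub> = T<sub>k</sub> max(0, m⁺−‖v<sub>k</sub>‖)² + λ(1−T<sub>k</sub>) max(0, ‖v<sub>k</sub>‖−m⁻)²,  m⁺ = 0.9, m⁻ = 0.1, λ = 0.5

with Adam (batch 64, learning rate 5·10⁻⁴) and early stopping. Every layer
and its backward pass is implemented in this package (hot loops in
RcppArmadillo) and verified against scalar reference implementations and
finite-difference gradient checks. `use_msc = FALSE` / `use_bigru = FALSE`
reproduce the published ablations.

## Worked example

Simulate a planted-motif dataset (the generator mirrors the benchmark's
shape: fixed-length pairs, balanced classes, and a conjunctive two-anchor
signal — positives carry a YY1-like 12-mer in *both* anchors, negatives in
at most one), train a reduced model, and evaluate a held-out split:

```r
library(loopcaps)

sim <- simulate_pairs(2000, seq_len = 100, noise_rate = 0.1, seed = 2026)
pairs_summary(sim)
#> # A tibble: 1 × 4
#>       n n_pos n_neg seq_len
#>   <int> <int> <int>   <int>
#> 1  2000  1000  1000     100

test_ids <- stratified_folds(sim$label, 5, seed = 1) == 1   # 20% held out
fit <- fit_capsnet(sim[!test_ids, ],
                   caps_config(seq_len = 100),
                   train_config(max_epochs = 12, patience = 4, seed = 11))
glance(fit)
#> # A tibble: 1 × 9
#>   n_params epochs best_epoch best_val_loss n_train n_valid seq_len use_msc use_bigru
#>      <int>  <int>      <int>         <dbl>   <int>   <int>   <int> <lgl>   <lgl>
#> 1   154944     12         11        0.0448    1440     160     100 TRUE    TRUE

evaluate_pairs(fit, sim[test_ids, ])
#> <loop_metrics>
#>   TP 193  TN 197  FP 3  FN 7
#>   Acc 0.9750  Precision 0.9847  Recall 0.9650  F1 0.9747
#>   AUC 0.9932  AUPR 0.9941
```

`n_params` counts every trainable weight; `best_val_loss` is the margin
loss on the internal early-stopping split at the restored best epoch. In
the evaluation report, `Acc`/`Precision`/`Recall`/`F1` use the argmax rule
over the two capsule lengths, while `AUC`/`AUPR` rank pairs by the loop
capsule's length — here the model separates held-out loop from non-loop
pairs with AUC ≈ 0.99, which is what a clean conjunctive motif signal at
10% substitution noise supports. `autoplot(fit)` draws the loss curves and
`autoplot(evaluate_pairs(...))` the ROC/PR curves; `tidy()`/`glance()`
methods return tibbles throughout.

Other entry points: `crossval_capsnet()` (stratified 10-fold CV with
per-fold and pooled metrics), `cross_cell_auc()` (train-on-one,
evaluate-on-other transfer matrices), `export_embeddings()` (capsule
vectors for t-SNE-style projection), `read_pairs()` /
`read_paired_fasta()` for the benchmark's formats, and
`inst/cli/loopcaps.R`, a command-line wrapper with `simulate`, `train`,
`evaluate`, `crosscell`, `predict` and `embed` subcommands.

## Tests

```r
# after installing
testthat::test_dir("tests/testthat", package = "loopcaps",
                   load_package = "installed")
```

The suite includes analytic identities (squash fixed points, margin-loss
worked values, routing coupling coefficients), equivalence against scalar
brute-force oracles (routing, convolution, GRU, ROC/PR AUC),
finite-difference gradient checks, shape and cross-validation invariants,
and end-to-end learnability plus cross-condition transfer experiments on
simulated data. The training-based tests take several minutes on one CPU.

## Acceptance script

`scripts/acceptance.R` re-runs the core pipeline from scratch against the
installed package — simulates a planted-motif dataset, trains the capsule
network with early stopping, prints the held-out evaluation report — and
writes its JSON result file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
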