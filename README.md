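# gnmc — joint gene-network estimation and multi-class classification

`gnmc` classifies samples (cell lines, patients) into three or more
phenotype classes from gene expression **through** a gene regulatory
network that is estimated at the same time as the classifier. Most
network-based classifiers consume a pre-estimated network; because the
class labels never inform which edges are kept, the resulting network
cannot explain *why* samples fall into a clinical state. Here the network
of regulator-to-target effects `B` and the multinomial classifier
`(θ_0, Θ)` minimise one objective jointly:

    -loglik(B, Θ)  +  ½ Σ_j Σ_i (y_ij − x_i'β_j)²
      + λ₁ Σ_j ‖β_j‖₁ + (λ₂/2) Σ_j ‖β_j‖₂²
      + λ₃ Σ_g ‖θ_g‖₁ + (λ₄/2) Σ_g θ_g' Lˢ_g θ_g

with class probabilities `π_g(x) ∝ exp(θ_g0 + x'Bθ_g)` — the classifier
acts on network-transformed expression `x'B`, and `Lˢ_g` is the
sign-adjusted normalised Laplacian of the graph implied by the current
`B`, which smooths coefficient magnitudes along estimated edges and makes
hub genes cheap to select. Fitting is Fisher-scoring working responses
plus cyclic coordinate descent with soft-thresholding (compiled engine),
with a step-halving safeguard so the objective trace never increases.
Penalties are selected by a validation-set BIC whose degrees of freedom
count the nonzero classifier coefficients.

The package is aimed at statistical genomicists who want interpretable
multi-class classification: the fitted object exposes the network (edge
lists, per-class re-estimated networks, common edges), the classifier
coefficients (marker genes), and the usual S3 surface
(`print`, `summary`, `coef`, `predict`, `plot`, `fitted`, `residuals`).

## Worked example

The built-in Monte-Carlo generator defines the study conditions: `T`
transcription factors with N(0,1) expression, each regulating ten target
genes (effect 0.7 in scenario 1), unit-variance target noise, and labels
drawn from the multinomial logistic model with a 44-entry coefficient
pattern per signal-carrying class; n = 150 samples split 120/15/15.

```r
library(gnmc)

sim <- simulate_scenario(scenario = 1, mode = "activators", n_tf = 10,
                         n = 150, seed = 1)
sim
#> Simulated dataset: scenario 1 (activators), 10 TFs, 100 targets, n=150
#>   class counts: class1=54 class2=55 class3=41
#>   split: train=120 validation=15 test=15

sel <- gnmc_select(sim$X, sim$labels, Y = sim$Y,
                   split = sim$split[c("train", "validation")])
sel
#> BIC selection over 75 lambda combinations
#>   selected: l1=2.4 l2=12 l3=6 l4=0 (BIC 24.503, df 2)
#> Joint network / multinomial classifier fit (gnmc)
#>   120 samples, 10 regulators -> 100 targets, 3 classes
#>   lambda: l1=2.4 l2=12 l3=6 l4=0
#>   9 cycles, converged; objective 4203.94
#>   nonzero: B 825/1000, Theta 2/300

test <- sim$split$test
pred <- predict(sel, sim$X[test, ])
classification_accuracy(sim$labels[test], pred)
#> [1] 0.7333333

selection_metrics(sim$true_B, coef(sel, type = "network"))[c("tpr", "tnr")]
#> $tpr
#> [1] 1
#> $tnr
#> [1] 0.1855556
```

Reading the output: the BIC picked a light lasso with some ridge on the
network and a classifier using 2 of 300 possible coefficients; held-out
accuracy is 0.73 on the 15 test samples. For context, the generating
model's own Bayes accuracy under these conditions is about 0.70 (labels
are drawn from the softmax, not assigned deterministically), so
replicate-level accuracies in this range are what the conditions support.
All 100 true edges are recovered (TPR 1.00); at this lightly-penalised
`λ₁` many spurious small edges remain (TNR 0.19) — larger `λ₁` values in
the grid trade that off.

`run_benchmark()` repeats simulate → select → fit → score over replicates
for the joint model (`gnmc`), the pre-estimated-network baseline
(`prnw`), and expression-level lasso/elastic-net (`la`, `ela`), mirroring
the accuracy and support-recovery tables of Monte-Carlo studies.
`class_networks()`, `variance_filter()` and `anova_screen()` support the
real-data interpretation workflow on square gene sets (per-class network
re-estimation, common-edge extraction, differential-expression screen).

A thin command line lives at `exec/gnmc.R`
(`simulate | fit | predict | benchmark | networks`).

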