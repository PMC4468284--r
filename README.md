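# mrrmrr

Robust, regularized supervised variable selection for noisy two-group
high-dimensional data (n ≪ p), with the classical minimum-redundancy
maximum-relevance (MRMR) baselines, an LDA/leave-one-out evaluation
harness, and a synthetic benchmark generator with three noise models.

## What it does

Given an n × p numeric matrix **X** with binary group labels **Y**, the
package performs greedy forward selection of m variables maximizing

    Rel(Z) − γ · Red(Z, S),    γ ≥ 0,

where, in the MRRMRR configuration (the default):

* **Relevance** is the absolute robust correlation |r_LWS(Y, X_k)|
  derived from least weighted squares (LWS) regression of the variable
  on the labels — a weighted sum of *ordered* squared residuals with
  rank-decreasing weights (adaptive 0/1 trimming, linear, or logistic
  schemes). With adaptive weights the coefficient keeps full efficiency
  on clean normal data and a finite-sample breakdown point of at least
  min(ε⁰, (⌊(n+1)/2⌋ − 2)/n) under contamination.
* **Redundancy** is the regularized squared multiple correlation
  r̃\*(Z, S) = R\*ᵀ_ZT (R\*_TT)⁻¹ R\*_ZT computed from the jointly
  shrunken correlation matrix R\* = (1 − λ\*) R̃ + λ\* I, with the
  distribution-free analytic intensity
  λ\* = Σ_{i<j} var-hat(S_ij) / Σ_{i<j} S_ij², so the redundancy of a
  candidate against the selected set is well defined even when the set
  outgrows the sample size.

Classical relevance measures (|r|, |r_S|, mutual information) and
redundancy measures (|r|, |r_S|, MI, Kolmogorov–Smirnov p-value, sign
test p-value) are available behind the same interface for comparison.
Classification performance is assessed by leave-one-out
cross-validation of pooled-covariance LDA on the selected columns, with
accuracy defined as (sensitivity + specificity)/2 and γ optimized over
a grid.

## Worked example

Simulate a small two-group benchmark (12 + 12 samples, 100 variables, 4
informative at 2 SD), contaminate every cell with heavy-tailed Cauchy
noise, and run the robust selection:

```r
library(mrrmrr)
d   <- generate(generator_spec(n1 = 12, n2 = 12, p = 100, p_inf = 4,
                               effect = 2, seed = 7))
dc  <- contaminate(d, noise_model("cauchy"), seed = 8)
cfg <- selection_config(m = 4, gamma = 0.9, seed = 7)
mrmr_forward(dc, cfg)
#> selection_result: 4 variables (gamma = 0.9, relevance = lws_adaptive_abs, redundancy = reg_multiple)
#>   index relevance redundancy     score    lambda
#> 1     3 0.8662763         NA 0.8662763        NA
#> 2    91 0.5452351 0.01169185 0.5347124 0.5774745
#> 3     2 0.7955605 0.26381666 0.5581255 0.2220418
#> 4     1 0.6775096 0.25637114 0.4467756 0.1903412
```

Each row is one greedy step: the winning column, its robust relevance,
its regularized redundancy against the set selected so far, the
resulting criterion score, and the shrinkage intensity λ\* of the joint
correlation matrix at that step (large λ\* = noise-dominated step).
Despite the Cauchy noise, three of the four planted variables (columns
3, 2, 1) are recovered. Evaluating over a γ grid:

```r
gamma_search(dc, cfg, gamma_grid = c(0, 0.3, 0.6, 0.9))
#> cv_report: best gamma = 0 (accuracy 1.000)
#>  gamma sensitivity specificity accuracy
#>    0.0           1           1        1
#>    0.3           1           1        1
#>    0.6           1           1        1
#>    0.9           1           1        1
```

The leave-one-out LDA on the selected columns classifies every sample
correctly at every γ (ties go to the smallest γ).

## Command line

A thin wrapper is installed under `inst/scripts/mrrmrr`:

```sh
mrrmrr simulate --n1 24 --n2 24 --p 500 --p-inf 10 --effect 1.5 \
                --noise cauchy --seed 7 --out sim.csv
mrrmrr select   --input sim.csv --labels group --m 10 --gamma 0.9 \
                --relevance lws_adaptive_abs --redundancy reg_multiple \
                --seed 42 --out report.tsv
mrrmrr evaluate --input sim.csv --labels group --m 10 \
                --gamma-grid 0:2:0.1 --seed 42 --out cv.tsv
```

Every flag can come from a `key = value` config file (`--config`,
explicit flags win) and every run writes a JSON manifest with the
resolved configuration, seed, package version and input digests.

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch against
the installed package: it generates the planted benchmark (24 + 24
samples, p = 500, 10 informative variables at 1.5 SD), performs the
robust selection with a γ grid search scored by leave-one-out LDA,
repeats the evaluation under the three noise models, logs the
summary, and writes a JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

* `R/data_matrix.R` — data container, delimited I/O, report writers
* `R/lws.R` — fast-LTS initializer, LWS regression, robust correlation
* `R/shrinkage.R` — analytic shrinkage intensity, regularized multiple
  correlation
* `R/measures.R` — relevance/redundancy measure catalogue
* `R/selection.R` — greedy forward search (vectorized scoring path)
* `R/evaluation.R` — LDA, leave-one-out CV, γ grid search
* `R/synthetic.R` — benchmark generator and noise models
* `R/cli.R` — command-line entry point
* `vignettes/mrrmrr-methods.Rmd` — model, assumptions, numerical
  choices, limitations
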