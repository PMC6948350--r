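# longjrc — joint longitudinal regression and classification

`longjrc` is for researchers who follow a cohort over repeated visits and
record, per patient per visit, a wide multimodal feature vector (regional
MRI measures, SNP genotypes, ...), continuous clinical scores (e.g. memory
tests) and a diagnostic category (e.g. AD / MCI / healthy). Instead of
fitting one model per score, per class and per visit, it fits a single
coefficient tensor for all tasks at all visits, so that related tasks and
adjacent visits share statistical strength, and it turns the fitted
coefficients into a ranked list of candidate biomarkers.

## The model

With features $X_t \in \mathbb{R}^{n\times d}$ at visits $t = 1,\dots,T$,
scores $Y_{rt} \in \mathbb{R}^{n\times c_r}$ and one-vs-all class labels
$y_{ikt}\in\{-1,+1\}$, the coefficient slices $V_t = [W_t\;P_t]$ are
concatenated column-wise into $V \in \mathbb{R}^{d\times(c_r+c_c)T}$ and
fitted by

$$
\min_{V, b}\ \sum_t \lVert X_t W_t - Y_{rt}\rVert_F^2
 + \sum_{t,i,k}\bigl(1 - (x_i^t p_k^t + b_{kt})y_{ikt}\bigr)_+
 + \gamma_1\lVert V\rVert_{2,1} + \gamma_2\lVert V\rVert_{G_1}
 + \gamma_3\lVert V\rVert_* .
$$

The $\ell_{2,1}$ norm selects features jointly across every task and visit
(longitudinally consistent biomarkers), the group $\ell_1$ norm acts on
modality row-blocks (whole data sources can drop out), and the trace norm
keeps the unfolded coefficients low-rank (correlated tasks). The composite
objective is minimized by a multi-block ADMM: auxiliary copies $F, G, H$ of
$V$ absorb one penalty each through closed-form proximal steps (row
shrinkage, block shrinkage, singular-value thresholding), per-element hinge
errors absorb the SVM loss, exact linear solves update the coefficients,
and a geometrically growing penalty $\mu \leftarrow \rho\mu$ drives the
copies back together. See the vignette
(`vignettes/joint-longitudinal-model.Rmd`) for the derived updates and all
numerical choices.

## Worked example

Fit the bundled synthetic generator's default cohort (200 patients, 100
features in 3 modality blocks, 4 visits, 3 scores, 3 diagnosis classes, 10
planted active features):

```r
library(longjrc)
syn <- make_synthetic(synthetic_config(n = 200, d = 100, T = 4, seed = 42))
fit <- jrc_fit(syn$data, jrc_control(), seed = 1)
fit
#> Joint regression-classification model: d=100, c_r=3, c_c=3, T=4
#>   nonzero coefficient rows: 100 / 100
#>   fitted in 74 iterations (final max gap 0.000949)
```

The solver stopped after 74 iterations because every coupling gap — the
largest difference between each auxiliary variable and the expression it
replaces — fell below the default tolerance of `1e-3`:

```r
tail(fit$history[, c("iter", "objective", "gap_max", "mu")], 3)
#>  iter objective     gap_max       mu
#>    72  2282.230 0.002011026 418.6667
#>    73  2280.934 0.001294863 502.4001
#>    74  2279.912 0.000948753 602.8801
```

Biomarker ranking orders features by the $\ell_2$ norm of their row of the
unfolded coefficient matrix; here the top of the list is exactly the
planted signal:

```r
head(rank_features(fit)$global, 5)
#>  rank feature feature_index modality    score
#>     1   feat1             1      MRI 6.395122
#>     2   feat8             8      MRI 4.554538
#>     3  feat91            91      PET 4.041687
#>     4  feat83            83      PET 3.799808
#>     5  feat81            81      PET 3.678143

recovery_metrics(syn$truth, fit)[c("precision", "recall", "f1")]
#> $precision [1] 1   $recall [1] 1   $f1 [1] 1

longitudinal_consistency(fit, k = 10)$mean_overlap
#> [1] 1
```

A mean pairwise top-10 overlap of 1 across the four visits is the
row-sparsity penalty at work: the same ten features lead at every visit.
Out-of-sample evaluation follows the repeated patient-level protocol —
`cross_validate(syn$data, jrc_control(), repeats = 10, folds = 5, seed = 1)`
runs 50 fits and reports RMSE per score (original scale) and per-class F1
averaged over visits; `grid_search()` tunes the three penalty weights over
powers of ten from `1e-5` to `1e5`.

A command-line wrapper with `simulate` / `fit` / `evaluate` / `rank`
subcommands, driven by a YAML config, is installed at
`system.file("cli", "longjrc.R", package = "longjrc")`.

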