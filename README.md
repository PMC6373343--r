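# streamlmm

Streaming (online) maximum-likelihood estimation of linear mixed models on
data streams.

## What it does

`streamlmm` fits the two-level linear mixed model

```
y_ij = x_ij' beta + z_ij' b_j + e_ij,   b_j ~ N(0, Phi),   e_ij ~ N(0, sigma^2)
```

when observations arrive one at a time and raw historical data cannot be
revisited. The estimator is a streaming variant of EM: for each individual
ever seen it stores a fixed-size summary (cross-products, current random-effect
posterior, and that individual's contributions to the complete-data sufficient
statistics). Each arriving point triggers

1. an **ingest** step that updates the individual's cross-products and the
   global normal equations — with a Sherman–Morrison rank-one update of
   `(X'X)^-1`, so no matrix solve is done per point;
2. an **E-step for that individual only**, whose new contributions replace its
   stale ones in the running totals;
3. a closed-form **M-step** from the totals.

Cost per point is constant in the stream length (it depends only on the
numbers of fixed and random effects) and memory is proportional to the number
of individuals, not the number of observations. A full sweep over the stored
summaries reproduces one exact batch-EM iteration, which is the basis of most
of the package's correctness tests.

The package also provides the classical offline EM estimator (`fitEM`), a
periodically-refit batch EM and a sliding-window EM as comparators, a
synthetic stream simulator with four preset conditions, a prequential
(predict-then-update) evaluation harness, JSON-lines/CSV stream readers and
writers, checkpointing, and a command-line interface
(`inst/cli/streamlmm`).

See `vignettes/streaming-em.Rmd` for the method, the design decisions, and
the known limitations (in particular the slow ridge shared by the intercept
and between-individual coefficients when the random-intercept variance is
large).

## Worked example

```r
library(streamlmm)

# a random-intercept stream: 80 individuals, 4000 points,
# beta_0 = 100, Phi = 50, sigma^2 = 5
stream <- simulateStream("A", nTotal = 4000, J = 80, seed = 42)

# train on the first 1000 points, then predict-then-update per point
res <- prequentialRun(stream, method = "sema", trainN = 1000)
res
#> Prequential run (sema): 3000 evaluated predictions after a training set of 1000
#> Linear mixed model parameters
#>   fixed effects (p = 15 ): 100.4, 0.1221, 0.5076, 0.876, 1.329 ...
#>   random-effect covariance (r = 1 ), diag: 37.42
#>   residual variance: 5.134

fit <- modelParams(res)
round(fixedEffects(fit)[1:6], 3)
#> [1] 100.389   0.122   0.508   0.876   1.329   1.683
round(c(phi = ranefCovariance(fit)[1, 1], sigma2 = residualVariance(fit)), 3)
#>    phi sigma2
#> 37.425  5.134
round(c(mae = mae(res), rmse = rmse(res)), 3)
#>  mae rmse
#> 1.86 2.32
```

(The random-intercept variance estimate of 37.4 against a generating value of
50 reflects having only 80 individuals in this small example; at the full
J = 1000 it concentrates near 50.)

The same pipeline from the shell:

```sh
Rscript inst/cli/streamlmm simulate --condition A --n 4000 --J 80 --seed 42 --out s.jsonl
Rscript inst/cli/streamlmm fit --input s.jsonl --method sema --train-n 1000 --out fit
Rscript inst/cli/streamlmm evaluate --log fit_predictions.csv --out stats.csv
```

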