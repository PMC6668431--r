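# covfdr: covariate-adaptive false discovery rate control

`covfdr` is an R package for large-scale multiple hypothesis testing when
each hypothesis comes with side information. In genomics and related fields a
test rarely arrives alone: an eQTL association test carries the SNP–gene
distance and allele frequency, a differential-expression test carries the
gene's expression level, an fMRI voxel carries its brain-region label.
Classical procedures such as Benjamini–Hochberg (BH) ignore this information
and apply one p-value cutoff to every hypothesis. When alternatives are
enriched at particular covariate values, a covariate-dependent cutoff can
make substantially more discoveries at the same error level.

## The method

Given p-values $P_i$ and covariates $x_i$ (mapped to the unit cube), the
package learns a rejection threshold from the family

$$t(x) = \exp(a^\top x + b) \;+\; \sum_{k=1}^{K}
  \exp\!\big[w_k - (x-\mu_k)^\top \mathrm{diag}(\sigma_k)(x-\mu_k)\big],$$

a log-linear "slope" term plus $K$ Gaussian "bumps" (default $K = 5$),
and rejects hypothesis $i$ when $P_i \le t(x_i)$. Because the false
discoveries among the rejections are unobservable, they are estimated by the
**mirror count** $\widehat{\mathrm{FD}}(t) = \#\{i : P_i \ge 1 - t(x_i)\}$:
null p-values are uniform given the covariates, so the mirrored region
catches at least as many nulls, in expectation, as the rejection region.
The estimated false discovery proportion is
$\widehat{\mathrm{FDP}} = \widehat{\mathrm{FD}} / \mathrm{D}$.

To keep the estimate honest the data are randomly split in two folds. On the
training fold the threshold is initialized from the p-value ensembles
(proxy nulls $P \ge 0.75$, proxy alternatives $P \le t_{\mathrm{BH}}$) by
weighted EM, then refined by adaptive-moment gradient descent on a
sigmoid-smoothed Lagrangian of "maximize discoveries subject to
$\widehat{\mathrm{FDP}} \le \alpha$". On the held-out fold the learned shape
$t^*$ is only rescaled: the procedure applies $\gamma^* t^*$ with the largest
$\gamma$ whose estimated FDP stays at or below $\alpha$ (and which makes at
least $c_0 N$ discoveries). Discoveries are the union over both folds. An
EM-only variant (`cov_fdr_fast()`, or `fast = TRUE`) skips the gradient
refinement and is the recommended choice below ~10,000 hypotheses.

## Worked example

```r
library(covfdr)

hs  <- simulate_testing_data(simulation_scenario("informative", n = 20000, seed = 42))
res <- cov_fdr(hs, alpha = 0.1, seed = 0)
print(res)
evaluate_fdp_power(res, hs$labels)
```

```
covariate-adaptive testing (full mode, alpha = 0.1, seed = 0)
discoveries: 342 of 20000 hypotheses
  fold 1: gamma* = 0.224, D = 142, FDP_hat = 0.0986
  fold 2: gamma* = 1.58, D = 200, FDP_hat = 0.1000
$fdp
[1] 0.0877193
$power
[1] 0.2650807
```

The simulated data contain 1177 true alternatives, enriched where the
covariate is near 0.8. The adaptive threshold makes 342 discoveries at a
realized FDP of 0.088 (nominal 0.1); on the same data BH makes 311 and
Storey-BH 326, so the covariate buys roughly 10% more discoveries here, and
far more when the enrichment is stronger. `explore_covariates(hs)` returns
the estimated null/alternative covariate densities behind that gain, and
`stratified_pvalue_histogram()` provides the standard model-check that null
p-values look uniform within covariate strata.

A shell interface with the same functionality lives in
`inst/cli/covfdr.R`:

```sh
Rscript inst/cli/covfdr.R simulate --scenario informative --n 20000 --seed 42 --output sim.csv
Rscript inst/cli/covfdr.R --input sim.csv --pval-col pval --covariates x1:num \
    --alpha 0.1 --seed 0 --output out.csv --explore-out diag
```

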