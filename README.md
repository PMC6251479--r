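# zinbwt — ZINB observation weights for zero-inflated differential expression

Single-cell RNA-seq count matrices carry many more zeros than the negative
binomial (NB) distribution underlying the standard bulk RNA-seq
differential-expression (DE) engines. Those excess zeros (dropouts,
bursting) get absorbed into the dispersion estimates, the mean–variance
trend inflates, and power collapses. `zinbwt` restores the bulk machinery
for zero-inflated data through *observation weights*:

1. **Fit a zero-inflated negative binomial regression** to the whole
   cells-by-genes matrix by penalized maximum likelihood,
   `ln μ = Xβ_μ + (Vγ_μ)ᵀ + Wα_μ`, `logit π = Xβ_π + (Vγ_π)ᵀ + Wα_π`,
   `ln θ = ζ` (`zinb_fit()`, an S3 model object with `print`, `summary`,
   `coef`, `logLik`/`AIC`, `predict`, `simulate`, `residuals` methods).
2. **Derive posterior weights** — the probability that each count came
   from the NB component,
   `w_ij = (1−π_ij) f_NB(y_ij; μ_ij, θ_j) / f_ZINB(y_ij; μ_ij, θ_j, π_ij)`,
   exactly 1 for every positive count (`posterior_weights()`,
   `zinb_weights()`).
3. **Run a weighted NB GLM testing pipeline** (`zinb_de()`): positive-count
   size factors, weighted Cox–Reid dispersion estimation with
   empirical-Bayes shrinkage, gene-wise weighted GLM fits, and a moderated
   F test whose residual degrees of freedom are reduced by the total
   downweighting, `df_j = Σ_i w_ij − p`, plus independent filtering and
   Benjamini–Hochberg correction. With all weights 1 the pipeline is
   byte-identical to its unweighted counterpart.

The package also ships the companion **simulation framework**
(`estimate_sim_model()`, `simulate_dataset()`, `synthetic_reference()`):
zero-truncated NB moment estimators of per-gene expression fractions and
dispersions from positive counts, a smooth logistic model of zero
abundance against expression strength and sequencing depth, and generation
of two-group datasets with known DE genes and labeled excess zeros — and
the **evaluation utilities** used to validate it (`fdp_tpr_curve()`,
`roc_curve()`, `pcer()`, `mock_null_split()`, `pvalue_diagnostics()`).

## Worked example

```r
library(zinbwt)

ref   <- synthetic_reference(seed = 1, n = 90, J = 2000, profile = "islam_like")
model <- estimate_sim_model(ref)
sim   <- simulate_dataset(model, n_per_group = c(45, 45), de_fraction = 0.1, seed = 2)

fl <- filter_genes(sim$counts, min_positive = 5)
cd <- data.frame(group = sim$group)
w  <- zinb_weights(fl$counts, X = ~group, cell_data = cd)
print(w)
#> zinb_weights: 90 x 1824; 62.0% of entries below 1 (zeros downweighted); mean zero weight 0.051

res <- zinb_de(fl$counts, design = ~group, weights = w, cell_data = cd)
print(res)
#> zinb_de (ftest, weighted): 1824 genes, 256 filtered, 81 DE at BH 0.05

truth <- sim$truth$genes$is_de[fl$kept]
rej <- !is.na(res$table$adjusted_p) & res$table$adjusted_p <= 0.05
c(FDP = sum(rej & !truth) / max(1, sum(rej)),
  TPR = sum(rej & truth) / sum(truth))
#>        FDP        TPR
#> 0.03703704 0.42162162
```

The same data analyzed *without* weights finds almost nothing (the
inflated dispersions swallow the signal); the weighted analysis recovers
roughly 42% of the true DE genes while keeping the false discovery
proportion below the nominal 5% level. `plot(res$dispersions)` draws the BCV
(biological coefficient of variation) plot with the fitted trend — the
diagnostic in which zero inflation shows up as striped patterns and
downweighting restores the clean mean–variance relationship.

## Acceptance script

`scripts/acceptance.R` recomputes the package's two headline numbers from
scratch — it simulates data from the synthetic reference, runs the full
weighted pipeline, and writes a small JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

`t1` is the median empirical false discovery proportion (in percent) of
the ZINB-weighted F-test pipeline at the BH 0.05 working point over ten
simulated two-group datasets (n = 90, J = 2000, 10% DE genes); `t2` is the
mean per-comparison error rate over thirty mock-null splits (two disjoint
groups of 45 cells) of one homogeneous simulated population at the raw
p ≤ 0.05 threshold. The run takes roughly ten minutes on one CPU.

## Package layout

- `R/zinb-fit.R`, `R/zinb-dist.R`, `R/zinb-methods.R` — ZINB distribution
  and penalized model fitting (S3 class `zinb_fit`)
- `R/weights.R` — posterior observation weights
- `R/normalization.R`, `R/dispersion.R`, `R/glm-weighted.R`, `R/de.R` —
  the weighted DE engine (class `zinb_de`)
- `R/simulate.R` — ZTNB estimators, zero-abundance model, simulator
- `R/evaluation.R` — FDP/TPR, ROC, PCER, mock-null splits, diagnostics
- `R/count-matrix.R`, `R/io.R` — containers and plain-text I/O
  (MatrixMarket, TSV, JSON manifests)
- `vignettes/zinb-observation-weights.Rmd` — the methods vignette: model,
  assumptions, penalty structure, simulator design, numerical choices and
  limitations
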