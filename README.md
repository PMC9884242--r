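# vaeimpute

Variational-autoencoder imputation of dropout zeros in single-cell RNA-seq
expression matrices, with the surrounding pipeline needed to use and judge
it: matrix I/O, preprocessing, Louvain clustering with ARI/FMI/silhouette
evaluation, a multi-classifier benchmark, and a ground-truth count
simulator.

## The problem

scRNA-seq count matrices are dominated by zeros, and a substantial share of
them are *dropouts* — transcripts that were present in the cell but failed
capture or amplification. Dropouts blur cell-type structure: embeddings
smear, clusters merge, classifiers degrade. `vaeimpute` learns a compressed
representation of each cell and uses it to fill in the suspect zeros.

## The model

The preprocessed matrix $m$ (cells × genes) is passed through a
probabilistic encoder $p_\psi$ producing, per cell, the mean $\mu$ and
diagonal standard deviation $\sigma$ of a Gaussian over a low-dimensional
bottleneck; a code is drawn by the reparameterization
$b = \mu + \sigma\odot\varepsilon$, $\varepsilon \sim N(0,I)$; a decoder
$q_\delta$ maps $b$ back to expression space. Training minimizes

$$\frac{1}{|M|}\sum_{(i,j)\in M}(x_{ij}-\hat x_{ij})^2 \;+\;
\beta\,\overline{\mathrm{KL}\left[N(\mu,\mathrm{diag}\,\sigma^2)\,\|\,N(0,I)\right]}$$

(masked reconstruction error plus KL regularizer, the negative ELBO) with
Adam at learning rate 0.001, batch size 100, 50 epochs. Imputation is
deterministic ($b=\mu$) and, under the default `zeros_only` policy,
replaces only positions whose raw count is zero — observed values pass
through untouched.

See `vignettes/vae-imputation-methods.Rmd` for the full account of the
model, the preprocessing chain, the simulator and the design choices.

## Worked example

```r
library(vaeimpute)

# clustered counts, 4 populations, 60% dropout, ground truth kept
sim <- simulate_counts(sim_config(n_cells = 600, n_genes = 300,
                                  n_clusters = 4, dropout_rate = 0.6,
                                  seed = 7))
pp  <- preprocess(sim$corrupted, preprocess_config(n_top_genes = 300))
fit <- train_vae(pp$matrix, pp$mask, training_config(seed = 11))
imp <- impute_matrix(pp$matrix, pp$raw, fit$params)

tail(fit$history, 1)
#>    epoch    total generative  bottleneck
#> 50    50 1.004975   1.003213 0.001761881

cmp <- compare_raw_vs_imputed(pp$matrix, imp, sim$labels, seed = 3)
subset(cmp, metric %in% c("ari", "mean_accuracy"))
#>      input        metric     value
#> 1      raw           ari 0.5797245
#> 11     raw mean_accuracy 0.8000000
#> 12 imputed           ari 0.6942097
#> 22 imputed mean_accuracy 0.8425926
```

The loss history shows the composite objective falling over the 50 epochs.
In the comparison table, Louvain clustering of the corrupted matrix agrees
with the true populations at ARI 0.58, and at 0.69 after imputation; the
mean held-out accuracy of three classifiers (logistic regression, random
forest, k-nearest neighbours) rises from 0.80 to 0.84. Because the
simulator records which zeros it introduced, recovery can also be measured
directly at those positions with `recovery_report()` — on this run the
imputed values correlate with the hidden truth at r = 0.75, against an
undefined correlation (all zeros) for the corrupted input.

A thin command-line wrapper with `simulate`, `preprocess`, `train`,
`impute`, `evaluate-clustering`, `evaluate-classification` and `run`
subcommands is installed at `inst/cli/vaeimpute.R`.

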