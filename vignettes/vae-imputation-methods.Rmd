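---
title: "Imputing scRNA-seq dropouts with a variational autoencoder: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing scRNA-seq dropouts with a variational autoencoder: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaeimpute)
```

## The problem

Droplet- and plate-based single-cell RNA-seq measures tens of thousands of
transcripts per cell, but a large fraction of the resulting count matrix is
zero. Some of those zeros are biological (the gene is simply not expressed
in that cell); others are *dropouts* — transcripts present in the cell that
failed to be captured, reverse-transcribed or amplified. Dropouts are more
frequent at low expression and shallow sequencing depth, and they distort
every downstream analysis that reads the matrix at face value: cells of the
same type scatter in embeddings, clusters blur together, and classifiers
trained on expression profiles lose accuracy.

This package imputes dropouts with a variational autoencoder (VAE) and then
quantifies, on data with known ground truth, how much the imputation helps
clustering and classification.

## The model

Let $m$ be the preprocessed expression matrix with cells in rows and genes
in columns, and $x_i$ the row for cell $i$. The model has three parts:

* a **probabilistic encoder** $p_\psi(x)$ — a stack of dense layers with
  rectifier activations followed by two linear heads — mapping each cell to
  the mean $\mu_i$ and diagonal standard deviation $\sigma_i$ of a Gaussian
  over a low-dimensional bottleneck;
* a **reparameterized bottleneck sample**
  $b_i = \mu_i + \sigma_i \odot \varepsilon_i$, $\varepsilon_i \sim N(0, I)$,
  so the sampling noise is an input rather than part of the computation
  graph and gradients flow through $\mu$ and $\sigma$;
* a **probabilistic decoder** $q_\delta(b)$ — the mirror-image stack with a
  linear output head — mapping the bottleneck code back to a reconstruction
  $\hat{x}_i$ in expression space.

Training minimizes the negative evidence lower bound written as

$$\mathcal{L} = \underbrace{\frac{1}{|M|}\sum_{(i,j) \in M}
  (x_{ij} - \hat{x}_{ij})^2}_{\text{generative loss}}
  + \beta \cdot \underbrace{\frac{1}{n}\sum_i
  \mathrm{KL}\!\left[N(\mu_i, \mathrm{diag}\,\sigma_i^2) \,\|\, N(0, I)\right]}
  _{\text{bottleneck loss}},$$

where $M$ is the set of mask-valid entries. The KL term has the closed form
$\tfrac12 \sum_d (\mu_d^2 + \sigma_d^2 - 1 - 2\ln\sigma_d)$ for a diagonal
Gaussian against the standard-normal prior; `kl_divergence()` implements it
and the test suite checks it against a Monte-Carlo estimate. A Gaussian
(squared-error) reconstruction likelihood is used because the model operates
on the scaled, log-transformed layer, where expression is approximately
continuous and symmetric; no negative-binomial or zero-inflated likelihood
is attempted.

The sign convention deserves a note: the ELBO is a quantity to *maximize*
(expected reconstruction log-likelihood minus KL). The package minimizes its
negation — reconstruction error plus KL — which is the standard VAE training
objective; the bottleneck term measures how far the encoder's posterior has
drifted from the prior, and driving it *up* would be incoherent with its
role as a regularizer.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `learning_rate` | 0.001 | Adam step size |
| `batch_size` | 100 cells | mini-batch size; last partial batch kept |
| `n_epochs` | 50 | fixed epoch budget, no early stopping |
| `kl_weight` ($\beta$) | 1.0 | regularization coefficient on the KL term |
| `hidden_dims` | 512, 128 | encoder widths; decoder mirrors them |
| `latent_dim` | 32 | bottleneck dimension |

Optimizer hyperparameters, batch size and epoch count follow common VAE
practice for matrices of a few hundred to a few thousand cells. The
architecture (two hidden layers tapering to a 32-dimensional bottleneck,
rectifier activations, linear heads) is a deliberate design choice: the
widths had to be fixed somewhere, and 512→128→32 keeps the parameter count
proportionate to matrices with up to a few thousand genes while leaving a
bottleneck narrow enough to force a compressed representation. All of it is
configurable through `training_config()`.

Weights initialize uniformly on $\pm 1/\sqrt{\text{fan-in}}$ from the run
seed; biases start at zero. The seed drives initialization, the per-epoch
shuffle and the reparameterization noise, which is what makes
`train_vae()` bitwise-reproducible — a property the tests assert rather
than assume.

## Preprocessing chain

The chain is fixed in order and enforced through layer tags, so running a
stage on the wrong layer is an error rather than a silent mistake:

1. **Gene detection filter** — genes with nonzero counts in fewer than
   `min_cells_per_gene` (default 3) cells are removed. The notion of a "bad
   gene" is not standardized; detection frequency is the conventional
   reading and the threshold is configurable.
2. **Library-size normalization** — each count is divided by its cell's
   total and rescaled by the median total:
   $x_{ij} \mapsto (x_{ij}/T_i)\cdot \mathrm{median}(T)$. Afterward every
   cell's total equals the pre-op median exactly, which the tests check to
   1e-9. Multiplicative rescaling to the median library size is used (not
   addition of a median constant): adding a constant to proportions would
   not equalize depth, while median rescaling is the standard practice this
   step exists for.
3. **Conditional log transform** — if the matrix maximum exceeds
   `log_threshold` (default 100), every entry becomes $\log_2(1+x)$. The
   pseudocount handles zeros; the condition leaves already-compressed
   dynamic ranges untouched.
4. **Highly-variable-gene selection** — the `n_top_genes` (default 2000)
   genes with the largest sample variance on the log layer are kept, ties
   resolved toward earlier columns, order preserved. Variance is computed
   after normalization and log transform so depth and dynamic range do not
   masquerade as biological variability.
5. **Per-gene scaling** — each gene is centered and divided by its
   population (n-denominator) standard deviation; constant genes are
   centered only. The population convention is documented so tests can be
   exact. The centers and scales are retained, and `unscale_matrix()` maps
   model output back to the log layer.

An optional outlier-cell pre-filter (off by default) removes cells whose
total count deviates from the median by more than `outlier_mads` median
absolute deviations; it exists as a guard for heavily contaminated inputs,
with no claim that any particular analysis requires it.

`build_mask()` marks non-finite entries and configurable sentinel values as
invalid; masked entries contribute nothing to the generative loss. On fully
observed input the mask is all-true and the loss is ordinary MSE.

## Imputation policy

Dropout candidacy is defined as *raw count zero*. The default `zeros_only`
policy replaces only those positions with the model reconstruction
(computed with $\varepsilon = 0$, i.e. $b = \mu$, so the output is
deterministic) and passes every observed nonzero through bit-exactly — the
conservative choice, since rewriting observed values risks erasing real
biological variation. A `full` mode returning the entire reconstruction is
provided for comparison with methods that rewrite everything. No mixture
model over dropout probability is fitted; zero-ness of the raw count is the
whole criterion.

## Synthetic data: what it emulates and what it does not

`simulate_counts()` generates the ground-truth substrate the package is
validated on:

* a log-normal baseline profile of gene means (meanlog $= \log 2$, sdlog 1),
  giving the skewed mean distribution typical of UMI data;
* $k$ clusters, each shifting its own random 10% of genes up or down by
  $2^{\pm 2}$ (4-fold) — marker-gene-like differential structure;
* negative-binomial counts with dispersion 0.1
  ($\mathrm{var} = \mu + 0.1\mu^2$), overdispersed as real counts are;
* log-normal per-cell depth factors (sdlog 0.3), mean-one by construction;
* a dropout process that zeroes only nonzero entries — `random` mode
  independently at the configured rate, `expression_dependent` mode with
  probability $\exp(-\lambda \log(1+x))$, $\lambda$ solved numerically so
  the expected zeroed fraction matches the configured rate.

Defaults (600 cells × 300 genes, 4 clusters, 60% dropout) produce a
corrupted matrix with roughly 70% zeros, matching the high-sparsity regime
of droplet data at a size where a full
simulate → preprocess → train → impute → evaluate cycle runs in well under
a minute; the repeated-seed studies in the tests use exactly these
conditions. The simulator does *not* emulate batch effects, trajectories,
gene–gene correlation beyond cluster structure, or ambient RNA. Passing
tests on this substrate therefore show that the model recovers clustered
negative-binomial signal through heavy dropout — not that it handles every
artifact of real experiments.

## Downstream evaluation

Clustering follows the standard four-stage procedure: PCA (default 30
components; a standard-deviation drop-off heuristic `choose_n_pcs()` is
available but not default, since no principled universal rule exists), a
k-nearest-neighbour graph (default 15 neighbours, Euclidean in PC space),
and Louvain modularity optimization (default resolution 0.8, inside the
0.6–1.2 band that behaves well in practice; cluster count grows with
resolution, which a test asserts). Agreement with reference labels is
scored by the adjusted Rand index and Fowlkes–Mallows index, and geometric
separation by the mean silhouette coefficient. Silhouette is computed in
the same PC space used for clustering: computing it in a 2-D t-SNE would
entangle the metric with a stochastic visualization, whereas PC space is
deterministic and is where the clustering actually happened.

All five metric formulas — ARI in the Hubert–Arabie pair-counting form,
FMI as the geometric mean of pairwise precision and recall, silhouette
$(y-x)/\max(x,y)$ with the singleton-cluster score set to 0 by convention,
accuracy from confusion counts, and one-vs-rest ROC AUC via the rank
statistic with midrank ties — are implemented in the package and tested
against brute-force $O(n^2)$ oracles, with cross-checks against independent
implementations where available.

The classifier benchmark stratifies a 70/30 split (stratification prevents
a class from vanishing from the test fold), grid-searches a small
documented grid per algorithm by 3-fold cross-validated accuracy on the
training portion, refits the winner and reports held-out accuracy and
macro one-vs-rest AUC. Seven algorithms are wired in: logistic regression
(ridge penalty over three decades), SVM (RBF, cost 0.1/1/10), random
forest (100/300 trees), naive Bayes (Laplace 0/1), k-nearest neighbours
(k = 3/5/11), a decision tree (complexity 0.01/0.001) and gradient
boosting (depth 3/6, 50 rounds). Macro (unweighted) AUC averaging is used
for multi-class problems.

## Numerical and degenerate-input choices

* $\sigma$ is parameterized as $\exp(\tfrac12\text{logvar})$, keeping it
  strictly positive without constraints; the covariance is diagonal, as the
  elementwise reparameterization requires.
* Mean reduction (not sum) over entries and cells in both loss terms, so
  $\beta = 1$ weights the terms on comparable scales regardless of batch
  and gene counts.
* A batch whose mask excludes every entry is an error, not a silent zero.
* Non-finite training loss aborts with the epoch and batch named.
* Empty matrices round-trip through every I/O format; MatrixMarket
  coordinates are converted from one-based at the boundary.
* Ties in variance ranking and in ROC scores are handled deterministically
  (original order; midranks).
* The per-stage seeds of a pipeline run derive from the global seed as
  `seed + 1000 * stage_index`, so stages rerun in isolation reproduce their
  slice of the full run.

## Problem sizes in the test battery

The test suite validates metrics on hundreds of random instances up to 200
items, the KL closed form against $10^6$-sample Monte-Carlo estimates, and
the full pipeline on the 600 × 300 / 4-cluster / 60%-dropout scenario —
once for the loss-trend, reproducibility and masked-recovery checks, and
over ten independent seeds for the downstream-improvement study. These
sizes were chosen as the smallest at which the clustered-dropout regime is
genuinely hard (the corrupted matrix clusters at ARI ≈ 0.5, leaving
headroom for imputation to help) while a complete cycle stays fast enough
to repeat across seeds.

## Known limitations

* The Gaussian reconstruction likelihood ignores count statistics; methods
  with NB/ZINB likelihoods model the raw scale directly.
* `zeros_only` cannot correct inflated nonzero counts, and `full` mode
  rewrites genuine biological zeros; neither distinguishes technical from
  biological zeros beyond the raw-zero criterion.
* With $\beta = 1$ and an expressive decoder the KL term can shrink toward
  posterior collapse on easy data; the imputation path uses $b = \mu$ and
  is unaffected, but latent-space analyses should lower $\beta$ with that
  trade-off in mind.
* Louvain on a kNN graph is seed-dependent on borderline data; the package
  fixes seeds rather than pretending stability.
* The simulator's independence assumptions (genes conditionally independent
  given cluster and depth) make it a favourable substrate; real-data
  performance claims require real data.
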