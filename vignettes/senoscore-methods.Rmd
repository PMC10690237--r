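---
title: "Scoring cellular senescence with a ZINB autoencoder: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cellular senescence with a ZINB autoencoder: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senoscore)
```

## The problem

Senescent cells (SnCs) — cells in permanent cell-cycle arrest — lack a
single definitive transcriptional marker. Published senescence gene sets
(SnGs) disagree heavily: pairwise Jaccard indices are typically below 0.2
and most genes appear on only one list. senoscore addresses this in two
steps: it distills a small consensus signature from many published lists,
and it scores each cell of a count matrix on a continuous senescence axis
learned *unsupervised* from the signature genes' covariation, rather than
by averaging marker expression.

## Consensus signature curation

`membership_counts()` tabulates, for each gene in a `gene_set_collection`,
how many member sets report it; `curate_consensus()` keeps the genes
reported by at least `min_sets` lists (default 5). When source sets
annotate a gene's direction (senescence-inducing vs -inhibiting), the
majority direction across sets is attached; exact ties become `unknown`
since no published rule covers them. Literature-database records (gene,
publication count, induce/inhibit report counts, as distributed by
SeneQuest) are filtered by `filter_senequest()`: a gene is kept if reported
by ≥ 15 publications, or by ≥ 4 publications with ≥ 70% directional
agreement; "at least 70%" is applied inclusively (`>=`), which also decides
the boundary case of exactly 70%.

Gene symbols are matched case-sensitively after whitespace trimming; an
`uppercase` flag and a user-supplied two-column `map_symbols()` table cover
mouse/human conventions. The package ships a 39-gene default signature
(`default_signature()`) with induce/inhibit directions. It is a
**constructed stand-in** assembled from canonical senescence biology (p21,
p16, SASP cytokines and proteases, proliferation genes lost in senescence),
shipped so the pipeline runs out of the box; a study reproducing published
results should pass its own curated signature.

## Preprocessing

The model consumes two matrices derived from a filtered count matrix (the
package performs no cell filtering; quality control belongs to the standard
upstream pipelines):

1. *(optional)* **Denoising**: a wider ZINB autoencoder (64–32–64, ReLU
   bottleneck, no correlation penalty) is fitted to all genes and each
   count is replaced by its fitted ZINB mean times the cell's size factor.
   Output is real-valued; all downstream likelihoods generalize the
   factorial through the gamma function. Genes with constant
   log-normalized expression are passed through untouched.
2. **Size factors**: `s_j` = library size of cell `j` / median library
   size, so `median(s) = 1`. The upstream method never writes a formula
   for its size factors; this total-count-to-median convention makes the
   likelihood mean `M = M' s` well scaled and is the one adopted here.
3. **Log-normalization**: `log(1 + x_ij / s_j)`.
4. **Subset + scale**: rows are restricted to the signature genes present
   (at least `min_genes = 5` required) and standardized to per-gene mean 0
   and standard deviation 1 across cells. The *population* sd (divide by
   n) is used; the difference from n−1 is immaterial and absorbed by the
   first network layer. Zero-variance signature genes are dropped with a
   warning rather than failing — targeted panels routinely contain
   undetected markers.

## The model

With `G` signature genes, the scaled matrix X′ (genes × cells) passes
through six dense layers, every one carrying a bias vector:

$$E = \mathrm{ReLU}(X' W_E),\quad B = \tanh(E W_B),\quad D = \mathrm{ReLU}(B W_D),$$
$$\Pi = \sigma(D W_\Pi),\quad M' = \exp(D W_{M'}),\quad \Theta = \exp(D W_\Theta),$$

with a 32-neuron encoder, a 2-neuron bottleneck, a 32-neuron decoder, and
three G-sized output heads giving per-gene-per-cell dropout probabilities,
library-free means and dispersions of a zero-inflated negative binomial.
The printed architecture omits biases, but the published parameter count
(5303 for 39 genes) is only reproducible with a bias on every layer, so
biases are included: `count_parameters(G)` = 131 G + 194, and
`n_learnable()` verifies this against an instantiated model by
introspection.

The objective is

$$L = -\frac{1}{IJ}\sum_{ij} \log Z(x_{ij};\ \pi_{ij},\ M'_{ij} s_j,\ \theta_{ij})
      \;+\; \lambda\, \rho(h_1, h_2)^2,$$

where `Z` is the ZINB mass function in the mean–dispersion
parameterization (variance `mu + mu^2/theta` — the convention of the
count-autoencoder literature; the source prints no pmf), and `rho` is the
Pearson correlation of the two **pre-activation** bottleneck neurons
across the cells of the (full) batch. The penalty pushes the two latent
axes to carry non-redundant information, so one can specialize in
senescence while the other absorbs nuisance structure. `lambda = 1` is the
default; it reliably leaves `|rho| < 0.1` after training (checked by the
test suite and the acceptance script on simulated data).

Numerical guards: dropout probabilities are clipped to
`[1e-6, 1 - 1e-6]` and the exp heads to `[1e-8, 1e8]` (via their linear
predictors), otherwise the exponential heads overflow early in training.
These bounds are this package's declared choice — whether the original
implementation clips is not stated anywhere.

All gradients are analytic (hand-derived back-propagation through the
ZINB likelihood and the correlation penalty) and are verified against
central finite differences in the test suite.

## Training schedule

`train_config()` defaults mirror the published schedule: full-batch Adam
at learning rate 0.005 for up to 300 epochs. A seeded 10% validation split
is drawn **once** before training and its ZINB negative log-likelihood
(penalty excluded) is recorded each epoch; re-drawing the split each epoch
would make "no improvement" ill-defined, so the fixed-split reading is
adopted. "Improvement" means beating the running best by a relative
1e-6. One shared non-improvement counter drives the schedule: the learning
rate halves each time the counter reaches a multiple of 10, and training
stops at 30 (whether the counter should reset on halving is unstated; a
single counter is the simpler reading). The final-epoch weights are
returned, matching the source's silence on weight restoration;
`restore_best = TRUE` returns the best-validation-epoch weights instead.
Weights are Glorot-uniform initialized; initialization and split both flow
from the single `seed`, making runs bit-reproducible.

## From bottleneck to score

The two bottleneck roles are undetermined during training, so the
senescence neuron is identified post hoc: for each neuron, the absolute
Pearson correlation between its tanh-activated values and each signature
gene row of X′ is averaged over genes, and the larger mean wins (exact
ties pick neuron 1). Activated values are used for both selection and
output — they are what the model emits; only the sign, not the choice, is
affected in practice. The score's sign is then anchored: if the
correlation with CDKN1A (p21) expression in X′ is negative, all scores
are flipped. A missing or constant anchor leaves scores unoriented with a
warning. Orientation is idempotent. Scores are the tanh neuron values, one
per cell (validation cells included), in (−1, 1), reported unscaled.

A one-line baseline ships for comparison: `marker_score()` scores cells by
the log-normalized expression of a single marker gene and calls cells with
positive expression senescent.

## Binarization

Two steps convert scores to senescent / non-senescent calls:

1. **Permutation uncertainty** — each cell's X′ column is shuffled across
   the signature genes (50 replicates, seeded; the shuffle is applied to
   X′ directly since per-cell shuffling preserves the cell's value multiset,
   and re-standardizing would leak information across cells) and pushed
   through the fitted encoder. A cell's uncertainty is the fraction of
   replicates whose recomputed (sign-anchored) neuron value **strictly
   exceeds** the original score.
2. **Cutoff + mixture** — the score cutoff is the smallest *observed*
   score value such that fewer than 1% of the cells above it have
   uncertainty above 0.5 (a smallest value over a continuum would be
   ill-defined, hence observed values as candidates; no qualifying value
   yields the "no callable SnCs" sentinel). One-dimensional Gaussian
   mixtures with unequal variances are fitted to all cells' scores for
   K = 2…10 (via mclust) and the K with lowest AIC kept. Components whose
   own 5% normal quantile (`mu - 1.6449 sd`; the constant is fixed to four
   decimals for cross-platform reproducibility) exceeds the cutoff
   qualify; the qualifying component with the smallest mean is the pivot,
   and cells assigned (by maximum posterior) to the pivot or to any
   higher-mean component are senescent.

## Evaluation statistics

`auroc()` uses the Mann–Whitney midrank formulation (ties half-credit),
identical to the trapezoidal ROC area and checked against an all-pairs
oracle in the tests. `accuracy_f1()` implements the standard
confusion-matrix definitions with `F1 = 0` when precision + recall is
degenerate. `snc_enrichment()` ranks cells, takes the top
`ceiling(top_frac n)` (stable order at ties — no published tie rule
exists, so a deterministic one is declared), and returns the ratio of
old-group fractions inside vs outside the top quantile; it is invariant
to monotone score transforms. `simulate_xenium_panel()` emulates targeted
in-situ panels: a base panel expanded by randomly sampled signature genes,
then intersected with the data.

## The synthetic generator

`simulate_counts()` generates the study conditions under which the
package's end-to-end behavior is verified:
`mu_ij = L_j exp(beta0_i + beta1_i s_j + beta2_i u_j)` and
`x_ij ~ ZINB(pi_i, mu_ij, theta_i)`, with a senescence factor `s_j` and a
nuisance factor `u_j` drawn independently standard normal — matching the
model's own assumption of two nearly uncorrelated latent axes. Signature
genes load at `±effect_size` (75% inducing, 25% inhibiting, echoing the
typical direction balance of curated signatures); a disjoint block carries
the nuisance loading; the rest is background. Defaults — 2000 cells, 150
genes, 39 signature genes, effect size 2 on the log scale, 10% senescent,
baseline log-means in [−1, 1.5], dispersions in [1, 10], per-gene dropout
in [0.05, 0.3], lognormal library spread 0.3 — were chosen once as a
realistic droplet-scale regime (mean counts of order 1–5, moderate
overdispersion and zero inflation). Truth labels take the top
`frac_senescent` quantile of `s_j`, representing senescence as the graded
process it is; `mode = "discrete"` instead plants a well-separated
senescent mode (shift 2, within-mode sd 0.25) for binarization tests. The
first inducing signature gene is named CDKN1A so the default sign anchor
exists in simulated data.

What the generator does **not** emulate: batch effects, doublets,
cell-type mixtures, spatial autocorrelation, or gene–gene correlation
beyond the two latent factors. Passing tests on these simulations
therefore demonstrate correctness of the machinery and recoverability of
a planted senescence axis — not performance on real tissue.

Problem sizes used by the checked examples (2000 cells for training-level
properties, 250–1000 cells for component-level ones) are the package's
choices for its own verification suite.

## Design notes and limitations

- Expression matrices stay genes × cells matrices — the field's
  convention — while everything naturally tabular (per-cell results,
  training history, gene tables) is returned as tibbles with
  `tidy()`/`glance()`/`autoplot()` methods.
- The denoising stage is a generic ZINB autoencoder sharing the scoring
  model's machinery; it is not a reimplementation of any specific
  denoising tool, and it is optional (`denoise = FALSE`).
- The likelihood accepts real-valued "counts" so denoised input needs no
  rounding.
- Binarization inherits a known fragility of the cutoff + mixture
  procedure: when AIC selects many components over the smooth bulk of the
  tanh-compressed score distribution, the pivot component can land inside
  the bulk and over-call senescent cells even when the continuous score
  separates the classes almost perfectly. The continuous score is the
  primary output; binary calls deserve inspection of the fitted mixture
  (returned in the result attributes, and visible via `autoplot()`).
- Under graded (continuous-mode) senescence, binary calls naturally
  capture a broader high-score tail than a sharp quantile-thresholded
  truth, so accuracy/F1 against such truth understates the score quality;
  discrete-mode data is the appropriate ground truth for binary calls.
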