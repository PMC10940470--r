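---
title: "Boosted link prediction for lncRNA–disease networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boosted link prediction for lncRNA–disease networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldaboost)
```

## The problem and the model

Curated lncRNA–disease catalogues are small, sparse bipartite graphs:
tens of lncRNAs, one or two hundred diseases, a few hundred verified
links. `ldaboost` treats candidate prioritization as supervised link
prediction on the binary incidence matrix `Y`. The working assumption is
that the association structure is approximately low rank — lncRNAs act
through a modest number of latent disease programmes — so a truncated SVD
embedding carries most of the predictable signal, and a flexible
classifier on concatenated (lncRNA, disease) embeddings can recover the
rest.

The pipeline is:

1. `svd_factorize(Y, e)` — best rank-`e` approximation `U_e Σ_e V_e^T`.
   Pair `(i, j)` is represented by `[U_e[i,] √Σ_e , V_e[j,] √Σ_e]`, a
   `d = 2e` vector.
2. `train_boosted_cnn()` — a SAMME.R AdaBoost ensemble of `Q` small 1-D
   convolutional networks with transfer learning between rounds.
3. `train_gbm()` — a gradient-boosted decision-tree head on the same
   features (delegated to xgboost; the split-gain machinery of
   gradient-boosted trees is mature and is not re-derived here).
4. `fuse_scores()` — the final score `P(x) = α C(x) + (1 − α) F(x)`.

Both heads are probabilistic classifiers; the fusion is convex, so fused
scores stay in `[0, 1]` and are monotone in each head.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `e` | 32 | SVD truncation rank; `d = 2e = 64` pair features. Equal widths for the lncRNA and disease sides, since neither axis is privileged. |
| `scaling` | `sqrt_sigma` | Splits `Σ` symmetrically between the sides so `⟨lnc, dis⟩ ≈ y_ij`; `raw` keeps orthonormal singular-vector rows. |
| `mode`, `neg_ratio` | `balanced`, 1 | All positives plus an equal number of zero cells sampled uniformly as presumed negatives. `all_pairs` trains on every cell instead. |
| `Q` | 100 | Boosting rounds of the CNN head. |
| `epochs` | 10 | SGD epochs per round. |
| `learning_rate` (boost) | 0.1 | Shrinkage in the SAMME.R weight update. Applied to the weight update only; the optimizer step size is a separate knob (`sgd_lr`, default 0.1) because the two rates play different roles. |
| `n_estimators`, `learning_rate` (trees) | 100, 0.1 | Tree head settings. |
| `alpha` | 0.4 | Fusion weight on the CNN head; `β = 1 − α` always, never independently set. `ablation_sweep()` evaluates the grid 0, 0.2, …, 1. |
| `threshold` | 0.5 | Decision threshold for precision/recall/accuracy/F1. On balanced test sets 0.5 is the natural operating point. |

## The CNN base learner

No published architecture accompanies the boosted-CNN idea at this scale,
so the package uses the smallest network that still exercises
convolution, pooling and dense softmax layers: conv(16 filters, width 3,
ReLU) → max-pool(2) → conv(32 filters, width 3, ReLU) → global average
pool → dense(32, ReLU) → dense(2, softmax), trained by minibatch SGD with
momentum 0.9, batch size 32. Convolutions are "valid"; kernel widths
clamp and pooling is skipped when a feature map is too short, so the same
code handles `d = 4` toy inputs and the default `d = 64`. The backward
pass is verified against central finite differences in the test suite.

Transfer learning means round `q + 1` starts from round `q`'s trained
parameters. This is what makes few-epoch rounds viable: each round
fine-tunes on the re-weighted distribution instead of restarting.

## Numerical choices

- **Sign convention.** SVD columns are sign-fixed (largest-magnitude
  entry of each `U` column positive, ties to the first index) so
  factorizations are bit-reproducible.
- **Rank deficiency.** If masking drops the matrix rank below `e`,
  trailing zero-singular-value triplets are kept as zero features so `d`
  never changes mid-experiment.
- **Probability floor.** Estimator probabilities are floored at `1e-12`
  before any logarithm (weight updates and log-odds aggregation).
- **Tie-breaks.** The aggregated argmax prefers non-association —
  conservative for biomarker nomination. Candidate rankings break score
  ties by lncRNA index order.
- **AUC / AUPR.** AUC is the Wilcoxon pairwise form with ties counting
  one half. AUPR uses step interpolation (average precision), not
  trapezoids, avoiding the optimistic bias of linear PR interpolation;
  both match brute-force oracles to `1e-9` in tests.
- **Seeds.** Every stochastic step draws a child seed from the master
  seed (`derive_seed`), so components can be re-run in isolation and
  whole experiments are bit-reproducible.

## Cross-validation design

`make_folds()` implements three fivefold cold-start protocols: held-out
lncRNAs, held-out diseases, held-out pairs. Fold sizes differ by at most
one; disjointness and coverage are property-tested across seeds.

Two design points deserve justification:

- **Negative sampling.** The training target `p = n × m` (every cell) is
  well defined, but with ~1% positives an all-pairs classifier
  concentrates on the majority class and thresholded metrics become
  uninformative. The default is therefore balanced sampling at
  `neg_ratio = 1` — all positives plus an equal number of randomly chosen
  zero cells — with `all_pairs` retained as an option. Test negatives are
  always drawn from the fold's own test side with a fold-specific seed.
- **Masking.** For the pair protocol, held-out positive cells are zeroed
  before the SVD refit (default `mask = TRUE`), so no test association
  influences the features. For entity protocols the held-out row or
  column would become all-zero under masking — its embedding would be
  identically zero and prediction vacuous — so the default there is
  unmasked, which matches how a practitioner would embed a new entity
  from its (unlabeled) profile. Both policies are exposed everywhere via
  `mask`.

## The synthetic generator

`simulate_association_matrix()` draws nonnegative rank-`r` factors
(absolute Gaussians), standardizes their product and squashes it through
a logistic whose offset is root-solved so the mean Bernoulli probability
equals the target density; cells are then realized independently and
optionally flipped with probability `noise`. It emulates the two features
the method actually exploits — low-rank structure and realistic sparsity
(default 60 × 80 at density 0.1, the scale of real catalogues) — and the
`noise` dial degrades recoverability smoothly, which the tests use as a
sanity gradient.

What it does *not* emulate: the heavy-tailed degree distributions of real
catalogues (hub lncRNAs studied far more than others), literature bias in
which pairs get tested, correlated disease ontology structure, and
positive-unlabeled label noise that is not symmetric. Passing recovery
tests therefore demonstrates that the pipeline learns planted low-rank
signal through the full cold-start protocol — not that it will reach the
same numbers on any particular curated dataset.

## Problem sizes in tests

The test suite and `scripts/acceptance.R` run at a reduced profile —
`e = 8`, `Q = 10`, `epochs = 3` on the 60 × 80 fixture; recovery is
averaged over 5 generator seeds, the noise sweep over 2–3 seeds per
level — chosen so the whole suite completes in minutes while every
contract (weight normalization, aggregation identities, fold integrity,
recovery above 0.85 AUC, chance-level nulls, noise monotonicity) is
exercised end to end. The study-scale defaults (`e = 32`, `Q = 100`,
`epochs = 10`) remain the exported defaults and are what `ldaboost()`
uses unless told otherwise.

## Known limitations

- Entirely new entities (no recorded associations at all) receive
  zero embeddings and uninformative scores; the method needs at least
  one observed link per entity to place it in the latent space.
- Presumed negatives are unlabeled pairs; scores are ranking scores, not
  calibrated association probabilities.
- The decision-stump AdaBoost ablation variant is intentionally simple
  (single-threshold learners) and serves as a baseline, not a tuned
  competitor.
- Fusion weights are fixed, not learned; stacking is out of scope.
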