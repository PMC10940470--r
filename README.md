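# ldaboost

Boosted link prediction for lncRNA–disease association networks.

Long non-coding RNAs (lncRNAs) are increasingly recognized as disease
biomarkers, but experimentally verified lncRNA–disease associations are
sparse: a typical curated catalogue records a few hundred links between
dozens of lncRNAs and a hundred-odd diseases. `ldaboost` is for
computational biologists who want to prioritize unverified (lncRNA,
disease) pairs for follow-up from nothing but such a catalogue — no
sequence, expression or ontology data required.

## The model

Let `Y ∈ {0,1}^{n×m}` be the binary incidence matrix over `n` lncRNAs and
`m` diseases, with `y_ij = 1` for a known association.

1. **Features.** A truncated SVD `Y ≈ U_e Σ_e V_e^T` keeps the `e` largest
   singular triplets (the best rank-`e` approximation in Frobenius norm).
   Row `i` of `U_e` embeds lncRNA `l_i`, row `j` of `V_e` embeds disease
   `d_j`; by default each side is scaled by `√Σ_e` so the inner product of
   the two embeddings approximates `y_ij`. A pair is represented by the
   concatenation of both embeddings, `d = 2e` (default `e = 32`, `d = 64`).
2. **Boosted CNN head.** A real-valued (SAMME.R) AdaBoost ensemble of `Q`
   small 1-D convolutional networks. Round `q` trains on sample weights
   `D`, which are then updated by
   `D_i ← D_i · exp(−ν · ½ · ỹ_i^T log p_q(x_i))` and renormalized
   (`ỹ` the ±1 class coding, `ν` the shrinkage); round `q+1`'s network is
   initialized from round `q`'s trained parameters (transfer learning).
   Estimator probabilities are aggregated through symmetric log-odds
   `c_k^q = log o_k^q − ½ Σ_{k'} log o_{k'}^q`, summed over rounds.
3. **Tree head.** A gradient-boosted decision-tree classifier (100 trees,
   shrinkage 0.1) on the same features.
4. **Fusion.** The final association score is the convex combination
   `P(x) = α·C(x) + (1−α)·F(x)` with default `α = 0.4`.

Evaluation supports three fivefold cold-start protocols — held-out lncRNAs,
held-out diseases, held-out pairs — with six metrics (precision, recall,
accuracy, F1, AUC, AUPR), an ablation harness over `α` and over boosting
variants (boosted CNN alone, classical stump AdaBoost, GBDT alone), and
top-k candidate ranking for a disease of interest. A planted low-rank
generator (`simulate_association_matrix`) makes the whole pipeline testable
without any external download.

## Worked example

```r
library(ldaboost)

sim <- simulate_association_matrix(
  synthetic_spec(60, 80, r = 4, density = 0.1, seed = 42))
sim$am
#> Binary lncRNA-disease association matrix: 60 lncRNAs x 80 diseases,
#>   469 associations (density 0.0977)

fit <- ldaboost(sim$am, e = 8, cnn = list(Q = 10, epochs = 3), seed = 42)
summary(fit)
#> Boosted lncRNA-disease association model
#>   matrix: 60 lncRNAs x 80 diseases, 469 associations
#>   features: truncated SVD rank e = 8 (d = 16, sqrt_sigma scaling)
#>   heads: boosted CNN (Q = 10) + 100-tree GBDT, fusion alpha = 0.40
#> Training-set (resubstitution) metrics:
#>   precision 0.9405  recall 0.9765  accuracy 0.9574  F1 0.9582  AUC 0.9968  AUPR 0.9970

rank_candidates(fit, "D17", k = 5)
#> Top 5 candidate lncRNAs for disease 'D17' (no observed association):
#>  rank lncRNA_id fused_score
#>     1       L31 0.172563997
#>     2       L38 0.015906475
#>     3       L15 0.006799501
#>     4        L6 0.004789308
#>     5       L42 0.003737622
```

The ranking lists the lncRNAs with no recorded link to disease `D17`,
ordered by fused association score — the model's nominations for follow-up.
Resubstitution metrics gauge fit, not generalization; for an honest
estimate use cold-start cross-validation:

```r
cfg <- list(e = 8, cnn = list(Q = 10, epochs = 3), seed = 7)
sim <- simulate_association_matrix(
  synthetic_spec(60, 80, r = 4, density = 0.1, seed = 7))
cross_validate(sim$am, cfg, make_folds(sim$am, "pair", 5, seed = 7))
#> 5-fold cold-start CV on pairs (5 folds used):
#>   precision 0.8491 +/- 0.0545
#>   recall    0.7966 +/- 0.0734
#>   accuracy  0.8249 +/- 0.0205
#>   f1        0.8183 +/- 0.0274
#>   auc       0.9043 +/- 0.0137
#>   aupr      0.9062 +/- 0.0260
```

Held-out positive cells are zeroed before the SVD refit in this protocol,
so no test association leaks into the features.

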