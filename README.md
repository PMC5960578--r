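# lmpairnet

Network-based prediction of associations between diseases and
lncRNA–miRNA pairs.

Many complex diseases are linked not just to individual non-coding RNAs
but to interacting lncRNA–miRNA pairs. `lmpairnet` treats an ordered
pair *p* = (*l*, *m*) as a single composite vertex and predicts
disease–pair associations from three binary catalogues — lncRNA–disease,
miRNA–disease and lncRNA–miRNA — plus a MeSH-style disease hierarchy.

The method, in brief:

1. **Triangle filtering.** A disease *d* is known-associated with pair
   (*l*, *m*) exactly when the three edges (*l*, *d*), (*m*, *d*) and
   (*l*, *m*) all occur in their catalogues. The surviving vertices form
   a disease × pair bipartite network with binary adjacency
   *DP* (N<sub>p</sub> × N<sub>d</sub>).
2. **Layered similarities.** Diseases: hierarchy-based semantic
   similarity (decay Δ = 0.5) integrated with a Gaussian
   interaction-profile (GIP) kernel over the two disease-linked
   networks. Genes: best-match-average functional similarity plus the
   GIP kernel over profile rows. Pairs: average, square-root, or
   centre-distance combination of the lncRNA and miRNA similarities.
3. **Truncated KATZ scoring.** On the block matrix
   DP\* = [[PairSim, DP], [DPᵀ, DisSim]] each candidate cell is scored by
   S₁₂ of Σ<sub>l≤K</sub> γˡ (DP\*)ˡ — walks of length ≤ K, each step
   discounted by γ (defaults γ = 0.01, K = 2).
4. **Evaluation.** Leave-one-out and repeated k-fold cross-validation;
   held-out scores are ranked against candidate cells and summarised by
   ROC/AUC.

A seeded synthetic-data generator with planted community structure makes
every stage testable offline.

## Worked example

```r
library(lmpairnet)

dat   <- generate_lmpair_data(synthetic_config(seed = 42))
model <- lmpair_model(dat$lnc_disease, dat$mir_disease, dat$lnc_mir, dat$dag)
model
#> <lmpair_model>
#>   networks: 40 lncRNA(s), 35 miRNA(s), 30 disease(s), 785 triangle(s)
#>   pair universe: 1400 pair(s) (full), 785 known association(s)
#>   similarities: delta = 0.5, pair method = 'average', scope = restricted

head(predict_associations(model, gamma = 0.01, K = 2), 3)
#> # A tibble: 3 × 6
#>   disease_id lncRNA_id miRNA_id  score  rank known
#> 1 d07        l13       m11      0.0145     1 TRUE
#> 2 d07        l13       m03      0.0145     2 TRUE
#> 3 d07        l08       m04      0.0145     3 TRUE

cv <- kfold_cv(model$network, model$pair_sim, model$dis_sim,
               k = 5, repeats = 5, seed = 1042)
cv
#> <lmpair_cv> kfold: mean AUC 0.8839 (sd 0.0041) over 5 repeat(s)
```

The score of a cell is the damped walk count between its pair and
disease vertices: a known direct edge contributes γ = 0.01, and
similarity-mediated two-step walks contribute at the γ² = 10⁻⁴ scale —
which is why known associations sit at the top of the ranking and
candidate pairs similar to them come next. The cross-validated AUC
(here 0.88) is the probability that a masked known association outranks
a random candidate cell.

`autoplot(cv)` draws the pooled ROC curve; `tidy(cv)` / `glance(cv)`
return per-repeat and summary tibbles. A thin command-line wrapper with
`synth` / `predict` / `loocv` / `kfold` subcommands lives at
`inst/cli/lmpairnet.R`.

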