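# circmint

Prediction of candidate circRNA–miRNA interactions from a sparse tripartite
association network.

Circular RNAs (circRNAs) can act as miRNA "sponges", and mapping which
circRNA binds which miRNA is central to understanding competing-endogenous-RNA
regulation in cancer. Experimentally confirmed circRNA–miRNA pairs are scarce
— curated resources hold on the order of a thousand interactions over
hundreds of entities, an adjacency density of ~0.3% — so the practical task
is link prediction: rank the unobserved pairs of a binary interaction matrix
by how likely they are to be real. `circmint` is aimed at computational
biologists who have three edge lists — circRNA–miRNA, circRNA–cancer and
miRNA–cancer associations — and want a ranked candidate list plus an honest
cross-validated estimate of how well the ranking works.

## Method

Let `CM ∈ {0,1}^{m×n}` be the circRNA–miRNA adjacency, and `CC`, `MC` the
cancer-association matrices of the two entity classes.

1. **Similarity fusion.** Gaussian interaction profile (GIP) kernel
   similarities are computed from the rows and columns of `CM`,
   `GCS(i,j) = exp(−γ‖CM(i,·) − CM(j,·)‖²)` with bandwidth
   `γ = m / Σᵢ‖CM(i,·)‖²`, and cosine functional similarities from the
   cancer profiles, `CCS(i,j) = ⟨CC(i,·), CC(j,·)⟩ / (‖CC(i,·)‖‖CC(j,·)‖)`.
   The fused similarity uses the cosine value where it is nonzero and falls
   back to the GIP kernel where the cancer profiles are disjoint or empty.
2. **Network embedding.** The heterogeneous graph `H = [[0, CM], [CMᵀ, 0]]`
   is embedded with exact small-window NetMF: the random-walk matrix
   polynomial `M = vol(G)/(bT) (Σ_{r=1..T} Pʳ) D⁻¹` is truncated at
   `M′ = log max(M, 1)` and factorized by rank-`d` SVD (default `d = 16`,
   `T = 10`, `b = 1`); the embedding is `U_d Σ_d^{1/2}`, min–max normalized
   per column to keep features non-negative.
3. **Feature fusion.** Per entity class, features are the concatenation
   `[embedding | fused similarity]`.
4. **Inductive matrix completion.** Scores come from the regularized
   non-negative bilinear model
   `min_{W,H≥0} ½‖CM − X W Hᵀ Yᵀ‖_F² + θ₁/2‖W‖_F² + θ₂/2‖H‖_F²`
   (`X`, `Y` the feature matrices, `θ₁ = θ₂ = 1`), solved by multiplicative
   updates and ensembled by averaging over several low-rank dimensions
   (default ranks 128 and 64).
5. **Evaluation.** 10-fold cross-validation over the known positives, with
   per-fold recomputation of GIP similarities and embeddings from the masked
   training matrix (no test-label leakage), tie-aware ROC/PR curves, and
   pooled AUROC/AUPR.

A synthetic generator (`synth_generate()`) produces tripartite networks in
which `CM`, `CC` and `MC` share non-negative low-rank latent factors, so the
assumption that functionally similar entities share interaction partners
holds by construction and the whole pipeline is testable without any
external database.

## Worked example

```r
library(circmint)

sd <- synth_generate(synth_config(seed = 1))   # 120 x 100 CM, ~2% density
ds <- sd$dataset
interaction_density(ds$CM)
#> [1] 0.02491667

cfg <- pipeline_config(ranks = c(32L, 16L), seed = 1L)
cv <- run_cv(ds, cfg)
round(c(AUROC = cv$auroc, AUPR = cv$aupr), 4)
#>  AUROC   AUPR
#> 0.8552 0.4304

scores <- predict_interactions(ds, cfg)
rank_query(scores, "miR_001", top_n = 3)
#>   rank  circRNA     score
#> 1    1 circ_109 0.3277360
#> 2    2 circ_082 0.2922900
#> 3    3 circ_046 0.2910024
```

The cross-validated AUROC of 0.855 says that a held-out true interaction
outranks a random non-interacting pair 86% of the time; the AUPR of 0.43 is
far above the positive prevalence (~2.5%), so the top of the ranking is
strongly enriched for real pairs. `rank_query()` returns the candidate list
a bench scientist would take to the literature, highest score first.

The same stages are available from a shell:

```sh
Rscript inst/cli/circmint.R simulate --out fixture --seed 1
Rscript inst/cli/circmint.R evaluate --cm fixture/cm_edges.tsv \
    --cc fixture/cc_edges.tsv --mc fixture/mc_edges.tsv --out eval_out
Rscript inst/cli/circmint.R rank --cm fixture/cm_edges.tsv \
    --cc fixture/cc_edges.tsv --mc fixture/mc_edges.tsv --query miR_001
```

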