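# kronmda

Prediction of candidate miRNA–disease associations from a known
association list and a disease hierarchy, by symmetric non-negative
matrix factorization of integrated similarity matrices followed by a
closed-form Kronecker regularized least-squares solver.

## The problem and the model

Experimentally verifying which miRNAs are involved in which diseases is
slow and expensive, so computational ranking of candidate pairs is a
standard triage step.  The guilt-by-association premise is that
functionally similar miRNAs tend to be involved in phenotypically
similar diseases.  `kronmda` turns that premise into a kernel ridge
regression over all disease–miRNA pairs:

1. **Adjacency.** Known associations form a binary matrix
   *A* ∈ {0,1}^(nd×nm) (rows = diseases, columns = miRNAs).
2. **Disease similarity.** Each disease's DAG (itself plus its ancestors
   in a MeSH-like hierarchy) yields two semantic similarities: model 1
   decays an ancestor's contribution geometrically with distance
   (factor Δ, default 0.5); model 2 weights each ancestor by its
   information content −log(fraction of disease DAGs containing it).
   Their average *SS* is combined with a Gaussian interaction-profile
   kernel *KD*(i,j) = exp(−γ_d‖A_i· − A_j·‖²) into
   *SD* = (*SS* + *KD*)/2.
3. **miRNA similarity.** Functional similarity *FS* (group-max matching
   of the two miRNAs' associated-disease sets under *SS*, or a
   precomputed MISIM-style matrix) is combined with the column-profile
   kernel *KM* into *SM* = (*FS* + *KM*)/2.
4. **SymNMF interpolation.** *SD* and *SM* are factorized as *P Pᵀ*
   (P ≥ 0) by damped multiplicative updates
   *P ← P ∘ (1 − α + α R)*, *R* = (*SD P*) ⊘ (*P PᵀP*), α = 0.999,
   with a cube-root fallback *P ← P ∘ R^(1/3)* whenever the damped step
   fails to lower ‖SD − P Pᵀ‖²_F.  The product *SD\** = *P Pᵀ* is a
   denoised, positive-semidefinite version of the similarity.
5. **KronRLS scoring.** All pairs are scored at once by
   vec(*S*) = *K*(*K* + λI)⁻¹vec(*A*) with the pairwise kernel
   *K* = *SD\** ⊗ *SM\** and λ = 1, computed through the two side
   eigendecompositions so the nd·nm × nd·nm kernel is never formed.

Evaluation utilities implement global and local leave-one-out
cross-validation (rank each held-out association against all unverified
pairs, or only the same disease's), repeated 5-fold CV, and rank-based
ROC/AUC.  A planted block-model generator provides fully synthetic
benchmarks with held-out truth, so the whole pipeline is testable
without any database download.

## Worked example

```r
library(kronmda)

ds <- default_benchmark(seed = 1)   # 30 diseases x 40 miRNAs, 3 communities
ds
#> <synthetic_dataset> 30 x 40, 164 true / 132 observed / 32 masked associations

a <- build_adjacency(ds$associations, ds$diseases, ds$mirnas)
scores <- mda_predict(a, ds$hierarchy)
round(scores[1:3, 1:4], 4)
#>            mirna_01 mirna_02 mirna_03 mirna_04
#> disease_01   0.6514   0.0728  -0.0055   0.7136
#> disease_02  -0.0085   0.1719   0.0126   0.0012
#> disease_03  -0.0009   0.0367   0.0447   0.0360
```

Scores are shrunken association probabilities: known pairs score high
(disease_01/mirna_01 is an observed association), and candidate pairs
inherit score from similar diseases and miRNAs.  Treating a disease as
*new* (zeroing its row and recomputing everything that depends on it)
ranks its candidate miRNAs:

```r
ranked <- predict_new_disease(a, ds$hierarchy, disease = "disease_01")
head(ranked, 5)
#>      mirna   score rank
#> 1 mirna_07 0.15886    1
#> 2 mirna_10 0.14266    2
#> 3 mirna_31 0.07899    3
#> 4 mirna_14 0.07109    4
#> 5 mirna_37 0.06945    5
```

Ranking disease_01's true miRNAs (none of which were visible to the
model) against the rest gives a recovery AUC of 0.821 on this seed.

A command-line front end at `inst/cli/kronmda.R` wires the same
functions into `simulate`, `compute-similarity`, `interpolate`,
`predict`, `predict-new-disease` and `evaluate` subcommands.

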