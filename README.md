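# ForestMQA

Single-model quality assessment for protein structure prediction: given a
pool of candidate 3D models ("decoys") for one target sequence, ForestMQA
ranks them by a random-forest estimate of their relative TM-score and
selects the model expected to be closest to the native structure.

It is aimed at structural bioinformaticians who generate decoy pools
(template-based modelling, fragment assembly, CASP-style server
predictions) and need to pick the best model without access to the native
structure, and at method developers who want a self-contained, fully
deterministic reference pipeline to benchmark against.

## The method

Each model in a target's pool is described by nine features:

| slot | feature |
|------|---------|
| F1-F3 | three knowledge-based potential energies (dDFIRE, RWplus and GOAP score files are ingested as tables; a built-in contact pseudo-potential makes the pipeline self-contained) |
| F4-F6 | fraction of residues whose secondary structure observed in the 3D model (DSSP-style assignment) matches the sequence-based prediction, split into helix, sheet and coil matches |
| F7 | confidence-weighted secondary-structure consistency, (1/N) Σᵢ δ(sᵢᵒᵇˢ, sᵢᵖʳᵉᵈ) · cᵢ |
| F8-F9 | Pearson correlation and cosine similarity between per-residue solvent accessibility computed from the model and predicted from sequence |

Within each pool, all features and the TM-score labels are min-max
normalized to [0, 1], so the learned score is a *relative* quality within
the pool. A regression random forest (bagging, m_try random features per
split, variance-reduction splits, node cutoff 5, out-of-bag permutation
importance; defaults n_tree = 3000, m_try = 1) maps the normalized
features to the normalized TM-score. Training pools are screened to their
top 50% of models by TM-score, and targets with mean TM-score below 0.3
are excluded; screening is never applied when ranking.

The package also implements the surrounding machinery from first
principles: a deterministic TM-score engine (Kabsch superposition with
iterative seed-fragment extension, d0(L) = max(0.5, 1.24 (L−15)^⅓ − 1.8)),
Kabsch–Sander hydrogen-bond secondary-structure assignment, Shrake–Rupley
solvent accessibility, parsers for PDB / DSSP / PSIPRED-style /
accessibility / energy-table files, target-level five-fold
cross-validation with an (n_tree × m_try) grid search, the full
evaluation-metric suite (CC_TM, Spearman ρ, TM-loss, selection Z-scores
and their bin distribution, per-target rank correlation, pairwise
gain/loss/equal counts), and a synthetic decoy generator so everything is
testable offline.

## Worked example

Train on five synthetic pools and rank a sixth, unseen pool:

```r
library(ForestMQA)

sims  <- makePoolSet(6, decoyGeneratorParams(
           n_residues = 24, n_decoys = 8,
           noise_sigmas = seq(0.3, 1.6, length.out = 8), seed = 1))
pools <- lapply(sims, `[[`, "pool")

poolLabels(pools$T001)
#> T001_m01 T001_m02 T001_m03 T001_m04 T001_m05 T001_m06 T001_m07 T001_m08
#>    0.775    0.524    0.380    0.430    0.264    0.235    0.275    0.165

forest <- fitFinal(pools[1:5], n_tree = 500, m_try = 1,
                   config = trainingConfig(seed = 1))
forest
#> RegressionForest: 500 trees, mTry 1, node cutoff 5, 20 training rows
#>   OOB MSE 0.02694

ranked <- rankPool(forest, normalizePool(pools$T006))
head(ranked, 3)
#>   model_id predicted_score rank
#> 1 T006_m01       0.7315005    1
#> 2 T006_m02       0.7281382    2
#> 3 T006_m03       0.6632621    3
```

The labels are TM-scores of each decoy against the pool's reference
structure (1 = identical); here the decoys were built with increasing
coordinate noise, so quality decreases from m01 to m08. The ranker,
trained only on the five other pools, selects `T006_m01` — the true best
model of the held-out pool (TM 0.697, TM-loss 0). `forestImportance(forest)`
returns the raw permutation importance of each feature.

A command-line wrapper with subcommands `simulate`, `extract`, `tmscore`,
`train`, `rank` and `eval` is installed at
`system.file("scripts/forestmqa", package = "ForestMQA")`.

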