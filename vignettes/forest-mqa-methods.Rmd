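---
title: "ForestMQA: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ForestMQA: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem and the model

Protein structure prediction pipelines produce pools of candidate 3D
models ("decoys") per target sequence; picking the model closest to the
(unknown) native structure is the model quality assessment (MQA)
problem. ForestMQA is a *single-model* method: each decoy is scored from
its own coordinates and sequence-based predictions, never from its
similarity to the other decoys, so it does not degrade when a pool is
dominated by poor or mutually dissimilar models the way consensus
methods do.

The score is a random-forest regression estimate of the decoy's
*relative* TM-score within its pool. Nine features describe a decoy:

* **F1–F3, statistical potentials.** Pseudo-energies from
  knowledge-based potentials (the dDFIRE, RWplus and GOAP slots).
  External score files are ingested as two-column tables
  (`readEnergyTable()`); the built-in `contactPotential()` — a
  deterministic CA-distance-binned contact energy weighted by pairwise
  hydrophobicity — fills the slots when external programs are not
  available. Because every feature is min–max normalized within the
  pool, only the *ordering* and relative spacing of the energies matter;
  units and offsets of the external programs are irrelevant. Convention:
  lower = better (a `flip_sign` option handles tables with the opposite
  convention).
* **F4–F6, secondary-structure match fractions.** The 3-state secondary
  structure observed in the model is compared position-by-position with
  the sequence-based prediction; the helix, sheet and coil match counts
  are each divided by the chain length.
* **F7, confidence-weighted consistency.**
  \((1/N_{res}) \sum_i \delta(s_i^{obs}, s_i^{pred})\, c_i\) with
  \(c_i \in [0,1]\) the predictor confidence. Normalizing by
  \(N_{res}\) (rather than \(\sum_i c_i\)) makes F7 a strict
  confidence-weighted refinement of F4+F5+F6 — it always satisfies
  F7 ≤ F4+F5+F6 with equality at full confidence — which is why it is
  the default; the \(\sum c_i\) variant is available via the
  `normalize = "confidence"` argument.
* **F8–F9, accessibility consistency.** Pearson correlation and cosine
  similarity between per-residue absolute solvent accessibility (Å²)
  computed from the model and predicted from sequence. Pearson is
  computed on the raw values, not ranks.

**Labels and normalization scope.** Training labels are TM-scores of
each decoy against the target's reference structure. Features *and*
labels are min–max normalized to [0, 1] **within each target's pool**,
never across targets: the method's output is explicitly a relative
quality, and per-pool normalization is what makes energies from
different programs and targets commensurable. Global normalization
would leak pool composition across targets and tie the score to the
units of specific energy programs. A `label_mode = "raw"` option trains
on raw TM-scores instead.

**Normalization before screening.** Training pools are screened to
their top half by TM-score (below). Normalization is computed over the
*full* pool first and screening applied second. The reverse order would
rescale the training features to the span of the surviving top half,
while `rankPool()` necessarily normalizes over the full pool it is
given — the two scales disagree exactly in the high-quality region the
selection depends on, which measurably degrades top-1 selection. With
normalization first, training and ranking see identical feature scales.

# The training protocol

* **Screening (training only).** A target whose pool's mean raw
  TM-score is below 0.3 is excluded entirely; otherwise the
  ⌈0.5 · n⌉ highest-labelled models are kept. Rationale: very poor
  pools and the poor tail of each pool teach the regressor little about
  distinguishing good models. Screening is never applied at ranking or
  evaluation time, and `rankPool()` output is by construction
  independent of the screening fraction.
* **Cross-validation.** Folds partition *targets*, never individual
  models, so no decoy of a held-out target can influence training. The
  default is 5 folds.
* **Grid search.** n_tree ∈ {500, 1000, …, 10000} × m_try ∈ {1..7}
  (140 combinations). The selection criterion — not pinned down by the
  protocol this reimplements — is the mean per-target Pearson
  correlation between out-of-bag ensemble predictions and the
  normalized labels on the training folds, maximized, with ties broken
  toward smaller n_tree then smaller m_try. OOB predictions give an
  honest validation signal without touching the held-out fold. Because
  per-tree random streams are derived from the root seed by fixed
  offsets, the first k trees of a large forest are bit-identical to a
  forest trained with n_tree = k, so the whole n_tree axis of the grid
  is evaluated from one forest per m_try (prefix reuse).
* **Final model.** n_tree = 3000, m_try = 1, node cutoff 5, trained on
  the concatenated normalized rows of all screened training pools.

# The regression forest

Written from scratch (C++ core): bootstrap samples of size n drawn with
replacement per tree; at each node m_try features drawn without
replacement; the split maximizes the decrease in within-node sum of
squared deviations; thresholds are midpoints between consecutive
distinct sorted values; a node with fewer than node_cutoff = 5 rows is
a leaf; leaves store the mean response; prediction is the ensemble
average. The protocol description this follows says "information gain
measure by Gini impurity", which is a classification criterion; for a
regression forest the variance-reduction criterion implemented here is
the regression analogue used by Breiman's own regression code, and is
the deliberate reading adopted.

Determinism is a contract, not an accident: the forest uses its own
splitmix64/xorshift64* generator, never R's RNG. Each tree's stream is
derived from the root seed by a fixed offset, and each permutation
stream in the importance computation from (seed, tree, feature), so
results are bit-identical across runs, platforms and execution order,
and growing more trees never reshuffles earlier ones. Equal-gain splits
resolve to the lowest feature index, then the lowest threshold.

**OOB statistics.** Out-of-bag rows give the OOB mean squared error and
the raw permutation importance: per tree, the OOB MSE is measured, each
feature is permuted among that tree's OOB rows, and the importance is
the mean error increase over trees with nonempty OOB sets (trees with
empty OOB sets are skipped, with a warning above 10%). A feature a tree
never splits on contributes exactly zero for that tree. Under a null
response the estimator is exactly unbiased, which the tests exploit.

A `bootstrap = FALSE` option trains every tree on all rows; it exists
so a single tree with m_try = p can be compared split-for-split against
an exhaustive CART search, which the test suite does.

# Structural stand-ins

The pipeline depends on quantities normally produced by external
binaries. Self-contained, documented stand-ins are provided; externally
produced files take precedence when supplied.

* **Secondary structure** (`assignSecondaryStructure()`): the
  Kabsch–Sander electrostatic hydrogen-bond criterion. The amide H is
  rebuilt 1.0 Å from N opposite the previous carbonyl; the H-bond
  energy \(E = 0.084 \cdot 332\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} -
  1/r_{CN})\) kcal/mol is thresholded at −0.5 kcal/mol; 3-, 4- and
  5-turns (two consecutive n-turns) give helix, parallel/antiparallel
  bridge patterns give strand, and the 8→3-state reduction is
  {H,G,I}→H, {E,B}→E, rest→C (the most common convention). Full ladder
  and sheet bookkeeping beyond what 3-state reduction needs is out of
  scope. Prolines cannot donate; fewer than 5 complete-backbone
  residues yields all-coil with a warning.
* **Solvent accessibility** (`computeASA()`): Shrake–Rupley with a
  deterministic golden-section spiral of 960 points per atom, probe
  1.4 Å, van der Waals radii C 1.70 / N 1.55 / O 1.52 / S 1.80 Å
  (others 1.70), summed over heavy atoms per residue. Coordinates are
  first expressed in a molecule-fixed frame (principal axes, signs
  fixed by the third moment), which makes the discretized areas exactly
  invariant under rigid motion of the input.
* **File formats**: classic DSSP text, PSIPRED vertical (.ss2) format
  (confidence = maximum class probability) or generic 3-column tables
  (integer 0–9 confidences divided by 9), absolute or relative
  accessibility tables (relative values converted through the shipped
  Tien et al. maximum-ASA table).

# The TM-score engine

TM = max over superpositions of \((1/L)\sum_i 1/(1+(d_i/d_0)^2)\) with
L the reference length and \(d_0(L) = 1.24\,(L-15)^{1/3} - 1.8\),
floored at 0.5 Å for short chains (the standard convention; the
protocol source is silent). Residue correspondence is positional after
a sequence-identity check — CASP-style decoys share target numbering,
so no alignment is performed; residues lacking CA in either structure
are skipped. The maximization uses the standard heuristic: seed windows
of lengths L, L/2, L/4 at staggered offsets are Kabsch-superposed, the
residue pairs within a d0-based cutoff (expanded in 0.5 Å steps until
at least 3 pairs survive) are re-fitted, and the select/fit cycle is
iterated to convergence (cap 20 iterations); the best score over all
seeds is returned. The engine is deterministic; small deltas (< 0.01)
against other TM-score implementations are expected. The test suite
checks it against an independent oracle that maximizes the same
objective numerically over rigid-body parameters from multiple starts.

# The synthetic generator

`makeDecoyPool()` emulates the study material end-to-end: a reference
backbone (N, CA, C, O) built by NeRF from ideal internal coordinates
(helix φ = −57°, ψ = −47°; strand φ = −120°, ψ = 120°; standard bond
lengths and angles; helix, helix-loop-helix and strand-pair
topologies); decoys formed by per-residue *rigid* Gaussian jitter — the
same displacement applied to a residue's four backbone atoms — so
hydrogen bonds and hence assigned secondary structure degrade smoothly
with noise (per-atom noise destroys H-bonds almost immediately);
labels by `tmScore()` against the reference; secondary-structure
predictions correct at a tunable rate with higher confidences on
correct positions; accessibility predictions as reference ASA plus
Gaussian noise; and energies constructed as ρ · standardized(1 − TM)
plus Gaussian noise, hitting a requested energy–quality correlation ρ.
Energies are simulated rather than computed by the built-in potential
precisely so tests can control that correlation.

Defaults (chosen once as plausible study conditions): 30-residue
helix-loop-helix targets, 10 decoys per pool, jitter scales spread over
0–3 Å (TM-scores from 1.0 down to ≈ 0.1 at these lengths), 85%
secondary-structure prediction accuracy, 15 Å² accessibility noise,
energy–quality correlation 0.8.

What the generator does **not** emulate: physically realistic decoy
ensembles (no side chains, no compactness constraint, no
topology-swapped decoys), correlated errors between predictors, or the
length distribution of real targets. Passing tests therefore
demonstrate the correctness and internal consistency of the machinery
and the learnability of quality signal under controlled conditions —
not performance on CASP-scale data, which requires external decoy sets
and scoring binaries.

# Evaluation metrics

Over labeled pools: CC_TM and Spearman ρ between the TM-score of each
method's selection and the pool best across targets; mean TM-loss
(TM_best − TM_selected; under tied maxima any maximal model counts as
best); mean per-target rank correlation (CC_rank); per-target selection
Z-scores (TM_selected − mean)/sd with the **sample** (n−1) standard
deviation by default and a population variant behind a flag; Z-score
bins Z<0, 0≤Z<1, 1≤Z<2, 2≤Z<3, Z≥3; sums of selected TM and Z; and
pairwise gain/loss/equal counts between two methods. Spearman uses the
rank-difference formula \(1 - 6\sum d_i^2/(n(n^2-1))\) when ranks are
distinct and the equivalent Pearson-on-mean-ranks under ties (the
printed formula assumes no ties). Degenerate cases (zero variance,
full ties) return NA with a warning rather than a fabricated value.

# Problem sizes and numerical choices

The test suite and `scripts/acceptance.R` run entirely on synthetic
material sized for a single CPU: the cross-validated study uses 20
pools of 8 decoys at 24 residues with per-pool noise floors spread over
0.15–0.7 Å (so the best attainable TM varies across targets, as in
real pools, and the hardest targets exercise the mean-TM exclusion
rule); the held-out selection experiment trains on 30 pools and ranks
10 unseen pools of 16-residue targets, repeated over seeds, with
n_tree = 500 for the repeated fits; reduced two-point hyperparameter
grids stand in for the full 140-combination grid wherever the grid
*content* is not itself under test. These sizes are the package's
choices for a reproducible desk-scale study; all constants of the
method itself (screening fraction, exclusion threshold, node cutoff,
default grids, final n_tree/m_try) are the published ones.

Other numerical choices: PDB coordinates are fixed-precision (1e-3 Å),
so file round-trips are compared at that tolerance; energies are
parsed as doubles and must be finite; constant feature columns within
a pool normalize to all-zeros with a warning (they carry no ranking
information); ranking ties break lexicographically by model id for
determinism; single-model pools are ranked trivially without
normalization.

# Known limitations

* The built-in contact potential is a testing stand-in, not a
  competitive statistical potential; real use should supply dDFIRE /
  RWplus / GOAP score tables.
* The secondary-structure stand-in reproduces the 3-state H/E/C
  classes, not DSSP's full 8-state ladder bookkeeping; isolated
  bridges are classed E without sheet merging.
* TM-score search is heuristic; it matches a direct numerical
  maximizer to < 0.005 on the tested fixtures but is not guaranteed
  globally optimal for pathological topologies.
* No disorder predictor is bundled; removing predicted-disordered
  regions before assessment is left to upstream preprocessing of the
  input PDB files (the parser drops CA-less residues and tolerates
  gaps, so pre-trimmed models are handled).
* CASP/I-TASSER benchmark figures are not reproducible here by design:
  they require external decoy archives and scoring binaries.
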