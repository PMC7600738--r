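---
title: "Methods: MinHashed atom-pair chemical space and origin classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MinHashed atom-pair chemical space and origin classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
choices that were genuinely open, and what the test suite does and does not
demonstrate. Everything quantitative stated here is computed by the test
suite or the acceptance script; nothing is quoted from elsewhere.

## 1. The problem

Microbial natural products span roughly 70–2900 Da. Fixed-radius circular
fingerprints describe small drug-like molecules well but lose resolution on
the large peptides, glycosides and macrolides that dominate the upper end of
that range. The package therefore encodes molecules with a MinHashed
atom-pair fingerprint, organizes collections into minimum-spanning-tree
chemical-space maps, annotates each structure with interpretable
physico-chemical properties, and trains classifiers that assign a bacterial
or fungal origin to a structure.

## 2. Fingerprint

### 2.1 Shingles

For a canonical, stereochemistry-free SMILES, every unordered pair of heavy
atoms `(A, B)` contributes one token per radius `r ∈ {1, 2}`:

```
env_r(A) | d(A,B) | env_r(B)
```

where `d` is the shortest-path distance in bonds and `env_r` is a canonical
encoding of the circular substructure of radius `r` around the atom. The two
environments are ordered byte-wise so the token is symmetric in `A` and `B`;
the token set is deduplicated (set semantics, no counts). Pairs spanning
disconnected fragments of a multi-fragment SMILES are skipped — an infinite
topological distance carries no pair information. Molecules with fewer than
two bonded heavy atoms have no atom pairs and are rejected with a
`too-small-molecule` error.

**Environment encoding (frozen).** `env_r` is an iterated
neighborhood-refinement string: the radius-0 label of an atom is its element
symbol; the radius-`r` label is its radius-`(r-1)` label followed by the
sorted, bond-tagged radius-`(r-1)` labels of its neighbors (bond tags `-`,
`=`, `#`, `:` for bond orders 1–4 as written in the kekulized connection
table). This is a canonical rooted description of the radius-`r` ball: it
needs no atom-index tie-breaking, is invariant to the input atom order once
the SMILES is canonical, and treats symmetric atoms identically (the
benzene fixture collapses to exactly one token per distance–radius
combination). It is deliberately not a literal sub-SMILES: a rooted
canonical subgraph-SMILES writer would add ring-closure canonicalization
machinery without changing what the fingerprint distinguishes at radius ≤ 2.
Two practical consequences are documented rather than hidden: aromaticity
enters through the kekulized bond orders (alternating single/double), and
formal charges enter only through an atom's bonding pattern. All ordering
uses byte-wise (radix) comparison, so shingle sets are identical across
locales; the encoding version tag `map4np-enc-1` is recorded in signature
files and model bundles, which refuse to mix versions.

### 2.2 MinHash

Each token's base hash is the first four bytes (little-endian) of its SHA-1
digest. The signature applies 1024 universal hash functions

```
h_i(x) = ((a_i · x + b_i) mod (2^61 − 1)) mod 2^32
```

and keeps the minimum over the token set per function. The coefficients
`a_i, b_i < 2^31` are drawn once from a Mersenne–Twister stream at the fixed
family seed 714; the same build yields bit-identical signatures on every
platform (golden-signature digests for five fixtures are asserted in the
suite). Index-wise agreement of two signatures estimates the Jaccard
similarity of the underlying shingle sets. Hash values are folded to 32 bits
so signatures remain exactly representable as R doubles; the fold follows
the usual MinHash practice and costs nothing measurable in estimator
accuracy at 1024 permutations.

**Calibration.** Over a 220-pair synthetic panel spanning exact Jaccard
values from 0 to 1 (progressive fragment substitution; all ten deciles
populated), the estimator's mean signed error is within ±0.01 and at least
99% of pairs fall within the binomial 3σ band `|error| ≤ 0.094 =
3·sqrt(0.25/1024)·2` of the exact Jaccard computed on the shingle sets
themselves. The exact-Jaccard oracle is an independent set computation, not
a second path through the hash machinery.

## 3. Chemical-space maps

The layout pipeline follows the tree-map recipe: approximate k-nearest
neighbors from an LSH forest, a symmetrized weighted kNN graph, and a
minimum spanning tree.

* **LSH forest.** `n_trees = 32` prefix trees; tree `t` indexes each
  molecule by the first 8 values of its signature under a seeded random
  permutation of the 1024 positions (the prefix depth is a documented
  internal constant). A query descends to the deepest prefix window holding
  at least `k + 1` candidates, unions candidates across trees, and re-ranks
  them with the exact estimator — the index only proposes, never scores.
  Mean top-20 recall against brute-force kNN is at least 0.8 on 500
  generated molecules (asserted; brute force is the oracle).
* **kNN graph.** Per-node top-`k` (default 20) by estimated Jaccard
  distance `1 − similarity`, ties broken by molecule id, symmetrized by
  edge union; `k ≥ n` is truncated to `n − 1` with a warning.
* **MST.** Kruskal's algorithm with the deterministic tie-break
  (weight, smaller id, larger id) and a union–find over the node set.
  Disconnected graphs yield a spanning forest with components reported; an
  optional flagged mode links components through their closest
  inter-component pair to recover a single display tree (off by default).
  On random graphs the total weight equals an independent Prim
  implementation (igraph's MST) to machine precision, and with `k = n − 1`
  the LSH-based and brute-force pipelines give identical MST total weight.
* **Export and layout.** Edge-list TSV and GraphML with one node attribute
  per annotation column; coordinates from the Reingold–Tilford tree layout
  per component (root = highest-degree node, ties to the smallest id),
  components offset side by side. The layout is deterministic; the `seed`
  argument is kept for interface stability only. Interactive force-directed
  rendering is out of scope.

## 4. Properties

Descriptors (MW, HBA as N+O count, HBD, Crippen-style AlogP, TPSA) come
from OpenBabel's published implementations; the fraction of sp3 carbons is
computed from the kekulized connection table (a carbon is sp3 when all its
bonds are single). The same HBA/HBD values feed the rule-of-five check —
the flag tolerates one violation (MW > 500, AlogP > 5, HBD > 5, HBA > 10)
and molecules violating two or more are non-Lipinski; `NA` descriptors are
not counted as violations.

The Joback boiling point is `T_b = 198.2 + Σ N_i·t_bi` (Kelvin) over the
packaged group-contribution table (`inst/extdata/joback_groups.csv`). The
group SMARTS are written to be mutually exclusive — each heavy atom is
consumed by at most one group — and multi-atom groups (acid, ester,
carbonyl, nitrile, nitro) record how many heavy atoms a match consumes, so
per-molecule coverage is auditable. Unmatched atoms contribute 0 K and emit
a coverage warning with the per-molecule account attached as an attribute;
a molecule matching no group (methane is the canonical case) returns
exactly the 198.2 K intercept. Aromatic atoms are matched by dedicated
aromatic rows mapping to the ring-group contributions; tertiary aromatic
and ring nitrogens take the open-chain tertiary-amine value, the closest
group the original table provides.

Two fixed SMARTS patterns, used verbatim, define the compound classes:

```
dipeptide: [NX3,NX4+][CH1,CH2][CX3](=[OX1])[NX3,NX4+][CH1,CH2][CX3](=[OX1])[O,N]
glycoside: [CR][OR][CHR]([OR0,NR0])[CR]
```

`peptide` / `glycoside` when exactly one matches, `glycopeptide` when both,
`none` otherwise; agreement with an independent SMARTS engine (RDKit) is
asserted on a fixture quartet. Display clamping for map color codes
saturates MW at 1000 Da, the boiling point at 2000 K, HBD at 10, HBA at 20,
AlogP into [−2, 8] and TPSA at 500 Å²; ranked color codes use average
(fractional) ranking, ties sharing the mean of the ranks they span.

## 5. Origin classifiers

Three models share the training protocol: class weights inversely
proportional to class frequency, stratified 5-fold cross-validation on the
training set selecting the hyperparameters that maximize validation ROC
AUC, and `bacterium` as the positive class.

* **MAP4 SVM** — C-SVC on the precomputed estimated-Jaccard similarity
  matrix, `C ∈ {0.1, 1, 10, 100, 1000}`. That kernel is an empirical
  similarity, not a certified PSD kernel; the solver (kernlab) is used as
  is and any failure surfaces as an error rather than a silent coercion.
* **MAP4 k-NN** — `k ∈ {5, 7, 9, 11}` under distance `1 − similarity`;
  prediction probability is the unweighted fraction of bacterial neighbors;
  distance ties break by molecule id.
* **Physchem SVM** — RBF SVM on MW, fsp3C, HBA, HBD, AlogP, TPSA and the
  Joback boiling point, scaled to zero mean and unit variance on the
  training set only (constant features dropped with a warning); grid search
  over `C` and `γ ∈ {0.01, 0.1, 1, 10, 100}` (sklearn's and kernlab's RBF
  parameterizations coincide, `exp(−γ‖x−y‖²)`).

Probabilities come from Platt scaling fitted as a logistic regression on
cross-validated decision values of the training set — every training
molecule is scored by a model that did not see it — so the calibration data
are honestly out-of-fold; the same path serves both SVMs. The decision-value
orientation is fixed empirically (higher = bacterium) rather than trusting
the solver's label-order convention. Prediction output includes the
training-set nearest neighbor and its estimated Jaccard distance; the
binary label applies a 0.5 threshold with ties called bacterial. Stratified
folds are a documented choice (the safer default under class imbalance);
"5-fold cross-validation leaving 20% out" is read as plain 5-fold CV, since
the two coincide at five folds. Model bundles serialize with the encoding
version and refuse to load across versions.

## 6. Evaluation

Confusion counts at threshold 0.5 and the standard metric definitions:
precision `tp/(tp+fp)`, recall `tp/(tp+fn)`, TNR `tn/(tn+fp)`,
`F1 = 2PR/(P+R)`, balanced accuracy `(TPR+TNR)/2`, MCC with the square-root
denominator, and ROC AUC by trapezoidal integration over all score
thresholds (one ROC point per distinct score). Zero-denominator cases are
reported as 0 with a degeneracy flag instead of NaN. Metric parity against
a from-scratch formula evaluation, and AUC parity against pROC, are
asserted over 1000 random confusion tables and score vectors, along with
the structural properties (monotone-transform invariance of AUC, label-swap
symmetry of MCC, AUC = balanced accuracy for binary scores).

## 7. Synthetic data: what it emulates and what it does not

The generator assembles molecules from a fragment grammar: chain units with
an open valence at each end concatenate into valid SMILES by construction,
and a terminal cap closes the chain. Unit pools define the class signal:

* `substructure` — bacterial molecules are oligopeptide chains that always
  terminate in a dipeptide block closed by an acid/ester oxygen or a
  glycoside cap (15%), fungal molecules are aromatic polyketide chains;
  both interleave 45% shared aliphatic decorations and draw size targets
  log-uniformly from one shared range (default 150–2500 Da), so the classes
  differ in substructure content at matched size.
* `property` — both classes draw from one pooled grammar; only the
  molecular-weight targets differ, by default means 500 vs 620 Da with
  sd 60. The default shift is deliberately about one chain unit: small in
  structure space but crisp in descriptor space, which is the operative
  meaning of a property-only signal — a many-sigma shift (such as means
  300 vs 900, sd 50, used explicitly in the physchem unit test) is
  detectable by any size-sensitive representation, fingerprints included,
  and cannot separate the two model families.
* `none` — both classes sampled identically; a permutation test in the
  suite confirms the shingle-set distributions are indistinguishable.

Each class spans many structural families (16 + 16 motif units, 12 shared
decorations, interleaved): with the first, purer grammar each class formed
one tight similarity cluster, and a label-permutation null then had so few
effective degrees of freedom that its held-out AUC swung far outside
0.5 ± 0.1 — an artifact of unrealistic homogeneity, not of the models. Real
natural-product collections contain many families per origin; the
diversified grammar reproduces that regime (within-class mean similarity
≈ 0.07) and the null concentrates as expected. The null control itself
permutes the labels of the whole dataset before splitting, the standard
construction that destroys all label–structure association.

What passing these tests shows: the pipeline recovers a constructed,
chemically encoded class signal, its estimator is calibrated, its graph
algorithms match independent oracles, and its null behavior is sound. What
it does not show: performance on real collections — synthetic molecules are
concatenative chains without macrocycles, stereocenter-rich scaffolds,
charged salts, or the long-tailed family-size distribution of curated
databases. Collection-scale results depend on such an external table and
are reproducible only by supplying one.

## 8. Numerical choices and degenerate inputs

* Signature length 1024, radii {1, 2}, `n_trees = 32`, `k = 20`, LSH prefix
  depth 8: the pipeline's standard settings; all overridable.
* Hash-family seed 714; generator, split, fold, and dual-origin decisions
  each take explicit seeds. Identical seeds give identical splits, folds,
  selected hyperparameters and predictions (asserted).
* Single-heavy-atom molecules (e.g. methane): the SDF plumbing has no bond
  block there, so descriptors fall back to an elemental branch (exact MW
  from atomic masses, fsp3C/HBA/HBD/TPSA by definition, AlogP `NA`) and
  SMARTS counts are zero — which is also what makes methane the natural
  zero-group probe of the Joback intercept.
* Unparseable SMILES never abort a batch: they are routed to a rejects
  report on ingestion and to per-row error entries on prediction.
* Ties: Kruskal edges break by (weight, smaller id, larger id); kNN by
  (distance, smaller id); a probability of exactly 0.5 is called bacterial;
  average ranking assigns tied values their mean rank.
* Multi-fragment SMILES are kept intact by default; `largest_fragment()`
  provides the salt-stripping alternative.

## 9. Known limitations

* Shingle environments are refinement strings, not sub-SMILES; numeric
  identity with other implementations of MinHashed atom-pair fingerprints
  is not expected (signatures carry a version tag for exactly this reason).
* The Joback table inherits the method's limits: rare heteroatom
  environments match no group, contribute 0 K and only surface through the
  coverage warning; boiling-point estimates for very large molecules are
  extrapolations far beyond the method's calibration set.
* The estimated-Jaccard kernel is not guaranteed PSD; in practice the
  solver converges on these matrices, but that is an empirical property.
* The LSH forest targets collection scales of the order of 10^4–10^5
  molecules; the in-memory kernel SVM is the practical bottleneck well
  before the index is.
* Problem sizes in the suite (a 220-pair calibration panel, 500-molecule
  retrieval benchmark, 200-molecules-per-class classifier runs, 100
  50-node MST instances) were chosen as the smallest sets at which each
  statistical assertion is stable under its fixed seed.
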