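---
title: "Methods: class-partitioned retention-time prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: class-partitioned retention-time prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`classrt` predicts liquid-chromatographic retention times (RT, seconds) by a
taxonomy-partitioned ensemble of per-class QSRR regressors. The pipeline has
four stages: (i) dataset ingestion with canonical-SMILES identity and a
deterministic 8:1:1 train/validation/test split; (ii) classification of the
training fold into functional-group subclasses by a weighted SMARTS rule
engine; (iii) per-class training-set augmentation by SMILES enumeration (SE)
and topology-guided active learning (Topo-AL), under a validation guard;
(iv) per-class expert selection among seven candidate regressors, with
taxonomy-first / similarity-fallback routing of queries at prediction time.

This vignette records the modelling assumptions, the parameters that matter,
the numerical choices, and the places where the design was genuinely open.

## Identity, splitting, leakage

The identity key everywhere is the toolkit-canonical SMILES string: two
renderings of one molecular graph are one compound. Stereochemistry is
preserved in the strings but not used to distinguish records, consistent
with reversed-phase C18 separations that do not resolve most optical
isomers. The split is drawn over *unique canonical forms* (floor of the
0.8/0.1/0.1 ratios for validation and test, remainder to train — training is
where augmentation operates, so the remainder is most useful there), and the
partition is exhaustive and disjoint by construction.

Leakage control is deliberately stricter than a naive reading of the source
protocol would be: enumerated SMILES variants duplicate their parent's
molecular graph, so if variants of one molecule could land on both sides of
a split, test metrics would collapse toward zero error without any
generalization being demonstrated. Near-perfect post-augmentation metrics
reported in the QSRR literature are consistent with exactly this failure
mode. `classrt` therefore (a) splits before augmenting, (b) removes from the
Topo-AL pool every canonical form occurring in validation or test, and
(c) asserts, in tests, that the augmented training set never intersects
validation ∪ test by canonical SMILES. Consequences: the package's
augmentation gains are modest and honest (direction, not miracle
magnitudes), and the ablation harness asserts ordering only.

## Taxonomy engine

Ontology web services are unavailable offline and their assignments are not
reproducible pinned artifacts, so classification is a local rule engine: a
TSV of `rule_id, smarts, weight, superclass, subclass` rows. All matching
rules are found; the maximal weight wins; ties break lexicographically by
`rule_id`; no match falls back to a configured class with weight 0. This
makes assignment total, deterministic and platform-stable. The shipped file
(49 rules, 13 superclasses: organic acids, benzenoids, organoheterocyclic,
organic nitrogen / oxygen / sulfur / phosphorus compounds, organohalogens,
1,3-dipolar compounds, lipids, phenylpropanoids and polyketides, alkaloids,
lignans) is an editable stand-in: the number of *subclasses* realized on a
dataset is data-dependent, not a fidelity target. Weights encode specificity:
defining functional groups (sulfonamide 10, benzoic acid 10, aniline 9) beat
generic environments (benzene ring 3, halogen 2, ether 2.5).

Classes smaller than `min_size` (default 15 — below that a per-class
validation split is statistically meaningless) are pooled into a single
residual class that trains one fallback submodel, so every molecule has a
home.

## Similarity

Fingerprints are ECFP-style circular fingerprints (radius 2, folded to 2048
bits). Similarity is Tanimoto, `|A ∩ B| / |A ∪ B|`. A printed form of this
coefficient circulating in the literature carries a factor of 2 in the
numerator; that form exceeds 1 (it is 2 for identical sets) and is
incompatible with similarity thresholds stated in [0, 1], so the standard
Jaccard form is implemented and the factor-of-2 form is treated as a typo.
Cosine similarity on the same bit vectors is available behind
`metric = "cosine"` for users who prefer it; Tanimoto is the default. Two
empty fingerprints have similarity 0 by convention (no evidence of
similarity). Between-class similarity summaries subsample at most 200
fingerprints per class under a derived seed to keep the full cross-product
desk-scale, and order classes by average-linkage clustering on
1 − similarity.

## Augmentation

**SE** (`k`, default 5): up to `k` randomized atom-order renderings per
training molecule, each verified to canonicalize back to the parent, each
distinct from the canonical string and from each other; the retry budget is
10·k draws, and a shortfall (e.g. methane admits no alternative rendering)
is allowed. For descriptor-based regressors the variants have identical
feature rows, so SE acts as deterministic sample re-weighting of training
molecules; the default of 5 reflects the saturation point reported for the
motivating data.

**Topo-AL** (`tau`, default 0.5): pool compounds (the full original training
fold, all classes) are recruited into a class's training set when their
maximum similarity to it is ≥ τ; the comparison is inclusive (the source
protocol states both "exceeding 0.5" and "50% or higher"; the inclusive
reading is taken and τ is configurable). Recruited records keep their own
measured RT.

**Guard** (`guard_enabled`, `guard_tolerance` = 0.01): augmentation proceeds
through multiples m = 0, 1, …, k (Topo-AL applied once, from m = 1), and a
cheap deterministic probe — ridge regression on the module's selected
descriptors — is scored on the class validation split after every step. If
the probe MAE exceeds the best seen by more than the relative tolerance, the
loop stops and the best-scoring set is returned. Including the m = 0
baseline means augmentation that never helps is simply not applied. The
probe is intentionally not the full seven-algorithm search: the guard must
cost O(k · cheap fit).

## Features

Descriptors are the full RDKit 2D block (> 200 columns: constitutional,
topological, VSA, logP-type), keyed by canonical SMILES so SE duplicates are
bit-identical. Columns with non-finite values are masked (`"nonfinite"`),
constants are masked (`"zero-variance"`). Selection is a deterministic
cascade: variance filter → redundancy pruning at |Pearson r| > 0.95 (keeping
the member more correlated with RT; ties lexicographic) → univariate ranking
by |corr with RT|, keeping `min(p, max(10, n/5))` columns. No PCA-style
extraction: it buys little for tree/kernel learners and destroys
per-descriptor interpretability. Scaling statistics (mean/sd) come from the
training fold only and are stored in the submodel, so prediction-time
features are transformed identically.

## The candidate registry and expert selection

The source protocol evaluates "7 ML algorithms" without naming them; the two
named winners are SVR and random forest. The registry here is the standard
QSRR suite implementable deterministically with the available numerical
stack: RBF kernel ridge regression (the kernel-machine family; closed form),
bagged depth-limited CART, gradient-boosted stumps, k-nearest-neighbours,
exact ridge/OLS (λ = 0 included deliberately, so noiseless linear signals
are fit to machine precision), elastic net, and a single-hidden-layer tanh
MLP trained by BFGS. Each algorithm gets a seeded random search of `budget`
configurations (default 20; the first is always the algorithm's default), all
scored by validation MAE; the global argmin is the class's expert (OPSRT).
Ties resolve to the earlier registry entry. The search log is retained in
the submodel so the argmin property is auditable after the fact. The
registry is a plain named list and fully pluggable.

## Routing

The discriminant stage ("SPDA" in the source, never specified there) is
defined here as: taxonomy assignment first; if the assigned subclass has a
submodel and the query's maximum similarity to that submodel's training
fingerprints reaches `min_route_sim` (default 0 — taxonomy is always trusted
when a submodel exists), route there; otherwise route to the submodel
maximizing the mean of the top-`m` (default 5) query–training similarities.
Ties break to the larger training class, then lexicographic id. Routing is
total and deterministic.

## Synthetic ground truth

The generator builds 2–8 scaffold families, each carrying one distinctive
functional group (benzoic acids, anilines, benzenesulfonamides, pyridines,
aliphatic esters, dialkyl ketones, haloalkanes, alkylbenzenes), decorated
with alkyl chains (length 2–8, optional methyl branch, optional terminal
halogen). The families were chosen so the shipped rule file separates them
with zero confusion — that is what makes routing accuracy assertable. RT is
`clip(a·logP + b·heavyAtoms + base + offset_c + ε)` with a = 100 s per logP
unit, b = 20 s per heavy atom, base = 150 s, class offsets evenly spaced
over ±150 s, ε ~ N(0, σ²) with σ = 10 s by default, clipped to the 60–1700 s
window of a ~30-minute gradient. The surrogates are *computed descriptors*
of the generated molecule, not the decoration parameters, so the feature
stage must genuinely recover the signal. Defaults (6 classes × 200, σ = 10)
describe a mid-size curated library with good chromatographic
reproducibility; with those defaults the linear surface stays inside the
clip window, and clipping is recorded in the truth object because it caps
attainable R² when σ is large.

What the generator does **not** emulate: real RT physics (pH, temperature,
gradient shape), activity cliffs, measurement heteroscedasticity,
class-imbalanced long tails, or inter-laboratory shifts. A green end-to-end
test therefore establishes that the pipeline recovers a known smooth
descriptor-linear signal with correct class structure and honest splits — it
does not certify accuracy on real chemical libraries.

The sparse regime (15 training molecules per class, a large scaffold-sharing
labeled pool) reproduces the data-sparsity setting that motivates
augmentation; the ablation harness runs a paired design (identical split
within each seed, only the augmentation arm varies) and asserts the
qualitative ordering — unaugmented never beats combined augmentation on mean
test MAE — rather than any printed magnitudes, for the leakage reasons above.

## Numerical choices and degenerate inputs

* Ridge with λ = 0 is solved by pivoted QR (`lm.fit`), collinear columns
  dropped to zero coefficients; λ > 0 by the normal equations.
* Kernel ridge solves (K + λI)α = y − ȳ; γ and λ are searched on log scales.
* The MLP standardizes the response internally, uses analytic gradients and
  a seeded uniform initialization, so fits are reproducible.
* Zero-variance scaling columns get sd 1 to avoid division by zero.
* MAPE is reported as a fraction (0.02, formatted as 2% where printed);
  `rt_metrics` refuses non-positive true RTs and zero-variance references.
* One user seed fans out to per-stage streams via a hash derivation
  (`derive_seed`), all below 2³¹; internals never disturb the caller's RNG
  state.
* Model persistence is a directory with a JSON manifest (schema version,
  rule hash, feature lists, routing configuration) as the compatibility
  contract plus serialized estimators; a schema mismatch is a hard error,
  never a silent reinterpretation.

## Known limitations

* The taxonomy stand-in reproduces superclass *names* and the
  highest-weight-wins mechanism, not any ontology's exact assignments; class
  counts on real data will differ from published ones.
* SE on descriptor-based learners is re-weighting, not new information; its
  value is largest for learners sensitive to effective sample size.
* The candidate registry substitutes closed-form kernel ridge for SVR and
  hand-rolled tree ensembles for the usual compiled libraries; on large
  classes the trees are the slowest candidates and budgets should be chosen
  accordingly.
* Retention times are treated as seconds throughout; minute-scaled inputs
  must be declared at ingest (`rt_unit = "min"`).
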