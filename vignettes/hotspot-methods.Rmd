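---
title: "Methods: interface hot-spot prediction with neighborhood-expanded residue descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface hot-spot prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A small minority of the residues at a protein-protein interface — the *hot
spots* — contribute most of the binding free energy. Experimentally they are
identified by alanine scanning: a residue whose mutation to alanine changes
the binding free energy by ddG >= 2.0 kcal/mol is a hot spot. `hotspotr`
implements a machine-learning pipeline that predicts this label for interface
residues of a complex structure: per-residue descriptors are computed from
sequence profiles, structure geometry, solvent exposure and contact
energetics, expanded over two kinds of structural neighborhood, reduced by a
two-step feature selection, and classified with gradient-boosted trees.

## The model, stage by stage

### Interface geometry and burial weights

Solvent accessible surface area (SASA) is computed by the Shrake-Rupley
method with a *deterministic* golden-section spiral lattice (default 960
points per atom, probe 1.4 Å), so repeated runs are bit-identical. The burial
of residue $i$ is $\Delta ASA_i = ASA_i^{monomer} - ASA_i^{complex}$, with
the monomer SASA computed on the residue's own binding side in isolation.
Residues with $\Delta ASA_i > 0.1$ Å² form the interface (the threshold is a
numerical-noise floor; the underlying papers never quantify "interface
residue", and any small positive floor gives the same set on realistic
burial scales). Each interface residue receives a fractional weight

$$W(i) = \frac{\Delta ASA_i}{\sum_j \Delta ASA_j}, \qquad
W_{FB}(i) = W(i)\,\frac{\Delta ASA_i}{ASA_i^{monomer}},$$

where the sum runs over interface residues, so $\sum_i W(i) = 1$ exactly.
$W_{FB}$, the *weighted fraction buried*, multiplies descriptors to form all
`W_`-prefixed feature variants.

### Structural neighborhoods

Two residue adjacency relations describe the micro-environment:

* **Euclidean** (`_EN`): residues whose minimum heavy-atom distance is
  <= 5 Å.
* **Voronoi** (`_VN`): residues sharing a Delaunay tetrahedron (equivalently
  a Voronoi facet between their atoms). The tessellation is computed over the
  heavy atoms of the *whole complex*, so neighborhoods cross the interface —
  cross-side contact features require this. An in-package Bowyer-Watson
  tessellation is used (no computational-geometry package is available in the
  target environment); each tetrahedron is verified against an independent
  empty-circumsphere oracle in the tests. Outer-hull Delaunay edges can be
  geometrically long, so Voronoi adjacencies whose minimum heavy-atom
  distance exceeds 8 Å are dropped (configurable). Near-cospherical inputs
  are retried once with a deterministic 1e-6 Å jitter; truly coplanar inputs
  are an error with guidance to jitter the fixture.

A context value is the **sum** of the site values over the central residue
and its neighbors. The sum (rather than the mean), and inclusion of the
center, are deliberate: summation preserves "micro-environment mass", which
reproduces the published scale difference between site and neighborhood
variants of exposure features; both choices are switchable
(`include_center`). Weighted context features multiply each residue's site
value by *that residue's own* $W_{FB}$ before aggregation (0 for
non-interface residues), matching the per-residue interpretation of the
burial weight.

### The site descriptor block

The canonical site block has 102 named columns (`site_feature_names()`):
physicochemical scales (12), side-chain environment pKa (2), PSSM log-odds
(20), conservation C-score (1, pluggable), ASA block (6), normalized
atom/residue contacts (6), pair potentials (3), topographical score (1,
pluggable), four-body pseudo-potential (1, pluggable), side-chain energy
scores (6, pluggable), local structural entropy (3, pluggable),
nearby-interface score (1, pluggable), Voronoi contact counts (2),
secondary-structure one-hot (3), disorder scores (6), BLOSUM62 row (20),
solvent exposure (7), PSSM entropy (1), hydrogen bonds (1). The published
block inventory sums to 102 although the headline count is "100 x 3 x 2 =
600"; which two columns the original authors merged is not recoverable, so
this implementation fixes the canonical 102-column list in code and exposes
6 x 102 = 612 expanded columns. Tests assert the structural invariant
(6 x |site block|), not the rounded 600.

Notable parameter choices, with rationale:

* **Half-sphere exposure** (radius 13 Å, the hsexpo convention): HSEA and
  HSEB both count neighboring C-alpha atoms within the radius, split by the
  plane through the C-alpha normal to an up-vector — the C-alpha-trace
  approximation of the side-chain direction for HSEA (falling back to the
  real/pseudo C-beta at chain breaks), the real C-beta vector for HSEB
  (ideal tetrahedral pseudo C-beta for glycine). This follows the cited
  exposure tool and keeps the exact identity HSEBU + HSEBD = CN
  (CN = all C-alpha neighbors); the alternative reading, counting C-beta
  atoms in HSEB, breaks that identity and was rejected.
* **Residue depth**: distance to the nearest solvent-exposed atom (per-atom
  SASA > 0) plus the probe radius — a cheap, deterministic approximation of
  surface-distance depth. RD averages a residue's atoms; RDa uses C-alpha.
* **Contacts**: heavy-atom contacts at 4.5 Å and anchor (C-beta, C-alpha for
  glycine) contacts at 6.5 Å, computed in the complex and in the residue's
  own monomer; normalization divides by a per-type reference mean. The
  original normalization constants are unpublished, and the packaged
  fixtures are poly-alanine backbones from which 20 distinct type means
  cannot be estimated, so the shipped reference is a neutral constant
  (6.0 for every type, user-overridable); the differential feature
  `Delncr` is unaffected by the constant.
* **Hydrogen bonds**: geometric criterion, donor-acceptor distance <= 3.5 Å
  and antecedent-donor-acceptor angle >= 90 deg, standing in for HBPLUS
  defaults; an HBPLUS `.hb2` reader bypasses the internal criterion.
* **Pair potential**: the exact published contact potential is not
  recoverable, so the shipped 20 x 20 matrix is a documented *synthetic
  stand-in* (negated outer product of rescaled Kyte-Doolittle
  hydrophobicities, favoring hydrophobic-hydrophobic contacts) and a
  configuration point — substitute any published matrix with the same
  layout.
* **Secondary structure**: DSSP letters G/H/I -> helix, B/E -> sheet,
  rest -> coil; without a DSSP file a phi/psi fallback assigns helix for
  phi in (-120, -30), psi in (-80, -5), sheet for phi < -45 with psi > 90 or
  < -150, coil otherwise (termini are coil).
* **External predictions** (PSSM, disorder, energy scores) are consumed
  through file readers with synthetic generator counterparts; missing
  externals are NA, flagged, and imputed with the training column mean only
  at model time — never silently zeroed.

### Two-step feature selection

Step one ranks all features by greedy mRMR using the **difference** form
(relevance minus mean redundancy; the source text does not choose between
the difference and quotient forms, and the difference form is the common
default). Mutual information is the plug-in histogram estimate on 3 bins
split at mean +/- sd — the classic discretization for mRMR on continuous
features. Step two is a wrapper: from the top-50, three features are chosen
by greedy forward search (best single, best pair extension, best triple
extension — 147 criterion evaluations rather than all C(50,3) triples, for
tractability); then sequential forward selection over the top-500 pool adds
the feature with the highest criterion

$$R_c = \frac{1}{n}\sum_{i=1}^n (ACC_i + SEN_i + SPE_i + AUC_i)$$

(mean over $n$ repeats of stratified 10-fold cross-validation, range [0, 4])
until no candidate strictly increases it. Ties break by mRMR rank. The
repeat count defaults to 5; the selection-time classifier defaults to a
scaled-down booster (100 trees, depth 3) because thousands of $R_c$
evaluations with the full 2000-tree model are not tractable at desk scale —
the full configuration remains the final-model default. The SFS pool is the
full mRMR top-500 minus already-selected features (whether the original
procedure excluded the top-50 from the pool is unstated; not excluding them
is the more permissive reading).

### Classifier and evaluation

The classifier is a gradient-boosted tree ensemble on the second-order
logistic objective with L2 leaf regularization and a minimum split gain —
the XGBoost formulation. No boosting library exists in the target R
environment, so the learner is implemented in compiled code inside the
package: exact greedy level-wise splits, shrinkage eta = 0.3, lambda = 1,
gamma and tree count/depth per the tuned configuration (2000 trees, depth 5,
gamma 0.005). Determinism is a design goal: no row/column subsampling, and
split-gain ties break on the lowest feature index, so identical inputs give
identical models. Evaluation reports pool out-of-fold probabilities within
each repeat of stratified 10-fold cross-validation, score them at a 0.5
probability threshold (exposed as a flag; the source is silent), and attach
trapezoidal ROC AUC and step-interpolated PR AUC. Metrics with zero
denominators are NA sentinels excluded from averages, never substituted by
zero. Every report records the engine version.

## What the synthetic fixtures emulate — and what they do not

`make_dimer()` builds two ideal poly-alanine alpha-helices (internal
coordinates phi = -57, psi = -47, standard bond geometry) packed to an exact
minimum inter-chain distance (default 4 Å), giving a genuine burial
interface, realistic SASA/exposure/contact behavior, and a valid Delaunay
substrate. `make_feature_matrix()` plants class-shifted Gaussian columns
(default effect 1.5 sigma at n = 300, emulating the published shifted
hot-spot feature distributions) among standard-normal noise, optionally with
exact duplicate columns to exercise redundancy handling. `make_tracks()`
writes syntactically valid PSSM/disorder/DSSP files for every reader.

These fixtures do **not** contain real side chains, evolutionary signal, or
the external energy terms, so a green test establishes algorithmic
correctness (geometry against brute-force oracles, selection against
independent greedy implementations, exact metric arithmetic, end-to-end
determinism) — it does not establish that published cross-validation
accuracies are reproduced. Those depend on the original external-tool
feature values on real complexes and are out of reach of a self-contained
test suite; the acceptance suite says so explicitly and tests properties
instead.

## Numerical choices and degenerate inputs

* SASA lattice is deterministic; 960 points agree with a 10,000-point
  reference within 2% on small clusters.
* Delaunay insertion flags near-cospherical configurations and retries once
  on deterministically jittered coordinates; coplanar inputs error.
* Alternate locations resolve to highest occupancy; waters and un-mappable
  hetero ligands are excluded; selenomethionine and similar residues map to
  their parent amino acid; residues with no heavy atoms are skipped with a
  warning; missing atoms are never imputed — geometry uses atoms present.
* A constant feature has zero mutual information and can never increase
  $R_c$, so selection ignores it; a fold with a single class is an error
  (stratification prevents it whenever each class has >= folds members).
* All stochastic steps (fold assignment, fixture generation, permutation
  tests) take explicit integer seeds and restore the caller's RNG state.

## Known limitations

* The boosted-tree learner implements the exact greedy core of the XGBoost
  objective but none of its approximations (no histogram splits, sparsity
  handling, or subsampling); identical hyperparameters will not bit-match
  another library's model, though they match its behavior at desk scale.
* Voronoi adjacency inherits floating-point, not exact, geometric
  predicates; the 8 Å edge cap suppresses hull artifacts but is a heuristic.
* The normalization constants, pair-potential matrix and the six disorder
  column semantics are documented configuration points, not recovered
  constants.
* mmCIF input, structure repair, hydrogen placement and weighted (Laguerre)
  tessellations are out of scope.
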