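---
title: "Interpreting fingerprint-based activity models with Shapley values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting fingerprint-based activity models with Shapley values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The attribution problem

A QSAR model maps a compound, represented as a fixed-length binary
fingerprint, to an activity score or a potency value (typically a
pK~i~). `shapfp` answers the local question: *for this compound, how much did
each fingerprint bit move this prediction, and in which direction?* The
answer it computes is the Shapley value of each feature,

$$\phi_i \;=\; \sum_{S \subseteq N \setminus \{i\}}
\frac{|S|!\,(|N|-|S|-1)!}{|N|!}\,\bigl[f(S \cup \{i\}) - f(S)\bigr],$$

the average marginal contribution of feature $i$ over all orders in which
features can be revealed to the model. It is the unique attribution
satisfying local accuracy ($\phi_0 + \sum_i \phi_i = f(x)$, with
$\phi_0 = f(\varnothing)$ the model's expected output), symmetry
(exchangeable features get equal credit), and the null effect (a feature the
model never consults gets exactly zero). Positive $\phi_i$ push the
prediction toward activity/higher potency; negative $\phi_i$ push it down —
including for bits that are *absent* from the compound, which is how the
package diagnoses underprediction of compounds missing features the model
learned to reward.

Everything hinges on the **value function** $f(S)$: what the model outputs
when only the features in $S$ are "known" to take the explained compound's
values. The package implements two, and every explainer is defined (and
tested) against them:

* **Interventional** (`interventional_value_fn`): out-of-coalition features
  are replaced by reference values. The default reference is the
  *prevalent* (per-feature majority) value of the training data; a
  `background-mean` mode instead averages predictions over substitutions
  from every background row. For binary fingerprints the prevalent
  reference is the majority bit, with ties resolved to 0 (absent) — the
  conservative choice for sparse fingerprints.
* **Cover-conditional** (`tree_value_fn`), for tree ensembles: at a split on
  an out-of-coalition feature, descend both branches and average their
  results weighted by *cover*, the number of training rows that reached each
  child. This is the path-dependent expectation the tree explainer
  attributes exactly.

The two differ in the presence of correlated features (the cover-conditional
form follows the training distribution down the tree; the interventional
form breaks dependencies). The synthetic generator's block-correlation
switch exists precisely to exercise that distinction.

## Three explainers, one contract

All three return the same `Explanation` container and satisfy local accuracy.

**`exact_shapley`** enumerates all $2^M$ coalitions, memoizing $f(S)$ by
bitmask. It is exponential and refuses universes beyond 20 features (a
`max_features` guard with advice to use the other explainers). Its role is
to be the oracle: simple enough to trust, checked in the tests against an
*independent* second oracle that averages marginal contributions over all
$|N|!$ permutations for $|N| \le 6$.

**`explain_kernel`** is the model-agnostic estimator. It fits the local
surrogate $g(z') = \phi_0 + \sum_i \phi_i z'_i$ over coalition masks $z'$ by
weighted least squares with the Shapley kernel
$\pi(z') = (M-1)/\binom{M}{|z'|}|z'|(M-|z'|)$. Design choices that matter:

* *Local accuracy as a hard constraint.* The boundary coalitions
  ($|z'| \in \{0, M\}$, infinite kernel weight) are not entered as
  high-weight rows; instead $\sum_i \phi_i = f(x) - f(\varnothing)$ is
  imposed exactly through the KKT system of the equality-constrained
  weighted least squares. Additivity then holds to machine precision at any
  sample budget.
* *Features equal to the reference leave the regression* and are attributed
  exactly 0: the value function cannot depend on them.
* *Coalition sampling.* All $2^M-2$ interior masks are enumerated whenever
  they fit the budget (then the estimator equals `exact_shapley` under the
  same value function — this is asserted to 1e−6 in the tests and is in fact
  tight to ~1e−15). Otherwise, coalition sizes are filled from the outside
  in (sizes 1 and $M-1$ first), each complementary size pair enumerated
  fully while the budget allows; the remainder of the budget is allocated
  *deterministically* across the open size pairs proportional to their
  kernel mass (largest-remainder rounding) and drawn as complementary pairs
  (mask and complement together), each pair's rows jointly carrying exactly
  that pair's kernel mass. Pairing and deterministic allocation are
  variance-reduction choices; both are recorded in the explanation metadata
  through the seed.
* *Regularization* $\Omega$ defaults to 0 (pure weighted least squares); an
  optional ridge weight exists for ill-conditioned designs but is never
  needed at full enumeration.

**`explain_tree`** computes exact Shapley values of the cover-conditional
value function in polynomial time. The implementation is the path-dependent
algorithm that walks each tree once, maintaining for the current
root-to-leaf path the fraction of feature subsets that would reach the node
with each path feature in or out of the coalition, together with
permutation weights per path length; the summary is extended at each split
and unwound at leaves to read off weighted marginal contributions. Per-tree
attributions combine linearly with ensemble weights, and the base value is
recomputed from covers ($\phi_0 =$ `base_offset` $+ \sum_t w_t \cdot$
cover-weighted leaf mean) rather than stored, so $f(\varnothing)$ is always
self-consistent. The defining contract — equality with
`exact_shapley(tree_value_fn(...))` on every fixture — is enforced in the
acceptance tests over hundreds of seeded random trees and ensembles at
1e−8 (observed agreement is ~1e−15), and cross-checked against an external
implementation of the same algorithm (xgboost's contribution predictor) at
float32 precision.

## Fingerprints with provenance

`featurize` computes ECFP-style circular fingerprints of radius 2 (diameter
4) folded to 1024 bits — both defaults chosen because they are the field's
standard operating point for activity prediction. SMILES parsing, aromaticity
perception and SMARTS matching are delegated to OpenBabel (through
ChemmineR); the environment *hashing* is the package's own: the initial atom
invariant hashes (element, heavy-atom degree, attached hydrogens, formal
charge, ring membership), and each radius iteration hashes the previous
identifier with the sorted (bond order, neighbour identifier) pairs, using
32-bit FNV-1a in exact double arithmetic so identifiers are platform
independent. Folding is plain modulo (`fold_identifier`). Environments whose
atom set duplicates an already-emitted environment are dropped (a radius-2
shell identical to a neighbouring radius-1 shell encodes the same
substructure), which is why ethanol sets between 3 and 6 bits: three
radius-0 environments plus at most three distinct larger shells.

Every set bit records its environments as SMARTS with explicit element,
full-molecule degree, and formal charge (`[#6;D2;+0]`...). Ring bonds are
written with an aromatic alternative (`-,:` and `=,:`) because the recorded
bond orders come from a kekulized structure while matching happens on the
aromatic-perceived molecule; without the alternative, benzene's own
environments would fail to re-match benzene. The tests verify that every
provenance SMARTS re-matches its source molecule across 100 fixture
compounds. Fold collisions (distinct environments on one bit) are counted
and reported, never resolved — reports list all colliding environments, and
`map_bits_to_substructures` returns an empty pattern list (with
`present = FALSE`) for bits absent from a compound, which is what the
absent-feature error analyses consume.

One boundary case is handled outside ChemmineR: its SDF reader cannot
represent bond-free molecules (a single heavy atom), so `parse_smiles` reads
the OpenBabel molfile atom lines directly for that case.

## Tree models

The trainers are deliberately minimal — enough to produce honest ensembles of
each family on binary fingerprints:

* `fit_tree`: greedy top-down induction, sum-of-squares impurity (for 0/1
  labels this is equivalent to Gini and leaves hold class-1 fractions, i.e.
  classification scores). Splits send `x[feature] <= threshold` left. Ties
  in the exhaustive search break to the lowest feature index, then lowest
  threshold — determinism is a design requirement, since explanations must
  be reproducible. A `random-threshold` mode draws one uniform threshold per
  candidate feature (extremely randomized trees). Constant responses yield
  single-leaf trees, not errors.
* `fit_ensemble`: `bagged` (bootstrap rows, `mtry` features per split),
  `extra` (full training set, randomized thresholds), `boosted` (base offset
  = response mean, least-squares fits to residuals scaled by the learning
  rate, optional row subsampling). Defaults: 300 trees (tests and examples
  use far fewer for speed), learning rate 0.1, depth 4 for boosting and 16
  otherwise, `mtry` rules `sqrt`/`log2`/`all` as configuration enumerations.
  `n_trees = 0` is legal and yields the constant predictor — the base-only
  ensemble is a meaningful degenerate case, so it is not treated as a
  configuration error.
* Cover is recorded at every node and validated
  (cover(parent) = cover(left) + cover(right)); tree SHAP refuses ensembles
  that violate it, since covers *are* its probability model.

The JSON interchange schema (0-based ids and feature indices, −1 for leaves)
round-trips field-identically, and `as_tree_ensemble_xgb` maps xgboost
boosters into it. xgboost routes `x < split` left versus this schema's
`x <= threshold`; the adapter keeps the split values, so predictions can
differ only exactly at a split point — irrelevant for continuous features,
and for binary fingerprints xgboost's splits fall strictly between 0 and 1.

## Evaluation machinery

Metrics follow their textbook definitions (MCC, balanced accuracy, MAE, MSE,
R²; AUC is computed as the Mann–Whitney rank statistic with mean ranks for
ties) and are pinned to hand-computed values at 1e−12 in the tests.
Degenerate inputs warn and return NaN (single-class labels for MCC, constant
response for R²) rather than failing a pipeline.

Method agreement (`compare_attributions`) reports Pearson correlation on
*absolute* attributions — importance magnitude, sign-blind — pooled over all
compounds, with per-compound correlations alongside since either pooling
level is defensible; Spearman is available by flag. Top-$k$ overlap is
computed on global rankings (mean |φ| across compounds, ties to the lower
feature index) for $k \in \{5, 10, 20, 30, 40, 50\}$ by default, with a
per-compound variant exposed.

Perturbation experiments flip features one at a time — by descending signed
attribution (most positive first, the contributions claimed to support the
prediction; absolute-value ordering available), or randomly from all bits
(`random_all`) or only the compound's set bits (`random_present`) — starting
from the compound (removal) or the zero vector (addition), re-predicting
after every cumulative flip. Random strategies report the mean trajectory
over seeded trials (500 by default, matching standard practice for such
controls). For a purely additive positive-weight model the SHAP-guided
removal trajectory is provably non-increasing, which the tests assert.

## Synthetic data: what it does and does not emulate

The generator produces independent Bernoulli bits (default density 0.1 — the
sparsity regime of folded 1024-bit fingerprints of drug-like molecules), a
handful of planted causal bits with additive effects (default 10 bits,
effects 0.5–1.5 pK~i~ units), a pK~i~-like response centred at 7.5 with
Gaussian noise (sd 0.3), thresholded binary labels, and sparse multi-target
panels (annotation density ~1.1%, the regime of public kinase panels). These
values put the synthetic task in the same numeric range as real potency
modelling: responses ~5–11, single-substructure effects of one-to-two
log units, models reaching R² ≈ 0.8.

What it deliberately does **not** emulate: real fingerprints are not
independent bits (substructures nest and co-occur — the block-correlation
switch gives a crude version of this); planted effects are additive while
real SAR has activity cliffs and interactions; and no chemistry constrains
which bit patterns are realizable. Passing the planted-recovery and
perturbation tests therefore demonstrates that the *attribution machinery*
finds and quantifies signal a model actually uses — it does not validate any
claim about real compounds. The fingerprint module is tested on real SMILES
precisely because the synthetic data cannot cover it.

## Numerical choices

* Shapley subset weights are computed in log-factorial space; coalition
  masks are memoized as vectors indexed by bitmask.
* The kernel regression solves the KKT system directly (`solve`); a singular
  design (too few samples for the varying features) is reported with advice
  to raise `n_samples` rather than silently regularized.
* Tolerances asserted in tests: tree-vs-oracle 1e−8 (observed ~1e−15),
  kernel-at-enumeration-vs-oracle 1e−6 (observed ~1e−15), local accuracy
  1e−6 across methods, ensemble linearity 1e−10, metric formulas 1e−12.
* All randomness flows through explicit integer seeds (`rng_seed`
  arguments, seeds recorded in `Explanation` and in every CLI artifact);
  repeated runs are byte-identical, and tree SHAP is deterministic by
  construction.

## Known limitations

* The kernel estimator's error-vs-budget curve is not guaranteed monotone at
  the very first doubling: the minimal budget ($2M$) fully enumerates the
  size-$\{1, M-1\}$ pair and is therefore deterministic (zero variance,
  small bias), while the next budget adds a few sampled middle-size rows
  that carry most of the remaining kernel mass. Under some seeds the median
  error ticks up there before descending to zero at full enumeration. The
  acceptance script reports the observed monotone fraction.
* Tree SHAP is the path-dependent (cover-conditional) variant only; the
  interventional tree variant and pairwise interaction values are out of
  scope, as are unfolded/count fingerprints and 2-D depiction of highlighted
  substructures (reports are text/JSON plus SMARTS).
* `exact_shapley` is exponential by design; its guard suggests the
  polynomial alternatives.
* Implicit hydrogen counts for exotic valences are approximated from
  standard valence rules; they only feed the initial atom invariant, so a
  miscount changes bit identities but never breaks provenance soundness
  (the emitted SMARTS do not constrain hydrogens).
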