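---
title: "Target-indication expansion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-indication expansion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Evidence platforms such as Open Targets summarise the support that a gene
(target) is linked to a disease through per-channel association scores in
[0, 1] — genetic association, somatic mutation, affected pathway, RNA
expression, animal model — plus a known-drug channel derived from clinical
trials. Predicting which target-disease pairs will acquire a known drug is a
positive-unlabeled (PU) problem: a pair with drug score 0 is not a confirmed
negative, merely not (yet) labelled. The raw evidence channels are weak
predictors of trial status on their own; what they lack is any notion of
*relatedness among targets* — co-expression in the same tissues, shared Gene
Ontology semantics, and proximity in the protein-protein interaction (PPI)
network all make two targets plausible substitutes for one another's
indications.

`otexpand` implements a collaborative-filtering answer to this. Three
families of target-target similarity are computed from orthogonal data
sources, and each similarity source is *encoded* into a new target-disease
feature: the similarity-weighted average of the known-drug scores of the
target's `k` most similar neighbors,

$$
\mathrm{enc}(j, d) \;=\;
\frac{\sum_{i=1}^{k} \mathrm{sim}(j, i)\, \mathrm{kd}(i, d)}
     {\sum_{i=1}^{k} \lvert \mathrm{sim}(j, i)\rvert}.
$$

A classifier trained on the five evidence scores plus the five encoded
scores (tissue, GO BP/MF/CC, PPI embedding) then predicts known-drug status
for held-out targets.

## The similarity sources

**Tissue specificity.** For each gene and tissue, an ordinary least-squares
linear model on `log2(x + 1)` expression contrasts the samples of that
tissue against the samples of all *other tissue groups* (same-group tissues
are excluded from the reference, since they are biologically close), with
age and sex as covariates; the gene's profile is the vector of t-statistics
across tissues, and gene similarity is the cosine of these profiles. Plain
OLS t-statistics are used rather than an empirical-Bayes moderated t: the
moderation prior adds a dependence on the whole gene set that is hard to
pin down, and at the sample sizes involved the two orderings are nearly
identical. The log2(x + 1) transform is the conventional variance
stabiliser for this kind of contrast. Samples are canonically ordered by
id before fitting so the statistic is exactly invariant to input order;
a gene with zero variance across a contrast gets statistic 0 with a
warning (its near-zero residuals are floating-point noise, not signal).

**Ontology semantics.** Wang-style graph similarity: the S-value of an
ancestor term t for an anchor A is the maximum product of edge weights
along any path from A up to t (`is_a` = 0.8, `part_of` = 0.6, the usual
defaults — exposed as an argument), term similarity is the normalised
shared-ancestor contribution, and gene similarity is the best-match average
(BMA: mean of the per-row and per-column maxima of the term-term matrix
between the two genes' annotation sets). BMA is the customary gene-level
combine; it is exposed as an argument for future alternatives. Genes with
no annotation in a namespace have *missing* similarity, which downstream
encoding treats as 0.

**Network embedding.** The interaction network is filtered to edges with
confidence strictly greater than 0.5 (the high-trust convention for STRING
scores), then embedded with node2vec: second-order biased random walks
(return parameter `p`, in-out parameter `q`, transition weight proportional
to edge confidence times the bias factor) feed a skip-gram model with
negative sampling, trained single-threaded for exact reproducibility under
a seed. Defaults follow the original node2vec settings
(`p = q = 1`, `dim = 128`, `walk_length = 80`, `num_walks = 10`,
`window = 10`, `negatives = 5`); all are configurable. Gene similarity is
again the cosine of embedding rows.

Degenerate profiles (zero-norm rows) receive similarity 0 to everything —
including themselves — rather than NaN, so top-k selection stays total.

## Encoding and leakage

`top_k_neighbors()` ranks neighbors by similarity descending, ties broken
lexicographically by id, and never includes the target itself: a training
target's own label must not leak into its feature. The denominator uses the
sum of *absolute* similarities exactly as the equation above states, so
negative cosine weights can produce signed features; they are not clipped.
The default `k` is 1000 (the published choice for a ~24k-gene universe);
for universes smaller than `k` the neighborhood is all-but-self.

Masking is the critical contract. Before encoding, the known-drug rows of
every held-out target (the test set, and the current validation fold during
cross-validation) are read as 0: a masked neighbor contributes nothing to
the numerator but its |similarity| still counts in the denominator — the
mask hides drug status, not similarity. (Removing masked neighbors from the
denominator instead is a one-line change; the two conventions agree
whenever masked known-drug scores are 0 anyway.) `leak_free_check()`
verifies the contract mechanically: it recomputes every encoded feature
from scratch on an association table whose masked rows are physically
zeroed, and demands exact (bitwise) agreement with the feature table the
pipeline trained on. Masking idempotence — mask M equals physically zeroed
rows — holds exactly and is tested.

Feature assembly takes the outer union of pairs seen in any source, fills
missing entries with 0 (missingness means "no evidence found"), drops rows
whose ten features are all zero (they carry no information and their count
is logged), and sets the binary label to 1 exactly when the pair's
known-drug score exceeds 0.

## Splitting and models

Splits are *grouped by target*: 70% of targets (floor rounding) to train,
the rest to test, and the five cross-validation folds deal targets — not
pairs — into near-equal groups (sizes differ by at most one target; 693
training targets give folds of 139/139/139/138/138). Per-fold row counts
therefore differ, because targets carry different numbers of pairs. The
split is uniform over targets, unstratified: stratifying by per-target
positive counts is not obviously better and adds a knob.

Three PU classifiers are provided with fixed, tuned hyperparameters as
defaults: XGBoost (`min_child_weight = 10`, `colsample_bytree = 0.6`,
`subsample = 0.6`, `max_depth = 8`, `reg_lambda = 10`, `eta = 0.1`,
`nrounds = 100` — the boosting-round count is this package's choice),
random forest (`n_estimators = 500`, `max_depth = 8`, `max_samples = 0.6`,
`max_features = 0.6`), and logistic regression with mandatory bagging over
100 bootstrap resamples whose prediction is the *mean* member probability.
Class imbalance is countered by weighting the positive class by
`n_neg / n_pos`. Training defaults to one thread so results are
reproducible bit-for-bit under a seed; parallel training is available for
exploratory runs.

## Evaluation machinery

AUPR is computed as average precision — the step-wise sum over distinct
score thresholds with no interpolation — because it is the standard
estimator and is directly checkable against an exhaustive threshold-scan
oracle. AUROC uses the rank statistic with midranks for ties. Threshold
semantics everywhere: predict positive when score >= threshold, candidates
are the observed scores, and F-beta ties resolve to the smallest threshold
(the recall-friendly end). Agreement statistics (sensitivity, specificity,
precision, F1, Cohen's kappa, MCC) flag rather than propagate empty
denominators: an undefined precision or an MCC with a zero marginal is
reported as 0 with a flag. Group-wise AUPR (per disease, per target, per
therapeutic area) reports the positive fraction for every group and marks
single-class groups not-evaluable, since accuracy in this design tracks the
fraction of already-known indications. Permutation importance shuffles one
feature column at a time within the evaluation set and reports the mean ±
sd decrease of AUPR over repeats. The hypergeometric overlap test is the
one-sided upper tail computed in log space, so extreme significance levels
remain representable; the caller supplies all four counts explicitly
because the choice of universe is a modelling decision, not a statistical
one.

## The synthetic world

Real inputs (expression compendia, ontology releases, interaction
databases, association snapshots) are too large and too version-dependent
to pin tests to, so the generator plants exactly the statistical structure
the method assumes: `n_modules` functional modules partition targets,
diseases and tissues. Module genes are over-expressed in their module's
tissue by a multiplicative factor `1 + signal_strength` (so
`signal_strength = 0` is the exact null world) on top of log-normal
baselines with small age and sex effects; each namespace ontology has a
per-module subtree with genes annotated to its leaves; the interaction
graph is a planted partition (within-module edge probability 0.3 with
confidence U(0.5, 1), between 0.02 with U(0.2, 0.8)); true indications are
same-module pairs, of which a `label_rate` fraction receives a known-drug
score U(0.3, 1) — the PU structure — and the five evidence scores are a
weak scaled indicator (`evidence_scale = 0.1`) plus truncated Gaussian
noise (`evidence_noise = 0.25`). Truncation rather than renormalisation
preserves the mass at zero that sparse association tables show. The weak
evidence calibration mirrors the observed regime in real data, where the
evidence channels alone barely beat the positive prevalence while encoded
features lift performance several-fold.

One further realism choice matters: the five sources must be
*complementary, imperfect views*, not copies. Each target's expression view
and each namespace's annotation view independently misassigns the module
with probability `view_noise = 0.25`, while the confidence-filtered network
remains the cleanest view. Without this, all five encoded features are
collinear and single-feature permutation importance is degenerate (any one
of five identical features can be shuffled harmlessly); with it, the
network-embedding encoding emerges as the dominant predictor, matching what
the method finds on real data.

What the generator does **not** emulate: real tissue hierarchies, the true
GO topology and annotation depth, degree heterogeneity of real
interactomes, disease-disease ontological structure, or correlated evidence
channels. Passing recovery tests on these worlds shows the pipeline's
plumbing and the encoder's statistics are correct under the method's own
assumptions — not that the method will attain any particular performance on
a given data release.

## Study sizing for the shipped benchmark

`run_indication_benchmark()` runs the complete study on one world:
300 targets, 60 diseases, 6 modules, `label_rate` 0.3, a 70/30 target
split, masked encoding, and XGBoost on all ten features versus the five
evidence features alone. At this scale the encoder neighborhood defaults to
`k = 50` — the scaled analogue of top-1000-of-24k, of the order of one
functional module — and the embedding uses `dim = 64`, `walk_length = 40`,
`num_walks = 10`, `window = 5`, which keeps one replicate at a few seconds
without changing any qualitative outcome. Across seeded replicates the
ten-feature model beats the evidence-only model on held-out AUPR, and
permutation importance ranks at least one encoded feature — usually the
network embedding — above every evidence feature; a planted pure-noise
column shows a mean decrease within twice its own standard deviation.

## Numerical conventions and edge cases

- Exact symmetry of similarity matrices is enforced by averaging with the
  transpose after cosine computation (floating-point dot products are not
  exactly symmetric); values are clamped to [-1, 1].
- Zero-norm profiles: similarity 0 everywhere, diagonal included, flagged
  in the `zero_norm` attribute.
- Zero encoder denominator returns 0, so the encoding is total.
- Ties: neighbor ranking and indication ranking break ties
  lexicographically by id; F-beta threshold ties take the smallest
  threshold; AUROC uses midranks.
- Degenerate labels (single class) are an error for training and for
  curve construction, never silently absorbed.
- All randomness flows from explicit seeds: world generation, splits,
  walks, SGNS initialisation and negative sampling, bootstrap resamples,
  and permutation shuffles are all reproducible bit-for-bit on one thread.

## Known limitations

- The Wang S-value pass enumerates each anchor's ancestor sub-DAG in R;
  it is comfortable for ontologies of thousands of terms but has not been
  engineered for the full ~45k-term GO graph in one call.
- The SGNS trainer is single-threaded by design (determinism first); for
  very large interactomes a multi-worker embedding would be preferable and
  would relax exact reproducibility.
- Bagged logistic regression uses unpenalised `glm`; strongly separable
  bootstrap resamples produce the usual fitted-probability warnings, which
  are suppressed and harmless for the averaged score.
- The package deliberately implements no disease-hierarchy features, no
  matrix-factorisation collaborative filtering, no probability calibration
  and no model stacking.
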