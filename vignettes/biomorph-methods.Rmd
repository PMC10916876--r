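---
title: "Building and using annotated morphological feature spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and using annotated morphological feature spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Image-based morphological profiling (Cell Painting) summarises each
perturbation as a vector of hundreds of engineered features — texture,
intensity, shape, correlation statistics over stained compartments. Models
trained on these features predict biological activity well, but a list of
important texture features is hard to read biologically. This package
builds a *term registry* that links subsets of morphological features to
interpretable biology, using a second, targeted assay (cell-health
readouts such as percent dead cells or γH2AX-positive fractions) measured
on the same gene-knockout perturbations. A term carries five levels of
annotation: assay type (level 1), measurement type (level 2), the specific
cell-health phenotype (level 3, a readout), the perturbed cell process
(level 4, a perturbation-group label), and the morphological feature
subset itself (level 5).

# The registry construction procedure

`build_registry()` runs, per readout:

* **Step A** — all-relevant feature selection (`all_relevant_select()`,
  regression task) against the readout. All-relevant selection keeps
  *every* feature carrying signal, including correlated duplicates; this
  matters because terms are meant to be descriptive groupings, not minimal
  predictive sets.
* **Step B** — a baseline ordinary-least-squares gate on a random 80/20
  split: the readout survives only if held-out R² strictly exceeds 0.25.
* **Step C** — per non-control perturbation group, all-relevant selection
  (classification task) of the step-A features that separate that group
  from the pooled negative controls.
* **Step D** — a baseline random-forest gate on a stratified 80/20 split:
  the (readout, group) pair becomes a term only if held-out Matthews
  correlation strictly exceeds 0.50.

Both gate thresholds are strict inequalities; a value exactly at the
threshold does not pass. Negative controls and group members are pooled
across cell lines — the consensus profiles already average within
perturbation, and stratifying by cell line would leave gate test sets too
small to be meaningful. Readouts whose step-A subset is empty skip step B:
an empty feature set cannot clear a regression gate and is reported with a
`-Inf` sentinel.

# The shadow-feature selection procedure

No all-relevant selection implementation is available as an R dependency,
so the package authors it in full. Each iteration appends one
row-permuted "shadow" copy of every live feature, fits a depth-limited
random forest (depth 5; tree count `10 * ceiling(sqrt(design columns))`
clipped to [64, 512]), and scores a *hit* for every real feature whose
impurity importance exceeds the maximum shadow importance. A two-sided
binomial test on accumulated hits (chance 0.5) confirms or rejects
features; rejected features leave the design; undecided features at the
iteration cap (default 100) are *tentative* and treated as not selected
downstream — the conservative reading.

Two calibration choices deserve emphasis, because the naive version of
this algorithm is measurably liberal under the null:

* The per-iteration decision level is `alpha / (p * iter)`: Bonferroni
  over *all* `p` input features (not just the currently undecided ones —
  the undecided count shrinks exactly when the survivors are the features
  selected for accidental association, which would loosen the level at
  the worst moment) and over the iteration index, because the same
  accumulating hit counts are re-tested every iteration.
* The shadow pool never shrinks below 20 columns (donor features are
  cycled). The hit bar is the *maximum* over shadows; with only one or
  two features left undecided, a pool of one or two permutations is
  trivially beatable by any feature with a little fixed-sample
  correlation. A floored pool keeps the bar where it was when the run
  started.

With these choices, selection on an independent response (n = 200, p = 30)
returns an empty confirmed set in the majority of seeds, while planted
signals (and their duplicated copies) are recovered reliably.

# Scoring profiles against terms

`score_term()` aggregates a *standardized* profile over a term's level-5
features with the chi-squared set statistic used in gene-set analysis:
`statistic = sum(z_j^2)` over the k subset features, and
`p = P(Chi2_k >= statistic)`. Under the reference population the
standardized values are approximately standard normal, so a small p flags
a profile whose morphology is collectively unusual on the term's
features. The statistic's exact form is this package's declared
interpretation of a set-level chi-squared test; it is pluggable
(`statistic_fn`) so alternatives (e.g. Fisher combination of per-feature
two-sided tests) can be swapped without touching the transform.

`biomorph_transform()` standardizes against the dataset itself by default
(per-dataset scaling, matching how new screens are processed in
practice), or against supplied reference statistics. Raw p-values are
never infinite; the matrix filter instead drops columns that are
degenerate — constant p-values (zero variance, e.g. a term whose features
are constant in the new dataset) or non-finite after column
standardization. An optional `-log10(p)` output mode clamps p at 1e-300.
On real registries this filter typically removes a handful of terms whose
features are uninformative in the new dataset.

# Activity models

`nested_cv_evaluate()` implements five-times-repeated stratified fourfold
nested cross-validation: 20 outer test sets. Hyperparameters come from a
successive-halving random search (inner stratified fivefold, optimising
AUC — the protocol's unstated objective; AUC is the headline metric, so
it is also the tuning target). The declared grid covers max depth
{5, 10, 20, unlimited}, max features {sqrt, log2, 0.3} and min samples
per leaf {1, 3, 5}; the number of trees acts as the halving *resource*
(rungs 25/75/225, one third of candidates kept per rung, winner refit at
500 trees), the convention of the search algorithm this protocol is
modelled on — a budget dimension is not sampled. Eight candidates are
drawn per search. The classification threshold is never 0.5: it is the
Youden-J maximiser (`youden_threshold()`) over inner cross-validation
predictions, candidate cuts being the distinct observed scores, ties
resolved towards the smallest threshold (maximal sensitivity).
`train_heldout()` applies the same tuning and thresholding on a
stratified 75% split and reports on the untouched 25%.

AUC is computed by the exact Mann–Whitney rank formula with midrank tie
handling; balanced accuracy and MCC are recomputed from stored confusion
counts, so reports are auditable. MCC's denominator is evaluated as one
square root of the exact integer product: four multiplied square roots
can push a rational value such as 1/2 off by an ulp, which matters
against a strict gate.

# Interpretation

Model-level importances (impurity) or per-compound attributions are
thresholded by the two-standard-deviation rule: important ⇔ value
strictly above mean + 2·SD, population convention; both the convention
and strictness are arguments, since reasonable implementations differ.
Per-compound attributions use path-based (Saabas) attribution over the
fitted forest: walking each tree's prediction path, the change in node
expectation at every split is credited to the split feature, node
expectations being computed by routing the training set through the
tree. Attributions are exactly additive (they sum to the forest
probability minus a constant baseline) and a feature the forest never
splits on receives exactly zero — the two contracts downstream analysis
relies on. Only held-out *true positives* are attributed: for a
false-positive prediction the attribution explains a mistake. Per
compound, only positive attributions (pushing towards activity) enter
the two-SD rule.

Enrichment arithmetic: a term's enrichment is the percentage of its
level-5 features present among the important features. Level-3 and
level-4 labels are scored by the arithmetic mean over the terms carrying
them. The hierarchical ladder propagates a ≥ 10 % rule upward: a level-3
label's score is the percentage of its terms with enrichment ≥ 10 %, a
level-2 label's the percentage of its level-3 children with ladder score
≥ 10 %, and likewise level 1 over level 2 — the ladder consumes its own
lower-level output, which is the only self-consistent reading of a
"progressive" level-by-level rule. `top_k()` breaks score ties
alphabetically so reports are deterministic.

# The synthetic-data generator

`sim_scenario()` defines the statistical structure every stage is tested
against: independent standard-normal baseline features; readouts that are
noisy linear combinations (weights ~ U(0.5, 1.5), drawn once per
scenario) of disjoint planted 8-feature subsets; perturbation groups
mean-shifted by δ on the subset of their paired readout; negative
controls from baseline; and a compound screen whose actives are shifted
by β on the first planted subset, so activity coincides with exactly one
synthetic term's features.

Default conditions: 200 features; 5 readouts (4 planted, 1 pure noise);
δ = 1.5 SD; readout noise SD 0.5; 15 groups × 14 profiles + 30 negative
controls = 240 profiles; screen of 400 compounds at 35 % prevalence with
β = 1.0 SD. The planted effect sizes are the study conditions of the
package's validation suite; the free sizes (group count/size, control
count, readout count, screen size) were chosen once as what a screen of
this kind plausibly looks like at desk scale, sized so the full
end-to-end suite runs in minutes on one CPU. The null scenario sets δ = 0
and makes every readout pure noise.

What the generator deliberately does *not* emulate: feature covariance
(real morphological features are heavily correlated in blocks), plate
effects, dose-response structure, non-linear readout links, and
class-dependent feature variance. Passing tests therefore demonstrate
that the machinery recovers planted structure under its own assumptions —
not that real Cell Painting data satisfies those assumptions.

All randomness flows from one master seed through named child streams
(subsets, weights, features, readout noise, labels, screen features), so
adding a stage never perturbs earlier draws, and every split, search and
forest seed in the pipeline derives deterministically from a master seed
and the loop indices.

# Numerical and degenerate-input choices

* Standardization uses population variance (divisor n); zero-variance
  columns map to zero with a warning.
* The dose-window consensus retains points with |dose − mean| ≤ 1 SD
  (sample SD); a singleton is always retained, and two points always both
  fall within one SD of their mean.
* Missing values are an error by default (`na_action = "drop"` removes
  affected rows) — the upstream data sources are silent on the point, so
  the loud option is the default.
* Compound identifiers are opaque strings; chemical-structure
  canonicalization (InChI standardization) is left to an upstream hook
  since no exact tool version could be pinned.
* p ∈ (0, 1] always; `p(statistic = 0) = 1` exactly.

# Known limitations

* Tentative features at the iteration cap are discarded; a longer
  `max_iter` recovers some of them at the cost of runtime.
* Gate test sets are small when groups are small (an 80/20 split of
  30 controls + 14 members tests on 9 profiles); MCC is coarse there, and
  occasional spurious terms survive both gates. The registry recovery
  tests quantify this (precision ≈ 0.8 at the default conditions).
* Saabas attributions, unlike Shapley values, can distribute credit
  unevenly among perfectly correlated features; they share the additivity
  and null-player contracts but not symmetry.
* The halving search optimises AUC; if balanced accuracy at the chosen
  threshold is the quantity of interest, the tuning objective and the
  threshold rule interact and may be jointly suboptimal.
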