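---
title: "Quantifying neuronal morphologies and benchmarking their cell-type discriminability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuronal morphologies and benchmarking their cell-type discriminability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphrep)
```

## The problem

A neuron's anatomy is the classical defining feature of its cell type, and
full reconstructions of axonal and dendritic arbors are now abundant in SWC
format: a rooted tree of 3D nodes, each with a compartment type (soma, axon,
dendrite), a position in micrometers, a radius and a parent. Many numeric
*representations* of such trees exist -- from coarse neurite density maps to
detailed branching statistics and topological persistence diagrams -- but
they answer the practical question "which representation should I use to
tell cell types apart?" very differently. `morphrep` implements four
families of representations together with a standardized, nested
cross-validated classification benchmark, so that representations can be
compared on equal footing, on real data or on synthetic populations with
planted, known differences.

Throughout, coordinates are micrometers; `z` is oriented along cortical or
retinal depth, `x` along the slice width and `y` along the slice depth. No
unit conversion is applied on input.

## Preprocessing chain

`preprocess_morphology()` applies, in order:

1. **Soma consolidation** (`consolidate_soma`). Reconstructions may contain
   several somatic nodes, or (for datasets without explicit soma labels) the
   soma may be identifiable only by thickness; a radius threshold (1 um for
   retinal bipolar cells) relabels thick nodes as somatic first. All somatic
   nodes are then contracted into a single root placed at the centroid of
   the somatic cluster. For the small, essentially convex clusters that
   occur in practice we use the mean of the distinct somatic positions,
   which coincides with the vertex centroid of their convex hull; the tree
   is re-rooted at the new soma so arbitrary label configurations stay
   connected.
2. **Branch-type harmonization** (`harmonize_branch_types`). Type labels can
   flicker between consecutive nodes near the soma. Each branch is
   relabelled by the majority vote over its sub-segment types. An exact
   axon/dendrite tie is resolved to axon -- a deterministic rule biased
   toward the compartment that dominates interneuron reconstructions.
3. **Resampling** (`resample`). Every sub-segment of length d is subdivided
   into `ceiling(d / spacing)` equal pieces by linear interpolation
   (default spacing 1 um). This keeps all original nodes, conserves the
   total path length exactly, and makes the operation a fixed point:
   resampling a resampled tree changes nothing. The alternative -- placing
   points at exactly equal arc length along each segment and discarding the
   original vertices -- shortens curved neurites (chords replace arcs) and
   is not idempotent, which would break downstream length-conservation
   checks; we therefore subdivide edges instead. On reconstruction data,
   where consecutive nodes are typically further apart than the target
   spacing, the two schemes coincide.
4. **Depth-axis smoothing** (`smooth_depth_axis`). The coordinate along the
   microscope's viewing direction (`y`) can contain sudden jumps in
   slice-based reconstructions. After 1-um resampling (so a window in
   micrometers is a window in samples), a 3rd-order Savitzky-Golay filter
   with a 21-sample window is applied to `y` along every unbranched run.
   Runs shorter than the window are left unfiltered (shrinking the window
   risks order > window failures), and run endpoints -- soma, branch
   points, tips -- are kept fixed so that a node shared by several runs is
   never assigned conflicting values.
5. **Centering** (`center_morphology`). Cortical cells are soma-centered in
   all axes. Retinal bipolar cells are soma-centered in x and y only, with
   z shifted by a supplied offset so z = 0 is the inner plexiform layer
   onset -- bipolar types are defined largely by their stratification depth
   within the IPL, which soma-centering in z would destroy.

Smoothing and resampling are intended for slice-based (cortical)
reconstructions; the bipolar mode skips them.

### Geometric conventions

* **Branch order** is centrifugal: the soma has order 0, and the order
  increments each time a branch point is passed on the way to a tip. A
  branch point itself carries the order of the branch it terminates, and a
  multi-stem soma is not counted as a branch point (stems have order 0).
* **Path angle** is the angle between two consecutive sub-segment
  *direction* vectors, so a straight continuation scores 0 degrees. The
  opposite convention (180 for straight) exists in the literature; all
  angles here are degrees in [0, 180].
* **Root angle** of a segment is the angle between its chord
  (end - start) and the radial direction (end - soma); radial outgrowth
  scores 0.
* **Euler root angles** decompose the minimal rotation aligning the
  soma-to-segment-end direction with the segment chord into extrinsic
  rotations about the fixed x, y, z axes (R = Rz Ry Rx), reported as
  absolute values. The rotation order and extrinsic/intrinsic choice are
  genuine convention choices; any fixed choice yields an equally valid
  (and equally comparable-within-a-dataset) feature.
* **Multifurcations** (out-degree > 2) are allowed everywhere.

## Density maps

Neurites are sampled with equidistant points every 25 nm
(`sample_points`), point clouds are min-max normalized to [0, 1] per axis
with *dataset-level* ranges (`fit_ranges`; serializable to JSON so fixed
ranges can be shared between runs), projected onto one axis or a
coordinate plane, and binned into 100 bins per axis spanning [-0.1, 1.1]
(`density_map`). The 0.1 margin gives the subsequent smoothing room at the
edges. The histogram is convolved with a unit-sum Gaussian kernel of 11
bins per axis and sigma = 2 bins ('same' convolution, zero padding); the
kernel is normalized to unit sum after truncation so that interior mass is
conserved exactly. Coordinates that fall outside the span -- possible only
with supplied fixed ranges narrower than the data -- are clipped into the
boundary bins rather than dropped (silently losing mass would bias the
maps), and the clipped count is recorded. Values mathematically on a bin
edge belong to the right-hand bin; a small floating-point guard enforces
this deterministically. Maps are flattened row-major into 10,000 (2D) or
100 (1D) features.

## Morphometric statistics and distributions

`compute_statistics()` returns 24 single-valued summaries (counts of branch
points, tips and stems; x/y/z extents; mean neurite radius; total path
length; surface area and volume from per-sub-segment truncated cones,
`pi (r + R) sqrt((R - r)^2 + h^2)` and `(pi/3) h (r^2 + rR + R^2)`; maximal
neurite length; maximal branch order; maximal Euclidean segment length;
median intermediate/terminal segment lengths; median and 99.5th-percentile
path angle and log-tortuosity; minimal/mean/maximal branch angle; maximal
node degree; tree asymmetry). The soma is excluded from thickness, surface
and volume (sub-segments touching the soma use the neurite-side radius at
both ends, so the inflated soma radius never enters). "Maxima" of path
angle and log-tortuosity are 99.5th percentiles (linear interpolation
between order statistics) to damp reconstruction artifacts. Statistics
undefined on a degenerate topology (e.g. branch angles of an unbranched
cell) are recorded as 0 with a warning so downstream feature matrices stay
finite.

**Tree asymmetry** is the weighted *sum* over branch points of the
proportional sum of absolute deviations,
`PSAD(p) = m / (2 (m-1)(n-m)) * sum_i |r_i - n/m|`, with weight 1 exactly
when the subtree at p has more than 3 leaves. The classical index is a
weighted mean; we implement the sum deliberately and note that the two
orderings of cells differ only by a size-dependent factor. A branch point
whose children are all tips (n = m) is perfectly balanced and scores 0.

The 17 one-dimensional distributions use fixed binnings (20 bins over
[0, 180] for angle histograms; 30 bins for radii; 36 Sholl circles; decile
vectors for the 3-star motif counts) with dataset-level upper edges for
lengths, radii and branch orders, computed once per dataset by
`dataset_edges()`. Histograms store raw counts -- densities would hide the
mass, and the PCA step of the benchmark handles scale. For the averaged
3-star-motif and maximal-distance vectors, sub-graphs are induced by the
i*10% of nodes closest in path length to 100 random center nodes; a node
of degree d >= 3 contributes d - 2 three-star motifs, and the "maximal
distance" is measured from the center node (the sub-graph diameter would
cost a quadratic scan per decile for little extra information). The six
two-dimensional distributions are 20 x 20 joint histograms whose axes
reuse the 1D binning, with the branch-order axis spanning [0, K] (dataset
maximal order) and flattened row-major to 400 features; their marginals
reproduce the 1D histograms by construction (shared binning code).

**Sholl profiles** count crossings of the projected skeleton with 36
concentric circles, radii equally spaced from the projected soma to the
most distant node: a sub-segment whose endpoint radial distances straddle a
circle contributes one crossing.

## Persistence

`compute_diagram()` runs the elder rule on the tree under one of four
filter functions (radial distance, path length, branch order,
z-projection; all are 0 at the soma). Each tip opens a branch at its filter
value ("birth"); sweeping toward the soma, at every branch point all
branches except the one with the maximal birth die at the branch point's
filter value, and the overall survivor dies at the soma (death 0). Ties in
birth are resolved toward the tip with the smaller node id -- deterministic
and stable under reconstruction order. Multifurcations kill all
non-surviving children simultaneously. The diagram always has exactly one
(birth, death) pair per tip, and under the path-length filter the summed
lifetimes equal the total neurite length exactly (each micrometre of
neurite is alive in exactly one branch) -- both properties are tested
against an independently implemented oracle.

Persistence images render diagrams comparable by Euclidean distance:
a 2D Gaussian kernel density estimate of the (birth, death) cloud
(Scott's rule on the full sample covariance) evaluated on a 100 x 100 grid
spanning [0, max_birth] x [0, max_death], with the maxima fixed per
dataset; and a 1D estimate of the branch lifetimes sampled at 100 points
on [0, max_birth]. Degenerate diagrams (fewer than 3 points, singular
covariance, or constant lifetimes) fall back to an isotropic kernel with
bandwidth 1% of max_birth; negative lifetimes, possible under the
radial-distance and z-projection filters, are clipped to 0 before the 1D
estimate (with a message). KDEs are fitted per cell: images are per-neuron
features.

## The classification benchmark

`fit_binary()` (and `fit_multiclass()`) implement one standardized
pipeline:

* **Outer loop**: 10-times-repeated stratified 5-fold cross-validation,
  all fold assignments derived deterministically from seed 17. Classes
  need at least 5 cells (one per fold); smaller classes should be excluded
  upstream.
* **Per-fold preprocessing**, fitted strictly on the training rows: PCA
  keeping the smallest number of components reaching 90% of the training
  variance, all components divided by the SD of the training PC1 scores
  (this puts different representations on a common scale and is what makes
  concatenating them meaningful). The 24 morphometric statistics are
  z-scored instead when analysed alone, but are PCA-reduced like everything
  else inside combined representations, where unscaled concatenation would
  overweight them.
* **Model**: logistic (or multinomial) regression with an elastic-net
  penalty, mixing parameter alpha = 0.5, over a 100-value lambda path
  log-spaced from the data-derived maximum down to 1e-3 of it, without
  internal re-standardization. Lambda is chosen by the one-standard-error
  rule on 3-fold inner cross-validated deviance (deviance is twice the
  log-loss, so the 1-SE selection is identical); inner folds are stratified
  and seeded from the outer seed. A single-component fold is padded with a
  zero column to satisfy the solver; the padding can only receive a zero
  coefficient.
* **Metrics**: test-fold log-loss (probabilities clipped at 1e-15),
  accuracy, macro-F1 (unweighted mean of per-class F1), and the Matthews
  correlation coefficient (multiclass generalization for K > 2; defined as
  0 on degenerate single-class folds, with a warning). Log-loss is the
  primary measure: it is a proper scoring rule, insensitive to class
  imbalance, with chance level ln K for K balanced classes.

`fit_alternative()` runs 3-nearest-neighbour and decision-tree classifiers
through the identical outer loop (log-loss is not meaningful there).
`shuffle_null()` repeats the full pipeline on label permutations to obtain
the empirical chance band; its mean sits at ln 2 for balanced pairs.

## Comparing representations

Per-pair log-losses are not independent across pairs -- two pairs sharing a
type share that type's cells -- so `jackknife_se()` estimates the standard
error of a mean log-loss difference delta(A, B) by leaving out one *type*
at a time (removing every pair that involves it) and applying the standard
jackknife formula to the leave-one-type-out means. `z_test()` reports the
two-sided normal p-value; p-values are deliberately unadjusted.
`rank_features()` orders representations by mean pairwise log-loss within
each modality and selects the union of the per-modality top five plus the
best morphometric distribution, so every representation category stays
represented.

`embed_features()` provides exact (non-approximate) t-SNE with seeded
random initialization for unsupervised inspection of combined, PCA-reduced
and PC1-scaled representations. The implementation uses the standard
early-exaggeration (factor 12 for 100 iterations) and adaptive-gain
gradient descent for 1000 iterations; perplexity (default 50) is capped at
(n - 1) / 3 for small samples. Per-type 95% coverage ellipses use the
minimum covariance determinant estimator with the chi-squared(2) quantile
radius, so a single outlying cell leaves an ellipse essentially unchanged.

## Truncation robustness

`truncate_morphology()` simulates partial tracings: of the B branches
(segments), the floor(fraction * B) with the highest branch order are
removed together with their subtrees. Ties at the removal boundary break
by the greater path distance of the branch's start from the soma, then by
the smaller start node id -- distal material goes first, the ordering is
deterministic, and removal sets are nested across fractions (a descendant
branch always has a strictly higher order than its ancestor, so subtree
removal is automatic). The fraction is capped so at least one stem
survives. Because high orders concentrate in the axon, increasing
truncation strips axonal arbors before dendritic ones, mimicking what
weak staining does to real reconstructions. `truncation_experiment()`
re-featurizes the truncated cells and repeats every pairwise
classification at each truncation level.

## The synthetic generator

`generate_population()` grows labelled SWC populations with a recursive
bifurcating random walk: segments of noisy length built from 2-um steps
whose direction is the previous direction plus Gaussian jitter, branching
into two daughters until a per-compartment depth is exhausted. The axon
first descends from the soma to a per-cell stratification depth drawn from
the type's z-offset distribution and then arborizes near that depth (a
weak plane attraction and a lateral-extent pull keep the arbor local). The
default type produces cells whose axon carries about 86% of the total
neurite length, matching the axon-dominated regime of locally projecting
interneurons; stratification depth, lateral extent, branch depth and stem
counts are the knobs that differ between synthetic types. All randomness
derives from a single seed (one derived seed per cell), so a population is
byte-identical across runs.

The generator is a statistical stand-in, not a biophysical growth model:
it produces valid, controllable trees with planted differences, but it
does not emulate reconstruction noise, tissue shrinkage, slice flattening,
layer structure, or realistic branch-diameter tapering. Tests that pass on
synthetic populations therefore certify the pipeline's correctness and its
power to recover planted differences, not performance on any particular
real dataset.

`toy_fixtures()` supplies the hand-traceable trees (Y-tree, caterpillar,
balanced tree, straight neurite, trifurcation, semicircle) whose feature
values are known in closed form and anchor the exact tests.

## Problem sizes and numerical choices

The test suite and the acceptance script run on deliberately small
problems chosen to exercise every code path: populations of 8-12 cells
per type, two cross-validation repeats instead of ten (the fold structure,
preprocessing and selection rules are identical), 200 small trees for the
property suites, and 10 generator seeds for the planted-signal ranking
check. The planted-stratification condition offsets two otherwise
identical types by five within-type standard deviations (50 um at 10 um
jitter); the ranking check uses a mirror-symmetric +-50 um offset so that
unsigned morphometric summaries are matched between the types and the
density family alone carries the signal. Key numeric guards: probability
clipping at 1e-15; bin-edge assignment to the right-hand bin with a 1e-9
relative guard; unit-sum kernel renormalization; zero-variance columns
z-scored with unit divisor; PSAD defined as 0 when all children are tips.

## Known limitations

* Neurolucida (.ASC) input is out of scope; convert to SWC externally.
* No shrinkage correction is applied to slice-based reconstructions.
* Wasserstein/bottleneck diagram distances and persistence landscapes are
  not implemented; diagrams are compared only through their images.
* The jackknife compares exactly two representations at a time; no
  multiple-testing correction is applied across comparisons.
* Normalization ranges, distribution bin maxima and persistence rectangles
  are dataset-level constants: features from different datasets are only
  comparable if ranges are shared explicitly via the config files.
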