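# morphrep

Quantitative representations of neuronal morphologies and a standardized
benchmark for how well they discriminate morphological cell types.

Anatomists and neuroinformaticians routinely face the question: given SWC
reconstructions of neurons with expert type labels, *which* numeric
description of a morphology — a coarse neurite density map, a vector of
branching statistics, a binned morphometric distribution, or a topological
persistence image — best captures the differences between types?
`morphrep` implements all four families of representations behind one
interface, the full preprocessing chain that makes them comparable, and a
nested cross-validated classification benchmark that scores each
representation on equal footing. A seeded generator of synthetic labelled
populations makes the entire pipeline testable end to end without any
data download.

## What is implemented

**Preprocessing** (`preprocess_morphology`): soma consolidation (with a
radius threshold for datasets lacking soma labels), majority-vote
branch-type harmonization, 1 µm resampling, Savitzky–Golay smoothing of
the slice-depth axis (window 21 µm, order 3), and soma- or IPL-centering.

**Representations** (`featurize_population`):

- *Density maps* — 25 nm skeleton sampling, dataset-level min–max
  normalization, 100 bins per axis on [−0.1, 1.1], Gaussian smoothing
  (11 bins, σ = 2); projections x/y/z and xy/xz/yz.
- *Morphometric statistics* — 24 single-valued summaries (tips, branch
  points, extents, total length, truncated-cone surface
  π(r+R)√((R−r)²+h²) and volume (π/3)h(r²+rR+R²), branch orders, segment
  lengths, path/branch angles, log-tortuosity percentiles, tree asymmetry
  as the weighted sum of per-branch-point PSAD scores, …).
- *Morphometric distributions* — 17 one-dimensional (angle histograms,
  Sholl intersection profiles with 36 circles, 3-star motif decile
  vectors, …) and six 20×20 two-dimensional histograms.
- *Persistence* — elder-rule persistence diagrams under four filter
  functions (radial distance, path length, branch order, z-projection),
  rendered as 1D/2D Gaussian persistence images on fixed dataset grids.

**Benchmark** (`fit_binary`, `fit_multiclass`, `fit_alternative`):
elastic-net (α = 0.5) logistic regression with per-fold PCA (90% variance,
PC1-scaled) or z-scoring, λ chosen by the one-standard-error rule on
3-fold inner CV, evaluated by 10×-repeated stratified 5-fold CV (seed 17);
metrics: log-loss (chance level ln K), accuracy, macro-F1, MCC; kNN and
decision-tree alternatives; shuffled-label chance bands (`shuffle_null`).

**Comparison** (`compare_representations`, `rank_features`,
`embed_features`): mean log-loss difference δ(A,B) over all type pairs
with a jackknife-across-types standard error
SE = [ (n−1)/n Σ_τ (δ₋τ − δ̄)² ]^½ and a two-sided z-test; per-modality
feature ranking; exact t-SNE embedding with robust (minimum covariance
determinant) 95% coverage ellipses.

**Robustness** (`truncate_morphology`, `truncation_experiment`): simulated
partial tracings by removing the highest-branch-order fraction of
branches, with nested removal sets across fractions.

**Synthetic data** (`generate_population`, `toy_fixtures`): seeded,
byte-reproducible populations of axon-dominated model interneurons with
controllable stratification depth, extent and branching, plus
hand-traceable toy trees with closed-form feature values.

## Worked example

Two synthetic types that differ only in axonal stratification depth
(50 µm apart at 10 µm within-type jitter — five local SDs):

```r
library(morphrep)

# the Y-tree toy fixture: stem 1 µm, daughters 2 µm and 1 µm
print(compute_diagram(toy_fixtures()$y_tree, "path_length"))
#> Persistence diagram (path_length, full): 2 branches
#>   birth death tip_id
#> 1     2     1      5
#> 2     3     0      4

spec <- population_spec(types = list(
  A = type_spec(n = 12, axon = list(z_offset = 0,  z_offset_sd = 10)),
  B = type_spec(n = 12, axon = list(z_offset = 50, z_offset_sd = 10))),
  seed = 1)
pop <- generate_population(spec)
print(pop$morphologies[[1]])
#> Neuron morphology: 2959 nodes, 80 tips, 75 branch points
#>   total neurite length 5916.0 um; types: soma=1, axon=2519, dendrite=439
#>   label: A

fm  <- featurize_population(pop$morphologies, "density_z")
res <- fit_binary(fm$x, factor(pop$manifest$label),
                  cv_config(outer_repeats = 2))
print(res)
#> Pairwise benchmark A vs B (logreg)
#> log_loss 0.0643 | accuracy 1.0000 | macro_f1 1.0000 | mcc 1.0000
#> (10 outer folds: 5 folds x 2 repeats)
```

The persistence diagram is the hand-traceable elder-rule result: the
younger daughter (birth 2) dies at the branch point (filter value 1), the
survivor (birth 3) dies at the soma. The benchmark log-loss of 0.064 is
far below the ln 2 ≈ 0.693 chance level, i.e. the Z density map recovers
the planted stratification difference almost perfectly; running the same
pair with identical type specs returns log-loss ≈ 0.693.

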