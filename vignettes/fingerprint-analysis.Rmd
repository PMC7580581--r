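---
title: "Colony and family signal in chemical fingerprints: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colony and family signal in chemical fingerprints: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(scentR)
```

## The problem

Skin-swab samples analysed by gas chromatography-mass spectrometry
(GC-MS) yield *chemical fingerprints*: one abundance per compound, with
compounds identified by their aligned retention times. In colonially
breeding animals such as fur seals, two questions recur: do animals
from different breeding colonies differ chemically, and are mothers
chemically more similar to their own pups than to other animals? Both
are questions about *group structure in a multivariate composition*,
asked of data that are sparse (a typical sample carries only ~40 of the
full compound library), non-negative, and heavily right-skewed.

scentR implements the full statistical pipeline for this setting:
preprocessing, Bray-Curtis dissimilarity, permutational MANOVA
(PERMANOVA) with a nested family-within-colony term, a multivariate
dispersion-homogeneity check, pairwise comparisons with Bonferroni
correction, NMDS visualisation, and a bootstrap standardisation of
R^2 effect sizes that makes effect magnitudes comparable between
studies with different sample sizes.

## Preprocessing

Three steps, in a fixed order:

1. **Rare-compound exclusion** (`filter_rare_compounds()`, default
   `min_samples = 2`): compounds seen in a single sample carry no
   group information and mostly reflect alignment noise.
2. **Relative abundance** (`to_relative_abundance()`): each sample row
   is scaled to sum to 100. Composition, not total signal, is the
   quantity of interest; totals vary with swab loading and injection.
3. **log(x+1)** (`log_transform()`): natural-log `ln(x+1)` cellwise,
   compressing dynamic range so dominant peaks do not swamp the
   distance. Zeros map to zeros, preserving presence/absence.

Filtering precedes normalisation so that excluded compounds never
influence the percent denominators. Two conventions deserve a note
because the downstream distances are sensitive to them, and tables in
the field rarely state them:

* **Percent (0-100), not proportions (0-1).** `log(x+1)` is
  scale-sensitive; the percent scale is the convention of the
  alignment toolchain this package sits behind. Both the unit scale
  and the log base are fixed choices here, recorded in the matrix's
  `unit_state` so a double transformation is an error rather than a
  silent corruption.
* **Natural log.** The transform is monotone for any base, so distance
  *ranks* (and hence NMDS) are base-invariant, but Bray-Curtis
  magnitudes and the PERMANOVA SS are not.

## Bray-Curtis and its geometry

`bray_curtis()` computes `d_ij = sum|x_i - x_j| / sum(x_i + x_j)`:
0 for identical fingerprints, 1 for disjoint compound sets. Bray-Curtis
is not Euclidean-embeddable in general
(`is_euclidean_embeddable()` reports the smallest eigenvalue of the
Gower-centred matrix); on sparse fingerprints the spectrum reliably
contains negative eigenvalues. Everything downstream is written to be
correct in that geometry: PERMANOVA works on the Gower-centred matrix
directly, and the dispersion test subtracts squared distances along
"imaginary" principal-coordinate axes, clamping (and counting) the
rare negative squared distances that result.

## PERMANOVA with nested terms

`permanova()` uses sequential (Type I) sums of squares on the
Gower-centred matrix `G = J(-D^2/2)J`: for cumulative design matrices
`X_0 (intercept) c X_1 c ... c X_k` with projectors `H_j`,

```
SS_j   = tr(H_j G) - tr(H_{j-1} G)
SS_res = tr((I - H_k) G),  SS_tot = tr(G)
F_j    = (SS_j / df_j) / (SS_res / df_res)
```

so term R^2 values and the residual sum exactly to 1 — the accounting
needed when R^2 is the cross-study currency. A nested term
(`"family_id %in% colony"`) is encoded as the parent:child interaction
placed after the parent's own term, giving it
`(families - colonies)` degrees of freedom. For the standard
mother-pup design the term order is age, colony, family-in-colony.

Significance comes from re-computing every term's pseudo-F under
random reorderings of the samples (rows and columns of `G` permuted
together; one shared permutation stream for all terms), with the
add-one convention `p = (#{F* >= F} + 1)/(B + 1)`; ties count as
exceeding, so p is never 0 and never anti-conservative at the
boundary. Free permutation of all samples is the default scheme (the
convention of the ecology toolchain for this model); a `strata`
argument restricts shuffling to within-stratum when a restricted null
is wanted. When `n! <= B` on a small sample the test switches to
exhaustive enumeration of all `n!` orderings and reports the exact
proportion (identity included) — the random and exhaustive routes
converge, which the test suite checks directly.

Two independent routes guard the implementation: `permanova_oneway()`
computes the one-factor decomposition straight from the group-sum
identity `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2` without any
projections, and the test suite also checks the nested fit against
vegan's `adonis2` to 1e-9.

## Dispersion homogeneity

A significant PERMANOVA can reflect location or spread.
`dispersion_test()` embeds the samples by PCoA, measures each sample's
distance to its group centre with the signed imaginary-axis
correction, and applies a one-way ANOVA to those distances
(`(k-1, n-k)` df, classical F p-value by default; a label-permutation
p and a spatial-median centre are options, since published analyses do
not always state the variant used). Group centres default to
centroids; the spatial median is found by quasi-Newton descent on a
smoothed objective starting from the centroid.

## Pairwise comparisons and count checks

`pairwise_permanova()` runs a one-way PERMANOVA on every unordered
pair of group levels — the grouping may be composite, e.g.
colony x age class — and multiplies p-values by the number of tests
emitted (Bonferroni, capped at 1). Levels with fewer than two samples
are skipped and reported, and the correction count is always the
number of tests actually in the table. `compare_counts()` covers the
univariate sanity check that groups do not simply differ in how many
compounds they carry (equal-variance t-test or one-way ANOVA).

## NMDS

`nmds()` is a from-scratch Kruskal stress-1 implementation:
configuration distances are fit by least-squares monotone (isotonic)
regression on the dissimilarity ranks (pool-adjacent-violators via
`isoreg`), and the configuration is updated by Guttman transforms.
Numerical choices:

* **Primary tie handling**: tied dissimilarities impose no order
  constraint among themselves (implemented by pre-sorting tie blocks
  by configuration distance). Ties are common in sparse Bray-Curtis
  data, where many pairs share disjoint-support distance 1.
* **Monotone stress trace**: a Guttman step that would increase
  stress-1 is step-halved toward the previous configuration; if no
  improvement is possible the start terminates. The per-iteration
  trace is therefore non-increasing by construction, and is stored on
  the result for inspection.
* **Starts**: the first start is the PCoA configuration, the remaining
  `restarts - 1` are random (seeded); the lowest-stress solution wins.
  20 restarts by default; stress is reported, no automatic dimension
  selection is attempted, and `k = 2` matches how fingerprint
  ordinations are shown.
* **Normalisation**: the returned configuration is centred with
  root-mean-square inter-point distance 1 (stress is invariant to
  this), so coordinates are comparable across runs.

NMDS is visualisation-only: no downstream statistic consumes its
coordinates.

## Bootstrap effect-size standardisation

p-values cannot be compared between studies of different size; R^2
distributions can, if both studies are resampled to a common design.
`bootstrap_effect_sizes()` draws `pairs_per_colony` (default 15)
families with replacement within each of the two colonies, carries
all members of a drawn family, recomputes Bray-Curtis on the
resampled rows, refits the PERMANOVA and records the focal terms'
R^2; with the defaults each replicate is a 60-individual dataset.
Design choices that matter:

* **The resampling unit is the family, not the individual.** The
  family term only exists when mothers and pups enter together;
  resampling individuals independently would destroy the very
  structure being measured, and 15 pairs x 2 colonies reproduces the
  60-individual replicate arithmetic.
* **Fresh family labels per copy.** A family drawn twice enters twice
  under distinct labels, keeping the family term's df at
  `families - colonies` in every replicate instead of collapsing
  duplicate draws.
* **Twin trios are carried whole**, so replicate sample counts may
  slightly exceed 60; that mirrors how twins occur in real designs.
* **Preprocessing happens once, on the full dataset.** Per-sample
  normalisation is resampling-invariant, and refiltering compounds
  per replicate would mix compound-set churn into what should be pure
  sampling variance.
* **No per-replicate permutation p-values**: only R^2 is consumed, so
  the permutation machinery is switched off inside replicates.

Distributions are summarised (`summarize_bootstrap()`) by median,
quartiles, 1.5 x IQR whiskers, 2.5/97.5% quantiles and the
**maximum-density estimate**: the mode of a Gaussian kernel density
with Silverman bandwidth on a 512-point grid spanning
`[min - 3h, max + 3h]`, ties broken toward the smaller value. The mode
is preferred over the mean because bootstrap R^2 distributions are
skewed near their df-driven floor.

One accounting subtlety is worth spelling out. In a proper sequential
decomposition a family term with many degrees of freedom has a large
*null* expectation: under no family signal at all, a term with `df_f`
of the `n - 1` total degrees of freedom absorbs roughly `df_f/(n-1)`
of the total SS. With 28 family df in a 60-sample replicate that floor
is ~0.48 of the post-colony remainder, so family R^2 values from this
package are interpreted *relative to that floor* (the pseudo-F, which
is df-corrected, is the better signal measure); colony R^2, a 1-df
term, has a floor of `1/(n-1)` and is directly interpretable. Reports
that quote small family R^2 values alongside large family F statistics
are using some other accounting, and their R^2 cannot be compared
with a sequential one.

## The synthetic generator

`generate_dataset()` draws from a hierarchical log-normal model: per
compound a baseline `b_m ~ N(base_log_mean, base_log_sd)`; additive
colony, family and individual effects on the log scale with standard
deviations `sigma_colony`, `sigma_family`, `sigma_individual`; latent
`L_im` exponentiated to an abundance when a logistic detection
indicator fires, `P(detect) = plogis(detection_slope * (L - tau))`.
Coupling detection to the latent abundance makes presence/absence and
abundance carry *correlated* group signal, as in real sparse
fingerprints. The threshold `tau` is solved numerically once per
dataset — conditional on the drawn compound baselines, integrating the
individual effects out by quadrature — so the expected number of
detected compounds per sample equals `mean_detected` (default 42, the
empirical mean for fur-seal skin swabs) while per-sample counts stay
random around it.

Defaults are calibrated study conditions, not free dials: with
`pool_size = 200`, `sigma_colony = 0.65`, `sigma_family = 0.6`,
`sigma_individual = 1.0`, the replication-design dataset yields a
colony R^2 of ~0.10 — the magnitude of real colony signal — and a mean
of ~42 detected compounds per sample. `sigma_colony` was fixed by a
one-off grid search against the R^2 target; the other two were set a
priori (family effects somewhat weaker than residual individual
variation). `study_preset()` provides the three sampling designs used
in this research programme: `"replication"` (2 colonies x 25
mother-pup families, one twin trio, 101 samples), `"original"` (41
pairs, 82 samples) and `"six_colony"` (pups only, 25+25+15+15+15+15 =
110 samples).

What the generator does *not* emulate: retention-time drift and
misalignment, co-eluting peaks, batch effects, instrument sensitivity
differences, compound-compound correlation beyond the shared group
effects, and the heavy overdispersion of real per-sample compound
counts (the real-data spread of ~±15 compounds s.d. exceeds the
model's Bernoulli-driven ~±6; the mean, which the statistics are
sensitive to, is matched). Tests passing on synthetic data therefore
validate the *statistical machinery*, not instrument-level robustness.

## Problem sizes and reproducibility

The test suite runs at desk scale by choice: type-I error is checked
with 500 null datasets of 40 samples at 199 permutations each;
exhaustive-vs-random permutation agreement on 7-sample instances
(5,040 orderings); bootstrap self-consistency with 500 replicates;
dispersion power with 100 replicates of 10 + 10 points. Production
analyses should use the defaults (99,999 permutations, 5,000
bootstrap replicates); permutation p-values are stable far below
that, which is why the pipeline exposes the count.

Every stochastic entry point takes a `seed` and is bitwise
reproducible from it; `run_study_pipeline()` derives per-stage seeds
from one master seed by fixed offsets, so adding a stage never
perturbs earlier streams, and writes a JSON manifest (seed, config,
version, input checksums) sufficient to reproduce a run exactly.

## Known limitations

* Only Bray-Curtis is provided; Jaccard, Aitchison and phylogenetic
  dissimilarities are out of scope.
* Sequential (Type I) SS only: term order matters and is the user's
  statement of the hypothesis hierarchy. Type II/III partitions and
  distance-based RDA with covariates are not implemented.
* The dispersion test's permutation mode permutes raw labels, not
  model residuals; with strongly unbalanced groups the classical F
  p-value is the better-behaved default.
* The bootstrap assumes exactly two colonies with intact families; it
  is the cross-study standardisation of that specific design, not a
  generic resampler.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(preset = "replication", permutations = 9999,
                  bootstrap_replicates = 500, outdir = "run1", seed = 1)
res <- run_study_pipeline(cfg)
res$permanova
summarize_bootstrap(res$bootstrap)
```
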