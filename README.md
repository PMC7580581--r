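# scentR

Multivariate analysis of GC-MS chemical fingerprints with colony and
family structure.

## What this is for

Skin-swab samples run through gas chromatography-mass spectrometry
give each animal a *chemical fingerprint*: a vector of peak abundances
indexed by aligned retention times. For colonially breeding animals
(the motivating system is fur-seal breeding beaches), the recurring
questions are whether animals from different colonies differ
chemically, and whether mothers and their pups are chemically more
similar than unrelated animals. scentR is for field ecologists and
chemical ecologists who have an **aligned peak table** (samples x
compounds) plus per-sample metadata (colony, age class, family) and
want the complete, reproducible statistical pipeline:

1. preprocessing — singleton-compound exclusion, relative abundance
   (percent), log(x+1);
2. Bray-Curtis dissimilarities, `d_ij = Σ|x_i − x_j| / Σ(x_i + x_j)`;
3. sequential (Type I) **PERMANOVA** with a nested
   family-within-colony term: on the Gower-centred matrix
   `G = J(−D²/2)J`, term sums of squares are
   `SS_j = tr(H_j G) − tr(H_{j−1} G)` for nested projectors `H_j`,
   with pseudo-`F_j = (SS_j/df_j)/(SS_res/df_res)`,
   `R²_j = SS_j/SS_tot`, and permutation p-values
   `p = (#{F* ≥ F} + 1)/(B + 1)`;
4. multivariate **dispersion homogeneity** (distances to group
   centroids in PCoA space with the imaginary-axis correction, one-way
   F on the distances) — separating location from spread effects;
5. **pairwise PERMANOVAs** with Bonferroni correction;
6. 2-D **NMDS** (Kruskal stress-1, primary tie handling) for
   visualisation;
7. **bootstrap effect-size standardisation**: resample 15
   mother-offspring families per colony with replacement, refit the
   PERMANOVA per replicate, and summarise the R² distribution by its
   kernel-density mode — making effect sizes comparable across studies
   with different sample sizes.

A hierarchical synthetic-data generator (colony / family / individual
variance components on log-abundance, logistic detection coupled to
latent abundance, calibrated to ~42 detected compounds per sample)
makes the whole pipeline testable without field data and doubles as a
power-analysis tool.

## Worked example

```r
library(scentR)

ds  <- generate_dataset(study_preset("replication", seed = 1))  # 101 samples
pre <- preprocess_pipeline(ds)                 # filter -> percent -> log(x+1)
D   <- bray_curtis(pre$abundance)

permanova(D, pre$metadata,
          c("age_class", "colony", "family_id %in% colony"),
          permutations = 9999, seed = 2)
#> PERMANOVA (sequential SS; random permutations: 9,999)
#>                   term  df      SS       F       R2      p
#>              age_class   1  0.1245  0.6166 0.004781 0.9762
#>                 colony   1  2.9770 14.7400 0.114300 0.0001
#>  family_id %in% colony  48 12.8500  1.3250 0.493300 0.0001
#>               Residual  50 10.1000      NA 0.387600     NA
#>                  Total 100 26.0500      NA 1.000000     NA
```

Colony membership explains 11.4% of the total Bray-Curtis variance
(F = 14.7 on 1 and 50 df) and is significant at the permutation floor
(p = 1e-4 with 9,999 permutations); the family term's F = 1.33 shows
mother-pup similarity beyond colony. A dispersion check confirms the
colony effect is about location, not spread:

```r
dispersion_test(D, pre$metadata$colony)
#> Homogeneity of multivariate dispersions (centroid, classical_F)
#> group mean distances to centroid :
#>    FWB    SSB
#> 0.4718 0.4814
#> F = 1.991 on (1, 99) df, p = 0.1614
```

Bootstrap standardisation (500 replicates of 15 families per colony,
i.e. 60 animals each):

```r
bt <- bootstrap_effect_sizes(pre, pairs_per_colony = 15,
                             replicates = 500, seed = 3)
summarize_bootstrap(bt)[, c("term", "median", "q2.5", "q97.5",
                            "max_density", "full_R2")]
#>                    term    median      q2.5     q97.5 max_density   full_R2
#> 1                colony 0.1311745 0.1135010 0.1523489   0.1297783 0.1143126
#> 2 family_id %in% colony 0.4688858 0.4408857 0.4947532   0.4665235 0.4932596
```

The maximum-density colony R² (0.130) is the sample-size-standardised
effect size: the number to compare across studies. The family term's
R² must be read against its degrees-of-freedom floor (28 family df in
a 59-df replicate absorb ~0.48 of the variance even under weak family
signal) — see the methods vignette
(`vignettes/fingerprint-analysis.Rmd`) for the accounting.

The same analysis runs end-to-end from files or a preset with
`run_study_pipeline(run_config(...))`, which writes every result
table, an NMDS coordinate file, and a JSON manifest that reproduces
the run exactly.

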