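# rehodyn

Static and dynamic **regional homogeneity (ReHo)** analysis of
resting-state fMRI, with a ground-truth synthetic cohort generator so
the whole chain can be validated end to end.

Resting-state studies of sensory loss (for example sudden sensorineural
hearing loss) ask two questions about local brain connectivity: *where*
is the synchronization of a voxel with its immediate neighbourhood
abnormal, and *how stable* is that synchronization over the scan. The
first is measured by ReHo — Kendall's coefficient of concordance

```
W = 12 * sum_t (R_t - Rbar)^2 / ( K^2 (n^3 - n) - K * sum_j T_j )
```

over the K ≤ 27 time series of a voxel's 3×3×3 neighbourhood (R_t =
rank sum at time t, T_j the tie correction of series j). The second is
measured by dynamic ReHo: W is recomputed in sliding windows (50 TRs,
step 5; 37 windows for a 230-volume scan) and summarized per voxel by
the coefficient of variation `CV = sd_pop(x) / mean(x)` of the windowed
values. Maps are Fisher-transformed (static) or z-standardized
(dynamic) and smoothed with a 6 mm FWHM Gaussian, then compared between
groups with a voxelwise GLM (age, sex, mean framewise displacement,
education, gray-matter volume as covariates) and cluster-level
correction — Freedman–Lane permutation on the maximum cluster extent
(reference method) or a Gaussian-random-field approximation. Downstream
helpers cover ROI extraction, Pearson ROI–clinical correlation, logistic
"predictive probability" ROC/AUC, and a fixed-hyperparameter classifier
comparison (SVM, decision tree, random forest, KNN, logistic) under
stratified cross-validation.

The package is aimed at methodologists who want a tested, scriptable
reimplementation of this pipeline whose every stage can be checked
against synthetic data with known ground truth.

## Worked example

Simulate a 20 + 20 cohort on a 24×24×16 grid (3 mm voxels, 240 volumes
at TR 2 s) with a lowered-sync region, a raised-sync region and a
time-modulated region in patients, then run the full analysis:

```r
library(rehodyn)

cfg <- cohort_config(seed = 7)        # desk-scale defaults
coh <- generate_cohort(cfg)           # BOLD + motion + clinical, with truth
an  <- analyze_cohort(coh, n_perm = 500, seed = 5)

summary(an$static_glm)
#> <reho_glm> permutation inference, voxel p < 0.001, cluster alpha 0.01
#>   2 candidate cluster(s), 2 significant
#>  cluster_id sign extent_voxels peak_x_mni peak_y_mni peak_z_mni    peak_t
#>           1    1           181       13.5       13.5       -1.5  7.468020
#>           2   -1           114      -16.5      -16.5       -1.5 -6.183131
#>    cluster_p significant
#>  0.007984032        TRUE
#>  0.007984032        TRUE
```

The two significant static clusters sit on the injected raised-sync
(positive t, peak at +13.5 mm) and lowered-sync (negative t) regions;
their overlap with the ground-truth masks is

```r
lab <- attr(an$static_glm$clusters, "labels")
dice_coefficient(an$static_glm$sig_mask & (lab < 0),
                 region_mask(cfg, "sync_down"))
#> [1] 0.9539749
```

and the dynamic contrast recovers the sync-modulated region the same
way (Dice 0.70 on this seed). The kernel itself can be inspected
directly:

```r
kendalls_w(cbind(c(1, 2, 3), c(1, 3, 2)))   # two series, one swap
#> [1] 0.75
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/rehodyn_cli.R` (subcommands `simulate`, `preprocess`,
`reho`, `dreho`, `group`, `classify`).

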