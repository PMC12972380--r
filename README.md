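# metmodnet

Weighted correlation network analysis of untargeted metabolomics cohorts
with dual-timepoint consensus modules.

`metmodnet` implements an end-to-end statistical pipeline for untargeted
serum metabolomics ion counts from multi-group cohorts measured at two
timepoints (baseline and immediately post exercise):

1. **QC / preprocessing** — sample-missingness screening,
   reference-aliquot batch-median normalization, a 25% coefficient-of-
   variation filter on pooled reference-serum wells, a 30% missingness
   filter, log2 transformation, overlap-rescaled k-nearest-neighbour
   imputation (k = 10), and ±3·IQR paired outlier removal with
   re-imputation (`run_qc()`).
2. **Network modules** — unsigned weighted adjacency `|cor|^6`,
   topological overlap, average-linkage clustering with a dynamic branch
   cut (minimum module size 30), eigenmetabolite merging and kME
   (`detect_modules()`).
3. **Consensus refinement** — baseline and post-exercise modules are
   matched by overlap and intersected; a metabolite must belong to the
   same module at both timepoints to stay in module-level analyses
   (`match_modules()`, `consensus_refine()`).
4. **Association** — module-trait linear models on eigenmetabolite and
   mean-z-score representatives (optionally group-adjusted), and
   module-group one-way ANOVA with Tukey–Kramer post-hoc contrasts
   (`module_trait_lm()`, `module_group_anova()`).
5. **Exercise response** — per-subject log2 fold changes with a two-tier
   paired-t rule (Bonferroni-exact tier 1, all-groups tier 2) and a
   group-differential response ANOVA (`paired_tests()`,
   `response_anova()`).
6. **Design sensitivity** — one-way ANOVA power and minimum detectable
   Cohen's f via the noncentral F distribution (`anova_power()`,
   `min_detectable_f()`).

A latent-factor synthetic cohort generator with full ground truth
(`simulate_cohort()`) makes every stage's recovery quantifiable; the
methods vignette (`vignettes/metmodnet-methods.Rmd`) documents the model,
the parameter choices and their rationale.

## Worked example

Simulate the default study design — 35 subjects in four athlete groups
(7 controls, 9 bodybuilders, 11 endurance, 8 sprint), 1020 metabolites
with five planted modules, two batches with reference-serum aliquots —
and run the full pipeline:

```r
library(metmodnet)

cohort <- simulate_cohort(sim_config(seed = 42))
cohort$matrix
#> ion_matrix: 1020 metabolites x 80 samples (ion-count scale), 4.9% missing

qc <- run_qc(cohort$matrix, cohort$samples)
qc$report
#> QC report
#>   samples flagged for missingness: 0 (threshold 0.093)
#>   metabolites: 1020 input, 68 excluded by CV, 84 by missingness, 868 retained
#>   IQR outliers: 550 points flagged, 1084 cells blanked

run <- run_pipeline(pipeline_config(seed = 42))
print(run$consensus)
#> module assignment (consensus)
#>   turquoise    158
#>   blue         110
#>   brown        82
#>   yellow       49
#>   green        31
#>   grey         233 (unassigned)
```

The planted group shifts (endurance on module 1, bodybuilding on module
2, sprint on module 3) surface in the module-group ANOVA, and the five
module-driving traits attach to their modules:

```r
print(run$module_group)
#> module ~ group one-way ANOVA (Bonferroni threshold 0.00833 )
#>      module      F        p p_bonferroni
#> 1 turquoise 17.121 9.67e-07     5.80e-06
#> 2      blue  8.527 2.82e-04     1.69e-03
#> 3     brown 12.029 2.17e-05     1.30e-04
#> 4    yellow  0.495 6.88e-01     1.00e+00
#> 5     green  1.230 3.16e-01     1.00e+00
#> 6      grey  1.406 2.60e-01     1.00e+00

subset(run$module_trait, measure == "eigenmetabolite" & p_fdr < 0.05,
       select = c(module, trait, beta, p_fdr))
#>       module              trait      beta        p_fdr
#> 1  turquoise             vo2max 0.6405762 8.974540e-04
#> 24      blue                bmi 0.7606559 5.017966e-06
#> 47     brown      grip_strength 0.7103888 5.767193e-05
#> 70    yellow  reactive_strength 0.9190963 8.849717e-13
#> 93    green  endurance_training 0.7978010 6.292163e-07

print(run$response)
#> exercise response: 868 metabolites | tier1 51 | tier2 43 | differential 62 | differential-and-changed 51

module_recovery_ari(run$consensus, run$truth)
#> [1] 1
```

Design sensitivity of the cohort (Bonferroni-corrected over six module
families, 80% power):

```r
min_detectable_f(k = 4, n = 7, alpha = 0.05 / 6, power = 0.80,
                 n_i = c(7, 9, 11, 8))
#> [1] 0.7434678
```

Only standardized group effects of roughly f ≥ 0.74 are reliably
detectable at these group sizes — smaller module-group differences
should be treated as exploratory.

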