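# ironmap

Automated differentiation of atypical parkinsonian syndromes from brain
iron patterns on susceptibility weighted MRI (SWI).

Progressive supranuclear palsy (PSP) and the variants of multiple system
atrophy (MSA-P, MSA-C) mimic Parkinson's disease (PD) clinically, but each
deposits iron in the deep gray nuclei with its own topography: MSA-P a
posterolateral putaminal hypointensity with lateral-to-medial gradient,
PSP an anteromedial pallidal hypointensity, PD at most a nonspecific
slit along the lateral putaminal margin. `ironmap` is for neuroimaging
researchers who want to quantify and classify those patterns
automatically, end to end:

1. **Preprocess** — white-matter intensity normalization of T1w to a mean
   of 110, affine SWI-to-T1w registration, resampling (`normalize_t1w_wm`,
   `register_affine`, `resample`).
2. **Hybrid contrast** — fuse T1w and SWI as `HC = w1·T1w + w2·SWI`, with
   `(w1, w2)` the least-squares solution matching the putamen and globus
   pallidus mean intensities of a reference template
   (`solve_weights`, `fuse`):
   `(w1*, w2*) = argmin ‖ [ [I_put^T1w, I_put^SWI], [I_pall^T1w, I_pall^SWI] ] w − [I_put^ref, I_pall^ref] ‖²`.
3. **Segment** — propagate template deep-gray-matter labels to the
   subject through the HC image (affine engine in-repo; external
   displacement fields accepted) with nearest-neighbor label transport
   (`propagate_labels`).
4. **Extract** — 178 radiomic features from SWI inside the putamen:
   19 first-order, 16 + 10 shape, and the GLCM/GLRLM/GLSZM/NGTDM/GLDM
   texture families, with GLCM and NGTDM at neighbor distances 1, 4 and 7
   voxels (`extract_all`). Signal-scale features are tagged and excluded
   from selection (`texture_safe_features`).
5. **Select** — Fisher-score ranking on training data only, top 10
   (`fisher_score`, `select_top_k`).
6. **Classify** — ten standard classifiers under repeated stratified 7:3
   splits with 3-fold CV tuning; AUC, balanced accuracy, sensitivity,
   specificity, accuracy (`run_task`).

A seeded phantom generator (`generate_cohort`) renders paired T1w/SWI
volumes with class-specific iron topographies and exact truth masks, so
the whole pipeline is testable without patient data.

## Worked example

```r
library(ironmap)

template <- phantom_template()
cohort   <- generate_cohort(c("MSA-P" = 10, "PD" = 14), master_seed = 1)
subject  <- cohort[[1]]

res <- segment_subject(subject$t1w, subject$swi, subject$truth,
                       template$volume, template$labels)
res$weights
#> <iron_hcweights> w1 = 1.63964, w2 = -0.417161, residual = 0

mask_quality_report(res$mask, subject$truth)[1, c("structure", "dice")]
#>   structure      dice
#> 1   putamen 0.9731766

fv <- extract_all(subject$swi, res$mask)
length(fv); fv["glcm_Autocorrelation7"]
#> [1] 178
#> glcm_Autocorrelation7
#>              3.108648
```

The fused weights reproduce the template's putamen/pallidus means exactly
(residual 0); Dice 0.97 against truth says the affine propagation found
the nucleus; `glcm_Autocorrelation7` is one of the distance-7
co-occurrence features that this kind of study finds most discriminative
between MSA-P and PD. Feeding the extracted cohort table to `run_task`
returns per-classifier AUC/bAcc/Sen/Spe/Acc averaged over repeated
splits.

A thin CLI wraps the same functions (`exec/ironmap`):
`ironmap simulate | preprocess | fuse | segment | extract | select |
classify | run`.

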