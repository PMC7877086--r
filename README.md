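# ecvtask

Free-breathing, ECG-less myocardial T1 and extracellular volume fraction
(ECV) mapping for small-animal cardiac MRI, by low-rank tensor image
reconstruction.

## The problem

ECV quantification needs co-registered native and post-contrast myocardial
T1 maps, blood T1 values, and the hematocrit (HCT):

    ECV = (1 - HCT) * dR1_myo / dR1_blood * 100%,   dR1 = 1/T1_post - 1/T1_pre

At rodent heart rates (~300 bpm) and respiration rates (~60 /min), ECG
triggering and respiratory gating are unreliable or wasteful.  This
package implements a self-gated alternative: a continuous
inversion-recovery FLASH acquisition interleaving k-space-center
"training" lines with randomly phase-encoded "imaging" lines, and a
five-dimensional image model

    A_(1) = U_x C_(1) (U_c (x) U_r (x) U_T1)^T

— a low-rank tensor over space x cardiac phase x respiratory phase x
inversion time.  The temporal factors come from Bloch-simulated dictionary
subspaces, self-gated k-means binning, tensor completion, and HOSVD; the
spatial basis from wavelet-regularized least squares on the imaging lines.
Native and post-contrast scans are reconstructed jointly, so the pixel-wise
fit constrains both curves to share `m0`, flip angle, and inversion
efficiency — 5 free parameters instead of 8 — and the maps are co-registered
by construction.

Since no raw data are deposited with the source study, the package ships a
first-class digital rat-heart phantom (beating, breathing, with blood
inflow and realistic 9.4 T tissue parameters) and an acquisition simulator
that reproduces the sampling scheme; every stage is validated against the
phantom's ground truth.

## Worked example

```r
library(ecvtask)

# full pipeline on the digital phantom (matrix 64 fast preset, ~7 min)
res <- run_pipeline(run_config("fast-test"), seed = 1)
res$ecv
res$summary[c("septal_ecv", "septal_ecv_truth",
              "median_rel_err_t1_pre", "median_rel_err_t1_post")]
```

which prints (seed 1):

```
ECV result: blood dR1 1.761 1/s, HCT 0.42
  septal ECV 21.6% (pixel SD 2.8%)
$septal_ecv
[1] 21.61949
$septal_ecv_truth
[1] 19.84562
$median_rel_err_t1_pre
[1] 0.02057276
$median_rel_err_t1_post
[1] 0.04184755
```

i.e. the recovered septal ECV is within 2 percentage points of the
phantom truth (19.85%), the fitted blood T1 pair is 2255/454 ms against a
true 2200/450 ms, and the myocardial T1 maps have 2-4% median error.
Step by step, the same pipeline is:

```r
sq   <- seq_params()                      # TR 7 ms, flip 5 deg, 85 IR blocks
ds   <- acquire(phantom_config(), sq, seed = 1)     # both scans' k-space
dict <- build_dictionary(dictionary_grid_spec(n_t1 = 21, n_alpha = 5,
                                              n_b = 5), sq)
bb   <- compute_block_t1_basis(dict, rank = 12)
bins <- bin_motion(ds, bb)                # 10 cardiac x 5 respiratory bins
tt   <- form_training_tensor(ds, bins)
comp <- complete_training_tensor(tt, compute_t1_basis(dict))
fi   <- extract_factors(comp, compute_t1_basis(dict))
fi   <- solve_spatial_basis(ds, bins, fi)
fr   <- reconstruct_image(fi, 1, 1, seq_len(832))   # end-diastole, end-exp
maps <- fit_t1_maps(fr, sq, dict, compute_t1_basis(dict))
blood <- fit_blood_t1(matrix(fr, ncol = 832), select_blood_pixels(maps$m0),
                      maps$m0, sq, dict)
ecv  <- compute_ecv(maps, blood, hct = 0.42,
                    septal_mask = ds$ground_truth$phantom$masks$septal)
```

A command-line front end covers the same workflow
(`inst/exec/ecvtask`): `simulate`, `bin`, `recon`, `fit`, `report`, and
`e2e`; raw data travel as HDF5, maps as NIfTI-1, statistics as JSON.

```sh
Rscript inst/exec/ecvtask e2e --preset fast-test --seed 7 -o summary.json
```

## Layout

* `R/sequence_model.R` — IR-FLASH Bloch signal model, dictionary, T1 bases
* `R/phantom.R` — digital rat-heart phantom + k-space acquisition simulator
* `R/binning.R` — self-gated respiratory/cardiac binning (modified k-means)
* `R/tensor.R`, `R/wavelet.R` — tensor completion, HOSVD, spatial solver
* `R/mapping.R` — joint 5-parameter fitting, blood model, ECV
* `R/stats.R` — Welch/Pearson/Bland-Altman/ICC/CoV reporting utilities
* `R/io.R`, `R/cli.R`, `R/pipeline.R` — HDF5/NIfTI/YAML/JSON, CLI, e2e
* `vignettes/methods.Rmd` — models, assumptions, parameter choices, limits
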