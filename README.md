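# gliohazard

Multimodal discrete-time recurrence-risk modelling for pediatric low-grade
glioma (pLGG), in R.

## The problem

After surgery for pLGG, recurrence risk is heterogeneous and hard to call
from clinical factors alone: gross total resection is protective, younger
age is adverse, but much of the variation is unexplained. This package
implements a pipeline that taps the *encoder of a 3D tumor-segmentation
U-Net* as a fixed image-feature extractor for preoperative T2-weighted MRI,
and fuses those deep image features with clinical covariates (age at
diagnosis, extent of resection) in a discrete-time survival network to
predict individualized event-free survival (EFS) curves.

The survival core is the **logistic-hazard model**: follow-up is cut into
bins `0 = e_0 < e_1 < ... < e_J`; the network emits one logit per bin;
the per-bin hazard is `h_j = sigmoid(z_j)`; and

    S(e_j) = prod_{m <= j} (1 - h_m),

trained with the negative log-likelihood of serial binary regressions

    -[ sum_{j<k} log(1 - h_j) + d log h_k + (1 - d) log(1 - h_k) ]

for a subject observed in bin `k` with event indicator `d`. Three model
variants share one 3-layer architecture: clinical-only, image-only, and
multimodal (the clinical vector is concatenated onto the activations
entering the final layer). The scalar risk score is `1 - S(36 months)`.

Because clinical MRI cohorts cannot be shipped, the package includes a
seeded **tumor-phantom cohort generator** with a known discrete-time hazard
(two sites with different event rates, ages and resection mixes; tumor
volume, age and resection drive the hazard), so the entire pipeline —
preprocessing, encoder transfer, survival training, evaluation — runs and
is tested end-to-end against simulated ground truth.

Also included: a preprocessing chain (iterative log-domain bias-field
correction, trilinear resampling to 1x1x3 mm, Otsu + connected-component
brain masking, z-score + crop/pad framing) and a hand-implemented
time-dependent evaluation suite (Antolini's C^td, bootstrap CIs, IPCW
time-dependent AUC and Brier/integrated Brier scores, 10-bin calibration
error, Kaplan-Meier, log-rank, median-split risk stratification).

## Worked example

A desk-scale end-to-end experiment: simulate a two-site cohort of 60
phantoms, pretrain the segmentation U-Net on 12 disjoint phantoms, extract
frozen-encoder features, train all three model variants with 3-fold
cross-validation on the 70% development split, and evaluate on the held-out
30%:

```r
library(gliohazard)

cfg <- experiment_config(
  n_cohort  = 60, n_pretrain = 12,
  phantom   = phantom_config(grid_shape = c(32, 32, 16),
                             voxel_spacing = c(3, 3, 6),
                             tumor_radius_range = c(8, 20),
                             tumor_contrast = 80, noise_sd = 3),
  unet      = unet_config(n_levels = 2, base_channels = 4,
                          input_size = c(32, 32, 16)),
  seg_train = seg_train_config(epochs = 4, lr = 2e-3),
  surv_train = surv_train_config(epochs = 60),
  n_boot = 50, seed = 7)

report <- run_experiment(cfg)
report
#> <experiment_report> n=60, config 00d1c34f, seed 7
#>   clinical   Ctd 0.291 (0.127-0.581)  AUC 0.354  ECE 0.261  IBS 0.269
#>   image      Ctd 0.686 (0.407-0.903)  AUC 0.862  ECE 0.144  IBS 0.160
#>   multimodal Ctd 0.709 (0.424-0.885)  AUC 0.932  ECE 0.107  IBS 0.174
```

Reading the output: `Ctd` is the time-dependent concordance on the 18
held-out subjects (with a percentile bootstrap CI), `AUC` the IPCW
time-dependent AUC for 3-year EFS, `ECE` the 10-bin expected calibration
error at 36 months, `IBS` the integrated Brier score. At this toy size the
test set holds only a handful of events, so the clinical arm (4 covariates,
weak default effects) is essentially noise while the image and multimodal
arms — whose tumor-volume signal the encoder features carry — discriminate
well; the test suite runs the same comparison at larger sizes where the
expected ordering (multimodal >= image-only, clinical-only) is checked over
repeated seeds.

Individual pieces are usable on their own:

```r
ph  <- generate_phantom(phantom_config(), subject_seed = 1)  # volume+mask+outcome
km  <- km_estimator(c(3, 5, 8), c(1, 0, 1))                  # product-limit
p   <- fisher_exact_2x2(matrix(c(7, 193, 15, 178), 2, byrow = TRUE))
```

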