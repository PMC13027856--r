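# mvbrain

Multi-view, dual-modal brain MRI classification on synthetic phantoms —
an end-to-end, fully testable implementation in base R.

## The problem

Case-control neuroimaging studies (the motivating case is autism spectrum
disorder versus typical controls, with cohorts shaped like the ABIDE I
NYU site: 79 affected, 105 controls) combine two kinds of evidence:

* **structural MRI** — a 3D anatomical volume per subject, carrying
  morphological differences such as cortical thickness;
* **functional MRI** — a 4D BOLD time series, carrying differences in
  inter-regional temporal coordination (functional connectivity).

Deep-learning pipelines for such data involve many interlocking pieces —
orientation handling, registration, motion censoring, filtering,
slice extraction, two network branches, fusion, losses, metrics,
saliency — and most published descriptions leave each piece just
under-specified enough that results cannot be checked. `mvbrain`
implements the whole pipeline with every piece verifiable: all networks
have exact hand-written gradients (checked against central differences),
all preprocessing math has closed-form or brute-force oracles, and all
learning claims are made on synthetic phantoms with planted, known
ground truth.

## The model

**Structural branch.** Each subject's volume is reduced to centred slice
stacks in the three anatomical planes (axial, coronal, sagittal). A
shared-weight hierarchical 3D CNN encodes each plane stack
(`F^(l) = ReLU(B(W^(l) * F^(l-1) + b^(l)))` with alternating kernel sizes
k ∈ {3, 5}, dilation rates d, spectral normalisation Ŵ = W/σ_max(W),
per-channel statistical normalisation, residual fusion through 1×1×1
convolutions, channel attention α = softmax(w_cᵀ g(F)) and a spatial
sigmoid mask), ending in global average pooling; plane embeddings are
concatenated and regularised by an entropy term H(softmax(z)).

**Functional branch.** ROI time series S ∈ R^{T×R} (motion-censored at
FD threshold 0.5 mm, ideal band-pass 0.01–0.1 Hz) are projected
(H = S W_p + b_p), encoded by a bidirectional LSTM, pooled with softmax
attention over time, and fused with the Fisher-z connectivity vector
z_ij = atanh(r_ij) as `[f_seq, f_fc, f_seq ⊙ f'_fc]`.

**Head and training.** Both branches (or their cross-modality fusion)
feed a shared MLP head — LayerNorm → 256-unit GELU → dropout 0.5 → two
logits — trained with focal loss
FL = −α_t (1 − p_t)^γ log p_t (α_t = 0.25, γ = 2), optional Mixup, and
seeded Adam. Evaluation reports accuracy, precision, recall,
specificity, F1, ROC/AUC, and Grad-CAM saliency volumes.

## Worked example

Generate a small phantom cohort with a strong morphological class effect,
split at subject level, train the structural branch, and evaluate on the
held-out subjects:

```r
library(mvbrain)

spec <- phantom_spec(n_asd = 16, n_control = 16, shape = c(16, 16, 16),
                     effect_size = 2, seed = 42)
man  <- subject_split(phantom_roster(spec), test_frac = 0.25, seed = 42,
                      planes = "axial")
ds   <- phantom_smri_dataset(spec, n_slices = 8, out_size = 16)
tr   <- dataset_split(ds, man, "train")
te   <- dataset_split(ds, man, "test")

model <- mvb_fit(tr$x, tr$y, modality = "smri",
                 smri_cfg = smri_config(channel_plan = c(8, 16),
                                        kernels = c(3, 3), dilations = c(1, 1)),
                 config = train_config(loss = "focal", lr = 1e-3, epochs = 30,
                                       batch_size = 8, seed = 42),
                 subject_ids = tr$subject_ids)
print(model)
print(evaluate_model(model, te$x, te$y, te$subject_ids))
cat(sprintf("held-out AUC: %.3f\n",
            roc_auc(predict(model, te$x), te$y == "ASD")$auc))
```

Output:

```
<mvb_model> modality: smri
  epochs trained: 30  final loss: 0.004032
confusion: TP=3 FP=0 FN=1 TN=4
accuracy 0.8750 | precision 1.0000 | recall 0.7500 | specificity 1.0000 | F1 0.8571
held-out AUC: 0.938
```

Of the 8 held-out subjects, 7 are classified correctly from a planted
2-voxel cortical-shell thickening (the one miss is a borderline subject
whose shell jitter shrinks the effect); the AUC of 0.938 says the
predicted probabilities rank 15 of the 16 affected/control pairs
correctly. `grad_cam(model, te$x[[1]])` returns a non-negative saliency
volume over the input slice stack highlighting where the evidence lives.

The functional branch works the same way via `phantom_fmri_dataset()`
and `modality = "fmri"`; `modality = "fused"` trains the cross-modality
fusion of both.

## Package layout

| Area | Functions |
|---|---|
| Volumes & I/O | `volume_image`, `load_nifti`, `save_nifti`, `resample_rigid`, `export_png` |
| Phantoms | `phantom_spec`, `make_smri_phantom`, `make_fmri_phantom`, `make_atlas`, `write_phantom_dataset` |
| Structural preprocessing | `brain_mask`, `apply_brain_mask`, `zscore_normalize`, `mutual_information`, `register_rigid`, `preprocess_smri` |
| Functional preprocessing | `estimate_motion`, `framewise_displacement`, `censor_frames`, `bandpass`, `roi_timeseries`, `connectivity`, `preprocess_fmri` |
| Slicing & splits | `mid_slice_indices`, `extract_plane_slices`, `subject_split`, `count_slices`, `augment`, `assemble_multiview` |
| Networks | `smri_config`/`smri_forward`, `fmri_config`/`fmri_forward`, `cross_modality_fuse`, `classifier_head`, plus all layer primitives with backward passes |
| Training & evaluation | `mvb_fit`, `predict`/`summary`/`plot` methods, `focal_loss`, `mixup`, `compute_metrics`, `roc_auc`, `grad_cam` |

The methods vignette (`vignettes/mvbrain-methods.Rmd`) documents the
model, the phantom generator's assumptions and limits, and every
numerical convention.
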