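# Convenience builders that turn a phantom cohort into per-subject model
# inputs, wiring the preprocessing and slicing modules together.

#' Build structural model inputs from a phantom cohort
#'
#' For each subject: generate the structural phantom, brain-mask and
#' z-score normalise it, and extract the centred multi-view slice stack.
#'
#' @param spec a [phantom_spec()].
#' @param roster data.frame with `subject_id`, `label` (defaults to the
#'   full [phantom_roster()]).
#' @param n_slices slices per plane.
#' @param out_size slice side length after resizing.
#' @return list with `x` (per-subject lists holding `mvt`), `y` labels,
#'   `subject_ids`.
#' @export
phantom_smri_dataset <- function(spec, roster = phantom_roster(spec),
                                 n_slices = 8, out_size = 16) {
  x <- vector("list", nrow(roster))
  for (i in seq_len(nrow(roster))) {
    ph <- make_smri_phantom(spec, roster$subject_id[i], roster$label[i])
    norm <- zscore_normalize(apply_brain_mask(ph$volume, ph$mask))
    x[[i]] <- list(mvt = multiview_from_volume(norm, n_slices, out_size,
                                               roster$subject_id[i]))
  }
  list(x = x, y = roster$label, subject_ids = roster$subject_id)
}

#' Build functional model inputs from a phantom cohort
#'
#' For each subject: generate the functional phantom, extract ROI time
#' series, band-pass filter them, and compute the Fisher-z connectivity
#' vector. Frames censored by the ground-truth motion trace are dropped
#' when the phantom specification injects motion spikes.
#'
#' @param spec a [phantom_spec()].
#' @param roster subject roster (defaults to the full cohort).
#' @param fd_threshold censoring threshold applied to the ground-truth
#'   motion trace.
#' @return list with `x` (per-subject lists holding `S` and `fc_vec`),
#'   `y`, `subject_ids`.
#' @export
phantom_fmri_dataset <- function(spec, roster = phantom_roster(spec),
                                 fd_threshold = 0.5) {
  x <- vector("list", nrow(roster))
  for (i in seq_len(nrow(roster))) {
    ph <- make_fmri_phantom(spec, roster$subject_id[i], roster$label[i])
    s_full <- roi_timeseries(ph$volume, ph$atlas)
    s_filt <- bandpass(s_full, spec$tr, spec$band[1], spec$band[2])
    retained <- censor_frames(framewise_displacement(ph$motion), fd_threshold)
    s <- s_filt[retained, , drop = FALSE]
    fc <- connectivity(s)
    x[[i]] <- list(S = s, fc_vec = fc_vectorize(fc$z_mat))
  }
  list(x = x, y = roster$label, subject_ids = roster$subject_id)
}

#' Subset a prepared dataset by manifest split
#' @param data a `phantom_*_dataset()` result.
#' @param manifest a [subject_split()] manifest.
#' @param split `"train"` or `"test"`.
#' @return dataset list restricted to the subjects of that split.
#' @export
dataset_split <- function(data, manifest, split) {
  ids <- unique(manifest$subject_id[manifest$split == split])
  keep <- data$subject_ids %in% ids
  list(x = data$x[keep], y = data$y[keep],
       subject_ids = data$subject_ids[keep])
}
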