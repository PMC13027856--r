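#' Specification of a synthetic case-control brain phantom cohort
#'
#' The defaults mirror the ABIDE I NYU site roster used throughout the
#' package: 79 affected (ASD) and 105 control subjects. Structural phantoms
#' are ellipsoidal "brains" with a cortical shell whose thickness carries
#' the class effect; functional phantoms carry band-limited ROI signals
#' with a class-dependent planted correlation between a designated ROI
#' pair, plus slow drift, white noise and optional rigid motion spikes.
#'
#' @param n_asd,n_control subject counts per class (defaults 79 / 105).
#' @param shape 3D grid size (voxels); at least 16 per axis for sMRI.
#' @param voxel_size voxel edge lengths in mm.
#' @param effect_size dimensionless class contrast: extra cortical-shell
#'   thickness (voxels) in the affected class, and the planted ROI-pair
#'   correlation `min(0.9, effect_size)` in affected functional phantoms.
#' @param tr repetition time in seconds (functional).
#' @param n_frames number of functional frames (>= 32).
#' @param n_rois number of atlas regions.
#' @param motion_spikes list of `list(frame =, translation = c(x,y,z) mm)`
#'   rigid motion events injected into the functional series.
#' @param noise_sd additive white-noise standard deviation.
#' @param shape_jitter per-subject SD (voxels) of cortical-shell thickness.
#' @param texture_amp amplitude of the bounded smooth anatomical texture
#'   added inside the structural brain (kept below 0.25 so tissue classes
#'   remain exactly separable by intensity).
#' @param bold_amp amplitude of the functional ROI fluctuations as a
#'   fraction of the static baseline intensity (BOLD-like fluctuations are
#'   small relative to the anatomy, which also keeps frame-to-frame
#'   registration well posed).
#' @param band passband `c(f_low, f_high)` in Hz for the ROI signals.
#' @param seed master seed; every phantom is a pure function of
#'   `(seed, subject_id)`.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_asd = 79, n_control = 105, shape = c(32, 32, 32),
                         voxel_size = c(2, 2, 2), effect_size = 2, tr = 2,
                         n_frames = 128, n_rois = 8, motion_spikes = list(),
                         noise_sd = 0.1, shape_jitter = 0.25, bold_amp = 0.05,
                         texture_amp = 0.15, band = c(0.01, 0.1), seed = 1) {
  stopifnot(n_asd >= 1, n_control >= 1, effect_size >= 0, noise_sd >= 0)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < 1 / (2 * tr)))
    stop("band must satisfy 0 < f_low < f_high < Nyquist (", 1 / (2 * tr), " Hz)")
  structure(list(n_asd = n_asd, n_control = n_control, shape = shape,
                 voxel_size = voxel_size, effect_size = effect_size, tr = tr,
                 n_frames = n_frames, n_rois = n_rois,
                 motion_spikes = motion_spikes, noise_sd = noise_sd,
                 shape_jitter = shape_jitter, bold_amp = bold_amp,
                 texture_amp = texture_amp, band = band, seed = seed),
            class = "phantom_spec")
}

#' Subject roster for a phantom cohort
#' @param spec a [phantom_spec()].
#' @return data.frame with `subject_id` and `label` (`"ASD"`/`"NC"`).
#' @export
phantom_roster <- function(spec) {
  n <- spec$n_asd + spec$n_control
  data.frame(subject_id = sprintf("sub-%04d", seq_len(n)),
             label = c(rep("ASD", spec$n_asd), rep("NC", spec$n_control)),
             stringsAsFactors = FALSE)
}

# squared normalised ellipsoid radius at every voxel (0-based centre coords)
ellipsoid_field <- function(shape, semi_axes, center = (shape - 1) / 2) {
  gx <- ((0:(shape[1] - 1)) - center[1]) / semi_axes[1]
  gy <- ((0:(shape[2] - 1)) - center[2]) / semi_axes[2]
  gz <- ((0:(shape[3] - 1)) - center[3]) / semi_axes[3]
  outer(outer(gx^2, gy^2, "+"), gz^2, "+")
}

# distinct semi-axes: real brains are longer than wide than tall, and the
# asymmetry keeps rigid rotations identifiable during registration
default_brain_axes <- function(shape) c(0.42, 0.37, 0.32) * shape

#' Generate one structural phantom
#'
#' Renders an ellipsoidal brain (distinct semi-axes) with interior
#' intensity 0.5 and a cortical shell of intensity 1.0 whose thickness is
#' `1.5 + effect_size * (label == "ASD") + N(0, shape_jitter)` voxels,
#' plus a bounded smooth texture and white noise of SD `noise_sd`.
#' Deterministic per `(seed, subject_id)`.
#'
#' @param spec a [phantom_spec()].
#' @param subject_id subject identifier string.
#' @param label `"ASD"` or `"NC"`.
#' @return a list with elements `volume` ([volume_image()]), `mask` (logical
#'   array), and `truth` (shell thickness and analytic shell voxel count).
#' @export
make_smri_phantom <- function(spec, subject_id, label) {
  shape <- spec$shape
  if (any(shape < 16)) stop("shape must be >= 16 per axis")
  axes <- default_brain_axes(shape)
  base_thick <- 1.5
  with_substream(spec$seed, subject_id, "smri", expr = {
    thick_class <- base_thick + spec$effect_size * (label == "ASD")
    if (any(axes - thick_class <= 1)) stop("shape too small to contain the shell")
    thick <- thick_class + spec$shape_jitter * stats::rnorm(1)
    # jitter may not push the shell outside the brain or below one voxel
    thick <- min(max(0.5, thick), min(axes) - 1.1)
    outer_f <- ellipsoid_field(shape, axes)
    inner_f <- ellipsoid_field(shape, axes - thick)
    mask <- outer_f <= 1
    shell <- mask & inner_f > 1
    vol <- array(0, dim = shape)
    vol[mask] <- 0.5
    vol[shell] <- 1
    # bounded smooth texture (|t| <= texture_amp < 0.25) preserves the
    # exact shell/interior separability at the 0.75 intensity threshold
    tex <- gauss_smooth3d(array(stats::rnorm(prod(shape)), dim = shape), 1.5)
    vol[mask] <- vol[mask] +
      spec$texture_amp * tanh(tex[mask] / stats::sd(tex))
    if (spec$noise_sd > 0)
      vol <- vol + array(stats::rnorm(prod(shape), sd = spec$noise_sd), dim = shape)
    aff <- diag(c(spec$voxel_size, 1))
    list(volume = volume_image(vol, aff),
         mask = mask,
         truth = list(shell_thickness = thick, shell_count = sum(shell),
                      brain_count = sum(mask)))
  })
}

#' Block parcellation of a brain mask into ROIs
#'
#' Partitions the mask voxels, ordered lexicographically along the first
#' axis, into `n_rois` contiguous near-equal blocks labelled 1..n_rois
#' (0 = background).
#'
#' @param shape 3D grid size.
#' @param n_rois number of regions (>= 1, <= number of mask voxels).
#' @param mask optional logical array; defaults to the standard ellipsoidal
#'   brain of this grid size.
#' @return a list of class `roi_atlas` with `labels` (integer array) and
#'   `n_rois`.
#' @export
make_atlas <- function(shape, n_rois, mask = NULL) {
  if (n_rois < 1) stop("n_rois must be >= 1")
  if (is.null(mask)) mask <- ellipsoid_field(shape, default_brain_axes(shape)) <= 1
  idx <- which(mask)  # column-major: fastest along x
  if (n_rois > length(idx)) stop("n_rois exceeds number of brain voxels")
  labels <- array(0L, dim = shape)
  breaks <- floor(seq(0, length(idx), length.out = n_rois + 1))
  for (r in seq_len(n_rois))
    labels[idx[(breaks[r] + 1):breaks[r + 1]]] <- r
  structure(list(labels = labels, n_rois = as.integer(n_rois)),
            class = "roi_atlas")
}

# unit-SD band-limited sinusoid mixture of n_comp components
bandlimited_signal <- function(tt, band, n_comp = 3) {
  f <- stats::runif(n_comp, band[1], band[2])
  a <- stats::runif(n_comp, 0.5, 1)
  ph <- stats::runif(n_comp, 0, 2 * pi)
  s <- colSums(a * sin(outer(2 * pi * f, tt) + ph))
  s / stats::sd(s)
}

#' Generate one functional phantom
#'
#' Each atlas ROI carries a unit-variance sinusoid mixture inside the
#' passband plus a slow 0.002 Hz drift; voxel-level white noise of SD
#' `noise_sd` is added on top. In affected subjects the designated ROI pair
#' (1, 2) has planted correlation `rho = min(0.9, effect_size)`; in
#' controls the pair is independent. Rigid motion is injected at the
#' spike frames by resampling those frames, and the injected parameters are
#' returned as the ground-truth motion trace.
#'
#' @param spec a [phantom_spec()].
#' @param subject_id subject identifier.
#' @param label `"ASD"` or `"NC"`.
#' @return list with `volume` (4D [volume_image()]), `atlas`
#'   ([make_atlas()] result), `motion` (T x 6 ground-truth trace),
#'   `true_fc` (planted R x R correlation matrix), `roi_signals`
#'   (noise-free T x R matrix, before motion), and `rho`.
#' @export
make_fmri_phantom <- function(spec, subject_id, label) {
  if (spec$n_frames < 32) stop("n_frames must be >= 32")
  shape <- spec$shape
  tt <- (seq_len(spec$n_frames) - 1) * spec$tr
  atlas <- make_atlas(shape, spec$n_rois)
  mask <- atlas$labels > 0
  rho <- min(0.9, spec$effect_size)
  for (sp in spec$motion_spikes)
    if (sp$frame < 1 || sp$frame > spec$n_frames) stop("spike frame out of range")
  with_substream(spec$seed, subject_id, "fmri", expr = {
    sig <- sapply(seq_len(spec$n_rois), function(r) bandlimited_signal(tt, spec$band))
    if (label == "ASD" && rho > 0 && spec$n_rois >= 2)
      sig[, 2] <- rho * sig[, 1] + sqrt(1 - rho^2) * sig[, 2]
    drift <- 0.5 * sin(2 * pi * 0.002 * tt + stats::runif(1, 0, 2 * pi))
    roi_sig <- sig + drift
    # static anatomy so motion estimation has spatial structure to latch
    # onto; the smooth random texture breaks the ellipsoid's rotational
    # near-symmetry, keeping the rotation parameters identifiable
    radial <- ellipsoid_field(shape, default_brain_axes(shape))
    texture <- gauss_smooth3d(array(stats::rnorm(prod(shape)), dim = shape), 1.5)
    texture <- texture / stats::sd(texture)
    static <- array(0, dim = shape)
    static[mask] <- 1 + 0.5 * (1 - radial[mask]) + 0.25 * texture[mask]
    aff <- diag(c(spec$voxel_size, 1))
    vol4 <- array(0, dim = c(shape, spec$n_frames))
    roi_idx <- lapply(seq_len(spec$n_rois), function(r) which(atlas$labels == r))
    for (t in seq_len(spec$n_frames)) {
      fr <- static
      for (r in seq_len(spec$n_rois))
        fr[roi_idx[[r]]] <- fr[roi_idx[[r]]] + spec$bold_amp * roi_sig[t, r]
      vol4[, , , t] <- fr
    }
    if (spec$noise_sd > 0)
      vol4 <- vol4 + array(stats::rnorm(length(vol4), sd = spec$noise_sd), dim = dim(vol4))
    motion <- matrix(0, spec$n_frames, 6,
                     dimnames = list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz")))
    for (sp in spec$motion_spikes) {
      tr3 <- volume_image(vol4[, , , sp$frame], aff)
      moved <- resample_rigid(tr3, rigid_transform(translation = sp$translation))
      vol4[, , , sp$frame] <- moved$data
      motion[sp$frame, 1:3] <- sp$translation
    }
    true_fc <- diag(spec$n_rois)
    if (spec$n_rois >= 2 && label == "ASD") true_fc[1, 2] <- true_fc[2, 1] <- rho
    list(volume = volume_image(vol4, diag(c(spec$voxel_size, 1)), tr = spec$tr),
         atlas = atlas, motion = motion, true_fc = true_fc,
         roi_signals = roi_sig, rho = if (label == "ASD") rho else 0)
  })
}

#' Write a phantom cohort to disk
#'
#' Generates every subject in the roster and writes structural and
#' functional NIfTI volumes, a roster CSV (`subject_id,label,smri_path,
#' fmri_path`), and a ground-truth JSON (shell thicknesses, planted
#' correlations, motion traces).
#'
#' @param spec a [phantom_spec()].
#' @param dir output directory (created if needed).
#' @param fmri whether to also generate functional phantoms.
#' @return the roster data.frame with file path columns, invisibly.
#' @export
write_phantom_dataset <- function(spec, dir, fmri = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  roster <- phantom_roster(spec)
  roster$smri_path <- file.path(dir, paste0(roster$subject_id, "_T1w.nii.gz"))
  roster$fmri_path <- if (fmri)
    file.path(dir, paste0(roster$subject_id, "_bold.nii.gz")) else NA_character_
  truth <- list()
  for (i in seq_len(nrow(roster))) {
    sm <- make_smri_phantom(spec, roster$subject_id[i], roster$label[i])
    save_nifti(sm$volume, roster$smri_path[i])
    rec <- list(shell_thickness = sm$truth$shell_thickness)
    if (fmri) {
      fm <- make_fmri_phantom(spec, roster$subject_id[i], roster$label[i])
      save_nifti(fm$volume, roster$fmri_path[i])
      rec$rho <- fm$rho
      rec$motion <- fm$motion
    }
    truth[[roster$subject_id[i]]] <- rec
  }
  utils::write.csv(roster, file.path(dir, "roster.csv"), row.names = FALSE)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(roster)
}
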