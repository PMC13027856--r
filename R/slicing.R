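# Multi-view slice extraction, augmentation, subject-level splitting, and
# the per-plane slice accounting of the standard cohort table.

PLANE_AXES <- c(sagittal = 1L, coronal = 2L, axial = 3L)

#' Centred mid-slice window indices
#'
#' Returns `n` contiguous, centred 0-based slice indices along an axis of
#' size `dim_size`. For `n > 1` the window starts at
#' `floor((dim_size - n) / 2)`; the single-slice case uses the central
#' coordinate `floor(dim_size / 2)`.
#'
#' @param dim_size axis length.
#' @param n number of successive slices (1 <= n <= dim_size).
#' @return integer vector of 0-based indices.
#' @export
mid_slice_indices <- function(dim_size, n) {
  if (n < 1 || n > dim_size) stop("need 1 <= n <= dim_size")
  if (n == 1) return(as.integer(floor(dim_size / 2)))
  start <- floor((dim_size - n) / 2)
  as.integer(start:(start + n - 1))
}

#' Extract resized mid-slices orthogonal to an anatomical plane
#'
#' Takes the `n` centred slices orthogonal to the plane axis (sagittal = x,
#' coronal = y, axial = z in canonical RAS order) and resizes each to
#' `out_size` x `out_size` with bilinear interpolation.
#'
#' @param vol canonical 3D [volume_image()].
#' @param plane one of `"axial"`, `"coronal"`, `"sagittal"`.
#' @param n number of successive mid-slices.
#' @param out_size output side length in pixels (default 224).
#' @param subject_id optional source subject identifier.
#' @return object of class `slice_stack`: list with `plane`, `indices`
#'   (0-based), `slices` (n x H x W array), `subject_id`.
#' @export
extract_plane_slices <- function(vol, plane, n, out_size = 224,
                                 subject_id = NULL) {
  stopifnot(is_volume_image(vol), length(dim(vol$data)) == 3)
  if (!plane %in% names(PLANE_AXES)) stop("unknown plane: ", plane)
  axis <- PLANE_AXES[[plane]]
  d <- dim(vol$data)
  idx <- mid_slice_indices(d[axis], n)
  slices <- array(0, dim = c(length(idx), out_size, out_size))
  for (i in seq_along(idx)) {
    sl <- switch(axis,
                 vol$data[idx[i] + 1, , ],
                 vol$data[, idx[i] + 1, ],
                 vol$data[, , idx[i] + 1])
    slices[i, , ] <- resize_bilinear(sl, out_size, out_size)
  }
  structure(list(plane = plane, indices = idx, slices = slices,
                 subject_id = subject_id),
            class = "slice_stack")
}

#' Retain all frames except the first and last k
#'
#' @param n_frames total frame count T (> 2k).
#' @param k endpoint exclusion count per side (default 10).
#' @return 1-based integer indices `k+1 .. T-k`.
#' @export
exclude_endpoints <- function(n_frames, k = 10) {
  if (n_frames <= 2 * k) stop("need T > 2k (T = ", n_frames, ", k = ", k, ")")
  seq.int(k + 1L, n_frames - k)
}

#' Subject-level train/test split
#'
#' Splits the roster at the subject level, per class, with
#' `floor(test_frac * n_class)` test subjects drawn by a seeded shuffle —
#' the rounding convention that reproduces the 64/15 and 84/21 split of a
#' 79/105 cohort at `test_frac = 0.2`.
#'
#' @param roster data.frame with `subject_id` and `label`.
#' @param test_frac test fraction in (0, 1).
#' @param seed split seed.
#' @param planes anatomical planes to enumerate in the manifest.
#' @return data.frame of class `dataset_manifest`: one row per subject per
#'   plane with columns `subject_id`, `label`, `split`, `plane`; the seed
#'   is stored as an attribute.
#' @export
subject_split <- function(roster, test_frac = 0.2, seed = 1,
                          planes = c("axial", "coronal", "sagittal")) {
  stopifnot(nrow(roster) > 0, test_frac > 0, test_frac < 1)
  split <- character(nrow(roster))
  for (cl in unique(roster$label)) {
    ids <- which(roster$label == cl)
    if (length(ids) < 2) stop("class ", cl, " has fewer than 2 subjects")
    n_test <- floor(test_frac * length(ids))
    shuffled <- with_substream(seed, "split", cl, expr = sample(ids))
    split[shuffled] <- c(rep("test", n_test),
                         rep("train", length(ids) - n_test))
  }
  out <- merge(data.frame(roster, split = split, stringsAsFactors = FALSE),
               data.frame(plane = planes, stringsAsFactors = FALSE))
  out <- out[order(out$plane, out$subject_id), ]
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  class(out) <- c("dataset_manifest", "data.frame")
  out
}

#' Per-plane, per-split, per-class slice accounting
#'
#' Each cell counts `subjects x n_slices` 2D images, reproducing the
#' slice-accounting table of the 79/105 cohort for any slice budget.
#'
#' @param manifest a [subject_split()] manifest.
#' @param n_slices slices extracted per plane per subject (>= 1).
#' @return data.frame with columns `plane`, `n_slices`, `train_asd`,
#'   `train_nc`, `test_asd`, `test_nc`.
#' @export
count_slices <- function(manifest, n_slices) {
  if (n_slices < 1) stop("n_slices must be >= 1")
  cell <- function(pl, sp, cl)
    sum(manifest$plane == pl & manifest$split == sp & manifest$label == cl) *
      n_slices
  planes <- unique(manifest$plane)
  data.frame(plane = planes, n_slices = n_slices,
             train_asd = vapply(planes, cell, 0, sp = "train", cl = "ASD"),
             train_nc = vapply(planes, cell, 0, sp = "train", cl = "NC"),
             test_asd = vapply(planes, cell, 0, sp = "test", cl = "ASD"),
             test_nc = vapply(planes, cell, 0, sp = "test", cl = "NC"),
             row.names = NULL)
}

# rotate a 2D slice about its centre (bilinear, zero fill)
rotate_slice <- function(mat, degrees) {
  if (degrees == 0) return(mat)
  th <- degrees * pi / 180
  h <- nrow(mat); w <- ncol(mat)
  cx <- (h - 1) / 2; cy <- (w - 1) / 2
  grid <- expand.grid(i = 0:(h - 1), j = 0:(w - 1))
  di <- grid$i - cx; dj <- grid$j - cy
  # inverse map: rotate output coords by -theta
  si <- cos(th) * di + sin(th) * dj + cx
  sj <- -sin(th) * di + cos(th) * dj + cy
  arr <- array(mat, dim = c(h, w, 1))
  vals <- trilinear_sample(arr, cbind(si, sj, 0))
  matrix(vals, h, w)
}

#' Draw augmentation parameters
#'
#' One draw per source volume: in-plane rotation within +-10 degrees,
#' horizontal and vertical flips with probability 0.5 each, and an
#' intensity scaling factor in \[0.9, 1.1\].
#'
#' @param seed,subject_id keys of the deterministic draw.
#' @return list with `rot_deg`, `hflip`, `vflip`, `scale`.
#' @export
augment_draw <- function(seed, subject_id = "") {
  with_substream(seed, subject_id, "augment", expr = list(
    rot_deg = stats::runif(1, -10, 10),
    hflip = stats::runif(1) < 0.5,
    vflip = stats::runif(1) < 0.5,
    scale = stats::runif(1, 0.9, 1.1)))
}

#' Augment a slice stack (training data only)
#'
#' Applies a single parameter draw — rotation (bilinear, zero fill), flips
#' and intensity scaling — consistently to every slice of the stack, so
#' the correlation structure between slices of one volume is preserved.
#' Refuses to run on test-split data.
#'
#' @param stack a `slice_stack`.
#' @param draw an [augment_draw()] list (or `seed` to derive one).
#' @param split data split the stack belongs to; must be `"train"`.
#' @param seed used with the stack's subject id when `draw` is `NULL`.
#' @return the augmented `slice_stack`.
#' @export
augment <- function(stack, draw = NULL, split = "train", seed = 1) {
  stopifnot(inherits(stack, "slice_stack"))
  if (!identical(split, "train"))
    stop("augmentation is restricted to training data (got split = '",
         split, "')")
  draw <- draw %||% augment_draw(seed, stack$subject_id %||% "")
  out <- stack
  for (i in seq_len(dim(stack$slices)[1])) {
    sl <- rotate_slice(stack$slices[i, , ], draw$rot_deg)
    if (draw$hflip) sl <- sl[, ncol(sl):1]
    if (draw$vflip) sl <- sl[nrow(sl):1, ]
    out$slices[i, , ] <- draw$scale * sl
  }
  attr(out, "augmentation") <- draw
  out
}

#' Assemble the three plane stacks into a multi-view tensor
#'
#' Stacks are reordered to the canonical (axial, coronal, sagittal) plane
#' order regardless of input order, giving a `3 x n x H x W` array.
#'
#' @param stacks list of three `slice_stack`s, one per plane, with equal
#'   slice counts and sizes.
#' @return object of class `multiview_tensor`: the `3 x n x H x W` array
#'   with attributes `planes` and `subject_id`.
#' @export
assemble_multiview <- function(stacks) {
  planes <- vapply(stacks, function(s) s$plane, "")
  want <- c("axial", "coronal", "sagittal")
  if (!setequal(planes, want)) stop("need exactly the three planes ",
                                    paste(want, collapse = ", "))
  stacks <- stacks[match(want, planes)]
  dims <- lapply(stacks, function(s) dim(s$slices))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("plane stacks must share n and H x W")
  d <- dims[[1]]
  out <- array(0, dim = c(3, d))
  for (p in 1:3) out[p, , , ] <- stacks[[p]]$slices
  structure(out, planes = want, subject_id = stacks[[1]]$subject_id,
            class = "multiview_tensor")
}

#' Multi-view tensor for one subject volume
#'
#' Convenience wrapper: extracts the centred slice window in all three
#' planes and assembles the canonical multi-view tensor.
#'
#' @inheritParams extract_plane_slices
#' @return a `multiview_tensor`.
#' @export
multiview_from_volume <- function(vol, n, out_size = 224, subject_id = NULL) {
  assemble_multiview(lapply(c("axial", "coronal", "sagittal"), function(p)
    extract_plane_slices(vol, p, n, out_size, subject_id)))
}
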