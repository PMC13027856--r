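#' Volume image container
#'
#' A dense 3D (structural) or 4D (functional) voxel grid together with its
#' 4x4 voxel-to-world affine (mm), voxel sizes derived from the affine
#' column norms, and the repetition time for 4D series. After loading,
#' volumes are always in canonical RAS axis order, so axis 1 is sagittal
#' (x), axis 2 coronal (y) and axis 3 axial (z).
#'
#' @param data numeric array, 3 or 4 dimensions, all extents >= 1.
#' @param affine 4x4 invertible voxel-to-world matrix (0-based voxel indices,
#'   world coordinates in mm). Defaults to identity spacing.
#' @param tr repetition time in seconds; required for 4D data.
#' @return an object of class `volume_image`.
#' @export
volume_image <- function(data, affine = NULL, tr = NULL) {
  data <- unclass(data)
  attributes(data) <- list(dim = dim(data))
  nd <- length(dim(data))
  if (!(nd %in% c(3L, 4L))) stop("volume data must be 3D or 4D, got ", nd, "D")
  if (any(dim(data) < 1)) stop("all dimensions must be >= 1")
  if (is.null(affine)) affine <- diag(4)
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4, 4))) stop("affine must be 4x4")
  if (abs(det(affine)) < 1e-12) stop("affine is singular")
  if (nd == 4L && is.null(tr)) stop("4D volumes require a repetition time `tr`")
  if (nd == 3L) tr <- NULL
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vox <= 0)) stop("voxel sizes must be positive")
  structure(list(data = data, affine = affine, voxel_size = vox, tr = tr),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat("<volume_image> ", paste(d, collapse = " x "),
      if (length(d) == 4) sprintf("  (tr = %g s)", x$tr) else "",
      "\n  voxel size: ", paste(signif(x$voxel_size, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

is_volume_image <- function(x) inherits(x, "volume_image")

#' Load a NIfTI image as a canonical-RAS volume
#'
#' Reads a NIfTI-1/2 file, reorients it to RAS axis order (so the stored
#' array axes are sagittal, coronal, axial), and wraps it as a
#' [volume_image()]. Voxel sizes are derived from the affine column norms;
#' the repetition time of a 4D series is taken from the header.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [volume_image()].
#' @export
load_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (!(nd %in% c(3L, 4L))) stop("NIfTI payload must be 3D or 4D, got ", nd, "D")
  RNifti::orientation(img) <- "RAS"
  aff <- unname(unclass(RNifti::xform(img)))
  attributes(aff) <- list(dim = c(4L, 4L))
  tr <- NULL
  if (nd == 4L) {
    hdr <- RNifti::niftiHeader(img)
    tr <- hdr$pixdim[5]
    if (!is.finite(tr) || tr <= 0) tr <- 1
  }
  volume_image(as.array(img), aff, tr = tr)
}

#' Save a volume to NIfTI
#'
#' @param vol a [volume_image()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_nifti <- function(vol, path) {
  stopifnot(is_volume_image(vol))
  nd <- length(dim(vol$data))
  pd <- c(-1, vol$voxel_size, if (nd == 4L) vol$tr else 0, 0, 0, 0)
  img <- RNifti::asNifti(vol$data, reference = list(pixdim = pd))
  aff <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Rigid-body transform (3 translations, 3 rotations)
#'
#' Rotations are extrinsic x-y-z Euler angles in radians (the x rotation is
#' applied first), translations in mm. A transform acts on world
#' coordinates as `x -> R (x - c) + c + t` where `c` is a rotation centre
#' supplied when the transform is realised as a matrix.
#'
#' @param translation numeric length-3, mm.
#' @param rotation numeric length-3, radians.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0)) {
  stopifnot(length(translation) == 3, length(rotation) == 3)
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> t = (%.3f, %.3f, %.3f) mm, r = (%.4f, %.4f, %.4f) rad\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$rotation[1], x$rotation[2], x$rotation[3]))
  invisible(x)
}

rotation_matrix <- function(rotation) {
  a <- rotation[1]; b <- rotation[2]; g <- rotation[3]
  rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' Realise a rigid transform as a 4x4 world-coordinate matrix
#' @param t a [rigid_transform()].
#' @param center rotation centre in world coordinates (mm).
#' @return 4x4 matrix.
#' @export
rt_matrix <- function(t, center = c(0, 0, 0)) {
  r <- rotation_matrix(t$rotation)
  offset <- center + t$translation - r %*% center
  rbind(cbind(r, offset), c(0, 0, 0, 1))
}

# Recover (translation, rotation) from a 4x4 rigid matrix for a given centre.
rt_from_matrix <- function(m, center = c(0, 0, 0)) {
  r <- m[1:3, 1:3]
  beta <- asin(max(-1, min(1, -r[3, 1])))
  alpha <- atan2(r[3, 2], r[3, 3])
  gamma <- atan2(r[2, 1], r[1, 1])
  trans <- m[1:3, 4] - center + r %*% center
  rigid_transform(as.numeric(trans), c(alpha, beta, gamma))
}

#' Compose / invert rigid transforms
#'
#' Composition and inversion are carried out on the 4x4 matrices about a
#' common rotation centre, then factored back into translation + Euler
#' angles. `rt_compose(a, b)` applies `b` first, then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @param t a [rigid_transform()].
#' @param center rotation centre (mm).
#' @return a [rigid_transform()].
#' @export
rt_compose <- function(a, b, center = c(0, 0, 0)) {
  rt_from_matrix(rt_matrix(a, center) %*% rt_matrix(b, center), center)
}

#' @rdname rt_compose
#' @export
rt_invert <- function(t, center = c(0, 0, 0)) {
  rt_from_matrix(solve(rt_matrix(t, center)), center)
}

#' Rigidly resample a volume onto a target grid
#'
#' Applies the rigid transform `t` to the image content (a feature at world
#' position `x` moves to `T(x)`), then samples the result on the target
#' grid with trilinear interpolation. Voxels mapping outside the moving
#' volume's field of view are set to zero. The rotation centre defaults to
#' the world coordinate of the centre of the target grid.
#'
#' @param moving a 3D [volume_image()].
#' @param t a [rigid_transform()].
#' @param target_shape integer length-3 grid size (defaults to the moving grid).
#' @param target_affine 4x4 affine of the target grid (defaults to moving affine).
#' @param center rotation centre in world mm, or `NULL` for the grid centre.
#' @return a [volume_image()] on the target grid.
#' @export
resample_rigid <- function(moving, t, target_shape = NULL, target_affine = NULL,
                           center = NULL) {
  stopifnot(is_volume_image(moving), length(dim(moving$data)) == 3)
  target_shape <- target_shape %||% dim(moving$data)
  target_affine <- target_affine %||% moving$affine
  if (is.null(center)) {
    cv <- (target_shape - 1) / 2
    center <- as.numeric(target_affine %*% c(cv, 1))[1:3]
  }
  m <- rt_matrix(t, center)
  # target voxel -> world -> undo transform -> moving voxel
  map <- solve(moving$affine) %*% solve(m) %*% target_affine
  if (abs(det(map)) < 1e-12) stop("combined resampling map is singular")
  grid <- as.matrix(expand.grid(x = 0:(target_shape[1] - 1),
                                y = 0:(target_shape[2] - 1),
                                z = 0:(target_shape[3] - 1)))
  src <- cbind(grid, 1) %*% t(map)
  vals <- trilinear_sample(moving$data, src[, 1:3, drop = FALSE])
  volume_image(array(vals, dim = target_shape), target_affine)
}

#' Export a 2D slice as an 8-bit grayscale PNG
#'
#' Values are min-max scaled to the full 8-bit range; a constant slice maps
#' to an all-zero image by convention.
#'
#' @param slice_2d finite numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_png <- function(slice_2d, path) {
  stopifnot(is.matrix(slice_2d))
  if (!all(is.finite(slice_2d))) stop("slice contains non-finite values")
  rng <- range(slice_2d)
  scaled <- if (rng[2] > rng[1]) (slice_2d - rng[1]) / (rng[2] - rng[1])
            else matrix(0, nrow(slice_2d), ncol(slice_2d))
  png::writePNG(scaled, path)
  invisible(path)
}

#' Load a grayscale PNG as a numeric matrix in \[0, 1\]
#' @param path PNG path.
#' @return numeric matrix.
#' @export
load_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
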