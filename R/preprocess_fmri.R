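# Functional preprocessing: motion estimation, framewise displacement,
# frame censoring, ideal band-pass filtering, per-frame projections, ROI
# time series and Pearson/Fisher-z connectivity.

#' Estimate a rigid motion trace from a 4D series
#'
#' Registers every frame to the reference frame by mutual-information
#' coordinate descent and reports, per frame, the rigid parameters of the
#' frame content relative to the reference (so an injected +2 mm shift at
#' frame k is reported as +2 mm at row k). The reference row is exactly
#' zero.
#'
#' @param vol4d a 4D [volume_image()].
#' @param reference_frame 1-based reference frame index.
#' @param opts registration options (see [register_rigid()]); defaults are
#'   light single-level settings suited to frame-to-frame motion.
#' @return T x 6 matrix (columns tx, ty, tz in mm; rx, ry, rz in rad) with
#'   a `converged` logical attribute per frame.
#' @export
estimate_motion <- function(vol4d, reference_frame = 1, opts = list()) {
  stopifnot(is_volume_image(vol4d), length(dim(vol4d$data)) == 4)
  d <- dim(vol4d$data)
  if (d[4] < 2) stop("motion estimation needs at least 2 frames")
  o <- utils::modifyList(list(metric = "ssd", levels = c(2, 1), n_starts = 0,
                              init_step_mm = 2, init_step_rad = 0.04,
                              max_iter = 30, smooth_sigma = 2,
                              rot_grid = 0, rot_restarts = 0), opts)
  smooth_sigma <- o$smooth_sigma
  o$smooth_sigma <- NULL
  aff3 <- vol4d$affine
  # light smoothing regularises the MI landscape against voxel noise
  frame_vol <- function(t) {
    fr <- vol4d$data[, , , t]
    if (smooth_sigma > 0) fr <- gauss_smooth3d(fr, smooth_sigma)
    volume_image(fr, aff3)
  }
  ref <- frame_vol(reference_frame)
  trace <- matrix(0, d[4], 6,
                  dimnames = list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz")))
  converged <- rep(TRUE, d[4])
  for (t in seq_len(d[4])) {
    if (t == reference_frame) next
    fr <- frame_vol(t)
    reg <- register_rigid(fr, ref, o)
    # reg aligns frame -> reference; content motion is its inverse
    inv <- rt_invert(reg$transform)
    trace[t, ] <- c(inv$translation, inv$rotation)
    converged[t] <- reg$converged
  }
  attr(trace, "converged") <- converged
  attr(trace, "reference_frame") <- reference_frame
  trace
}

#' Framewise displacement from a motion trace
#'
#' `FD_t = |d tx| + |d ty| + |d tz| + r (|d rx| + |d ry| + |d rz|)` on the
#' backward first differences of the trace, with rotations converted to mm
#' by the brain radius `r` (about 50 mm). The first frame has FD 0.
#'
#' @param trace T x 6 motion trace (mm, rad).
#' @param radius brain radius in mm.
#' @return numeric vector of length T, class `fd_series` with the radius
#'   stored as an attribute.
#' @export
framewise_displacement <- function(trace, radius = 50) {
  stopifnot(ncol(trace) == 6)
  d <- rbind(0, diff(as.matrix(trace)))
  fd <- rowSums(abs(d[, 1:3, drop = FALSE])) +
    radius * rowSums(abs(d[, 4:6, drop = FALSE]))
  structure(fd, radius = radius, class = "fd_series")
}

#' Censor high-motion frames
#'
#' Frames whose framewise displacement exceeds the threshold are discarded.
#'
#' @param fd an [framewise_displacement()] series.
#' @param threshold FD threshold in mm (> 0); default 0.5 mm.
#' @return integer vector of retained (1-based) frame indices.
#' @export
censor_frames <- function(fd, threshold = 0.5) {
  if (threshold <= 0) stop("threshold must be > 0")
  keep <- which(as.numeric(fd) <= threshold)
  if (!length(keep)) stop("all frames censored: no frame with FD <= ", threshold)
  keep
}

#' Ideal band-pass filter via the discrete Fourier transform
#'
#' Masks the DFT of each column to the frequency band
#' `[f_low, f_high]` (inclusive) and inverts; components outside the band,
#' including the DC term, are removed exactly, making the filter idempotent
#' and energy-preserving inside the band.
#'
#' @param x numeric vector or T x R matrix sampled uniformly at `tr`.
#' @param tr sampling interval in seconds.
#' @param f_low,f_high passband edges in Hz (defaults 0.01 and 0.1).
#' @return filtered object of the same shape.
#' @export
bandpass <- function(x, tr, f_low = 0.01, f_high = 0.1) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  n <- nrow(m)
  if (n < 8) stop("need at least 8 samples")
  nyq <- 1 / (2 * tr)
  if (f_low <= 0 || f_high <= f_low || f_high > nyq)
    stop("band must satisfy 0 < f_low < f_high <= Nyquist (", nyq, " Hz)")
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) / (n * tr)
  keep <- freq >= f_low & freq <= f_high
  xf <- stats::mvfft(m)
  xf[!keep, ] <- 0
  out <- Re(stats::mvfft(xf, inverse = TRUE)) / n
  if (vec) drop(out) else out
}

#' Per-frame mean projections along the three anatomical axes
#'
#' For each frame of a 4D series, averages the volume along each axis,
#' producing one 2D mean-projection image per anatomical plane while
#' preserving the temporal dimension.
#'
#' @param vol4d 4D [volume_image()].
#' @return list with arrays `sagittal` (T x Y x Z), `coronal` (T x X x Z),
#'   `axial` (T x X x Y).
#' @export
frame_mean_images <- function(vol4d) {
  stopifnot(is_volume_image(vol4d), length(dim(vol4d$data)) == 4)
  a <- vol4d$data
  list(sagittal = aperm(apply(a, c(2, 3, 4), mean), c(3, 1, 2)),
       coronal  = aperm(apply(a, c(1, 3, 4), mean), c(3, 1, 2)),
       axial    = aperm(apply(a, c(1, 2, 4), mean), c(3, 1, 2)))
}

#' Regional BOLD time series by within-ROI averaging
#'
#' `S[t, r]` is the mean signal over the voxels of ROI `r` at retained
#' frame `t`.
#'
#' @param vol4d 4D [volume_image()].
#' @param atlas a `roi_atlas` (see [make_atlas()]) on the same grid.
#' @param retained optional integer vector of retained frame indices.
#' @return T_retained x R matrix with attributes `tr` and `retained`.
#' @export
roi_timeseries <- function(vol4d, atlas, retained = NULL) {
  stopifnot(is_volume_image(vol4d), length(dim(vol4d$data)) == 4,
            inherits(atlas, "roi_atlas"))
  d <- dim(vol4d$data)
  if (!identical(dim(atlas$labels), d[1:3])) stop("atlas grid does not match volume")
  retained <- retained %||% seq_len(d[4])
  lab <- as.integer(atlas$labels)
  counts <- tabulate(lab, nbins = atlas$n_rois)
  if (any(counts == 0)) stop("empty ROI: ", which(counts == 0)[1])
  vox <- matrix(vol4d$data, prod(d[1:3]), d[4])[, retained, drop = FALSE]
  inb <- lab > 0
  sums <- rowsum(vox[inb, , drop = FALSE], lab[inb])  # R x T
  s <- t(sums / counts)
  dimnames(s) <- list(NULL, paste0("roi", seq_len(atlas$n_rois)))
  attr(s, "tr") <- vol4d$tr
  attr(s, "retained") <- retained
  s
}

#' Pearson and Fisher-z functional connectivity
#'
#' Pairwise Pearson correlation of the ROI time series, and its
#' variance-stabilised Fisher transform `z = atanh(r)` (with `r` clipped
#' away from +-1; the diagonal of `z` is 0 by convention).
#'
#' @param s T x R ROI time-series matrix, T >= 3, no constant column.
#' @return list of class `connectivity_matrix` with `r_mat` and `z_mat`.
#' @export
connectivity <- function(s) {
  s <- as.matrix(s)
  if (nrow(s) < 3) stop("need at least 3 time points")
  sds <- apply(s, 2, stats::sd)
  if (any(sds == 0))
    stop("constant ROI time series: column ", which(sds == 0)[1])
  r <- stats::cor(s)
  z <- atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
  diag(z) <- 0
  structure(list(r_mat = r, z_mat = z), class = "connectivity_matrix")
}

#' Full functional preprocessing chain
#'
#' Motion estimation (or a supplied trace), framewise displacement, ideal
#' band-pass filtering of the ROI series over the full sampling grid, then
#' censoring of high-motion frames and connectivity. Filtering precedes
#' frame removal because a Fourier filter is only defined on a uniformly
#' sampled series.
#'
#' @param vol4d 4D [volume_image()].
#' @param atlas `roi_atlas` on the same grid.
#' @param motion optional T x 6 trace; estimated from the data when `NULL`.
#' @param fd_threshold censoring threshold in mm.
#' @param band passband in Hz.
#' @param radius brain radius for FD (mm).
#' @param motion_opts options for [estimate_motion()].
#' @return list with `S` (censored, filtered T x R series), `fc`
#'   ([connectivity()] result), `fd`, `retained`, `motion`.
#' @export
preprocess_fmri <- function(vol4d, atlas, motion = NULL, fd_threshold = 0.5,
                            band = c(0.01, 0.1), radius = 50,
                            motion_opts = list()) {
  if (is.null(motion)) motion <- estimate_motion(vol4d, opts = motion_opts)
  fd <- framewise_displacement(motion, radius)
  retained <- censor_frames(fd, fd_threshold)
  s_full <- roi_timeseries(vol4d, atlas)
  s_filt <- bandpass(s_full, vol4d$tr, band[1], band[2])
  s <- s_filt[retained, , drop = FALSE]
  attr(s, "tr") <- vol4d$tr
  attr(s, "retained") <- retained
  list(S = s, fc = connectivity(s), fd = fd, retained = retained,
       motion = motion)
}
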