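test_that("phantoms are bit-identical under the same (seed, subject)", {
  spec <- small_spec()
  a <- make_smri_phantom(spec, "sub-0001", "ASD")
  b <- make_smri_phantom(spec, "sub-0001", "ASD")
  expect_identical(a$volume$data, b$volume$data)
  fa <- make_fmri_phantom(spec, "sub-0001", "ASD")
  fb <- make_fmri_phantom(spec, "sub-0001", "ASD")
  expect_identical(fa$volume$data, fb$volume$data)
  expect_identical(fa$motion, fb$motion)
  # keyed substreams: other subjects do not perturb this one
  invisible(make_smri_phantom(spec, "sub-0099", "NC"))
  c_ <- make_smri_phantom(spec, "sub-0001", "ASD")
  expect_identical(a$volume$data, c_$volume$data)
})

test_that("with no class effect, shell voxel counts show no class difference", {
  spec <- phantom_spec(n_asd = 20, n_control = 20, shape = c(16, 16, 16),
                       effect_size = 0, seed = 7)
  counts <- function(lbl) vapply(1:20, function(i)
    make_smri_phantom(spec, sprintf("%s-%02d", lbl, i), lbl)$truth$shell_count,
    0)
  asd <- counts("ASD"); nc <- counts("NC")
  sem <- sqrt(stats::var(asd) / 20 + stats::var(nc) / 20)
  expect_lt(abs(mean(asd) - mean(nc)), 3 * sem)
})

test_that("noise-free shells match the analytic two-ellipsoid voxel counts", {
  spec <- phantom_spec(n_asd = 1, n_control = 1, shape = c(24, 24, 24),
                       effect_size = 2, noise_sd = 0, shape_jitter = 0, seed = 3)
  analytic_count <- function(thick) {
    shape <- spec$shape; axes <- c(0.42, 0.37, 0.32) * shape
    ctr <- (shape - 1) / 2
    grid <- as.matrix(expand.grid(x = 0:(shape[1] - 1), y = 0:(shape[2] - 1),
                                  z = 0:(shape[3] - 1)))
    r_out <- rowSums(sweep(sweep(grid, 2, ctr), 2, axes, "/")^2)
    r_in <- rowSums(sweep(sweep(grid, 2, ctr), 2, axes - thick, "/")^2)
    sum(r_out <= 1 & r_in > 1)
  }
  asd <- make_smri_phantom(spec, "a", "ASD")
  nc <- make_smri_phantom(spec, "b", "NC")
  # rendered shells recovered by thresholding the clean image (the bounded
  # texture cannot cross the 0.75 separating threshold)
  expect_equal(sum(asd$volume$data > 0.75), analytic_count(3.5))
  expect_equal(sum(nc$volume$data > 0.75), analytic_count(1.5))
  expect_equal(sum(asd$volume$data > 0.75) - sum(nc$volume$data > 0.75),
               analytic_count(3.5) - analytic_count(1.5))
})

test_that("atlas block parcellation partitions the brain mask", {
  at1 <- make_atlas(c(16, 16, 16), 1)
  mask <- at1$labels > 0
  expect_true(all(at1$labels[mask] == 1))

  at8 <- make_atlas(c(32, 32, 32), 8)
  counts <- tabulate(at8$labels[at8$labels > 0], 8)
  expect_true(all(counts > 0))
  expect_equal(sum(counts), sum(at8$labels > 0))
  expect_error(make_atlas(c(16, 16, 16), 0), "n_rois")
  expect_error(make_atlas(c(16, 16, 16), 1e6), "exceeds")
})

test_that("functional phantom carries the planted correlation and motion", {
  spec <- phantom_spec(n_asd = 1, n_control = 1, shape = c(16, 16, 16),
                       effect_size = 0.8, noise_sd = 0.1, n_frames = 256,
                       tr = 2, n_rois = 4, seed = 21,
                       motion_spikes = list(list(frame = 10,
                                                 translation = c(2, 0, 0))))
  fm <- make_fmri_phantom(spec, "s1", "ASD")
  # ground-truth FD from the injected parameters
  fd <- framewise_displacement(fm$motion)
  expect_gte(fd[10], 2)
  quiet <- make_fmri_phantom(phantom_spec(n_asd = 1, n_control = 1,
                                          shape = c(16, 16, 16), n_frames = 32,
                                          n_rois = 4, seed = 21), "s1", "NC")
  expect_true(all(framewise_displacement(quiet$motion) == 0))
  # designated pair correlation, recovered from the rendered volume
  s <- roi_timeseries(fm$volume, fm$atlas)
  r12 <- stats::cor(s[, 1], s[, 2])
  expect_lt(abs(r12 - 0.8), 0.1)
  expect_equal(fm$true_fc[1, 2], 0.8)
  ctrl <- make_fmri_phantom(spec, "s2", "NC")
  expect_equal(ctrl$true_fc[1, 2], 0)
  expect_error(make_fmri_phantom(
    phantom_spec(n_frames = 32, motion_spikes = list(list(frame = 99,
                                                          translation = 1:3))),
    "s", "NC"), "out of range")
})

test_that("ROI signals concentrate spectral mass inside the passband", {
  spec <- phantom_spec(n_asd = 1, n_control = 1, shape = c(16, 16, 16),
                       n_frames = 256, tr = 2, n_rois = 4, seed = 13)
  fm <- make_fmri_phantom(spec, "s1", "ASD")
  for (r in 1:4) {
    x <- fm$roi_signals[, r] - mean(fm$roi_signals[, r])
    pw <- Mod(stats::fft(x))^2
    n <- length(x)
    freq <- pmin(0:(n - 1), n - 0:(n - 1)) / (n * spec$tr)
    inband <- freq >= spec$band[1] & freq <= spec$band[2]
    expect_gt(sum(pw[inband]), sum(pw[!inband]))
  }
})

test_that("the morphological class effect is linearly recoverable", {
  spec <- phantom_spec(n_asd = 40, n_control = 40, shape = c(16, 16, 16),
                       effect_size = 2, seed = 31)
  roster <- phantom_roster(spec)
  counts <- vapply(seq_len(nrow(roster)), function(i)
    make_smri_phantom(spec, roster$subject_id[i],
                      roster$label[i])$truth$shell_count, 0)
  y <- as.integer(roster$label == "ASD")
  # one-dimensional linear classifier: threshold at the class-mean midpoint
  thr <- (mean(counts[y == 1]) + mean(counts[y == 0])) / 2
  acc <- mean((counts > thr) == y)
  expect_gte(acc, 0.9)
})

test_that("a phantom cohort can be written to and read back from disk", {
  dir <- withr::local_tempdir()
  spec <- phantom_spec(n_asd = 2, n_control = 2, shape = c(16, 16, 16),
                       n_frames = 32, n_rois = 4, seed = 41)
  roster <- write_phantom_dataset(spec, dir)
  expect_true(all(file.exists(roster$smri_path)))
  expect_true(all(file.exists(roster$fmri_path)))
  expect_true(file.exists(file.path(dir, "roster.csv")))
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_length(truth, 4)
  back <- load_nifti(roster$fmri_path[1])
  expect_equal(dim(back$data)[4], 32)
})
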