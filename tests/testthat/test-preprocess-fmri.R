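test_that("framewise displacement follows the radius-weighted L1 rule", {
  zero <- matrix(0, 5, 6)
  expect_true(all(framewise_displacement(zero) == 0))

  tr_ <- matrix(0, 2, 6)
  tr_[2, ] <- c(1, 1, 1, 0.01, 0.01, 0.01)
  fd <- framewise_displacement(tr_, radius = 50)
  expect_equal(fd[2], 3 + 50 * 0.03)  # 4.5 mm
  # doubling the radius doubles only the rotational term
  fd2 <- framewise_displacement(tr_, radius = 100)
  expect_equal(fd2[2] - fd[2], 50 * 0.03)
  expect_equal(fd[1], 0)
})

test_that("censoring drops exactly the high-motion frames", {
  tr_ <- matrix(0, 10, 6)
  tr_[4, 1] <- 2; tr_[8, 2] <- -1
  fd <- framewise_displacement(tr_)
  expect_equal(censor_frames(fd, Inf), 1:10)
  kept <- censor_frames(fd, 0.5)
  expect_false(any(c(4, 5, 8, 9) %in% kept))  # spike and return frames
  # monotonicity: lowering the threshold never retains more
  ths <- c(5, 2, 1, 0.5)
  ns <- vapply(ths, function(t) length(censor_frames(fd, t)), 0)
  expect_true(all(diff(ns) <= 0))
  expect_error(censor_frames(fd + 10, 0.5), "all frames censored")
  expect_error(censor_frames(fd, 0), "threshold")
})

test_that("the ideal band-pass passes in-band and rejects out-of-band tones", {
  tr <- 2; n <- 256; tt <- (0:(n - 1)) * tr
  amp <- function(x) (max(x) - min(x)) / 2
  inband <- sin(2 * pi * 0.05 * tt)
  outband <- sin(2 * pi * 0.2 * tt)
  expect_gte(amp(bandpass(inband, tr)), 0.95)
  expect_lte(amp(bandpass(outband, tr)), 0.05)
  # DC removal and idempotence
  expect_true(all(abs(bandpass(rep(3, n), tr)) < 1e-12))
  once <- bandpass(inband + outband + 5, tr)
  expect_lt(max(abs(bandpass(once, tr) - once)), 1e-9)
  # Parseval: in-band spectral energy is preserved exactly
  x <- rnorm(n)
  keep <- {
    freq <- pmin(0:(n - 1), n - 0:(n - 1)) / (n * tr)
    freq >= 0.01 & freq <= 0.1
  }
  e_in <- sum(Mod(stats::fft(x))[keep]^2) / n
  y <- bandpass(x, tr)
  expect_lt(abs(sum(y^2) - e_in) / e_in, 1e-9)
  expect_error(bandpass(x, tr, 0.01, 0.5), "Nyquist")
})

test_that("per-frame mean projections average along each anatomical axis", {
  arr <- array(0, dim = c(4, 5, 6, 3))
  arr[, , , 2] <- 7
  v <- volume_image(arr, diag(4), tr = 1)
  pr <- frame_mean_images(v)
  expect_equal(dim(pr$axial), c(3, 4, 5))
  expect_equal(dim(pr$coronal), c(3, 4, 6))
  expect_equal(dim(pr$sagittal), c(3, 5, 6))
  expect_true(all(pr$axial[2, , ] == 7))
  expect_true(all(pr$axial[1, , ] == 0))
  # one-hot along the averaging axis -> v / L
  arr2 <- array(0, dim = c(4, 5, 6, 1))
  arr2[, 2, 3, 1] <- 0  # keep zero elsewhere
  arr2[1, 2, 3, 1] <- 4
  v2 <- volume_image(arr2, diag(4), tr = 1)
  pr2 <- frame_mean_images(v2)
  expect_equal(pr2$sagittal[1, 2, 3], 4 / 4)  # mean over x-line of length 4
})

test_that("ROI averaging matches a brute-force per-voxel loop", {
  lab <- array(0L, dim = c(2, 2, 1))
  lab[1, 1, 1] <- 1L; lab[2, 1, 1] <- 1L; lab[1, 2, 1] <- 2L; lab[2, 2, 1] <- 2L
  atlas <- structure(list(labels = lab, n_rois = 2L), class = "roi_atlas")
  arr <- array(0, dim = c(2, 2, 1, 2))
  arr[1, 1, 1, 1] <- 1; arr[2, 1, 1, 1] <- 3
  v <- volume_image(arr, diag(4), tr = 1)
  s <- roi_timeseries(v, atlas)
  expect_equal(unname(s[1, 1]), 2)

  set.seed(23)
  arr2 <- array(rnorm(8 * 8 * 8 * 16), dim = c(8, 8, 8, 16))
  v2 <- volume_image(arr2, diag(4), tr = 1)
  atl <- make_atlas(c(8, 8, 8), 3, mask = array(TRUE, dim = c(8, 8, 8)))
  s2 <- roi_timeseries(v2, atl)
  oracle <- matrix(0, 16, 3)
  for (t in 1:16) for (r in 1:3) {
    acc <- 0; nn <- 0
    for (i in 1:8) for (j in 1:8) for (k in 1:8)
      if (atl$labels[i, j, k] == r) { acc <- acc + arr2[i, j, k, t]; nn <- nn + 1 }
    oracle[t, r] <- acc / nn
  }
  expect_lt(max(abs(unname(s2) - oracle)), 1e-10)

  # one ROI covering everything = global mean series
  atl1 <- make_atlas(c(8, 8, 8), 1, mask = array(TRUE, dim = c(8, 8, 8)))
  s1 <- roi_timeseries(v2, atl1)
  expect_equal(as.numeric(s1), apply(arr2, 4, mean), tolerance = 1e-12)
})

test_that("connectivity gives exact Pearson/Fisher values and structure", {
  a <- rnorm(20)
  s <- cbind(a, a + 0, -a, rnorm(20))
  fc <- connectivity(s)
  expect_equal(fc$r_mat[1, 2], 1)
  expect_equal(fc$r_mat[1, 3], -1)
  expect_equal(atanh(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fc$z_mat, t(fc$z_mat))
  expect_true(all(diag(fc$z_mat) == 0))
  expect_true(all(diag(fc$r_mat) == 1))
  ev <- eigen(fc$r_mat, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  s_bad <- s; s_bad[, 2] <- 5
  expect_error(connectivity(s_bad), "column 2")
})

test_that("motion estimation recovers injected rigid motion per frame", {
  spec <- phantom_spec(n_asd = 1, n_control = 1, shape = c(16, 16, 16),
                       noise_sd = 0.1, n_frames = 32, n_rois = 4, seed = 29,
                       motion_spikes = list(list(frame = 5,
                                                 translation = c(2, 0, 0))))
  fm <- make_fmri_phantom(spec, "s1", "ASD")
  sub <- volume_image(fm$volume$data[, , , 1:8], fm$volume$affine, tr = 2)
  trace <- estimate_motion(sub)
  expect_true(all(trace[1, ] == 0))  # reference row
  expect_lt(abs(trace[5, 1] - 2), 0.5)
  still <- trace[c(2:4, 6:8), 1:3]
  expect_lt(max(abs(still)), 0.1 * 2 + 1e-9)  # 0.1 voxel of 2 mm
})

test_that("the full functional chain recovers the planted connectivity", {
  spec <- phantom_spec(n_asd = 1, n_control = 1, shape = c(16, 16, 16),
                       effect_size = 0.8, noise_sd = 0.1, n_frames = 64,
                       tr = 2, n_rois = 4, seed = 37,
                       motion_spikes = list(list(frame = 20,
                                                 translation = c(0, 3, 0))))
  fm <- make_fmri_phantom(spec, "s1", "ASD")
  out <- preprocess_fmri(fm$volume, fm$atlas, motion = fm$motion)
  expect_false(20 %in% out$retained)
  z <- out$fc$z_mat
  offdiag <- abs(z[upper.tri(z)])
  expect_gte(abs(z[1, 2]), max(offdiag) - 1e-12)  # planted pair dominates
  expect_equal(nrow(out$S), length(out$retained))
})
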