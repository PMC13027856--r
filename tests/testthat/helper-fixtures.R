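# Shared helpers: numerical gradient checking and small phantom specs.

num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

small_spec <- function(...) {
  phantom_spec(n_asd = 4, n_control = 4, shape = c(16, 16, 16),
               n_frames = 32, n_rois = 4, seed = 99, ...)
}

tiny_smri_cfg <- function(...) {
  smri_config(channel_plan = c(4, 8), kernels = c(3, 3), dilations = c(1, 1),
              ...)
}

tiny_fmri_cfg <- function(...) fmri_config(d_h = 4, latent = 8, ...)

rand_volume <- function(shape = c(8, 8, 8), seed = 1, vox = 1) {
  set.seed(seed)
  volume_image(array(rnorm(prod(shape)), dim = shape), diag(c(rep(vox, 3), 1)))
}
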