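test_that("3D convolution matches identity, counting and brute-force oracles", {
  set.seed(61)
  # identity kernel
  x <- array(rnorm(6^3), dim = c(6, 6, 6, 1))
  w_id <- array(0, dim = c(3, 3, 3, 1, 1)); w_id[2, 2, 2, 1, 1] <- 1
  expect_lt(max(abs(conv3d(x, w_id)$out - x)), 1e-12)
  # all-ones kernel on constant input: interior voxel sums 27
  ones <- array(1, dim = c(5, 5, 5, 1))
  w1 <- array(1, dim = c(3, 3, 3, 1, 1))
  expect_equal(conv3d(ones, w1)$out[3, 3, 3, 1], 27)

  # nested-loop oracle, 20 random instances
  for (trial in 1:20) {
    d <- sample(3:6, 3, replace = TRUE)
    cin <- sample(1:2, 1); cout <- sample(1:2, 1)
    xx <- array(rnorm(prod(d) * cin), dim = c(d, cin))
    ww <- array(rnorm(27 * cin * cout), dim = c(3, 3, 3, cin, cout))
    bb <- rnorm(cout)
    got <- conv3d(xx, ww, bb)$out
    xp <- array(0, dim = c(d + 2, cin))
    xp[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3]), ] <- xx
    want <- array(0, dim = c(d, cout))
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
      for (co in seq_len(cout)) {
        s <- bb[co]
        for (a in 0:2) for (b_ in 0:2) for (cc in 0:2) for (ci in seq_len(cin))
          s <- s + xp[i + a, j + b_, k + cc, ci] * ww[a + 1, b_ + 1, cc + 1, ci, co]
        want[i, j, k, co] <- s
      }
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("dilated convolution equals the zero-inflated kernel and has the right receptive field", {
  set.seed(62)
  x <- array(rnorm(9^3 * 2), dim = c(9, 9, 9, 2))
  w <- array(rnorm(27 * 2 * 2), dim = c(3, 3, 3, 2, 2))
  expect_equal(dilated_conv3d(x, w, d = 1)$out, conv3d(x, w)$out)
  # inflate the kernel to 5^3 with zeros between taps
  w_inf <- array(0, dim = c(5, 5, 5, 2, 2))
  w_inf[c(1, 3, 5), c(1, 3, 5), c(1, 3, 5), , ] <- w
  expect_lt(max(abs(dilated_conv3d(x, w, d = 2)$out - conv3d(x, w_inf)$out)),
            1e-12)
  # impulse response support = (k-1)d + 1 per axis
  imp <- array(0, dim = c(11, 11, 11, 1)); imp[6, 6, 6, 1] <- 1
  wr <- array(rnorm(27), dim = c(3, 3, 3, 1, 1))
  resp <- dilated_conv3d(imp, wr, d = 2)$out[, , , 1]
  nz <- which(resp != 0, arr.ind = TRUE)
  expect_equal(max(nz[, 1]) - min(nz[, 1]) + 1, (3 - 1) * 2 + 1)
})

test_that("spectral normalisation rescales to unit top singular value", {
  set.seed(63)
  w <- array(rnorm(27 * 2 * 4), dim = c(3, 3, 3, 2, 4)) * 4
  sn <- spectral_normalize(w, n_iter = 20)
  sv <- svd(matrix(aperm(sn$w_hat, c(5, 1, 2, 3, 4)), 4))$d[1]
  expect_lt(abs(sv - 1), 1e-3)
  # scale invariance
  sn2 <- spectral_normalize(3 * w, n_iter = 20)
  expect_equal(sn2$w_hat, sn$w_hat, tolerance = 1e-6)
  # an orthogonal matrix is already unit-norm
  q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  snq <- spectral_normalize(q, n_iter = 20)
  expect_equal(as.matrix(snq$w_hat), q, tolerance = 1e-4)
  expect_warning(spectral_normalize(matrix(0, 3, 3)), "all-zero")
})

test_that("statistical normalisation standardises each channel", {
  set.seed(64)
  x <- array(rnorm(4^3 * 3, mean = 2, sd = 3), dim = c(4, 4, 4, 3))
  out <- stat_normalize(x, gamma = rep(1, 3), beta = rep(0, 3))$out
  for (c_ in 1:3) {
    ch <- out[, , , c_]
    expect_lt(abs(mean(ch)), 1e-6)
    expect_lt(abs(mean((ch - mean(ch))^2) - 1), 1e-4)
  }
  # two-voxel channel {0, 2} -> {-1, 1}
  tw <- array(c(0, 2), dim = c(2, 1, 1, 1))
  expect_equal(as.numeric(stat_normalize(tw, 1, 0, eps = 1e-12)$out), c(-1, 1),
               tolerance = 1e-5)
  # beta shifts the mean by exactly beta
  outb <- stat_normalize(x, gamma = rep(1, 3), beta = c(5, -2, 0))$out
  expect_equal(mean(outb[, , , 1]), 5, tolerance = 1e-6)
  # zero-variance channel is eps-stabilised, not an error
  z <- array(1, dim = c(3, 3, 3, 1))
  expect_true(all(is.finite(stat_normalize(z, 1, 0)$out)))
})

test_that("channel attention weights are simplex-valued and selective", {
  set.seed(65)
  # identical channels and symmetric projection -> uniform weights
  base <- array(rnorm(27), dim = c(3, 3, 3))
  x <- array(rep(base, 4), dim = c(3, 3, 3, 4))
  ca <- channel_attention(x, matrix(1, 4, 4))
  expect_equal(ca$alpha, rep(0.25, 4), tolerance = 1e-9)
  # weights sum to one for random inputs
  for (i in 1:5) {
    xr <- array(rnorm(27 * 4), dim = c(3, 3, 3, 4))
    expect_lt(abs(sum(channel_attention(xr, matrix(rnorm(16), 4, 4))$alpha) - 1),
              1e-9)
  }
  # a +10 logit dominates
  wa <- matrix(0, 4, 4); g <- colMeans(matrix(x, 27, 4))
  wa[2, ] <- 10 / sum(g)
  expect_gte(channel_attention(x, wa)$alpha[2], 0.999)
})

test_that("the spatial sigmoid mask scales features within (0, 1)", {
  set.seed(66)
  x <- array(rnorm(4^3 * 2), dim = c(4, 4, 4, 2))
  sa0 <- spatial_attention(x, wm = c(0, 0), bm = 0)
  expect_equal(sa0$out, x / 2, tolerance = 1e-12)
  sa_inf <- spatial_attention(x, wm = c(0, 0), bm = 50)
  expect_equal(sa_inf$out, x, tolerance = 1e-6)
  sar <- spatial_attention(x, wm = rnorm(2), bm = rnorm(1))
  expect_true(all(sar$mask > 0 & sar$mask < 1))
})

test_that("graph propagation follows H' = act(A H W) exactly", {
  h <- diag(2)
  a <- matrix(c(0, 1, 1, 0), 2, 2)
  out <- graph_propagate(h, a, diag(2), act = "identity")$out
  expect_equal(out, matrix(c(0, 1, 1, 0), 2, 2))
  hp <- matrix(abs(rnorm(6)), 3, 2)
  expect_equal(graph_propagate(hp, diag(3), diag(2))$out, hp)
  expect_true(all(graph_propagate(hp, matrix(0, 3, 3), diag(2))$out == 0))
})

test_that("global average pooling and the entropy penalty behave as stated", {
  x <- array(3.5, dim = c(2, 3, 4, 2))
  expect_equal(global_avg_pool(x)$out, c(3.5, 3.5))
  oh <- array(0, dim = c(2, 3, 4, 1)); oh[1, 2, 3, 1] <- 6
  expect_equal(global_avg_pool(oh)$out, 6 / 24)
  set.seed(67)
  f_ <- array(rnorm(24), dim = c(2, 3, 4, 1))
  g_ <- array(rnorm(24), dim = c(2, 3, 4, 1))
  expect_equal(global_avg_pool(2 * f_ + 3 * g_)$out,
               2 * global_avg_pool(f_)$out + 3 * global_avg_pool(g_)$out)

  expect_equal(entropy_penalty(rep(1, 4))$value, log(4), tolerance = 1e-12)
  z <- c(30, 0, 0, 0)
  expect_lt(entropy_penalty(z)$value, 1e-9)
  for (i in 1:1000) {
    h <- entropy_penalty(rnorm(5, sd = 3))$value
    expect_gte(h, 0); expect_lte(h, log(5) + 1e-12)
  }
})

test_that("every layer's analytic gradient matches central differences", {
  set.seed(68)
  x <- array(rnorm(4^3 * 2), dim = c(4, 4, 4, 2))
  w <- array(rnorm(27 * 2 * 3), dim = c(3, 3, 3, 2, 3))
  b <- rnorm(3)
  cv <- conv3d(x, w, b, stride = 2, dilation = 2)
  dout <- array(rnorm(length(cv$out)), dim = dim(cv$out))
  bk <- conv3d_backward(dout, cv$cache)
  expect_lt(max(abs(bk$dx - num_grad(function(xx)
    sum(conv3d(xx, w, b, stride = 2, dilation = 2)$out * dout), x))), 1e-7)
  expect_lt(max(abs(bk$dw - num_grad(function(ww)
    sum(conv3d(x, ww, b, stride = 2, dilation = 2)$out * dout), w))), 1e-7)

  g <- rnorm(2); be <- rnorm(2)
  x2 <- array(rnorm(4^3 * 2), dim = c(4, 4, 4, 2))
  sn <- stat_normalize(x2, g, be)
  d2 <- array(rnorm(length(sn$out)), dim = dim(sn$out))
  sb <- stat_normalize_backward(d2, sn$cache)
  expect_lt(max(abs(sb$dx - num_grad(function(xx)
    sum(stat_normalize(xx, g, be)$out * d2), x2))), 1e-7)

  wa <- matrix(rnorm(4), 2, 2)
  ca <- channel_attention(x2, wa)
  cb <- channel_attention_backward(d2, ca$cache)
  expect_lt(max(abs(cb$dx - num_grad(function(xx)
    sum(channel_attention(xx, wa)$out * d2), x2))), 1e-7)
  expect_lt(max(abs(cb$dwa - num_grad(function(ww)
    sum(channel_attention(x2, ww)$out * d2), wa))), 1e-7)

  wm <- rnorm(2)
  sa <- spatial_attention(x2, wm, 0.2)
  sab <- spatial_attention_backward(d2, sa$cache)
  expect_lt(max(abs(sab$dx - num_grad(function(xx)
    sum(spatial_attention(xx, wm, 0.2)$out * d2), x2))), 1e-7)

  hh <- matrix(rnorm(6), 3, 2)
  aa <- matrix(runif(9), 3, 3); aa <- aa + t(aa); diag(aa) <- 0
  wg <- matrix(rnorm(4), 2, 2)
  gp <- graph_propagate(hh, aa, wg)
  dg <- matrix(rnorm(6), 3, 2)
  gb <- graph_propagate_backward(dg, gp$cache)
  expect_lt(max(abs(gb$dx - num_grad(function(xx)
    sum(graph_propagate(xx, aa, wg)$out * dg), hh))), 1e-7)
  expect_lt(max(abs(gb$dw - num_grad(function(ww)
    sum(graph_propagate(hh, aa, ww)$out * dg), wg))), 1e-7)
})

test_that("the bidirectional LSTM matches a hand-written gate recursion", {
  # independent scalar (d_h = 1) reimplementation of the gate equations
  manual_lstm <- function(x, wx, wh, b, reverse = FALSE) {
    sig <- function(v) 1 / (1 + exp(-v))
    idx <- if (reverse) rev(seq_len(nrow(x))) else seq_len(nrow(x))
    h <- 0; c_ <- 0
    out <- numeric(nrow(x))
    for (t in idx) {
      pre <- drop(x[t, ] %*% wx) + h * wh + b
      i <- sig(pre[1]); f <- sig(pre[2]); g <- tanh(pre[3]); o <- sig(pre[4])
      c_ <- f * c_ + i * g
      h <- o * tanh(c_)
      out[t] <- h
    }
    out
  }
  set.seed(69)
  for (trial in 1:10) {
    tt <- sample(1:3, 1)
    x <- matrix(rnorm(tt * 2), tt, 2)
    pf <- list(wx = matrix(rnorm(8), 2, 4), wh = matrix(rnorm(4), 1, 4),
               b = rnorm(4))
    pb <- list(wx = matrix(rnorm(8), 2, 4), wh = matrix(rnorm(4), 1, 4),
               b = rnorm(4))
    got <- bilstm_encode(x, list(fwd = pf, bwd = pb))$out
    want <- cbind(manual_lstm(x, pf$wx, pf$wh, pf$b),
                  manual_lstm(x, pb$wx, pb$wh, pb$b, reverse = TRUE))
    expect_lt(max(abs(got - want)), 1e-10)
  }
  # zero input, zero parameters -> zero output; width contract
  zp <- list(wx = matrix(0, 2, 8), wh = matrix(0, 2, 8), b = rep(0, 8))
  z <- bilstm_encode(matrix(0, 5, 2), list(fwd = zp, bwd = zp))$out
  expect_true(all(z == 0))
  expect_equal(ncol(z), 2 * 2)
})

test_that("attention pooling is a softmax-weighted convex combination", {
  h1 <- matrix(rnorm(4), 1, 4)
  ap1 <- attention_pool(h1, rnorm(4))
  expect_equal(ap1$out, drop(h1))
  expect_equal(ap1$alpha, 1)

  h <- matrix(rnorm(12), 3, 4)
  ap <- attention_pool(h, rep(0, 4))
  expect_equal(ap$out, colMeans(h), tolerance = 1e-12)
  expect_lt(abs(sum(ap$alpha) - 1), 1e-9)

  # one step dominating by +20 score
  hd <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0))
  w <- c(20, 0, 0, 0)
  apd <- attention_pool(hd, w)
  expect_lt(max(abs(apd$out - hd[1, ])), 1e-6)

  # pooled output lies in the convex hull (coordinate-wise bounds)
  for (i in 1:10) {
    hh <- matrix(rnorm(20), 5, 4)
    z <- attention_pool(hh, rnorm(4))$out
    expect_true(all(z >= apply(hh, 2, min) - 1e-12))
    expect_true(all(z <= apply(hh, 2, max) + 1e-12))
  }
})
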