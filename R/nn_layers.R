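# Neural-network primitives with exact hand-written forward/backward passes.
# Feature maps are 4D arrays [d1, d2, d3, C]; every backward function takes
# the upstream gradient and the forward cache and returns gradients for the
# inputs and parameters. All layers are gradient-checked against central
# differences in the test suite.

conv_out_dim <- function(d, stride) floor((d - 1) / stride) + 1

# reshape conv kernel [k,k,k,cin,cout] to (k^3*cin) x cout, rows ordered
# tap-major then channel, matching the im2col column order below
kernel_matrix <- function(w) {
  k3 <- prod(dim(w)[1:3])
  cin <- dim(w)[4]; cout <- dim(w)[5]
  matrix(aperm(w, c(4, 1, 2, 3, 5)), k3 * cin, cout)
}

kernel_unmatrix <- function(wm, k, cin, cout) {
  aperm(array(wm, dim = c(cin, k, k, k, cout)), c(2, 3, 4, 1, 5))
}

#' 3D convolution (cross-correlation) with zero padding
#'
#' Same-padding cross-correlation: at stride 1 spatial dimensions are
#' preserved; dilation spaces the kernel taps `dilation` voxels apart,
#' giving a receptive field of `(k - 1) * dilation + 1` per axis.
#' Implemented by im2col + matrix product; the unfolded input is cached
#' for the exact backward pass.
#'
#' @param x input array `[d1, d2, d3, cin]`.
#' @param w kernel `[k, k, k, cin, cout]`, `k` odd.
#' @param b bias vector length `cout`.
#' @param stride spatial stride.
#' @param dilation tap spacing (>= 1).
#' @return list with `out` `[o1, o2, o3, cout]` and `cache`.
#' @export
conv3d <- function(x, w, b = NULL, stride = 1, dilation = 1) {
  d <- dim(x); k <- dim(w)[1]; cin <- dim(w)[4]; cout <- dim(w)[5]
  stopifnot(length(d) == 4, d[4] == cin, k %% 2 == 1, dilation >= 1)
  if (is.null(b)) b <- numeric(cout)
  p <- (k - 1) * dilation / 2
  dp <- d[1:3] + 2 * p
  xp <- array(0, dim = c(dp, cin))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3]), ] <- x
  o <- conv_out_dim(d[1:3], stride)
  n <- prod(o)
  xcol <- matrix(0, n, k^3 * cin)
  taps <- expand.grid(a = 0:(k - 1), bb = 0:(k - 1), cc = 0:(k - 1))
  idx_axis <- function(off, oo) seq(1 + off * dilation, by = stride, length.out = oo)
  for (t in seq_len(nrow(taps))) {
    ia <- idx_axis(taps$a[t], o[1]); jb <- idx_axis(taps$bb[t], o[2])
    kc <- idx_axis(taps$cc[t], o[3])
    slab <- xp[ia, jb, kc, , drop = FALSE]
    # column block: channel-major rows of the kernel matrix are (tap, ci),
    # so place this tap's cin columns at positions (ci-1)*k^3 + t
    xcol[, (seq_len(cin) - 1) * k^3 + t] <- matrix(slab, n, cin)
  }
  wm <- matrix(w, k^3 * cin, cout)  # native layout: tap fastest within channel
  out_mat <- xcol %*% wm
  out_mat <- sweep(out_mat, 2, b, "+")
  out <- array(out_mat, dim = c(o, cout))
  list(out = out,
       cache = list(xcol = xcol, wm = wm, dims = d, out_dims = o, k = k,
                    cin = cin, cout = cout, stride = stride,
                    dilation = dilation, pad = p, taps = taps))
}

#' Backward pass of [conv3d()]
#' @param dout upstream gradient `[o1, o2, o3, cout]`.
#' @param cache forward cache.
#' @return list with `dx`, `dw`, `db`.
#' @export
conv3d_backward <- function(dout, cache) {
  ca <- cache
  n <- prod(ca$out_dims)
  dy <- matrix(dout, n, ca$cout)
  dwm <- crossprod(ca$xcol, dy)
  dw <- array(dwm, dim = c(ca$k, ca$k, ca$k, ca$cin, ca$cout))
  db <- colSums(dy)
  dxcol <- tcrossprod(dy, ca$wm)
  dp <- ca$dims[1:3] + 2 * ca$pad
  dxp <- array(0, dim = c(dp, ca$cin))
  idx_axis <- function(off, oo) seq(1 + off * ca$dilation, by = ca$stride,
                                    length.out = oo)
  for (t in seq_len(nrow(ca$taps))) {
    ia <- idx_axis(ca$taps$a[t], ca$out_dims[1])
    jb <- idx_axis(ca$taps$bb[t], ca$out_dims[2])
    kc <- idx_axis(ca$taps$cc[t], ca$out_dims[3])
    block <- array(dxcol[, (seq_len(ca$cin) - 1) * ca$k^3 + t],
                   dim = c(ca$out_dims, ca$cin))
    dxp[ia, jb, kc, ] <- dxp[ia, jb, kc, , drop = FALSE] + block
  }
  sel <- lapply(1:3, function(i) ca$pad + seq_len(ca$dims[i]))
  dx <- dxp[sel[[1]], sel[[2]], sel[[3]], , drop = FALSE]
  list(dx = dx, dw = dw, db = db)
}

#' Dilated 3D convolution
#'
#' Equivalent to [conv3d()] with `dilation = d`; provided as a named
#' entry point mirroring the architecture description.
#'
#' @inheritParams conv3d
#' @param d dilation rate.
#' @export
dilated_conv3d <- function(x, w, b = NULL, d = 1, stride = 1)
  conv3d(x, w, b, stride = stride, dilation = d)

#' Spectral normalisation of a convolution kernel
#'
#' Reshapes the kernel to an `cout x (k^3 cin)` matrix, estimates its
#' largest singular value by power iteration (5 steps, warm-started from a
#' persistent vector), and rescales the kernel to unit spectral norm. An
#' all-zero kernel is returned unchanged with a warning.
#'
#' @param w kernel `[k, k, k, cin, cout]` (or a plain matrix).
#' @param u optional persistent left singular vector estimate.
#' @param n_iter power-iteration steps.
#' @return list with `w_hat`, `sigma`, and updated `u`.
#' @export
spectral_normalize <- function(w, u = NULL, n_iter = 5) {
  dw <- dim(w)
  wm <- if (length(dw) == 5) t(kernel_matrix(w)) else as.matrix(w)
  if (all(wm == 0)) {
    warning("all-zero kernel: spectral normalisation skipped")
    return(list(w_hat = w, sigma = 0, u = u))
  }
  if (is.null(u)) u <- rep(1 / sqrt(nrow(wm)), nrow(wm))
  for (i in seq_len(n_iter)) {
    v <- drop(crossprod(wm, u)); v <- v / sqrt(sum(v^2))
    u <- drop(wm %*% v); u <- u / sqrt(sum(u^2))
  }
  sigma <- drop(t(u) %*% wm %*% v)
  list(w_hat = w / sigma, sigma = sigma, u = u)
}

#' Per-channel statistical normalisation (instance norm)
#'
#' Standardises each channel by its spatial mean and population variance
#' (epsilon-stabilised), then applies the learnable affine
#' `gamma * xhat + beta`.
#'
#' @param x feature map `[d1, d2, d3, C]`.
#' @param gamma,beta length-C affine parameters.
#' @param eps stabiliser.
#' @return list with `out` and `cache`.
#' @export
stat_normalize <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); n <- prod(d[1:3]); cc <- d[4]
  xm <- matrix(x, n, cc)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc^2)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv_sd, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = array(y, dim = d),
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma, n = n, d = d))
}

#' @rdname stat_normalize
#' @param dout upstream gradient.
#' @param cache forward cache.
#' @export
stat_normalize_backward <- function(dout, cache) {
  ca <- cache
  dy <- matrix(dout, ca$n, length(ca$gamma))
  dgamma <- colSums(dy * ca$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, ca$gamma, "*")
  # dx = inv_sd/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat * xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * ca$xhat)
  dx <- sweep(ca$n * dxhat, 2, s1) - sweep(ca$xhat, 2, s2, "*")
  dx <- sweep(dx, 2, ca$inv_sd / ca$n, "*")
  list(dx = array(dx, dim = ca$d), dgamma = dgamma, dbeta = dbeta)
}

relu <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(dout, cache) dout * cache

#' Gaussian Error Linear Unit
#' @param x numeric array.
#' @return list with `out` and `cache` (exact `x * pnorm(x)` form).
#' @export
gelu <- function(x) list(out = x * stats::pnorm(x), cache = x)
gelu_backward <- function(dout, cache)
  dout * (stats::pnorm(cache) + cache * stats::dnorm(cache))

#' Channel attention by softmax-normalised projection of pooled features
#'
#' Per-channel global average pooling `g(F)` is projected by a learnable
#' `C x C` matrix and softmax-normalised into weights `alpha` (summing to
#' one); each channel is rescaled by its weight.
#'
#' @param x feature map `[d1, d2, d3, C]`.
#' @param wa projection matrix `C x C` (row c holds w_c).
#' @return list with `out`, `alpha`, `cache`.
#' @export
channel_attention <- function(x, wa) {
  d <- dim(x); n <- prod(d[1:3]); cc <- d[4]
  xm <- matrix(x, n, cc)
  g <- colMeans(xm)
  logits <- drop(wa %*% g)
  alpha <- softmax_vec(logits)
  y <- sweep(xm, 2, alpha, "*")
  list(out = array(y, dim = d), alpha = alpha,
       cache = list(xm = xm, g = g, alpha = alpha, wa = wa, n = n, d = d))
}

#' @rdname channel_attention
#' @param dout upstream gradient.
#' @param cache forward cache.
#' @export
channel_attention_backward <- function(dout, cache) {
  ca <- cache
  dy <- matrix(dout, ca$n, length(ca$alpha))
  dalpha <- colSums(dy * ca$xm)
  dx <- sweep(dy, 2, ca$alpha, "*")
  dlogits <- ca$alpha * (dalpha - sum(ca$alpha * dalpha))
  dwa <- outer(dlogits, ca$g)
  dg <- drop(crossprod(ca$wa, dlogits))
  dx <- dx + matrix(dg / ca$n, ca$n, length(ca$alpha), byrow = TRUE)
  list(dx = array(dx, dim = ca$d), dwa = dwa)
}

#' Spatial attention by a 3D sigmoid mask
#'
#' Mask logits are a learnable 1x1x1 projection of the channels at each
#' voxel; the sigmoid mask (strictly in (0,1)) multiplies every channel.
#'
#' @param x feature map `[d1, d2, d3, C]`.
#' @param wm length-C projection weights.
#' @param bm scalar bias.
#' @return list with `out`, `mask`, `cache`.
#' @export
spatial_attention <- function(x, wm, bm = 0) {
  d <- dim(x); n <- prod(d[1:3]); cc <- d[4]
  xm <- matrix(x, n, cc)
  logits <- drop(xm %*% wm) + bm
  m <- sigmoid(logits)
  y <- xm * m
  list(out = array(y, dim = d), mask = array(m, dim = d[1:3]),
       cache = list(xm = xm, m = m, wm = wm, d = d))
}

#' @rdname spatial_attention
#' @param dout upstream gradient.
#' @param cache forward cache.
#' @export
spatial_attention_backward <- function(dout, cache) {
  ca <- cache
  dy <- matrix(dout, nrow(ca$xm), ncol(ca$xm))
  dm <- rowSums(dy * ca$xm)
  dlogits <- dm * ca$m * (1 - ca$m)
  dx <- dy * ca$m + outer(dlogits, ca$wm)
  dwm <- drop(crossprod(ca$xm, dlogits))
  dbm <- sum(dlogits)
  list(dx = array(dx, dim = ca$d), dwm = dwm, dbm = dbm)
}

#' Graph feature propagation `H' = act(A H W)`
#'
#' One propagation layer over ROI-level node embeddings, exactly as the
#' printed rule: no added self-loops and no degree normalisation.
#'
#' @param h node features `n x d_in`.
#' @param a adjacency `n x n` (symmetric, non-negative).
#' @param w weight matrix `d_in x d_out`.
#' @param act `"relu"` or `"identity"`.
#' @return list with `out` and `cache`.
#' @export
graph_propagate <- function(h, a, w, act = c("relu", "identity")) {
  act <- match.arg(act)
  stopifnot(ncol(a) == nrow(h), ncol(h) == nrow(w))
  z <- a %*% h %*% w
  out <- if (act == "relu") pmax(z, 0) else z
  list(out = out, cache = list(h = h, a = a, w = w, z = z, act = act))
}

#' @rdname graph_propagate
#' @param dout upstream gradient.
#' @param cache forward cache.
#' @export
graph_propagate_backward <- function(dout, cache) {
  ca <- cache
  dz <- if (ca$act == "relu") dout * (ca$z > 0) else dout
  dh <- t(ca$a) %*% dz %*% t(ca$w)
  dw <- t(ca$h) %*% t(ca$a) %*% dz
  list(dx = dh, dw = dw)
}

#' Global average pooling over the spatial dimensions
#' @param x feature map `[d1, d2, d3, C]`.
#' @return list with `out` (length-C vector) and `cache`.
#' @export
global_avg_pool <- function(x) {
  d <- dim(x); n <- prod(d[1:3])
  list(out = colMeans(matrix(x, n, d[4])), cache = d)
}

#' @rdname global_avg_pool
#' @param dout upstream gradient (length C).
#' @param cache forward cache.
#' @export
global_avg_pool_backward <- function(dout, cache) {
  d <- cache; n <- prod(d[1:3])
  array(matrix(dout / n, n, d[4], byrow = TRUE), dim = d)
}

#' Shannon entropy of the softmax of an embedding, in nats
#'
#' The compactness regulariser added to the training loss: uniform
#' embeddings attain the maximum `log d`, one-hot-like embeddings approach
#' zero.
#'
#' @param z numeric vector (length >= 2).
#' @return list with `value` (nats) and `grad` (d value / d z).
#' @export
entropy_penalty <- function(z) {
  stopifnot(length(z) >= 2)
  logp <- z - logsumexp(z)
  p <- exp(logp)
  h <- -sum(p * logp)
  list(value = h, grad = -p * (logp + h))
}

# dense layer on a row vector
dense <- function(x, w, b) {
  list(out = drop(x %*% w) + b, cache = list(x = x, w = w))
}
dense_backward <- function(dout, cache) {
  list(dx = drop(cache$w %*% dout), dw = outer(drop(cache$x), dout), db = dout)
}

#' Layer normalisation of a feature vector
#'
#' Zero mean and unit population variance across the features of one
#' sample, followed by the learnable affine `gain * u + bias`.
#'
#' @param f numeric vector.
#' @param gain,bias affine parameters (same length as `f`).
#' @param eps stabiliser.
#' @return list with `out` and `cache`.
#' @export
layer_norm <- function(f, gain, bias, eps = 1e-5) {
  mu <- mean(f)
  v <- mean((f - mu)^2)
  inv_sd <- 1 / sqrt(v + eps)
  u <- (f - mu) * inv_sd
  list(out = gain * u + bias,
       cache = list(u = u, inv_sd = inv_sd, gain = gain, n = length(f)))
}

#' @rdname layer_norm
#' @param dout upstream gradient.
#' @param cache forward cache.
#' @export
layer_norm_backward <- function(dout, cache) {
  ca <- cache
  dgain <- dout * ca$u
  dbias <- dout
  du <- dout * ca$gain
  n <- ca$n
  dx <- (ca$inv_sd / n) * (n * du - sum(du) - ca$u * sum(du * ca$u))
  list(dx = dx, dgain = dgain, dbias = dbias)
}

# inverted dropout; caller controls the RNG stream
dropout <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, cache = NULL))
  mask <- (stats::runif(length(x)) >= p) / (1 - p)
  list(out = x * mask, cache = mask)
}
dropout_backward <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

# ---- LSTM ----------------------------------------------------------------

#' Initialise one LSTM direction
#'
#' Gate weights are stacked input, forget, cell and output blocks of
#' width `d_h` each (`wx`: `d_in x 4 d_h`, `wh`: `d_h x 4 d_h`, `b`).
#'
#' @param d_in input width.
#' @param d_h hidden width.
#' @param seed,key seeded-initialisation keys.
#' @return parameter list with `wx`, `wh`, `b`.
#' @export
lstm_init <- function(d_in, d_h, seed = 1, key = "lstm") {
  with_substream(seed, key, expr = {
    sc <- sqrt(1 / d_in)
    list(wx = matrix(stats::runif(d_in * 4 * d_h, -sc, sc), d_in, 4 * d_h),
         wh = matrix(stats::runif(d_h * 4 * d_h, -sc, sc), d_h, 4 * d_h),
         b = numeric(4 * d_h))
  })
}

lstm_cell <- function(x, h_prev, c_prev, p) {
  d_h <- length(h_prev)
  pre <- drop(x %*% p$wx) + drop(h_prev %*% p$wh) + p$b
  i <- sigmoid(pre[1:d_h])
  f <- sigmoid(pre[d_h + 1:d_h])
  g <- tanh(pre[2 * d_h + 1:d_h])
  o <- sigmoid(pre[3 * d_h + 1:d_h])
  c_t <- f * c_prev + i * g
  tc <- tanh(c_t)
  h_t <- o * tc
  list(h = h_t, c = c_t,
       cache = list(x = x, h_prev = h_prev, c_prev = c_prev,
                    i = i, f = f, g = g, o = o, c_t = c_t, tc = tc))
}

lstm_cell_backward <- function(dh, dc, cache, p) {
  ca <- cache
  do_ <- dh * ca$tc
  dc_t <- dc + dh * ca$o * (1 - ca$tc^2)
  di <- dc_t * ca$g
  df <- dc_t * ca$c_prev
  dg <- dc_t * ca$i
  dc_prev <- dc_t * ca$f
  dpre <- c(di * ca$i * (1 - ca$i),
            df * ca$f * (1 - ca$f),
            dg * (1 - ca$g^2),
            do_ * ca$o * (1 - ca$o))
  list(dx = drop(p$wx %*% dpre),
       dh_prev = drop(p$wh %*% dpre),
       dc_prev = dc_prev,
       dwx = outer(drop(ca$x), dpre),
       dwh = outer(drop(ca$h_prev), dpre),
       db = dpre)
}

# one-directional LSTM over a T x d_in sequence; returns T x d_h outputs
lstm_run <- function(x, p, reverse = FALSE) {
  tt <- nrow(x); d_h <- nrow(p$wh)
  order_idx <- if (reverse) rev(seq_len(tt)) else seq_len(tt)
  h <- numeric(d_h); c_ <- numeric(d_h)
  out <- matrix(0, tt, d_h)
  caches <- vector("list", tt)
  for (pos in seq_len(tt)) {
    t <- order_idx[pos]
    step <- lstm_cell(x[t, , drop = FALSE], h, c_, p)
    h <- step$h; c_ <- step$c
    out[t, ] <- h
    caches[[pos]] <- step$cache
  }
  list(out = out, caches = caches, order_idx = order_idx)
}

lstm_run_backward <- function(dout, run, p) {
  tt <- nrow(dout); d_h <- ncol(dout)
  dwx <- p$wx * 0; dwh <- p$wh * 0; db <- p$b * 0
  dx <- matrix(0, tt, nrow(p$wx))
  dh_next <- numeric(d_h); dc_next <- numeric(d_h)
  for (pos in rev(seq_len(tt))) {
    t <- run$order_idx[pos]
    g <- lstm_cell_backward(dout[t, ] + dh_next, dc_next, run$caches[[pos]], p)
    dx[t, ] <- g$dx
    dh_next <- g$dh_prev; dc_next <- g$dc_prev
    dwx <- dwx + g$dwx; dwh <- dwh + g$dwh; db <- db + g$db
  }
  list(dx = dx, dwx = dwx, dwh = dwh, db = db)
}

#' Bidirectional LSTM encoding of a temporal sequence
#'
#' Runs independent forward and backward LSTMs over the projected time
#' series and concatenates their per-step hidden states, giving a
#' `T x 2 d_h` output.
#'
#' @param h input sequence `T x d_in`.
#' @param params list with `fwd` and `bwd` LSTM parameter sets
#'   (see the gate layout in the package vignette).
#' @return list with `out` (`T x 2 d_h`) and `cache`.
#' @export
bilstm_encode <- function(h, params) {
  fw <- lstm_run(h, params$fwd, reverse = FALSE)
  bw <- lstm_run(h, params$bwd, reverse = TRUE)
  list(out = cbind(fw$out, bw$out), cache = list(fw = fw, bw = bw))
}

#' @rdname bilstm_encode
#' @param dout upstream gradient `T x 2 d_h`.
#' @param cache forward cache.
#' @param params parameter list used in the forward pass.
#' @export
bilstm_encode_backward <- function(dout, cache, params) {
  d_h <- ncol(dout) / 2
  gf <- lstm_run_backward(dout[, 1:d_h, drop = FALSE], cache$fw, params$fwd)
  gb <- lstm_run_backward(dout[, d_h + 1:d_h, drop = FALSE], cache$bw, params$bwd)
  list(dx = gf$dx + gb$dx,
       dfwd = list(wx = gf$dwx, wh = gf$dwh, b = gf$db),
       dbwd = list(wx = gb$dwx, wh = gb$dwh, b = gb$db))
}

#' Attention pooling over time steps
#'
#' Scores each hidden state by `w' h_t`, softmax-normalises the scores
#' into simplex weights, and returns the weighted sum — a point in the
#' convex hull of the hidden states.
#'
#' @param h hidden states `T x D`.
#' @param w score vector length D.
#' @return list with `out` (length D), `alpha`, `cache`.
#' @export
attention_pool <- function(h, w) {
  scores <- drop(h %*% w)
  alpha <- softmax_vec(scores)
  z <- drop(crossprod(h, alpha))
  list(out = z, alpha = alpha, cache = list(h = h, w = w, alpha = alpha))
}

#' @rdname attention_pool
#' @param dout upstream gradient (length D).
#' @param cache forward cache.
#' @export
attention_pool_backward <- function(dout, cache) {
  ca <- cache
  dh <- outer(ca$alpha, dout)
  dalpha <- drop(ca$h %*% dout)
  dscores <- ca$alpha * (dalpha - sum(ca$alpha * dalpha))
  dh <- dh + outer(dscores, ca$w)
  dw <- drop(crossprod(ca$h, dscores))
  list(dx = dh, dw = dw)
}

# seeded uniform fan-in initialisers
init_mat <- function(nr, nc, seed, key) {
  with_substream(seed, key, expr = {
    sc <- sqrt(6 / nr)
    matrix(stats::runif(nr * nc, -sc, sc), nr, nc)
  })
}

init_kernel <- function(k, cin, cout, seed, key) {
  with_substream(seed, key, expr = {
    fan_in <- k^3 * cin
    sc <- sqrt(6 / fan_in)
    array(stats::runif(k^3 * cin * cout, -sc, sc), dim = c(k, k, k, cin, cout))
  })
}
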