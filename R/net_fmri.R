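# Temporal (fMRI) branch: ROI-series projection, bidirectional LSTM with
# attention pooling, functional-connectivity fusion, cross-modality fusion,
# and the shared MLP classifier head.

#' Configuration of the functional (temporal) branch
#'
#' @param d_h hidden width shared by the temporal projection and each LSTM
#'   direction (default 128; scale down for desk-size runs).
#' @param latent width of the shared latent space for `f_seq` and the
#'   projected connectivity vector.
#' @param fc_in_concat which connectivity vector enters the joint
#'   representation: `"raw"` (the packed Fisher-z upper triangle, as the
#'   joint-representation rule prints it) or `"projected"`.
#' @return list of class `fmri_config`.
#' @export
fmri_config <- function(d_h = 128, latent = 256,
                        fc_in_concat = c("raw", "projected")) {
  structure(list(d_h = d_h, latent = latent,
                 fc_in_concat = match.arg(fc_in_concat)),
            class = "fmri_config")
}

# width of f_concat for R ROIs under this config
fmri_concat_dim <- function(config, n_rois) {
  npair <- n_rois * (n_rois - 1) / 2
  fcw <- if (config$fc_in_concat == "raw") npair else config$latent
  2 * config$latent + fcw
}

#' Initialise the functional branch parameters
#' @param config an [fmri_config()].
#' @param n_rois number of atlas ROIs (columns of the time-series matrix).
#' @param seed initialisation seed.
#' @return nested parameter list.
#' @export
fmri_init <- function(config, n_rois, seed = 1) {
  d_h <- config$d_h
  npair <- n_rois * (n_rois - 1) / 2
  list(wp = init_mat(n_rois, d_h, seed, "fmri.proj"),
       bp = numeric(d_h),
       lstm = list(fwd = lstm_init(d_h, d_h, seed, "fmri.lstm.f"),
                   bwd = lstm_init(d_h, d_h, seed, "fmri.lstm.b")),
       w_att = drop(init_mat(2 * d_h, 1, seed, "fmri.att")),
       wf = init_mat(2 * d_h, config$latent, seed, "fmri.seq"),
       bf = numeric(config$latent),
       wfc = init_mat(npair, config$latent, seed, "fmri.fc"),
       bfc = numeric(config$latent))
}

#' Project the ROI time series into a lower-dimensional temporal embedding
#'
#' Row-wise affine map `H = S Wp + bp`.
#'
#' @param s `T x R` ROI time-series matrix.
#' @param wp `R x d_h` projection weights.
#' @param bp length-`d_h` bias.
#' @return `T x d_h` matrix.
#' @export
temporal_project <- function(s, wp, bp) {
  stopifnot(ncol(s) == nrow(wp))
  sweep(s %*% wp, 2, bp, "+")
}

#' Pack a symmetric connectivity matrix into its upper-triangle vector
#'
#' Row-major upper triangle excluding the diagonal, length `R(R-1)/2`.
#' Excluding the diagonal avoids duplicated information and the infinite
#' Fisher-z diagonal.
#'
#' @param z_mat symmetric `R x R` matrix.
#' @return numeric vector of length `R(R-1)/2`.
#' @export
fc_vectorize <- function(z_mat) {
  z_mat <- as.matrix(z_mat)
  r <- nrow(z_mat)
  if (!isSymmetric(unname(z_mat), tol = 1e-8)) stop("connectivity matrix must be symmetric")
  unlist(lapply(seq_len(r - 1), function(i) z_mat[i, (i + 1):r]))
}

#' Unpack an upper-triangle vector into a symmetric matrix
#' @param v vector of length `R(R-1)/2`.
#' @param diag_value value placed on the diagonal (default 0).
#' @return symmetric `R x R` matrix.
#' @export
fc_unvectorize <- function(v, diag_value = 0) {
  r <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (r != round(r)) stop("length is not R(R-1)/2 for integer R")
  m <- matrix(diag_value, r, r)
  pos <- 0
  for (i in seq_len(r - 1)) {
    m[i, (i + 1):r] <- v[pos + seq_len(r - i)]
    pos <- pos + r - i
  }
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Forward pass of the functional branch
#'
#' Temporal projection, bidirectional LSTM, attention pooling, ReLU
#' sequence transform, connectivity projection, elementwise
#' cross-interaction, and concatenation into the joint representation
#' `[f_seq, f_fc, f_cross]`.
#'
#' @param params [fmri_init()] parameters.
#' @param config [fmri_config()].
#' @param s `T x R` (filtered, censored) ROI time-series matrix.
#' @param fc_vec packed Fisher-z connectivity vector ([fc_vectorize()]).
#' @return list with `f_concat`, components (`f_seq`, `f_fc_proj`,
#'   `f_cross`, `alpha`), and `cache`.
#' @export
fmri_forward <- function(params, config, s, fc_vec) {
  h <- temporal_project(s, params$wp, params$bp)
  bl <- bilstm_encode(h, params$lstm)
  ap <- attention_pool(bl$out, params$w_att)
  fs_pre <- dense(matrix(ap$out, 1), params$wf, params$bf)
  fs_act <- relu(fs_pre$out)
  f_seq <- fs_act$out
  fc_pre <- dense(matrix(fc_vec, 1), params$wfc, params$bfc)
  f_fc_proj <- fc_pre$out
  f_cross <- f_seq * f_fc_proj
  f_fc_used <- if (config$fc_in_concat == "raw") fc_vec else f_fc_proj
  f_concat <- c(f_seq, f_fc_used, f_cross)
  list(f_concat = f_concat, f_seq = f_seq, f_fc_proj = f_fc_proj,
       f_cross = f_cross, alpha = ap$alpha,
       cache = list(s = s, h = h, bl = bl$cache, ap = ap$cache,
                    fs_pre = fs_pre$cache, fs_act = fs_act$cache,
                    fc_pre = fc_pre$cache, f_seq = f_seq,
                    f_fc_proj = f_fc_proj, fc_vec = fc_vec))
}

#' Backward pass of the functional branch
#' @param dconcat gradient with respect to `f_concat`.
#' @param fwd the [fmri_forward()] result.
#' @param params,config as in the forward pass.
#' @return parameter gradient tree (same shape as [fmri_init()]).
#' @export
fmri_backward <- function(dconcat, fwd, params, config) {
  ca <- fwd$cache
  nl <- config$latent
  d_fs <- dconcat[seq_len(nl)]
  fcw <- length(dconcat) - 2 * nl
  d_fc_used <- dconcat[nl + seq_len(fcw)]
  d_cross <- dconcat[nl + fcw + seq_len(nl)]
  d_fseq <- d_fs + d_cross * ca$f_fc_proj
  d_fcproj <- d_cross * ca$f_seq
  if (config$fc_in_concat == "projected") d_fcproj <- d_fcproj + d_fc_used
  gfc <- dense_backward(d_fcproj, ca$fc_pre)
  d_fs_pre <- relu_backward(d_fseq, ca$fs_act)
  gfs <- dense_backward(d_fs_pre, ca$fs_pre)
  gap_ <- attention_pool_backward(gfs$dx, ca$ap)
  gbl <- bilstm_encode_backward(gap_$dx, ca$bl, params$lstm)
  dh <- gbl$dx
  dwp <- crossprod(ca$s, dh)
  dbp <- colSums(dh)
  list(wp = dwp, bp = dbp,
       lstm = list(fwd = gbl$dfwd, bwd = gbl$dbwd),
       w_att = gap_$dw, wf = gfs$dw, bf = gfs$db,
       wfc = gfc$dw, bfc = gfc$db)
}

# ---- cross-modality fusion ----------------------------------------------

#' Initialise cross-modality fusion parameters
#' @param d_smri,d_fmri widths of the two branch representations.
#' @param common shared projection width.
#' @param seed initialisation seed.
#' @return parameter list.
#' @export
fuse_init <- function(d_smri, d_fmri, common = 256, seed = 1) {
  list(ws = init_mat(d_smri, common, seed, "fuse.s"), bs = numeric(common),
       wf = init_mat(d_fmri, common, seed, "fuse.f"), bf = numeric(common))
}

#' Cross-modality fusion of the two branch representations
#'
#' Both embeddings are projected to a common width and combined as
#' `[proj_s, proj_f, proj_s * proj_f]` — the same
#' interaction-plus-concatenation pattern used inside the functional
#' branch, lifted to the modality level. The fused width is three times
#' the common width.
#'
#' @param params [fuse_init()] parameters.
#' @param z_smri structural embedding.
#' @param f_concat functional joint representation.
#' @return list with `fused` and `cache`.
#' @export
cross_modality_fuse <- function(params, z_smri, f_concat) {
  if (is.null(z_smri) || is.null(f_concat))
    stop("fusion requires both modality representations")
  ps <- dense(matrix(z_smri, 1), params$ws, params$bs)
  pf <- dense(matrix(f_concat, 1), params$wf, params$bf)
  fused <- c(ps$out, pf$out, ps$out * pf$out)
  list(fused = fused,
       cache = list(ps = ps, pf = pf))
}

#' @rdname cross_modality_fuse
#' @param dfused upstream gradient.
#' @param fwd forward result.
#' @export
cross_modality_fuse_backward <- function(dfused, fwd) {
  ca <- fwd$cache
  m <- length(ca$ps$out)
  dps <- dfused[seq_len(m)] + dfused[2 * m + seq_len(m)] * ca$pf$out
  dpf <- dfused[m + seq_len(m)] + dfused[2 * m + seq_len(m)] * ca$ps$out
  gs <- dense_backward(dps, ca$ps$cache)
  gf <- dense_backward(dpf, ca$pf$cache)
  list(dz_smri = gs$dx, df_concat = gf$dx,
       grads = list(ws = gs$dw, bs = gs$db, wf = gf$dw, bf = gf$db))
}

# ---- shared classifier head ----------------------------------------------

#' Initialise the shared MLP classifier head
#'
#' Layer normalisation, a 256-unit GELU dense layer, dropout (p = 0.5,
#' training only), and a linear map to two diagnostic-class logits.
#'
#' @param d input feature width.
#' @param hidden hidden width (default 256).
#' @param seed initialisation seed.
#' @return parameter list.
#' @export
head_init <- function(d, hidden = 256, seed = 1) {
  list(ln_gain = rep(1, d), ln_bias = numeric(d),
       w1 = init_mat(d, hidden, seed, "head.w1"), b1 = numeric(hidden),
       w2 = init_mat(hidden, 2, seed, "head.w2"), b2 = numeric(2))
}

#' Classifier head forward pass
#'
#' @param params [head_init()] parameters.
#' @param f input feature vector.
#' @param training enable dropout (p = `dropout_p`); softmax probabilities
#'   are computed externally from the returned logits.
#' @param dropout_p dropout probability.
#' @return list with `logits` (length 2), `prob` (softmax of the logits),
#'   and `cache`.
#' @export
classifier_head <- function(params, f, training = FALSE, dropout_p = 0.5) {
  ln <- layer_norm(f, params$ln_gain, params$ln_bias)
  d1 <- dense(matrix(ln$out, 1), params$w1, params$b1)
  g1 <- gelu(d1$out)
  dr <- dropout(g1$out, dropout_p, training)
  d2 <- dense(matrix(dr$out, 1), params$w2, params$b2)
  list(logits = d2$out, prob = softmax_vec(d2$out),
       cache = list(ln = ln$cache, d1 = d1$cache, g1 = g1$cache,
                    dr = dr$cache, d2 = d2$cache))
}

#' @rdname classifier_head
#' @param dlogits gradient with respect to the logits.
#' @param fwd forward result.
#' @export
classifier_head_backward <- function(dlogits, fwd, params) {
  ca <- fwd$cache
  g2 <- dense_backward(dlogits, ca$d2)
  ddr <- dropout_backward(g2$dx, ca$dr)
  dg1 <- gelu_backward(ddr, ca$g1)
  g1 <- dense_backward(dg1, ca$d1)
  gl <- layer_norm_backward(g1$dx, ca$ln)
  list(dx = gl$dx,
       grads = list(ln_gain = gl$dgain, ln_bias = gl$dbias,
                    w1 = g1$dw, b1 = g1$db, w2 = g2$dw, b2 = g2$db))
}

# ---- elementary fusion operations (exposed for direct use) ---------------

#' Nonlinear transform of the pooled sequence embedding
#' @param z_seq pooled sequence embedding.
#' @param wf,bf affine parameters.
#' @return `ReLU(Wf' z_seq + bf)`, a non-negative vector.
#' @export
seq_transform <- function(z_seq, wf, bf) pmax(drop(matrix(z_seq, 1) %*% wf) + bf, 0)

#' Affine projection of the packed connectivity vector into the latent space
#' @param f_fc packed connectivity vector.
#' @param wfc,bfc affine parameters.
#' @return projected vector.
#' @export
fc_project <- function(f_fc, wfc, bfc) drop(matrix(f_fc, 1) %*% wfc) + bfc

#' Elementwise cross-interaction of sequence and connectivity features
#' @param f_seq,f_fc_proj equal-width vectors.
#' @return Hadamard product.
#' @export
cross_interaction <- function(f_seq, f_fc_proj) {
  if (length(f_seq) != length(f_fc_proj)) stop("width mismatch")
  f_seq * f_fc_proj
}

#' Concatenate sequence, connectivity and interaction features
#' @param f_seq,f_fc,f_cross component vectors.
#' @return `c(f_seq, f_fc, f_cross)` in that order.
#' @export
concat_features <- function(f_seq, f_fc, f_cross) {
  stopifnot(all(is.finite(f_seq)), all(is.finite(f_fc)), all(is.finite(f_cross)))
  c(f_seq, f_fc, f_cross)
}
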