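# Model fitting surface: seeded minibatch training with Adam, focal loss /
# cross-entropy, optional Mixup, subject-leakage guard, and S3 methods for
# the fitted model.

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  params <- tree_map(function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
                     params, state$m, state$v)
  list(params = params, state = state)
}

#' Training configuration
#'
#' @param loss `"focal"` (alpha_t = 0.25, gamma = 2) or `"ce"`.
#' @param alpha_t,gamma focal-loss parameters.
#' @param mixup enable Mixup; `mixup_a` is the Beta(a, a) parameter
#'   (default 0.2).
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param seed seed governing initialisation, shuffling, dropout and Mixup.
#' @param dropout_p classifier-head dropout probability.
#' @param lambda_ent entropy-penalty weight (structural branch).
#' @return list of class `train_config`.
#' @export
train_config <- function(loss = c("focal", "ce"), alpha_t = 0.25, gamma = 2,
                         mixup = FALSE, mixup_a = 0.2, lr = 1e-4,
                         batch_size = 16, epochs = 30, seed = 1,
                         dropout_p = 0.5, lambda_ent = 1e-3) {
  stopifnot(gamma >= 0, alpha_t > 0, alpha_t <= 1)
  structure(list(loss = match.arg(loss), alpha_t = alpha_t, gamma = gamma,
                 mixup = mixup, mixup_a = mixup_a, lr = lr,
                 batch_size = batch_size, epochs = epochs, seed = seed,
                 dropout_p = dropout_p, lambda_ent = lambda_ent),
            class = "train_config")
}

# forward to logits for one sample; returns logits + caches for backward
model_forward <- function(model, xi, training = FALSE) {
  md <- model$modality
  smf <- fmf <- fuf <- NULL
  if (md %in% c("smri", "fused")) {
    smf <- smri_forward(model$params$smri, model$smri_cfg, xi$mvt,
                        sn_state = model$sn_state)
    feat <- smf$z
  }
  if (md %in% c("fmri", "fused")) {
    fmf <- fmri_forward(model$params$fmri, model$fmri_cfg, xi$S, xi$fc_vec)
    feat <- fmf$f_concat
  }
  if (md == "fused") {
    fuf <- cross_modality_fuse(model$params$fuse, smf$z, fmf$f_concat)
    feat <- fuf$fused
  }
  hd <- classifier_head(model$params$head, feat, training = training,
                        dropout_p = model$config$dropout_p)
  list(logits = hd$logits, prob = hd$prob, head = hd, smri = smf, fmri = fmf,
       fuse = fuf)
}

model_backward <- function(model, fwd, dlogits) {
  hb <- classifier_head_backward(dlogits, fwd$head, model$params$head)
  grads <- list()
  dfeat <- hb$dx
  md <- model$modality
  if (md == "fused") {
    fb <- cross_modality_fuse_backward(dfeat, fwd$fuse)
    grads$fuse <- fb$grads
    dz_smri <- fb$dz_smri
    df_concat <- fb$df_concat
  } else {
    dz_smri <- df_concat <- dfeat
  }
  if (md %in% c("smri", "fused")) {
    lam <- model$config$lambda_ent
    dz <- dz_smri + lam * fwd$smri$entropy_grad
    grads$smri <- smri_backward(dz, fwd$smri, model$params$smri, model$smri_cfg)
  }
  if (md %in% c("fmri", "fused"))
    grads$fmri <- fmri_backward(df_concat, fwd$fmri, model$params$fmri,
                                model$fmri_cfg)
  grads$head <- hb$grads
  grads[names(model$params)]
}

#' Fit a multi-view dual-modal brain MRI classifier
#'
#' Trains the structural branch, the functional branch, or their
#' cross-modality fusion on per-subject inputs with seeded minibatch Adam.
#' Training refuses to start if any subject id appears in both the
#' training set and the supplied validation set (subject leakage).
#'
#' @param x list of per-subject inputs. Each element is a list with,
#'   depending on the modality, `mvt` (a `multiview_tensor`) and/or `S`
#'   (T x R ROI series) plus `fc_vec` (packed connectivity vector).
#' @param y class labels (`"ASD"` / `"NC"` character or factor).
#' @param modality `"smri"`, `"fmri"` or `"fused"`.
#' @param smri_cfg an [smri_config()] (structural/fused modality).
#' @param fmri_cfg an [fmri_config()] (functional/fused modality).
#' @param config a [train_config()].
#' @param subject_ids optional per-sample subject identifiers (leakage
#'   guard and subject-level evaluation).
#' @param val optional validation list `list(x =, y =, subject_ids =)`;
#'   the epoch with the lowest validation loss is retained.
#' @param fuse_common common projection width for the fused modality.
#' @param verbose print per-epoch losses.
#' @return an object of class `mvb_model` with elements `params`,
#'   `history` (per-epoch data.frame), `config`, and the branch configs.
#' @export
mvb_fit <- function(x, y, modality = c("smri", "fmri", "fused"),
                    smri_cfg = smri_config(), fmri_cfg = fmri_config(),
                    config = train_config(), subject_ids = NULL, val = NULL,
                    fuse_common = 64, verbose = FALSE) {
  modality <- match.arg(modality)
  y <- as.character(y)
  stopifnot(length(x) == length(y), all(y %in% c("ASD", "NC")))
  if (!is.null(val) && !is.null(subject_ids) && !is.null(val$subject_ids) &&
      length(intersect(subject_ids, val$subject_ids)) > 0)
    stop("subject leakage: ids present in both training and validation sets")
  seed <- config$seed
  params <- list()
  if (modality %in% c("smri", "fused"))
    params$smri <- smri_init(smri_cfg, seed)
  if (modality %in% c("fmri", "fused")) {
    n_rois <- ncol(x[[1]]$S)
    params$fmri <- fmri_init(fmri_cfg, n_rois, seed)
  }
  feat_dim <- switch(modality,
    smri = smri_embed_dim(smri_cfg),
    fmri = fmri_concat_dim(fmri_cfg, ncol(x[[1]]$S)),
    fused = 3 * fuse_common)
  if (modality == "fused")
    params$fuse <- fuse_init(smri_embed_dim(smri_cfg),
                             fmri_concat_dim(fmri_cfg, ncol(x[[1]]$S)),
                             common = fuse_common, seed = seed)
  params$head <- head_init(feat_dim, seed = seed)
  model <- list(params = params, modality = modality, smri_cfg = smri_cfg,
                fmri_cfg = fmri_cfg, config = config,
                sn_state = new.env(parent = emptyenv()),
                classes = c("NC", "ASD"), subject_ids = subject_ids)
  class(model) <- "mvb_model"
  n <- length(x)
  yi <- ifelse(y == "ASD", 2L, 1L)  # column 2 = positive class
  onehot <- matrix(0, n, 2); onehot[cbind(seq_len(n), yi)] <- 1
  opt <- adam_init(params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(val = Inf, params = params)
  loss_fn <- function(logits, targets) {
    if (config$loss == "focal")
      focal_loss(logits, targets, config$alpha_t, config$gamma)
    else cross_entropy_loss(logits, targets)
  }
  for (epoch in seq_len(config$epochs)) {
    ord <- with_substream(seed, "shuffle", epoch, expr = sample(n))
    epoch_loss <- 0; n_batches <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      bx <- x[idx]; by <- onehot[idx, , drop = FALSE]
      if (config$mixup && length(idx) > 1) {
        mx <- with_substream(seed, "mixup", epoch, start, expr = list(
          lambda = stats::rbeta(1, config$mixup_a, config$mixup_a),
          perm = sample(length(idx))))
        # mix every numeric field the modality uses
        fields <- switch(modality, smri = "mvt", fmri = c("S", "fc_vec"),
                         fused = c("mvt", "S", "fc_vec"))
        mixed <- lapply(seq_along(bx), function(i) {
          out <- bx[[i]]
          for (f in fields)
            out[[f]] <- mx$lambda * bx[[i]][[f]] +
              (1 - mx$lambda) * bx[[mx$perm[i]]][[f]]
          out
        })
        bx <- mixed
        by <- mx$lambda * by + (1 - mx$lambda) * by[mx$perm, , drop = FALSE]
      }
      grads_sum <- NULL
      batch_loss <- 0
      for (i in seq_along(bx)) {
        fwd <- with_substream(seed, "dropout", epoch, start, i, expr =
          model_forward(model, bx[[i]], training = TRUE))
        lf <- loss_fn(fwd$logits, by[i, , drop = FALSE])
        batch_loss <- batch_loss + lf$value +
          if (model$modality %in% c("smri", "fused"))
            config$lambda_ent * fwd$smri$entropy else 0
        g <- model_backward(model, fwd, drop(lf$grad))
        grads_sum <- if (is.null(grads_sum)) g else tree_map(`+`, grads_sum, g)
      }
      grads <- tree_map(function(g) g / length(bx), grads_sum)
      st <- adam_step(model$params, grads, opt, config$lr)
      model$params <- st$params
      opt <- st$state
      epoch_loss <- epoch_loss + batch_loss / length(bx)
      n_batches <- n_batches + 1
    }
    epoch_loss <- epoch_loss / n_batches
    val_loss <- NA_real_
    if (!is.null(val)) {
      vl <- 0
      vy <- ifelse(as.character(val$y) == "ASD", 2L, 1L)
      for (i in seq_along(val$x)) {
        fwd <- model_forward(model, val$x[[i]], training = FALSE)
        vl <- vl + loss_fn(fwd$logits, vy[i])$value
      }
      val_loss <- vl / length(val$x)
      if (val_loss < best$val) best <- list(val = val_loss,
                                            params = model$params)
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = epoch_loss,
                                         val_loss = val_loss))
    if (verbose)
      cat(sprintf("epoch %3d  loss %.4f%s\n", epoch, epoch_loss,
                  if (is.na(val_loss)) "" else sprintf("  val %.4f", val_loss)))
  }
  if (!is.null(val) && is.finite(best$val)) model$params <- best$params
  model$history <- history
  model
}

#' @export
print.mvb_model <- function(x, ...) {
  cat("<mvb_model> modality:", x$modality, "\n")
  cat("  epochs trained:", nrow(x$history),
      " final loss:", signif(utils::tail(x$history$loss, 1), 4), "\n")
  invisible(x)
}

#' @export
summary.mvb_model <- function(object, ...) {
  n_par <- sum(unlist(tree_map(length, object$params)))
  cat("Multi-view dual-modal brain MRI classifier\n")
  cat("  modality       :", object$modality, "\n")
  cat("  parameters     :", n_par, "\n")
  cat("  loss           :", object$config$loss, "\n")
  cat("  epochs         :", nrow(object$history), "\n")
  cat("  final train loss:", signif(utils::tail(object$history$loss, 1), 4), "\n")
  if (any(is.finite(object$history$val_loss)))
    cat("  best val loss  :",
        signif(min(object$history$val_loss, na.rm = TRUE), 4), "\n")
  invisible(object)
}

#' @export
plot.mvb_model <- function(x, ...) {
  graphics::plot(x$history$epoch, x$history$loss, type = "l",
                 xlab = "epoch", ylab = "loss", main = "Training loss", ...)
  if (any(is.finite(x$history$val_loss)))
    graphics::lines(x$history$epoch, x$history$val_loss, lty = 2)
  invisible(x)
}

#' Predict from a fitted model
#'
#' @param object an `mvb_model`.
#' @param newdata list of per-subject inputs (same structure as in
#'   [mvb_fit()]).
#' @param type `"prob"` (positive-class probability), `"class"`, or
#'   `"logit"`.
#' @param ... unused.
#' @return numeric vector, character vector, or `n x 2` logit matrix.
#' @export
predict.mvb_model <- function(object, newdata,
                              type = c("prob", "class", "logit"), ...) {
  type <- match.arg(type)
  out <- t(vapply(newdata, function(xi)
    model_forward(object, xi, training = FALSE)$logits, numeric(2)))
  if (type == "logit") return(out)
  prob <- t(apply(out, 1, softmax_vec))[, 2]
  if (type == "prob") prob else ifelse(prob >= 0.5, "ASD", "NC")
}

#' Evaluate a fitted model
#'
#' Computes sample-level metrics, and subject-level metrics by averaging
#' the predicted positive-class probabilities over each subject's samples
#' (mean-probability aggregation) when subject ids are supplied.
#'
#' @param model an `mvb_model`.
#' @param x,y evaluation inputs and labels.
#' @param subject_ids optional subject id per sample.
#' @param aggregation `"slice"` (per sample) or `"subject"`.
#' @return a `metrics_report`, with the probabilities attached as
#'   attribute `prob`.
#' @export
evaluate_model <- function(model, x, y, subject_ids = NULL,
                           aggregation = c("slice", "subject")) {
  aggregation <- match.arg(aggregation)
  if (length(x) == 0) stop("empty evaluation set")
  y <- as.character(y)
  prob <- predict(model, x, type = "prob")
  if (aggregation == "subject") {
    if (is.null(subject_ids)) stop("subject aggregation needs subject_ids")
    agg <- tapply(prob, subject_ids, mean)
    ylab <- tapply(y, subject_ids, function(v) v[1])
    prob <- as.numeric(agg); y <- as.character(ylab)
  }
  pred <- ifelse(prob >= 0.5, "ASD", "NC")
  rep_ <- compute_metrics(pred = pred, truth = y)
  attr(rep_, "prob") <- prob
  rep_
}

#' Grad-CAM saliency for the structural branch
#'
#' Backpropagates the target-class logit to the activations of the chosen
#' encoder block (of the chosen plane), weights each channel by its
#' spatially averaged gradient, and returns the ReLU of the weighted
#' activation sum upsampled to the plane's input grid — a non-negative
#' saliency volume over (slice, H, W).
#'
#' @param model a fitted `mvb_model` (modality `"smri"` or `"fused"`).
#' @param xi one subject input (with `mvt`).
#' @param target class whose logit is explained (`"ASD"` or `"NC"`).
#' @param plane plane index 1..3 (axial, coronal, sagittal).
#' @param block encoder block whose activations are used (default: last).
#' @return saliency array with the plane-stack input shape.
#' @export
grad_cam <- function(model, xi, target = "ASD", plane = 1, block = NULL) {
  if (!model$modality %in% c("smri", "fused"))
    stop("Grad-CAM requires the structural branch")
  nb <- length(model$smri_cfg$channel_plan)
  block <- block %||% nb
  if (block < 1 || block > nb) stop("block not on the differentiable path")
  fwd <- model_forward(model, xi, training = FALSE)
  dlogits <- c(0, 0)
  dlogits[if (target == "ASD") 2 else 1] <- 1
  hb <- classifier_head_backward(dlogits, fwd$head, model$params$head)
  dfeat <- hb$dx
  if (model$modality == "fused")
    dfeat <- cross_modality_fuse_backward(dfeat, fwd$fuse)$dz_smri
  smf <- fwd$smri
  ep <- smf$cache$embed_per_plane
  dzp <- dfeat[((plane - 1) * ep + 1):(plane * ep)]
  # walk the plane encoder backwards down to the requested block's output
  ca <- smf$cache$encs[[plane]]$cache
  dx <- global_avg_pool_backward(dzp, ca$gap)
  if (model$smri_cfg$attention) {
    gs <- spatial_attention_backward(dx, ca$att$sp)
    dx <- channel_attention_backward(gs$dx, ca$att$ch)$dx
  }
  b <- nb
  activations <- NULL
  while (b > block) {
    bc <- ca$blocks[[b]]
    grs <- conv3d_backward(dx, bc$res)
    gsn <- stat_normalize_backward(relu_backward(dx, bc$relu), bc$stat)
    gcv <- conv3d_backward(gsn$dx, bc$conv)
    dx <- gcv$dx + grs$dx
    b <- b - 1
  }
  # reconstruct the chosen block's output activations from the next cache
  act <- block_output_activation(smf, plane, block, model, xi)
  grad_cam_map(act, dx, out_dim = dim(xi$mvt)[2:4])
}

#' Grad-CAM map from activations and their gradients
#'
#' The core saliency rule: each channel is weighted by the spatial mean of
#' its gradient, the weighted activation sum is rectified, and the map is
#' trilinearly upsampled to `out_dim`.
#'
#' @param activations feature map `[d1, d2, d3, C]`.
#' @param grads gradient of the target logit with respect to
#'   `activations` (same shape).
#' @param out_dim output grid size (defaults to the activation grid).
#' @return non-negative saliency array of size `out_dim`.
#' @export
grad_cam_map <- function(activations, grads, out_dim = NULL) {
  dims <- dim(activations)
  weights <- colMeans(matrix(grads, prod(dims[1:3]), dims[4]))
  cam <- array(matrix(activations, prod(dims[1:3]), dims[4]) %*% weights,
               dim = dims[1:3])
  cam <- pmax(cam, 0)
  if (is.null(out_dim) || all(out_dim == dims[1:3])) cam
  else resize_trilinear(cam, out_dim)
}

# recompute the activations at a block output for one plane (cheap second
# forward pass; caches store unfolded inputs, not activations)
block_output_activation <- function(smf, plane, block, model, xi) {
  d <- dim(xi$mvt)
  x <- array(xi$mvt[plane, , , ], dim = c(d[2], d[3], d[4], 1))
  cfg <- model$smri_cfg
  for (b in seq_len(block)) {
    bp <- model$params$smri$blocks[[b]]
    w <- bp$w
    if (cfg$spectral_norm) w <- spectral_normalize(w)$w_hat
    cv <- conv3d(x, w, bp$b, stride = 2, dilation = cfg$dilations[b])
    sn <- stat_normalize(cv$out, bp$gamma, bp$beta)
    rl <- relu(sn$out)
    rs <- conv3d(x, bp$wres, bp$bres, stride = 2)
    x <- rl$out + rs$out
  }
  x
}
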