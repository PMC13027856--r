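# Hierarchical multi-view 3D convolutional branch for structural MRI.
# One shared-weight encoder is applied to each anatomical plane's slice
# stack (treated as a 3D volume [n_slices, H, W, 1]); the per-plane
# embeddings are concatenated and regularised by an entropy term.

#' Configuration of the structural (3D hierarchical CNN) branch
#'
#' @param channel_plan output channels per block; the default follows the
#'   hierarchical 32-64-128-256 progression (scale it down for desk-size
#'   inputs).
#' @param kernels kernel size per block; defaults alternate 3 and 5.
#' @param dilations dilation rate per block; defaults alternate 1 and 2.
#' @param spectral_norm rescale each kernel to unit spectral norm.
#' @param attention enable the channel + spatial attention stage.
#' @param graph list: `enabled`, `n_nodes` (spatial blocks along the slice
#'   axis used as graph nodes), `d_out` (propagation output width,
#'   defaults to the final channel count).
#' @param lambda_ent weight of the embedding entropy penalty.
#' @return list of class `smri_config`.
#' @export
smri_config <- function(channel_plan = c(32, 64, 128, 256), kernels = NULL,
                        dilations = NULL, spectral_norm = TRUE,
                        attention = TRUE,
                        graph = list(enabled = FALSE, n_nodes = 4, d_out = NULL),
                        lambda_ent = 1e-3) {
  nb <- length(channel_plan)
  kernels <- kernels %||% rep(c(3, 5), length.out = nb)
  dilations <- dilations %||% rep(c(1, 2), length.out = nb)
  stopifnot(all(kernels %% 2 == 1), all(dilations >= 1))
  graph <- utils::modifyList(list(enabled = FALSE, n_nodes = 4, d_out = NULL),
                             graph)
  graph$d_out <- graph$d_out %||% channel_plan[nb]
  structure(list(channel_plan = channel_plan, kernels = kernels,
                 dilations = dilations, spectral_norm = spectral_norm,
                 attention = attention, graph = graph,
                 lambda_ent = lambda_ent),
            class = "smri_config")
}

# embedding width produced by smri_forward under this config
smri_embed_dim <- function(config) {
  cl <- config$channel_plan[length(config$channel_plan)]
  3 * cl + if (config$graph$enabled) config$graph$d_out else 0
}

#' Initialise the structural branch parameters
#' @param config an [smri_config()].
#' @param seed initialisation seed.
#' @return nested parameter list.
#' @export
smri_init <- function(config, seed = 1) {
  plan <- config$channel_plan
  nb <- length(plan)
  blocks <- vector("list", nb)
  cin <- 1
  for (b in seq_len(nb)) {
    cout <- plan[b]; k <- config$kernels[b]
    blocks[[b]] <- list(
      w = init_kernel(k, cin, cout, seed, paste0("smri.conv", b)),
      b = numeric(cout),
      gamma = rep(1, cout), beta = numeric(cout),
      wres = init_kernel(1, cin, cout, seed, paste0("smri.res", b)),
      bres = numeric(cout))
    cin <- cout
  }
  cl <- plan[nb]
  params <- list(blocks = blocks)
  if (config$attention) {
    params$wa <- init_mat(cl, cl, seed, "smri.chatt")
    params$wm <- drop(init_mat(cl, 1, seed, "smri.spatt"))
    params$bm <- 0
  }
  if (config$graph$enabled)
    params$wg <- init_mat(cl, config$graph$d_out, seed, "smri.graph")
  params
}

# chain adjacency over the n_nodes slice-axis blocks of the feature grid
graph_chain_adjacency <- function(n_nodes) {
  a <- matrix(0, n_nodes, n_nodes)
  if (n_nodes > 1)
    for (i in seq_len(n_nodes - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  a
}

# average-pool the feature map over n contiguous blocks along axis 1
pool_nodes <- function(f, n_nodes) {
  d <- dim(f)
  if (d[1] < n_nodes)
    stop("graph n_nodes (", n_nodes, ") exceeds the final feature grid (",
         d[1], " planes); lower graph$n_nodes or use a deeper slice stack")
  breaks <- floor(seq(0, d[1], length.out = n_nodes + 1))
  h <- matrix(0, n_nodes, d[4])
  for (i in seq_len(n_nodes)) {
    sel <- (breaks[i] + 1):breaks[i + 1]
    block <- f[sel, , , , drop = FALSE]
    h[i, ] <- colMeans(matrix(block, prod(d[2:3]) * length(sel), d[4]))
  }
  list(h = h, breaks = breaks, d = d)
}

pool_nodes_backward <- function(dh, cache) {
  d <- cache$d
  dx <- array(0, dim = d)
  for (i in seq_len(nrow(dh))) {
    sel <- (cache$breaks[i] + 1):cache$breaks[i + 1]
    n <- prod(d[2:3]) * length(sel)
    dx[sel, , , ] <- array(matrix(dh[i, ] / n, n, d[4], byrow = TRUE),
                           dim = c(length(sel), d[2:3], d[4]))
  }
  dx
}

# encoder over a single plane stack [n, H, W, 1]; returns embedding + caches
smri_encode_plane <- function(x, params, config, sn_state = NULL) {
  nb <- length(config$channel_plan)
  caches <- vector("list", nb)
  sigmas <- numeric(nb)
  for (b in seq_len(nb)) {
    bp <- params$blocks[[b]]
    w <- bp$w
    if (config$spectral_norm) {
      key <- paste0("u", b)
      u0 <- if (!is.null(sn_state)) sn_state[[key]] else NULL
      sn <- spectral_normalize(w, u = u0)
      if (!is.null(sn_state)) assign(key, sn$u, envir = sn_state)
      w <- sn$w_hat
      sigmas[b] <- sn$sigma
    } else sigmas[b] <- 1
    cv <- conv3d(x, w, bp$b, stride = 2, dilation = config$dilations[b])
    sn_ <- stat_normalize(cv$out, bp$gamma, bp$beta)
    rl <- relu(sn_$out)
    rs <- conv3d(x, bp$wres, bp$bres, stride = 2)
    out <- rl$out + rs$out
    caches[[b]] <- list(conv = cv$cache, stat = sn_$cache, relu = rl$cache,
                        res = rs$cache, sigma = sigmas[b])
    x <- out
  }
  att <- NULL
  if (config$attention) {
    cha <- channel_attention(x, params$wa)
    spa <- spatial_attention(cha$out, params$wm, params$bm)
    att <- list(ch = cha$cache, sp = spa$cache)
    x <- spa$out
  }
  gp <- global_avg_pool(x)
  list(embed = gp$out, final_map = x,
       cache = list(blocks = caches, att = att, gap = gp$cache))
}

smri_encode_plane_backward <- function(dembed, dfinal, cache, params, config) {
  grads <- list(blocks = lapply(params$blocks, tree_zeros_like))
  dx <- global_avg_pool_backward(dembed, cache$gap)
  if (!is.null(dfinal)) dx <- dx + dfinal
  if (config$attention) {
    gs <- spatial_attention_backward(dx, cache$att$sp)
    grads$wm <- gs$dwm; grads$bm <- gs$dbm
    gc_ <- channel_attention_backward(gs$dx, cache$att$ch)
    grads$wa <- gc_$dwa
    dx <- gc_$dx
  }
  for (b in rev(seq_along(cache$blocks))) {
    bc <- cache$blocks[[b]]
    grs <- conv3d_backward(dx, bc$res)
    drl <- relu_backward(dx, bc$relu)
    gsn <- stat_normalize_backward(drl, bc$stat)
    gcv <- conv3d_backward(gsn$dx, bc$conv)
    grads$blocks[[b]] <- list(
      w = gcv$dw / bc$sigma,  # spectral scale treated as constant
      b = gcv$db, gamma = gsn$dgamma, beta = gsn$dbeta,
      wres = grs$dw, bres = grs$db)
    dx <- gcv$dx + grs$dx
  }
  list(grads = grads, dx = dx)
}

#' Forward pass of the structural branch
#'
#' Applies the shared hierarchical encoder to each plane of the multi-view
#' tensor (axial, coronal, sagittal order), concatenates the per-plane
#' pooled embeddings, optionally appends a graph-propagated ROI-block
#' summary, and computes the entropy penalty of the embedding.
#'
#' @param params [smri_init()] parameters.
#' @param config [smri_config()].
#' @param mvt a `multiview_tensor` (`3 x n x H x W`).
#' @param sn_state optional environment holding persistent power-iteration
#'   vectors for spectral normalisation.
#' @return list with `z` (embedding), `entropy`, `entropy_grad`, `cache`.
#' @export
smri_forward <- function(params, config, mvt, sn_state = NULL) {
  stopifnot(length(dim(mvt)) == 4, dim(mvt)[1] == 3)
  d <- dim(mvt)
  planes <- lapply(1:3, function(p)
    array(mvt[p, , , ], dim = c(d[2], d[3], d[4], 1)))
  encs <- lapply(planes, smri_encode_plane, params = params, config = config,
                 sn_state = sn_state)
  z <- unlist(lapply(encs, `[[`, "embed"))
  gcache <- NULL
  if (config$graph$enabled) {
    fmean <- Reduce(`+`, lapply(encs, `[[`, "final_map")) / 3
    pn <- pool_nodes(fmean, config$graph$n_nodes)
    a <- graph_chain_adjacency(config$graph$n_nodes)
    gp <- graph_propagate(pn$h, a, params$wg, act = "relu")
    gvec <- colMeans(gp$out)
    z <- c(z, gvec)
    gcache <- list(pool = pn, prop = gp$cache, n_nodes = config$graph$n_nodes)
  }
  ent <- entropy_penalty(z)
  list(z = z, entropy = ent$value, entropy_grad = ent$grad,
       cache = list(encs = encs, graph = gcache, embed_per_plane =
                      length(encs[[1]]$embed)))
}

#' Backward pass of the structural branch
#' @param dz gradient of the loss with respect to the embedding `z`.
#' @param fwd the [smri_forward()] result.
#' @param params,config as in the forward pass.
#' @return parameter gradient tree (shared encoder gradients summed over
#'   planes).
#' @export
smri_backward <- function(dz, fwd, params, config) {
  ca <- fwd$cache
  ep <- ca$embed_per_plane
  dfinal <- vector("list", 3)
  grads_total <- NULL
  if (config$graph$enabled) {
    gdim <- config$graph$d_out
    dgvec <- dz[(3 * ep + 1):(3 * ep + gdim)]
    n_nodes <- ca$graph$n_nodes
    dhout <- matrix(dgvec / n_nodes, n_nodes, gdim, byrow = TRUE)
    gg <- graph_propagate_backward(dhout, ca$graph$prop)
    dfmean <- pool_nodes_backward(gg$dx, ca$graph$pool)
    for (p in 1:3) dfinal[[p]] <- dfmean / 3
    grads_total <- list(wg = gg$dw)
  }
  for (p in 1:3) {
    dzp <- dz[((p - 1) * ep + 1):(p * ep)]
    bk <- smri_encode_plane_backward(dzp, dfinal[[p]], ca$encs[[p]]$cache,
                                     params, config)
    g <- bk$grads
    if (is.null(grads_total)) grads_total <- g
    else {
      grads_total$blocks <- if (is.null(grads_total$blocks)) g$blocks
        else tree_map(`+`, grads_total$blocks, g$blocks)
      for (nm in c("wa", "wm", "bm"))
        if (!is.null(g[[nm]]))
          grads_total[[nm]] <- (grads_total[[nm]] %||% 0) + g[[nm]]
    }
  }
  # order fields like params for the optimiser
  out <- list(blocks = grads_total$blocks)
  if (config$attention) {
    out$wa <- grads_total$wa; out$wm <- grads_total$wm; out$bm <- grads_total$bm
  }
  if (config$graph$enabled) out$wg <- grads_total$wg
  out
}
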