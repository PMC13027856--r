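# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression under a derived, isolated RNG substream
#'
#' Hashes `(seed, key...)` into a 31-bit stream seed, runs `expr` under that
#' seed, and restores the caller's RNG state afterwards. Keyed streams make
#' every generated object a pure function of its identifiers, so adding
#' subjects to a phantom roster never perturbs previously generated ones.
#'
#' @param seed integer master seed.
#' @param ... character/numeric keys identifying the stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_substream <- function(seed, ..., expr) {
  h <- substream_seed(seed, ...)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(h)
  expr
}

# FNV-1a style 31-bit hash of the concatenated keys, mixed with the seed.
substream_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "\r")
  bytes <- utf8ToInt(key)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Trilinear interpolation of a 3D array at fractional voxel coordinates
#'
#' Coordinates are 0-based voxel indices; samples falling outside the array
#' extent return `fill` (zero by default), matching the zero-padded field of
#' view convention used throughout rigid resampling.
#'
#' @param arr 3D numeric array.
#' @param coords n x 3 matrix of 0-based voxel coordinates.
#' @param fill value for out-of-bounds samples.
#' @return numeric vector of length n.
#' @keywords internal
trilinear_sample <- function(arr, coords, fill = 0) {
  trilinear_sample_prepared(trilinear_prepare(arr), coords, fill)
}

# pre-pad a volume with one zero layer per side so interpolation corners of
# any in-bounds point are always valid array indices (hot path: the padded
# array is reused across the many evaluations of a registration objective)
trilinear_prepare <- function(arr) {
  d <- dim(arr)
  dp <- d + 2L
  padded <- array(0, dim = dp)
  padded[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- arr
  list(padded = padded, d = d, dp = dp)
}

trilinear_sample_prepared <- function(prep, coords, fill = 0) {
  d <- prep$d; dp <- prep$dp
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  inside <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
    z >= 0 & z <= d[3] - 1
  out <- rep(fill, length(x))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  sx <- 1L; sy <- dp[1]; sz <- dp[1] * dp[2]
  base <- (x0 + 2) + dp[1] * (y0 + 1) + sz * (z0 + 1)
  a <- prep$padded
  interp <-
    a[base] * (1 - fx) * (1 - fy) * (1 - fz) +
    a[base + sx] * fx * (1 - fy) * (1 - fz) +
    a[base + sy] * (1 - fx) * fy * (1 - fz) +
    a[base + sx + sy] * fx * fy * (1 - fz) +
    a[base + sz] * (1 - fx) * (1 - fy) * fz +
    a[base + sx + sz] * fx * (1 - fy) * fz +
    a[base + sy + sz] * (1 - fx) * fy * fz +
    a[base + sx + sy + sz] * fx * fy * fz
  out[inside] <- interp
  out
}

#' Bilinear resize of a 2D matrix (align-corners convention)
#'
#' Maps output pixel i to source coordinate `(i-1) * (H_in-1) / (H_out-1)`,
#' so resizing to the input size is an exact identity and constant images
#' stay constant.
#'
#' @param mat numeric matrix.
#' @param out_h,out_w output dimensions.
#' @return `out_h` x `out_w` matrix.
#' @export
resize_bilinear <- function(mat, out_h, out_w) {
  stopifnot(is.matrix(mat), out_h >= 1, out_w >= 1)
  h <- nrow(mat); w <- ncol(mat)
  sx <- if (out_h == 1) rep(0, out_h) else (seq_len(out_h) - 1) * (h - 1) / (out_h - 1)
  sy <- if (out_w == 1) rep(0, out_w) else (seq_len(out_w) - 1) * (w - 1) / (out_w - 1)
  x0 <- pmin(floor(sx), h - 2); x0[h == 1] <- 0
  y0 <- pmin(floor(sy), w - 2); y0[w == 1] <- 0
  if (h == 1) { x0 <- rep(0, out_h); fx <- rep(0, out_h) } else fx <- sx - x0
  if (w == 1) { y0 <- rep(0, out_w); fy <- rep(0, out_w) } else fy <- sy - y0
  i0 <- x0 + 1; j0 <- y0 + 1
  i1 <- pmin(i0 + 1, h); j1 <- pmin(j0 + 1, w)
  a <- mat[i0, j0, drop = FALSE]; b <- mat[i1, j0, drop = FALSE]
  c_ <- mat[i0, j1, drop = FALSE]; d_ <- mat[i1, j1, drop = FALSE]
  top <- a * (1 - fx) + b * fx
  bot <- c_ * (1 - fx) + d_ * fx
  sweep(top, 2, 1 - fy, "*") + sweep(bot, 2, fy, "*")
}

#' Trilinear resize of a 3D array (align-corners convention)
#' @param arr 3D array.
#' @param out_dim length-3 integer output shape.
#' @return resized 3D array.
#' @keywords internal
resize_trilinear <- function(arr, out_dim) {
  d <- dim(arr)
  ax <- function(n_out, n_in) if (n_out == 1 || n_in == 1) rep(0, n_out)
    else (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  gx <- ax(out_dim[1], d[1]); gy <- ax(out_dim[2], d[2]); gz <- ax(out_dim[3], d[3])
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  array(trilinear_sample(arr, grid), dim = out_dim)
}

# Map a function over every numeric leaf of a nested parameter list,
# preserving structure. Used by the optimiser and gradient utilities.
tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.list(t1)) {
    out <- lapply(seq_along(t1), function(i) {
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(t1)
    out
  } else {
    do.call(f, trees)
  }
}

tree_zeros_like <- function(tree) tree_map(function(x) x * 0, tree)
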