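# Layer primitives with explicit forward/backward passes.
#
# Feature maps are numeric arrays dim c(H, W, C); convolution weights are
# (K*K*Cin) x Cout matrices matching the .im2col column layout (kernel row
# offset fastest, then column offset, then input channel); depthwise weights
# are (K, K, C) arrays. GEMMs go through R's BLAS; the im2col/col2im and
# depthwise kernels are compiled.

# Activations carry dim c(H, W, C) (single image) or c(H, W, B, C)
# (minibatch, channels last so channel-matrix reshapes are contiguous).
conv_fwd <- function(x, w, b, stride = 1L, pad = 1L, k = 3L) {
  d <- dim(x)
  nd <- length(d)
  if (k == 1L && stride == 1L) {
    # 1x1 convolution: plain GEMM on the channel matrix, no im2col
    cols <- x
    dim(cols) <- c(prod(d[-nd]), d[nd])
    od <- d[-nd]
  } else {
    cols <- .im2col(x, as.integer(k), as.integer(stride), as.integer(pad))
    odv <- attr(cols, "out_dim")                     # c(Ho, Wo, B)
    od <- if (nd == 4L) odv else odv[1:2]
  }
  y <- .addcol(cols %*% w, b)
  dim(y) <- c(od, ncol(w))
  list(y = y, cache = list(cols = cols, xdim = d, k = as.integer(k),
                           stride = as.integer(stride), pad = as.integer(pad)))
}

conv_bwd <- function(cache, w, gy) {
  cout <- ncol(w)
  gyf <- gy
  dim(gyf) <- c(length(gy) / cout, cout)
  gw <- crossprod(cache$cols, gyf)
  gb <- .colSums(gyf, nrow(gyf), cout)
  gcols <- tcrossprod(gyf, w)
  d <- cache$xdim
  nd <- length(d)
  if (cache$k == 1L && cache$stride == 1L) {
    gx <- gcols
    dim(gx) <- d
  } else {
    B <- if (nd == 4L) d[3] else 1L
    gx <- .col2im(gcols, d[1], d[2], B, d[nd],
                  cache$k, cache$stride, cache$pad, nd == 4L)
  }
  list(gx = gx, gw = gw, gb = gb)
}

dw_fwd <- function(x, w, stride = 1L, pad = 1L) {
  y <- .dwconv_fwd(x, w, as.integer(stride), as.integer(pad))
  list(y = y, cache = list(x = x, stride = as.integer(stride),
                           pad = as.integer(pad)))
}

dw_bwd <- function(cache, w, gy) {
  .dwconv_bwd(cache$x, w, gy, cache$stride, cache$pad)
}

# Batch normalisation with per-sample statistics: each image in the batch
# is normalised over its own spatial positions during training (batched
# images occupy contiguous row blocks of the channel matrix). Running
# averages (the per-channel mean over images) are used at inference.
bn_fwd <- function(x, gamma, beta, stats, training, momentum = 0.1,
                   eps = 1e-5) {
  d <- dim(x)
  nd <- length(d)
  ng <- d[1] * d[2]
  B <- if (nd == 4L) d[3] else 1L
  xm <- x
  dim(xm) <- c(ng * B, d[nd])
  if (ng < 4L) {
    # grids too small for meaningful spatial statistics (deep taps on small
    # inputs): plain per-channel affine, running stats left at their
    # initial identity so inference matches
    nc <- d[nd]
    y <- .bn_eval(xm, gamma, beta, numeric(nc), rep(1 - eps, nc), eps)
    dim(y) <- d
    return(list(y = y, stats = stats,
                cache = list(xm = xm, d = d, training = "affine")))
  }
  if (training) {
    r <- .bn_train_g(xm, gamma, beta, eps, as.integer(ng), as.integer(B))
    stats$mean <- (1 - momentum) * stats$mean + momentum * r$mean
    stats$var <- (1 - momentum) * stats$var + momentum * r$var
    y <- r$y
    cache <- list(xhat = r$xhat, invstd = r$invstd, d = d, ng = ng, B = B,
                  training = TRUE)
  } else {
    y <- .bn_eval(xm, gamma, beta, stats$mean, stats$var, eps)
    cache <- list(d = d, training = FALSE)
  }
  dim(y) <- d
  list(y = y, stats = stats, cache = cache)
}

bn_bwd <- function(cache, gamma, gy) {
  d <- cache$d
  nd <- length(d)
  nc <- d[nd]
  gym <- gy
  dim(gym) <- c(prod(d[-nd]), nc)
  if (identical(cache$training, "affine")) {
    gx <- .bn_eval(gym, gamma, numeric(nc), numeric(nc),
                   rep(1 - 1e-5, nc), 1e-5)
    dim(gx) <- d
    return(list(gx = gx, ggamma = colSums(gym * cache$xm),
                gbeta = colSums(gym)))
  }
  if (isTRUE(cache$training)) {
    r <- .bn_bwd_g(gym, cache$xhat, gamma, cache$invstd,
                   as.integer(cache$ng), as.integer(cache$B))
    gx <- r$gx
    dim(gx) <- d
    list(gx = gx, ggamma = r$ggamma, gbeta = r$gbeta)
  } else {
    stop("backward through eval-mode batch norm is not supported")
  }
}

relu6_fwd <- function(x) {
  r <- .relu6(x)
  list(y = r$y, cache = r$mask)
}

relu6_bwd <- function(cache, gy) .maskmul(gy, cache)

dropout_fwd <- function(x, p, training, seed) {
  if (!training || p <= 0) return(list(y = x, cache = NULL))
  mask <- with_seed(seed, array(runif(length(x)) >= p, dim(x))) / (1 - p)
  list(y = x * mask, cache = mask)
}

dropout_bwd <- function(cache, gy) if (is.null(cache)) gy else gy * cache

resize_fwd <- function(x, h, w) {
  list(y = .bilinear_fwd(x, as.integer(h), as.integer(w)),
       cache = dim(x)[1:2])
}

resize_bwd <- function(cache, gy) .bilinear_bwd(gy, cache[1], cache[2])

he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

xavier_init <- function(nr, nc) {
  matrix(rnorm(nr * nc, 0, sqrt(1 / nr)), nr, nc)
}

# ---- exported building blocks ------------------------------------------

#' Learnable multi-scale aggregation weights
#'
#' Raw scalars normalised by softmax; the normalised weights sum to 1 and
#' each lies in (0, 1), keeping the aggregation a convex combination.
#'
#' @param raw numeric vector of raw (learnable) scalars.
#' @return object of class `forceseg_scale_weights` with `raw` and
#'   `normalized`.
#' @export
scale_weights <- function(raw) {
  e <- exp(raw - max(raw))
  structure(list(raw = raw, normalized = e / sum(e)),
            class = "forceseg_scale_weights")
}

#' Multi-scale feature aggregation
#'
#' Each feature map is optionally projected to a common channel width by a
#' 1x1 convolution, resized to the first (finest) map's grid by bilinear
#' interpolation, and summed with softmax-normalised weights.
#'
#' @param features list of H x W x C arrays, spatial sizes non-increasing.
#' @param weights a `forceseg_scale_weights` with one weight per map.
#' @param projections optional list of `list(w, b)` 1x1 projections
#'   (`w` is Cin x Cout); `NULL` requires all maps to share a channel count.
#' @return fused H x W x C array on the first map's grid.
#' @export
aggregate_multiscale <- function(features, weights, projections = NULL) {
  L <- length(features)
  if (length(weights$normalized) != L)
    stop_forceseg(sprintf("got %d maps but %d weights", L,
                          length(weights$normalized)),
                  "forceseg_shape_error")
  target <- dim(features[[1]])[1:2]
  acc <- NULL
  for (l in seq_len(L)) {
    f <- features[[l]]
    if (!is.null(projections)) {
      d <- dim(f)
      fm <- matrix(f, ncol = d[3]) %*% projections[[l]]$w
      fm <- sweep(fm, 2, projections[[l]]$b, `+`)
      f <- array(fm, c(d[1], d[2], ncol(projections[[l]]$w)))
    }
    if (!all(dim(f)[1:2] == target))
      f <- .bilinear_fwd(f, as.integer(target[1]), as.integer(target[2]))
    term <- weights$normalized[l] * f
    acc <- if (is.null(acc)) term else acc + term
  }
  acc
}

#' Attention configuration
#'
#' @param d embedding dimension of the query/key/value projections (>= 1).
#' @param seed seed for default projection initialisation.
#' @return object of class `forceseg_attention_config`.
#' @export
attention_config <- function(d = 64, seed = 0) {
  stopifnot(d >= 1)
  structure(list(d = d, seed = seed), class = "forceseg_attention_config")
}

#' Cross-scale attention between a fine and a coarse feature map
#'
#' Queries come from the fine (low-layer) map, keys and values from the
#' coarse (high-layer) map, one token per spatial position. Scaled
#' dot-product attention (`softmax(Q K^T / sqrt(d)) V`) is reshaped back to
#' the fine grid and added residually.
#'
#' @param low H x W x C_low array (queries).
#' @param high h x w x C_high array (keys/values).
#' @param config an `attention_config()`.
#' @param weights optional list `Wq` (C_low x d), `Wk` (C_high x d),
#'   `Wv` (C_high x C_low); seeded Xavier initialisation when `NULL`.
#' @return H x W x C_low array (`low` plus the attended values); the
#'   attention matrix is attached as attribute `"attention"`.
#' @export
cross_scale_attention <- function(low, high, config = attention_config(),
                                  weights = NULL) {
  dl <- dim(low); dh <- dim(high)
  if (is.null(weights)) {
    weights <- with_seed(config$seed, list(
      Wq = xavier_init(dl[3], config$d),
      Wk = xavier_init(dh[3], config$d),
      Wv = xavier_init(dh[3], dl[3])))
  }
  att <- attention_fwd(low, high, weights, config$d)
  structure(att$y, attention = att$cache$A)
}

attention_fwd <- function(low, high, weights, d) {
  dl <- dim(low); dh <- dim(high)
  lowm <- matrix(low, ncol = dl[3])
  highm <- matrix(high, ncol = dh[3])
  Q <- lowm %*% weights$Wq
  K <- highm %*% weights$Wk
  V <- highm %*% weights$Wv
  S <- tcrossprod(Q, K) / sqrt(d)
  S <- S - apply(S, 1, max)
  E <- exp(S)
  A <- E / rowSums(E)
  O <- A %*% V
  y <- low + array(O, dl)
  list(y = y, cache = list(lowm = lowm, highm = highm, Q = Q, K = K, V = V,
                           A = A, d = d, dl = dl, dh = dh))
}

attention_bwd <- function(cache, weights, gy) {
  gyf <- matrix(gy, ncol = cache$dl[3])
  gO <- gyf
  gA <- tcrossprod(gO, cache$V)
  gV <- crossprod(cache$A, gO)
  gS <- cache$A * (gA - rowSums(gA * cache$A))
  gS <- gS / sqrt(cache$d)
  gQ <- gS %*% cache$K
  gK <- crossprod(gS, cache$Q)
  glow <- gyf + tcrossprod(gQ, weights$Wq)
  ghigh <- tcrossprod(gK, weights$Wk) + tcrossprod(gV, weights$Wv)
  list(glow = array(glow, cache$dl), ghigh = array(ghigh, cache$dh),
       gWq = crossprod(cache$lowm, gQ),
       gWk = crossprod(cache$highm, gK),
       gWv = crossprod(cache$highm, gV))
}
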