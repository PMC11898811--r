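#' Model configuration for the lightweight encoder-decoder
#'
#' Inverted-residual encoder (expansion factor `expansion`) with taps at
#' strides 4/8/16/32, learnable softmax-weighted multi-scale aggregation at
#' the stride-4 grid, cross-scale attention between the stride-4 (queries)
#' and stride-32 (keys/values) taps, optional force-field channels
#' concatenated to the aggregated features, and a bilinear-upsampling decoder
#' with a stem skip connection, batch normalisation and dropout.
#'
#' @param width_mult channel width multiplier.
#' @param stem_channels stem channels (stride-2 3x3 convolution).
#' @param stage_channels output channels of the five encoder stages.
#' @param stage_strides per-stage strides (the stride-1 stage is a residual
#'   inverted-residual block).
#' @param expansion inverted-residual expansion factor.
#' @param agg_channels common width of the multi-scale aggregation grid.
#' @param attn_d attention embedding dimension.
#' @param decoder_channels channels of the three decoder stages
#'   (stride 4, 2, 1).
#' @param dropout dropout rate after the head convolution.
#' @param use_force_channels append the 2-channel force field after
#'   aggregation.
#' @param param_budget maximum trainable parameter count.
#' @param force_alpha,force_mode,force_threshold force-field parameters used
#'   by [segment()]'s two-pass refinement.
#' @return object of class `forceseg_model_config`.
#' @export
model_config <- function(width_mult = 1, stem_channels = 16,
                         stage_channels = c(24, 32, 32, 48, 64),
                         stage_strides = c(2, 2, 1, 2, 2),
                         expansion = 3, agg_channels = 64, attn_d = 64,
                         decoder_channels = c(32, 16, 8), dropout = 0.1,
                         use_force_channels = TRUE, param_budget = 5.2e6,
                         force_alpha = 1, force_mode = "unit",
                         force_threshold = 0.5) {
  sc <- pmax(4L, as.integer(round(stage_channels * width_mult)))
  structure(list(
    width_mult = width_mult,
    stem_channels = max(4L, as.integer(round(stem_channels * width_mult))),
    stage_channels = sc, stage_strides = as.integer(stage_strides),
    expansion = expansion,
    agg_channels = max(4L, as.integer(round(agg_channels * width_mult))),
    attn_d = as.integer(attn_d),
    decoder_channels = pmax(4L, as.integer(round(decoder_channels * width_mult))),
    dropout = dropout, use_force_channels = use_force_channels,
    param_budget = param_budget, force_alpha = force_alpha,
    force_mode = force_mode, force_threshold = force_threshold,
    tap_stages = c(1L, 3L, 4L, 5L),   # cumulative strides 4, 8, 16, 32
    input_channels = 3L), class = "forceseg_model_config")
}

init_ir_stage <- function(cin, cout, expansion) {
  ce <- cin * expansion
  list(ew = he_init(cin, ce, cin), eb = numeric(ce),
       ebn_g = rep(1, ce), ebn_b = numeric(ce),
       dw = array(rnorm(9 * ce, 0, sqrt(2 / 9)), c(3L, 3L, ce)),
       dbn_g = rep(1, ce), dbn_b = numeric(ce),
       pw = he_init(ce, cout, ce), pb = numeric(cout),
       pbn_g = rep(1, cout), pbn_b = numeric(cout))
}

bn_zero <- function(c) list(mean = numeric(c), var = rep(1, c))

#' Build the segmentation model
#'
#' Initialises all parameters reproducibly from the seed and verifies the
#' trainable parameter budget; construction fails with the offending count
#' if the budget is exceeded.
#'
#' @param config a [model_config()].
#' @param seed initialisation seed.
#' @return object of class `forceseg_model`: list with `params`, `bn_stats`,
#'   `config`, `seed`.
#' @export
build_model <- function(config = model_config(), seed = 0) {
  cfg <- config
  # every parameter group draws from its own derived seed, so two configs
  # differing only in one group (e.g. force channels on/off, which changes
  # the head's input width) share identical initial weights everywhere else
  gs <- derive_seeds(seed, 12L + length(cfg$stage_channels))
  p <- list()
  p$stem_w <- with_seed(gs[1], he_init(9L * cfg$input_channels,
                                       cfg$stem_channels,
                                       9L * cfg$input_channels))
  p$stem_b <- numeric(cfg$stem_channels)
  p$stem_bn_g <- rep(1, cfg$stem_channels)
  p$stem_bn_b <- numeric(cfg$stem_channels)
  cin <- cfg$stem_channels
  p$stages <- list()
  for (i in seq_along(cfg$stage_channels)) {
    p$stages[[i]] <- with_seed(gs[1L + i],
      init_ir_stage(cin, cfg$stage_channels[i], cfg$expansion))
    cin <- cfg$stage_channels[i]
  }
  ns <- length(cfg$stage_channels)
  tap_ch <- cfg$stage_channels[cfg$tap_stages]
  p$proj <- with_seed(gs[ns + 2L], lapply(tap_ch, function(c)
    list(w = he_init(c, cfg$agg_channels, c), b = numeric(cfg$agg_channels))))
  p$attn <- with_seed(gs[ns + 3L],
    list(Wq = xavier_init(cfg$agg_channels, cfg$attn_d),
         Wk = xavier_init(cfg$agg_channels, cfg$attn_d),
         Wv = xavier_init(cfg$agg_channels, cfg$agg_channels)))
  p$alpha_raw <- numeric(length(cfg$tap_stages))
  cin_head <- cfg$agg_channels + if (cfg$use_force_channels) 2L else 0L
  dc <- cfg$decoder_channels
  p$head_w <- with_seed(gs[ns + 4L],
                        he_init(9L * cin_head, dc[1], 9L * cin_head))
  p$head_b <- numeric(dc[1])
  p$head_bn_g <- rep(1, dc[1]); p$head_bn_b <- numeric(dc[1])
  cin_u1 <- dc[1] + cfg$stem_channels
  p$u1_w <- with_seed(gs[ns + 5L], he_init(9L * cin_u1, dc[2], 9L * cin_u1))
  p$u1_b <- numeric(dc[2])
  p$u1_bn_g <- rep(1, dc[2]); p$u1_bn_b <- numeric(dc[2])
  p$u2_w <- with_seed(gs[ns + 6L], he_init(9L * dc[2], dc[3], 9L * dc[2]))
  p$u2_b <- numeric(dc[3])
  p$u2_bn_g <- rep(1, dc[3]); p$u2_bn_b <- numeric(dc[3])
  p$out_w <- with_seed(gs[ns + 7L], he_init(dc[3], 1L, dc[3]))
  p$out_b <- numeric(1)
  params <- p
  model <- structure(list(params = params, config = cfg, seed = seed,
                          bn_stats = init_bn_stats(cfg)),
                     class = "forceseg_model")
  n <- count_parameters(model)
  if (n > cfg$param_budget)
    stop_forceseg(sprintf(
      "parameter budget exceeded: %d trainable parameters > budget %g",
      n, cfg$param_budget), "forceseg_budget_error", count = n)
  model
}

init_bn_stats <- function(cfg) {
  s <- list(stem = bn_zero(cfg$stem_channels))
  for (i in seq_along(cfg$stage_channels)) {
    ce <- (if (i == 1) cfg$stem_channels else cfg$stage_channels[i - 1]) *
      cfg$expansion
    s[[paste0("s", i, "_e")]] <- bn_zero(ce)
    s[[paste0("s", i, "_d")]] <- bn_zero(ce)
    s[[paste0("s", i, "_p")]] <- bn_zero(cfg$stage_channels[i])
  }
  dc <- cfg$decoder_channels
  s$head <- bn_zero(dc[1]); s$u1 <- bn_zero(dc[2]); s$u2 <- bn_zero(dc[3])
  s
}

#' Count trainable parameters of a model (or bare parameter list)
#'
#' Arrays carrying `attr(x, "trainable") == FALSE` are excluded.
#'
#' @param model a `forceseg_model`, or any (nested) list of numeric arrays.
#' @return integer count of trainable scalars.
#' @export
count_parameters <- function(model) {
  params <- if (inherits(model, "forceseg_model")) model$params else model
  count <- function(x) {
    if (is.list(x)) return(sum(vapply(x, count, numeric(1))))
    if (!is.numeric(x)) return(0)
    tr <- attr(x, "trainable")
    if (!is.null(tr) && identical(tr, FALSE)) return(0)
    length(x)
  }
  as.integer(count(params))
}

# Channels sit in the last dimension of an activation array; these helpers
# work for both single images c(H, W, C) and minibatches c(H, W, B, C).
nchan <- function(x) dim(x)[length(dim(x))]
chslice <- function(x, idx) {
  if (length(dim(x)) == 4L) x[, , , idx, drop = FALSE]
  else x[, , idx, drop = FALSE]
}
chcat <- function(a, b) {
  d <- dim(a); nd <- length(d)
  array(c(a, b), c(d[-nd], d[nd] + nchan(b)))
}
img_slice <- function(x, b) {
  if (length(dim(x)) == 4L) array(x[, , b, ], dim(x)[c(1, 2, 4)]) else x
}

# Forward pass. x: normalised image c(H, W, 3) or minibatch c(H, W, B, 3);
# force: matching c(H, W, 2) / c(H, W, B, 2) field or NULL (zeros).
# Returns prob (H x W matrix, or H x W x B for a batch), cache and updated
# bn stats.
model_forward <- function(model, x, force = NULL, training = FALSE,
                          dropout_seed = 0L) {
  p <- model$params; cfg <- model$config; bs <- model$bn_stats
  cache <- list()
  d <- dim(x)
  H <- d[1]; W <- d[2]
  batched <- length(d) == 4L
  B <- if (batched) d[3] else 1L
  cache$batched <- batched; cache$B <- B

  cv <- conv_fwd(x, p$stem_w, p$stem_b, stride = 2L, pad = 1L)
  cache$stem_conv <- cv$cache
  bn <- bn_fwd(cv$y, p$stem_bn_g, p$stem_bn_b, bs$stem, training)
  bs$stem <- bn$stats; cache$stem_bn <- bn$cache
  rl <- relu6_fwd(bn$y); cache$stem_relu <- rl$cache
  S <- rl$y

  f <- S
  taps <- list(); tap_k <- 0L
  cache$stages <- list()
  for (i in seq_along(p$stages)) {
    st <- p$stages[[i]]
    stride <- cfg$stage_strides[i]
    cin <- nchan(f); cout <- length(st$pb)
    residual <- stride == 1L && cin == cout
    sc <- list(residual = residual)
    e <- conv_fwd(f, st$ew, st$eb, stride = 1L, pad = 0L, k = 1L)
    sc$e <- e$cache
    bn <- bn_fwd(e$y, st$ebn_g, st$ebn_b, bs[[paste0("s", i, "_e")]], training)
    bs[[paste0("s", i, "_e")]] <- bn$stats; sc$ebn <- bn$cache
    r1 <- relu6_fwd(bn$y); sc$erelu <- r1$cache
    dd <- dw_fwd(r1$y, st$dw, stride = stride, pad = 1L)
    sc$d <- dd$cache
    bn <- bn_fwd(dd$y, st$dbn_g, st$dbn_b, bs[[paste0("s", i, "_d")]], training)
    bs[[paste0("s", i, "_d")]] <- bn$stats; sc$dbn <- bn$cache
    r2 <- relu6_fwd(bn$y); sc$drelu <- r2$cache
    pr <- conv_fwd(r2$y, st$pw, st$pb, stride = 1L, pad = 0L, k = 1L)
    sc$p <- pr$cache
    bn <- bn_fwd(pr$y, st$pbn_g, st$pbn_b, bs[[paste0("s", i, "_p")]], training)
    bs[[paste0("s", i, "_p")]] <- bn$stats; sc$pbn <- bn$cache
    out <- if (residual) f + bn$y else bn$y
    cache$stages[[i]] <- sc
    f <- out
    if (i %in% cfg$tap_stages) {
      tap_k <- tap_k + 1L
      taps[[tap_k]] <- f
    }
  }

  # 1x1 projections to the common aggregation width
  P <- vector("list", length(taps))
  cache$proj <- vector("list", length(taps))
  for (l in seq_along(taps)) {
    pr <- conv_fwd(taps[[l]], p$proj[[l]]$w, p$proj[[l]]$b,
                   stride = 1L, pad = 0L, k = 1L)
    P[[l]] <- pr$y
    cache$proj[[l]] <- pr$cache
  }

  # cross-scale attention: stride-4 queries, stride-32 keys/values,
  # one (small) attention problem per image
  L <- length(P)
  cache$attn_high_dim <- dim(P[[L]])
  if (batched) {
    att_caches <- vector("list", B)
    y1 <- P[[1]]
    for (bb in seq_len(B)) {
      a <- attention_fwd(img_slice(P[[1]], bb), img_slice(P[[L]], bb),
                         p$attn, cfg$attn_d)
      y1[, , bb, ] <- a$y
      att_caches[[bb]] <- a$cache
    }
    cache$attn <- att_caches
    P[[1]] <- y1
  } else {
    att <- attention_fwd(P[[1]], P[[L]], p$attn, cfg$attn_d)
    cache$attn <- att$cache
    P[[1]] <- att$y
  }

  # softmax-weighted aggregation on the stride-4 grid
  alpha <- scale_weights(p$alpha_raw)$normalized
  grid <- dim(P[[1]])[1:2]
  R <- vector("list", length(P))
  cache$resize <- vector("list", length(P))
  for (l in seq_along(P)) {
    if (all(dim(P[[l]])[1:2] == grid)) {
      R[[l]] <- P[[l]]
      cache$resize[[l]] <- NULL
    } else {
      rs <- resize_fwd(P[[l]], grid[1], grid[2])
      R[[l]] <- rs$y
      cache$resize[[l]] <- rs$cache
    }
  }
  Fagg <- Reduce(`+`, Map(function(a, r) a * r, as.list(alpha), R))
  cache$alpha <- alpha; cache$R <- R

  if (cfg$use_force_channels) {
    if (is.null(force))
      force <- if (batched) array(0, c(H, W, B, 2L)) else array(0, c(H, W, 2L))
    ff <- resize_fwd(force, grid[1], grid[2])
    head_in <- chcat(Fagg, ff$y)
  } else {
    head_in <- Fagg
  }
  cache$agg_channels <- nchan(Fagg)

  cv <- conv_fwd(head_in, p$head_w, p$head_b, stride = 1L, pad = 1L)
  cache$head_conv <- cv$cache
  bn <- bn_fwd(cv$y, p$head_bn_g, p$head_bn_b, bs$head, training)
  bs$head <- bn$stats; cache$head_bn <- bn$cache
  rl <- relu6_fwd(bn$y); cache$head_relu <- rl$cache
  dr <- dropout_fwd(rl$y, cfg$dropout, training, dropout_seed)
  cache$head_drop <- dr$cache
  h1 <- dr$y

  up1 <- resize_fwd(h1, dim(S)[1], dim(S)[2])
  cache$up1 <- up1$cache
  u1_in <- chcat(up1$y, S)
  cv <- conv_fwd(u1_in, p$u1_w, p$u1_b, stride = 1L, pad = 1L)
  cache$u1_conv <- cv$cache
  bn <- bn_fwd(cv$y, p$u1_bn_g, p$u1_bn_b, bs$u1, training)
  bs$u1 <- bn$stats; cache$u1_bn <- bn$cache
  rl <- relu6_fwd(bn$y); cache$u1_relu <- rl$cache
  u1 <- rl$y

  # final 3x3 refinement runs at the stride-2 grid; only the 1x1 output
  # convolution runs at full resolution (4x cheaper, boundary detail is
  # preserved within the 2 px the bilinear upsample spans)
  cv <- conv_fwd(u1, p$u2_w, p$u2_b, stride = 1L, pad = 1L)
  cache$u2_conv <- cv$cache
  bn <- bn_fwd(cv$y, p$u2_bn_g, p$u2_bn_b, bs$u2, training)
  bs$u2 <- bn$stats; cache$u2_bn <- bn$cache
  rl <- relu6_fwd(bn$y); cache$u2_relu <- rl$cache
  up2 <- resize_fwd(rl$y, H, W)
  cache$up2 <- up2$cache

  cv <- conv_fwd(up2$y, p$out_w, p$out_b, stride = 1L, pad = 0L, k = 1L)
  cache$out_conv <- cv$cache
  logits <- cv$y
  dim(logits) <- if (batched) c(H, W, B) else c(H, W)
  prob <- 1 / (1 + exp(-logits))
  cache$prob <- prob
  cache$h1_channels <- nchan(h1)
  cache$S_channels <- nchan(S)
  list(prob = prob, cache = cache, bn_stats = bs)
}

# Backward pass from d loss / d prob (same shape as prob). Returns
# gradients with the same structure as model$params.
model_backward <- function(model, cache, gprob) {
  p <- model$params; cfg <- model$config
  g <- list()
  batched <- cache$batched

  glogits <- gprob * cache$prob * (1 - cache$prob)
  glog <- array(glogits, c(dim(cache$prob), 1L))
  bw <- conv_bwd(cache$out_conv, p$out_w, glog)
  g$out_w <- bw$gw; g$out_b <- bw$gb
  gy <- resize_bwd(cache$up2, bw$gx)
  gy <- relu6_bwd(cache$u2_relu, gy)
  bw2 <- bn_bwd(cache$u2_bn, p$u2_bn_g, gy)
  g$u2_bn_g <- bw2$ggamma; g$u2_bn_b <- bw2$gbeta
  bw <- conv_bwd(cache$u2_conv, p$u2_w, bw2$gx)
  g$u2_w <- bw$gw; g$u2_b <- bw$gb
  gu1 <- bw$gx

  gy <- relu6_bwd(cache$u1_relu, gu1)
  bw2 <- bn_bwd(cache$u1_bn, p$u1_bn_g, gy)
  g$u1_bn_g <- bw2$ggamma; g$u1_bn_b <- bw2$gbeta
  bw <- conv_bwd(cache$u1_conv, p$u1_w, bw2$gx)
  g$u1_w <- bw$gw; g$u1_b <- bw$gb
  nh1 <- cache$h1_channels
  gup1 <- chslice(bw$gx, seq_len(nh1))
  gS_dec <- chslice(bw$gx, nh1 + seq_len(cache$S_channels))
  gh1 <- resize_bwd(cache$up1, gup1)

  gy <- dropout_bwd(cache$head_drop, gh1)
  gy <- relu6_bwd(cache$head_relu, gy)
  bw2 <- bn_bwd(cache$head_bn, p$head_bn_g, gy)
  g$head_bn_g <- bw2$ggamma; g$head_bn_b <- bw2$gbeta
  bw <- conv_bwd(cache$head_conv, p$head_w, bw2$gx)
  g$head_w <- bw$gw; g$head_b <- bw$gb
  gFagg <- chslice(bw$gx, seq_len(cache$agg_channels))
  # force channels receive no parameter gradient (computed, not learned)

  # aggregation backward
  alpha <- cache$alpha
  R <- cache$R
  galpha <- vapply(seq_along(R), function(l) sum(R[[l]] * gFagg), numeric(1))
  g$alpha_raw <- alpha * (galpha - sum(galpha * alpha))
  gP <- vector("list", length(R))
  for (l in seq_along(R)) {
    gr <- alpha[l] * gFagg
    gP[[l]] <- if (is.null(cache$resize[[l]])) gr
               else resize_bwd(cache$resize[[l]], gr)
  }

  # attention backward (queries = projected stride-4, kv = stride-32)
  L <- length(gP)
  if (batched) {
    gWq <- 0; gWk <- 0; gWv <- 0
    glow <- gP[[1]]
    ghigh <- array(0, cache$attn_high_dim)
    for (bb in seq_len(cache$B)) {
      ab <- attention_bwd(cache$attn[[bb]], p$attn, img_slice(gP[[1]], bb))
      glow[, , bb, ] <- ab$glow
      ghigh[, , bb, ] <- ab$ghigh
      gWq <- gWq + ab$gWq; gWk <- gWk + ab$gWk; gWv <- gWv + ab$gWv
    }
    g$attn <- list(Wq = gWq, Wk = gWk, Wv = gWv)
    gP[[1]] <- glow
    gP[[L]] <- gP[[L]] + ghigh
  } else {
    ab <- attention_bwd(cache$attn, p$attn, gP[[1]])
    g$attn <- list(Wq = ab$gWq, Wk = ab$gWk, Wv = ab$gWv)
    gP[[1]] <- ab$glow
    gP[[L]] <- gP[[L]] + ab$ghigh
  }

  # projection backward -> per-tap gradients
  g$proj <- vector("list", length(gP))
  gtaps <- vector("list", length(gP))
  for (l in seq_along(gP)) {
    bw <- conv_bwd(cache$proj[[l]], p$proj[[l]]$w, gP[[l]])
    g$proj[[l]] <- list(w = bw$gw, b = bw$gb)
    gtaps[[l]] <- bw$gx
  }

  # encoder stages in reverse, accumulating tap gradients
  g$stages <- vector("list", length(p$stages))
  gf <- NULL
  tap_k <- length(cfg$tap_stages)
  for (i in rev(seq_along(p$stages))) {
    if (i %in% cfg$tap_stages) {
      gf <- if (is.null(gf)) gtaps[[tap_k]] else gf + gtaps[[tap_k]]
      tap_k <- tap_k - 1L
    }
    st <- p$stages[[i]]; sc <- cache$stages[[i]]
    gout <- gf
    bw2 <- bn_bwd(sc$pbn, st$pbn_g, gout)
    gs <- list(pbn_g = bw2$ggamma, pbn_b = bw2$gbeta)
    bw <- conv_bwd(sc$p, st$pw, bw2$gx)
    gs$pw <- bw$gw; gs$pb <- bw$gb
    gy <- relu6_bwd(sc$drelu, bw$gx)
    bw2 <- bn_bwd(sc$dbn, st$dbn_g, gy)
    gs$dbn_g <- bw2$ggamma; gs$dbn_b <- bw2$gbeta
    dwb <- dw_bwd(sc$d, st$dw, bw2$gx)
    gs$dw <- dwb$gw
    gy <- relu6_bwd(sc$erelu, dwb$gx)
    bw2 <- bn_bwd(sc$ebn, st$ebn_g, gy)
    gs$ebn_g <- bw2$ggamma; gs$ebn_b <- bw2$gbeta
    bw <- conv_bwd(sc$e, st$ew, bw2$gx)
    gs$ew <- bw$gw; gs$eb <- bw$gb
    gf <- bw$gx
    if (sc$residual) gf <- gf + gout
    g$stages[[i]] <- gs
  }

  # stem (decoder skip gradient joins here)
  gf <- gf + gS_dec
  gy <- relu6_bwd(cache$stem_relu, gf)
  bw2 <- bn_bwd(cache$stem_bn, p$stem_bn_g, gy)
  g$stem_bn_g <- bw2$ggamma; g$stem_bn_b <- bw2$gbeta
  bw <- conv_bwd(cache$stem_conv, p$stem_w, bw2$gx)
  g$stem_w <- bw$gw; g$stem_b <- bw$gb
  g
}

normalize_image <- function(image) {
  array(as.numeric(image) / 255 - 0.5, dim(image))
}

pad_to_multiple <- function(x, m = 32L) {
  d <- dim(x)
  H2 <- as.integer(ceiling(d[1] / m) * m)
  W2 <- as.integer(ceiling(d[2] / m) * m)
  if (H2 == d[1] && W2 == d[2]) return(list(x = x, orig = d[1:2]))
  out <- array(0, c(H2, W2, d[3]))
  out[seq_len(d[1]), seq_len(d[2]), ] <- x
  list(x = out, orig = d[1:2])
}

#' Segment an image (optionally with two-pass force refinement)
#'
#' Pass 1 runs the network with zero force channels. With `two_pass`, a
#' force field is derived from the first-pass probabilities
#' ([force_field_from_prediction()]) and fed to a second pass. Instances are
#' the 8-connected components of the thresholded probability map.
#'
#' @param model a `forceseg_model`.
#' @param image H x W x 3 RGB array in `[0, 255]` (any size; padded
#'   internally to a multiple of 32).
#' @param two_pass run the force-refined second pass (only meaningful when
#'   the model uses force channels).
#' @param threshold instance threshold on the probability map.
#' @return list with `prob` (H x W), `labels` (H x W integer instance map)
#'   and `prob_first_pass`.
#' @export
segment <- function(model, image, two_pass = FALSE, threshold = 0.5) {
  image <- check_rgb(image)
  pd <- pad_to_multiple(normalize_image(image))
  fw <- model_forward(model, pd$x, force = NULL, training = FALSE)
  prob1 <- fw$prob[seq_len(pd$orig[1]), seq_len(pd$orig[2])]
  prob <- prob1
  if (two_pass && model$config$use_force_channels) {
    ff <- force_field_from_prediction(fw$prob,
                                      alpha = model$config$force_alpha,
                                      threshold = model$config$force_threshold,
                                      mode = model$config$force_mode)
    fw2 <- model_forward(model, pd$x, force = ff$field, training = FALSE)
    prob <- fw2$prob[seq_len(pd$orig[1]), seq_len(pd$orig[2])]
  }
  labels <- .label8(matrix(as.integer(prob >= threshold),
                           nrow(prob), ncol(prob)))
  list(prob = prob, labels = labels, prob_first_pass = prob1)
}
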