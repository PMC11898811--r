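#' Augmentation parameters
#'
#' @param rotate_deg rotation range (degrees, uniform in `±rotate_deg`).
#' @param hflip_prob horizontal flip probability.
#' @param elastic_grid control-grid size of the elastic deformation.
#' @param elastic_sigma control-point displacement s.d. in pixels.
#' @param gamma_range contrast jitter as a gamma exponent range.
#' @param scale_jitter optional isotropic scale jitter (fraction, 0 = off).
#' @return list of class `forceseg_aug_params`.
#' @export
aug_params <- function(rotate_deg = 15, hflip_prob = 0.5, elastic_grid = 4,
                       elastic_sigma = 3, gamma_range = c(0.8, 1.2),
                       scale_jitter = 0) {
  structure(list(rotate_deg = rotate_deg, hflip_prob = hflip_prob,
                 elastic_grid = elastic_grid, elastic_sigma = elastic_sigma,
                 gamma_range = gamma_range, scale_jitter = scale_jitter),
            class = "forceseg_aug_params")
}

#' Jointly augment an image and its label map
#'
#' Random rotation, horizontal flip, elastic deformation and gamma jitter.
#' The identical geometric transform is applied to image (bilinear) and
#' labels (nearest neighbour); extreme points are recomputed from the
#' transformed label map, never transformed as coordinates.
#'
#' @param image H x W x 3 array in `[0, 255]`.
#' @param labels H x W integer instance map.
#' @param seed seed controlling all random draws.
#' @param params an [aug_params()].
#' @return list with `image`, `labels`, `extreme_points`, and the drawn
#'   `angle` (deg), `flipped`, `gamma`.
#' @export
augment <- function(image, labels, seed, params = aug_params()) {
  stopifnot(all(dim(image)[1:2] == dim(labels)))
  h <- nrow(labels); w <- ncol(labels)
  with_seed(seed, {
    angle <- runif(1, -params$rotate_deg, params$rotate_deg)
    flip <- runif(1) < params$hflip_prob
    gamma <- runif(1, params$gamma_range[1], params$gamma_range[2])
    scale <- if (params$scale_jitter > 0)
      1 + runif(1, -params$scale_jitter, params$scale_jitter) else 1
    ng <- params$elastic_grid
    disp_r <- matrix(rnorm(ng * ng, 0, params$elastic_sigma), ng, ng)
    disp_c <- matrix(rnorm(ng * ng, 0, params$elastic_sigma), ng, ng)

    rr <- matrix(0:(h - 1), h, w)
    cc <- matrix(0:(w - 1), h, w, byrow = TRUE)
    cr <- (h - 1) / 2; col0 <- (w - 1) / 2
    th <- angle * pi / 180
    dr <- rr - cr; dc <- cc - col0
    if (flip) dc <- -dc
    src_r <- cr + (cos(th) * dr - sin(th) * dc) / scale
    src_c <- col0 + (sin(th) * dr + cos(th) * dc) / scale
    if (params$elastic_sigma > 0 && ng > 1) {
      er <- .bilinear_fwd(array(disp_r, c(ng, ng, 1L)),
                          as.integer(h), as.integer(w))[, , 1]
      ec <- .bilinear_fwd(array(disp_c, c(ng, ng, 1L)),
                          as.integer(h), as.integer(w))[, , 1]
      src_r <- src_r + er
      src_c <- src_c + ec
    }
    img_out <- sample_bilinear(image, src_r, src_c)
    lab_out <- sample_nearest(labels, src_r, src_c)
    img_out <- clamp(255 * (clamp(img_out, 0, 255) / 255)^gamma, 0, 255)
    ids <- sort(unique(lab_out[lab_out > 0]))
    eps <- lapply(ids, function(i) extract_extreme_points(lab_out == i))
    names(eps) <- as.character(ids)
    list(image = img_out, labels = lab_out, extreme_points = eps,
         angle = angle, flipped = flip, gamma = gamma)
  })
}

sample_bilinear <- function(image, src_r, src_c) {
  image <- as_image_array(image)
  h <- dim(image)[1]; w <- dim(image)[2]; nc <- dim(image)[3]
  r <- clamp(src_r, 0, h - 1); c <- clamp(src_c, 0, w - 1)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  r1 <- pmin(r0 + 1, h - 1); c1 <- pmin(c0 + 1, w - 1)
  out <- array(0, c(nrow(src_r), ncol(src_r), nc))
  for (ch in seq_len(nc)) {
    plane <- image[, , ch]
    g <- function(ri, ci) plane[ri + ci * h + 1]
    out[, , ch] <- (1 - fr) * (1 - fc) * g(r0, c0) + fr * (1 - fc) * g(r1, c0) +
      (1 - fr) * fc * g(r0, c1) + fr * fc * g(r1, c1)
  }
  out
}

sample_nearest <- function(labels, src_r, src_c) {
  h <- nrow(labels); w <- ncol(labels)
  r <- round(src_r); c <- round(src_c)
  ok <- r >= 0 & r <= h - 1 & c >= 0 & c <= w - 1
  out <- matrix(0L, nrow(src_r), ncol(src_r))
  idx <- which(ok)
  out[idx] <- labels[r[idx] + c[idx] * h + 1]
  out
}

#' Cosine-annealed learning rate
#'
#' `base_lr * 0.5 * (1 + cos(pi * epoch / n_epochs))`, 0-based epochs.
#'
#' @param epoch 0-based epoch index (`0 <= epoch < n_epochs`).
#' @param n_epochs total epochs.
#' @param base_lr initial learning rate.
#' @return learning rate for the epoch (non-negative).
#' @export
cosine_lr <- function(epoch, n_epochs, base_lr) {
  stopifnot(epoch >= 0, epoch < n_epochs)
  max(0, base_lr * 0.5 * (1 + cos(pi * epoch / n_epochs)))
}

#' Training configuration
#'
#' Defaults follow the training recipe: Adam with learning rate 0.001 and
#' weight decay 1e-5, cosine annealing, batch size 8, early stopping with
#' patience 10, loss weights 1.0/0.5/0.3 ramped over the first half of
#' training. The ablation mode selects which refinement components are
#' active: `"none"` (segmentation loss only), `"force_only"` (force
#' channels), `"points_only"` (point/boundary losses), `"full"` (both).
#'
#' @param n_epochs,batch_size,base_lr,weight_decay optimizer settings.
#' @param patience early-stopping patience in epochs.
#' @param seed master seed for the whole run.
#' @param ablation one of `"none"`, `"force_only"`, `"points_only"`,
#'   `"full"`.
#' @param weights a [loss_weights()].
#' @param aug an [aug_params()].
#' @param model a [model_config()] (its `use_force_channels` flag is
#'   overridden by the ablation mode).
#' @param bf_tol boundary-F1 tolerance used for validation metrics.
#' @return list of class `forceseg_train_config`.
#' @export
train_config <- function(n_epochs = 100, batch_size = 8, base_lr = 0.001,
                         weight_decay = 1e-5, patience = 10, seed = 0,
                         ablation = c("full", "none", "force_only",
                                      "points_only"),
                         weights = loss_weights(), aug = aug_params(),
                         model = model_config(), bf_tol = 2) {
  ablation <- match.arg(ablation)
  stopifnot(n_epochs >= 1, batch_size >= 1, base_lr > 0)
  structure(list(n_epochs = n_epochs, batch_size = batch_size,
                 base_lr = base_lr, weight_decay = weight_decay,
                 patience = patience, seed = seed, ablation = ablation,
                 weights = weights, aug = aug, model = model,
                 bf_tol = bf_tol),
            class = "forceseg_train_config")
}

uses_force <- function(mode) mode %in% c("force_only", "full")
uses_points <- function(mode) mode %in% c("points_only", "full")

# Boundary set of an instance label map: pixels whose 4-neighbourhood
# contains background or a different instance (image border counts).
label_boundary <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  pad <- matrix(-1L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- labels
  diff4 <- (pad[1:h, 2:(w + 1)] != labels) |
    (pad[3:(h + 2), 2:(w + 1)] != labels) |
    (pad[2:(h + 1), 1:w] != labels) | (pad[2:(h + 1), 3:(w + 2)] != labels)
  idx <- which(labels > 0 & diff4, arr.ind = TRUE)
  structure(list(points = cbind(row = idx[, 1] - 1L, col = idx[, 2] - 1L),
                 shape = c(h, w), instance_id = NA_integer_),
            class = "forceseg_boundary")
}

# Differentiable refinement terms optimised during training.
#
# Boundary term: misclassification penalty weighted by the distance
# transform of the ground-truth boundary — predicted foreground mass
# outside the true mask costs its distance to the boundary, missing mass
# inside costs the same. Zero exactly at the true mask; per-pixel gradients
# are commensurate with the mean-BCE gradient (the spec-shaped
# weighted-average surrogate in differentiable_surrogates() is kept for
# evaluation; its normalised gradients destabilise training).
#
# Point term: the same misclassification penalty concentrated around the
# four extreme points by Gaussian windows (sd `sigma` px) — the anchors
# must lie on the predicted boundary, so prediction errors near them are
# penalised specifically.
refinement_terms_grad <- function(pred, truth, tb, extremes, sigma = 3) {
  dmap <- boundary_distance_map(tb)
  inside <- truth > 0
  # distances normalised by the image diagonal: keeps the term's gradient
  # at or below the mean-BCE gradient so it refines rather than dominates
  diag_len <- sqrt(nrow(pred)^2 + ncol(pred)^2)
  phi_out <- dmap / diag_len; phi_out[inside] <- 0
  phi_in <- dmap / diag_len; phi_in[!inside] <- 0
  n <- length(pred)
  val_b <- sum(pred * phi_out + (1 - pred) * phi_in) / n
  grad_b <- (phi_out - phi_in) / n

  h <- nrow(pred); w <- ncol(pred)
  wmap <- matrix(0, h, w)
  rr <- matrix(0:(h - 1), h, w)
  cc <- matrix(0:(w - 1), h, w, byrow = TRUE)
  for (ep in extremes) {
    for (nm in c("top", "bottom", "left", "right")) {
      p <- ep[[nm]]
      wmap <- wmap + exp(-((rr - p[1])^2 + (cc - p[2])^2) / (2 * sigma^2))
    }
  }
  ws <- sum(wmap)
  mis_out <- (!inside) * 1
  if (ws > 0) {
    val_pd <- sum(wmap * (pred * mis_out + (1 - pred) * inside)) / ws
    grad_pd <- wmap * (mis_out - inside) / ws
  } else {
    val_pd <- 0
    grad_pd <- matrix(0, h, w)
  }
  list(l_boundary = val_b, grad_boundary = grad_b,
       l_pd = val_pd, grad_pd = grad_pd)
}

# Gradient of the segmentation consistency loss w.r.t. pred.
seg_loss_grad <- function(pred, y, lam) {
  eps <- 1e-7
  p <- clamp(pred, eps, 1 - eps)
  n <- length(p)
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  gbce <- (-y / p + (1 - y) / (1 - p)) / n
  num <- 2 * sum(p * y) + 1
  den <- sum(p) + sum(y) + 1
  dice <- num / den
  gdice <- (2 * y * den - num) / den^2
  active <- (pred > eps & pred < 1 - eps) * 1
  list(value = bce + lam * (1 - dice),
       grad = (gbce - lam * gdice) * active)
}

adam_init <- function(params) {
  zero_like <- function(x) if (is.list(x)) lapply(x, zero_like) else x * 0
  list(m = zero_like(params), v = zero_like(params), t = 0)
}

# One Adam step over the nested parameter list. The aggregation weights
# alpha_raw form their own group: 0.1x learning rate, weight decay 1e-4.
adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  upd <- function(p, g, m, v, name) {
    if (is.list(p)) {
      named <- !is.null(names(p)) && !is.null(names(g))
      nms <- if (is.null(names(p))) as.character(seq_along(p)) else names(p)
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {
        gi <- if (named) g[[nms[i]]] else g[[i]]
        r <- upd(p[[i]], gi, m[[i]], v[[i]], nms[i])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    tr <- attr(p, "trainable")
    if (!is.null(tr) && identical(tr, FALSE))
      return(list(p = p, m = m, v = v))
    alpha_group <- identical(name, "alpha_raw")
    wd <- if (alpha_group) 1e-4 else weight_decay
    lr_eff <- if (alpha_group) 0.1 * lr else lr
    g <- g + wd * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr_eff * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v, "")
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) return(Map(acc_grads, a, b))
  a + b
}

scale_grads <- function(g, s) {
  if (is.list(g)) return(lapply(g, scale_grads, s = s))
  g * s
}

load_dataset <- function(dataset) {
  if (is.data.frame(dataset)) {
    scenes <- lapply(seq_len(nrow(dataset)), function(i) {
      list(image = read_image(dataset$image[i]),
           labels = read_label_png(dataset$labels[i]),
           extreme_points = read_extreme_points_json(dataset$points[i]))
    })
    list(scenes = scenes, split = dataset$split)
  } else {
    stopifnot(is.list(dataset$scenes), length(dataset$split) ==
                length(dataset$scenes))
    dataset
  }
}

#' Train the segmentation model
#'
#' Implements the full training loop: per-sample augmentation, the
#' segmentation consistency loss plus differentiable point/boundary
#' surrogates under the curriculum ramp, Adam with cosine annealing, and
#' early stopping on the validation total loss. Force-equipped modes train
#' in two passes per sample — a zero-force pass and a pass whose force
#' channels are derived from the model's own first-pass prediction — so
#' training matches the two-pass inference scheme exactly. Fully seeded:
#' equal config and data give identical histories and parameters.
#'
#' @param dataset a manifest data.frame from [make_dataset()] /
#'   [read_manifest()], or a list with `scenes` and `split` as produced by
#'   [synth_dataset()].
#' @param config a [train_config()].
#' @param out_dir optional directory; when given, `history.csv` is written.
#' @param verbose print a line per epoch.
#' @return list with `model` (parameters restored from the best epoch),
#'   `history` (one row per epoch), `best_epoch`, `stopped_early`.
#' @export
train <- function(dataset, config = train_config(), out_dir = NULL,
                  verbose = FALSE) {
  ds <- load_dataset(dataset)
  tr_idx <- which(ds$split == "train")
  va_idx <- which(ds$split == "val")
  if (length(tr_idx) == 0 || length(va_idx) == 0)
    stop_forceseg("dataset must contain non-empty train and val splits",
                  "forceseg_empty_split")
  mode <- config$ablation
  mcfg <- config$model
  mcfg$use_force_channels <- uses_force(mode)
  model <- build_model(mcfg, seed = config$seed)
  astate <- adam_init(model$params)

  N <- config$n_epochs
  B <- config$batch_size
  seeds <- derive_seeds(config$seed + 1L, 4L)
  epoch_seeds <- derive_seeds(seeds[1], N)

  history <- list()
  # validation total loss uses the raw (fully ramped) weights throughout so
  # that epochs are comparable for early stopping / best-epoch selection
  w_val <- c(seg = config$weights$beta_seg,
             boundary = if (uses_points(mode)) config$weights$beta_boundary
                        else 0,
             pd = if (uses_points(mode)) config$weights$beta_pd else 0)
  best_val <- Inf; best_epoch <- 0L; best_params <- NULL; best_bn <- NULL
  wait <- 0L; stopped_early <- FALSE

  for (epoch in seq_len(N)) {
    lr <- cosine_lr(epoch - 1, N, config$base_lr)
    ramp <- curriculum_ramp(epoch - 1, N)
    w_eff <- c(seg = config$weights$beta_seg,
               boundary = if (uses_points(mode))
                 config$weights$beta_boundary * ramp else 0,
               pd = if (uses_points(mode)) config$weights$beta_pd * ramp else 0)
    es <- derive_seeds(epoch_seeds[epoch], 3L)
    order_idx <- with_seed(es[1], sample(tr_idx))
    sample_seeds <- derive_seeds(es[2], length(order_idx) * 2L)
    tl <- c(seg = 0, boundary = 0, pd = 0, total = 0); nb <- 0L

    batches <- split(order_idx, ceiling(seq_along(order_idx) / B))
    batch_seeds <- derive_seeds(es[3], length(batches) * 2L)
    si <- 0L
    for (bi in seq_along(batches)) {
      batch <- batches[[bi]]
      nbatch <- length(batch)
      aus <- vector("list", nbatch)
      for (k in seq_len(nbatch)) {
        si <- si + 1L
        sc <- ds$scenes[[batch[k]]]
        aus[[k]] <- augment(sc$image, sc$labels, seed = sample_seeds[si],
                            params = config$aug)
      }
      # common canvas (samples are zero-padded into the top-left corner)
      Hb <- as.integer(ceiling(max(vapply(aus, function(a) nrow(a$labels),
                                          numeric(1))) / 32) * 32)
      Wb <- as.integer(ceiling(max(vapply(aus, function(a) ncol(a$labels),
                                          numeric(1))) / 32) * 32)
      xb <- array(0, c(Hb, Wb, nbatch, 3L))
      ys <- vector("list", nbatch)
      for (k in seq_len(nbatch)) {
        au <- aus[[k]]
        h <- nrow(au$labels); w <- ncol(au$labels)
        xb[seq_len(h), seq_len(w), k, ] <- normalize_image(au$image)
        y <- matrix(0, Hb, Wb)
        y[seq_len(h), seq_len(w)] <- (au$labels > 0) * 1
        lab <- matrix(0L, Hb, Wb)
        lab[seq_len(h), seq_len(w)] <- au$labels
        ys[[k]] <- list(y = y, labels = lab, extreme_points = au$extreme_points)
      }

      sample_loss_grad <- function(prob, k) {
        yk <- ys[[k]]
        sg <- seg_loss_grad(prob, yk$y, config$weights$lam)
        gprob <- w_eff["seg"] * sg$grad
        l_bnd <- 0; l_pd <- 0
        if (uses_points(mode) && ramp > 0 && max(yk$labels) > 0) {
          tb <- label_boundary(yk$labels)
          sr <- refinement_terms_grad(prob, yk$y, tb, yk$extreme_points)
          l_bnd <- sr$l_boundary; l_pd <- sr$l_pd
          gprob <- gprob + w_eff["boundary"] * sr$grad_boundary +
            w_eff["pd"] * sr$grad_pd
        }
        list(l = c(seg = as.numeric(sg$value), boundary = as.numeric(l_bnd),
                   pd = as.numeric(l_pd),
                   total = as.numeric(w_eff["seg"] * sg$value +
                     w_eff["boundary"] * l_bnd + w_eff["pd"] * l_pd)),
             gprob = gprob)
      }

      run_pass <- function(force, dropout_seed) {
        fw <- model_forward(model, xb, force = force, training = TRUE,
                            dropout_seed = dropout_seed)
        model$bn_stats <<- fw$bn_stats
        gpb <- array(0, c(Hb, Wb, nbatch))
        lsum <- c(seg = 0, boundary = 0, pd = 0, total = 0)
        for (k in seq_len(nbatch)) {
          lg <- sample_loss_grad(fw$prob[, , k], k)
          gpb[, , k] <- lg$gprob / nbatch
          lsum <- lsum + lg$l
        }
        list(g = model_backward(model, fw$cache, gpb),
             losses = lsum / nbatch, prob = fw$prob)
      }

      # pass 1: zero force channels (the regime inference pass 1 runs in)
      p1 <- run_pass(NULL, batch_seeds[2L * bi - 1L])
      g <- p1$g
      losses <- p1$losses

      if (uses_force(mode)) {
        # pass 2: force fields derived from the model's own first-pass
        # predictions, exactly as at inference; both passes carry loss.
        # The injected magnitude follows the same curriculum ramp as the
        # refinement losses, so early epochs (when first-pass predictions
        # are still noise) do not train on misleading fields.
        fb <- array(0, c(Hb, Wb, nbatch, 2L))
        if (ramp > 0) for (k in seq_len(nbatch)) {
          ff <- force_field_from_prediction(
            p1$prob[, , k], alpha = mcfg$force_alpha,
            threshold = mcfg$force_threshold, mode = mcfg$force_mode)
          fb[, , k, ] <- ramp * ff$field
        }
        p2 <- run_pass(fb, batch_seeds[2L * bi])
        g <- scale_grads(acc_grads(g, p2$g), 0.5)
        losses <- (losses + p2$losses) / 2
      }

      if (!is.finite(losses["total"]))
        stop_forceseg(sprintf(
          "non-finite loss at epoch %d (seg=%.4g bnd=%.4g pd=%.4g)",
          epoch, losses["seg"], losses["boundary"], losses["pd"]),
          "forceseg_nan_loss")
      tl <- tl + losses * nbatch
      nb <- nb + nbatch

      st <- adam_step(model$params, g, astate, lr, config$weight_decay)
      model$params <- st$params
      astate <- st$state
    }
    tl <- tl / nb

    val <- evaluate_split(model, ds, va_idx, mode, config, w_val)
    history[[epoch]] <- data.frame(
      epoch = epoch, lr = lr,
      train_l_seg = tl["seg"], train_l_boundary = tl["boundary"],
      train_l_pd = tl["pd"], train_l_total = tl["total"],
      w_seg = w_eff["seg"], w_boundary_eff = w_eff["boundary"],
      w_pd_eff = w_eff["pd"],
      val_loss = val$loss, val_dice = val$dice, val_iou = val$iou,
      val_bf = val$bf, row.names = NULL)
    if (verbose)
      message(sprintf("epoch %d lr=%.5f train=%.4f val=%.4f dice=%.3f",
                      epoch, lr, tl["total"], val$loss, val$dice))
    if (val$loss < best_val - 1e-9) {
      best_val <- val$loss; best_epoch <- epoch
      best_params <- model$params; best_bn <- model$bn_stats
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) { stopped_early <- TRUE; break }
    }
  }
  hist <- do.call(rbind, history)
  hist$stopped_early <- stopped_early
  hist$best_epoch <- best_epoch
  model$params <- best_params
  model$bn_stats <- best_bn
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_history_csv(hist, file.path(out_dir, "history.csv"))
  }
  list(model = model, history = hist, best_epoch = best_epoch,
       stopped_early = stopped_early)
}

# History CSV with platform-independent full-precision formatting, so that
# identical runs produce byte-identical files.
write_history_csv <- function(hist, path) {
  fmt <- function(x) if (is.numeric(x)) sprintf("%.12g", x) else as.character(x)
  out <- as.data.frame(lapply(hist, fmt), stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

evaluate_split <- function(model, ds, idx, mode, config, w_eff) {
  tot <- 0; dice <- 0; iou <- 0; bf <- 0
  for (i in idx) {
    sc <- ds$scenes[[i]]
    x <- normalize_image(sc$image)
    fw <- model_forward(model, x, force = NULL, training = FALSE)
    if (uses_force(mode)) {
      ff <- force_field_from_prediction(
        fw$prob, alpha = config$model$force_alpha,
        threshold = config$model$force_threshold,
        mode = config$model$force_mode)
      fw <- model_forward(model, x, force = ff$field, training = FALSE)
    }
    y <- (sc$labels > 0) * 1
    l_seg <- segmentation_consistency_loss(fw$prob, y, config$weights$lam)
    l_bnd <- 0; l_pd <- 0
    if (uses_points(mode) && max(sc$labels) > 0) {
      sr <- refinement_terms_grad(fw$prob, y, label_boundary(sc$labels),
                                  sc$extreme_points)
      l_bnd <- sr$l_boundary; l_pd <- sr$l_pd
    }
    tot <- tot + w_eff["seg"] * l_seg + w_eff["boundary"] * l_bnd +
      w_eff["pd"] * l_pd
    pred <- (fw$prob >= 0.5) * 1
    m <- region_metrics(confusion(pred, y))
    dice <- dice + m$dice; iou <- iou + m$iou
    bf <- bf + boundary_f1(pred, y, config$bf_tol)
  }
  n <- length(idx)
  list(loss = as.numeric(tot) / n, dice = dice / n, iou = iou / n, bf = bf / n)
}

#' Run the ablation study over refinement components
#'
#' Trains one model per mode with shared data and seed, evaluates mean Dice
#' and boundary F1 on the test split (two-pass inference for force-equipped
#' modes), and returns an ablation table.
#'
#' @param dataset as in [train()] (must contain a test split).
#' @param config a [train_config()]; its `ablation` field is overridden.
#' @param modes at least two of `"none"`, `"force_only"`, `"points_only"`,
#'   `"full"`.
#' @param out_dir optional; writes `ablation.csv` and per-mode history CSVs.
#' @return list with `table` (data.frame mode/dice/bf), `histories` and
#'   `models` (named by mode).
#' @export
run_ablation <- function(dataset, config = train_config(),
                         modes = c("none", "force_only", "points_only",
                                   "full"),
                         out_dir = NULL) {
  stopifnot(length(modes) >= 2)
  ds <- load_dataset(dataset)
  te_idx <- which(ds$split == "test")
  if (length(te_idx) == 0)
    stop_forceseg("dataset has no test split", "forceseg_empty_split")
  rows <- list(); histories <- list(); models <- list()
  for (mode in modes) {
    cfg <- config
    cfg$ablation <- mode
    fit <- train(ds, cfg,
                 out_dir = if (!is.null(out_dir))
                   file.path(out_dir, mode) else NULL)
    ev <- evaluate_test(fit$model, ds, te_idx, two_pass = uses_force(mode),
                        bf_tol = config$bf_tol)
    rows[[mode]] <- data.frame(mode = mode, dice = ev$dice, bf = ev$bf,
                               stringsAsFactors = FALSE)
    histories[[mode]] <- fit$history
    models[[mode]] <- fit$model
  }
  table <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(table, file.path(out_dir, "ablation.csv"), row.names = FALSE)
  }
  list(table = table, histories = histories, models = models)
}

evaluate_test <- function(model, ds, idx, two_pass, bf_tol = 2) {
  dice <- 0; bf <- 0
  for (i in idx) {
    sc <- ds$scenes[[i]]
    sg <- segment(model, sc$image, two_pass = two_pass)
    pred <- (sg$labels > 0) * 1
    y <- (sc$labels > 0) * 1
    dice <- dice + region_metrics(confusion(pred, y))$dice
    bf <- bf + boundary_f1(pred, y, bf_tol)
  }
  list(dice = dice / length(idx), bf = bf / length(idx))
}
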