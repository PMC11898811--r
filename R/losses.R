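#' Boundary pixels of a binary mask
#'
#' A boundary pixel is a foreground pixel with at least one background
#' 4-neighbour; the image border counts as background.
#'
#' @param mask binary H x W matrix.
#' @param instance_id optional id recorded in the result.
#' @return object of class `forceseg_boundary`: list with `points`
#'   (n x 2 matrix of 0-based (row, col)), `shape` (c(H, W)) and
#'   `instance_id`. Empty mask gives zero points.
#' @export
extract_boundary <- function(mask, instance_id = NA_integer_) {
  m <- mask > 0
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  bg4 <- !pad[1:h, 2:(w + 1)] | !pad[3:(h + 2), 2:(w + 1)] |
         !pad[2:(h + 1), 1:w] | !pad[2:(h + 1), 3:(w + 2)]
  idx <- which(m & bg4, arr.ind = TRUE)
  structure(list(points = cbind(row = idx[, 1] - 1L, col = idx[, 2] - 1L),
                 shape = c(h, w), instance_id = instance_id),
            class = "forceseg_boundary")
}

boundary_sentinel <- function(shape) sqrt(sum(shape^2))

min_dists_to_set <- function(points, set_points) {
  # for each row of `points`, Euclidean distance to the nearest row of
  # `set_points`
  d2 <- outer(rowSums(points^2), rep(1, nrow(set_points))) +
    outer(rep(1, nrow(points)), rowSums(set_points^2)) -
    2 * points %*% t(set_points)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Point distance loss: extreme points to the predicted boundary
#'
#' Sum over the four extreme points of the Euclidean distance to the nearest
#' boundary point; zero iff all four lie on the boundary. An empty boundary
#' returns the sentinel penalty `4 * sqrt(H^2 + W^2)` (total miss).
#'
#' @param extremes a `forceseg_extreme_points` object.
#' @param boundary a `forceseg_boundary` object (the predicted boundary).
#' @return non-negative scalar.
#' @export
point_distance_loss <- function(extremes, boundary) {
  if (nrow(boundary$points) == 0)
    return(4 * boundary_sentinel(boundary$shape))
  e <- do.call(rbind, extremes[c("top", "bottom", "left", "right")])
  sum(min_dists_to_set(e, boundary$points))
}

#' Boundary alignment loss: directed mean distance pred -> target
#'
#' Mean over predicted boundary points of the Euclidean distance to the
#' nearest target boundary point; zero iff the predicted boundary is a
#' subset of the target. Either side empty returns the sentinel
#' `sqrt(H^2 + W^2)`.
#'
#' @param pred_boundary,target_boundary `forceseg_boundary` objects.
#' @return non-negative scalar.
#' @export
boundary_alignment_loss <- function(pred_boundary, target_boundary) {
  if (nrow(pred_boundary$points) == 0 || nrow(target_boundary$points) == 0)
    return(boundary_sentinel(pred_boundary$shape))
  mean(min_dists_to_set(pred_boundary$points, target_boundary$points))
}

#' Segmentation consistency loss: BCE plus weighted soft-Dice deficit
#'
#' Mean binary cross-entropy over pixels (predictions clipped to
#' `[1e-7, 1 - 1e-7]`) plus `lam * (1 - soft Dice)`, where soft Dice uses
#' probability mass with additive smoothing 1 in numerator and denominator.
#'
#' @param pred H x W matrix of probabilities.
#' @param truth H x W binary matrix.
#' @param lam non-negative Dice weight (default 0.5).
#' @return non-negative scalar.
#' @export
segmentation_consistency_loss <- function(pred, truth, lam = 0.5) {
  if (!all(dim(pred) == dim(truth)))
    stop_forceseg("pred and truth shapes differ", "forceseg_shape_error")
  eps <- 1e-7
  p <- clamp(pred, eps, 1 - eps)
  y <- (truth > 0) * 1
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  dice <- (2 * sum(p * y) + 1) / (sum(p) + sum(y) + 1)
  bce + lam * (1 - dice)
}

#' Loss weights and curriculum descriptor
#'
#' Raw magnitudes default to the training recipe's 1.0 (segmentation),
#' 0.5 (boundary alignment), 0.3 (point distance), with the Dice weight
#' `lam = 0.5`. The curriculum ramps the boundary/point weights linearly
#' from 0 to their raw values over the first half of training.
#'
#' @param beta_seg,beta_boundary,beta_pd non-negative raw weights.
#' @param lam non-negative Dice weight inside the segmentation loss.
#' @param curriculum schedule descriptor (only `"linear-half"` implemented).
#' @return object of class `forceseg_loss_weights`.
#' @export
loss_weights <- function(beta_seg = 1.0, beta_boundary = 0.5, beta_pd = 0.3,
                         lam = 0.5, curriculum = "linear-half") {
  w <- c(beta_seg, beta_boundary, beta_pd, lam)
  if (any(w < 0) || all(w[1:3] == 0))
    stop("weights must be non-negative with at least one positive")
  structure(list(beta_seg = beta_seg, beta_boundary = beta_boundary,
                 beta_pd = beta_pd, lam = lam, curriculum = curriculum),
            class = "forceseg_loss_weights")
}

curriculum_ramp <- function(epoch, n_epochs) {
  stopifnot(epoch >= 0, epoch < n_epochs)
  min(1, 2 * epoch / n_epochs)
}

#' Weighted total loss under the training curriculum
#'
#' Effective weights: the segmentation weight stays at its raw value; the
#' boundary and point weights are multiplied by
#' `ramp = min(1, 2 * epoch / n_epochs)` (linear 0 to 1 over the first half
#' of training). Epochs are 0-based.
#'
#' @param l_pd,l_boundary,l_seg non-negative component losses.
#' @param weights a `forceseg_loss_weights` object.
#' @param epoch 0-based epoch index.
#' @param n_epochs total number of epochs.
#' @return object of class `forceseg_loss_breakdown`: list with `l_pd`,
#'   `l_boundary`, `l_seg`, `l_total`, `ramp`, `weights_raw`, `weights_eff`.
#' @export
total_loss <- function(l_pd, l_boundary, l_seg, weights = loss_weights(),
                       epoch = 0, n_epochs = 1) {
  if (any(c(l_pd, l_boundary, l_seg) < 0))
    stop("component losses must be non-negative")
  ramp <- curriculum_ramp(epoch, n_epochs)
  eff <- c(seg = weights$beta_seg,
           boundary = weights$beta_boundary * ramp,
           pd = weights$beta_pd * ramp)
  structure(list(
    l_pd = l_pd, l_boundary = l_boundary, l_seg = l_seg,
    l_total = eff["seg"] * l_seg + eff["boundary"] * l_boundary +
      eff["pd"] * l_pd,
    ramp = ramp,
    weights_raw = c(seg = weights$beta_seg, boundary = weights$beta_boundary,
                    pd = weights$beta_pd),
    weights_eff = eff), class = "forceseg_loss_breakdown")
}

# Soft boundary map: probability mass not shared with the 3x3 neighbourhood
# minimum. Reduces to the 8-connected discrete boundary on hard masks.
# Differences below `cutoff` are treated as flat (zero boundary mass): this
# keeps noise-level micro-variation of a soft probability field from
# carrying boundary mass, which would otherwise spread the normalising mass
# over the whole image and destabilise the surrogate's gradients.
soft_boundary_map <- function(pred, cutoff = 0.1) {
  mp <- .minpool3(pred)
  b <- pred - mp$value
  b[b < cutoff] <- 0
  list(b = b, argmin = mp$argmin)
}

# Distance transform: per-pixel Euclidean distance to the nearest point of
# a boundary set.
boundary_distance_map <- function(boundary) {
  h <- boundary$shape[1]; w <- boundary$shape[2]
  img <- matrix(1, h, w)
  if (nrow(boundary$points) > 0)
    img[cbind(boundary$points[, 1] + 1L, boundary$points[, 2] + 1L)] <- 0
  as.matrix(EBImage::distmap(img, metric = "euclidean"))
}

#' Differentiable surrogates of the discrete boundary and point losses
#'
#' The discrete minimum-distance losses are not differentiable in the
#' predicted probabilities; training uses these soft counterparts. The
#' boundary surrogate is the soft-boundary-weighted mean of the target
#' boundary's distance transform:
#' `sum(b * D) / sum(b)` with `b = max(pred - minpool3(pred), 0)`.
#' The point surrogate replaces each extreme point's hard minimum with a
#' log-sum-exp soft minimum (temperature `tau`, default 1 px) of its
#' distances to the soft boundary mass. Both reduce to the discrete losses
#' within 1 px of discretisation when `pred` is a hard mask.
#'
#' @param pred H x W probability matrix.
#' @param target_boundary a `forceseg_boundary` (ground-truth or refined).
#' @param extremes list of `forceseg_extreme_points`, one per instance
#'   (may be empty).
#' @param tau soft-min temperature in pixels.
#' @return list with `l_pd_soft` and `l_boundary_soft` (non-negative
#'   scalars).
#' @export
differentiable_surrogates <- function(pred, target_boundary, extremes,
                                      tau = 1) {
  sb <- soft_boundary_map(pred)
  b <- sb$b
  s <- sum(b)
  dmap <- boundary_distance_map(target_boundary)
  l_boundary_soft <- if (s > 1e-12) sum(b * dmap) / s
                     else boundary_sentinel(target_boundary$shape)
  l_pd_soft <- 0
  if (length(extremes) > 0) {
    h <- nrow(pred); w <- ncol(pred)
    rr <- matrix(0:(h - 1), h, w)
    cc <- matrix(0:(w - 1), h, w, byrow = TRUE)
    for (ep in extremes) {
      for (nm in c("top", "bottom", "left", "right")) {
        p <- ep[[nm]]
        r <- sqrt((rr - p[1])^2 + (cc - p[2])^2)
        z <- sum(b * exp(-r / tau))
        l_pd_soft <- l_pd_soft +
          if (z > 1e-12) max(-tau * log(z), 0)
          else boundary_sentinel(c(h, w))
      }
    }
  }
  list(l_pd_soft = l_pd_soft, l_boundary_soft = l_boundary_soft)
}

# Value + gradient (w.r.t. pred) of both surrogates, used by the trainer.
# Gradient routing through the soft boundary map: d b_p / d pred_p = 1 and
# d b_p / d pred_argmin(p) = -1 wherever b_p > 0.
surrogates_with_grad <- function(pred, target_boundary, extremes, tau = 1) {
  h <- nrow(pred); w <- ncol(pred)
  sb <- soft_boundary_map(pred)
  b <- sb$b
  s <- sum(b)
  dmap <- boundary_distance_map(target_boundary)
  gb <- matrix(0, h, w)   # d(total surrogate)/d b
  if (s > 1e-12) {
    l_boundary_soft <- sum(b * dmap) / s
    gb_boundary <- (dmap - l_boundary_soft) / s
  } else {
    l_boundary_soft <- boundary_sentinel(target_boundary$shape)
    gb_boundary <- matrix(0, h, w)
  }
  l_pd_soft <- 0
  gb_pd <- matrix(0, h, w)
  if (length(extremes) > 0) {
    rr <- matrix(0:(h - 1), h, w)
    cc <- matrix(0:(w - 1), h, w, byrow = TRUE)
    for (ep in extremes) {
      for (nm in c("top", "bottom", "left", "right")) {
        p <- ep[[nm]]
        r <- sqrt((rr - p[1])^2 + (cc - p[2])^2)
        k <- exp(-r / tau)
        z <- sum(b * k)
        if (z > 1e-12) {
          d_e <- -tau * log(z)
          if (d_e > 0) {
            l_pd_soft <- l_pd_soft + d_e
            gb_pd <- gb_pd - tau * k / z
          }
        } else {
          l_pd_soft <- l_pd_soft + boundary_sentinel(c(h, w))
        }
      }
    }
  }
  route <- function(g) {
    g[b <= 0] <- 0
    gp <- g
    scatter <- tapply(as.numeric(g), sb$argmin, sum)
    idx <- as.integer(names(scatter)) + 1L
    gp[idx] <- gp[idx] - scatter
    gp
  }
  list(l_pd_soft = l_pd_soft, l_boundary_soft = l_boundary_soft,
       grad_boundary = route(gb_boundary), grad_pd = route(gb_pd))
}
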