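#' Convert an RGB image to CIELAB
#'
#' Standard sRGB (D65) to CIELAB conversion via [grDevices::convertColor()].
#' L is on the 0–100 scale, a/b roughly in `[-110, 110]`.
#'
#' @param image H x W x 3 array with values in `[0, 255]`.
#' @return H x W x 3 numeric array (L, a, b).
#' @export
convert_to_lab <- function(image) {
  image <- check_rgb(image)
  d <- dim(image)
  pix <- matrix(as.numeric(image), ncol = 3) / 255
  lab <- grDevices::convertColor(pix, from = "sRGB", to = "Lab")
  array(lab, d)
}

#' Colour clustering of a LAB image with seeded k-means++
#'
#' Lloyd iterations from a k-means++ initialisation under a fixed seed, run
#' to convergence (no pixel changes cluster) or the iteration cap. Images
#' with fewer than `k` distinct colours return fewer populated clusters.
#'
#' @param lab_image H x W x 3 LAB array (see [convert_to_lab()]).
#' @param k number of clusters (>= 2, default 3).
#' @param seed RNG seed for the k-means++ initialisation.
#' @param max_iter Lloyd iteration cap.
#' @return object of class `forceseg_clusters`: list with `labels`
#'   (H x W integer matrix, clusters numbered `0..k-1`), `k`, `centers`
#'   (k x 3 matrix of mean LAB colours; `NA` rows for unpopulated clusters)
#'   and `sizes`.
#' @export
cluster_colors <- function(lab_image, k = 3, seed = 0, max_iter = 100) {
  stopifnot(k >= 2)
  lab_image <- check_rgb(lab_image)
  d <- dim(lab_image)
  x <- matrix(as.numeric(lab_image), ncol = 3)
  ux <- unique(x)
  k_eff <- min(k, nrow(ux))
  init <- with_seed(seed, kmeanspp_init(x, k_eff))
  if (k_eff == 1L) {
    assign <- rep(1L, nrow(x))
    centers <- matrix(colMeans(x), 1)
  } else {
    km <- kmeans(x, centers = init, iter.max = max_iter, algorithm = "Lloyd")
    assign <- km$cluster
    centers <- km$centers
  }
  full_centers <- matrix(NA_real_, k, 3)
  full_centers[seq_len(k_eff), ] <- centers
  structure(list(
    labels = matrix(assign - 1L, d[1], d[2]),
    k = k,
    centers = full_centers,
    sizes = tabulate(assign, nbins = k)
  ), class = "forceseg_clusters")
}

# k-means++ seeding (Arthur & Vassilvitskii): first centre uniform, later
# centres sampled proportional to squared distance to the nearest centre.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      cand <- which(!seq_len(n) %in% idx[seq_len(j)])
      idx[j + 1] <- cand[1]
    } else {
      idx[j + 1] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums((x - matrix(x[idx[j + 1], ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  x[idx, , drop = FALSE]
}

#' Designate foreground clusters by distance from the border colour
#'
#' The image border is assumed background-dominant: the cluster whose mean
#' LAB colour lies farthest (Euclidean) from the median colour of the 1-px
#' image border is foreground, and any other cluster farther than half that
#' maximum distance joins it. If the maximum distance falls below
#' `min_contrast` the input is considered degenerate (near-uniform) and an
#' empty mask is returned, flagged via `attr(, "degenerate")`.
#'
#' @param clusters a `forceseg_clusters` object.
#' @param lab_image the LAB image the clusters were computed from.
#' @param min_contrast LAB distance below which no foreground is declared.
#' @return binary H x W matrix (1 = foreground), with attribute `degenerate`.
#' @export
extract_foreground <- function(clusters, lab_image, min_contrast = 8) {
  lab_image <- check_rgb(lab_image)
  h <- dim(lab_image)[1]; w <- dim(lab_image)[2]
  border <- rbind(
    matrix(lab_image[c(1, h), , ], ncol = 3),
    matrix(lab_image[, c(1, w), ], ncol = 3))
  border_med <- apply(border, 2, median)
  dists <- sqrt(rowSums((clusters$centers -
                           matrix(border_med, clusters$k, 3, byrow = TRUE))^2))
  dists[clusters$sizes == 0] <- NA
  maxd <- suppressWarnings(max(dists, na.rm = TRUE))
  degenerate <- !is.finite(maxd) || maxd < min_contrast
  if (degenerate) {
    message("extract_foreground: degenerate input (no contrast against border)")
    fg_ids <- integer(0)
  } else {
    fg_ids <- which(!is.na(dists) & dists > 0.5 * maxd)
    fg_ids <- union(which.max(dists), fg_ids)
  }
  mask <- matrix(0L, h, w)
  mask[clusters$labels %in% (fg_ids - 1L)] <- 1L
  structure(mask, degenerate = degenerate)
}

# Gabor filter bank: real/imaginary pairs at the given orientations (deg)
# and wavelengths (px). sigma follows the common bandwidth-1-octave rule.
gabor_bank <- function(orientations = c(0, 45, 90, 135), wavelengths = c(4, 8)) {
  kernels <- list()
  for (lambda in wavelengths) {
    sigma <- 0.56 * lambda
    half <- ceiling(2.5 * sigma)
    g <- expand.grid(y = -half:half, x = -half:half)
    for (th in orientations * pi / 180) {
      xr <- g$x * cos(th) + g$y * sin(th)
      yr <- -g$x * sin(th) + g$y * cos(th)
      env <- exp(-(xr^2 + 0.25 * yr^2) / (2 * sigma^2))
      n <- 2 * half + 1
      kernels[[length(kernels) + 1]] <- list(
        re = matrix(env * cos(2 * pi * xr / lambda), n, n),
        im = matrix(env * sin(2 * pi * xr / lambda), n, n))
    }
  }
  kernels
}

gabor_energy <- function(gray, bank = gabor_bank()) {
  energy <- 0
  for (kk in bank) {
    re <- as.matrix(EBImage::filter2(gray, kk$re))
    im <- as.matrix(EBImage::filter2(gray, kk$im))
    energy <- energy + sqrt(re^2 + im^2)
  }
  as.matrix(EBImage::gblur(energy, 2))
}

# Uniform LBP (radius 1, 8 points): per pixel, the 8-bit neighbour >= centre
# code. The response used for thresholding is the smoothed density of
# "edge-like" uniform patterns (<= 2 bit transitions, 1..7 ones): high in
# locally monotone (granular/textured) regions, low both in flat areas and
# in unstructured iid noise (dominated by non-uniform codes).
lbp_response <- function(gray) {
  h <- nrow(gray); w <- ncol(gray)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- gray
  pad[1, ] <- pad[2, ]; pad[h + 2, ] <- pad[h + 1, ]
  pad[, 1] <- pad[, 2]; pad[, w + 2] <- pad[, w + 1]
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  bits <- lapply(offs, function(o)
    (pad[2:(h + 1) + o[1], 2:(w + 1) + o[2]] >= gray) * 1L)
  trans <- 0L; ones <- 0L
  for (i in seq_along(bits)) {
    j <- if (i == length(bits)) 1L else i + 1L
    trans <- trans + (bits[[i]] != bits[[j]])
    ones <- ones + bits[[i]]
  }
  edgey <- (trans <= 2L) & (ones >= 1L) & (ones <= 7L)
  as.matrix(EBImage::gblur(edgey * 1, 2))
}

#' Texture refinement of a colour-derived foreground mask
#'
#' Keeps only mask pixels whose Gabor energy (4 orientations x 2 wavelengths)
#' and uniform-LBP response both exceed Otsu thresholds computed within the
#' current mask. Strictly a restriction: never adds pixels.
#'
#' @param mask binary H x W matrix.
#' @param image grayscale H x W matrix (any monotone intensity scale).
#' @return binary H x W matrix, a subset of `mask`.
#' @export
texture_refine <- function(mask, image) {
  stopifnot(all(dim(mask) == dim(image)))
  if (!any(mask > 0)) return(mask * 0L)
  gray <- image / max(abs(image), 1e-12)
  ge <- gabor_energy(gray)
  lr <- lbp_response(gray)
  inside <- mask > 0
  keep <- inside &
    (ge > otsu_threshold(ge[inside])) &
    (lr > otsu_threshold(lr[inside]))
  matrix(as.integer(keep), nrow(mask), ncol(mask))
}

# Otsu's threshold on a numeric sample (256-bin histogram over its range).
otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) < 1e-12) return(rng[1] - 1)
  m <- matrix(v, ncol = 1)
  EBImage::otsu(m - rng[1], range = c(0, diff(rng)), levels = 256) + rng[1]
}

#' Morphological cleanup: 3x3 opening then 5x5 closing
#'
#' Square (box) structuring elements, exactly in that order: opening removes
#' speckle smaller than 3x3, closing fills gaps up to the 5x5 reach.
#'
#' @param mask binary H x W matrix.
#' @return binary H x W matrix.
#' @export
morphological_clean <- function(mask) {
  m <- (mask > 0) * 1
  m <- EBImage::opening(m, EBImage::makeBrush(3L, "box"))
  m <- EBImage::closing(m, EBImage::makeBrush(5L, "box"))
  matrix(as.integer(as.matrix(m) > 0), nrow(mask), ncol(mask))
}

#' Connected-component instances from a binary mask
#'
#' 8-connected labelling; components below the minimum area are dropped and
#' the survivors renumbered 1..n in row-major order of their top-left-most
#' pixel.
#'
#' @param mask binary H x W matrix.
#' @param min_area smallest component kept, in pixels (default 20).
#' @return object of class `forceseg_pseudo_labels`: list with `labels`
#'   (H x W integer instance map, 0 = background), `n`, `connectivity` (8)
#'   and `provenance` (`"pseudo"`).
#' @export
components_to_instances <- function(mask, min_area = 20) {
  lab <- .label8(matrix(as.integer(mask > 0), nrow(mask), ncol(mask)))
  sizes <- tabulate(lab[lab > 0], nbins = max(lab, 0))
  keep <- which(sizes >= min_area)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  structure(list(labels = out, n = length(keep), connectivity = 8L,
                 provenance = "pseudo"),
            class = "forceseg_pseudo_labels")
}

#' Extreme points (top / bottom / left / right) of an instance mask
#'
#' Deterministic tie-breaks: topmost pixel with the smallest column,
#' bottom-most with the largest column, leftmost with the smallest row,
#' rightmost with the largest row. Coordinates are 0-based (row, col).
#'
#' @param mask binary or logical H x W matrix with at least one pixel set.
#' @return object of class `forceseg_extreme_points`: list with `top`,
#'   `bottom`, `left`, `right`, each a `(row, col)` pair.
#' @export
extract_extreme_points <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop_forceseg("empty instance: mask has no pixels", "forceseg_empty_instance")
  r <- idx[, 1] - 1L; c <- idx[, 2] - 1L
  top_i <- which(r == min(r)); top_i <- top_i[which.min(c[top_i])]
  bot_i <- which(r == max(r)); bot_i <- bot_i[which.max(c[bot_i])]
  lef_i <- which(c == min(c)); lef_i <- lef_i[which.min(r[lef_i])]
  rig_i <- which(c == max(c)); rig_i <- rig_i[which.max(r[rig_i])]
  structure(list(top = pt(r[top_i], c[top_i]),
                 bottom = pt(r[bot_i], c[bot_i]),
                 left = pt(r[lef_i], c[lef_i]),
                 right = pt(r[rig_i], c[rig_i])),
            class = "forceseg_extreme_points")
}

#' Full preprocessing pipeline: image to pseudo-labels and extreme points
#'
#' Resizes to `target_size` (bilinear), applies per-channel histogram
#' equalization and CLAHE, then runs colour clustering, foreground
#' designation, texture refinement, morphological cleanup, connected
#' components and extreme-point extraction, in that order.
#'
#' @param image H x W x 3 RGB array in `[0, 255]`.
#' @param k number of colour clusters (default 3).
#' @param seed clustering seed.
#' @param target_size working resolution (default 256).
#' @param min_area minimum instance area in pixels at the working resolution.
#' @return list with `pseudo_labels` (a `forceseg_pseudo_labels`),
#'   `extreme_points` (per instance), `mask` (binary foreground after
#'   cleanup) and `size` (working resolution).
#' @export
preprocess_image <- function(image, k = 3, seed = 0, target_size = 256,
                             min_area = 20) {
  image <- check_rgb(image)
  img <- resize_image(image, target_size, target_size)
  img <- enhance_contrast(img)
  lab <- convert_to_lab(img)
  cl <- cluster_colors(lab, k = k, seed = seed)
  fg <- extract_foreground(cl, lab)
  fg <- texture_refine(fg, lab[, , 1])
  fg <- morphological_clean(fg)
  pl <- components_to_instances(fg, min_area = min_area)
  eps <- lapply(seq_len(pl$n), function(i) extract_extreme_points(pl$labels == i))
  names(eps) <- as.character(seq_len(pl$n))
  list(pseudo_labels = pl, extreme_points = eps, mask = fg, size = target_size)
}

#' Bilinear image resize (channels independently)
#'
#' @param image H x W x C array.
#' @param height,width output size.
#' @return resized array.
#' @export
resize_image <- function(image, height, width) {
  image <- as_image_array(image)
  .bilinear_fwd(array(as.numeric(image), dim(image)),
                as.integer(height), as.integer(width))
}

# Histogram normalisation as a per-channel quantile stretch (1st-99th
# percentile mapped to the full range) followed by CLAHE (clip limit 2,
# 8 x 8 tiles) on the luminance channel. Full per-channel equalization was
# rejected: it stretches the (majority) background across the whole range
# and destroys the colour separation the clustering step relies on.
enhance_contrast <- function(image, clahe_strength = 0.5, min_range = 25) {
  out <- array(0, dim(image))
  for (ch in seq_len(dim(image)[3])) {
    x <- image[, , ch]
    q <- stats::quantile(x, c(0.01, 0.99))
    if (q[2] - q[1] < min_range) {
      # nothing but noise in this channel: stretching would amplify it
      out[, , ch] <- clamp(x, 0, 255)
    } else {
      out[, , ch] <- clamp((x - q[1]) / (q[2] - q[1]), 0, 1) * 255
    }
  }
  lum <- (out[, , 1] + out[, , 2] + out[, , 3]) / (3 * 255)
  lum_eq <- as.matrix(EBImage::clahe(clamp(lum, 0, 1), nx = 8, ny = 8,
                                     limit = 2))
  gain <- (clahe_strength * lum_eq + (1 - clahe_strength) * lum) /
    pmax(lum, 1e-3)
  for (ch in 1:3) out[, , ch] <- clamp(out[, , ch] * gain, 0, 255)
  out
}
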