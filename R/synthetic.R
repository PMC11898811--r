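#' Synthetic cytology scenes with exact ground truth
#'
#' Generates stained-smear-like scenes of elliptical cells (nucleus +
#' cytoplasm) on a textured background, with controllable neighbour overlap,
#' staining jitter, Gaussian blur and noise, so that every downstream
#' component can be exercised against exact instance masks and extreme-point
#' annotations. Pixels claimed by more than one ellipse are arbitrated to the
#' instance with the nearest centre (ties to the lower instance id), and
#' extreme points are extracted from the final arbitrated masks, not from the
#' analytic ellipses.
#'
#' @param height,width scene size in pixels (>= 32).
#' @param n_cells number of cells to place (>= 1).
#' @param overlap_target requested fraction of cell pixels covered by more
#'   than one ellipse before arbitration, in `[0, 1)`. 0 requests disjoint
#'   cells with a small safety margin.
#' @param staining_jitter magnitude of the per-scene stain colour/intensity
#'   perturbation (fraction, default 0.1).
#' @param seed integer seed; scenes are byte-identical for equal arguments.
#' @param blur_sigma Gaussian blur applied to the rendered image (px).
#' @param noise_sd additive Gaussian pixel noise (8-bit units).
#' @param max_attempts placement attempts per cell before a
#'   `forceseg_placement_failure` error is signalled.
#' @return an object of class `forceseg_scene`: list with `image`
#'   (H x W x 3 integer array in `[0, 255]`), `labels` (H x W integer matrix,
#'   0 = background), `extreme_points` (named list per instance), realized
#'   `overlap_fraction`, `cells` (per-cell specs), `clipped` flags and `seed`.
#' @export
generate_scene <- function(height = 64, width = 64, n_cells = 4,
                           overlap_target = 0.15, staining_jitter = 0.1,
                           seed = 1, blur_sigma = 0.8, noise_sd = 5,
                           max_attempts = 200) {
  stopifnot(height >= 32, width >= 32, n_cells >= 1,
            overlap_target >= 0, overlap_target < 1)
  with_seed(seed, {
    cells <- place_cells(height, width, n_cells, overlap_target, max_attempts)
    masks <- lapply(cells, rasterize_ellipse, height = height, width = width)
    cover <- Reduce(`+`, masks)
    n_union <- sum(cover > 0)
    overlap_fraction <- if (n_union > 0) sum(cover > 1) / n_union else 0

    labels <- arbitrate_overlaps(masks, cells, height, width)

    keep <- which(tabulate(labels[labels > 0], nbins = length(cells)) > 0)
    if (length(keep) < length(cells)) {
      relab <- integer(length(cells))
      relab[keep] <- seq_along(keep)
      labels[labels > 0] <- relab[labels[labels > 0]]
      cells <- cells[keep]
      masks <- masks[keep]
    }

    eps <- lapply(seq_along(cells), function(i)
      extract_extreme_points(labels == i))
    names(eps) <- as.character(seq_along(cells))

    image <- render_scene(height, width, cells, masks, labels, cover,
                          staining_jitter, blur_sigma, noise_sd)
    structure(list(image = image, labels = labels, extreme_points = eps,
                   overlap_fraction = overlap_fraction, seed = seed,
                   cells = cells,
                   clipped = vapply(cells, function(cl) cl$clipped, logical(1))),
              class = "forceseg_scene")
  })
}

# Sample one cell's shape; placement is handled by place_cells().
sample_cell_spec <- function(height, width) {
  s <- min(height, width)
  a <- runif(1, 0.11, 0.18) * s
  b <- a * runif(1, 0.6, 0.95)
  b <- max(b, 2.05)
  list(center = NULL, semi_axes = c(a = a, b = b),
       rotation = runif(1, 0, pi),
       nucleus_fraction = runif(1, 0.3, 0.55),
       cytoplasm_color = clamp(c(160, 188, 214) + rnorm(3, 0, 12), 90, 250),
       nucleus_color = clamp(c(92, 62, 132) + rnorm(3, 0, 10), 20, 200),
       category = sample(c("Dyskeratotic", "Koilocytotic", "Parabasal",
                           "Superficial-Intermediate", "Metaplastic"), 1),
       clipped = FALSE)
}

ellipse_membership <- function(center, semi_axes, rotation, height, width) {
  rr <- matrix(0:(height - 1), height, width)
  cc <- matrix(0:(width - 1), height, width, byrow = TRUE)
  dr <- rr - center[1]; dc <- cc - center[2]
  co <- cos(rotation); si <- sin(rotation)
  u <- (dc * co + dr * si) / semi_axes[1]
  v <- (-dc * si + dr * co) / semi_axes[2]
  u * u + v * v <= 1
}

rasterize_ellipse <- function(cell, height, width) {
  ellipse_membership(cell$center, cell$semi_axes, cell$rotation, height, width)
}

# Sequential placement. First cell lands anywhere it fits; later cells are
# either rejection-sampled to be disjoint (overlap_target = 0, 2 px margin)
# or pulled next to a random anchor cell with the centre distance
# binary-searched so that each new cell shares roughly
# u = n * t / ((n - 1)(1 + t)) of its own area with earlier cells, which
# makes the realized scene-level shared fraction come out near t.
place_cells <- function(height, width, n_cells, overlap_target, max_attempts) {
  cells <- list()
  occupied <- matrix(FALSE, height, width)
  per_cell_target <- if (n_cells > 1)
    n_cells * overlap_target / ((n_cells - 1) * (1 + overlap_target)) else 0

  for (i in seq_len(n_cells)) {
    spec <- sample_cell_spec(height, width)
    r <- spec$semi_axes[1] + 1
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      if (i == 1L || overlap_target == 0) {
        if (height - 2 * r < 1 || width - 2 * r < 1) break
        ctr <- c(runif(1, r, height - 1 - r), runif(1, r, width - 1 - r))
        m <- ellipse_membership(ctr, spec$semi_axes, spec$rotation,
                                height, width)
        if (i == 1L || !any(m & dilate_box(occupied, 2L))) {
          spec$center <- ctr; placed <- TRUE
        }
      } else {
        anchor <- cells[[sample.int(length(cells), 1)]]
        theta <- runif(1, 0, 2 * pi)
        rsum <- spec$semi_axes[1] + anchor$semi_axes[1]
        lo <- 0.3 * rsum; hi <- 1.25 * rsum
        area <- NULL
        for (it in 1:12) {
          d <- (lo + hi) / 2
          ctr <- anchor$center + d * c(sin(theta), cos(theta))
          ctr <- clamp(ctr, r, c(height, width) - 1 - r)
          m <- ellipse_membership(ctr, spec$semi_axes, spec$rotation,
                                  height, width)
          area <- sum(m)
          frac <- if (area > 0) sum(m & occupied) / area else 1
          if (frac > per_cell_target) lo <- d else hi <- d
        }
        ok <- area > 0 &&
          abs(sum(m & occupied) / area - per_cell_target) < 0.12 &&
          min(sqrt(colSums((vapply(cells, function(cl) cl$center,
                                   numeric(2)) - ctr)^2))) > 1
        if (ok) { spec$center <- ctr; placed <- TRUE }
      }
      if (placed) break
    }
    if (!placed)
      stop_forceseg(sprintf(
        "placement failure: placed %d of %d cells", i - 1L, n_cells),
        "forceseg_placement_failure", achieved = i - 1L)
    m <- rasterize_ellipse(spec, height, width)
    spec$clipped <- ellipse_extends_outside(spec, height, width)
    occupied <- occupied | m
    cells[[i]] <- spec
  }
  cells
}

ellipse_extends_outside <- function(cell, height, width) {
  r <- cell$semi_axes[1]
  any(cell$center - r < 0) || cell$center[1] + r > height - 1 ||
    cell$center[2] + r > width - 1
}

dilate_box <- function(mask, k) {
  if (!any(mask)) return(mask)
  EBImage::dilate(mask * 1, EBImage::makeBrush(2L * k + 1L, "box")) > 0
}

# Nearest analytic centre wins; ties go to the lower instance id (handled by
# strict inequality while scanning ids in order).
arbitrate_overlaps <- function(masks, cells, height, width) {
  labels <- matrix(0L, height, width)
  best <- matrix(Inf, height, width)
  rr <- matrix(0:(height - 1), height, width)
  cc <- matrix(0:(width - 1), height, width, byrow = TRUE)
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    d2 <- (rr - cells[[i]]$center[1])^2 + (cc - cells[[i]]$center[2])^2
    take <- m & (d2 < best)
    labels[take] <- i
    best[m & take] <- d2[m & take]
  }
  labels
}

render_scene <- function(height, width, cells, masks, labels, cover,
                         staining_jitter, blur_sigma, noise_sd) {
  bg <- c(235, 228, 238)
  img <- array(0, c(height, width, 3))
  # coarse background blotches: low-frequency stain unevenness
  blotch <- .bilinear_fwd(array(rnorm(8 * 8, 0, 6), c(8L, 8L, 1L)),
                          as.integer(height), as.integer(width))[, , 1]
  for (ch in 1:3) img[, , ch] <- bg[ch] + blotch
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    inst <- labels == i
    # granular cytoplasm texture so cells are texturally distinct from the
    # additive-noise background (what Gabor/LBP refinement keys on)
    gran <- .bilinear_fwd(array(rnorm(ceiling(height / 3) * ceiling(width / 3),
                                      0, 6),
                                c(as.integer(ceiling(height / 3)),
                                  as.integer(ceiling(width / 3)), 1L)),
                          as.integer(height), as.integer(width))[, , 1]
    nuc <- ellipse_membership(cell$center,
                              rep(cell$nucleus_fraction * cell$semi_axes[2], 2),
                              0, height, width)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[inst] <- cell$cytoplasm_color[ch] + gran[inst]
      plane[inst & nuc] <- cell$nucleus_color[ch] + 0.5 * gran[inst & nuc]
      img[, , ch] <- plane
    }
  }
  # overlapping stain absorbs more light
  over <- cover > 1
  if (any(over)) for (ch in 1:3) {
    plane <- img[, , ch]; plane[over] <- plane[over] * 0.93
    img[, , ch] <- plane
  }
  if (staining_jitter > 0) {
    gain <- 1 + runif(3, -staining_jitter, staining_jitter)
    shift <- runif(1, -staining_jitter, staining_jitter) * 30
    for (ch in 1:3) img[, , ch] <- img[, , ch] * gain[ch] + shift
  }
  if (blur_sigma > 0)
    for (ch in 1:3)
      img[, , ch] <- as.matrix(EBImage::gblur(img[, , ch], blur_sigma))
  img <- img + array(rnorm(length(img), 0, noise_sd), dim(img))
  array(as.integer(round(clamp(img, 0, 255))), dim(img))
}

#' Generate an in-memory synthetic dataset with a seeded 60/20/20 split
#'
#' @param n_scenes number of scenes (>= 1).
#' @param scene_params named list of arguments passed to [generate_scene()]
#'   (everything except `seed`).
#' @param seed master seed; per-scene seeds and the split shuffle derive
#'   from it.
#' @return list with `scenes` (list of `forceseg_scene`) and `split`
#'   (character vector `"train"/"val"/"test"`, largest-remainder 60/20/20).
#' @export
synth_dataset <- function(n_scenes, scene_params = list(), seed = 1) {
  stopifnot(n_scenes >= 1)
  seeds <- derive_seeds(seed, n_scenes + 1L)
  scenes <- lapply(seq_len(n_scenes), function(i)
    do.call(generate_scene, c(scene_params, list(seed = seeds[i]))))
  split <- assign_split(n_scenes, seeds[n_scenes + 1L])
  list(scenes = scenes, split = split)
}

# Largest-remainder rounding of the 60/20/20 rule; ties favour the earlier
# split in (train, val, test) order. Assignment is a seeded shuffle.
assign_split <- function(n, seed, props = c(train = 0.6, val = 0.2, test = 0.2)) {
  counts <- floor(n * props)
  rem <- n * props - counts
  short <- n - sum(counts)
  if (short > 0) {
    order_idx <- order(-rem, seq_along(props))
    counts[order_idx[seq_len(short)]] <- counts[order_idx[seq_len(short)]] + 1
  }
  lab <- rep(names(props), counts)
  with_seed(seed, lab[order(sample.int(n))])
}

#' Write a synthetic dataset to disk (images, label maps, extreme points)
#'
#' Images are 8-bit RGB PNG, label maps 16-bit single-channel PNG, extreme
#' points JSON in the package schema, plus a JSON-lines manifest recording
#' file paths and the seeded, disjoint train/val/test split.
#'
#' @inheritParams synth_dataset
#' @param out_dir output directory (created if missing).
#' @return data.frame manifest (columns `image`, `labels`, `points`, `split`),
#'   invisibly; also written to `manifest.jsonl` in `out_dir`.
#' @export
make_dataset <- function(n_scenes, scene_params = list(), out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop_forceseg(sprintf("cannot create output directory '%s'", out_dir),
                  "forceseg_io_error")
  ds <- synth_dataset(n_scenes, scene_params, seed)
  rows <- lapply(seq_len(n_scenes), function(i) {
    base <- sprintf("scene_%04d", i)
    img <- file.path(out_dir, paste0(base, ".png"))
    lab <- file.path(out_dir, paste0(base, "_labels.png"))
    pts <- file.path(out_dir, paste0(base, "_points.json"))
    sc <- ds$scenes[[i]]
    write_image_png(sc$image, img)
    write_label_png(sc$labels, lab)
    write_extreme_points_json(sc$extreme_points, basename(img), pts)
    data.frame(image = img, labels = lab, points = pts,
               split = ds$split[i], stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  con <- file(file.path(out_dir, "manifest.jsonl"), "w")
  on.exit(close(con))
  for (i in seq_len(nrow(manifest)))
    writeLines(jsonlite::toJSON(as.list(manifest[i, ]), auto_unbox = TRUE), con)
  invisible(manifest)
}

#' Write per-instance extreme points in the package JSON schema
#'
#' Schema: `{"image": str, "instances": {"<id>": {"top": [r,c], "bottom":
#' [r,c], "left": [r,c], "right": [r,c]}}}`, 0-based (row, col) coordinates.
#'
#' @param extreme_points named list of extreme-point sets (one per instance).
#' @param image_name image file name recorded in the JSON.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_extreme_points_json <- function(extreme_points, image_name, path) {
  inst <- lapply(extreme_points, function(ep)
    lapply(ep[c("top", "bottom", "left", "right")], function(p) unname(as.integer(p))))
  jsonlite::write_json(list(image = image_name, instances = inst), path,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read extreme points written by [write_extreme_points_json()]
#'
#' @param path JSON file path.
#' @return named list of extreme-point sets (0-based (row, col) integers).
#' @export
read_extreme_points_json <- function(path) {
  x <- jsonlite::read_json(path)
  lapply(x$instances, function(ep)
    structure(lapply(ep, function(p) pt(p[[1]], p[[2]])),
              class = "forceseg_extreme_points"))
}

#' Load a dataset manifest written by [make_dataset()]
#'
#' @param path path to a `manifest.jsonl` file or its directory.
#' @return data.frame with columns `image`, `labels`, `points`, `split`.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.jsonl")
  rows <- lapply(readLines(path), function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
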