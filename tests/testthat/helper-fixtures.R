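# Shared fixtures, built in code at test time.

random_mask <- function(h, w, p = 0.4, seed = NULL) {
  gen <- function() matrix(rbinom(h * w, 1, p), h, w)
  if (is.null(seed)) gen() else forceseg:::with_seed(seed, gen())
}

# Brute-force extreme points: scan every pixel and apply the tie rules.
scan_extreme_points <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  r <- idx[, 1] - 1L; c <- idx[, 2] - 1L
  best <- function(keep, ord) {
    i <- which(keep)[order(ord[keep])][1]
    c(r[i], c[i])
  }
  list(top = best(r == min(r), c),
       bottom = best(r == max(r), -c),
       left = best(c == min(c), r),
       right = best(c == max(c), -r))
}

# Brute-force boundary: foreground with a background 4-neighbour.
scan_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pts <- NULL
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (mask[i, j] <= 0) next
    nb <- c(if (i > 1) mask[i - 1, j] else 0,
            if (i < h) mask[i + 1, j] else 0,
            if (j > 1) mask[i, j - 1] else 0,
            if (j < w) mask[i, j + 1] else 0)
    if (any(nb <= 0) || i == 1 || i == h || j == 1 || j == w)
      pts <- rbind(pts, c(i - 1L, j - 1L))
  }
  pts
}

# Exhaustive directed distances between point sets.
brute_min_dists <- function(from, to) {
  apply(from, 1, function(p) min(sqrt(colSums((t(to) - p)^2))))
}

small_scene_params <- list(height = 64, width = 64, n_cells = 4,
                           overlap_target = 0.15, staining_jitter = 0.1)
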