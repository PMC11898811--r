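test_that("LAB conversion matches reference colorimetry", {
  black <- array(0, c(2, 2, 3))
  expect_true(all(abs(convert_to_lab(black)[, , 1]) < 1e-6))
  white <- array(255, c(2, 2, 3))
  expect_true(all(abs(convert_to_lab(white)[, , 1] - 100) < 0.01))

  # independent oracle: hand-coded sRGB -> XYZ (D65) -> Lab
  ref_lab <- function(rgb) {
    v <- rgb / 255
    lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
    M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                  0.2126729, 0.7151522, 0.0721750,
                  0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
    xyz <- as.numeric(M %*% lin)
    wn <- c(0.95047, 1.0, 1.08883)
    f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3),
                            t / (3 * (6 / 29)^2) + 4 / 29)
    fx <- f(xyz / wn)
    c(116 * fx[2] - 16, 500 * (fx[1] - fx[2]), 200 * (fx[2] - fx[3]))
  }
  pix <- rbind(c(255, 0, 0), c(0, 128, 255), c(40, 200, 90), c(180, 180, 180))
  img <- array(0, c(2, 2, 3))
  for (ch in 1:3) img[, , ch] <- matrix(pix[, ch], 2, 2)
  got <- convert_to_lab(img)
  for (k in 1:4) {
    i <- (k - 1) %% 2 + 1; j <- (k - 1) %/% 2 + 1
    expect_true(all(abs(got[i, j, ] - ref_lab(pix[k, ])) < 0.5))
  }
  expect_error(convert_to_lab(matrix(0, 4, 4)), class = "forceseg_shape_error")
})

test_that("colour clustering separates flat regions and is deterministic", {
  img <- array(0, c(12, 12, 3))
  img[1:4, , 1] <- 255
  img[5:8, , 2] <- 255
  img[9:12, , 3] <- 255
  lab <- convert_to_lab(img)
  cl <- cluster_colors(lab, k = 3, seed = 1)
  expect_equal(length(unique(as.vector(cl$labels[1:4, ]))), 1)
  expect_equal(length(unique(as.vector(cl$labels[5:8, ]))), 1)
  expect_equal(length(unique(as.vector(cl$labels[9:12, ]))), 1)
  expect_equal(length(unique(c(cl$labels[1, 1], cl$labels[5, 1],
                               cl$labels[9, 1]))), 3)
  cl2 <- cluster_colors(lab, k = 3, seed = 1)
  expect_identical(cl, cl2)
})

test_that("k-means reaches the exhaustive-initialisation optimum on a toy set", {
  # 20 pixels in two well-separated colour groups
  pts <- forceseg:::with_seed(42, rbind(
    matrix(rnorm(30, mean = 10, sd = 1), 10, 3),
    matrix(rnorm(30, mean = 60, sd = 1), 10, 3)))
  lab <- array(0, c(4, 5, 3))
  for (ch in 1:3) lab[, , ch] <- matrix(pts[, ch], 4, 5)
  cl <- cluster_colors(lab, k = 2, seed = 3)
  wss_of <- function(assign) {
    sum(vapply(unique(assign), function(g) {
      m <- colMeans(pts[assign == g, , drop = FALSE])
      sum(t(t(pts[assign == g, , drop = FALSE]) - m)^2)
    }, numeric(1)))
  }
  got_wss <- wss_of(as.vector(cl$labels) + 1L)
  # oracle: Lloyd from every distinct pixel pair as initial centres
  best <- Inf
  for (i in 1:19) for (j in (i + 1):20) {
    if (all(pts[i, ] == pts[j, ])) next
    km <- suppressWarnings(kmeans(pts, centers = pts[c(i, j), ],
                                  iter.max = 100, algorithm = "Lloyd"))
    best <- min(best, sum(km$withinss))
  }
  expect_equal(got_wss, best, tolerance = 1e-8)
})

test_that("clustering an image with fewer distinct colours than k succeeds", {
  img <- array(0, c(8, 8, 3)); img[1:4, , ] <- 120
  cl <- cluster_colors(convert_to_lab(img), k = 3, seed = 0)
  expect_lte(length(unique(as.vector(cl$labels))), 3)
  expect_equal(sum(cl$sizes > 0), 2)
})

test_that("foreground designation keeps cells and flags degenerate input", {
  # controlled three-region image: light background, two cell colours
  img <- array(0, c(96, 96, 3))
  for (ch in 1:3) img[, , ch] <- c(232, 228, 236)[ch]
  cellA <- c(135, 165, 205); cellB <- c(155, 120, 185)
  truth <- matrix(FALSE, 96, 96)
  truth[20:45, 15:50] <- TRUE; truth[55:85, 45:80] <- TRUE
  for (ch in 1:3) {
    p <- img[, , ch]
    p[20:45, 15:50] <- cellA[ch]; p[55:85, 45:80] <- cellB[ch]
    img[, , ch] <- p
  }
  lab <- convert_to_lab(img)
  cl <- cluster_colors(lab, 3, seed = 1)
  fg <- extract_foreground(cl, lab)
  cover <- sum(fg == 1 & truth) / sum(truth)
  expect_gte(cover, 0.95)

  flat <- array(100, c(16, 16, 3))
  labf <- convert_to_lab(flat)
  clf <- cluster_colors(labf, 3, seed = 1)
  expect_message(fgf <- extract_foreground(clf, labf), "degenerate")
  expect_true(attr(fgf, "degenerate"))
})

test_that("texture refinement is a restriction and removes background leakage", {
  sc <- generate_scene(96, 96, 3, 0, 0.1, seed = 6)
  lab <- convert_to_lab(sc$image)
  gray <- lab[, , 1]
  truth <- sc$labels > 0
  # leaky mask: true cells plus random background speckle
  leak <- truth
  spots <- forceseg:::with_seed(8, sample(which(!truth), 400))
  leak[spots] <- TRUE
  refined <- texture_refine(leak * 1, gray)
  expect_true(all(refined[leak == 0] == 0))          # never adds pixels
  expect_lt(sum(refined == 1 & !truth), sum(leak & !truth))  # fewer FP
  expect_identical(texture_refine(matrix(0L, 96, 96), gray),
                   matrix(0L, 96, 96))
})

test_that("morphological cleanup opens 3x3 then closes 5x5", {
  m <- matrix(0L, 20, 20); m[5, 5] <- 1L
  expect_equal(sum(morphological_clean(m)), 0)       # speckle removed

  solid <- matrix(0L, 30, 30); solid[6:25, 6:25] <- 1L
  expect_identical(morphological_clean(solid), solid)

  gap <- solid; gap[10:12, 10:12] <- 0L              # 3-px internal hole
  cleaned <- morphological_clean(gap)
  # brute-force oracle: erode(dilate(open(gap))) with the same elements
  brute_shift <- function(m, set, k) {
    h <- nrow(m); w <- ncol(m); r <- (k - 1) / 2
    out <- matrix(0L, h, w)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      wins <- m[max(1, i - r):min(h, i + r), max(1, j - r):min(w, j + r)]
      out[i, j] <- if (set == "dilate") as.integer(any(wins > 0))
                   else as.integer(all(wins > 0) &&
                                     length(wins) == k * k)
    }
    out
  }
  open3 <- brute_shift(brute_shift(gap, "erode", 3), "dilate", 3)
  close5 <- brute_shift(brute_shift(open3, "dilate", 5), "erode", 5)
  expect_equal(sum(cleaned[10:12, 10:12]), 9)        # gap filled
  expect_identical(cleaned[8:23, 8:23], close5[8:23, 8:23])
})

test_that("connected components match a brute-force flood fill", {
  two <- matrix(0L, 12, 12); two[2:4, 2:4] <- 1L; two[8:11, 7:11] <- 1L
  pl <- components_to_instances(two, min_area = 1)
  expect_setequal(unique(as.vector(pl$labels)), 0:2)
  expect_equal(pl$labels[2, 2], 1L)                  # row-major ordering

  empty <- matrix(0L, 8, 8)
  expect_equal(max(components_to_instances(empty)$labels), 0)

  flood_fill <- function(mask) {
    h <- nrow(mask); w <- ncol(mask)
    lab <- matrix(0L, h, w); nxt <- 0L
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (mask[i, j] == 0 || lab[i, j] > 0) next
      nxt <- nxt + 1L
      stack <- list(c(i, j)); lab[i, j] <- nxt
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          a <- p[1] + di; b <- p[2] + dj
          if (a >= 1 && a <= h && b >= 1 && b <= w &&
              mask[a, b] > 0 && lab[a, b] == 0) {
            lab[a, b] <- nxt
            stack[[length(stack) + 1]] <- c(a, b)
          }
        }
      }
    }
    lab
  }
  for (seed in 1:5) {
    m <- random_mask(16, 16, 0.45, seed = seed)
    got <- components_to_instances(m, min_area = 1)$labels
    expect_identical(got, flood_fill(m))
  }
})

test_that("extreme points obey the tie rules and match the exhaustive scan", {
  single <- matrix(0L, 10, 12); single[6, 10] <- 1L
  ep <- extract_extreme_points(single)
  for (nm in c("top", "bottom", "left", "right"))
    expect_equal(unname(ep[[nm]]), c(5, 9))

  sq <- matrix(0L, 8, 8); sq[3:5, 3:5] <- 1L        # corner (2,2) 0-based
  ep <- extract_extreme_points(sq)
  expect_equal(unname(ep$top), c(2, 2))
  expect_equal(unname(ep$bottom), c(4, 4))
  expect_equal(unname(ep$left), c(2, 2))
  expect_equal(unname(ep$right), c(4, 4))   # max-col tie resolved to max row

  expect_error(extract_extreme_points(matrix(0L, 4, 4)),
               class = "forceseg_empty_instance")

  for (seed in 1:50) {
    m <- random_mask(14, 14, 0.3, seed = 100 + seed)
    if (!any(m > 0)) next
    ep <- extract_extreme_points(m)
    ref <- scan_extreme_points(m)
    for (nm in names(ref))
      expect_equal(unname(ep[[nm]]), as.numeric(ref[[nm]]))
    idx <- which(m > 0, arr.ind = TRUE) - 1L
    expect_true(all(idx[, 1] >= ep$top[1] & idx[, 1] <= ep$bottom[1]))
    expect_true(all(idx[, 2] >= ep$left[2] & idx[, 2] <= ep$right[2]))
  }
})

test_that("the end-to-end preprocessing pipeline recovers instances", {
  sc1 <- generate_scene(96, 96, 1, 0, 0, seed = 12)
  pp1 <- preprocess_image(sc1$image, seed = 1)
  expect_equal(pp1$pseudo_labels$n, 1)
  expect_length(pp1$extreme_points, 1)

  blank <- forceseg:::with_seed(3, {
    img <- array(0, c(96, 96, 3))
    for (ch in 1:3) img[, , ch] <- 230 + matrix(rnorm(96 * 96, 0, 4), 96, 96)
    array(as.integer(pmax(pmin(img, 255), 0)), dim(img))
  })
  pp0 <- suppressMessages(preprocess_image(blank, seed = 1))
  expect_equal(pp0$pseudo_labels$n, 0)

  sc5 <- generate_scene(128, 128, 5, 0, 0.1, seed = 21)
  pp5 <- preprocess_image(sc5$image, seed = 1)
  # map recovered components back to generator instances by majority vote
  rr <- matrix((0:255 + 0.5) / 256 * 128 - 0.5, 256, 256)
  truth <- forceseg:::sample_nearest(sc5$labels, rr, t(rr))
  hit <- logical(max(sc5$labels))
  for (k in seq_len(pp5$pseudo_labels$n)) {
    tv <- truth[pp5$pseudo_labels$labels == k]
    maj <- as.integer(names(which.max(table(tv))))
    if (maj > 0 && mean(tv == maj) > 0.5) hit[maj] <- TRUE
  }
  expect_gte(sum(hit), 4)
})

test_that("preprocessing is deterministic under a fixed seed", {
  sc <- generate_scene(96, 96, 3, 0.1, 0.1, seed = 17)
  a <- preprocess_image(sc$image, seed = 9)
  b <- preprocess_image(sc$image, seed = 9)
  expect_identical(a$pseudo_labels$labels, b$pseudo_labels$labels)
  expect_identical(a$extreme_points, b$extreme_points)
})
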