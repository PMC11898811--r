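test_that("confusion counts are exact", {
  ones <- matrix(1L, 4, 4)
  expect_equal(confusion(ones, ones), list(tp = 16, fp = 0, fn = 0, tn = 0))
  inv <- 1L - ones
  cc <- confusion(inv, ones)
  expect_equal(cc$tp, 0); expect_equal(cc$tn, 0)
  for (seed in 1:10) {
    a <- random_mask(16, 16, 0.5, seed = seed)
    b <- random_mask(16, 16, 0.5, seed = 100 + seed)
    cc <- confusion(a, b)
    tally <- c(0, 0, 0, 0)
    for (i in 1:16) for (j in 1:16) {
      k <- if (a[i, j] && b[i, j]) 1 else if (a[i, j]) 2
           else if (b[i, j]) 3 else 4
      tally[k] <- tally[k] + 1
    }
    expect_equal(unlist(cc), c(tp = tally[1], fp = tally[2],
                               fn = tally[3], tn = tally[4]))
    expect_equal(sum(unlist(cc)), 256)
  }
  expect_error(confusion(matrix(0, 2, 2), ones),
               class = "forceseg_shape_error")
})

test_that("region metrics follow the printed formulas and conventions", {
  # |A| = 4, |B| = 6, |A∩B| = 3  ->  dice 0.6, iou 3/7
  m <- region_metrics(list(tp = 3, fp = 1, fn = 3, tn = 57))
  expect_equal(m$dice, 0.6)
  expect_equal(m$iou, 3 / 7)
  expect_equal(m$precision, 3 / 4)
  expect_equal(m$recall, 3 / 6)

  ident <- region_metrics(list(tp = 10, fp = 0, fn = 0, tn = 6))
  expect_true(all(unlist(ident) == 1))
  disjoint <- region_metrics(list(tp = 0, fp = 5, fn = 5, tn = 6))
  expect_equal(disjoint$dice, 0); expect_equal(disjoint$f1, 0)
  both_empty <- region_metrics(list(tp = 0, fp = 0, fn = 0, tn = 16))
  expect_true(all(unlist(both_empty) == 1))
  one_empty <- region_metrics(list(tp = 0, fp = 0, fn = 7, tn = 9))
  expect_true(all(unlist(one_empty) == 0))
})

test_that("dice, iou and f1 identities hold on random pairs", {
  forceseg:::with_seed(21, {
    for (rep in 1:200) {
      a <- random_mask(12, 12, runif(1, 0.2, 0.8))
      b <- random_mask(12, 12, runif(1, 0.2, 0.8))
      m <- region_metrics(confusion(a, b))
      if (m$iou > 0) {
        expect_equal(m$dice, 2 * m$iou / (1 + m$iou), tolerance = 1e-12)
        expect_equal(m$f1, m$dice, tolerance = 1e-12)
      }
    }
  })
})

test_that("boundary F1 respects the tolerance", {
  sq <- matrix(0L, 20, 20); sq[6:14, 6:14] <- 1L
  expect_equal(boundary_f1(sq, sq, 0), 1)
  expect_equal(boundary_f1(sq, sq, 3), 1)

  shifted3 <- matrix(0L, 20, 20); shifted3[9:17, 6:14] <- 1L
  # every boundary pixel of one mask is >= 3 px from ... not all; constructed
  # so precision/recall are partial: verify against the exhaustive loop
  bf_brute <- function(p, t, tol) {
    bp <- extract_boundary(p)$points; bt <- extract_boundary(t)$points
    pr <- mean(brute_min_dists(bp, bt) <= tol)
    rc <- mean(brute_min_dists(bt, bp) <= tol)
    if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
  }
  expect_equal(boundary_f1(sq, shifted3, 2), bf_brute(sq, shifted3, 2))

  # translation beyond tolerance on a thin bar -> 0
  bar <- matrix(0L, 16, 16); bar[4, 3:12] <- 1L
  bar2 <- matrix(0L, 16, 16); bar2[9, 3:12] <- 1L   # 5 px away
  expect_equal(boundary_f1(bar, bar2, 2), 0)

  for (seed in 1:10) {
    a <- random_mask(14, 14, 0.4, seed = seed)
    b <- random_mask(14, 14, 0.4, seed = 77 + seed)
    if (!any(a > 0) || !any(b > 0)) next
    expect_equal(boundary_f1(a, b, 2), bf_brute(a, b, 2))
  }

  expect_equal(boundary_f1(matrix(0L, 5, 5), matrix(0L, 5, 5), 2), 1)
  expect_equal(boundary_f1(matrix(0L, 5, 5), matrix(1L, 5, 5), 2), 0)
})

test_that("boundary F1 is non-decreasing in tolerance", {
  forceseg:::with_seed(31, {
    for (rep in 1:10) {
      a <- random_mask(16, 16, 0.4)
      b <- random_mask(16, 16, 0.4)
      vals <- vapply(0:5, function(tol) boundary_f1(a, b, tol), numeric(1))
      expect_true(all(diff(vals) >= -1e-12))
    }
  })
})

test_that("metrics are invariant under simultaneous rotation", {
  forceseg:::with_seed(41, {
    for (rep in 1:20) {
      a <- random_mask(15, 15, 0.4)
      b <- random_mask(15, 15, 0.4)
      rot <- function(m) t(m)[ncol(m):1, ]
      m1 <- region_metrics(confusion(a, b))
      m2 <- region_metrics(confusion(rot(a), rot(b)))
      expect_equal(m1, m2)
      expect_equal(boundary_f1(a, b, 2), boundary_f1(rot(a), rot(b), 2))
    }
  })
})

test_that("dataset evaluation aggregates per-image metrics", {
  sq <- matrix(0L, 10, 10); sq[3:6, 3:6] <- 1L
  tab <- evaluate_dataset(list(a = sq), list(a = sq), tolerance = 2)
  expect_true(all(unlist(tab[tab$image_id == "mean", -1]) == 1))

  half <- matrix(0L, 10, 10); half[3:6, 5:8] <- 1L  # overlap 8 -> dice 0.5
  tab2 <- evaluate_dataset(list(a = sq, b = half), list(a = sq, b = sq))
  expect_equal(tab2$dice[tab2$image_id == "mean"],
               mean(tab2$dice[tab2$image_id != "mean"]))
  expect_equal(sort(tab2$dice[tab2$image_id != "mean"]), c(0.5, 1),
               tolerance = 1e-12)

  expect_error(evaluate_dataset(list(a = sq), list(b = sq)),
               class = "forceseg_id_mismatch")

  csv <- tempfile(fileext = ".csv")
  evaluate_dataset(list(a = sq), list(a = sq), out_csv = csv)
  re <- read.csv(csv)
  expect_equal(names(re), c("image_id", "dice", "iou", "precision",
                            "recall", "f1", "bf"))
})
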