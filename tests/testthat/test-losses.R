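test_that("boundary extraction matches the exhaustive neighbour scan", {
  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  b <- extract_boundary(one)
  expect_equal(unname(b$points), matrix(c(2L, 2L), 1))

  sq <- matrix(0L, 8, 8); sq[3:6, 3:6] <- 1L        # solid 4x4
  expect_equal(nrow(extract_boundary(sq)$points), 12)

  for (seed in 1:10) {
    m <- random_mask(12, 12, 0.4, seed = seed)
    got <- extract_boundary(m)$points
    ref <- scan_boundary(m)
    if (is.null(ref)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                   unname(ref[order(ref[, 1], ref[, 2]), , drop = FALSE]),
                   ignore_attr = TRUE)
    }
  }
})

test_that("point distance loss follows the minimum-distance definition", {
  sq <- matrix(0L, 10, 10); sq[3:6, 3:6] <- 1L
  ep <- extract_extreme_points(sq)
  b <- extract_boundary(sq)
  expect_equal(point_distance_loss(ep, b), 0)

  # all four extremes at (3,4), boundary a single point at (0,0)
  ep345 <- structure(list(top = c(row = 3, col = 4), bottom = c(row = 3, col = 4),
                          left = c(row = 3, col = 4), right = c(row = 3, col = 4)),
                     class = "forceseg_extreme_points")
  b00 <- structure(list(points = matrix(c(0L, 0L), 1,
                                        dimnames = list(NULL, c("row", "col"))),
                        shape = c(10L, 10L), instance_id = NA),
                   class = "forceseg_boundary")
  expect_equal(point_distance_loss(ep345, b00), 20)  # 4 x 5

  empty <- structure(list(points = matrix(integer(0), 0, 2),
                          shape = c(10L, 10L), instance_id = NA),
                     class = "forceseg_boundary")
  expect_equal(point_distance_loss(ep, empty), 4 * sqrt(200))

  # brute force on a shifted square boundary
  sq2 <- matrix(0L, 10, 10); sq2[3:6, 4:7] <- 1L
  b2 <- extract_boundary(sq2)
  e <- do.call(rbind, ep[c("top", "bottom", "left", "right")])
  expect_equal(point_distance_loss(ep, b2),
               sum(brute_min_dists(e, b2$points)))
})

test_that("boundary alignment loss is the directed mean distance", {
  sq <- matrix(0L, 12, 12); sq[4:7, 4:7] <- 1L
  b <- extract_boundary(sq)
  expect_equal(boundary_alignment_loss(b, b), 0)

  shifted <- matrix(0L, 12, 12); shifted[5:8, 4:7] <- 1L
  bs <- extract_boundary(shifted)
  expect_equal(boundary_alignment_loss(bs, b),
               mean(brute_min_dists(bs$points, b$points)))
  expect_equal(boundary_alignment_loss(bs, b), 0.5)  # interior ring shift

  for (seed in 1:10) {
    a <- extract_boundary(random_mask(14, 14, 0.35, seed = seed))
    t <- extract_boundary(random_mask(14, 14, 0.35, seed = 50 + seed))
    if (nrow(a$points) == 0 || nrow(t$points) == 0) next
    expect_equal(boundary_alignment_loss(a, t),
                 mean(brute_min_dists(a$points, t$points)))
  }

  empty <- structure(list(points = matrix(integer(0), 0, 2),
                          shape = c(12L, 12L), instance_id = NA),
                     class = "forceseg_boundary")
  expect_equal(boundary_alignment_loss(empty, b), sqrt(288))
})

test_that("segmentation consistency loss combines BCE and soft Dice", {
  y <- matrix(0L, 8, 8); y[3:6, 3:6] <- 1L
  perfect <- segmentation_consistency_loss(y * 1, y, lam = 0.5)
  expect_lt(perfect, 0.05)

  half <- matrix(0.5, 8, 8)
  yh <- matrix(0L, 8, 8); yh[, 1:4] <- 1L
  expect_equal(segmentation_consistency_loss(half, yh, lam = 0), log(2),
               tolerance = 1e-9)

  p <- forceseg:::with_seed(2, matrix(runif(64), 8, 8))
  got <- segmentation_consistency_loss(p, yh, lam = 0.5)
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  bce <- -mean(yh * log(pc) + (1 - yh) * log(1 - pc))
  dice <- (2 * sum(pc * yh) + 1) / (sum(pc) + sum(yh) + 1)
  expect_equal(got, bce + 0.5 * (1 - dice), tolerance = 1e-12)

  expect_error(segmentation_consistency_loss(matrix(0.5, 4, 4), yh),
               class = "forceseg_shape_error")
})

test_that("the weighted total follows the curriculum ramp", {
  w <- loss_weights()
  late <- total_loss(1, 1, 1, w, epoch = 10, n_epochs = 20)
  expect_equal(unname(late$l_total), 1.8)
  expect_equal(unname(total_loss(1, 1, 1, w, epoch = 15, n_epochs = 20)$l_total),
               1.8)
  expect_equal(unname(total_loss(1, 1, 1, w, epoch = 0, n_epochs = 20)$l_total),
               1.0)
  quarter <- total_loss(1, 1, 1, w, epoch = 5, n_epochs = 20)
  expect_equal(unname(quarter$l_total), 1.4)
  expect_equal(quarter$ramp, 0.5)
  # breakdown consistency invariant
  for (ep in c(0, 3, 7, 13, 19)) {
    lb <- total_loss(0.7, 2.1, 0.4, w, epoch = ep, n_epochs = 20)
    expect_equal(unname(lb$l_total),
                 unname(sum(lb$weights_eff * c(lb$l_seg, lb$l_boundary, lb$l_pd))),
                 tolerance = 1e-9)
  }
  expect_error(total_loss(-1, 0, 0, w, 0, 10))
})

test_that("losses increase monotonically as a prediction translates away", {
  base <- matrix(0L, 24, 24); base[9:14, 9:14] <- 1L
  tb <- extract_boundary(base)
  ep <- extract_extreme_points(base)
  pd_prev <- -1; ba_prev <- -1
  for (shift in 1:5) {
    moved <- matrix(0L, 24, 24); moved[9:14 + shift, 9:14 + shift] <- 1L
    mb <- extract_boundary(moved)
    pd <- point_distance_loss(ep, mb)
    ba <- boundary_alignment_loss(mb, tb)
    expect_gt(pd, pd_prev)
    expect_gt(ba, ba_prev)
    pd_prev <- pd; ba_prev <- ba
  }
})

test_that("differentiable surrogates track the discrete losses", {
  y <- matrix(0L, 20, 20); y[6:13, 5:14] <- 1L
  tb <- extract_boundary(y)
  eps_list <- list(extract_extreme_points(y))
  s <- differentiable_surrogates(y * 1, tb, eps_list)
  expect_lt(s$l_boundary_soft, 1e-9)
  expect_lt(s$l_pd_soft, 1e-9)

  shifted <- matrix(0L, 20, 20); shifted[8:15, 5:14] <- 1L
  ssh <- differentiable_surrogates(shifted * 1, tb, eps_list)
  discrete <- boundary_alignment_loss(extract_boundary(shifted), tb)
  expect_lt(abs(ssh$l_boundary_soft - discrete), 1.0)

  p <- forceseg:::with_seed(7, matrix(runif(400), 20, 20))
  sr <- differentiable_surrogates(p, tb, eps_list)
  expect_true(is.finite(sr$l_pd_soft) && sr$l_pd_soft >= 0)
  expect_true(is.finite(sr$l_boundary_soft) && sr$l_boundary_soft >= 0)
})

test_that("surrogate gradients match finite differences", {
  forceseg:::with_seed(4, {
    pred <- matrix(runif(12 * 12, 0.05, 0.95), 12, 12)
    truth <- matrix(0L, 12, 12); truth[4:9, 5:10] <- 1L
    tb <- extract_boundary(truth)
    eps_list <- list(extract_extreme_points(truth))
    sr <- forceseg:::surrogates_with_grad(pred, tb, eps_list)
    h <- 1e-6
    for (i in sample(144, 25)) {
      pp <- pred; pp[i] <- pred[i] + h
      pm <- pred; pm[i] <- pred[i] - h
      sp <- differentiable_surrogates(pp, tb, eps_list)
      sm <- differentiable_surrogates(pm, tb, eps_list)
      expect_equal(sr$grad_boundary[i],
                   (sp$l_boundary_soft - sm$l_boundary_soft) / (2 * h),
                   tolerance = 1e-4)
      expect_equal(sr$grad_pd[i],
                   (sp$l_pd_soft - sm$l_pd_soft) / (2 * h), tolerance = 1e-4)
    }
  })
})

test_that("discrete losses equal exhaustive double loops on random pairs", {
  forceseg:::with_seed(11, {
    for (rep in 1:30) {
      a <- random_mask(16, 16, 0.35)
      b <- random_mask(16, 16, 0.35)
      ba <- extract_boundary(a); bb <- extract_boundary(b)
      if (nrow(ba$points) == 0 || nrow(bb$points) == 0) next
      expect_equal(boundary_alignment_loss(ba, bb),
                   mean(brute_min_dists(ba$points, bb$points)))
      ep <- extract_extreme_points(a)
      e <- do.call(rbind, ep[c("top", "bottom", "left", "right")])
      expect_equal(point_distance_loss(ep, bb),
                   sum(brute_min_dists(e, bb$points)))
    }
  })
})
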