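test_that("the default model meets shape, range and budget contracts", {
  m <- build_model(model_config(), seed = 1)
  expect_lte(count_parameters(m), 5.2e6)

  img <- generate_scene(64, 64, 2, 0.1, 0.1, seed = 1)$image
  sg <- segment(m, img)
  expect_equal(dim(sg$prob), c(64, 64))
  expect_true(all(sg$prob > 0 & sg$prob < 1))
  expect_true(all(is.finite(sg$prob)))

  m2 <- build_model(model_config(), seed = 1)
  expect_identical(m$params, m2$params)
  m3 <- build_model(model_config(), seed = 2)
  expect_false(identical(m$params$stem_w, m3$params$stem_w))

  expect_error(build_model(model_config(param_budget = 1000), seed = 1),
               class = "forceseg_budget_error")
})

test_that("parameter counting matches hand counts and honours freezing", {
  conv <- list(w = array(0, c(3, 3, 1, 1)), b = 0)
  expect_equal(count_parameters(conv), 10)          # 3*3*1*1 + 1

  frozen <- conv
  attr(frozen$w, "trainable") <- FALSE
  expect_equal(count_parameters(frozen), 1)

  m <- build_model(model_config(), seed = 1)
  flat_sum <- 0
  walk <- function(x) {
    if (is.list(x)) for (e in x) walk(e) else flat_sum <<- flat_sum + length(x)
  }
  walk(m$params)
  expect_equal(count_parameters(m), flat_sum)
})

test_that("multi-scale aggregation is a convex projected sum", {
  f <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  w2 <- scale_weights(c(0.3, -1.2))
  expect_equal(sum(w2$normalized), 1)
  expect_true(all(w2$normalized > 0 & w2$normalized < 1))

  # identical maps, any weights -> the map itself
  agg <- aggregate_multiscale(list(f, f), w2)
  expect_equal(agg, f, tolerance = 1e-12)

  # softmax saturation: second weight -> -inf surrogate
  g <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  sat <- aggregate_multiscale(list(f, g), scale_weights(c(0, -40)))
  expect_equal(sat, f, tolerance = 1e-12)

  # step-by-step recomputation with projections and resizing
  maps <- list(array(rnorm(8 * 8 * 3), c(8, 8, 3)),
               array(rnorm(4 * 4 * 5), c(4, 4, 5)),
               array(rnorm(2 * 2 * 2), c(2, 2, 2)))
  proj <- forceseg:::with_seed(5, lapply(c(3, 5, 2), function(cin)
    list(w = matrix(rnorm(cin * 4), cin, 4), b = rnorm(4))))
  w3 <- scale_weights(c(0.5, 0.1, -0.3))
  got <- aggregate_multiscale(maps, w3, proj)
  acc <- array(0, c(8, 8, 4))
  for (l in 1:3) {
    d <- dim(maps[[l]])
    pm <- matrix(maps[[l]], ncol = d[3]) %*% proj[[l]]$w
    pm <- sweep(pm, 2, proj[[l]]$b, `+`)
    pa <- array(pm, c(d[1], d[2], 4))
    if (d[1] != 8) pa <- forceseg:::.bilinear_fwd(pa, 8L, 8L)
    acc <- acc + w3$normalized[l] * pa
  }
  expect_equal(got, acc, tolerance = 1e-12)

  # linearity in the inputs for fixed weights/projections
  a1 <- aggregate_multiscale(list(maps[[1]], maps[[2]], maps[[3]]), w3, proj)
  zero_maps <- lapply(maps, function(m) m * 0)
  b1 <- aggregate_multiscale(zero_maps, w3, proj)
  two <- lapply(maps, function(m) 2 * m)
  c1 <- aggregate_multiscale(two, w3, proj)
  expect_equal(c1 - b1, 2 * (a1 - b1), tolerance = 1e-10)

  expect_error(aggregate_multiscale(list(f), w2),
               class = "forceseg_shape_error")
})

test_that("cross-scale attention matches the explicit matrix computation", {
  low <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  high <- array(rnorm(2 * 2 * 5), c(2, 2, 5))
  wts <- forceseg:::with_seed(9, list(Wq = matrix(rnorm(3 * 4), 3, 4),
                                      Wk = matrix(rnorm(5 * 4), 5, 4),
                                      Wv = matrix(rnorm(5 * 3), 5, 3)))
  got <- cross_scale_attention(low, high, attention_config(d = 4), wts)
  Q <- matrix(low, 4, 3) %*% wts$Wq
  K <- matrix(high, 4, 5) %*% wts$Wk
  V <- matrix(high, 4, 5) %*% wts$Wv
  S <- Q %*% t(K) / 2
  A <- exp(S) / rowSums(exp(S))
  ref <- low + array(A %*% V, dim(low))
  expect_equal(unclass(got), ref, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(rowSums(attr(got, "attention")), rep(1, 4), tolerance = 1e-12)

  # single key: softmax is identically 1 regardless of the query
  high1 <- array(rnorm(1 * 1 * 5), c(1, 1, 5))
  got1 <- cross_scale_attention(low, high1, attention_config(d = 4), wts)
  v1 <- as.numeric(matrix(high1, 1, 5) %*% wts$Wv)
  for (i in 1:2) for (j in 1:2)
    expect_equal(got1[i, j, ] - low[i, j, ], v1, tolerance = 1e-12)

  # two keys with equal logits share weight 0.5 each
  loww <- array(0, c(1, 1, 2))
  highh <- array(0, c(2, 1, 2))
  wts2 <- list(Wq = matrix(1, 2, 1), Wk = matrix(0, 2, 1),
               Wv = matrix(rnorm(4), 2, 2))
  got2 <- cross_scale_attention(loww, highh, attention_config(d = 1), wts2)
  expect_equal(as.numeric(attr(got2, "attention")), c(0.5, 0.5))
})

test_that("segmentation handles force channels and the empty fixed point", {
  m <- build_model(model_config(), seed = 4)
  img <- generate_scene(64, 64, 3, 0.2, 0.1, seed = 3)$image
  one <- segment(m, img, two_pass = FALSE)
  two <- segment(m, img, two_pass = TRUE)
  expect_equal(dim(two$prob), c(64, 64))
  expect_equal(two$prob_first_pass, one$prob)
  # if pass 1 predicts nothing, the force field is all zero and the second
  # pass reproduces the first exactly
  if (max(one$prob) < 0.5) expect_equal(two$prob, one$prob)

  ff <- force_field_from_prediction(one$prob)
  if (max(one$prob) >= 0.5 && any(ff$field != 0))
    expect_false(identical(two$prob, one$prob))
})

test_that("a full forward pass at 256x256 is fast enough for CPU use", {
  m <- build_model(model_config(), seed = 1)
  img <- array(128, c(256, 256, 3))
  invisible(segment(m, img))                        # warm-up allocation
  t0 <- Sys.time()
  invisible(segment(m, img))
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 2)
})

test_that("model forward is deterministic and respects force input", {
  m <- build_model(model_config(), seed = 6)
  x <- forceseg:::with_seed(1, array(rnorm(64 * 64 * 3, 0, 0.3), c(64, 64, 3)))
  f1 <- forceseg:::model_forward(m, x, NULL, training = FALSE)$prob
  f2 <- forceseg:::model_forward(m, x, NULL, training = FALSE)$prob
  expect_identical(f1, f2)
  fr <- forceseg:::with_seed(2, array(rnorm(64 * 64 * 2), c(64, 64, 2)))
  f3 <- forceseg:::model_forward(m, x, fr, training = FALSE)$prob
  expect_false(identical(f1, f3))
})
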