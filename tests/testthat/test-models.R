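test_that("conv3d matches its definition and the brute-force oracle", {
  set.seed(21)
  x <- array(rnorm(5 * 5 * 5), c(5, 5, 5))

  # identity 1x1x1 kernel
  expect_equal(conv3d(x, array(1, c(1, 1, 1)), 0), x)

  # all-ones 2-cube on an all-ones 2-cube with bias 1: 8 + 1 = 9
  ones <- array(1, c(2, 2, 2))
  expect_equal(as.vector(conv3d(ones, ones, bias = 1, padding = "valid")),
               9)

  # bias enters uniformly
  k <- array(rnorm(27), c(3, 3, 3))
  expect_equal(conv3d(x, k, bias = 2) - conv3d(x, k, bias = 0),
               array(2, c(3, 3, 3)))

  # random multi-channel instances vs the seven-loop oracle, both paddings
  for (rep in 1:3) {
    ci <- sample(1:3, 1)
    co <- sample(1:2, 1)
    xi <- array(rnorm(6 * 5 * 6 * ci), c(6, 5, 6, ci))
    w <- array(rnorm(27 * ci * co), c(3, 3, 3, ci, co))
    b <- rnorm(co)
    for (pad in c("valid", "same")) {
      got <- conv3d(xi, w, b, padding = pad)
      want <- conv3d_oracle(xi, w, b, same = pad == "same")
      expect_lt(max(abs(got - want)), 1e-6)
    }
  }
  expect_error(conv3d(array(1, c(2, 2, 2)),
                      array(1, c(5, 5, 5, 1, 1)), padding = "valid"),
               "larger")
})

test_that("whole-volume architecture exposes the printed filter sequence", {
  m <- build_whole_volume_model(seed = 1)
  s <- model_summary(m)
  expect_identical(s$filters, c(32L, 64L, 128L))
  expect_identical(dim(m$params$conv1_w), c(3L, 3L, 3L, 1L, 32L))
  expect_identical(dim(m$params$conv2_w), c(3L, 3L, 3L, 32L, 64L))
  expect_identical(dim(m$params$conv3_w), c(3L, 3L, 3L, 64L, 128L))
  # seeded initialization is reproducible
  m2 <- build_whole_volume_model(seed = 1)
  expect_identical(m$params, m2$params)
  expect_false(identical(
    m$params$conv1_w, build_whole_volume_model(seed = 2)$params$conv1_w))
})

test_that("whole-volume forward pass yields probabilities in (0, 1)", {
  sp <- whole_volume_spec(input_shape = c(24, 26, 24),
                          filters = c(4, 8, 16), dense_units = 16)
  m <- build_whole_volume_model(sp, seed = 2)
  set.seed(22)
  p <- predict_proba(m, array(rnorm(24 * 26 * 24), c(24, 26, 24)))
  expect_true(p > 0 && p < 1)
  expect_error(predict_proba(m, array(0, c(10, 10, 10))), "shape")
})

test_that("region model fuses K embeddings with K z-scores", {
  # default: K = 22 -> 2816 patch features + 22 z-scores = 2838
  m22 <- build_region_model(seed = 1)
  s <- model_summary(m22)
  expect_equal(s$fused_width, 2838)
  expect_equal(s$patch_feature_width, 2816)
  expect_equal(s$patch_side_sequence, c(15, 7, 3))
  expect_equal(nrow(m22$params$fuse_w), 128)
  expect_equal(ncol(m22$params$fuse_w), 2838)

  # the 128 K + K formula across K
  for (K in c(1, 5, 18)) {
    mk <- build_region_model(K = K, seed = 1)
    expect_equal(model_summary(mk)$fused_width, 128 * K + K)
  }

  # shared encoder: permuting patches permutes embeddings identically
  sp <- region_spec(n_patches = 3, filters = c(2, 3), dense_units = 4,
                    fusion_units = 5, dropout = 0)
  m <- build_region_model(spec = sp, seed = 3)
  set.seed(23)
  inp <- list(patches = array(rnorm(15^3 * 3), c(15, 15, 15, 3)),
              z_scores = rnorm(3))
  f1 <- model_forward(m, inp)
  perm <- c(2, 3, 1)
  f2 <- model_forward(m, list(patches = inp$patches[, , , perm],
                              z_scores = inp$z_scores[perm]))
  expect_equal(f2$cache$feats, f1$cache$feats[, perm])

  expect_error(model_forward(m, list(patches = array(0, c(7, 7, 7, 3)),
                                     z_scores = rnorm(3))),
               "patches")
  expect_error(model_forward(m, list(patches = inp$patches,
                                     z_scores = rnorm(2))),
               "z-score")
})

test_that("binary cross-entropy matches the closed form", {
  eps <- 1e-7
  expect_equal(binary_cross_entropy(1, 1 - eps), eps, tolerance = 1e-6)
  expect_equal(binary_cross_entropy(1, 0.5), -log(0.5))
  expect_equal(-log(0.5), 0.6931, tolerance = 1e-4)
  p <- c(0.1, 0.4, 0.9)
  expect_equal(binary_cross_entropy(1, p), binary_cross_entropy(0, 1 - p))
  expect_gte(min(binary_cross_entropy(c(0, 1), c(0.3, 0.3))), 0)
  expect_error(binary_cross_entropy(0.5, 0.5), "labels")
})

test_that("analytic gradients agree with numerical differentiation", {
  # whole-volume
  sp <- whole_volume_spec(input_shape = c(22, 24, 22), filters = c(2, 3, 4),
                          dense_units = 5, dropout = 0)
  m <- build_whole_volume_model(sp, seed = 3)
  set.seed(24)
  x <- array(rnorm(22 * 24 * 22), c(22, 24, 22))
  fw <- model_forward(m, x)
  bw <- model_backward(m, fw$cache, 1, want_input_grad = TRUE)
  num <- function(model, input, nm, i, eps = 1e-5) {
    m2 <- model
    m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
    f1 <- model_forward(m2, input)$logit
    m2$params[[nm]][i] <- m2$params[[nm]][i] - 2 * eps
    (f1 - model_forward(m2, input)$logit) / (2 * eps)
  }
  for (nm in names(m$params)) {
    n <- length(m$params[[nm]])
    for (i in unique(c(1L, n %/% 2 + 1L, n)))
      expect_equal(bw$grads[[nm]][i], num(m, x, nm, i), tolerance = 1e-5)
  }
  i <- 777
  xp <- x; xp[i] <- xp[i] + 1e-5
  xm <- x; xm[i] <- xm[i] - 1e-5
  expect_equal(bw$ginput[i],
               (model_forward(m, xp)$logit -
                  model_forward(m, xm)$logit) / 2e-5,
               tolerance = 1e-5)

  # region
  rs <- region_spec(n_patches = 2, patch_side = 7, filters = c(2, 3),
                    dense_units = 4, fusion_units = 5, dropout = 0)
  r <- build_region_model(spec = rs, seed = 4)
  set.seed(25)
  inp <- list(patches = array(rnorm(7^3 * 2), c(7, 7, 7, 2)),
              z_scores = rnorm(2))
  fwr <- model_forward(r, inp)
  bwr <- model_backward(r, fwr$cache, 1, want_input_grad = TRUE)
  for (nm in names(r$params)) {
    n <- length(r$params[[nm]])
    for (i in unique(c(1L, n %/% 2 + 1L, n)))
      expect_equal(bwr$grads[[nm]][i], num(r, inp, nm, i), tolerance = 1e-5)
  }
})

test_that("saliency is the absolute input gradient of the logit", {
  sp <- whole_volume_spec(input_shape = c(22, 24, 22), filters = c(2, 3, 4),
                          dense_units = 5, dropout = 0)
  m <- build_whole_volume_model(sp, seed = 5)
  set.seed(26)
  x <- array(rnorm(22 * 24 * 22), c(22, 24, 22))
  sal <- saliency_map(m, x)
  expect_identical(dim(sal), dim(x))
  expect_true(all(sal >= 0))
  # spot-check against numerical input gradients
  for (i in c(1000L, 5000L)) {
    xp <- x; xp[i] <- xp[i] + 1e-5
    xm <- x; xm[i] <- xm[i] - 1e-5
    g <- (model_forward(m, xp)$logit - model_forward(m, xm)$logit) / 2e-5
    expect_equal(sal[i], abs(g), tolerance = 1e-4)
  }

  # a classifier that ignores its input has (near-)zero saliency
  m0 <- m
  m0$params$out_w[] <- 0
  expect_lt(max(saliency_map(m0, x)), 1e-12)

  # region model: per-patch magnitudes and z-score channel
  r <- build_region_model(spec = region_spec(n_patches = 2, patch_side = 7,
                                             filters = c(2, 2),
                                             dense_units = 3,
                                             fusion_units = 4),
                          seed = 6)
  inp <- list(patches = array(rnorm(7^3 * 2), c(7, 7, 7, 2)),
              z_scores = rnorm(2))
  salr <- saliency_map(r, inp)
  expect_identical(dim(salr$patches), c(7L, 7L, 7L, 2L))
  expect_true(all(salr$patches >= 0) && all(salr$z_scores >= 0))

  f <- tempfile(fileext = ".png")
  write_triplanar(sal, f)
  expect_true(file.exists(f))
  unlink(f)
})
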