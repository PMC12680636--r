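test_that("bias correction recovers planted fields on a pure-tissue phantom", {
  ph <- block_phantom(seed = 2)
  dims <- dim(ph$volume$grid)
  mask <- array(TRUE, dims)

  # flat-bias input: estimated field is 1 and the volume passes through
  bc <- correct_bias(ph$volume, poly_order = 2, mask = mask)
  expect_lt(max(abs(bc$bias$field - 1)), 1e-3 + 3 * 0.01 / 0.25)
  expect_equal(mean(bc$corrected$grid), mean(ph$volume$grid),
               tolerance = 0.01)

  # planted order-2 multiplicative field
  set.seed(7)
  planted <- mciprog:::random_bias_field(dims, 2, 0.1)
  biased <- brain_volume(ph$volume$grid * planted, diag(4))
  bc2 <- correct_bias(biased, poly_order = 2, mask = mask)
  expect_gt(cor(as.vector(bc2$bias$field), as.vector(planted)), 0.95)
  # mean in-mask intensity preserved (zero-mean log-field convention)
  expect_equal(mean(bc2$corrected$grid), mean(biased$grid),
               tolerance = 0.01 * mean(biased$grid))
  expect_true(all(bc2$bias$field > 0))

  expect_error(correct_bias(ph$volume, poly_order = -1), "non-negative")
  neg <- ph$volume
  neg$grid[1, 1, 1] <- -1
  expect_error(correct_bias(neg, mask = mask), "strictly positive")
})

test_that("flat-bias head volumes are left (nearly) untouched", {
  tb <- coarse_template()
  co <- generate_cohort(2, seed = 6)
  quiet <- noise_config(bias_log_sd = 0, noise_sd = 0.01)
  raw <- synthesize_scan(co$subjects[1, ], tb, atrophy_spec(), quiet,
                         seed = 3)
  bc <- correct_bias(raw)
  m <- head_mask(raw)
  # on head-like anatomy a few percent of apparent field is residual
  # partial-volume structure; with no planted field the estimate stays
  # clearly below the default planted amplitude (log-sd 0.1)
  expect_lt(sd(log(bc$bias$field[m])), 0.08)
  # and the corrected volume keeps three ordered, well-separated tissue
  # modes (some contrast compression from anatomy leakage is tolerated)
  tis <- segment_tissues(bc$corrected)
  expect_true(all(diff(tis$means) > 0.1))
})

test_that("segmentation labels a separable phantom accurately", {
  ph <- block_phantom(seed = 3)
  dims <- dim(ph$volume$grid)
  mask <- array(TRUE, dims)
  tis <- segment_tissues(ph$volume, mask = mask)
  post <- cbind(as.vector(tis$csf_prob$grid), as.vector(tis$gm_prob$grid),
                as.vector(tis$wm_prob$grid))
  # posteriors sum to one at every in-mask voxel
  expect_lt(max(abs(rowSums(post) - 1)), 1e-6)
  # labels match the constructed ground truth
  truth <- match(as.vector(ph$truth), c(0.25, 0.55, 0.85))
  acc <- mean(max.col(post) == truth)
  expect_gte(acc, 0.95)
  # intensity ordering: CSF < GM < WM means
  expect_true(all(diff(tis$means) > 0))

  expect_error(segment_tissues(brain_volume(array(1, c(10, 10, 10)),
                                            diag(4)),
                               mask = array(TRUE, c(10, 10, 10))),
               "distinguishable")
})

test_that("segmentation posteriors are invariant to affine intensity rescaling", {
  ph <- block_phantom(seed = 4)
  mask <- array(TRUE, dim(ph$volume$grid))
  t1 <- segment_tissues(ph$volume, mask = mask)
  resc <- brain_volume(ph$volume$grid * 3 + 10, diag(4))
  t2 <- segment_tissues(resc, mask = mask)
  expect_lt(max(abs(t1$gm_prob$grid - t2$gm_prob$grid)), 1e-3)
  expect_lt(max(abs(t1$wm_prob$grid - t2$wm_prob$grid)), 1e-3)
})

test_that("smoothing implements the FWHM-parameterized separable Gaussian", {
  tb <- coarse_template()
  v <- tb$template
  expect_identical(smooth_volume(v, 0)$grid, v$grid)

  # FWHM 8 mm at 1.5 mm voxels: sigma = 8 / (2 sqrt(2 ln 2)) / 1.5 voxels
  sigma <- 8 / (2 * sqrt(2 * log(2))) / 1.5
  expect_equal(sigma, 2.264858, tolerance = 1e-6)
  dims <- c(31, 31, 31)
  imp <- array(0, dims)
  imp[16, 16, 16] <- 1
  vol <- brain_volume(imp, mciprog:::template_affine(1.5))
  sm <- smooth_volume(vol, 8)$grid
  # kernel values along an axis match the closed-form Gaussian ratio
  for (off in 1:2)
    expect_equal(sm[16 + off, 16, 16] / sm[16, 16, 16],
                 exp(-off^2 / (2 * sigma^2)), tolerance = 1e-6)
  # total mass of an interior impulse is conserved
  expect_equal(sum(sm), 1, tolerance = 1e-6)

  const <- brain_volume(array(0.7, dims), diag(4))
  expect_lt(max(abs(smooth_volume(const, 8)$grid - 0.7)), 1e-6)
  expect_error(smooth_volume(v, -1), "non-negative")
})

test_that("smoothing commutes with spatial shift in the interior", {
  set.seed(11)
  dims <- c(24, 24, 24)
  g <- array(0, dims)
  g[9:16, 9:16, 9:16] <- rnorm(512)
  v <- brain_volume(g, diag(4))
  s1 <- smooth_volume(v, 3)$grid
  gs <- array(0, dims)
  gs[11:18, 9:16, 9:16] <- g[9:16, 9:16, 9:16]
  s2 <- smooth_volume(brain_volume(gs, diag(4)), 3)$grid
  expect_lt(max(abs(s2[11:18, 9:16, 9:16] - s1[9:16, 9:16, 9:16])), 1e-10)
})

test_that("intensity scaling maps to [0, 1] with declared degenerate behavior", {
  v <- brain_volume(array(c(2, 4, 6, 2, 4, 6, 2, 4), c(2, 2, 2)), diag(4))
  sc <- scale_intensity(v)
  expect_equal(sort(unique(as.vector(sc$grid))), c(0, 0.5, 1))
  const <- brain_volume(array(5, c(3, 3, 3)), diag(4))
  expect_true(all(scale_intensity(const)$grid == 0))
  expect_identical(scale_intensity(sc)$grid, sc$grid)  # idempotent
})

test_that("QC correlation flags low-similarity pairs and is well-formed", {
  set.seed(5)
  dims <- c(22, 22, 22)
  mask <- array(TRUE, dims)
  a <- brain_volume(array(rnorm(prod(dims)), dims), diag(4),
                    scan_id = "a")
  b <- brain_volume(array(rnorm(prod(dims)), dims), diag(4),
                    scan_id = "b")
  qc <- qc_correlation(list(a, a, b), mask)
  R <- qc$correlation_matrix
  expect_equal(diag(R), rep(1, 3), ignore_attr = TRUE)
  expect_identical(R, t(R))
  expect_equal(R[1, 2], 1)
  expect_lt(abs(R[1, 3]), 0.05)  # independent noise, > 10^4 voxels
  expect_gt(nrow(qc$flags), 0)
  expect_error(qc_correlation(list(a), mask), "two volumes")
  expect_error(qc_correlation(list(a, b), array(FALSE, dims)), "empty")
})

test_that("slice montage writes deterministic images and validates input", {
  tb <- make_template(c(29, 35, 29), 6)
  vols <- list(tb$template, tb$gm_prior, tb$wm_prior, tb$csf_prior)
  f1 <- tempfile(fileext = ".png")
  f2 <- tempfile(fileext = ".png")
  qc_slice_montage(vols, "axial", out_path = f1)
  qc_slice_montage(vols, "axial", out_path = f2)
  expect_true(file.exists(f1))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_error(qc_slice_montage(vols, "oblique", out_path = f1))
  expect_error(qc_slice_montage(vols, "axial", index = 999, out_path = f1),
               "out of bounds")
  unlink(c(f1, f2))
})

test_that("affine normalization recovers planted misalignment", {
  tb <- coarse_template()
  co <- generate_cohort(2, seed = 8)
  subj <- co$subjects[1, ]

  # identity ground truth: output equals input up to interpolation
  quiet <- noise_config(bias_log_sd = 0, noise_sd = 0,
                        max_translation_mm = 0, max_rotation_deg = 0,
                        max_scale_delta = 0)
  raw <- synthesize_scan(subj, tb, atrophy_spec(effect_fraction = 0), quiet,
                         seed = 1)
  reg <- normalize_to_template(raw, tb,
                               transform = mciprog:::transform_params())
  expect_lt(max(abs(reg$grid - raw$grid)), 1e-3)
  expect_identical(dim(reg$grid), dim(tb$template$grid))
  expect_identical(reg$space, "template")

  # planted 4 mm translation + 3 degree rotation
  noisy <- noise_config(bias_log_sd = 0.05, noise_sd = 0.01,
                        max_translation_mm = 4, max_rotation_deg = 3,
                        max_scale_delta = 0.02)
  raw2 <- synthesize_scan(subj, tb, atrophy_spec(), noisy, seed = 21)
  gt <- attr(raw2, "ground_truth")$transform
  reg2 <- normalize_to_template(raw2, tb)
  tf <- attr(reg2, "transform")
  expect_lt(max(abs(tf$translation - gt$translation)), 3)    # one voxel
  expect_lt(max(abs(tf$rotation_deg - gt$rotation_deg)), 1)  # one degree
  # registration improves correlation to the template
  mask <- brain_mask(tb)
  before <- cor(raw2$grid[mask], tb$template$grid[mask])
  after <- cor(reg2$grid[mask], tb$template$grid[mask])
  expect_gt(after, before)
})
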