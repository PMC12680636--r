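test_that("template construction is deterministic with the declared geometry", {
  tb <- make_template(c(113, 137, 113), 1.5)
  expect_identical(dim(tb$template$grid), c(113L, 137L, 113L))
  expect_equal(diag(tb$template$affine)[1:3], c(-1.5, 1.5, 1.5))
  expect_equal(tb$template$affine[1:3, 4], c(84, -120, -72))
  tb2 <- make_template(c(113, 137, 113), 1.5)
  expect_identical(tb$template$grid, tb2$template$grid)
  expect_true(all(tb$gm_prior$grid >= 0 & tb$gm_prior$grid <= 1))
  expect_true(all(tb$gm_prior$grid + tb$wm_prior$grid +
                    tb$csf_prior$grid <= 1 + 1e-6))
  expect_error(make_template(c(0, 10, 10), 1.5), "grid_shape")
  expect_error(make_template(c(10, 10, 10), -1), "voxel")
})

test_that("cohorts are balanced, seeded, and carry one or two scans", {
  co <- generate_cohort(10, seed = 3)
  expect_equal(as.vector(table(co$subjects$group)), c(10L, 10L))
  expect_false(anyDuplicated(co$subjects$subject_id) > 0)
  expect_true(all(co$subjects$n_scans %in% 1:2))
  # every scan belongs to exactly one subject
  expect_equal(sort(unique(co$scans$subject_id)),
               sort(co$subjects$subject_id))
  expect_identical(generate_cohort(10, seed = 3), co)
  expect_false(identical(generate_cohort(10, seed = 4), co))
  expect_error(generate_cohort(1), "at least 2")
})

test_that("planted atrophy follows the multiplicative Gaussian lesion model", {
  tb <- coarse_template()
  spec0 <- atrophy_spec(effect_fraction = 0, age_slope = 0)
  prog <- list(group = "progressive", age = 70)
  expect_identical(plant_atrophy(tb$gm_prior, spec0, prog)$grid,
                   tb$gm_prior$grid)

  # at the lesion center the reduction equals effect_fraction exactly
  ctr <- c(24, -30, 0)
  spec <- atrophy_spec(centers = list(ctr), effect_fraction = 0.3,
                       radius_mm = 8, age_slope = 0, age_ref = 70)
  vox <- mni_to_voxel(ctr, tb$gm_prior$affine, dim(tb$gm_prior$grid))
  before <- tb$gm_prior$grid[vox[1] + 1, vox[2] + 1, vox[3] + 1]
  after <- plant_atrophy(tb$gm_prior, spec, prog)
  expect_equal(after$grid[vox[1] + 1, vox[2] + 1, vox[3] + 1],
               before * 0.7, tolerance = 1e-10)
  expect_equal(0.8 * (1 - 0.3), 0.56)  # the stated worked instance

  # three sigma out the effect has decayed below 2 % of its peak
  expect_lt(exp(-(3 * 8)^2 / (2 * 8^2)), 0.02)
  far <- vox + c(round(3 * 8 / 3), 0, 0)   # 3 sigma along x at 3 mm voxels
  rel <- 1 - after$grid[far[1] + 1, far[2] + 1, far[3] + 1] /
    tb$gm_prior$grid[far[1] + 1, far[2] + 1, far[3] + 1]
  expect_lt(rel, 0.02 * 0.3)

  # stable subjects receive no focal effect
  stab <- list(group = "stable", age = 70)
  expect_identical(plant_atrophy(tb$gm_prior, spec, stab)$grid,
                   tb$gm_prior$grid)
  expect_error(
    plant_atrophy(tb$gm_prior, atrophy_spec(centers = list(c(500, 0, 0))),
                  prog),
    "field of view")
})

test_that("group contrast at a planted center matches the configured effect", {
  tb <- coarse_template()
  spec <- atrophy_spec(effect_fraction = 0.4, age_slope = 0)
  co <- generate_cohort(20, seed = 5)
  vox <- mni_to_voxel(spec$centers[[1]], tb$gm_prior$affine) + 1L
  vals <- vapply(seq_len(nrow(co$subjects)), function(i) {
    g <- plant_atrophy(tb$gm_prior, spec, co$subjects[i, ])
    g$grid[vox[1], vox[2], vox[3]]
  }, numeric(1))
  grp <- co$subjects$group
  m_prog <- mean(vals[grp == "progressive"])
  m_stab <- mean(vals[grp == "stable"])
  expect_lt(m_prog, m_stab)
  expect_equal((m_stab - m_prog) / m_stab, 0.4, tolerance = 0.02)
})

test_that("synthesized scans are seeded, recorded, and NIfTI round-trip", {
  tb <- coarse_template()
  co <- generate_cohort(2, seed = 2)
  subj <- co$subjects[1, ]

  # identity pipeline: no noise, no bias, no misalignment
  quiet <- noise_config(bias_log_sd = 0, noise_sd = 0,
                        max_translation_mm = 0, max_rotation_deg = 0,
                        max_scale_delta = 0)
  raw <- synthesize_scan(subj, tb, atrophy_spec(effect_fraction = 0), quiet,
                         seed = 1)
  ideal <- 0.25 * tb$csf_prior$grid +
    0.55 * plant_atrophy(tb$gm_prior, atrophy_spec(effect_fraction = 0),
                         subj)$grid +
    0.85 * tb$wm_prior$grid + 0.01
  expect_lt(max(abs(raw$grid - ideal)), 1e-8)

  # determinism and ground-truth bookkeeping
  noisy <- noise_config(max_translation_mm = 4)
  s1 <- synthesize_scan(subj, tb, atrophy_spec(), noisy, seed = 9)
  s2 <- synthesize_scan(subj, tb, atrophy_spec(), noisy, seed = 9)
  expect_identical(s1$grid, s2$grid)
  gt <- attr(s1, "ground_truth")
  expect_length(gt$transform$translation, 3)
  expect_true(all(abs(gt$transform$translation) <= 4))

  # NIfTI write -> read preserves grid and affine
  f <- tempfile(fileext = ".nii.gz")
  write_volume(s1, f)
  back <- read_volume(f)
  expect_lt(max(abs(back$grid - s1$grid)), 1e-6)
  expect_lt(max(abs(back$affine - s1$affine)), 1e-6)
  unlink(f)
})

test_that("write_cohort emits manifest, volumes, and truth sidecars", {
  tb <- make_template(c(29, 35, 29), 6)
  co <- generate_cohort(2, seed = 4)
  dir <- tempfile("cohort")
  mpath <- write_cohort(co, tb, atrophy_spec(), noise_config(), seed = 4,
                        out_dir = dir)
  man <- read.delim(mpath)
  expect_equal(nrow(man), nrow(co$scans))
  expect_true(all(file.exists(man$path)))
  truth <- jsonlite::read_json(
    file.path(dir, paste0(man$scan_id[1], "_truth.json")))
  expect_length(truth$translation, 3)
  unlink(dir, recursive = TRUE)
})
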