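make_subjects <- function(n_per_group, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("s%02d", seq_len(2 * n_per_group)),
    group = rep(c("progressive", "stable"), each = n_per_group),
    age = runif(2 * n_per_group, 60, 85),
    sex = rbinom(2 * n_per_group, 1, 0.5),
    stringsAsFactors = FALSE
  )
}

test_that("design matrix has the declared columns, coding, and guards", {
  subj <- make_subjects(2)
  d <- build_design_matrix(subj)
  expect_identical(d$columns, c("intercept", "group", "age", "sex"))
  expect_equal(dim(d$matrix), c(4L, 4L))
  expect_equal(qr(d$matrix)$rank, 4L)
  expect_equal(mean(d$matrix[, "age"]), 0)
  expect_equal(d$matrix[, "group"], c(1, 1, 0, 0), ignore_attr = TRUE)
  expect_equal(d$contrast, c(0, -1, 0, 0))
  expect_equal(build_design_matrix(subj,
                                   "progressive_minus_stable")$contrast,
               c(0, 1, 0, 0))

  one <- subj[subj$group == "stable", ]
  expect_error(build_design_matrix(one), "one group")
  bad <- subj
  bad$age[1] <- NA
  expect_error(build_design_matrix(bad), "missing")
})

test_that("vectorized voxelwise OLS equals the per-voxel oracle", {
  subj <- make_subjects(5, seed = 2)
  d <- build_design_matrix(subj)
  X <- d$matrix
  n <- nrow(X)

  # noise-free: exact recovery of the generating coefficients
  beta_true <- matrix(rnorm(4 * 6), 4, 6)
  Y0 <- X %*% beta_true
  fit0 <- fit_voxelwise_glm(Y0, d)
  expect_lt(max(abs(fit0$beta - beta_true)), 1e-10)
  expect_lt(max(fit0$sigma2), 1e-20)
  sm0 <- contrast_tmap(fit0)
  expect_true(all(is.finite(sm0$t_values)))  # sigma2 = 0 convention

  # random instance vs brute force
  set.seed(3)
  Y <- Y0 + matrix(rnorm(n * 6), n, 6)
  Y <- cbind(Y, matrix(rnorm(n * 44), n, 44))
  fit <- fit_voxelwise_glm(Y, d)
  orc <- glm_oracle(Y, X, d$contrast)
  expect_lt(max(abs(t(fit$beta) - orc[, 1:4])), 1e-8)
  expect_lt(max(abs(fit$sigma2 - orc[, 5])), 1e-8)
  sm <- contrast_tmap(fit)
  expect_lt(max(abs(sm$t_values - orc[, 6])), 1e-8)

  d2 <- structure(list(matrix = cbind(intercept = 1, group = c(1, 0)),
                       columns = c("intercept", "group"),
                       contrast = c(0, 1), subject_ids = c("a", "b"),
                       group = c(1, 0)),
                  class = "design_matrix")
  expect_error(fit_voxelwise_glm(matrix(rnorm(2 * 5), 2, 5), d2),
               "more subjects")
  expect_error(contrast_tmap(fit, contrast = c(0, 0, 0, 0)), "non-zero")
})

test_that("the two-group worked example gives the pooled t statistic", {
  subj <- data.frame(subject_id = c("a", "b", "c", "d"),
                     group = c("stable", "stable", "progressive",
                               "progressive"),
                     age = c(70, 70, 70, 70), sex = c(0, 0, 0, 0))
  X <- cbind(intercept = 1, group = as.integer(subj$group == "progressive"))
  d <- list(matrix = X, columns = c("intercept", "group"),
            contrast = c(0, 1), subject_ids = subj$subject_id,
            group = X[, 2])
  class(d) <- "design_matrix"
  fit <- fit_voxelwise_glm(matrix(c(1, 2, 3, 4), 4, 1), d)
  sm <- contrast_tmap(fit)
  expect_equal(sm$t_values, 2 / sqrt(0.5), tolerance = 1e-10)
  expect_equal(sm$df, 2)

  # identical responses across subjects give t = 0
  fit0 <- fit_voxelwise_glm(matrix(1, 4, 1), d)
  expect_equal(contrast_tmap(fit0)$t_values, 0)
  # contrast negation negates t
  expect_equal(contrast_tmap(fit, contrast = c(0, -1))$t_values,
               -sm$t_values)
})

test_that("t to Z conversion is exact, symmetric, and saturation-free", {
  expect_equal(t_to_z(0, df = 5), 0)
  t <- 2 / sqrt(0.5)
  # closed-form df = 2 CDF: F(t) = (1 + t / sqrt(t^2 + 2)) / 2
  z_oracle <- qnorm(0.5 * (1 + t / sqrt(t^2 + 2)))
  expect_equal(t_to_z(t, df = 2), z_oracle, tolerance = 1e-8)
  expect_equal(z_oracle, 1.6184, tolerance = 1e-4)
  expect_equal(t_to_z(-t, df = 2), -z_oracle, tolerance = 1e-8)
  # limiting normal behavior at large df
  for (tt in c(-4, -1, 0.5, 4))
    expect_equal(t_to_z(tt, df = 1e6), tt, tolerance = 1e-3)
  # extreme statistics stay finite and monotone
  zz <- t_to_z(c(10, 20, 40), df = 30)
  expect_true(all(is.finite(zz)) && all(diff(zz) > 0))
  expect_error(t_to_z(1, df = 0.5), "df")
})

test_that("permutation maxT threshold is seeded and monotone in alpha", {
  subj <- make_subjects(6, seed = 4)
  d <- build_design_matrix(subj)
  set.seed(5)
  Y <- matrix(rnorm(12 * 200), 12, 200)
  t1 <- fwe_threshold(Y, d, n_perm = 200, alpha = 0.05, seed = 9)
  t2 <- fwe_threshold(Y, d, n_perm = 200, alpha = 0.05, seed = 9)
  expect_equal(as.numeric(t1), as.numeric(t2))
  t01 <- fwe_threshold(Y, d, n_perm = 200, alpha = 0.01, seed = 9)
  expect_gte(as.numeric(t01), as.numeric(t1))
  expect_error(fwe_threshold(Y, d, n_perm = 50, alpha = 0.05, seed = 1),
               "at least 100")
  small <- make_subjects(2)
  ds <- build_design_matrix(small)
  expect_error(fwe_threshold(matrix(rnorm(4 * 10), 4, 10), ds,
                             n_perm = 100, alpha = 0.001, seed = 1),
               "too few distinct permutations")
})

test_that("peak extraction finds, orders, and suppresses local maxima", {
  dims <- c(21, 21, 21)
  A <- diag(4)

  bump <- function(center, height, sigma = 2) {
    idx <- arrayInd(seq_len(prod(dims)), dims) - 1
    d2 <- rowSums(sweep(idx, 2, center)^2)
    array(height * exp(-d2 / (2 * sigma^2)), dims)
  }
  mk_map <- function(z) {
    structure(list(t_values = as.vector(z), z_values = as.vector(z),
                   df = 10, contrast = c(0, 1), mask = NULL, dims = dims,
                   affine = A), class = "stat_map")
  }

  # single bump: exactly one peak at its center
  p1 <- extract_peaks(mk_map(bump(c(10, 10, 10), 5)), z_threshold = 2)
  expect_equal(nrow(p1), 1L)
  expect_equal(unname(c(p1$x_mm, p1$y_mm, p1$z_mm)), c(10, 10, 10))

  # two bumps 15 voxels apart with 8 mm separation: both retained,
  # ordered by descending z
  two <- bump(c(4, 10, 10), 5) + bump(c(19, 10, 10), 4)
  p2 <- extract_peaks(mk_map(two), z_threshold = 2, min_separation_mm = 8)
  expect_equal(nrow(p2), 2L)
  expect_true(all(diff(p2$z_score) <= 0))

  # two maxima 4 mm apart with 8 mm separation: only the higher kept
  ridge <- array(0, dims)
  ridge[10, 10, 10] <- 5
  ridge[14, 10, 10] <- 4.5
  p3 <- extract_peaks(mk_map(ridge), z_threshold = 2, min_separation_mm = 8)
  expect_equal(nrow(p3), 1L)
  expect_equal(p3$x_mm, 9)  # 0-based voxel 9 under an identity affine

  # empty result allowed
  p0 <- extract_peaks(mk_map(array(0, dims)), z_threshold = 2)
  expect_equal(nrow(p0), 0L)
})

test_that("standardize implements (x - mu) / sigma with guards", {
  expect_equal(standardize(5, 5, 2), 0)
  expect_equal(standardize(7, 5, 1), 2)
  set.seed(6)
  x <- rnorm(500, 3, 2)
  z <- standardize(x, mean(x), sd(x))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(standardize(1, 0, 0), "positive")
})

test_that("peak tables round-trip through TSV in the Table-3 schema", {
  pk <- structure(
    data.frame(z_score = c(4.79, 4.77), x_mm = c(24, -15),
               y_mm = c(-30, -37.5), z_mm = c(0, 3),
               label = c("right thalamus proper", "left hippocampus"),
               stringsAsFactors = FALSE),
    class = c("peak_table", "data.frame"))
  f <- tempfile(fileext = ".tsv")
  write_peak_table(pk, f)
  back <- read_peak_table(f)
  expect_equal(as.data.frame(back), as.data.frame(pk))
  expect_identical(names(back),
                   c("z_score", "x_mm", "y_mm", "z_mm", "label"))
  unlink(f)
})
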