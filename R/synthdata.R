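# Synthetic cohort and volume generation.
#
# The generator emulates the statistical structure the downstream method
# assumes: template-space grey-matter probability maps with group-dependent
# focal loss at configured MNI coordinates, age/sex covariates, multiplicative
# low-frequency bias fields, rigid+scale misalignment, and additive noise.

# Canonical template geometry: RAS-consistent affine with origin chosen so
# the field of view spans x in [-84, 84], y in [-120, 84], z in [-72, 96] mm
# at the default 1.5 mm / (113, 137, 113) grid. Coarser grids keep the same
# field of view.
template_affine <- function(voxel_size_mm) {
  rbind(c(-voxel_size_mm, 0, 0, 84),
        c(0, voxel_size_mm, 0, -120),
        c(0, 0, voxel_size_mm, -72),
        c(0, 0, 0, 1))
}

HEAD_CENTER <- c(0, -18, 12)     # mm, world
HEAD_AXES <- c(72, 88, 62)       # mm, ellipsoid semi-axes

#' Build the synthetic head template and tissue priors
#'
#' Constructs a deterministic, smooth head-like intensity template on the
#' declared template grid together with grey-matter, white-matter, and CSF
#' prior maps. The head is an ellipsoid with a white-matter core, a
#' grey-matter shell, a thin CSF rim, lateral-ventricle-like CSF pockets, and
#' two deep grey-matter nuclei (thalamus- and hippocampus-like) placed at the
#' default atrophy coordinates so focal grey-matter loss there is meaningful.
#'
#' @param grid_shape integer length-3, template grid dimensions. The default
#'   `c(113, 137, 113)` at 1.5 mm matches the whole-volume model input.
#' @param voxel_size_mm positive scalar voxel edge length.
#' @return A list of class `template_bundle` with `template` (raw intensity),
#'   `gm_prior`, `wm_prior`, `csf_prior` (probability `brain_volume`s sharing
#'   the template grid/affine).
#' @export
make_template <- function(grid_shape = c(113, 137, 113), voxel_size_mm = 1.5) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("grid_shape must be three positive integers (>= 8)")
  if (!is.numeric(voxel_size_mm) || voxel_size_mm <= 0)
    stop("voxel_size_mm must be positive")
  A <- template_affine(voxel_size_mm)
  wx <- A[1, 4] + A[1, 1] * (seq_len(grid_shape[1]) - 1)
  wy <- A[2, 4] + A[2, 2] * (seq_len(grid_shape[2]) - 1)
  wz <- A[3, 4] + A[3, 3] * (seq_len(grid_shape[3]) - 1)

  rx2 <- ((wx - HEAD_CENTER[1]) / HEAD_AXES[1])^2
  ry2 <- ((wy - HEAD_CENTER[2]) / HEAD_AXES[2])^2
  rz2 <- ((wz - HEAD_CENTER[3]) / HEAD_AXES[3])^2
  r <- sqrt(outer(outer(rx2, ry2, "+"), rz2, "+"))

  lgt <- function(r0, w = 0.03) 1 / (1 + exp(-(r - r0) / w))
  s60 <- lgt(0.60); s88 <- lgt(0.88); s96 <- lgt(0.96)
  wm <- 1 - s60
  gm <- s60 - s88
  csf <- s88 - s96
  rm(s60, s88, s96, r)

  gauss_blob <- function(center, sigma) {
    dx2 <- ((wx - center[1]) / sigma[1])^2
    dy2 <- ((wy - center[2]) / sigma[2])^2
    dz2 <- ((wz - center[3]) / sigma[3])^2
    exp(-0.5 * outer(outer(dx2, dy2, "+"), dz2, "+"))
  }
  # deep grey nuclei: transfer white matter to grey matter
  for (ctr in list(c(24, -30, 0), c(-15, -37.5, 3), c(3, -60, 24))) {
    m <- 0.9 * gauss_blob(ctr, c(9, 9, 9))
    gm <- gm + wm * m
    wm <- wm * (1 - m)
  }
  # lateral-ventricle-like CSF pockets carved from white matter
  for (ctr in list(c(12, -30, 16), c(-12, -30, 16))) {
    m <- 0.95 * gauss_blob(ctr, c(7, 14, 7))
    csf <- csf + wm * m
    wm <- wm * (1 - m)
  }
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  gm <- clip01(gm); wm <- clip01(wm); csf <- clip01(csf)
  intensity <- 0.25 * csf + 0.55 * gm + 0.85 * wm + 0.01

  vol <- function(g, kind) brain_volume(g, A, subject_id = "template",
                                        scan_id = "template",
                                        space = "template", kind = kind)
  structure(list(template = vol(intensity, "raw"),
                 gm_prior = vol(gm, "gm_prob"),
                 wm_prior = vol(wm, "wm_prob"),
                 csf_prior = vol(csf, "csf_prob")),
            class = "template_bundle")
}

#' Specify planted focal grey-matter atrophy
#'
#' @param centers list (or 3-column matrix) of MNI mm coordinates at which
#'   progressive subjects lose grey matter. The defaults are the template's
#'   three deep grey-matter nuclei (thalamus-, hippocampus-, and posterior
#'   cingulate-like), pairwise more than 35 mm apart; planting lesions on
#'   locally symmetric grey-matter structures keeps the statistical peak at
#'   the planted coordinate.
#' @param effect_fraction peak fractional grey-matter reduction in `[0, 1]`.
#' @param radius_mm Gaussian spatial scale (sigma) of each lesion, mm.
#' @param age_slope global fractional grey-matter reduction per year of age
#'   relative to `age_ref` (applies to both groups).
#' @param age_ref reference age in years.
#' @return A list of class `atrophy_spec`.
#' @export
atrophy_spec <- function(centers = list(c(24, -30, 0), c(-15, -37.5, 3),
                                        c(3, -60, 24)),
                         effect_fraction = 0.4, radius_mm = 8,
                         age_slope = 0.002, age_ref = 72.5) {
  if (is.matrix(centers)) centers <- lapply(seq_len(nrow(centers)),
                                            function(i) centers[i, ])
  stopifnot(length(centers) >= 1)
  if (effect_fraction < 0 || effect_fraction > 1)
    stop("effect_fraction must lie in [0, 1]")
  if (radius_mm <= 0) stop("radius_mm must be positive")
  structure(list(centers = centers, effect_fraction = effect_fraction,
                 radius_mm = radius_mm, age_slope = age_slope,
                 age_ref = age_ref),
            class = "atrophy_spec")
}

#' Generate a balanced synthetic cohort
#'
#' Subjects are split evenly between the progressive (MCI converter) and
#' stable (non-converter) groups, with ages drawn uniformly from `age_range`,
#' sex from a fair Bernoulli, and one or two scans per subject (a second scan
#' with probability `p_second_scan`).
#'
#' @param n_per_group subjects per group (at least 2).
#' @param age_range length-2 numeric, years.
#' @param seed integer seed; the cohort is a pure function of the arguments.
#' @param p_second_scan probability a subject contributes a second scan.
#' @return A list of class `cohort` with `subjects` and `scans` data frames
#'   and the seed.
#' @export
generate_cohort <- function(n_per_group, age_range = c(60, 85), seed = 1,
                            p_second_scan = 0.5) {
  if (n_per_group < 2) stop("n_per_group must be at least 2")
  set.seed(substream_seed(seed, "cohort"))
  n <- 2L * as.integer(n_per_group)
  subject_id <- sprintf("sub-%03d", seq_len(n))
  group <- rep(c("progressive", "stable"), each = n_per_group)
  age <- runif(n, age_range[1], age_range[2])
  sex <- rbinom(n, 1, 0.5)
  n_scans <- 1L + rbinom(n, 1, p_second_scan)
  scans <- data.frame(
    scan_id = unlist(lapply(seq_len(n), function(i)
      sprintf("%s_scan-%d", subject_id[i], seq_len(n_scans[i])))),
    subject_id = rep(subject_id, n_scans),
    stringsAsFactors = FALSE
  )
  structure(list(
    subjects = data.frame(subject_id = subject_id, group = group, age = age,
                          sex = sex, n_scans = n_scans,
                          stringsAsFactors = FALSE),
    scans = scans, seed = seed
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%s), %d scans, seed %d\n",
              nrow(x$subjects),
              paste(sprintf("%d %s", table(x$subjects$group),
                            names(table(x$subjects$group))), collapse = ", "),
              nrow(x$scans), x$seed))
  invisible(x)
}

#' Plant focal grey-matter atrophy in a template-space GM map
#'
#' Progressive subjects have grey matter multiplied by
#' `1 - effect_fraction * g(d)` at each lesion center, where `g` is a
#' unit-peak Gaussian with scale `radius_mm` and `d` the world distance to
#' the center; stable subjects receive no focal effect. Both groups receive
#' the global age scaling `1 - age_slope * (age - age_ref)`. The output is
#' clipped to `[0, 1]`.
#'
#' @param gm_map template-space grey-matter probability `brain_volume`.
#' @param spec an [atrophy_spec()].
#' @param subject a list or one-row data frame with `group` and `age`.
#' @return The modified grey-matter `brain_volume`.
#' @export
plant_atrophy <- function(gm_map, spec, subject) {
  stopifnot(inherits(gm_map, "brain_volume"), inherits(spec, "atrophy_spec"))
  if (gm_map$space != "template")
    stop("gm_map must be a template-space volume")
  d <- dim(gm_map$grid)
  A <- gm_map$affine
  wx <- A[1, 4] + A[1, 1] * (seq_len(d[1]) - 1)
  wy <- A[2, 4] + A[2, 2] * (seq_len(d[2]) - 1)
  wz <- A[3, 4] + A[3, 3] * (seq_len(d[3]) - 1)
  fov <- function(ctr) {
    ctr[1] <= max(wx) + 1e-9 && ctr[1] >= min(wx) - 1e-9 &&
      ctr[2] <= max(wy) + 1e-9 && ctr[2] >= min(wy) - 1e-9 &&
      ctr[3] <= max(wz) + 1e-9 && ctr[3] >= min(wz) - 1e-9
  }
  g <- gm_map$grid
  if (identical(as.character(subject$group), "progressive") &&
      spec$effect_fraction > 0) {
    for (ctr in spec$centers)
      if (!fov(ctr))
        stop(sprintf("atrophy center (%s) outside the field of view",
                     paste(ctr, collapse = ", ")))
    g <- g * focal_attenuation(dim(g), gm_map$affine, spec)
  }
  g <- g * (1 - spec$age_slope * (subject$age - spec$age_ref))
  with_grid(gm_map, pmin(pmax(g, 0), 1), kind = "gm_prob")
}

# Multiplicative focal-loss field shared by all progressive subjects;
# memoised on (dims, affine, spec) since it is subject-independent.
focal_attenuation <- local({
  key_cache <- NULL
  val_cache <- NULL
  function(dims, affine, spec) {
    key <- paste(c(dims, affine, unlist(spec$centers), spec$effect_fraction,
                   spec$radius_mm), collapse = ",")
    if (identical(key, key_cache)) return(val_cache)
    wx <- affine[1, 4] + affine[1, 1] * (seq_len(dims[1]) - 1)
    wy <- affine[2, 4] + affine[2, 2] * (seq_len(dims[2]) - 1)
    wz <- affine[3, 4] + affine[3, 3] * (seq_len(dims[3]) - 1)
    f <- array(1, dims)
    for (ctr in spec$centers) {
      d2 <- outer(outer((wx - ctr[1])^2, (wy - ctr[2])^2, "+"),
                  (wz - ctr[3])^2, "+")
      f <- f * (1 - spec$effect_fraction * exp(-d2 / (2 * spec$radius_mm^2)))
    }
    key_cache <<- key
    val_cache <<- f
    f
  }
})

#' Configure scan-level corruption
#'
#' @param bias_log_sd standard deviation of the log bias field over the head
#'   (0 disables the field).
#' @param bias_order polynomial order of the log bias field.
#' @param noise_sd additive Gaussian intensity noise.
#' @param max_translation_mm,max_rotation_deg,max_scale_delta bounds of the
#'   uniform rigid+scale misalignment applied to each scan.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(bias_log_sd = 0.1, bias_order = 3, noise_sd = 0.02,
                         max_translation_mm = 4, max_rotation_deg = 3,
                         max_scale_delta = 0.02) {
  stopifnot(bias_log_sd >= 0, bias_order >= 0, noise_sd >= 0,
            max_translation_mm >= 0, max_rotation_deg >= 0,
            max_scale_delta >= 0, max_scale_delta < 1)
  structure(as.list(environment()), class = "noise_config")
}

# World-space rigid+scale transform: x -> R S (x - c) + c + t, rotation
# R = Rz Ry Rx in degrees, scaling about the head center c.
world_transform <- function(translation, rotation_deg, scale,
                            center = HEAD_CENTER) {
  th <- rotation_deg * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  RS <- Rz %*% Ry %*% Rx %*% diag(scale, 3)
  M <- diag(4)
  M[1:3, 1:3] <- RS
  M[1:3, 4] <- center + translation - RS %*% center
  M
}

transform_params <- function(translation = c(0, 0, 0),
                             rotation_deg = c(0, 0, 0), scale = c(1, 1, 1)) {
  list(translation = translation, rotation_deg = rotation_deg, scale = scale,
       matrix = world_transform(translation, rotation_deg, scale))
}

# Evaluate a seeded random order-`order` polynomial log bias field over the
# grid. The field is normalized to zero mean log and the requested log sd
# over `mask_idx` (the head region when supplied): the amplitude describes
# the inhomogeneity across the head, where it matters, not across the empty
# corners of the grid.
random_bias_field <- function(dims, order, log_sd, mask_idx = NULL) {
  if (log_sd <= 0 || order < 1) {
    out <- array(1, dims)
    attr(out, "coefficients") <- numeric(0)
    return(out)
  }
  if (is.null(mask_idx)) mask_idx <- seq_len(prod(dims))
  basis <- poly_basis_grid(dims, order)
  coef <- rnorm(ncol(basis))
  coef[1] <- 0
  f <- as.vector(basis %*% coef)
  mu <- mean(f[mask_idx])
  s <- sd(f[mask_idx])
  if (s > 0) {
    scl <- log_sd / s
    f <- (f - mu) * scl
    coef <- coef * scl
    coef[1] <- -mu * scl
  }
  # physical scanner fields are bounded: clamp rare polynomial extremes
  f <- pmin(pmax(f, -3 * log_sd), 3 * log_sd)
  out <- array(exp(f), dims)
  attr(out, "coefficients") <- coef
  out
}

# Monomial basis x^a y^b z^c (a+b+c <= order) in coordinates normalized to
# [-1, 1] along each grid axis; first column is the intercept.
poly_basis_grid <- function(dims, order, subset = NULL) {
  idx <- if (is.null(subset)) seq_len(prod(dims)) else subset
  ijk <- arrayInd(idx, dims)
  nc <- sweep(ijk - 1, 2, (dims - 1) / 2, "-")
  nc <- sweep(nc, 2, pmax((dims - 1) / 2, 1), "/")
  cols <- list()
  for (a in 0:order) for (b in 0:(order - a)) for (c in 0:(order - a - b))
    cols[[length(cols) + 1L]] <- nc[, 1]^a * nc[, 2]^b * nc[, 3]^c
  do.call(cbind, cols)
}

#' Synthesize one native-space raw scan
#'
#' Applies the subject's atrophy to the template tissue model, renders a raw
#' intensity volume, moves it through a random rigid+scale misalignment,
#' multiplies a smooth polynomial bias field, and adds Gaussian noise. The
#' planted transform, bias coefficients, and noise level are attached as the
#' `ground_truth` attribute for downstream recovery checks.
#'
#' @param subject one-row data frame (or list) with `subject_id`, `group`,
#'   `age`.
#' @param template a `template_bundle` from [make_template()].
#' @param spec an [atrophy_spec()].
#' @param noise a [noise_config()].
#' @param seed integer; together with `scan_id` it determines every random
#'   draw.
#' @param scan_id scan identifier string.
#' @return A native-space raw `brain_volume` with attribute `ground_truth`.
#' @export
synthesize_scan <- function(subject, template, spec = atrophy_spec(),
                            noise = noise_config(), seed = 1,
                            scan_id = paste0(subject$subject_id, "_scan-1")) {
  stopifnot(inherits(template, "template_bundle"))
  set.seed(substream_seed(seed, paste0("scan/", scan_id)))
  gm <- plant_atrophy(template$gm_prior, spec, subject)
  ideal <- 0.25 * template$csf_prior$grid + 0.55 * gm$grid +
    0.85 * template$wm_prior$grid + 0.01
  A <- template$template$affine
  dims <- dim(ideal)

  tr <- runif(3, -noise$max_translation_mm, noise$max_translation_mm)
  ro <- runif(3, -noise$max_rotation_deg, noise$max_rotation_deg)
  sc <- runif(3, 1 - noise$max_scale_delta, 1 + noise$max_scale_delta)
  tf <- transform_params(tr, ro, sc)

  # native(v) = ideal at voxel A^-1 M^-1 A v (content moved by M in world)
  Q <- solve(A) %*% solve(tf$matrix) %*% A
  raw <- .resample_affine_cpp(ideal, dims, dims, Q, 0.01)

  bias <- random_bias_field(dims, noise$bias_order, noise$bias_log_sd,
                            mask_idx = which(raw > 0.1))
  raw <- raw * bias
  if (noise$noise_sd > 0) raw <- raw + rnorm(length(raw), 0, noise$noise_sd)
  raw <- array(raw, dims)

  out <- brain_volume(raw, A, subject_id = subject$subject_id,
                      scan_id = scan_id, space = "native", kind = "raw")
  attr(out, "ground_truth") <- list(
    transform = tf, bias_field = bias,
    bias_coefficients = attr(bias, "coefficients"), noise_sd = noise$noise_sd)
  out
}

#' Simulate and write a full cohort to disk
#'
#' Writes one NIfTI per scan, a per-scan ground-truth JSON (transform
#' parameters and noise level), and a cohort manifest TSV.
#'
#' @inheritParams synthesize_scan
#' @param cohort a [generate_cohort()] result.
#' @param out_dir output directory (created if needed).
#' @return Path to the manifest TSV, invisibly.
#' @export
write_cohort <- function(cohort, template, spec = atrophy_spec(),
                         noise = noise_config(), seed = 1, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(nrow(cohort$scans))) {
    sid <- cohort$scans$subject_id[i]
    scid <- cohort$scans$scan_id[i]
    subj <- cohort$subjects[cohort$subjects$subject_id == sid, ]
    vol <- synthesize_scan(subj, template, spec, noise, seed, scan_id = scid)
    path <- file.path(out_dir, paste0(scid, ".nii.gz"))
    write_volume(vol, path)
    gt <- attr(vol, "ground_truth")
    jsonlite::write_json(
      list(scan_id = scid, translation = gt$transform$translation,
           rotation_deg = gt$transform$rotation_deg,
           scale = gt$transform$scale,
           bias_coefficients = gt$bias_coefficients, noise_sd = gt$noise_sd),
      file.path(out_dir, paste0(scid, "_truth.json")),
      auto_unbox = TRUE, digits = NA)
    rows[[i]] <- data.frame(subject_id = sid, group = subj$group,
                            age = subj$age, sex = subj$sex, scan_id = scid,
                            path = path, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.tsv")
  write.table(manifest, mpath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' Simulate template-space smoothed GM maps directly
#'
#' Shortcut for group-level simulations: skips the native-space rendering and
#' preprocessing chain and emits one smoothed, template-space grey-matter map
#' per subject (atrophy + voxel noise + FWHM smoothing). This is the input
#' contract of the voxel-wise GLM stage.
#'
#' @inheritParams write_cohort
#' @param fwhm_mm smoothing kernel FWHM in mm.
#' @param gm_noise_sd per-voxel Gaussian noise added before smoothing.
#' @return Named list (by subject_id) of smoothed `brain_volume`s.
#' @export
simulate_gm_maps <- function(cohort, template, spec = atrophy_spec(),
                             fwhm_mm = 8, gm_noise_sd = 0.02, seed = 1) {
  out <- vector("list", nrow(cohort$subjects))
  names(out) <- cohort$subjects$subject_id
  for (i in seq_len(nrow(cohort$subjects))) {
    subj <- cohort$subjects[i, ]
    set.seed(substream_seed(seed, paste0("gm/", subj$subject_id)))
    gm <- plant_atrophy(template$gm_prior, spec, subj)
    g <- gm$grid + rnorm(length(gm$grid), 0, gm_noise_sd)
    gm <- with_grid(gm, pmin(pmax(g, 0), 1))
    gm$subject_id <- subj$subject_id
    gm$scan_id <- paste0(subj$subject_id, "_scan-1")
    out[[i]] <- smooth_volume(gm, fwhm_mm)
  }
  out
}
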