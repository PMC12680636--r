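# Self-contained preprocessing chain: polynomial bias-field correction,
# Gaussian-mixture tissue segmentation, affine normalization to the template
# grid, FWHM-parameterized smoothing, intensity scaling, and QC checks.

FWHM_TO_SIGMA <- 2 * sqrt(2 * log(2))  # = 2.3548...

#' Intensity-based head mask
#'
#' Voxels brighter than `frac` times the 99th intensity percentile. Adequate
#' for synthetic heads on a dark background; real skull-stripping is out of
#' scope.
#'
#' @param volume a `brain_volume`.
#' @param frac threshold fraction of the robust maximum.
#' @return Logical array of the grid shape.
#' @export
head_mask <- function(volume, frac = 0.2) {
  volume$grid > frac * quantile(volume$grid, 0.99, names = FALSE)
}

#' Template-space brain analysis mask
#'
#' @param template a `template_bundle`.
#' @param threshold prior-sum cutoff.
#' @return Logical array: GM + WM + CSF prior above `threshold`.
#' @export
brain_mask <- function(template, threshold = 0.1) {
  (template$gm_prior$grid + template$wm_prior$grid +
     template$csf_prior$grid) > threshold
}

# Three-component Gaussian mixture fit on a numeric vector (unequal
# variances, components ordered by ascending mean). Returns NULL when three
# modes are not distinguishable.
fit_gmm3 <- function(values, max_fit = 20000) {
  if (sd(values) < 1e-10) return(NULL)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
  sub <- if (length(values) > max_fit)
    values[seq(1L, length(values), length.out = max_fit)] else values
  init_sub <- seq(1L, length(sub), length.out = min(length(sub), 1500L))
  fit <- tryCatch(
    mclust::Mclust(sub, G = 3, modelNames = "V", verbose = FALSE,
                   initialization = list(subset = init_sub)),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$parameters)) return(NULL)
  mu <- fit$parameters$mean
  sig <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sig) == 1L) sig <- rep(sig, 3)
  pro <- fit$parameters$pro
  if (anyNA(c(mu, sig, pro)) || any(sig <= 0)) return(NULL)
  if (min(diff(sort(mu))) < 1e-6 * max(abs(mu), 1)) return(NULL)
  ord <- order(mu)
  list(mean = mu[ord], sd = sig[ord], pro = pro[ord])
}

gmm3_posterior <- function(gmm, values) {
  dens <- vapply(seq_len(3), function(k)
    gmm$pro[k] * stats::dnorm(values, gmm$mean[k], gmm$sd[k]),
    numeric(length(values)))
  tot <- rowSums(dens)
  tot[tot == 0] <- 1
  dens / tot
}

# Evaluate the polynomial with given coefficients over the whole grid,
# chunked to bound memory.
eval_poly_grid <- function(dims, order, coef) {
  logf <- numeric(prod(dims))
  chunk <- 262144L
  for (s in seq(1L, prod(dims), by = chunk)) {
    e <- min(s + chunk - 1L, prod(dims))
    logf[s:e] <- poly_basis_grid(dims, order, subset = s:e) %*% coef
  }
  logf
}

# Shift an array by an offset, filling with NA.
shift_array <- function(a, dx) {
  d <- dim(a)
  out <- array(NA, d)
  sx <- max(1, 1 + dx[1]):min(d[1], d[1] + dx[1])
  sy <- max(1, 1 + dx[2]):min(d[2], d[2] + dx[2])
  sz <- max(1, 1 + dx[3]):min(d[3], d[3] + dx[3])
  out[sx - dx[1], sy - dx[2], sz - dx[3]] <- a[sx, sy, sz]
  out
}

FACE_NEIGHBORS <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1))

# Keep voxels whose 6-neighborhood (iterated n times) shares their label.
erode_label_interior <- function(lab, n) {
  keep <- array(TRUE, dim(lab))
  for (i in seq_len(n)) {
    masked <- lab
    masked[!keep] <- -1L
    for (dx in FACE_NEIGHBORS) {
      nb <- shift_array(masked, dx)
      keep <- keep & (is.na(nb) | nb == lab)
    }
  }
  keep
}

#' Multiplicative bias-field correction
#'
#' Models the scanner's low-frequency intensity inhomogeneity as the
#' exponential of a low-order polynomial in normalized grid coordinates and
#' estimates it by least squares in the log domain. To keep the head's own
#' tissue contrast out of the field estimate, voxels are first classified
#' into three tissue classes with a Gaussian mixture fit on a
#' locally-normalized image (intensity divided by its ~25 mm in-mask mean,
#' which cancels the smooth field before classification); only confidently
#' classified voxels away from class boundaries (twice-eroded class
#' interiors) enter the fit, and log-intensity is regressed jointly on
#' per-class intercepts and the polynomial, with two robust reweighting
#' passes that drop outlier voxels (e.g. focal lesions). If the input has no
#' three-mode intensity structure (a constant-tissue phantom), the
#' polynomial is fit to log-intensity directly, which is exact in that
#' case. The field is normalized to zero mean log over the mask, preserving
#' mean in-mask intensity.
#'
#' @param volume a `brain_volume`, strictly positive inside the mask.
#' @param poly_order polynomial order (default 3).
#' @param mask optional logical array; defaults to [head_mask()].
#' @param n_pass classify-and-fit passes (default 1). Repeated passes
#'   reclassify on the corrected image; in practice a single pass is the
#'   stable choice — later passes can compound partial-volume leakage into
#'   the field estimate.
#' @param max_fit_voxels fit subsample cap (evenly spaced; deterministic).
#' @return List with `corrected` (`brain_volume`) and `bias` (list with
#'   `coefficients` and the evaluated `field` array, strictly positive,
#'   zero-mean log over the mask).
#' @export
correct_bias <- function(volume, poly_order = 3, mask = NULL, n_pass = 1,
                         max_fit_voxels = 40000) {
  if (poly_order < 0) stop("poly_order must be non-negative")
  if (is.null(mask)) mask <- head_mask(volume)
  idx <- which(mask)
  if (length(idx) < 10L) stop("mask is (nearly) empty")
  v <- volume$grid
  if (any(v[idx] <= 0))
    stop("intensities must be strictly positive inside the mask")
  dims <- dim(v)
  sigma_vox <- 25 / voxel_size(volume)
  den <- .gauss_smooth_cpp(mask * 1.0, dims, sigma_vox)

  logf_total <- numeric(length(v))
  pcoef_total <- numeric(choose(poly_order + 3, 3))
  for (pass in seq_len(max(n_pass, 1L))) {
    vcur <- v / exp(logf_total)
    # classification on the locally-normalized image (field cancels out)
    num <- .gauss_smooth_cpp(array(vcur * mask, dims), dims, sigma_vox)
    vn <- vcur[idx] / pmax(num[idx] / pmax(den[idx], 1e-9), 1e-9)
    gmm <- fit_gmm3(vn, max_fit = 10000)

    use <- NULL
    ucls <- NULL
    if (!is.null(gmm)) {
      post <- gmm3_posterior(gmm, vn)
      cls <- max.col(post)
      lab <- array(0L, dims)
      lab[idx] <- cls
      interior <- erode_label_interior(lab, 2L)
      conf <- array(FALSE, dims)
      conf[idx] <- post[cbind(seq_along(cls), cls)] > 0.95
      use <- which(mask & interior & conf)
      ucls <- lab[use]
      if (length(use) < 20L * (poly_order + 1L)^3)
        use <- NULL  # not enough pure voxels; fall back to the plain fit
    }
    if (!is.null(use)) {
      # the regression is identified only when the pure voxels span at
      # least two tissue classes; a one-class fit has no cross-class
      # constraint and absorbs anatomy into the field (typical of very
      # coarse grids, where partial volume leaves no pure interiors).
      counts <- table(ucls)
      keep_cls <- as.integer(names(counts)[counts >= 200])
      if (length(keep_cls) < 2L) {
        if (pass == 1L) {
          field <- array(1, dims)
          return(list(corrected = volume,
                      bias = list(coefficients = pcoef_total,
                                  field = field)))
        }
        break
      }
      sel <- ucls %in% keep_cls
      use <- use[sel]
      ucls <- ucls[sel]
    }
    plain <- is.null(use)
    if (plain) {
      use <- idx
      ucls <- rep(1L, length(use))
    }
    if (length(use) > max_fit_voxels) {
      sel <- seq(1L, length(use), length.out = max_fit_voxels)
      use <- use[sel]
      ucls <- ucls[sel]
    }
    classes <- sort(unique(ucls))
    D <- vapply(classes, function(k) as.numeric(ucls == k),
                numeric(length(ucls)))
    B <- poly_basis_grid(dims, poly_order, subset = use)[, -1, drop = FALSE]
    X <- cbind(D, B)
    y <- log(vcur[use])
    w <- rep(1, length(y))
    for (r in 1:3) {  # LS + two robust re-fits dropping gross outliers
      fit <- lm.fit(X * sqrt(w), y * sqrt(w))
      coef <- fit$coefficients
      coef[is.na(coef)] <- 0
      res <- y - drop(X %*% coef)
      s <- stats::mad(res)
      if (s <= 0) break
      w <- as.numeric(abs(res) < 2.5 * s)
    }
    pcoef <- c(0, coef[-seq_along(classes)])
    logf_pass <- eval_poly_grid(dims, poly_order, pcoef)
    logf_total <- logf_total + logf_pass
    pcoef_total <- pcoef_total + pcoef
    if (plain || sd(logf_pass[idx]) < 0.02) break
  }

  logf_total <- logf_total - mean(logf_total[idx])
  field <- array(exp(logf_total), dims)
  # exact mean-preservation inside the mask (a small scalar on top of the
  # zero-mean-log convention)
  field <- field * (mean(v[idx] / field[idx]) / mean(v[idx]))
  corrected <- with_grid(volume, v / field)
  list(corrected = corrected,
       bias = list(coefficients = pcoef_total, field = field))
}

#' Gaussian-mixture tissue segmentation
#'
#' Fits a three-component Gaussian mixture (unequal variances) to in-mask
#' intensities of a bias-corrected volume and returns voxelwise posterior
#' probability maps, with components labeled CSF < GM < WM by ascending mean
#' intensity. Posteriors sum to one inside the mask and are zero outside.
#'
#' @param volume bias-corrected `brain_volume`.
#' @param mask optional logical array; defaults to [head_mask()].
#' @param max_fit_voxels deterministic evenly-spaced subsample cap for the
#'   mixture fit (posteriors are evaluated at every masked voxel).
#' @return A list of class `tissue_maps` with `csf_prob`, `gm_prob`,
#'   `wm_prob` `brain_volume`s.
#' @export
segment_tissues <- function(volume, mask = NULL, max_fit_voxels = 20000) {
  if (is.null(mask)) mask <- head_mask(volume)
  idx <- which(mask)
  if (length(idx) < 30L) stop("mask is (nearly) empty")
  v <- volume$grid[idx]
  gmm <- fit_gmm3(v, max_fit = max_fit_voxels)
  if (is.null(gmm))
    stop("fewer than 3 distinguishable intensity modes in the input")
  post <- gmm3_posterior(gmm, v)
  dims <- dim(volume$grid)
  mk <- function(k, kind) {
    g <- array(0, dims)
    g[idx] <- post[, k]
    with_grid(volume, g, kind = kind)
  }
  structure(list(csf_prob = mk(1, "csf_prob"), gm_prob = mk(2, "gm_prob"),
                 wm_prob = mk(3, "wm_prob"),
                 means = gmm$mean, sds = gmm$sd, mask = mask),
            class = "tissue_maps")
}

# Downsample a logical/numeric array by integer stride (for the image pyramid).
stride_array <- function(a, f) {
  d <- dim(a)
  a[seq(1L, d[1], by = f), seq(1L, d[2], by = f), seq(1L, d[3], by = f),
    drop = FALSE]
}

# Normalized cross-correlation objective of moving resampled at template mask
# points through the candidate world transform.
ncc_objective <- function(moving_grid, moving_dims, Ainv_mov, A_tmp,
                          pts, tvals, params) {
  M <- world_transform(params[1:3], params[4:6], params[7:9])
  Q <- Ainv_mov %*% M %*% A_tmp
  s <- .sample_affine_points_cpp(moving_grid, moving_dims, pts, Q, 0)
  if (sd(s) < 1e-12) return(-1)
  cor(s, tvals)
}

#' Affine spatial normalization to the template grid
#'
#' Estimates a 9-parameter transform (translation, rotation, anisotropic
#' scale) from native to template space by multiresolution maximization of
#' the normalized cross-correlation with the template intensity, using
#' coordinate descent with step halving, then resamples the input onto the
#' template grid with trilinear interpolation.
#'
#' @param volume native-space `brain_volume`.
#' @param template a `template_bundle`.
#' @param transform optional precomputed transform (as returned in the output
#'   attribute) to apply without re-estimation, e.g. to carry a registration
#'   estimated on the raw intensity over to its tissue maps.
#' @param levels integer downsampling factors, coarse to fine.
#' @param min_corr error floor: estimated alignment below this normalized
#'   cross-correlation aborts with diagnostics.
#' @return Template-space `brain_volume` with attribute `transform` (a list
#'   with `translation`, `rotation_deg`, `scale`, `matrix`, `ncc`).
#' @export
normalize_to_template <- function(volume, template, transform = NULL,
                                  levels = c(4, 2, 1), min_corr = 0.25) {
  stopifnot(inherits(template, "template_bundle"))
  A_t <- template$template$affine
  A_m <- volume$affine
  dims_t <- dim(template$template$grid)
  dims_m <- dim(volume$grid)
  Ainv_mov <- solve(A_m)

  if (is.null(transform)) {
    p <- c(0, 0, 0, 0, 0, 0, 1, 1, 1)
    mask <- brain_mask(template)
    vox <- voxel_size(template$template)
    ncc <- NA_real_
    # drop pyramid levels that would leave too few voxels to be informative
    levels <- levels[min(dims_t) %/% levels >= 16 | levels == 1]
    for (f in levels) {
      mask_f <- stride_array(mask, f)
      keep <- which(mask_f)
      # cap objective points for speed; evenly spaced within the mask
      if (length(keep) > 60000L)
        keep <- keep[seq(1L, length(keep), length.out = 60000L)]
      ijk <- arrayInd(keep, dim(mask_f)) - 1L
      pts <- (ijk * f) * 1.0          # voxel indices on the full template grid
      tmpl_f <- stride_array(template$template$grid, f)
      tvals <- tmpl_f[keep]
      obj <- function(par) ncc_objective(volume$grid, dims_m, Ainv_mov, A_t,
                                         pts, tvals, par)
      steps <- c(rep(1.5 * f * vox[1], 3), rep(1.5 * f, 3), rep(0.015 * f, 3))
      tol <- c(rep(0.01 * vox[1], 3), rep(0.01, 3), rep(1e-4, 3))
      cur <- obj(p)
      repeat {
        improved <- FALSE
        for (d in seq_along(p)) {
          if (steps[d] < tol[d]) next
          for (sgn in c(1, -1)) {
            cand <- p
            cand[d] <- cand[d] + sgn * steps[d]
            val <- obj(cand)
            if (val > cur + 1e-10) {
              p <- cand
              cur <- val
              improved <- TRUE
            }
          }
        }
        if (!improved) {
          if (all(steps < tol)) break
          steps <- steps / 2
        }
      }
      ncc <- cur
    }
    if (!is.finite(ncc) || ncc < min_corr)
      stop(sprintf(paste0("registration failed: normalized cross-correlation",
                          " %.3f below floor %.3f (scan %s)"),
                   ncc, min_corr, volume$scan_id))
    transform <- transform_params(p[1:3], p[4:6], p[7:9])
    transform$ncc <- ncc
  }

  Q <- Ainv_mov %*% transform$matrix %*% A_t
  g <- .resample_affine_cpp(volume$grid, dims_m, dims_t, Q, 0)
  out <- brain_volume(array(pmax(g, if (grepl("prob", volume$kind)) 0 else
    -Inf), dims_t), A_t,
    subject_id = volume$subject_id, scan_id = volume$scan_id,
    space = "template", kind = volume$kind)
  attr(out, "transform") <- transform
  out
}

#' Gaussian spatial smoothing parameterized by FWHM
#'
#' Separable Gaussian filter with `sigma_mm = fwhm_mm / (2 sqrt(2 ln 2))`,
#' converted to voxel units through the affine's voxel sizes. Edges use
#' replicate padding, so constant volumes are preserved exactly and interior
#' signal mass is conserved.
#'
#' @param volume a `brain_volume`.
#' @param fwhm_mm kernel full width at half maximum, mm (0 = identity).
#' @return Smoothed `brain_volume` (kind `"smoothed"` unless the input was a
#'   probability map, whose kind is retained).
#' @export
smooth_volume <- function(volume, fwhm_mm) {
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  if (fwhm_mm == 0) return(volume)
  sigma_vox <- (fwhm_mm / FWHM_TO_SIGMA) / voxel_size(volume)
  g <- .gauss_smooth_cpp(volume$grid, dim(volume$grid), sigma_vox)
  kind <- if (grepl("prob", volume$kind)) volume$kind else "smoothed"
  with_grid(volume, array(g, dim(volume$grid)), kind = kind)
}

#' Min-max intensity scaling to [0, 1]
#'
#' @param volume a `brain_volume` (finite everywhere).
#' @return Scaled `brain_volume`; constant volumes map to all zeros.
#' @export
scale_intensity <- function(volume) {
  g <- volume$grid
  if (!all(is.finite(g))) stop("volume contains non-finite values")
  rng <- range(g)
  g <- if (rng[2] > rng[1]) (g - rng[1]) / (rng[2] - rng[1]) else
    array(0, dim(g))
  with_grid(volume, g)
}

#' Pairwise scan-correlation quality control
#'
#' Computes the Pearson correlation between every pair of volumes over the
#' in-mask voxels; preprocessed anatomical scans of one cohort are expected
#' to correlate highly (0.8-0.9), and pairs below `threshold` are flagged.
#'
#' @param volumes list of >= 2 `brain_volume`s on one grid.
#' @param mask logical array (non-empty).
#' @param threshold flagging threshold (default 0.8).
#' @return A list of class `qc_report`: `correlation_matrix` (symmetric, unit
#'   diagonal, dimnames = scan ids), `flags` (data frame of low pairs),
#'   `threshold`.
#' @export
qc_correlation <- function(volumes, mask, threshold = 0.8) {
  if (length(volumes) < 2L) stop("need at least two volumes")
  stopifnot_same_grid(volumes)
  if (!any(mask)) stop("mask is empty")
  idx <- which(mask)
  X <- vapply(volumes, function(v) v$grid[idx], numeric(length(idx)))
  R <- stats::cor(X)
  ids <- vapply(volumes, function(v) v$scan_id, character(1))
  if (any(ids == "") || anyDuplicated(ids)) ids <- paste0("scan", seq_along(volumes))
  dimnames(R) <- list(ids, ids)
  lo <- which(R < threshold & upper.tri(R), arr.ind = TRUE)
  flags <- data.frame(scan_a = ids[lo[, 1]], scan_b = ids[lo[, 2]],
                      r = R[lo], stringsAsFactors = FALSE)
  structure(list(correlation_matrix = R, flags = flags,
                 threshold = threshold),
            class = "qc_report")
}

#' Slice montage for visual quality control
#'
#' Writes a grayscale PNG tiling the same slice from each volume with shared
#' intensity scaling and fixed styling (byte-stable for identical inputs).
#'
#' @param volumes list of `brain_volume`s sharing a grid.
#' @param axis `"axial"` (z), `"coronal"` (y), or `"sagittal"` (x).
#' @param index 0-based slice index; defaults to the mid slice.
#' @param out_path output PNG path.
#' @return `out_path`, invisibly.
#' @export
qc_slice_montage <- function(volumes, axis = c("axial", "coronal",
                                               "sagittal"),
                             index = NULL, out_path) {
  axis <- match.arg(axis)
  d <- stopifnot_same_grid(volumes)
  ax <- switch(axis, sagittal = 1L, coronal = 2L, axial = 3L)
  if (is.null(index)) index <- (d[ax] - 1L) %/% 2L
  if (index < 0 || index >= d[ax]) stop("slice index out of bounds")
  slices <- lapply(volumes, function(v)
    switch(axis,
           sagittal = v$grid[index + 1L, , ],
           coronal = v$grid[, index + 1L, ],
           axial = v$grid[, , index + 1L]))
  rng <- range(unlist(lapply(slices, range)))
  norm <- lapply(slices, function(s)
    if (rng[2] > rng[1]) (s - rng[1]) / (rng[2] - rng[1]) else s * 0)
  n <- length(norm)
  ncol <- ceiling(sqrt(n))
  nrow <- ceiling(n / ncol)
  sh <- dim(norm[[1]])
  canvas <- matrix(0, nrow * sh[2] + nrow + 1, ncol * sh[1] + ncol + 1)
  for (i in seq_len(n)) {
    r <- (i - 1) %/% ncol
    cc <- (i - 1) %% ncol
    # display with the first grid axis horizontal, second/third vertical (up)
    img <- t(norm[[i]])[rev(seq_len(sh[2])), , drop = FALSE]
    canvas[(r * (sh[2] + 1) + 2):((r + 1) * (sh[2] + 1)),
           (cc * (sh[1] + 1) + 2):((cc + 1) * (sh[1] + 1))] <- img
  }
  png::writePNG(pmin(pmax(canvas, 0), 1), out_path)
  invisible(out_path)
}

#' Run the full preprocessing chain on one native scan
#'
#' Bias correction, tissue segmentation, affine normalization of the
#' bias-corrected intensity to the template grid (the same transform is then
#' applied to the grey-matter posterior), and FWHM Gaussian smoothing of the
#' normalized grey-matter map.
#'
#' @param volume native-space raw `brain_volume`.
#' @param template a `template_bundle`.
#' @param fwhm_mm smoothing kernel FWHM, mm.
#' @param poly_order bias polynomial order.
#' @param levels registration pyramid factors.
#' @return List with `gm_smooth` (template-space smoothed GM map),
#'   `registered` (normalized intensity), `tissue` (native tissue maps),
#'   `bias`, and `transform`.
#' @export
preprocess_scan <- function(volume, template, fwhm_mm = 8, poly_order = 3,
                            levels = c(4, 2, 1)) {
  bc <- correct_bias(volume, poly_order = poly_order)
  tis <- segment_tissues(bc$corrected)
  reg <- normalize_to_template(bc$corrected, template, levels = levels)
  tf <- attr(reg, "transform")
  gm_t <- normalize_to_template(tis$gm_prob, template, transform = tf)
  gm_t <- with_grid(gm_t, pmin(pmax(gm_t$grid, 0), 1), kind = "gm_prob")
  gm_s <- smooth_volume(gm_t, fwhm_mm)
  list(gm_smooth = gm_s, registered = reg, tissue = tis, bias = bc$bias,
       transform = tf)
}
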