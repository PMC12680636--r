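# Group-level voxel-based morphometry: design matrix with covariates,
# mass-univariate ordinary least squares, contrast t maps, Z conversion,
# permutation-based family-wise error control (maxT), and peak extraction.

#' Build the group-comparison design matrix
#'
#' Columns are `[intercept, group, age, sex]` with the group coded
#' progressive = 1, stable = 0 and age centered at its sample mean. The
#' default contrast selects grey-matter excess in the stable group
#' (stable - progressive), i.e. grey-matter loss in converters appears as
#' positive statistics.
#'
#' @param cohort a [generate_cohort()]-style cohort (or its `subjects` data
#'   frame) with both groups present.
#' @param direction `"stable_minus_progressive"` (default) or
#'   `"progressive_minus_stable"`.
#' @return A list of class `design_matrix` with `matrix`, `columns`,
#'   `contrast`, `subject_ids`, `group` (0/1 coding).
#' @export
build_design_matrix <- function(cohort,
                                direction = c("stable_minus_progressive",
                                              "progressive_minus_stable")) {
  direction <- match.arg(direction)
  subj <- if (inherits(cohort, "cohort")) cohort$subjects else cohort
  req <- c("subject_id", "group", "age", "sex")
  if (!all(req %in% names(subj)) || anyNA(subj[req]))
    stop("cohort must provide subject_id, group, age, sex without missing values")
  g <- as.integer(subj$group == "progressive")
  if (length(unique(g)) < 2L)
    stop("design is rank-deficient: only one group present")
  X <- cbind(intercept = 1, group = g, age = subj$age - mean(subj$age),
             sex = as.numeric(subj$sex))
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank-deficient")
  contrast <- c(0, if (direction == "stable_minus_progressive") -1 else 1,
                0, 0)
  structure(list(matrix = X, columns = colnames(X), contrast = contrast,
                 subject_ids = subj$subject_id, group = g),
            class = "design_matrix")
}

# Stack subject-level GM volumes into an n x V matrix over the mask,
# averaging multiple volumes per subject voxelwise.
gm_matrix <- function(gm_volumes, design, mask = NULL) {
  if (is.matrix(gm_volumes)) return(gm_volumes)
  first <- if (inherits(gm_volumes[[1]], "brain_volume")) gm_volumes[[1]]
    else gm_volumes[[1]][[1]]
  dims <- dim(first$grid)
  idx <- if (is.null(mask)) seq_len(prod(dims)) else which(mask)
  t(vapply(gm_volumes, function(v) {
    if (inherits(v, "brain_volume")) return(v$grid[idx])
    rowMeans(vapply(v, function(s) s$grid[idx], numeric(length(idx))))
  }, numeric(length(idx))))
}

#' Fit the voxel-wise general linear model
#'
#' Ordinary least squares independently at every voxel, vectorized:
#' `beta = (X'X)^-1 X' y`, `sigma2 = RSS / (n - p)`.
#'
#' @param gm_volumes one smoothed template-space GM `brain_volume` per
#'   subject, in design order (a subject may instead map to a list of scans,
#'   which are averaged voxelwise), or an `n x V` data matrix.
#' @param design a [build_design_matrix()] result.
#' @param mask optional logical analysis-mask array.
#' @return A list of class `vbm_fit` with `beta` (p x V), `sigma2` (V),
#'   `xtx_inv`, `df`, `design`, `mask`, `dims`, `affine`.
#' @export
fit_voxelwise_glm <- function(gm_volumes, design, mask = NULL) {
  X <- design$matrix
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("need more subjects than design columns")
  if (qr(X)$rank < p) stop("design matrix is rank-deficient")
  geom <- NULL
  if (!is.matrix(gm_volumes)) {
    first <- if (inherits(gm_volumes[[1]], "brain_volume")) gm_volumes[[1]]
      else gm_volumes[[1]][[1]]
    geom <- list(dims = dim(first$grid), affine = first$affine)
  }
  Y <- gm_matrix(gm_volumes, design, mask)
  if (nrow(Y) != n) stop("one (set of) volume(s) per design row is required")
  xtx_inv <- solve(crossprod(X))
  beta <- xtx_inv %*% crossprod(X, Y)
  resid <- Y - X %*% beta
  sigma2 <- colSums(resid^2) / (n - p)
  structure(list(beta = beta, sigma2 = sigma2, xtx_inv = xtx_inv,
                 df = n - p, design = design, mask = mask,
                 dims = geom$dims, affine = geom$affine),
            class = "vbm_fit")
}

#' Contrast t map from a fitted voxel-wise GLM
#'
#' `t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c)` per voxel with `df = n - p`;
#' voxels with zero residual variance are assigned t = 0 by convention.
#'
#' When localization matters more than exact Student-t calibration (peak
#' reporting with strong effects and small samples), the per-voxel variance
#' can be spatially smoothed before forming the statistic
#' (`var_smooth_fwhm_mm > 0`, a pseudo-t in the SnPM tradition): the raw t
#' map's spatial argmax is dominated by variance-estimate noise when effects
#' are large, and variance smoothing restores the effect profile's peak.
#'
#' @param fit a [fit_voxelwise_glm()] result.
#' @param contrast optional contrast vector overriding the design default.
#' @param var_smooth_fwhm_mm FWHM of Gaussian variance smoothing over the
#'   analysis mask (0 = classical t).
#' @return A list of class `stat_map` with `t_volume`, an empty `z_volume`
#'   slot (see [t_to_z()]), `df`, `contrast`, plus grid geometry when the fit
#'   was built from volumes.
#' @export
contrast_tmap <- function(fit, contrast = NULL, var_smooth_fwhm_mm = 0) {
  cvec <- contrast %||% fit$design$contrast
  if (all(cvec == 0)) stop("contrast must be non-zero")
  num <- drop(crossprod(cvec, fit$beta))
  sigma2 <- fit$sigma2
  if (var_smooth_fwhm_mm > 0) {
    if (is.null(fit$dims))
      stop("variance smoothing needs grid geometry (volume-based fit)")
    sigma2 <- smooth_masked_values(sigma2, fit$dims, fit$mask, fit$affine,
                                   var_smooth_fwhm_mm)
  }
  se2 <- sigma2 * drop(crossprod(cvec, fit$xtx_inv %*% cvec))
  t <- ifelse(se2 > 0, num / sqrt(se2), 0)
  structure(list(t_values = t, z_values = NULL, df = fit$df,
                 contrast = cvec, mask = fit$mask, dims = fit$dims,
                 affine = fit$affine),
            class = "stat_map")
}

#' Convert t statistics to Z-score equivalents
#'
#' `z = Phi^-1(F_t(t; df))`, computed tail-symmetrically in log space so
#' large statistics do not saturate; monotone in t with matching sign.
#'
#' @param stat_map a [contrast_tmap()] result (or numeric t values with a
#'   `df` argument).
#' @param df residual degrees of freedom when `stat_map` is numeric.
#' @return The `stat_map` with `z_values` filled (or a numeric vector).
#' @export
t_to_z <- function(stat_map, df = NULL) {
  tv <- if (inherits(stat_map, "stat_map")) stat_map$t_values else stat_map
  df <- if (inherits(stat_map, "stat_map")) stat_map$df else df
  if (is.null(df) || df < 1) stop("df must be at least 1")
  z <- numeric(length(tv))
  up <- tv >= 0
  # upper tail in log space, mirrored for negative t
  z[up] <- -qnorm(pt(tv[up], df, lower.tail = FALSE, log.p = TRUE),
                  log.p = TRUE)
  z[!up] <- qnorm(pt(tv[!up], df, lower.tail = TRUE, log.p = TRUE),
                  log.p = TRUE)
  if (inherits(stat_map, "stat_map")) {
    stat_map$z_values <- z
    stat_map
  } else z
}

# Mask-normalized Gaussian smoothing of a masked value vector.
smooth_masked_values <- function(values, dims, mask, affine, fwhm_mm) {
  m <- mask %||% array(TRUE, dims)
  full <- array(0, dims)
  full[which(m)] <- values
  sig <- (fwhm_mm / FWHM_TO_SIGMA) / voxel_size(affine)
  num <- .gauss_smooth_cpp(full, dims, sig)
  den <- .gauss_smooth_cpp(m * 1.0, dims, sig)
  (num / pmax(den, 1e-12))[which(m)]
}

# Reshape a masked statistic vector into a full grid array.
stat_volume <- function(values, dims, mask) {
  g <- array(0, dims)
  g[if (is.null(mask)) seq_len(prod(dims)) else which(mask)] <- values
  g
}

#' Permutation (maxT) family-wise-error threshold
#'
#' Re-fits the GLM under `n_perm` random relabelings of the group column
#' (covariates held fixed), records the maximum |Z| over the mask for each,
#' and returns the `1 - alpha` empirical quantile of that null maximum
#' distribution. A voxel whose observed |Z| exceeds the threshold is
#' significant at FWE-corrected level `alpha`.
#'
#' @inheritParams fit_voxelwise_glm
#' @param n_perm number of permutations (>= 100).
#' @param alpha familywise error level.
#' @param seed integer seed for the permutation draws.
#' @param contrast optional contrast override.
#' @return The Z threshold (numeric scalar) with attribute `max_null`, the
#'   permutation null maxima.
#' @export
fwe_threshold <- function(gm_volumes, design, n_perm = 1000, alpha = 0.05,
                          seed = 1, mask = NULL, contrast = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  g <- design$group
  n1 <- sum(g == 1)
  if (n1 < 2 || sum(g == 0) < 2) stop("need at least 2 subjects per group")
  if (choose(length(g), n1) < 1 / alpha)
    stop("too few distinct permutations for the requested alpha")
  Y <- gm_matrix(gm_volumes, design, mask)
  X <- design$matrix
  gcol <- which(design$columns == "group")
  cvec <- contrast %||% design$contrast
  df <- nrow(X) - ncol(X)
  set.seed(substream_seed(seed, "fwe-maxT"))
  maxz <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    Xp <- X
    Xp[, gcol] <- sample(g)
    xtx_inv <- solve(crossprod(Xp))
    beta <- xtx_inv %*% crossprod(Xp, Y)
    resid <- Y - Xp %*% beta
    sigma2 <- colSums(resid^2) / df
    se2 <- sigma2 * drop(crossprod(cvec, xtx_inv %*% cvec))
    t <- ifelse(se2 > 0, drop(crossprod(cvec, beta)) / sqrt(se2), 0)
    maxz[b] <- max(abs(t_to_z(t, df = df)))
  }
  # exact-test order statistic: with B permutations the observed arrangement
  # is the (B+1)-th member of the reference set
  k <- min(n_perm, ceiling((1 - alpha) * (n_perm + 1)))
  thr <- sort(maxz, partial = k)[k]
  attr(thr, "max_null") <- maxz
  thr
}

#' Extract significant peak coordinates
#'
#' Finds local maxima of the Z volume over the 26-neighborhood above the
#' threshold (exact ties resolved toward the lowest linear voxel index),
#' then greedily retains them in descending Z subject to a minimum pairwise
#' world distance, mapping voxel indices to MNI millimeters via the affine.
#'
#' @param stat_map a [t_to_z()]-completed `stat_map` carrying grid geometry.
#' @param z_threshold retain only peaks with Z above this value.
#' @param min_separation_mm minimum distance between reported peaks.
#' @return A data frame of class `peak_table` with columns `z_score`, `x_mm`,
#'   `y_mm`, `z_mm`, `label` (pass-through text, `NA` by default), sorted by
#'   descending `z_score`; attribute `voxel` holds the 0-based indices.
#' @export
extract_peaks <- function(stat_map, z_threshold, min_separation_mm = 8) {
  if (is.null(stat_map$z_values)) stop("run t_to_z() first")
  if (is.null(stat_map$dims))
    stop("stat_map carries no grid geometry (fit was matrix-based)")
  zvol <- stat_volume(stat_map$z_values, stat_map$dims, stat_map$mask)
  mask <- stat_map$mask %||% array(TRUE, stat_map$dims)
  pk <- .local_maxima_cpp(zvol, dim(zvol), mask, z_threshold)
  empty <- data.frame(z_score = numeric(0), x_mm = numeric(0),
                      y_mm = numeric(0), z_mm = numeric(0),
                      label = character(0), stringsAsFactors = FALSE)
  if (nrow(pk) == 0)
    return(structure(empty, class = c("peak_table", "data.frame")))
  zv <- zvol[pk + 1L]
  ord <- order(-zv)
  pk <- pk[ord, , drop = FALSE]
  zv <- zv[ord]
  world <- t(apply(pk, 1, function(v) voxel_to_mni(v, stat_map$affine)))
  keep <- integer(0)
  for (i in seq_along(zv)) {
    if (length(keep) == 0L) {
      keep <- i
      next
    }
    d <- sqrt(rowSums((world[keep, , drop = FALSE] -
                         matrix(world[i, ], length(keep), 3,
                                byrow = TRUE))^2))
    if (all(d >= min_separation_mm)) keep <- c(keep, i)
  }
  out <- data.frame(z_score = zv[keep], x_mm = world[keep, 1],
                    y_mm = world[keep, 2], z_mm = world[keep, 3],
                    label = NA_character_, stringsAsFactors = FALSE)
  attr(out, "voxel") <- pk[keep, , drop = FALSE]
  structure(out, class = c("peak_table", "data.frame"))
}

#' Z-standardize a value
#'
#' @param x data value(s).
#' @param mu distribution mean.
#' @param sigma distribution standard deviation (> 0).
#' @return `(x - mu) / sigma`.
#' @export
standardize <- function(x, mu, sigma) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  (x - mu) / sigma
}

#' Write / read a peak table as TSV
#'
#' Columns `z_score`, `x_mm`, `y_mm`, `z_mm`, `label`.
#' @param peaks a `peak_table`.
#' @param path TSV path.
#' @return the path (write) or the `peak_table` (read).
#' @export
write_peak_table <- function(peaks, path) {
  write.table(as.data.frame(peaks), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df <- df[order(-df$z_score), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("peak_table", "data.frame"))
}

#' One-call group-level analysis
#'
#' Fits the voxel-wise GLM on subject-level smoothed GM maps, converts the
#' contrast map to Z, computes the permutation FWE threshold, and extracts
#' the significant peak table.
#'
#' @inheritParams fwe_threshold
#' @param min_separation_mm peak separation, mm.
#' @param var_smooth_fwhm_mm optional variance smoothing for the reported
#'   map (see [contrast_tmap()]); the FWE threshold is always computed from
#'   the classical statistic.
#' @return List with `stat_map`, `threshold`, `peaks`.
#' @export
run_vbm <- function(gm_volumes, design, mask = NULL, alpha = 0.05,
                    n_perm = 1000, seed = 1, min_separation_mm = 8,
                    var_smooth_fwhm_mm = 0) {
  fit <- fit_voxelwise_glm(gm_volumes, design, mask)
  sm <- t_to_z(contrast_tmap(fit, var_smooth_fwhm_mm = var_smooth_fwhm_mm))
  thr <- fwe_threshold(gm_volumes, design, n_perm = n_perm, alpha = alpha,
                       seed = seed, mask = mask)
  peaks <- extract_peaks(sm, z_threshold = as.numeric(thr),
                         min_separation_mm = min_separation_mm)
  list(stat_map = sm, threshold = thr, peaks = peaks)
}
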