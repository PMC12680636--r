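# Shared small fixtures, built in code.

# Coarse template bundle reused across tests (3 mm grid, same field of view
# as the full-resolution template).
coarse_template <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_template(c(57, 69, 57), 3)
    cache
  }
})

# Piecewise-constant three-tissue block phantom with a little noise; pure
# classes everywhere, so bias-field recovery is identifiable.
block_phantom <- function(dims = c(40, 40, 40), noise_sd = 0.01, seed = 1) {
  set.seed(seed)
  g <- array(0.25, dims)
  g[(dims[1] %/% 3):dims[1], , ] <- 0.55
  g[(2 * dims[1] %/% 3):dims[1], , ] <- 0.85
  truth <- g
  g <- g + array(rnorm(prod(dims), 0, noise_sd), dims)
  list(volume = brain_volume(g, diag(4)), truth = truth)
}

# Naive seven-loop cross-correlation oracle (single output position cost is
# irrelevant at the tiny sizes used).
conv3d_oracle <- function(x, w, b, same = FALSE) {
  xd <- dim(x)
  wd <- dim(w)
  px <- if (same) (wd[1:3] - 1) %/% 2 else c(0L, 0L, 0L)
  od <- if (same) xd[1:3] else xd[1:3] - wd[1:3] + 1L
  out <- array(0, c(od, wd[5]))
  for (co in seq_len(wd[5]))
    for (zo in seq_len(od[3])) for (yo in seq_len(od[2]))
      for (xo in seq_len(od[1])) {
        acc <- b[co]
        for (ci in seq_len(wd[4]))
          for (dz in seq_len(wd[3])) for (dy in seq_len(wd[2]))
            for (dx in seq_len(wd[1])) {
              xi <- xo + dx - 1L - px[1]
              yi <- yo + dy - 1L - px[2]
              zi <- zo + dz - 1L - px[3]
              if (xi >= 1 && yi >= 1 && zi >= 1 &&
                  xi <= xd[1] && yi <= xd[2] && zi <= xd[3])
                acc <- acc + x[xi, yi, zi, ci] * w[dx, dy, dz, ci, co]
            }
        out[xo, yo, zo, co] <- acc
      }
  out
}

# Per-voxel normal-equations OLS oracle.
glm_oracle <- function(Y, X, cvec) {
  n <- nrow(X)
  p <- ncol(X)
  t(vapply(seq_len(ncol(Y)), function(v) {
    fit <- lm.fit(X, Y[, v])
    beta <- fit$coefficients
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / (n - p)
    se2 <- sigma2 * drop(t(cvec) %*% solve(crossprod(X)) %*% cvec)
    tval <- if (se2 > 0) sum(cvec * beta) / sqrt(se2) else 0
    c(beta, sigma2 = sigma2, t = tval)
  }, numeric(p + 2)))
}

# Template-space subject GM maps for group-level tests: one map per subject.
simulate_vbm_inputs <- function(n_per_group, template, spec, seed,
                                fwhm_mm = 8) {
  cohort <- generate_cohort(n_per_group, seed = seed, p_second_scan = 0)
  maps <- simulate_gm_maps(cohort, template, spec, fwhm_mm = fwhm_mm,
                           seed = seed)
  list(cohort = cohort, maps = maps)
}
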