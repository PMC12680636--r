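# The two 3D CNN classifiers: a whole-volume network and a region-guided
# patch network with Z-score fusion. Forward and backward passes are written
# explicitly against the package's C++ convolution/pooling kernels; gradient
# correctness is checked against numerical differentiation in the tests.

#' 3D convolution with bias (cross-correlation convention)
#'
#' `O(x,y,z) = sum_{i,j,k} I(x+i, y+j, z+k) K(i,j,k) + b`, the convolution
#' contract used by all network layers. `"valid"` padding shrinks each
#' dimension by `kernel - 1`; `"same"` zero-pads to preserve dimensions.
#'
#' @param input 3D array (single channel) or 4D array `(X, Y, Z, C_in)`.
#' @param kernel 3D array (single in/out channel) or 5D array
#'   `(kx, ky, kz, C_in, C_out)` with odd spatial dimensions.
#' @param bias per-output-filter bias (recycled scalar allowed).
#' @param padding `"valid"` or `"same"`.
#' @return Feature map array; 3D when both input and kernel are
#'   single-channel, otherwise 4D.
#' @export
conv3d <- function(input, kernel, bias = 0, padding = c("valid", "same")) {
  padding <- match.arg(padding)
  was3d <- length(dim(input)) == 3L
  x <- if (was3d) array(input, c(dim(input), 1L)) else input
  w <- if (length(dim(kernel)) == 3L) array(kernel, c(dim(kernel), 1L, 1L))
       else kernel
  if (length(dim(x)) != 4L || length(dim(w)) != 5L)
    stop("input must be 3D/4D and kernel 3D/5D")
  if (dim(x)[4] != dim(w)[4]) stop("channel mismatch between input and kernel")
  co <- dim(w)[5]
  b <- rep_len(as.numeric(bias), co)
  out <- .conv3d_fwd_cpp(x, dim(x), w, dim(w), b, as.integer(padding == "same"))
  if (was3d && co == 1L) array(out, dim(out)[1:3]) else out
}

#' Binary cross-entropy loss
#'
#' `-[y log(p) + (1 - y) log(1 - p)]` with predictions clipped to
#' `[eps, 1 - eps]` — the two-class instance of categorical cross-entropy.
#'
#' @param y true label(s) in `{0, 1}`.
#' @param y_hat predicted probability(ies).
#' @param eps clipping constant.
#' @return Elementwise loss.
#' @export
binary_cross_entropy <- function(y, y_hat, eps = 1e-7) {
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1")
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

lrelu <- function(x, alpha) ifelse(x > 0, x, alpha * x)
lrelu_grad <- function(x, alpha) ifelse(x > 0, 1, alpha)
sigmoid <- function(x) 1 / (1 + exp(-x))

he_init <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)),
                                        dims)

#' Whole-volume 3D CNN specification
#'
#' Three (convolution, leaky-ReLU, 2x2x2 max-pool) blocks with 32/64/128
#' filters and 3x3x3 kernels, then flatten, a 128-unit dense layer, dropout,
#' and a single sigmoid output. Convolutions use valid padding (the
#' framework-default choice; the source architecture does not state it).
#'
#' @param input_shape grid dimensions of the input volume.
#' @param filters three conv filter counts.
#' @param dense_units dense head width.
#' @param dropout dropout rate.
#' @param leaky_slope leaky-ReLU negative slope.
#' @return A list of class `whole_volume_spec`.
#' @export
whole_volume_spec <- function(input_shape = c(113, 137, 113),
                              filters = c(32, 64, 128), dense_units = 128,
                              dropout = 0.5, leaky_slope = 0.01) {
  stopifnot(length(filters) == 3, all(filters >= 1))
  structure(list(input_shape = as.integer(input_shape),
                 filters = as.integer(filters), kernel = 3L,
                 dense_units = as.integer(dense_units), dropout = dropout,
                 leaky_slope = leaky_slope),
            class = "whole_volume_spec")
}

# spatial dims through one valid conv (k=3) + pool-2 block
block_dims <- function(d, k = 3L) (d - k + 1L) %/% 2L

#' Build the whole-volume classifier
#'
#' @param spec a [whole_volume_spec()].
#' @param seed integer controlling weight initialization.
#' @return A `cnn_classifier` mapping an `input_shape` volume to a
#'   probability in (0, 1).
#' @export
build_whole_volume_model <- function(spec = whole_volume_spec(), seed = 1) {
  set.seed(substream_seed(seed, "init/whole"))
  f <- spec$filters
  k <- spec$kernel
  d <- spec$input_shape
  for (i in 1:3) d <- block_dims(d, k)
  if (any(d < 1)) stop("input_shape too small for three conv/pool blocks")
  flat <- prod(d) * f[3]
  params <- list(
    conv1_w = he_init(c(k, k, k, 1, f[1]), k^3),
    conv1_b = numeric(f[1]),
    conv2_w = he_init(c(k, k, k, f[1], f[2]), k^3 * f[1]),
    conv2_b = numeric(f[2]),
    conv3_w = he_init(c(k, k, k, f[2], f[3]), k^3 * f[2]),
    conv3_b = numeric(f[3]),
    dense1_w = he_init(c(spec$dense_units, flat), flat),
    dense1_b = numeric(spec$dense_units),
    out_w = he_init(c(1, spec$dense_units), spec$dense_units),
    out_b = 0
  )
  structure(list(type = "whole_volume", spec = spec, params = params,
                 flatten_dim = flat, seed = seed),
            class = "cnn_classifier")
}

#' Region-guided patch CNN specification
#'
#' A shared per-patch encoder — same-padded 3x3x3 convolutions with 32 then
#' 64 filters, each followed by leaky-ReLU and 2x2x2 max pooling (patch side
#' 15 -> 7 -> 3), flatten, dense embedding — applied identically to each of
#' the K coordinate patches. The K embeddings are concatenated with the K
#' regional Z-scores (width `K * dense_units + K`; 2838 at the default
#' K = 22), then passed through a dense fusion layer, dropout 0.5, and a
#' sigmoid output.
#'
#' @param n_patches K, the coordinate/patch count.
#' @param patch_side odd patch side length.
#' @param filters two encoder filter counts.
#' @param dense_units per-patch embedding width.
#' @param fusion_units fusion dense width.
#' @param dropout dropout rate.
#' @param leaky_slope leaky-ReLU negative slope.
#' @return A list of class `region_spec`.
#' @export
region_spec <- function(n_patches = 22, patch_side = 15, filters = c(32, 64),
                        dense_units = 128, fusion_units = 128, dropout = 0.5,
                        leaky_slope = 0.01) {
  stopifnot(n_patches >= 1, patch_side %% 2 == 1, length(filters) == 2)
  structure(list(n_patches = as.integer(n_patches),
                 patch_side = as.integer(patch_side),
                 filters = as.integer(filters), kernel = 3L,
                 dense_units = as.integer(dense_units),
                 fusion_units = as.integer(fusion_units), dropout = dropout,
                 leaky_slope = leaky_slope),
            class = "region_spec")
}

#' Build the region-guided classifier
#'
#' @param K number of coordinate patches (overrides the spec's `n_patches`).
#' @param spec a [region_spec()].
#' @param seed integer controlling weight initialization.
#' @return A `cnn_classifier` mapping `(K patches of patch_side^3, K
#'   z-scores)` to a probability.
#' @export
build_region_model <- function(K = NULL, spec = region_spec(), seed = 1) {
  if (!is.null(K)) spec$n_patches <- as.integer(K)
  if (spec$n_patches < 1) stop("K must be at least 1")
  set.seed(substream_seed(seed, "init/region"))
  f <- spec$filters
  k <- spec$kernel
  s1 <- spec$patch_side %/% 2L        # same-pad conv keeps side, pool halves
  s2 <- s1 %/% 2L
  if (s2 < 1) stop("patch_side too small for two pooling stages")
  flat <- s2^3 * f[2]
  fused <- spec$n_patches * spec$dense_units + spec$n_patches
  params <- list(
    enc_conv1_w = he_init(c(k, k, k, 1, f[1]), k^3),
    enc_conv1_b = numeric(f[1]),
    enc_conv2_w = he_init(c(k, k, k, f[1], f[2]), k^3 * f[1]),
    enc_conv2_b = numeric(f[2]),
    enc_dense_w = he_init(c(spec$dense_units, flat), flat),
    enc_dense_b = numeric(spec$dense_units),
    fuse_w = he_init(c(spec$fusion_units, fused), fused),
    fuse_b = numeric(spec$fusion_units),
    out_w = he_init(c(1, spec$fusion_units), spec$fusion_units),
    out_b = 0
  )
  structure(list(type = "region", spec = spec, params = params,
                 flatten_dim = flat, fused_width = fused,
                 pooled_sides = c(s1, s2), seed = seed),
            class = "cnn_classifier")
}

#' @export
print.cnn_classifier <- function(x, ...) {
  s <- model_summary(x)
  if (x$type == "whole_volume")
    cat(sprintf(paste0("<cnn_classifier: whole volume> input %s, filters ",
                       "(%s), dense %d, flatten %d\n"),
                paste(x$spec$input_shape, collapse = "x"),
                paste(s$filters, collapse = ", "), x$spec$dense_units,
                s$flatten_dim))
  else
    cat(sprintf(paste0("<cnn_classifier: region guided> K = %d patches of ",
                       "%d^3, encoder filters (%s), side %d -> %d -> %d, ",
                       "fused width %d\n"),
                x$spec$n_patches, x$spec$patch_side,
                paste(s$filters, collapse = ", "), x$spec$patch_side,
                s$patch_side_sequence[2], s$patch_side_sequence[3],
                s$fused_width))
  invisible(x)
}

#' Architecture introspection
#'
#' Reports the structural quantities of a built classifier by running a
#' shape-traced forward pass: filter counts, the per-patch pooled side
#' sequence, the concatenated patch-feature width, and the fused input width
#' of the region model's fusion layer.
#'
#' @param model a `cnn_classifier`.
#' @return A list of structural fields (depending on model type).
#' @export
model_summary <- function(model) {
  stopifnot(inherits(model, "cnn_classifier"))
  if (model$type == "whole_volume") {
    return(list(type = model$type, filters = model$spec$filters,
                dense_units = model$spec$dense_units,
                flatten_dim = model$flatten_dim))
  }
  sp <- model$spec
  # trace an actual dummy patch through the encoder and record shapes
  x <- array(0, c(sp$patch_side, sp$patch_side, sp$patch_side, 1))
  c1 <- .conv3d_fwd_cpp(x, dim(x), model$params$enc_conv1_w,
                        dim(model$params$enc_conv1_w),
                        model$params$enc_conv1_b, 1L)
  p1 <- .maxpool3d_fwd_cpp(c1, dim(c1))$out
  c2 <- .conv3d_fwd_cpp(p1, dim(p1), model$params$enc_conv2_w,
                        dim(model$params$enc_conv2_w),
                        model$params$enc_conv2_b, 1L)
  p2 <- .maxpool3d_fwd_cpp(c2, dim(c2))$out
  list(type = model$type, filters = sp$filters, n_patches = sp$n_patches,
       patch_side_sequence = c(sp$patch_side, dim(p1)[1], dim(p2)[1]),
       flatten_dim = prod(dim(p2)),
       patch_feature_width = sp$n_patches * sp$dense_units,
       fused_width = sp$n_patches * sp$dense_units + sp$n_patches)
}

# ---------------------------------------------------------------------------
# forward/backward passes

conv_block_fwd <- function(x, w, b, alpha, same) {
  c <- .conv3d_fwd_cpp(x, dim(x), w, dim(w), b, same)
  a <- lrelu(c, alpha)
  pl <- .maxpool3d_fwd_cpp(a, dim(a))
  list(x = x, c = c, a = a, p = pl$out, arg = pl$argmax)
}

conv_block_bwd <- function(blk, w, gp, alpha, same) {
  ga <- .maxpool3d_bwd_cpp(gp, blk$arg, dim(blk$a))
  gc <- ga * lrelu_grad(blk$c, alpha)
  bw <- .conv3d_bwd_cpp(blk$x, dim(blk$x), w, dim(w), gc, same)
  bw
}

as_model_input <- function(model, input) {
  if (model$type == "whole_volume") {
    g <- if (inherits(input, "brain_volume")) input$grid else input
    if (length(dim(g)) == 3L) g <- array(g, c(dim(g), 1L))
    if (!identical(dim(g)[1:3], model$spec$input_shape))
      stop(sprintf("input shape (%s) does not match the model's (%s)",
                   paste(dim(g)[1:3], collapse = ","),
                   paste(model$spec$input_shape, collapse = ",")))
    g
  } else {
    if (inherits(input, "patch_sample"))
      input <- list(patches = input$patches, z_scores = input$z_scores)
    sp <- model$spec
    pd <- dim(input$patches)
    if (!identical(as.integer(pd),
                   c(rep(sp$patch_side, 3L), sp$n_patches)))
      stop(sprintf("patches must be %d^3 x K=%d", sp$patch_side,
                   sp$n_patches))
    if (length(input$z_scores) != sp$n_patches)
      stop("z-score count must equal K")
    input
  }
}

model_forward <- function(model, input, drop_mask = NULL) {
  p <- model$params
  sp <- model$spec
  a <- sp$leaky_slope
  if (model$type == "whole_volume") {
    x <- as_model_input(model, input)
    b1 <- conv_block_fwd(x, p$conv1_w, p$conv1_b, a, 0L)
    b2 <- conv_block_fwd(b1$p, p$conv2_w, p$conv2_b, a, 0L)
    b3 <- conv_block_fwd(b2$p, p$conv3_w, p$conv3_b, a, 0L)
    f <- as.vector(b3$p)
    h <- drop(p$dense1_w %*% f) + p$dense1_b
    ha <- lrelu(h, a)
    hd <- if (is.null(drop_mask)) ha else ha * drop_mask
    logit <- drop(p$out_w %*% hd) + p$out_b
    cache <- list(b1 = b1, b2 = b2, b3 = b3, f = f, h = h, ha = ha, hd = hd,
                  drop_mask = drop_mask)
  } else {
    inp <- as_model_input(model, input)
    K <- sp$n_patches
    D <- sp$dense_units
    feats <- matrix(0, D, K)
    enc <- vector("list", K)
    for (k in seq_len(K)) {
      xk <- array(inp$patches[, , , k], c(rep(sp$patch_side, 3L), 1L))
      e1 <- conv_block_fwd(xk, p$enc_conv1_w, p$enc_conv1_b, a, 1L)
      e2 <- conv_block_fwd(e1$p, p$enc_conv2_w, p$enc_conv2_b, a, 1L)
      fk <- as.vector(e2$p)
      hk <- drop(p$enc_dense_w %*% fk) + p$enc_dense_b
      feats[, k] <- lrelu(hk, a)
      enc[[k]] <- list(e1 = e1, e2 = e2, fk = fk, hk = hk)
    }
    fused <- c(as.vector(feats), inp$z_scores)
    fh <- drop(p$fuse_w %*% fused) + p$fuse_b
    fha <- lrelu(fh, a)
    fhd <- if (is.null(drop_mask)) fha else fha * drop_mask
    logit <- drop(p$out_w %*% fhd) + p$out_b
    cache <- list(enc = enc, feats = feats, fused = fused, fh = fh,
                  fha = fha, fhd = fhd, drop_mask = drop_mask, input = inp)
  }
  list(prob = sigmoid(logit), logit = logit, cache = cache)
}

model_backward <- function(model, cache, dlogit, want_input_grad = FALSE) {
  p <- model$params
  sp <- model$spec
  a <- sp$leaky_slope
  g <- list()
  if (model$type == "whole_volume") {
    g$out_w <- matrix(dlogit * cache$hd, 1)
    g$out_b <- dlogit
    ghd <- drop(t(p$out_w)) * dlogit
    gha <- if (is.null(cache$drop_mask)) ghd else ghd * cache$drop_mask
    gh <- gha * lrelu_grad(cache$h, a)
    g$dense1_w <- gh %o% cache$f
    g$dense1_b <- gh
    gf <- drop(crossprod(p$dense1_w, gh))
    gp3 <- array(gf, dim(cache$b3$p))
    bw3 <- conv_block_bwd(cache$b3, p$conv3_w, gp3, a, 0L)
    g$conv3_w <- bw3$gw; g$conv3_b <- bw3$gb
    bw2 <- conv_block_bwd(cache$b2, p$conv2_w, bw3$gx, a, 0L)
    g$conv2_w <- bw2$gw; g$conv2_b <- bw2$gb
    bw1 <- conv_block_bwd(cache$b1, p$conv1_w, bw2$gx, a, 0L)
    g$conv1_w <- bw1$gw; g$conv1_b <- bw1$gb
    ginput <- if (want_input_grad) bw1$gx else NULL
  } else {
    K <- sp$n_patches
    D <- sp$dense_units
    g$out_w <- matrix(dlogit * cache$fhd, 1)
    g$out_b <- dlogit
    gfhd <- drop(t(p$out_w)) * dlogit
    gfha <- if (is.null(cache$drop_mask)) gfhd else gfhd * cache$drop_mask
    gfh <- gfha * lrelu_grad(cache$fh, a)
    g$fuse_w <- gfh %o% cache$fused
    g$fuse_b <- gfh
    gfused <- drop(crossprod(p$fuse_w, gfh))
    gfeats <- matrix(gfused[seq_len(K * D)], D, K)
    gz <- gfused[K * D + seq_len(K)]
    g$enc_dense_w <- matrix(0, nrow(p$enc_dense_w), ncol(p$enc_dense_w))
    g$enc_dense_b <- numeric(length(p$enc_dense_b))
    g$enc_conv1_w <- array(0, dim(p$enc_conv1_w))
    g$enc_conv1_b <- numeric(length(p$enc_conv1_b))
    g$enc_conv2_w <- array(0, dim(p$enc_conv2_w))
    g$enc_conv2_b <- numeric(length(p$enc_conv2_b))
    gpatches <- if (want_input_grad)
      array(0, dim(cache$input$patches)) else NULL
    for (k in seq_len(K)) {
      ek <- cache$enc[[k]]
      ghk <- gfeats[, k] * lrelu_grad(ek$hk, a)
      g$enc_dense_w <- g$enc_dense_w + ghk %o% ek$fk
      g$enc_dense_b <- g$enc_dense_b + ghk
      gfk <- drop(crossprod(p$enc_dense_w, ghk))
      gp2 <- array(gfk, dim(ek$e2$p))
      bw2 <- conv_block_bwd(ek$e2, p$enc_conv2_w, gp2, a, 1L)
      g$enc_conv2_w <- g$enc_conv2_w + bw2$gw
      g$enc_conv2_b <- g$enc_conv2_b + bw2$gb
      bw1 <- conv_block_bwd(ek$e1, p$enc_conv1_w, bw2$gx, a, 1L)
      g$enc_conv1_w <- g$enc_conv1_w + bw1$gw
      g$enc_conv1_b <- g$enc_conv1_b + bw1$gb
      if (want_input_grad)
        gpatches[, , , k] <- array(bw1$gx, dim(gpatches)[1:3])
    }
    ginput <- if (want_input_grad) list(patches = gpatches, z_scores = gz)
      else NULL
  }
  list(grads = g, ginput = ginput)
}

#' Predict class probabilities
#'
#' @param model a `cnn_classifier`.
#' @param inputs a single input (volume/`brain_volume` for the whole-volume
#'   model; `patch_sample` or `list(patches, z_scores)` for the region model)
#'   or a list of them.
#' @return Numeric probability vector (progressive class).
#' @export
predict_proba <- function(model, inputs) {
  single <- inherits(inputs, c("brain_volume", "patch_sample")) ||
    is.array(inputs) ||
    (is.list(inputs) && !is.null(inputs$patches))
  if (single) inputs <- list(inputs)
  vapply(inputs, function(x) model_forward(model, x)$prob, numeric(1))
}

#' Gradient saliency map
#'
#' Voxelwise magnitude of the gradient of the output logit with respect to
#' the input, `|d logit / d input|`, computed with dropout disabled.
#'
#' @param model a `cnn_classifier`.
#' @param input a model input (see [predict_proba()]).
#' @return For the whole-volume model, an array of the input shape; for the
#'   region model, a list with `patches` (per-patch gradient magnitudes) and
#'   `z_scores`.
#' @export
saliency_map <- function(model, input) {
  if (!inherits(model, "cnn_classifier"))
    stop("saliency requires a differentiable cnn_classifier")
  fw <- model_forward(model, input)
  bw <- model_backward(model, fw$cache, 1, want_input_grad = TRUE)
  if (model$type == "whole_volume") {
    g <- abs(bw$ginput)
    array(g, dim(g)[1:3])
  } else {
    list(patches = abs(bw$ginput$patches),
         z_scores = abs(bw$ginput$z_scores))
  }
}

#' Write a tri-planar (axial/coronal/sagittal mid-slice) PNG of a volume
#'
#' @param volume 3D array or `brain_volume` (e.g. a saliency map).
#' @param out_path PNG path.
#' @return `out_path`, invisibly.
#' @export
write_triplanar <- function(volume, out_path) {
  g <- if (inherits(volume, "brain_volume")) volume$grid else volume
  d <- dim(g)
  rng <- range(g)
  nrm <- function(s) if (rng[2] > rng[1]) (s - rng[1]) / (rng[2] - rng[1])
    else s * 0
  panels <- list(t(nrm(g[, , (d[3] + 1) %/% 2])),
                 t(nrm(g[, (d[2] + 1) %/% 2, ])),
                 t(nrm(g[(d[1] + 1) %/% 2, , ])))
  h <- max(vapply(panels, nrow, integer(1)))
  w <- sum(vapply(panels, ncol, integer(1))) + 2
  canvas <- matrix(0, h, w)
  off <- 0
  for (p in panels) {
    canvas[seq_len(nrow(p)), off + seq_len(ncol(p))] <- p[rev(seq_len(nrow(p))), ]
    off <- off + ncol(p) + 1
  }
  png::writePNG(pmin(pmax(canvas, 0), 1), out_path)
  invisible(out_path)
}
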