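# Subject-level splitting, augmentation, Adam training, and evaluation,
# tying all stages into a reproducible end-to-end experiment.

#' Subject-level stratified train/validation/test split
#'
#' Shuffles subjects within each group and partitions them so that every
#' scan of a subject inherits one subset (no identity leakage). Rounding
#' rule: train gets `floor(r_train * n)`, test gets `floor(r_test * n)`,
#' validation gets the remainder, per group.
#'
#' @param cohort a [generate_cohort()] cohort.
#' @param ratios train/validation/test fractions summing to 1.
#' @param seed integer seed.
#' @return A data frame of class `split_assignment` with `subject_id`,
#'   `group`, `subset`; attribute `seed`.
#' @export
split_subjects <- function(cohort, ratios = c(0.8, 0.1, 0.1), seed = 1) {
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  subj <- cohort$subjects
  set.seed(substream_seed(seed, "split"))
  parts <- lapply(split(subj, subj$group), function(gs) {
    n <- nrow(gs)
    n_train <- floor(ratios[1] * n)
    n_test <- floor(ratios[3] * n)
    n_val <- n - n_train - n_test
    if (n_train < 1 || n_val < 1 || n_test < 1)
      stop("too few subjects in a group for the requested ratios")
    ord <- sample.int(n)
    data.frame(subject_id = gs$subject_id[ord], group = gs$group[ord],
               subset = rep(c("train", "val", "test"),
                            c(n_train, n_val, n_test)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  structure(out, seed = seed, class = c("split_assignment", "data.frame"))
}

#' Flip a volume along a grid axis
#'
#' Exact array reversal (an involution: flipping twice restores the input
#' bitwise).
#'
#' @param volume `brain_volume` or 3D array.
#' @param axis grid axis 1, 2, or 3.
#' @return Same type as the input.
#' @export
flip_volume <- function(volume, axis) {
  g <- if (inherits(volume, "brain_volume")) volume$grid else volume
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- rev(seq_len(dim(g)[axis]))
  gf <- do.call(`[`, c(list(g), idx))
  if (inherits(volume, "brain_volume")) with_grid(volume, gf) else gf
}

#' Augmentation configuration
#'
#' @param max_rotation_deg rotation magnitude bound about a random axis.
#' @param flip_axes grid axes eligible for random flips (the two in-plane
#'   axes by default).
#' @param flip_prob per-axis flip probability.
#' @param zoom_delta zoom factor drawn uniformly from
#'   `[1 - zoom_delta, 1 + zoom_delta]` (center-anchored, output shape
#'   preserved).
#' @return List of class `augment_config`.
#' @export
augment_config <- function(max_rotation_deg = 5, flip_axes = c(1, 2),
                           flip_prob = 0.5, zoom_delta = 0.05) {
  if (max_rotation_deg < 0 || max_rotation_deg > 45)
    stop("max_rotation_deg must lie in [0, 45]")
  if (zoom_delta < 0 || zoom_delta >= 0.5)
    stop("zoom_delta must lie in [0, 0.5)")
  if (flip_prob < 0 || flip_prob > 1) stop("flip_prob must lie in [0, 1]")
  structure(list(max_rotation_deg = max_rotation_deg, flip_axes = flip_axes,
                 flip_prob = flip_prob, zoom_delta = zoom_delta),
            class = "augment_config")
}

#' Randomly augment a training volume
#'
#' Applies a random rotation about a random axis (uniform within the
#' configured bound), independent Bernoulli flips on the configured axes,
#' and a center-anchored uniform zoom; the output grid shape always equals
#' the input's. Intended for training scans only.
#'
#' @param volume template-space `brain_volume` (or 3D array with an identity
#'   world frame).
#' @param config an [augment_config()].
#' @param seed integer seed.
#' @return Augmented volume of the same type and shape.
#' @export
augment <- function(volume, config = augment_config(), seed = 1) {
  set.seed(substream_seed(seed, "augment"))
  is_bv <- inherits(volume, "brain_volume")
  g <- if (is_bv) volume$grid else volume
  A <- if (is_bv) volume$affine else diag(4)
  d <- dim(g)
  axis <- rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  ang <- runif(1, -config$max_rotation_deg, config$max_rotation_deg) *
    pi / 180
  zoom <- runif(1, 1 - config$zoom_delta, 1 + config$zoom_delta)
  flips <- runif(length(config$flip_axes)) < config$flip_prob
  if (ang != 0 || zoom != 1) {
    K <- rbind(c(0, -axis[3], axis[2]), c(axis[3], 0, -axis[1]),
               c(-axis[2], axis[1], 0))
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    ctr <- drop(A %*% c((d - 1) / 2, 1))[1:3]
    M <- diag(4)
    M[1:3, 1:3] <- R * zoom
    M[1:3, 4] <- ctr - (R * zoom) %*% ctr
    Q <- solve(A) %*% solve(M) %*% A
    g <- array(.resample_affine_cpp(g, d, d, Q, 0), d)
  }
  for (i in seq_along(config$flip_axes))
    if (flips[i]) g <- flip_volume(g, config$flip_axes[i])
  if (is_bv) with_grid(volume, g) else g
}

#' Training configuration
#'
#' @param epochs training epochs.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size (gradient averaged over the batch).
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @param seed integer seed controlling shuffling and dropout.
#' @return List of class `train_config`.
#' @export
train_config <- function(epochs = 5, learning_rate = 1e-4, batch_size = 2,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         seed = 1) {
  structure(as.list(environment()), class = "train_config")
}

sample_label <- function(s) {
  if (inherits(s, "patch_sample")) return(s$label)
  s$label
}
sample_subject <- function(s) {
  if (inherits(s, "patch_sample")) return(s$subject_id)
  s$subject_id %||% NA_character_
}
sample_input <- function(s) {
  if (inherits(s, "patch_sample")) return(s)
  s$x
}

dataset_loss <- function(model, samples) {
  probs <- vapply(samples, function(s)
    model_forward(model, sample_input(s))$prob, numeric(1))
  labels <- vapply(samples, sample_label, numeric(1))
  list(loss = mean(binary_cross_entropy(labels, probs)),
       acc = mean((probs >= 0.5) == labels), probs = probs, labels = labels)
}

#' Train a classifier with Adam on the cross-entropy loss
#'
#' Minimizes the binary cross-entropy with minibatch Adam, records per-epoch
#' training/validation loss and accuracy, and returns the parameters of the
#' epoch with the best validation loss. Fully seeded: identical
#' configuration yields identical history.
#'
#' Samples are `patch_sample`s (region model) or lists with fields `x`
#' (volume array), `label`, `subject_id` (whole-volume model).
#'
#' @param model a `cnn_classifier`.
#' @param train_samples,val_samples sample lists with disjoint subjects.
#' @param config a [train_config()].
#' @return The trained `cnn_classifier` with attribute `history` (data frame
#'   of epoch metrics).
#' @export
train_classifier <- function(model, train_samples, val_samples,
                             config = train_config()) {
  labels <- vapply(train_samples, sample_label, numeric(1))
  if (length(unique(labels)) < 2L)
    stop("training set contains a single class")
  tr_subj <- vapply(train_samples, sample_subject, character(1))
  va_subj <- vapply(val_samples, sample_subject, character(1))
  leak <- intersect(tr_subj, va_subj)
  if (length(leak) > 0)
    stop(sprintf("subject leakage between train and validation: %s",
                 paste(leak, collapse = ", ")))

  p <- model$params
  m1 <- lapply(p, function(x) x * 0)
  m2 <- m1
  tstep <- 0
  drop_rate <- model$spec$dropout
  drop_len <- if (model$type == "whole_volume") model$spec$dense_units else
    model$spec$fusion_units
  history <- data.frame()
  best <- list(loss = Inf, params = p)
  set.seed(substream_seed(config$seed, "train"))
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(length(train_samples))
    for (bstart in seq(1, length(ord), by = config$batch_size)) {
      batch <- ord[bstart:min(bstart + config$batch_size - 1, length(ord))]
      acc_g <- NULL
      for (si in batch) {
        s <- train_samples[[si]]
        dm <- if (drop_rate > 0)
          (runif(drop_len) >= drop_rate) / (1 - drop_rate) else NULL
        fw <- model_forward(list(type = model$type, spec = model$spec,
                                 params = p), sample_input(s), drop_mask = dm)
        dlogit <- (fw$prob - sample_label(s)) / length(batch)
        bw <- model_backward(list(type = model$type, spec = model$spec,
                                  params = p), fw$cache, dlogit)
        acc_g <- if (is.null(acc_g)) bw$grads else
          Map(`+`, acc_g, bw$grads)
      }
      tstep <- tstep + 1
      for (nm in names(p)) {
        m1[[nm]] <- config$beta1 * m1[[nm]] + (1 - config$beta1) * acc_g[[nm]]
        m2[[nm]] <- config$beta2 * m2[[nm]] +
          (1 - config$beta2) * acc_g[[nm]]^2
        mhat <- m1[[nm]] / (1 - config$beta1^tstep)
        vhat <- m2[[nm]] / (1 - config$beta2^tstep)
        p[[nm]] <- p[[nm]] - config$learning_rate * mhat /
          (sqrt(vhat) + config$adam_eps)
      }
    }
    mtmp <- model
    mtmp$params <- p
    tr <- dataset_loss(mtmp, train_samples)
    va <- dataset_loss(mtmp, val_samples)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = tr$loss, train_acc = tr$acc,
      val_loss = va$loss, val_acc = va$acc))
    if (va$loss < best$loss) best <- list(loss = va$loss, params = p)
  }
  out <- model
  out$params <- best$params
  attr(out, "history") <- history
  out
}

confusion_counts <- function(labels, pred) {
  c(TP = sum(pred == 1 & labels == 1), FP = sum(pred == 1 & labels == 0),
    TN = sum(pred == 0 & labels == 0), FN = sum(pred == 0 & labels == 1))
}

#' Precision-recall curve and average precision
#'
#' Sweeps the decision threshold over the observed scores (descending) and
#' computes step-interpolated average precision
#' `AP = sum_i (R_i - R_{i-1}) P_i`.
#'
#' @param labels 0/1 vector.
#' @param scores classifier scores.
#' @return List with `curve` (data frame `recall`, `precision`) and
#'   `average_precision`.
#' @export
pr_curve <- function(labels, scores) {
  ord <- order(-scores)
  lab <- labels[ord]
  tp <- cumsum(lab)
  fp <- cumsum(1 - lab)
  npos <- sum(lab)
  precision <- tp / (tp + fp)
  recall <- if (npos > 0) tp / npos else tp * 0
  ap <- sum(diff(c(0, recall)) * precision)
  list(curve = data.frame(recall = recall, precision = precision),
       average_precision = ap)
}

#' Evaluate a classifier on held-out samples
#'
#' @param model a `cnn_classifier`.
#' @param test_samples sample list (see [train_classifier()]).
#' @param threshold decision threshold on the predicted probability.
#' @return A list of class `eval_metrics`: `accuracy`, `sensitivity`,
#'   `specificity`, `confusion` (TP, FP, TN, FN), `pr_curve`,
#'   `average_precision`, `scores`, `labels`.
#' @export
evaluate_classifier <- function(model, test_samples, threshold = 0.5) {
  if (length(test_samples) == 0) stop("test set is empty")
  scores <- vapply(test_samples, function(s)
    model_forward(model, sample_input(s))$prob, numeric(1))
  labels <- vapply(test_samples, sample_label, numeric(1))
  pred <- as.integer(scores >= threshold)
  cf <- confusion_counts(labels, pred)
  pr <- pr_curve(labels, scores)
  structure(list(
    accuracy = (cf["TP"] + cf["TN"]) / sum(cf),
    sensitivity = if (cf["TP"] + cf["FN"] > 0)
      cf["TP"] / (cf["TP"] + cf["FN"]) else NA_real_,
    specificity = if (cf["TN"] + cf["FP"] > 0)
      cf["TN"] / (cf["TN"] + cf["FP"]) else NA_real_,
    confusion = cf, pr_curve = pr$curve,
    average_precision = pr$average_precision,
    scores = scores, labels = labels
  ), class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(paste0("<eval_metrics> accuracy %.3f  sensitivity %.3f  ",
                     "specificity %.3f  AP %.3f  (TP %d FP %d TN %d FN %d)\n"),
              x$accuracy, x$sensitivity, x$specificity, x$average_precision,
              x$confusion["TP"], x$confusion["FP"], x$confusion["TN"],
              x$confusion["FN"]))
  invisible(x)
}

#' Default end-to-end experiment configuration
#'
#' Desk-scale study conditions: 20 subjects per group on a 4.5 mm,
#' (39, 47, 39) template grid (same field of view as the full-resolution
#' template — the coarsest grid on which three valid-conv/pool blocks retain
#' usable spatial structure), strong planted atrophy, reduced-width
#' networks, no dropout (at these widths and sample sizes dropout noise
#' swamps the class signal), and enough epochs for the small Adam runs to
#' reach their loss plateau. All sizes are overridable.
#'
#' @param ... overrides of the default fields.
#' @return Named list of experiment settings.
#' @export
experiment_config <- function(...) {
  cfg <- list(
    n_per_group = 20, grid_shape = c(39, 47, 39), voxel_size_mm = 4.5,
    effect_fraction = 0.5, radius_mm = 8, fwhm_mm = 8, poly_order = 3,
    alpha = 0.05, n_perm = 200, min_separation_mm = 8, max_patches = 22,
    patch_side = 15, qc_threshold = 0.8,
    whole_filters = c(4, 8, 16), whole_dense = 32,
    region_filters = c(8, 16), region_dense = 32, region_fusion = 32,
    dropout = 0, epochs = 15, learning_rate = 1e-3, batch_size = 2,
    seed = 1, out_dir = NULL
  )
  utils::modifyList(cfg, list(...))
}

#' Run the full end-to-end experiment
#'
#' Simulate a cohort -> preprocess every scan -> QC -> group-level analysis
#' on training subjects only (so peak coordinates never see validation/test
#' data) -> patch extraction -> train and evaluate both classifiers.
#' Deterministic given the config seed.
#'
#' @param config an [experiment_config()].
#' @return A list of class `experiment_report` with metrics for both models,
#'   the peak table, the QC report, split assignment, training histories,
#'   and the config. When `config$out_dir` is set, a JSON + Markdown report,
#'   the peak TSV, and PR/saliency figures are also written there.
#' @export
run_experiment <- function(config = experiment_config()) {
  seed <- config$seed
  tmpl <- make_template(config$grid_shape, config$voxel_size_mm)
  spec <- atrophy_spec(effect_fraction = config$effect_fraction,
                       radius_mm = config$radius_mm)
  cohort <- generate_cohort(config$n_per_group, seed = seed)

  # simulate + preprocess every scan
  scans <- vector("list", nrow(cohort$scans))
  names(scans) <- cohort$scans$scan_id
  for (i in seq_len(nrow(cohort$scans))) {
    subj <- cohort$subjects[cohort$subjects$subject_id ==
                              cohort$scans$subject_id[i], ]
    raw <- synthesize_scan(subj, tmpl, spec, noise_config(), seed,
                           scan_id = cohort$scans$scan_id[i])
    pp <- preprocess_scan(raw, tmpl, fwhm_mm = config$fwhm_mm,
                          poly_order = config$poly_order)
    scans[[i]] <- pp$gm_smooth
  }
  qc <- qc_correlation(scans, brain_mask(tmpl),
                       threshold = config$qc_threshold)

  split <- split_subjects(cohort, seed = seed)
  stopifnot(!any(duplicated(split$subject_id)))

  # group-level analysis on training subjects only
  train_ids <- split$subject_id[split$subset == "train"]
  train_subj <- cohort$subjects[cohort$subjects$subject_id %in% train_ids, ]
  design <- build_design_matrix(train_subj)
  by_subject <- lapply(train_subj$subject_id, function(sid)
    scans[cohort$scans$scan_id[cohort$scans$subject_id == sid]])
  mask <- tmpl$gm_prior$grid > 0.2
  vbm <- run_vbm(by_subject, design, mask = mask, alpha = config$alpha,
                 n_perm = config$n_perm, seed = seed,
                 min_separation_mm = config$min_separation_mm)
  peaks <- head(vbm$peaks, config$max_patches)
  if (nrow(peaks) == 0)
    stop("group-level analysis found no significant peaks; ",
         "cannot build the region-guided model")

  # assemble datasets
  scaled <- lapply(scans, scale_intensity)
  scan_subj <- cohort$scans$subject_id
  scan_group <- cohort$subjects$group[match(scan_subj,
                                            cohort$subjects$subject_id)]
  labels <- as.integer(scan_group == "progressive")
  patch_ds <- assemble_patch_dataset(scaled, peaks, labels,
                                     side = config$patch_side)
  whole_ds <- lapply(seq_along(scaled), function(i)
    list(x = array(scaled[[i]]$grid, c(dim(scaled[[i]]$grid), 1L)),
         label = labels[i], subject_id = scan_subj[i]))
  subset_of <- split$subset[match(scan_subj, split$subject_id)]
  pick <- function(ds, set) ds[subset_of == set]

  tc <- train_config(epochs = config$epochs,
                     learning_rate = config$learning_rate,
                     batch_size = config$batch_size, seed = seed)
  whole <- build_whole_volume_model(
    whole_volume_spec(input_shape = config$grid_shape,
                      filters = config$whole_filters,
                      dense_units = config$whole_dense,
                      dropout = config$dropout), seed = seed)
  whole <- train_classifier(whole, pick(whole_ds, "train"),
                            pick(whole_ds, "val"), tc)
  region <- build_region_model(
    K = nrow(peaks),
    spec = region_spec(n_patches = nrow(peaks),
                       patch_side = config$patch_side,
                       filters = config$region_filters,
                       dense_units = config$region_dense,
                       fusion_units = config$region_fusion,
                       dropout = config$dropout), seed = seed)
  region <- train_classifier(region, pick(patch_ds, "train"),
                             pick(patch_ds, "val"), tc)

  metrics <- list(whole_volume = evaluate_classifier(whole,
                                                     pick(whole_ds, "test")),
                  region = evaluate_classifier(region,
                                               pick(patch_ds, "test")))
  sal <- saliency_map(whole, pick(whole_ds, "test")[[1]]$x)
  report <- structure(list(
    saliency = brain_volume(array(sal, dim(sal)[1:3]),
                            tmpl$template$affine, space = "template"),
    metrics = metrics, peaks = peaks, threshold = as.numeric(vbm$threshold),
    qc = qc, split = split,
    history = list(whole_volume = attr(whole, "history"),
                   region = attr(region, "history")),
    models = list(whole_volume = whole, region = region),
    config = config
  ), class = "experiment_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf(paste0("<experiment_report> %d peaks (Z threshold %.2f), min ",
                     "QC r %.3f\n"),
              nrow(x$peaks), x$threshold,
              min(x$qc$correlation_matrix[upper.tri(x$qc$correlation_matrix)])))
  cat("  whole-volume: "); print(x$metrics$whole_volume)
  cat("  region-guided:"); print(x$metrics$region)
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_peak_table(report$peaks, file.path(out_dir, "peaks.tsv"))
  met <- lapply(report$metrics, function(m)
    list(accuracy = unname(m$accuracy), sensitivity = unname(m$sensitivity),
         specificity = unname(m$specificity),
         average_precision = m$average_precision,
         confusion = as.list(m$confusion)))
  jsonlite::write_json(list(metrics = met,
                            z_threshold = report$threshold,
                            qc_min_r = min(report$qc$correlation_matrix[
                              upper.tri(report$qc$correlation_matrix)])),
                       file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(report$metrics)) {
    grDevices::png(file.path(out_dir, paste0("pr_", nm, ".png")), 480, 480)
    m <- report$metrics[[nm]]
    plot(m$pr_curve$recall, m$pr_curve$precision, type = "s",
         xlim = c(0, 1), ylim = c(0, 1), xlab = "Recall",
         ylab = "Precision",
         main = sprintf("%s (AP = %.3f)", nm, m$average_precision))
    grDevices::dev.off()
  }
  write_volume(report$saliency, file.path(out_dir, "saliency.nii.gz"))
  write_triplanar(report$saliency, file.path(out_dir, "saliency.png"))
  md <- c("# Experiment report", "",
          sprintf("- Peaks above FWE threshold (Z >= %.2f): %d",
                  report$threshold, nrow(report$peaks)),
          sprintf("- Peak table: %s", file.path(out_dir, "peaks.tsv")),
          "", "## Metrics", "",
          vapply(names(report$metrics), function(nm) {
            m <- report$metrics[[nm]]
            sprintf("- %s: accuracy %.3f, sensitivity %.3f, specificity %.3f, AP %.3f",
                    nm, m$accuracy, m$sensitivity, m$specificity,
                    m$average_precision)
          }, character(1)))
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
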