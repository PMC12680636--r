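# MNI coordinate <-> voxel conversion and fixed-size cubic patch extraction
# around group-analysis peaks, assembling per-scan samples for the
# region-guided classifier.

#' Convert an MNI mm coordinate to a voxel index
#'
#' `v = round(A^-1 [x, y, z, 1])` with round-half-away-from-zero; voxel
#' indices are 0-based (NIfTI convention).
#'
#' @param coord_mm numeric length-3 world coordinate.
#' @param affine 4x4 voxel-to-world matrix.
#' @param dims optional grid dimensions; when given, out-of-bounds results
#'   raise an error naming the coordinate.
#' @return Integer length-3 0-based voxel index.
#' @export
mni_to_voxel <- function(coord_mm, affine, dims = NULL) {
  v <- solve(affine, c(coord_mm, 1))[1:3]
  v <- as.integer(sign(v) * floor(abs(v) + 0.5))
  if (!is.null(dims) && (any(v < 0) || any(v > dims - 1L)))
    stop(sprintf("MNI coordinate (%s) maps outside the grid: voxel (%s)",
                 paste(coord_mm, collapse = ", "),
                 paste(v, collapse = ", ")))
  v
}

#' Convert a voxel index to MNI millimeters
#'
#' @param voxel numeric length-3 0-based voxel index.
#' @param affine 4x4 voxel-to-world matrix.
#' @return Numeric length-3 world coordinate.
#' @export
voxel_to_mni <- function(voxel, affine) {
  drop(affine %*% c(voxel, 1))[1:3]
}

#' Extract a cubic patch centered on a voxel
#'
#' Returns a cube of odd side length centered at `center_voxel`; parts that
#' fall outside the volume are filled with `pad_value`, so the output shape
#' is always `side^3`.
#'
#' @param volume a `brain_volume` or 3D array.
#' @param center_voxel 0-based voxel index triple (must be in bounds).
#' @param side odd patch side length (default 15).
#' @param pad_value fill value outside the volume.
#' @return `side x side x side` numeric array.
#' @export
extract_patch <- function(volume, center_voxel, side = 15, pad_value = 0) {
  g <- if (inherits(volume, "brain_volume")) volume$grid else volume
  if (side %% 2 == 0) stop("side must be odd")
  d <- dim(g)
  center_voxel <- as.integer(center_voxel)
  if (any(center_voxel < 0) || any(center_voxel > d - 1L))
    stop(sprintf("center voxel (%s) out of bounds",
                 paste(center_voxel, collapse = ", ")))
  h <- (side - 1L) %/% 2L
  patch <- array(pad_value, c(side, side, side))
  lo <- pmax(center_voxel - h, 0L)            # 0-based source window
  hi <- pmin(center_voxel + h, d - 1L)
  plo <- lo - (center_voxel - h)              # 0-based destination offset
  patch[(plo[1] + 1L):(plo[1] + hi[1] - lo[1] + 1L),
        (plo[2] + 1L):(plo[2] + hi[2] - lo[2] + 1L),
        (plo[3] + 1L):(plo[3] + hi[3] - lo[3] + 1L)] <-
    g[(lo[1] + 1L):(hi[1] + 1L), (lo[2] + 1L):(hi[2] + 1L),
      (lo[3] + 1L):(hi[3] + 1L)]
  patch
}

#' Assemble per-scan patch samples from a peak table
#'
#' For every scan, extracts one cubic patch per peak-table row (in table
#' order, i.e. descending Z) and pairs the patches with the table's K
#' Z-scores and the scan's binary label.
#'
#' @param scans list of template-space, intensity-scaled `brain_volume`s.
#' @param peak_table a non-empty `peak_table` (or data frame with `z_score`,
#'   `x_mm`, `y_mm`, `z_mm`).
#' @param labels integer vector (0 = stable, 1 = progressive) aligned with
#'   `scans`.
#' @param side odd patch side length.
#' @return List of `patch_sample` objects: `subject_id`, `scan_id`,
#'   `patches` (`side^3 x K` 4D array), `z_scores` (length K), `label`.
#' @export
assemble_patch_dataset <- function(scans, peak_table, labels, side = 15) {
  if (nrow(peak_table) == 0) stop("peak table is empty")
  if (length(labels) != length(scans))
    stop("labels must align with scans")
  aff <- scans[[1]]$affine
  dims <- dim(scans[[1]]$grid)
  centers <- lapply(seq_len(nrow(peak_table)), function(i)
    mni_to_voxel(c(peak_table$x_mm[i], peak_table$y_mm[i],
                   peak_table$z_mm[i]), aff, dims))
  K <- length(centers)
  lapply(seq_along(scans), function(s) {
    v <- scans[[s]]
    patches <- array(0, c(side, side, side, K))
    for (k in seq_len(K))
      patches[, , , k] <- extract_patch(v, centers[[k]], side = side)
    structure(list(subject_id = v$subject_id, scan_id = v$scan_id,
                   patches = patches, z_scores = peak_table$z_score,
                   label = as.integer(labels[s])),
              class = "patch_sample")
  })
}
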