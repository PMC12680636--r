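#' 3D brain volume container
#'
#' A `brain_volume` couples a 3D scalar grid with the 4x4 affine mapping
#' 0-based voxel indices to world (MNI-style) millimeter coordinates, plus
#' subject/scan identity and bookkeeping tags. All public voxel coordinates in
#' this package are 0-based, matching the NIfTI convention; conversion to R's
#' 1-based array subscripts happens only at indexing time.
#'
#' @param grid numeric 3D array (intensities or tissue probability).
#' @param affine 4x4 numeric matrix, `world = affine %*% c(i, j, k, 1)` with
#'   0-based `i, j, k`.
#' @param subject_id,scan_id identifier strings.
#' @param space `"native"` or `"template"`.
#' @param kind one of `"raw"`, `"gm_prob"`, `"wm_prob"`, `"csf_prob"`,
#'   `"smoothed"`.
#' @return An object of class `brain_volume`.
#' @export
brain_volume <- function(grid, affine, subject_id = "", scan_id = "",
                         space = c("native", "template"),
                         kind = c("raw", "gm_prob", "wm_prob", "csf_prob",
                                  "smoothed")) {
  space <- match.arg(space)
  kind <- match.arg(kind)
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("grid must be a 3D array")
  if (!all(is.finite(grid))) stop("grid must be finite everywhere")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix")
  if (kind %in% c("gm_prob", "wm_prob", "csf_prob") &&
      (min(grid) < -1e-9 || max(grid) > 1 + 1e-9))
    stop("probability volumes must lie in [0, 1]")
  structure(
    list(grid = grid, affine = affine, subject_id = subject_id,
         scan_id = scan_id, space = space, kind = kind),
    class = "brain_volume"
  )
}

#' @export
print.brain_volume <- function(x, ...) {
  cat(sprintf("<brain_volume> %s/%s  %s %s  grid %s  voxel %s mm\n",
              x$subject_id, x$scan_id, x$space, x$kind,
              paste(dim(x$grid), collapse = "x"),
              paste(signif(voxel_size(x), 4), collapse = "x")))
  invisible(x)
}

#' @export
dim.brain_volume <- function(x) dim(x$grid)

#' Voxel edge lengths in millimeters
#' @param volume a `brain_volume` (or a 4x4 affine matrix).
#' @return numeric length-3 vector of voxel sizes.
#' @export
voxel_size <- function(volume) {
  A <- if (inherits(volume, "brain_volume")) volume$affine else volume
  sqrt(colSums(A[1:3, 1:3]^2))
}

#' Write a brain volume to a NIfTI-1 file
#'
#' The affine is stored in both qform and sform; grids are written as
#' double precision so write/read round-trips are exact.
#'
#' @param volume a `brain_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  g <- volume$grid
  attr(g, "pixdim") <- voxel_size(volume)
  img <- RNifti::asNifti(g, datatype = "double")
  xf <- structure(volume$affine, code = 2L)
  RNifti::`qform<-`(img, xf) -> img
  RNifti::`sform<-`(img, xf) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 file as a brain volume
#'
#' @param path NIfTI file path.
#' @inheritParams brain_volume
#' @return A `brain_volume`.
#' @export
read_volume <- function(path, subject_id = "", scan_id = "",
                        space = "native", kind = "raw") {
  img <- RNifti::readNifti(path)
  g <- as.array(img)
  if (length(dim(g)) > 3L) g <- array(g, dim(g)[1:3])
  brain_volume(g, structure(RNifti::xform(img), dimnames = NULL),
               subject_id = subject_id, scan_id = scan_id,
               space = space, kind = kind)
}

# Replace the grid, keeping geometry/identity; optionally retag the kind.
with_grid <- function(volume, grid, kind = volume$kind) {
  v <- volume
  v$grid <- grid
  v$kind <- kind
  v
}

stopifnot_same_grid <- function(volumes) {
  d <- dim(volumes[[1]]$grid)
  ok <- vapply(volumes, function(v) identical(dim(v$grid), d), logical(1))
  if (!all(ok)) stop("volumes do not share a common grid")
  invisible(d)
}
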