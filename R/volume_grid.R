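#' Construct a volume grid
#'
#' A `volume_grid` is the package's container for a 3D label lattice with
#' physical metadata: per-axis voxel spacing in millimetres and a 4x4 affine
#' mapping 0-based voxel indices (voxel-centre convention) to world
#' millimetre coordinates.
#'
#' @param data 3D array of label values. Binarised masks hold 0/1.
#' @param spacing Numeric length-3, strictly positive voxel edge lengths (mm).
#' @param transform 4x4 affine, voxel index -> world mm. Defaults to an
#'   axis-aligned scaling by `spacing` with origin at 0.
#' @param label Semantic name of the foreground label, e.g. `"tumor"`.
#' @return An object of class `volume_grid`.
#' @export
#' @examples
#' g <- volume_grid(array(1L, c(4, 4, 4)), spacing = c(1, 1, 1))
#' mask_volume(g)  # 64 mm^3
volume_grid <- function(data, spacing, transform = NULL, label = "mask") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    ts_validation_error("'data' must be a 3D array")
  }
  if (any(dim(data) < 1L)) {
    ts_validation_error("'data' must have extent >= 1 on every axis")
  }
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    ts_validation_error(sprintf(
      "'spacing' must be three strictly positive values, got (%s)",
      paste(signif(spacing, 6), collapse = ", ")))
  }
  if (is.null(transform)) {
    transform <- diag(4)
    transform[1:3, 1:3] <- diag(spacing)
  }
  transform <- as.matrix(transform)
  if (!all(dim(transform) == c(4L, 4L)) || any(!is.finite(transform))) {
    ts_validation_error("'transform' must be a finite 4x4 matrix")
  }
  if (abs(det(transform[1:3, 1:3])) < 1e-12) {
    ts_validation_error("'transform' has a degenerate (non-invertible) linear part")
  }
  structure(
    list(data = data, spacing = spacing, transform = transform, label = label),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid '%s'> %s voxels, spacing (%s) mm, %d foreground\n",
              x$label, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = ", "),
              sum(x$data != 0)))
  invisible(x)
}

is_binary_grid <- function(grid) {
  all(grid$data %in% c(0, 1))
}

#' Read a segmentation mask from a NIfTI file
#'
#' Reads a NIfTI-1 or NIfTI-2 volume (optionally gzipped), binarises it by a
#' nonzero test, and carries spacing and affine from the header. The affine
#' preference order is sform, then qform, then plain pixdim scaling.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param label Semantic label name attached to the grid.
#' @return A binary [volume_grid()].
#' @export
read_mask <- function(path, label = "mask") {
  raw <- read_nifti(path)
  data <- array(as.integer(raw$data != 0), dim = dim(raw$data))
  volume_grid(data, raw$spacing, raw$transform, label = label)
}

#' Write a segmentation mask to a NIfTI-1 file
#'
#' The lattice, spacing (pixdim) and affine (sform) survive a
#' write/[read_mask()] round trip bit-identically. Output is gzipped when
#' `path` ends in `.gz`.
#'
#' @param grid A [volume_grid()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_mask <- function(grid, path) {
  stopifnot(inherits(grid, "volume_grid"))
  write_nifti(grid$data, grid$spacing, grid$transform, path)
  invisible(path)
}

#' Validate a tumor/brain mask pair
#'
#' Checks that both binary grids live on the identical lattice (dimensions,
#' spacing, affine) and that the tumor is contained in the dura-enclosed
#' brain region. Containment violations are an error reporting the voxel
#' count, never silently clipped.
#'
#' @param tumor,brain Binary [volume_grid()]s.
#' @param provenance Optional free-text source identifier.
#' @return An object of class `segmentation_pair` with elements
#'   `tumor`, `brain`, `provenance`.
#' @export
validate_pair <- function(tumor, brain, provenance = "") {
  stopifnot(inherits(tumor, "volume_grid"), inherits(brain, "volume_grid"))
  if (!is_binary_grid(tumor) || !is_binary_grid(brain)) {
    ts_validation_error("both grids must be binary (values 0/1)")
  }
  if (!identical(dim(tumor$data), dim(brain$data))) {
    ts_validation_error(sprintf(
      "geometry mismatch: dimensions differ (%s vs %s)",
      paste(dim(tumor$data), collapse = "x"),
      paste(dim(brain$data), collapse = "x")))
  }
  if (!isTRUE(all.equal(tumor$spacing, brain$spacing, tolerance = 1e-9))) {
    ts_validation_error(sprintf(
      "geometry mismatch: spacing differs ((%s) vs (%s)) mm",
      paste(signif(tumor$spacing, 6), collapse = ", "),
      paste(signif(brain$spacing, 6), collapse = ", ")))
  }
  if (!isTRUE(all.equal(tumor$transform, brain$transform, tolerance = 1e-9))) {
    ts_validation_error("geometry mismatch: affine transforms differ")
  }
  outside <- sum(tumor$data != 0 & brain$data == 0)
  if (outside > 0) {
    ts_validation_error(sprintf(
      "containment violation: %d tumor voxel%s outside the brain mask",
      outside, if (outside == 1) "" else "s"), count = outside)
  }
  structure(list(tumor = tumor, brain = brain, provenance = provenance),
            class = "segmentation_pair")
}

#' @export
print.segmentation_pair <- function(x, ...) {
  cat(sprintf("<segmentation_pair> %s voxels, %d tumor / %d brain foreground\n",
              paste(dim(x$tumor$data), collapse = "x"),
              sum(x$tumor$data != 0), sum(x$brain$data != 0)))
  invisible(x)
}

#' Resample a binary grid onto an isotropic lattice
#'
#' Nearest-neighbour resampling onto an axis-aligned isotropic lattice
#' covering the same world extent (bounding box of voxel volumes). Labels
#' stay binary; any interpolating scheme would invent partial labels.
#'
#' @param grid A binary [volume_grid()].
#' @param target_spacing Isotropic voxel edge length in mm, > 0.
#' @return A binary [volume_grid()] with spacing
#'   `c(target_spacing, target_spacing, target_spacing)`.
#' @export
resample_isotropic <- function(grid, target_spacing) {
  stopifnot(inherits(grid, "volume_grid"))
  target_spacing <- as.double(target_spacing)
  if (length(target_spacing) != 1L || !is.finite(target_spacing) ||
      target_spacing <= 0) {
    ts_validation_error("'target_spacing' must be a single positive value (mm)")
  }
  dims <- dim(grid$data)
  # world-space corners of the voxel *volume* (centres +- half spacing)
  idx_corners <- as.matrix(expand.grid(c(-0.5, dims[1] - 0.5),
                                       c(-0.5, dims[2] - 0.5),
                                       c(-0.5, dims[3] - 0.5)))
  world <- grid$transform %*% rbind(t(idx_corners), 1)
  lo <- apply(world[1:3, , drop = FALSE], 1, min)
  hi <- apply(world[1:3, , drop = FALSE], 1, max)
  new_dims <- pmax(1L, as.integer(ceiling((hi - lo) / target_spacing - 1e-9)))
  new_tf <- diag(4)
  new_tf[1:3, 1:3] <- diag(rep(target_spacing, 3))
  new_tf[1:3, 4] <- lo + target_spacing / 2

  # map new voxel centres through the inverse source affine, round to nearest
  inv <- solve(grid$transform)
  ax <- lapply(1:3, function(a) lo[a] + (seq_len(new_dims[a]) - 0.5) * target_spacing)
  # build index arrays axis by axis to avoid a dense expand.grid of coords
  M <- inv %*% new_tf  # new index -> old index, both homogeneous
  i_new <- seq_len(new_dims[1]) - 1
  j_new <- seq_len(new_dims[2]) - 1
  k_new <- seq_len(new_dims[3]) - 1
  # old index coordinate = M[ ,1]*i + M[,2]*j + M[,3]*k + M[,4]
  old_i <- outer(outer(M[1, 1] * i_new, M[1, 2] * j_new, "+"),
                 M[1, 3] * k_new, "+") + M[1, 4]
  old_j <- outer(outer(M[2, 1] * i_new, M[2, 2] * j_new, "+"),
                 M[2, 3] * k_new, "+") + M[2, 4]
  old_k <- outer(outer(M[3, 1] * i_new, M[3, 2] * j_new, "+"),
                 M[3, 3] * k_new, "+") + M[3, 4]
  ii <- as.integer(round(old_i)) + 1L
  jj <- as.integer(round(old_j)) + 1L
  kk <- as.integer(round(old_k)) + 1L
  ok <- ii >= 1L & ii <= dims[1] & jj >= 1L & jj <= dims[2] &
    kk >= 1L & kk <= dims[3]
  out <- array(0L, dim = new_dims)
  lin <- (kk[ok] - 1L) * (dims[1] * dims[2]) + (jj[ok] - 1L) * dims[1] + ii[ok]
  out[ok] <- as.integer(grid$data[lin] != 0)
  volume_grid(out, rep(target_spacing, 3), new_tf, label = grid$label)
}
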