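# Geometric scores: volume, total surface area A, dural-contact area B,
# contact surface area CSA = A - B, sphericity index SI, and the extent of
# resection (EOR) outcome. Internal units are mm/mm^2/mm^3; reports convert
# to cm^2/cm^3 (divide by 100 / 1000).

#' Foreground volume of a binary mask
#'
#' Foreground voxel count times the voxel volume (product of the spacing
#' components). An empty mask has volume 0.
#'
#' @param grid A binary [volume_grid()].
#' @return Volume in mm^3.
#' @export
mask_volume <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  sum(grid$data != 0) * prod(grid$spacing)
}

#' Surface area of the sphere with a given volume
#'
#' `(36*pi)^(1/3) * volume^(2/3)`, the denominator of the sphericity index.
#'
#' @param volume Volume, >= 0 (any consistent cubed unit).
#' @return Area in the matching squared unit.
#' @export
equal_volume_sphere_area <- function(volume) {
  if (any(volume < 0)) ts_validation_error("'volume' must be >= 0")
  (36 * pi)^(1 / 3) * volume^(2 / 3)
}

#' Sphericity index
#'
#' Ratio of a body's surface area to the surface area of the sphere with the
#' same volume. Exactly 1 for a sphere; larger for every other shape
#' (isoperimetric inequality), so a higher SI means a less spherical tumor.
#'
#' @param total_area Surface area, > 0.
#' @param volume Volume, > 0 (units consistent with `total_area`).
#' @return Dimensionless SI.
#' @export
sphericity_index <- function(total_area, volume) {
  if (any(volume <= 0)) ts_validation_error("'volume' must be > 0")
  if (any(total_area <= 0)) ts_validation_error("'total_area' must be > 0")
  total_area / equal_volume_sphere_area(volume)
}

#' Dural contact area of a tumor (the "B" patch)
#'
#' Extracts the tumor and brain boundary meshes and sums the area of tumor
#' triangles whose centroid lies within `tolerance` (point-to-mesh distance)
#' of the brain-mask boundary. By contract B = 0 when the tumor is
#' everywhere at least `tolerance` interior to the brain mask.
#'
#' The distance rule is this package's reproducible surrogate for the
#' manually traced dura patch; the tolerance (default half the largest voxel
#' spacing) is an explicit parameter.
#'
#' @param pair A `segmentation_pair` from [validate_pair()].
#' @param tolerance Contact distance in mm; default `max(spacing)/2`.
#' @param smooth_sigma Passed to [extract_surface()].
#' @return Contact area in mm^2.
#' @export
dural_contact_area <- function(pair, tolerance = NULL, smooth_sigma = NULL) {
  if (!inherits(pair, "segmentation_pair")) {
    ts_validation_error("'pair' must be a segmentation_pair from validate_pair()")
  }
  parts <- contact_decomposition(pair, tolerance, smooth_sigma)
  parts$dural_area
}

# Shared workhorse: tumor mesh, per-triangle contact flags, areas.
contact_decomposition <- function(pair, tolerance = NULL, smooth_sigma = NULL) {
  if (is.null(tolerance)) tolerance <- max(pair$tumor$spacing) / 2
  if (!is.finite(tolerance) || tolerance <= 0) {
    ts_validation_error("'tolerance' must be > 0 (mm)")
  }
  tumor_mesh <- extract_surface(pair$tumor, smooth_sigma = smooth_sigma)
  brain_mesh <- extract_surface(pair$brain, smooth_sigma = smooth_sigma)
  areas <- mesh_triangle_areas(tumor_mesh)
  f <- tumor_mesh$triangles
  centroids <- (tumor_mesh$vertices[f[, 1], , drop = FALSE] +
                  tumor_mesh$vertices[f[, 2], , drop = FALSE] +
                  tumor_mesh$vertices[f[, 3], , drop = FALSE]) / 3
  contact <- points_near_mesh(centroids, brain_mesh$vertices,
                              brain_mesh$triangles, tolerance)
  list(tumor_mesh = tumor_mesh, contact = contact, areas = areas,
       total_area = sum(areas), dural_area = sum(areas[contact]),
       tolerance = tolerance)
}

#' Compute the full per-tumor shape report
#'
#' Assembles volume, total surface area A, dural contact area B,
#' CSA = A - B, the equal-volume sphere area, and SI for a validated
#' tumor/brain pair. Areas are reported in cm^2 and the volume in cm^3.
#'
#' @param pair A `segmentation_pair` from [validate_pair()].
#' @param tolerance Dural-contact distance in mm (default `max(spacing)/2`).
#' @param smooth_sigma Passed to [extract_surface()].
#' @param id Optional identifier carried into the report.
#' @return An object of class `shape_report`: list with `volume_cm3`,
#'   `total_area_cm2`, `dural_area_cm2`, `csa_cm2`, `sphere_area_cm2`,
#'   `sphericity_index`, `tolerance_mm`, `id`.
#' @export
compute_shape_report <- function(pair, tolerance = NULL, smooth_sigma = NULL,
                                 id = NA_character_) {
  if (!inherits(pair, "segmentation_pair")) {
    ts_validation_error("'pair' must be a segmentation_pair from validate_pair()")
  }
  vol_mm3 <- mask_volume(pair$tumor)
  if (vol_mm3 <= 0) ts_validation_error("tumor mask is empty")
  parts <- contact_decomposition(pair, tolerance, smooth_sigma)
  A <- parts$total_area
  B <- parts$dural_area
  si <- sphericity_index(A, vol_mm3)
  total_cm2 <- A / 100
  dural_cm2 <- B / 100
  report <- list(
    id = id,
    volume_cm3 = vol_mm3 / 1000,
    total_area_cm2 = total_cm2,
    dural_area_cm2 = dural_cm2,
    # defined by subtraction on the reporting scale so the additivity
    # invariant CSA = A - B is bitwise exact
    csa_cm2 = total_cm2 - dural_cm2,
    sphere_area_cm2 = equal_volume_sphere_area(vol_mm3) / 100,
    sphericity_index = si,
    tolerance_mm = parts$tolerance
  )
  class(report) <- "shape_report"
  report
}

#' @export
print.shape_report <- function(x, ...) {
  cat(sprintf(
    paste0("<shape_report%s>\n  volume  %8.2f cm^3\n  A       %8.2f cm^2\n",
           "  B       %8.2f cm^2\n  CSA     %8.2f cm^2\n  SI      %8.4f\n"),
    if (is.na(x$id)) "" else paste0(" ", x$id),
    x$volume_cm3, x$total_area_cm2, x$dural_area_cm2, x$csa_cm2,
    x$sphericity_index))
  invisible(x)
}

#' Shape report as a one-row data frame
#' @param report A `shape_report`.
#' @return data.frame with columns id, volume_cm3, total_area_cm2,
#'   dural_area_cm2, csa_cm2, si.
#' @export
shape_report_row <- function(report) {
  data.frame(id = report$id, volume_cm3 = report$volume_cm3,
             total_area_cm2 = report$total_area_cm2,
             dural_area_cm2 = report$dural_area_cm2,
             csa_cm2 = report$csa_cm2, si = report$sphericity_index,
             stringsAsFactors = FALSE)
}

#' Extent of resection from pre/post volumes
#'
#' The fractional decrease in measurable tumor volume,
#' `1 - post/pre`, clamped into `[0, 1]` (tumor growth between the scans is
#' out of scope).
#'
#' @param pre_volume Preoperative volume, > 0 (cm^3).
#' @param post_volume Postoperative residual volume, >= 0 (cm^3).
#' @return EOR fraction in `[0, 1]`.
#' @export
compute_eor <- function(pre_volume, post_volume) {
  if (any(!is.finite(pre_volume)) || any(pre_volume <= 0)) {
    ts_validation_error("'pre_volume' must be > 0")
  }
  if (any(!is.finite(post_volume)) || any(post_volume < 0)) {
    ts_validation_error("'post_volume' must be >= 0")
  }
  pmin(pmax(1 - post_volume / pre_volume, 0), 1)
}

#' Group EOR values into GTR and three STR tertiles
#'
#' Records with EOR exactly 1 (no measurable residual) are gross total
#' resections; the remaining records are split into three tertile groups by
#' rank on EOR, with boundaries at ranks `ceiling(n/3)` and `ceiling(2n/3)`
#' and ties broken by stable input order.
#'
#' @param eors Numeric vector of EOR fractions in `[0, 1]`.
#' @return Factor with levels `STR-lower`, `STR-middle`, `STR-upper`, `GTR`
#'   in increasing EOR order, one per input record.
#' @export
group_eor <- function(eors) {
  if (length(eors) == 0L) ts_validation_error("'eors' must be nonempty")
  if (any(!is.finite(eors)) || any(eors < 0 | eors > 1)) {
    ts_validation_error("EOR values must lie in [0, 1]")
  }
  levels <- c("STR-lower", "STR-middle", "STR-upper", "GTR")
  out <- character(length(eors))
  gtr <- eors == 1
  out[gtr] <- "GTR"
  str_idx <- which(!gtr)
  n <- length(str_idx)
  if (n > 0) {
    r <- rank(eors[str_idx], ties.method = "first")
    b1 <- ceiling(n / 3)
    b2 <- ceiling(2 * n / 3)
    grp <- ifelse(r <= b1, "STR-lower", ifelse(r <= b2, "STR-middle", "STR-upper"))
    out[str_idx] <- grp
  }
  factor(out, levels = levels)
}
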