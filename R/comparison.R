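# Agreement between two tumor outlines: Boolean intersection, percentile
# Hausdorff distances on voxel boundary-face surfaces, and the paired
# under/overestimation statistics.

#' Boolean intersection of two masks
#' @param mask_a,mask_b Logical 3D arrays on the same grid.
#' @return Logical 3D array, the voxelwise AND.
#' @export
boolean_intersection <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) {
    sm_error("masks are on different grids", "specimargin_error_grid_mismatch")
  }
  mask_a & mask_b
}

#' Boundary surface of a mask as a point set
#'
#' Centers of the exposed voxel faces (faces between an inside voxel and an
#' outside 6-neighbor), in world mm. This is the surface representation used
#' for percentile Hausdorff distances.
#'
#' @param mask Logical 3D array.
#' @param spacing,origin Grid geometry.
#' @return n x 3 numeric matrix.
#' @export
mask_surface_points <- function(mask, spacing, origin) {
  if (!any(mask)) {
    sm_error("mask is empty", "specimargin_error_empty_mask")
  }
  boundary_face_centers(mask, spacing, origin)
}

#' Percentile Hausdorff distance between two point sets
#'
#' The symmetric form: the maximum of the two directed p-th percentile
#' distances, where a directed distance is the p-th percentile, over points
#' of one set, of the nearest distance to the other set. `p = 100` gives the
#' classical Hausdorff distance.
#'
#' @param surf_a,surf_b n x 3 matrices of surface points (nonempty).
#' @param p Percentile in (0, 100].
#' @return Distance in the point units (mm); attribute `directed` holds the
#'   two directed values.
#' @export
percentile_hausdorff <- function(surf_a, surf_b, p = 95) {
  surf_a <- matrix(as.numeric(surf_a), ncol = 3)
  surf_b <- matrix(as.numeric(surf_b), ncol = 3)
  if (!nrow(surf_a) || !nrow(surf_b)) {
    sm_error("point sets must be nonempty", "specimargin_error_empty_mask")
  }
  if (p <= 0 || p > 100) {
    sm_error("percentile must be in (0, 100]", "specimargin_error_bad_percentile")
  }
  dab <- RANN::nn2(data = surf_b, query = surf_a, k = 1L)$nn.dists[, 1]
  dba <- RANN::nn2(data = surf_a, query = surf_b, k = 1L)$nn.dists[, 1]
  dir <- c(as.numeric(quantile(dab, p / 100, names = FALSE)),
           as.numeric(quantile(dba, p / 100, names = FALSE)))
  structure(max(dir), directed = dir)
}

#' Under- and overestimation percentile Hausdorff distances
#'
#' Quantifies how a test observer's tumor outline deviates from a reference
#' outline via the Boolean intersection I of the two supports:
#' underestimation = percentile Hausdorff between the reference surface and
#' the surface of I (parts of the reference missing from the test outline);
#' overestimation = percentile Hausdorff between the test surface and the
#' surface of I (parts the test outline adds).
#'
#' @param reference_tumor,test_tumor Logical 3D arrays on the same grid.
#' @param spacing,origin Grid geometry.
#' @param p Percentile (default 95).
#' @return Object of class `comparison_result`: `U95HD_mm`, `O95HD_mm`,
#'   `percentile`, `intersection_volume_mm3`, `defined` (FALSE when the
#'   intersection is empty — then both distances are NA, flagged rather than
#'   infinite).
#' @export
under_over_95hd <- function(reference_tumor, test_tumor, spacing, origin,
                            p = 95) {
  if (!identical(dim(reference_tumor), dim(test_tumor))) {
    sm_error("masks are on different grids", "specimargin_error_grid_mismatch")
  }
  if (!any(reference_tumor) || !any(test_tumor)) {
    sm_error("tumor masks must be nonempty", "specimargin_error_empty_mask")
  }
  inter <- boolean_intersection(reference_tumor, test_tumor)
  vol <- sum(inter) * prod(spacing)
  if (!any(inter)) {
    res <- list(U95HD_mm = NA_real_, O95HD_mm = NA_real_, percentile = p,
                intersection_volume_mm3 = 0, defined = FALSE)
    return(structure(res, class = "comparison_result"))
  }
  si <- mask_surface_points(inter, spacing, origin)
  sr <- mask_surface_points(reference_tumor, spacing, origin)
  st <- mask_surface_points(test_tumor, spacing, origin)
  structure(list(U95HD_mm = as.numeric(percentile_hausdorff(sr, si, p)),
                 O95HD_mm = as.numeric(percentile_hausdorff(st, si, p)),
                 percentile = p, intersection_volume_mm3 = vol,
                 defined = TRUE),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  if (!x$defined) {
    cat("<comparison_result> disjoint outlines: distances not defined\n")
  } else {
    cat(sprintf("<comparison_result> U%gHD %.2f mm, O%gHD %.2f mm, intersection %.1f mm^3\n",
                x$percentile, x$U95HD_mm, x$percentile, x$O95HD_mm,
                x$intersection_volume_mm3))
  }
  invisible(x)
}
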