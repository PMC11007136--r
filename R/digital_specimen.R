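#' Digital specimen: outer surface, tumor support and mucosa flags
#'
#' A digital specimen is the 3D representation of one resection specimen as
#' outlined by one observer: the outer surface of the specimen, the tumor
#' voxel support, and per-vertex flags marking which outer-surface vertices
#' belong to the mucosa (an anatomical surface, not a resection plane).
#'
#' @param outer_surface A [surface_mesh()] of the specimen contour.
#' @param tumor_mask Logical 3D array, the tumor voxel support.
#' @param mucosa_vertex_flags Logical vector, one per surface vertex.
#' @param spacing,origin Geometry of the grid `tumor_mask` lives on.
#' @param role One of `"MR-DS"`, `"HE-DS"`, `"ground-truth"`.
#' @param observer Observer identifier string.
#' @return Object of class `digital_specimen`.
#' @export
digital_specimen <- function(outer_surface, tumor_mask, mucosa_vertex_flags,
                             spacing, origin,
                             role = c("MR-DS", "HE-DS", "ground-truth"),
                             observer = "truth") {
  role <- match.arg(role)
  if (length(mucosa_vertex_flags) != nrow(outer_surface$vertices)) {
    sm_error("mucosa_vertex_flags length must equal the vertex count",
             "specimargin_error_bad_flags")
  }
  if (!any(tumor_mask)) {
    sm_error("tumor mask is empty", "specimargin_error_empty_tumor")
  }
  # containment spot-check: sampled tumor voxel centers must fall inside the
  # surface's bounding box (full point-in-mesh testing is not attempted)
  tidx <- which(tumor_mask)
  smp <- tidx[round(seq(1, length(tidx), length.out = min(200L, length(tidx))))]
  pts <- voxel_world_coords(smp, dim(tumor_mask), spacing, origin)
  lo <- apply(outer_surface$vertices, 2, min) - 1e-6
  hi <- apply(outer_surface$vertices, 2, max) + 1e-6
  if (any(sweep(pts, 2, lo, `<`)) || any(sweep(pts, 2, hi, `>`))) {
    sm_error("tumor support extends outside the outer surface",
             "specimargin_error_tumor_outside")
  }
  structure(list(outer_surface = outer_surface, tumor_mask = tumor_mask,
                 mucosa_vertex_flags = as.logical(mucosa_vertex_flags),
                 spacing = as.numeric(spacing), origin = as.numeric(origin),
                 role = role, observer = observer),
            class = "digital_specimen")
}

#' @export
print.digital_specimen <- function(x, ...) {
  cat(sprintf("<digital_specimen> role %s, observer %s\n", x$role, x$observer))
  cat(sprintf("  surface: %d vertices (%d mucosa), tumor: %d voxels\n",
              nrow(x$outer_surface$vertices), sum(x$mucosa_vertex_flags),
              sum(x$tumor_mask)))
  invisible(x)
}

#' Build a digital specimen from a labeled volume
#'
#' Extracts the outer surface of the specimen support, takes the tumor voxel
#' support, and flags surface vertices as mucosa when their nearest
#' support-boundary voxel carries the mucosa label.
#'
#' @param vol A [labeled_volume()].
#' @param role,observer Provenance tags, see [digital_specimen()].
#' @param tumor_mask Optional replacement tumor support (e.g. an observer's
#'   outline on the same grid); defaults to the volume's tumor label.
#' @param smoothing Passed to [extract_surface()].
#' @return A [digital_specimen()].
#' @export
as_digital_specimen <- function(vol, role = "ground-truth", observer = "truth",
                                tumor_mask = NULL, smoothing = FALSE) {
  surf <- extract_surface(vol, smoothing = smoothing)
  support <- specimen_support(vol)
  bnd <- which(boundary_voxels(support))
  bpts <- voxel_world_coords(bnd, dim(vol$grid), vol$spacing, vol$origin)
  nn <- RANN::nn2(data = bpts, query = surf$vertices, k = 1L)
  blab <- vol$grid[bnd]
  muc <- blab[nn$nn.idx[, 1]] == specimen_labels()[["mucosa"]]
  tm <- tumor_mask %||% label_mask(vol, "tumor")
  digital_specimen(surf, tm, muc, vol$spacing, vol$origin,
                   role = role, observer = observer)
}
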