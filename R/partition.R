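# Five-region anatomical partition of the specimen surface: a 45-degree cone
# under the tumor designates the deep central region; the remainder is split
# into anterior / posterior / craniomedial / caudolateral quadrants by
# azimuth about the cone axis.

#' A plane in 3D
#' @param point_mm A point on the plane (mm).
#' @param normal Plane normal (normalized internally).
#' @return Object of class `plane`.
#' @export
plane <- function(point_mm, normal) {
  structure(list(point_mm = as.numeric(point_mm),
                 unit_normal = normalize(as.numeric(normal))),
            class = "plane")
}

#' A one-sided infinite cone
#' @param apex_mm Apex position (mm).
#' @param axis Cone axis direction (normalized internally), pointing from the
#'   apex into the cone.
#' @param half_angle_deg Half-opening angle in degrees, in (0, 90).
#' @return Object of class `cone`.
#' @export
cone <- function(apex_mm, axis, half_angle_deg = 45) {
  if (half_angle_deg <= 0 || half_angle_deg >= 90) {
    sm_error("half angle must be in (0, 90) degrees",
             "specimargin_error_bad_cone")
  }
  structure(list(apex_mm = as.numeric(apex_mm),
                 unit_axis = normalize(as.numeric(axis)),
                 half_angle_deg = half_angle_deg),
            class = "cone")
}

#' Cone membership test
#'
#' A point is inside the cone when it lies strictly forward of the apex along
#' the axis and the angle between `point - apex` and the axis is at most the
#' half angle (boundary points count as inside — the deterministic
#' tie-break into the deep central region).
#'
#' @param con A [cone()].
#' @param points n x 3 matrix of world points.
#' @return Logical vector.
#' @export
in_cone <- function(con, points) {
  v <- sweep(matrix(as.numeric(points), ncol = 3), 2, con$apex_mm)
  along <- as.numeric(v %*% con$unit_axis)
  r2 <- pmax(rowSums(v^2) - along^2, 0)
  ang <- atan2(sqrt(r2), along)
  along > 0 & rad2deg(ang) <= con$half_angle_deg
}

#' Fit the mucosa plane of a digital specimen
#'
#' Total-least-squares plane through the mucosa-flagged surface vertices
#' (smallest principal component of their scatter), with the normal oriented
#' from the mucosa centroid toward the specimen interior: the "deep"
#' direction.
#'
#' @param specimen A [digital_specimen()].
#' @return A [plane()]; extra field `rms_mm` holds the orthogonal rms
#'   residual.
#' @export
fit_mucosa_plane <- function(specimen) {
  pts <- specimen$outer_surface$vertices[specimen$mucosa_vertex_flags, ,
                                         drop = FALSE]
  if (nrow(pts) < 3) {
    sm_error("need at least 3 mucosa vertices to fit a plane",
             "specimargin_error_too_few_mucosa")
  }
  cen <- colMeans(pts)
  X <- sweep(pts, 2, cen)
  sv <- svd(X, nu = 0)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    sm_error("mucosa vertices are collinear; plane is undefined",
             "specimargin_error_degenerate")
  }
  n <- sv$v[, 3]
  interior <- colMeans(specimen$outer_surface$vertices)
  if (sum(n * (interior - cen)) < 0) n <- -n
  pl <- plane(cen, n)
  pl$rms_mm <- sqrt(mean((X %*% pl$unit_normal)^2))
  pl
}

#' Build the deep-central cone of a digital specimen
#'
#' Apex at the tumor-support centroid (or an explicit override, mirroring
#' manual placement "in the middle of the tumor"), axis along the mucosa
#' plane's deep-oriented normal, default half angle 45 degrees.
#'
#' @param specimen A [digital_specimen()].
#' @param mucosa_plane A [plane()] from [fit_mucosa_plane()].
#' @param apex_override Optional explicit apex (mm).
#' @param half_angle_deg Cone half angle.
#' @return A [cone()].
#' @export
build_deep_cone <- function(specimen, mucosa_plane, apex_override = NULL,
                            half_angle_deg = 45) {
  if (is.null(apex_override)) {
    tidx <- which(specimen$tumor_mask)
    if (!length(tidx)) {
      sm_error("tumor mask is empty", "specimargin_error_empty_tumor")
    }
    pts <- voxel_world_coords(tidx, dim(specimen$tumor_mask),
                              specimen$spacing, specimen$origin)
    apex <- colMeans(pts)
  } else {
    apex <- as.numeric(apex_override)
  }
  cone(apex, mucosa_plane$unit_normal, half_angle_deg)
}

#' Partition a specimen surface into the five margin regions
#'
#' Vertices inside the cone become `deep_central`. Remaining vertices are
#' classified by azimuth about the cone axis, measured from the anterior
#' direction (the projection of posterior-to-anterior onto the cone-base
#' plane): `[-45, 45)` anterior, `[135, 225)` posterior, and the two
#' remaining quadrants craniomedial / caudolateral, disambiguated by which
#' side `craniomedial_hint` projects into. Boundary azimuths fall into the
#' half-open interval on their lower side (deterministic tie-break).
#'
#' @param specimen A [digital_specimen()].
#' @param deep_cone A [cone()] from [build_deep_cone()].
#' @param anterior_point,posterior_point World points marking the anterior
#'   and posterior ends of the specimen.
#' @param craniomedial_hint Direction (mm vector) pointing toward the
#'   craniomedial side; must not be parallel to the anterior-posterior
#'   direction.
#' @return Object of class `region_partition`: `region` (factor per vertex,
#'   levels [margin_regions()]), plus the generating `cone`, frame vectors
#'   and reference points.
#' @export
partition_surface <- function(specimen, deep_cone, anterior_point,
                              posterior_point, craniomedial_hint) {
  anterior_point <- as.numeric(anterior_point)
  posterior_point <- as.numeric(posterior_point)
  craniomedial_hint <- as.numeric(craniomedial_hint)
  ap <- anterior_point - posterior_point
  if (vnorm(ap) < 1e-9) {
    sm_error("anterior and posterior points must be distinct",
             "specimargin_error_degenerate")
  }
  w <- deep_cone$unit_axis
  e1 <- ap - sum(ap * w) * w
  if (vnorm(e1) < 1e-9) {
    sm_error("anterior-posterior direction is parallel to the cone axis",
             "specimargin_error_degenerate")
  }
  e1 <- normalize(e1)
  e2 <- c(w[2] * e1[3] - w[3] * e1[2],
          w[3] * e1[1] - w[1] * e1[3],
          w[1] * e1[2] - w[2] * e1[1])
  hint_perp <- craniomedial_hint - sum(craniomedial_hint * w) * w
  hp <- c(sum(hint_perp * e1), sum(hint_perp * e2))
  if (vnorm(hp) < 1e-9) {
    sm_error("craniomedial hint is parallel to the cone axis",
             "specimargin_error_degenerate")
  }
  hint_az <- rad2deg(atan2(hp[2], hp[1]))
  if (abs(hint_az) < 1e-9 || abs(abs(hint_az) - 180) < 1e-9) {
    sm_error("craniomedial hint is parallel to the anterior-posterior direction",
             "specimargin_error_degenerate")
  }
  verts <- specimen$outer_surface$vertices
  lab <- character(nrow(verts))
  deep <- in_cone(deep_cone, verts)
  lab[deep] <- "deep_central"
  v <- sweep(verts, 2, deep_cone$apex_mm)
  az <- rad2deg(atan2(as.numeric(v %*% e2), as.numeric(v %*% e1)))
  upper_is_cm <- hint_az >= 45 & hint_az < 135
  sector <- ifelse(az >= -45 & az < 45, "anterior",
            ifelse(az >= 135 | az < -135, "posterior",
            ifelse(az >= 45 & az < 135,
                   if (upper_is_cm) "craniomedial" else "caudolateral",
                   if (upper_is_cm) "caudolateral" else "craniomedial")))
  lab[!deep] <- sector[!deep]
  structure(list(region = factor(lab, levels = margin_regions()),
                 cone = deep_cone, e_anterior = e1, e_lateral = e2,
                 anterior_point = anterior_point,
                 posterior_point = posterior_point,
                 craniomedial_hint = craniomedial_hint),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("<region_partition>\n")
  print(table(x$region))
  invisible(x)
}

#' Summarize a region partition (vertex counts and areas)
#'
#' @param object A `region_partition`.
#' @param specimen The [digital_specimen()] it was computed on.
#' @param ... Unused.
#' @return Data frame with per-region vertex counts and surface areas
#'   (each face's area credited in thirds to its corner vertices).
#' @export
summary.region_partition <- function(object, specimen = NULL, ...) {
  out <- data.frame(region = margin_regions(),
                    vertices = as.integer(table(object$region)[margin_regions()]))
  if (!is.null(specimen)) {
    mesh <- specimen$outer_surface
    f <- mesh$faces; v <- mesh$vertices
    a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    fa <- sqrt(rowSums(cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])^2)) / 2
    va <- numeric(nrow(v))
    for (k in 1:3) {
      acc <- rowsum(fa / 3, f[, k])
      va[as.integer(rownames(acc))] <- va[as.integer(rownames(acc))] + acc
    }
    out$area_mm2 <- vapply(margin_regions(),
                           function(r) sum(va[object$region == r]), numeric(1))
  }
  out
}
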