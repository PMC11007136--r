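# Margin mapping: tumor-to-resection-surface distances on the specimen
# surface, per-region adequacy calls at the 5 mm threshold, and the
# conventional slice-based emulation of histopathological margin reporting.

#' Compute the margin map of a digital specimen
#'
#' Interpolates a tumor distance field (trilinear) at every outer-surface
#' vertex. Mucosa vertices are excluded by default: the mucosa is an
#' anatomical surface, not a resection plane, so it carries no margin.
#'
#' @param specimen A [digital_specimen()].
#' @param distance_field A `distance_field` to the tumor, built on the
#'   specimen's grid (see [euclidean_distance_field()]).
#' @param threshold_mm Adequacy threshold (default 5).
#' @param exclude_mucosa Set `FALSE` to include mucosa vertices (sensitivity
#'   analysis).
#' @return Object of class `margin_map`: `distance_mm` (per-vertex, NA on
#'   excluded vertices), `threshold_mm`, `excluded` (logical per vertex).
#' @export
compute_margin_map <- function(specimen, distance_field, threshold_mm = 5,
                               exclude_mucosa = TRUE) {
  if (threshold_mm <= 0) {
    sm_error("threshold must be positive", "specimargin_error_bad_threshold")
  }
  if (!isTRUE(all.equal(specimen$spacing, distance_field$spacing)) ||
      !isTRUE(all.equal(specimen$origin, distance_field$origin))) {
    sm_error("distance field and specimen are on different grids",
             "specimargin_error_grid_mismatch")
  }
  d <- sample_field(distance_field, specimen$outer_surface$vertices)
  excl <- if (exclude_mucosa) specimen$mucosa_vertex_flags else
    rep(FALSE, length(d))
  d[excl] <- NA_real_
  structure(list(distance_mm = d, threshold_mm = threshold_mm,
                 excluded = excl),
            class = "margin_map")
}

#' @export
print.margin_map <- function(x, ...) {
  ok <- !is.na(x$distance_mm)
  cat(sprintf("<margin_map> %d vertices (%d assessed), min %.2f mm, threshold %g mm\n",
              length(x$distance_mm), sum(ok), min(x$distance_mm[ok]),
              x$threshold_mm))
  invisible(x)
}

#' Per-region margin report
#'
#' Minimum margin per region over the assessed (non-mucosa) vertices, called
#' `inadequate` iff strictly below the threshold (adequate means >= 5 mm);
#' regions with no assessable vertex are reported `not_assessable`, never
#' silently adequate.
#'
#' @param map A [compute_margin_map()] result.
#' @param partition A [partition_surface()] result on the same surface.
#' @return Object of class `margin_report`: data frame `regions` with
#'   `region`, `min_margin_mm`, `call`; plus `threshold_mm`.
#' @export
classify_regions <- function(map, partition) {
  if (length(map$distance_mm) != length(partition$region)) {
    sm_error("margin map and partition refer to different surfaces",
             "specimargin_error_grid_mismatch")
  }
  rows <- lapply(margin_regions(), function(r) {
    d <- map$distance_mm[partition$region == r]
    d <- d[!is.na(d)]
    if (!length(d)) {
      data.frame(region = r, min_margin_mm = NA_real_, call = "not_assessable")
    } else {
      m <- min(d)
      data.frame(region = r, min_margin_mm = m,
                 call = if (m < map$threshold_mm) "inadequate" else "adequate")
    }
  })
  structure(list(regions = do.call(rbind, rows),
                 threshold_mm = map$threshold_mm),
            class = "margin_report")
}

#' @export
print.margin_report <- function(x, ...) {
  cat(sprintf("<margin_report> threshold %g mm\n", x$threshold_mm))
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Portable colormap specification for margin maps
#'
#' Continuous colormap used when rendering margin maps externally: dark red
#' below the adequacy threshold, grading to green at and above it.
#'
#' @param threshold_mm Adequacy threshold.
#' @param max_mm Distance mapped to the last color stop.
#' @return List with `stops` (data frame of distance/color) and `threshold_mm`;
#'   serializable to JSON as-is.
#' @export
margin_colormap <- function(threshold_mm = 5, max_mm = 15) {
  list(threshold_mm = threshold_mm,
       stops = data.frame(
         distance_mm = c(0, threshold_mm * 0.999, threshold_mm, max_mm),
         color = c("#67000d", "#cb181d", "#ffffbf", "#1a9850")))
}

#' Conventional slice-based margin assessment
#'
#' Emulates the pathologist's protocol on cross-sectional blocks cut
#' perpendicular to the anterior-posterior axis:
#' anterior / posterior margins are the count of tumor-free blocks at the
#' respective end multiplied by the mean block thickness (specimen length /
#' block count); on each tumor-bearing section the deep central margin is the
#' minimum tumor-to-contour distance inside the wedge between two 45-degree
#' lines from the tumor centroid relative to a line parallel to the mucosa,
#' and the craniomedial / caudolateral margins are the minima on either side
#' of the wedge, all aggregated across sections by minimum.
#'
#' @param stack A `section_stack` from [simulate_sectioning()], or a
#'   [labeled_volume()] (then jitter-free sections of `mean_thickness_mm` are
#'   taken internally).
#' @param craniomedial_hint_2d In-plane direction (x, z) of the craniomedial
#'   side.
#' @param threshold_mm Adequacy threshold.
#' @param mean_thickness_mm Block thickness when `stack` is a volume.
#' @return Object of class `conventional_report`: data frame `regions`
#'   (`region`, `margin_mm`, `call`), `mean_thickness_mm`, `threshold_mm`.
#' @export
conventional_slice_margins <- function(stack, craniomedial_hint_2d = c(1, 0),
                                       threshold_mm = 5,
                                       mean_thickness_mm = 4) {
  if (inherits(stack, "labeled_volume") || inherits(stack, "phantom")) {
    stack <- simulate_sectioning(stack, mean_thickness_mm = mean_thickness_mm,
                                 spacing_jitter_mm = 0, shrink_healthy = 1,
                                 rupture = FALSE, mount_rotation_deg = 0,
                                 mount_translation_mm = 0, seed = 0L)
  }
  ns <- length(stack$sections)
  tumor_code <- specimen_labels()[["tumor"]]
  has_tumor <- vapply(stack$sections,
                      function(s) any(s$image == tumor_code), logical(1))
  if (!any(has_tumor)) {
    sm_error("no tumor-bearing section", "specimargin_error_empty_tumor")
  }
  mean_th <- stack$length_mm / ns
  # sections are ordered along +y (posterior to anterior)
  n_free_ant <- ns - max(which(has_tumor))
  n_free_post <- min(which(has_tumor)) - 1L
  anterior <- n_free_ant * mean_th
  posterior <- n_free_post * mean_th
  xs <- stack$origin2d[1] + (seq_len(stack$dim2d[1]) - 1) * stack$spacing2d[1]
  zs <- stack$origin2d[2] + (seq_len(stack$dim2d[2]) - 1) * stack$spacing2d[2]
  sec_mins <- vapply(which(has_tumor), function(i) {
    section_sector_margins(stack$sections[[i]]$image, xs, zs,
                           craniomedial_hint_2d)
  }, numeric(3))
  agg <- apply(matrix(sec_mins, nrow = 3), 1, min, na.rm = TRUE)
  margins <- c(anterior = anterior, posterior = posterior,
               craniomedial = agg[2], caudolateral = agg[3],
               deep_central = agg[1])
  rows <- data.frame(region = margin_regions(),
                     margin_mm = as.numeric(margins[margin_regions()]))
  rows$call <- ifelse(is.finite(rows$margin_mm),
                      ifelse(rows$margin_mm < threshold_mm,
                             "inadequate", "adequate"),
                      "not_assessable")
  rows$margin_mm[!is.finite(rows$margin_mm)] <- NA_real_
  structure(list(regions = rows, mean_thickness_mm = mean_th,
                 threshold_mm = threshold_mm),
            class = "conventional_report")
}

#' @export
print.conventional_report <- function(x, ...) {
  cat(sprintf("<conventional_report> mean block thickness %.2f mm, threshold %g mm\n",
              x$mean_thickness_mm, x$threshold_mm))
  print(x$regions, row.names = FALSE)
  invisible(x)
}

# per-section 2D sector margins: c(deep, craniomedial, caudolateral).
# 45-degree lines from the tumor centroid relative to the mucosa-parallel
# line; contour = non-mucosa boundary pixels of the section support.
section_sector_margins <- function(img, xs, zs, hint2d) {
  nx <- length(xs); nz <- length(zs)
  sup <- img != 0L
  tum <- img == specimen_labels()[["tumor"]]
  muc <- img == specimen_labels()[["mucosa"]]
  if (!any(tum)) return(c(NA_real_, NA_real_, NA_real_))
  pix <- cbind(rep(xs, times = nz), rep(zs, each = nx))
  tpts <- pix[as.vector(tum), , drop = FALSE]
  cen <- colMeans(tpts)
  # 4-neighbor boundary of the support
  nb_in <- matrix(TRUE, nx, nz)
  nb_in[-1, ] <- nb_in[-1, ] & sup[-nx, ]
  nb_in[-nx, ] <- nb_in[-nx, ] & sup[-1, ]
  nb_in[, -1] <- nb_in[, -1] & sup[, -nz]
  nb_in[, -nz] <- nb_in[, -nz] & sup[, -1]
  nb_in[c(1, nx), ] <- FALSE; nb_in[, c(1, nz)] <- FALSE
  contour <- sup & !nb_in & !muc
  if (!any(contour)) return(c(NA_real_, NA_real_, NA_real_))
  cpts <- pix[as.vector(contour), , drop = FALSE]
  # mucosa-parallel line direction; fall back to horizontal if mucosa absent
  if (sum(muc) >= 2) {
    mpts <- pix[as.vector(muc), , drop = FALSE]
    pc <- prcomp(mpts, center = TRUE)
    u <- pc$rotation[, 1]
    mcen <- colMeans(mpts)
    down <- c(-u[2], u[1])
    if (sum(down * (cen - mcen)) < 0) down <- -down
  } else {
    u <- c(1, 0)
    down <- c(0, -1)
  }
  if (sum(u * hint2d) < 0) u <- -u  # orient u toward the craniomedial side
  v <- sweep(cpts, 2, cen)
  ang_down <- acos(pmin(pmax((v %*% down) / sqrt(rowSums(v^2)), -1), 1))
  in_wedge <- rad2deg(as.numeric(ang_down)) <= 45
  side_cm <- as.numeric(v %*% u) >= 0
  dmin <- RANN::nn2(data = tpts, query = cpts, k = 1L)$nn.dists[, 1]
  sector_min <- function(sel) if (any(sel)) min(dmin[sel]) else NA_real_
  c(sector_min(in_wedge),
    sector_min(!in_wedge & side_cm),
    sector_min(!in_wedge & !side_cm))
}
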