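# Synthetic specimens with known ground truth.
#
# Shapes are smoothed ellipsoids (optionally radially perturbed) rather than
# anatomical tongue meshes: the margin rules depend only on orientation, and
# ellipsoids keep analytic oracles available. The mucosa is the surface cap
# whose outward normal lies within a configurable angle of the up axis,
# mimicking the mucosal lid of an ex-vivo tongue specimen.

#' Phantom configuration
#'
#' Defaults emulate the study conditions: specimens fitting a 59 mm-diameter
#' container bore, tumors a few mm under the mucosal cap at clinical
#' depth-of-invasion scale, isotropic 0.3 mm voxels.
#'
#' @param specimen_axes_mm Ellipsoid semi-axes (x lateral, y
#'   anterior-posterior, z deep-superficial) in mm.
#' @param tumor_center_mm Tumor ellipsoid center in mm (world frame centered
#'   on the specimen).
#' @param tumor_axes_mm Tumor ellipsoid semi-axes in mm.
#' @param mucosa_cap_angle_deg Surface voxels whose outward normal is within
#'   this angle of +z are flagged mucosa.
#' @param spacing_mm Isotropic voxel spacing in mm.
#' @param seed Integer seed; all randomness is derived from it.
#' @param bumpiness_mm Amplitude (mm, ~1 sd) of the smooth random radial
#'   perturbation of the specimen surface; 0 gives an exact ellipsoid.
#' @param pad_mm Background padding around the specimen.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(specimen_axes_mm = c(18, 25, 14),
                           tumor_center_mm = c(0, 0, 6),
                           tumor_axes_mm = c(6, 7, 5),
                           mucosa_cap_angle_deg = 60,
                           spacing_mm = 0.3,
                           seed = 1L,
                           bumpiness_mm = 0.5,
                           pad_mm = 2) {
  cfg <- list(specimen_axes_mm = as.numeric(specimen_axes_mm),
              tumor_center_mm = as.numeric(tumor_center_mm),
              tumor_axes_mm = as.numeric(tumor_axes_mm),
              mucosa_cap_angle_deg = mucosa_cap_angle_deg,
              spacing_mm = spacing_mm, seed = as.integer(seed),
              bumpiness_mm = bumpiness_mm, pad_mm = pad_mm)
  if (spacing_mm <= 0) sm_error("spacing must be positive", "specimargin_error_bad_spacing")
  # container bore: 59 mm inner diameter, axis along y
  if (any(2 * (cfg$specimen_axes_mm[c(1, 3)] + cfg$bumpiness_mm * 3) > 59)) {
    sm_error("specimen does not fit the 59 mm container bore",
             "specimargin_error_container")
  }
  ell <- sqrt(sum((cfg$tumor_center_mm / cfg$specimen_axes_mm)^2))
  reach <- max(cfg$tumor_axes_mm / cfg$specimen_axes_mm)
  if (ell + reach >= 1) {
    sm_error("tumor is not strictly inside the specimen ellipsoid",
             "specimargin_error_tumor_outside")
  }
  if (any(2 * cfg$tumor_axes_mm / spacing_mm < 3)) {
    sm_error("spacing too coarse to resolve the tumor (< 3 voxels across an axis)",
             "specimargin_error_unresolved_tumor")
  }
  structure(cfg, class = "phantom_config")
}

# smooth unit-variance random field: Gaussian-filtered white noise (FFT,
# periodic wrap -- harmless for interior geometry)
smooth_noise_field <- function(dim, spacing, corr_mm = 6, seed = NULL) {
  with_seed(seed, {
    noise <- array(rnorm(prod(dim)), dim)
    ax_kernels <- lapply(1:3, function(ax) {
      x <- (seq_len(dim[ax]) - 1) * spacing[ax]
      x <- pmin(x, max(x) + spacing[ax] - x)  # wrapped distance
      k <- exp(-x^2 / (2 * corr_mm^2))
      k / sum(k)
    })
    kern <- outer(outer(ax_kernels[[1]], ax_kernels[[2]]), ax_kernels[[3]])
    sm <- Re(fft(fft(noise) * fft(kern), inverse = TRUE)) / prod(dim)
    (sm - mean(sm)) / sd(sm)
  })
}

#' Generate a synthetic specimen phantom with brute-force ground truth
#'
#' Builds the labeled volume (specimen / tumor / mucosa), samples the
#' resection surface densely (boundary voxel-face centers, mucosa excluded),
#' classifies every sample into the five margin regions with a classifier
#' written independently of the pipeline's partition code, and records the
#' per-region minimum tumor distance as ground truth.
#'
#' @param config A [phantom_config()].
#' @return Object of class `phantom`: fields `volume` ([labeled_volume()]),
#'   `truth_margins` (named numeric, mm, the five regions),
#'   `truth_surface` (list: `points`, `region` per sample),
#'   `anterior_point`, `posterior_point`, `craniomedial_hint`, `up_axis`,
#'   `tumor_centroid`, `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  h <- config$spacing_mm
  ax <- config$specimen_axes_mm
  ext <- ax + config$pad_mm + 3 * config$bumpiness_mm
  n <- ceiling(2 * ext / h) + 1
  origin <- -(n - 1) / 2 * h  # specimen centered at world 0
  coords <- lapply(1:3, function(k) origin[k] + (seq_len(n[k]) - 1) * h)
  # ellipsoid field e(x) = |diag(1/a) (x - c)|
  e2 <- outer(outer((coords[[1]] / ax[1])^2, (coords[[2]] / ax[2])^2, `+`),
              (coords[[3]] / ax[3])^2, `+`)
  e <- sqrt(e2)
  if (config$bumpiness_mm > 0) {
    bump <- config$bumpiness_mm *
      smooth_noise_field(n, rep(h, 3), corr_mm = 6, seed = config$seed)
    support <- e <= 1 + bump / mean(ax)
  } else {
    support <- e <= 1
  }
  tc <- config$tumor_center_mm; ta <- config$tumor_axes_mm
  t2 <- outer(outer(((coords[[1]] - tc[1]) / ta[1])^2,
                    ((coords[[2]] - tc[2]) / ta[2])^2, `+`),
              ((coords[[3]] - tc[3]) / ta[3])^2, `+`)
  tumor <- t2 <= 1
  if (!any(tumor)) {
    sm_error("tumor unresolved on this grid", "specimargin_error_unresolved_tumor")
  }
  if (any(tumor & !support)) {
    sm_error("tumor extends outside the specimen support",
             "specimargin_error_tumor_outside")
  }
  bnd <- boundary_voxels(support)
  if (any(tumor & bnd)) {
    sm_error("tumor reaches the specimen surface (not strictly inside)",
             "specimargin_error_tumor_outside")
  }
  # mucosa: boundary voxels whose outward (ellipsoid) normal is close to +z
  bidx <- which(bnd)
  bai <- arrayInd(bidx, n)
  bxyz <- cbind(coords[[1]][bai[, 1]], coords[[2]][bai[, 2]], coords[[3]][bai[, 3]])
  nrm <- sweep(bxyz, 2, ax^2, `/`)  # gradient of the ellipsoid level set
  nrm <- nrm / sqrt(rowSums(nrm^2))
  is_muc <- nrm[, 3] >= cos(deg2rad(config$mucosa_cap_angle_deg))
  grid <- array(0L, n)
  grid[support] <- specimen_labels()[["specimen"]]
  grid[bidx[is_muc]] <- specimen_labels()[["mucosa"]]
  grid[tumor] <- specimen_labels()[["tumor"]]
  vol <- labeled_volume(grid, spacing = rep(h, 3), origin = origin,
                        check_mucosa = FALSE)

  # dense resection-surface samples: boundary voxel-face centers of the
  # support, excluding faces of mucosa voxels
  samp <- boundary_face_centers(support, rep(h, 3), origin,
                                exclude = bidx[is_muc])
  tidx <- which(tumor)
  tpts <- voxel_world_coords(tidx, n, rep(h, 3), origin)
  apex <- colMeans(tpts)
  # reference points: extreme boundary samples along y
  all_faces <- boundary_face_centers(support, rep(h, 3), origin)
  anterior_point <- all_faces[which.max(all_faces[, 2]), ]
  posterior_point <- all_faces[which.min(all_faces[, 2]), ]
  hint <- c(1, 0, 0)
  region <- truth_region_classifier(samp, apex = apex, down = c(0, 0, -1),
                                    half_angle_deg = 45,
                                    anterior_point = anterior_point,
                                    posterior_point = posterior_point,
                                    hint = hint)
  nn <- RANN::nn2(data = tpts, query = samp, k = 1L)
  dmin <- as.numeric(nn$nn.dists)
  truth <- vapply(margin_regions(), function(r) {
    i <- region == r
    if (!any(i)) NA_real_ else min(dmin[i])
  }, numeric(1))
  names(truth) <- margin_regions()
  structure(list(volume = vol, truth_margins = truth,
                 truth_surface = list(points = samp, region = region,
                                      tumor_distance = dmin),
                 anterior_point = anterior_point,
                 posterior_point = posterior_point,
                 craniomedial_hint = hint, up_axis = c(0, 0, 1),
                 tumor_centroid = apex, config = config),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> seed", x$config$seed, "\n")
  print(x$volume)
  cat("  truth margins (mm):",
      paste(sprintf("%s=%.2f", names(x$truth_margins), x$truth_margins),
            collapse = ", "), "\n")
  invisible(x)
}

#' The five anatomical margin regions
#' @return Character vector of region names in canonical order.
#' @export
margin_regions <- function() {
  c("anterior", "posterior", "craniomedial", "caudolateral", "deep_central")
}

# boundary voxel-face centers of a mask (world mm); optionally drop faces
# belonging to specific voxels (linear indices), e.g. mucosa
boundary_face_centers <- function(mask, spacing, origin, exclude = integer(0)) {
  d <- dim(mask)
  res <- vector("list", 6)
  k <- 1
  excl <- logical(prod(d)); excl[exclude] <- TRUE
  for (axis in 1:3) for (dir in c(-1, 1)) {
    nb <- array(FALSE, d)
    idx <- lapply(d, seq_len)
    src <- idx; dst <- idx
    if (dir == 1) { src[[axis]] <- 2:d[axis]; dst[[axis]] <- 1:(d[axis] - 1) }
    else { src[[axis]] <- 1:(d[axis] - 1); dst[[axis]] <- 2:d[axis] }
    nb[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
    face <- mask & !nb  # neighbor in +dir*axis outside (or grid edge)
    fidx <- which(face & !excl)
    if (length(fidx)) {
      pts <- voxel_world_coords(fidx, d, spacing, origin)
      pts[, axis] <- pts[, axis] + dir * spacing[axis] / 2
      res[[k]] <- pts
    }
    k <- k + 1
  }
  do.call(rbind, res)
}

# independent five-region classifier used only for phantom ground truth;
# intentionally parallel to (but coded separately from) partition_surface()
truth_region_classifier <- function(points, apex, down, half_angle_deg,
                                    anterior_point, posterior_point, hint) {
  v <- sweep(points, 2, apex, `-`)
  w <- normalize(down)
  proj_len <- as.numeric(v %*% w)
  r <- sqrt(pmax(rowSums(v^2) - proj_len^2, 0))
  # inside cone: forward of apex and within half-angle of the axis
  ang <- atan2(r, proj_len)  # in [0, pi]
  in_cone <- proj_len > 0 & rad2deg(ang) <= half_angle_deg
  adir <- anterior_point - posterior_point
  e1 <- normalize(adir - as.numeric(adir %*% w) * w)
  e2 <- c(w[2] * e1[3] - w[3] * e1[2],
          w[3] * e1[1] - w[1] * e1[3],
          w[1] * e1[2] - w[2] * e1[1])
  az <- rad2deg(atan2(as.numeric(v %*% e2), as.numeric(v %*% e1)))
  hint_az <- rad2deg(atan2(sum(hint * e2), sum(hint * e1)))
  cm_first <- hint_az >= 45 & hint_az < 135
  out <- character(nrow(points))
  out[in_cone] <- "deep_central"
  rest <- !in_cone
  a <- az >= -45 & az < 45
  p <- az >= 135 | az < -135
  q1 <- az >= 45 & az < 135
  out[rest & a] <- "anterior"
  out[rest & p] <- "posterior"
  out[rest & q1] <- if (cm_first) "craniomedial" else "caudolateral"
  out[rest & !a & !p & !q1] <- if (cm_first) "caudolateral" else "craniomedial"
  out
}

#' Perturb a tumor outline like a human observer
#'
#' Applies a smoothly varying signed offset to the tumor support: the new
#' support is `{x : sdist(x) - noise(x) <= bias_mm}` where `sdist` is the
#' signed center-to-center distance to the tumor surface and `noise` is a
#' Gaussian-filtered random field with standard deviation `roughness_mm`.
#' Positive bias dilates (observer overestimation), negative bias erodes
#' (underestimation). The result is clipped to the specimen support.
#'
#' @param vol A [labeled_volume()] carrying the tumor.
#' @param bias_mm Mean signed offset in mm.
#' @param roughness_mm Spatial sd of the smooth noise in mm (0 = exact
#'   morphological offset).
#' @param seed Integer seed for the noise field.
#' @param corr_mm Correlation length of the noise in mm.
#' @return Logical 3D array: the perturbed tumor support.
#' @export
perturb_tumor_outline <- function(vol, bias_mm, roughness_mm = 0, seed = 1L,
                                  corr_mm = 4) {
  tmask <- label_mask(vol, "tumor")
  if (!any(tmask)) sm_error("volume has no tumor", "specimargin_error_empty_tumor")
  if (bias_mm == 0 && roughness_mm == 0) return(tmask)
  d_out <- euclidean_distance_field(vol, tmask)$grid
  d_in <- euclidean_distance_field(vol, !tmask)$grid
  sdist <- d_out - d_in
  noise <- if (roughness_mm > 0) {
    roughness_mm * smooth_noise_field(dim(vol$grid), vol$spacing,
                                      corr_mm = corr_mm, seed = seed)
  } else 0
  new_mask <- (sdist - noise) <= bias_mm
  new_mask <- new_mask & specimen_support(vol)
  if (!any(new_mask)) {
    need <- min(sdist - noise)
    sm_error(sprintf(
      "erosion annihilates the tumor; smallest surviving bias is about %.2f mm",
      need), "specimargin_error_annihilated_tumor")
  }
  new_mask
}
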