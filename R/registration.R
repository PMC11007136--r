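#' 2D similarity transform (rotation, isotropic scale, translation)
#'
#' @param rotation_deg Counter-clockwise rotation in degrees.
#' @param scale Isotropic scale factor (> 0; reflections are not
#'   representable).
#' @param translation_mm Length-2 translation in mm.
#' @return Object of class `similarity_transform_2d`.
#' @export
similarity_transform_2d <- function(rotation_deg = 0, scale = 1,
                                    translation_mm = c(0, 0)) {
  if (!is.finite(scale) || scale <= 0) {
    sm_error("scale must be strictly positive", "specimargin_error_bad_transform")
  }
  structure(list(rotation_deg = as.numeric(rotation_deg),
                 scale = as.numeric(scale),
                 translation_mm = as.numeric(translation_mm)),
            class = "similarity_transform_2d")
}

#' @export
print.similarity_transform_2d <- function(x, ...) {
  cat(sprintf("<similarity_transform_2d> rot %.3f deg, scale %.5f, t (%.3f, %.3f) mm\n",
              x$rotation_deg, x$scale, x$translation_mm[1], x$translation_mm[2]))
  invisible(x)
}

tf_matrix <- function(tf) {
  th <- deg2rad(tf$rotation_deg)
  tf$scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Apply a 2D similarity transform to points
#' @param tf A [similarity_transform_2d()].
#' @param points n x 2 matrix (or length-2 vector) in mm.
#' @return Transformed n x 2 matrix.
#' @export
apply_transform <- function(tf, points) {
  p <- matrix(as.numeric(points), ncol = 2)
  sweep(p %*% t(tf_matrix(tf)), 2, tf$translation_mm, `+`)
}

#' Invert a 2D similarity transform
#' @param tf A [similarity_transform_2d()].
#' @return The inverse [similarity_transform_2d()].
#' @export
invert_transform <- function(tf) {
  th <- deg2rad(-tf$rotation_deg)
  s <- 1 / tf$scale
  R <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  similarity_transform_2d(-tf$rotation_deg, s,
                          as.numeric(-R %*% tf$translation_mm))
}

#' Least-squares similarity registration of corresponding 2D landmarks
#'
#' Closed-form least-squares fit (SVD of the cross-covariance, the standard
#' orthogonal-Procrustes solution) of the rotation, isotropic scale and
#' translation mapping `src` onto `dst`, with reflections disallowed.
#' Correspondence is by row order.
#'
#' @param src,dst n x 2 matrices of corresponding points in mm (n >= 2).
#' @return A [similarity_transform_2d()] with an extra field `rms_mm`, the
#'   root-mean-square residual of the fit.
#' @export
fit_similarity_transform <- function(src, dst) {
  src <- matrix(as.numeric(src), ncol = 2)
  dst <- matrix(as.numeric(dst), ncol = 2)
  n <- nrow(src)
  if (nrow(dst) != n) {
    sm_error("landmark sets must have equal point counts",
             "specimargin_error_landmark_mismatch")
  }
  if (n < 2) {
    sm_error("at least 2 landmark pairs are required",
             "specimargin_error_too_few_landmarks")
  }
  ms <- colMeans(src); md <- colMeans(dst)
  X <- sweep(src, 2, ms); Y <- sweep(dst, 2, md)
  var_s <- sum(X^2) / n
  if (var_s < 1e-24) {
    sm_error("source landmarks are all coincident",
             "specimargin_error_degenerate")
  }
  S <- crossprod(Y, X) / n
  sv <- svd(S)
  sgn <- sign(det(sv$u %*% t(sv$v)))
  if (sgn == 0) sgn <- 1
  D <- diag(c(1, sgn))
  R <- sv$u %*% D %*% t(sv$v)
  scale <- sum(sv$d * c(1, sgn)) / var_s
  if (scale <= 0) {
    sm_error("degenerate landmark configuration (non-positive scale)",
             "specimargin_error_degenerate")
  }
  trans <- md - as.numeric(scale * R %*% ms)
  rot <- rad2deg(atan2(R[2, 1], R[1, 1]))
  tf <- similarity_transform_2d(rot, scale, trans)
  res <- sweep(src %*% t(scale * R), 2, trans, `+`) - dst
  tf$rms_mm <- sqrt(mean(rowSums(res^2)))
  tf
}

#' Stack registered 2D sections into a labeled volume
#'
#' Each section image is resampled through its similarity transform into the
#' common in-plane frame (nearest neighbor, labels are categorical), placed
#' at cumulative out-of-plane positions along y, and inter-section voxels are
#' filled by nearest-section label replication (slab model, mirroring how a
#' thin stained section stands in for its whole tissue block).
#'
#' @param stack A `section_stack` from [simulate_sectioning()].
#' @param transforms List of [similarity_transform_2d()], one per section,
#'   mapping each section's frame to the common reference frame. Defaults to
#'   identity transforms.
#' @param spacings_mm Center-to-center distances between consecutive sections
#'   (length = sections - 1, all > 0). Defaults to the stack's true spacings.
#' @return A [labeled_volume()] of the reconstructed specimen.
#' @export
stack_sections <- function(stack, transforms = NULL, spacings_mm = NULL) {
  ns <- length(stack$sections)
  if (is.null(transforms)) {
    transforms <- replicate(ns, similarity_transform_2d(), simplify = FALSE)
  }
  if (length(transforms) != ns) {
    sm_error("one transform per section required",
             "specimargin_error_transform_mismatch")
  }
  centers_true <- vapply(stack$sections, `[[`, numeric(1), "y_center")
  spacings_mm <- spacings_mm %||% diff(centers_true)
  if (ns > 1 && length(spacings_mm) != ns - 1) {
    sm_error("one spacing per gap required", "specimargin_error_spacing_mismatch")
  }
  if (any(spacings_mm <= 0)) {
    sm_error("spacings must be strictly positive (overlapping slabs)",
             "specimargin_error_spacing_mismatch")
  }
  th <- vapply(stack$sections, `[[`, numeric(1), "thickness")
  centers <- stack$y0 + th[1] / 2 + c(0, cumsum(spacings_mm))
  ylo <- centers[1] - th[1] / 2
  yhi <- centers[ns] + th[ns] / 2
  hy <- stack$y_spacing
  ny <- max(1L, ceiling((yhi - ylo) / hy))
  ycent <- ylo + (seq_len(ny) - 0.5) * ((yhi - ylo) / ny)
  # resample every section into the reference in-plane frame
  nx <- stack$dim2d[1]; nz <- stack$dim2d[2]
  xs <- stack$origin2d[1] + (seq_len(nx) - 1) * stack$spacing2d[1]
  zs <- stack$origin2d[2] + (seq_len(nz) - 1) * stack$spacing2d[2]
  outpts <- cbind(rep(xs, times = nz), rep(zs, each = nx))
  resampled <- lapply(seq_len(ns), function(i) {
    inv <- invert_transform(transforms[[i]])
    srcp <- apply_transform(inv, outpts)
    ci <- round((srcp[, 1] - stack$origin2d[1]) / stack$spacing2d[1]) + 1
    cj <- round((srcp[, 2] - stack$origin2d[2]) / stack$spacing2d[2]) + 1
    ok <- ci >= 1 & ci <= nx & cj >= 1 & cj <= nz
    img <- stack$sections[[i]]$image
    out <- integer(nrow(outpts))
    out[ok] <- img[cbind(ci[ok], cj[ok])]
    matrix(out, nx, nz)
  })
  nearest_sec <- vapply(ycent, function(y) which.min(abs(centers - y)), integer(1))
  grid <- array(0L, c(nx, ny, nz))
  for (j in seq_len(ny)) grid[, j, ] <- resampled[[nearest_sec[j]]]
  labeled_volume(grid,
                 spacing = c(stack$spacing2d[1], (yhi - ylo) / ny,
                             stack$spacing2d[2]),
                 origin = c(stack$origin2d[1], ycent[1], stack$origin2d[2]),
                 check_mucosa = FALSE)
}
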