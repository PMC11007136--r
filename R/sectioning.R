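# Emulation of conventional histopathological sectioning: coronal cuts
# perpendicular to the anterior-posterior (y) axis at jittered positions,
# differential shrinkage of healthy tissue around the (unshrunk) tumor,
# optional rupture, per-section anatomical landmarks, and random in-plane
# mounting transforms recorded as ground truth.

#' Simulate slicing of a phantom into histological sections
#'
#' @param phantom A [generate_phantom()] result (or any `phantom`-like list
#'   with a `volume` field).
#' @param mean_thickness_mm Nominal block thickness in mm (1 to 10; the
#'   conventional protocol uses 3 to 5).
#' @param spacing_jitter_mm Half-width of the uniform jitter applied to each
#'   block thickness (must be < `mean_thickness_mm`; thicknesses are rescaled
#'   so the stack spans the specimen).
#' @param shrink_healthy In-plane scale factor applied to healthy tissue
#'   outside the tumor (in (0.5, 1]; tumor pixels keep their size, with the
#'   transition blended radially).
#' @param rupture If `TRUE`, one randomly chosen section loses a peripheral
#'   wedge of tissue.
#' @param mount_rotation_deg,mount_translation_mm Half-widths of the uniform
#'   random in-plane rotation/translation each section receives when
#'   "mounted" (recorded as ground truth).
#' @param n_landmarks Landmarks per section (>= 3), taken on the section's
#'   true outer contour and carried through all applied maps.
#' @param seed Integer seed.
#' @return Object of class `section_stack`: `sections` (each with `image`,
#'   `thickness`, `y_center`, `landmarks_image`, `landmarks_ref`,
#'   `transform`), plus grid geometry (`dim2d`, `spacing2d`, `origin2d`,
#'   `y_spacing`, `y0`), `mean_thickness` and `length_mm`.
#' @export
simulate_sectioning <- function(phantom, mean_thickness_mm = 4,
                                spacing_jitter_mm = 1,
                                shrink_healthy = 0.95, rupture = FALSE,
                                mount_rotation_deg = 10,
                                mount_translation_mm = 2,
                                n_landmarks = 5L, seed = 1L) {
  vol <- if (inherits(phantom, "labeled_volume")) phantom else phantom$volume
  if (mean_thickness_mm < 1 || mean_thickness_mm > 10) {
    sm_error("mean thickness must be in [1, 10] mm",
             "specimargin_error_bad_thickness")
  }
  if (spacing_jitter_mm >= mean_thickness_mm) {
    sm_error("jitter >= mean thickness makes section order ambiguous",
             "specimargin_error_bad_jitter")
  }
  if (shrink_healthy <= 0.5 || shrink_healthy > 1) {
    sm_error("shrink_healthy must be in (0.5, 1]",
             "specimargin_error_bad_shrink")
  }
  if (n_landmarks < 3L) {
    sm_error("at least 3 landmarks per section required",
             "specimargin_error_too_few_landmarks")
  }
  d <- dim(vol$grid)
  support <- specimen_support(vol)
  ypresent <- which(apply(support, 2, any))
  ycent <- vol$origin[2] + (ypresent - 1) * vol$spacing[2]
  y0 <- min(ycent) - vol$spacing[2] / 2
  y1 <- max(ycent) + vol$spacing[2] / 2
  L <- y1 - y0
  nsec <- ceiling(L / mean_thickness_mm)
  xs <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1]
  zs <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  with_seed(seed, {
    th <- mean_thickness_mm + runif(nsec, -spacing_jitter_mm, spacing_jitter_mm)
    th <- th * L / sum(th)
    cuts <- y0 + c(0, cumsum(th))
    centers <- (head(cuts, -1) + tail(cuts, -1)) / 2
    rupture_sec <- if (isTRUE(rupture)) sample.int(nsec, 1L) else 0L
    sections <- vector("list", nsec)
    for (i in seq_len(nsec)) {
      jy <- which.min(abs(vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2]
                          - centers[i]))
      true_img <- vol$grid[, jy, ]
      sec <- build_section(true_img, xs, zs, shrink_healthy,
                           ruptured = (i == rupture_sec),
                           mount_rotation_deg, mount_translation_mm,
                           n_landmarks)
      sec$thickness <- th[i]
      sec$y_center <- centers[i]
      sections[[i]] <- sec
    }
    structure(list(sections = sections, dim2d = c(d[1], d[3]),
                   spacing2d = vol$spacing[c(1, 3)],
                   origin2d = vol$origin[c(1, 3)],
                   y_spacing = vol$spacing[2], y0 = y0, length_mm = L,
                   mean_thickness = L / nsec, seed = seed),
              class = "section_stack")
  })
}

#' @export
print.section_stack <- function(x, ...) {
  cat(sprintf("<section_stack> %d sections, mean thickness %.2f mm, span %.1f mm\n",
              length(x$sections), x$mean_thickness, x$length_mm))
  invisible(x)
}

# one section: differential shrink about the tumor, optional rupture,
# random mounting transform; landmarks carried through every map
build_section <- function(true_img, xs, zs, shrink, ruptured,
                          mount_rotation_deg, mount_translation_mm,
                          n_landmarks) {
  nx <- length(xs); nz <- length(zs)
  sup <- true_img != 0L
  tum <- true_img == specimen_labels()[["tumor"]]
  pix <- cbind(rep(xs, times = nz), rep(zs, each = nx))
  if (any(tum)) {
    cen <- colMeans(pix[as.vector(tum), , drop = FALSE])
    r_t <- max(sqrt(rowSums(sweep(pix[as.vector(tum), , drop = FALSE], 2, cen)^2)))
  } else if (any(sup)) {
    cen <- colMeans(pix[as.vector(sup), , drop = FALSE])
    r_t <- 0
  } else {
    cen <- c(mean(xs), mean(zs)); r_t <- 0
  }
  tf <- similarity_transform_2d(
    rotation_deg = runif(1, -mount_rotation_deg, mount_rotation_deg),
    scale = 1,
    translation_mm = runif(2, -mount_translation_mm, mount_translation_mm))
  # forward map: shrink radially outside the tumor, then mount
  fwd <- function(p) {
    v <- sweep(matrix(p, ncol = 2), 2, cen)
    r <- sqrt(rowSums(v^2))
    rs <- ifelse(r <= r_t, r, r_t + shrink * (r - r_t))
    f <- ifelse(r > 0, rs / r, 1)
    apply_transform(tf, sweep(v * f, 2, cen, `+`))
  }
  # image is built by inverse resampling on the same grid
  invp <- apply_transform(invert_transform(tf), pix)
  v <- sweep(invp, 2, cen)
  r <- sqrt(rowSums(v^2))
  rsrc <- ifelse(r <= r_t, r, r_t + (r - r_t) / shrink)
  f <- ifelse(r > 0, rsrc / r, 1)
  src <- sweep(v * f, 2, cen, `+`)
  ci <- round((src[, 1] - xs[1]) / (xs[2] - xs[1])) + 1
  cj <- round((src[, 2] - zs[1]) / (zs[2] - zs[1])) + 1
  ok <- ci >= 1 & ci <= nx & cj >= 1 & cj <= nz
  img <- integer(nx * nz)
  img[ok] <- true_img[cbind(ci[ok], cj[ok])]
  img <- matrix(img, nx, nz)
  if (ruptured && any(sup)) {
    az <- atan2(pix[, 2] - cen[2], pix[, 1] - cen[1])
    a0 <- runif(1, -pi, pi)
    dsec <- sqrt(rowSums(sweep(pix, 2, cen)^2))
    wedge <- abs(((az - a0 + pi) %% (2 * pi)) - pi) < deg2rad(15) &
      dsec > 0.35 * max(dsec[as.vector(sup)])
    img[matrix(wedge, nx, nz)] <- 0L
  }
  # landmarks: points on the true outer contour at spread azimuths
  lm_ref <- section_contour_landmarks(true_img, xs, zs, n_landmarks)
  lm_img <- fwd(lm_ref)
  list(image = img, landmarks_ref = lm_ref, landmarks_image = lm_img,
       transform = tf, shrink = shrink, ruptured = ruptured && any(sup))
}

# landmark picker: farthest support pixel within each azimuth bin
section_contour_landmarks <- function(img, xs, zs, n_landmarks) {
  sup <- which(img != 0L, arr.ind = TRUE)
  if (!nrow(sup)) return(matrix(numeric(0), 0, 2))
  pts <- cbind(xs[sup[, 1]], zs[sup[, 2]])
  cen <- colMeans(pts)
  v <- sweep(pts, 2, cen)
  az <- atan2(v[, 2], v[, 1])
  r <- sqrt(rowSums(v^2))
  target <- seq(-pi, pi, length.out = n_landmarks + 1)[seq_len(n_landmarks)] +
    runif(1, 0, 2 * pi / n_landmarks)
  out <- matrix(NA_real_, n_landmarks, 2)
  for (k in seq_len(n_landmarks)) {
    dd <- abs(((az - target[k] + pi) %% (2 * pi)) - pi)
    cand <- which(dd < pi / n_landmarks)
    if (!length(cand)) cand <- which.min(dd)
    out[k, ] <- pts[cand[which.max(r[cand])], ]
  }
  out
}
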