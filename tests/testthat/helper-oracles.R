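# Shared fixtures and independent brute-force oracles. Oracles here are
# written from the definitions directly (exhaustive loops, closed forms) and
# never call the code paths they check.

# digital ball: labeled volume with a spherical specimen and optional
# concentric/offset spherical tumor
make_ball_volume <- function(R = 10, r = NULL, spacing = 0.5,
                             tumor_center = c(0, 0, 0), pad = 2,
                             mucosa_cap_cos = NULL) {
  ext <- R + pad
  n <- ceiling(2 * ext / spacing) + 1
  org <- -(n - 1) / 2 * spacing
  x <- org + (seq_len(n) - 1) * spacing
  d2 <- outer(outer(x^2, x^2, `+`), x^2, `+`)
  grid <- array(0L, rep(n, 3))
  grid[d2 <= R^2] <- 1L
  if (!is.null(r)) {
    t2 <- outer(outer((x - tumor_center[1])^2, (x - tumor_center[2])^2, `+`),
                (x - tumor_center[3])^2, `+`)
    grid[t2 <= r^2] <- 2L
  }
  labeled_volume(grid, spacing = rep(spacing, 3), origin = rep(org, 3),
                 check_mucosa = FALSE)
}

# random small label grid with a guaranteed nonempty blob of each label
make_random_volume <- function(n = 20, spacing = c(0.5, 0.5, 2.0), seed = 1) {
  set.seed(seed)
  grid <- array(0L, rep(n, 3))
  cx <- sample(4:(n - 3), 3)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (sum(((c(i, j, k) - cx) * spacing)^2) <= (n * min(spacing) / 3)^2) {
      grid[i, j, k] <- 1L
    }
  }
  tum <- which(grid == 1L)
  grid[sample(tum, max(1, length(tum) %/% 8))] <- 2L
  labeled_volume(grid, spacing = spacing, origin = c(-1, 2, 0.5),
                 check_mucosa = FALSE)
}

# exhaustive all-pairs distance field oracle (mm, center-to-center):
# the full query-by-target squared-distance matrix, minimized per row
brute_distance_field <- function(vol, label_code) {
  d <- dim(vol$grid)
  tgt <- which(vol$grid == label_code)
  ai <- arrayInd(seq_len(prod(d)), d)
  pts <- sweep(ai - 1, 2, vol$spacing, `*`)
  array(brute_nn(pts, pts[tgt, , drop = FALSE]), d)
}

# brute-force nearest distance from each row of a to the point set b, via
# the complete pairwise squared-distance matrix (exact per-coordinate
# differences -- the expanded |a|^2+|b|^2-2ab form cancels catastrophically)
brute_nn <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2 +
    outer(a[, 3], b[, 3], `-`)^2
  sqrt(apply(d2, 1, min))
}

# percentile Hausdorff from the definition, via brute-force distances
brute_phd <- function(a, b, p) {
  max(quantile(brute_nn(a, b), p / 100, names = FALSE),
      quantile(brute_nn(b, a), p / 100, names = FALSE))
}

# independent per-vertex five-region classifier (same definitions as the
# partition: 45-degree cone from the apex along `down`, azimuth quadrants
# from the anterior direction, hint picks the craniomedial side)
oracle_regions <- function(verts, apex, down, anterior_point, posterior_point,
                           hint, half_angle = 45) {
  down <- down / sqrt(sum(down^2))
  ap <- anterior_point - posterior_point
  e1 <- ap - sum(ap * down) * down
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(down[2] * e1[3] - down[3] * e1[2],
          down[3] * e1[1] - down[1] * e1[3],
          down[1] * e1[2] - down[2] * e1[1])
  hperp <- hint - sum(hint * down) * down
  hint_az <- atan2(sum(hperp * e2), sum(hperp * e1)) * 180 / pi
  upper_cm <- hint_az >= 45 && hint_az < 135
  out <- character(nrow(verts))
  for (i in seq_len(nrow(verts))) {
    v <- verts[i, ] - apex
    along <- sum(v * down)
    perp <- sqrt(max(sum(v^2) - along^2, 0))
    if (along > 0 && atan2(perp, along) * 180 / pi <= half_angle) {
      out[i] <- "deep_central"
    } else {
      az <- atan2(sum(v * e2), sum(v * e1)) * 180 / pi
      out[i] <- if (az >= -45 && az < 45) "anterior"
        else if (az >= 135 || az < -135) "posterior"
        else if (az >= 45 && az < 135) {
          if (upper_cm) "craniomedial" else "caudolateral"
        } else {
          if (upper_cm) "caudolateral" else "craniomedial"
        }
    }
  }
  out
}

# minimal hand-built margin_map / region_partition pair for contract tests
mock_margin_inputs <- function(mins, threshold = 5) {
  k <- length(margin_regions())
  region <- factor(rep(margin_regions(), each = 2), levels = margin_regions())
  dist <- as.numeric(rbind(mins, mins + 1))
  map <- structure(list(distance_mm = dist, threshold_mm = threshold,
                        excluded = rep(FALSE, length(dist))),
                   class = "margin_map")
  part <- structure(list(region = region), class = "region_partition")
  list(map = map, partition = part)
}

# small synthetic section stack built directly (disk specimen, blob tumor)
make_synthetic_stack <- function(n_sections, tumor_sections, thickness,
                                 img_n = 30, spacing2d = c(1, 1),
                                 tumor_offset = c(0, -3)) {
  xs <- (seq_len(img_n) - (img_n + 1) / 2) * spacing2d[1]
  sections <- lapply(seq_len(n_sections), function(i) {
    img <- matrix(0L, img_n, img_n)
    pix2 <- outer(xs^2, xs^2, `+`)
    img[pix2 <= 10^2] <- 1L
    muc <- pix2 <= 10^2 & pix2 > 8.5^2 & outer(rep(1, img_n), xs) > 7
    img[muc] <- 3L
    if (i %in% tumor_sections) {
      t2 <- outer((xs - tumor_offset[1])^2, (xs - tumor_offset[2])^2, `+`)
      img[t2 <= 3^2] <- 2L
    }
    list(image = img, thickness = thickness,
         y_center = (i - 0.5) * thickness,
         landmarks_ref = cbind(c(0, 5, -5), c(9, -7, -7)),
         landmarks_image = cbind(c(0, 5, -5), c(9, -7, -7)),
         transform = similarity_transform_2d())
  })
  structure(list(sections = sections, dim2d = c(img_n, img_n),
                 spacing2d = spacing2d,
                 origin2d = c(xs[1], xs[1]), y_spacing = 1,
                 y0 = 0, length_mm = n_sections * thickness,
                 mean_thickness = thickness, seed = 0L),
            class = "section_stack")
}
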