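# Mucosa plane fitting, the deep cone and the five-region surface partition.

make_spec <- function(seed, spacing = 1.0, bump = 0.4) {
  set.seed(seed)
  cfg <- phantom_config(
    specimen_axes_mm = c(runif(1, 15, 20), runif(1, 18, 24), runif(1, 11, 15)),
    tumor_axes_mm = c(runif(1, 3, 6), runif(1, 3, 6), runif(1, 2.5, 5)),
    tumor_center_mm = c(runif(1, -3, 3), runif(1, -3, 3), runif(1, -4, 4)),
    spacing_mm = spacing, seed = seed, bumpiness_mm = bump)
  ph <- generate_phantom(cfg)
  list(ph = ph, spec = as_digital_specimen(ph$volume))
}

test_that("exactly coplanar mucosa vertices give that plane with zero residual", {
  set.seed(5)
  pts <- cbind(runif(50, -10, 10), runif(50, -10, 10), 0)
  pts3 <- pts %*% diag(3) + 1  # still coplanar (z = 1)
  mesh <- surface_mesh(rbind(pts3, c(0, 0, -20)),
                       cbind(1:50, c(2:50, 1), 51))
  spec <- structure(list(outer_surface = mesh,
                         mucosa_vertex_flags = c(rep(TRUE, 50), FALSE),
                         tumor_mask = array(TRUE, c(1, 1, 1)),
                         spacing = rep(1, 3), origin = c(0, 0, -20)),
                    class = "digital_specimen")
  pl <- fit_mucosa_plane(spec)
  expect_equal(abs(pl$unit_normal), c(0, 0, 1), tolerance = 1e-9)
  expect_lt(pl$rms_mm, 1e-9)
  expect_equal(pl$unit_normal[3], -1)  # oriented toward the interior (deep)
})

test_that("total-least-squares plane recovery under Gaussian displacement", {
  set.seed(8)
  n0 <- c(0.2, -0.1, 1); n0 <- n0 / sqrt(sum(n0^2))
  b1 <- c(1, 0, -n0[1] / n0[3]); b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(n0[2] * b1[3] - n0[3] * b1[2], n0[3] * b1[1] - n0[1] * b1[3],
          n0[1] * b1[2] - n0[2] * b1[1])
  uv <- cbind(runif(500, -10, 10), runif(500, -10, 10))
  pts <- uv %*% rbind(b1, b2) + cbind(rnorm(500, 0, 0.2)) %*% t(n0)
  mesh <- surface_mesh(rbind(pts, c(0, 0, -30)),
                       cbind(1:500, c(2:500, 1), 501))
  spec <- structure(list(outer_surface = mesh,
                         mucosa_vertex_flags = c(rep(TRUE, 500), FALSE),
                         tumor_mask = array(TRUE, c(1, 1, 1)),
                         spacing = rep(1, 3), origin = c(0, 0, -30)),
                    class = "digital_specimen")
  pl <- fit_mucosa_plane(spec)
  ang <- acos(min(abs(sum(pl$unit_normal * n0)), 1)) * 180 / pi
  expect_lt(ang, 2)
})

test_that("phantom mucosa cap recovers the deep direction", {
  s <- make_spec(3)
  pl <- fit_mucosa_plane(s$spec)
  ang <- acos(sum(pl$unit_normal * c(0, 0, -1))) * 180 / pi
  expect_lt(ang, 15)
})

test_that("cone apex defaults to the tumor centroid and override is exact", {
  vol <- make_ball_volume(R = 12, r = 4, spacing = 0.5,
                          tumor_center = c(2, -1, 3))
  spec <- as_digital_specimen(vol)
  pl <- plane(c(0, 0, 12), c(0, 0, -1))
  con <- build_deep_cone(spec, pl)
  expect_lt(max(abs(con$apex_mm - c(2, -1, 3))), 0.25)  # half a voxel
  con2 <- build_deep_cone(spec, pl, apex_override = c(1, 2, 3))
  expect_identical(con2$apex_mm, c(1, 2, 3))
  expect_error(cone(c(0, 0, 0), c(0, 0, 1), half_angle_deg = 95),
               class = "specimargin_error_bad_cone")
})

test_that("cone membership matches an independent 2D sector test", {
  con <- cone(c(1, 2, 3), c(0.3, -0.2, -1), half_angle_deg = 40)
  set.seed(12)
  pts <- matrix(runif(600, -20, 20), ncol = 3)
  got <- in_cone(con, pts)
  # 2D check in the plane containing the axis and each point
  w <- con$unit_axis
  for (i in seq_len(nrow(pts))) {
    v <- pts[i, ] - con$apex_mm
    along <- sum(v * w)
    perp <- sqrt(max(sum(v * v) - along^2, 0))
    in2d <- along > 0 && (atan2(perp, along) <= 40 * pi / 180)
    expect_identical(got[i], in2d)
  }
})

test_that("vertices along the anterior direction and cone boundary classify per tie-breaks", {
  apex <- c(0, 0, 0)
  con <- cone(apex, c(0, 0, -1), 45)
  verts <- rbind(c(0, 10, 0),    # exactly anterior
                 c(7, 0, -7),    # exactly on the 45-degree cone boundary
                 c(10, 0, 0),    # lateral, hint side
                 c(0, -10, 0))   # posterior
  mesh <- surface_mesh(verts, cbind(1, 2, 3))
  spec <- structure(list(outer_surface = mesh,
                         mucosa_vertex_flags = rep(FALSE, 4),
                         tumor_mask = array(TRUE, c(1, 1, 1)),
                         spacing = rep(1, 3), origin = c(0, 0, 0)),
                    class = "digital_specimen")
  part <- partition_surface(spec, con, anterior_point = c(0, 15, 0),
                            posterior_point = c(0, -15, 0),
                            craniomedial_hint = c(1, 0, 0))
  expect_identical(as.character(part$region),
                   c("anterior", "deep_central", "craniomedial", "posterior"))
})

test_that("partition equals the independent brute-force classifier on random phantoms", {
  for (seed in 1:10) {
    s <- make_spec(seed, spacing = 1.4, bump = 0.5)
    pl <- fit_mucosa_plane(s$spec)
    con <- build_deep_cone(s$spec, pl)
    part <- partition_surface(s$spec, con, s$ph$anterior_point,
                              s$ph$posterior_point, s$ph$craniomedial_hint)
    oracle <- oracle_regions(s$spec$outer_surface$vertices, con$apex_mm,
                             con$unit_axis, s$ph$anterior_point,
                             s$ph$posterior_point, s$ph$craniomedial_hint)
    expect_identical(as.character(part$region), oracle)
    # labels partition the vertex set: no gaps, all five present
    expect_false(anyNA(part$region))
    expect_setequal(unique(as.character(part$region)), margin_regions())
  }
})

test_that("region labels are invariant under a common rigid motion", {
  s <- make_spec(4, spacing = 1.4)
  pl <- fit_mucosa_plane(s$spec)
  con <- build_deep_cone(s$spec, pl)
  part <- partition_surface(s$spec, con, s$ph$anterior_point,
                            s$ph$posterior_point, s$ph$craniomedial_hint)
  th <- 0.6
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  shift <- c(5, -3, 2)
  rot <- function(p) sweep(matrix(p, ncol = 3) %*% t(Rz), 2, shift, `+`)
  mesh_r <- surface_mesh(rot(s$spec$outer_surface$vertices),
                         s$spec$outer_surface$faces)
  spec_r <- structure(list(outer_surface = mesh_r,
                           mucosa_vertex_flags = s$spec$mucosa_vertex_flags,
                           tumor_mask = s$spec$tumor_mask,
                           spacing = s$spec$spacing, origin = s$spec$origin),
                      class = "digital_specimen")
  con_r <- cone(as.numeric(rot(con$apex_mm)),
                as.numeric(Rz %*% con$unit_axis), con$half_angle_deg)
  part_r <- partition_surface(spec_r, con_r,
                              as.numeric(rot(s$ph$anterior_point)),
                              as.numeric(rot(s$ph$posterior_point)),
                              as.numeric(Rz %*% s$ph$craniomedial_hint))
  expect_identical(as.character(part_r$region), as.character(part$region))
})

test_that("degenerate reference points raise named errors", {
  s <- make_spec(6, spacing = 1.6)
  pl <- fit_mucosa_plane(s$spec)
  con <- build_deep_cone(s$spec, pl)
  expect_error(partition_surface(s$spec, con, c(0, 5, 0), c(0, 5, 0),
                                 c(1, 0, 0)),
               class = "specimargin_error_degenerate")
  expect_error(partition_surface(s$spec, con, s$ph$anterior_point,
                                 s$ph$posterior_point,
                                 s$ph$anterior_point - s$ph$posterior_point),
               class = "specimargin_error_degenerate")
})
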