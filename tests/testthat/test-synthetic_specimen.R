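# Phantom generator: ground-truth margins, determinism, observer
# perturbation, sectioning simulation.

test_that("concentric-ball phantom has 5 mm margins all around", {
  cfg <- phantom_config(specimen_axes_mm = c(15, 15, 15),
                        tumor_axes_mm = c(10, 10, 10),
                        tumor_center_mm = c(0, 0, 0),
                        spacing_mm = 0.6, bumpiness_mm = 0, seed = 1)
  ph <- generate_phantom(cfg)
  vd <- sqrt(3) * 0.6
  expect_true(all(abs(ph$truth_margins - 5.0) <= vd))
})

test_that("phantom generation is deterministic under a fixed seed", {
  cfg <- phantom_config(spacing_mm = 1.2, seed = 42, bumpiness_mm = 0.8)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$volume$grid, b$volume$grid)
  expect_identical(a$truth_margins, b$truth_margins)
})

test_that("displaced tumor shrinks the deep margin as constructed", {
  cfg <- phantom_config(specimen_axes_mm = c(15, 15, 15),
                        tumor_axes_mm = c(8, 8, 8),
                        tumor_center_mm = c(0, 0, -4),
                        spacing_mm = 0.6, bumpiness_mm = 0, seed = 1)
  ph <- generate_phantom(cfg)
  vd <- sqrt(3) * 0.6
  expect_lt(abs(ph$truth_margins[["deep_central"]] - 3.0), vd)
  expect_gt(ph$truth_margins[["craniomedial"]],
            ph$truth_margins[["deep_central"]])
  expect_gt(ph$truth_margins[["caudolateral"]],
            ph$truth_margins[["deep_central"]])
})

test_that("phantom config rejects impossible geometries", {
  expect_error(phantom_config(specimen_axes_mm = c(35, 25, 14)),
               class = "specimargin_error_container")
  expect_error(phantom_config(tumor_center_mm = c(0, 0, 12),
                              tumor_axes_mm = c(6, 7, 5)),
               class = "specimargin_error_tumor_outside")
  expect_error(phantom_config(spacing_mm = 5, tumor_axes_mm = c(6, 7, 5)),
               class = "specimargin_error_unresolved_tumor")
})

test_that("phantom volumes satisfy the labeled-volume invariants", {
  ph <- generate_phantom(phantom_config(spacing_mm = 1, seed = 3,
                                        bumpiness_mm = 0.6))
  # revalidation including the mucosa-on-boundary invariant must succeed
  expect_s3_class(labeled_volume(ph$volume$grid, ph$volume$spacing,
                                 ph$volume$origin, check_mucosa = TRUE),
                  "labeled_volume")
  expect_true(any(ph$volume$grid == 3L))
})

test_that("truth margins agree with the pipeline margin map on random phantoms", {
  set.seed(202)
  for (k in 1:6) {
    cfg <- phantom_config(
      specimen_axes_mm = c(runif(1, 15, 20), runif(1, 18, 24), runif(1, 11, 15)),
      tumor_axes_mm = c(runif(1, 3, 6), runif(1, 3, 6), runif(1, 2.5, 5)),
      tumor_center_mm = c(runif(1, -3, 3), runif(1, -3, 3), runif(1, -4, 4)),
      spacing_mm = 1.0, seed = k, bumpiness_mm = 0.4)
    ph <- generate_phantom(cfg)
    spec <- as_digital_specimen(ph$volume)
    pl <- fit_mucosa_plane(spec)
    con <- build_deep_cone(spec, pl)
    part <- partition_surface(spec, con, ph$anterior_point,
                              ph$posterior_point, ph$craniomedial_hint)
    mm <- compute_margin_map(spec, euclidean_distance_field(ph$volume, "tumor"))
    rep <- classify_regions(mm, part)
    got <- stats::setNames(rep$regions$min_margin_mm, rep$regions$region)
    diffs <- abs(got[names(ph$truth_margins)] - ph$truth_margins)
    expect_lt(max(diffs, na.rm = TRUE), sqrt(3) * 1.0)  # one voxel diagonal
  }
})

test_that("tumor outline perturbation: identity, dilation, annihilation", {
  vol <- make_ball_volume(R = 14, r = 6, spacing = 0.7)
  tm <- label_mask(vol, "tumor")
  expect_identical(perturb_tumor_outline(vol, 0, 0), tm)
  vd <- sqrt(3) * 0.7
  dil <- perturb_tumor_outline(vol, bias_mm = 2, roughness_mm = 0)
  expect_false(any(tm & !dil))  # dilation is a superset
  # every added voxel lies within 2 mm (+1 voxel diagonal) of the old support
  added <- which(dil & !tm)
  if (length(added)) {
    d <- dim(vol$grid)
    ap <- specimargin:::voxel_world_coords(added, d, vol$spacing, vol$origin)
    op <- specimargin:::voxel_world_coords(which(tm), d, vol$spacing, vol$origin)
    dd <- RANN::nn2(op, ap, k = 1)$nn.dists[, 1]
    expect_lte(max(dd), 2 + vd)
    expect_gte(min(dd), 0)
  }
  expect_error(perturb_tumor_outline(vol, bias_mm = -30, roughness_mm = 0),
               class = "specimargin_error_annihilated_tumor")
  # determinism of the noisy field
  a <- perturb_tumor_outline(vol, 1, 0.5, seed = 5)
  b <- perturb_tumor_outline(vol, 1, 0.5, seed = 5)
  expect_identical(a, b)
})

test_that("perturbation bias is recovered by the comparison statistics", {
  vol <- make_ball_volume(R = 14, r = 6, spacing = 0.7)
  tm <- label_mask(vol, "tumor")
  vd <- sqrt(3) * 0.7
  for (b in c(1, 3)) {
    dil <- perturb_tumor_outline(vol, bias_mm = b, roughness_mm = 0)
    cmp <- under_over_95hd(tm, dil, vol$spacing, vol$origin)
    expect_lte(abs(cmp$O95HD_mm - b), vd)
    expect_lte(cmp$U95HD_mm, vd)
  }
})

test_that("sectioning: count, determinism and precondition errors", {
  ph <- generate_phantom(phantom_config(spacing_mm = 1, seed = 8,
                                        bumpiness_mm = 0))
  st <- simulate_sectioning(ph, mean_thickness_mm = 4, spacing_jitter_mm = 0,
                            shrink_healthy = 1, seed = 2)
  L <- st$length_mm
  expect_identical(length(st$sections), as.integer(ceiling(L / 4)))
  st2 <- simulate_sectioning(ph, mean_thickness_mm = 4, spacing_jitter_mm = 0,
                             shrink_healthy = 1, seed = 2)
  expect_identical(lapply(st$sections, `[[`, "image"),
                   lapply(st2$sections, `[[`, "image"))
  expect_error(simulate_sectioning(ph, mean_thickness_mm = 3,
                                   spacing_jitter_mm = 3),
               class = "specimargin_error_bad_jitter")
  expect_error(simulate_sectioning(ph, mean_thickness_mm = 0.5),
               class = "specimargin_error_bad_thickness")
  expect_error(simulate_sectioning(ph, shrink_healthy = 0.3),
               class = "specimargin_error_bad_shrink")
  # landmark lists: at least 3 points per section
  expect_true(all(vapply(st$sections,
                         function(s) nrow(s$landmarks_image) >= 3, logical(1))))
})

test_that("artifact-free sectioning conserves tumor volume when restacked", {
  ph <- generate_phantom(phantom_config(spacing_mm = 0.8, seed = 5,
                                        bumpiness_mm = 0))
  st <- simulate_sectioning(ph, mean_thickness_mm = 4, spacing_jitter_mm = 0,
                            shrink_healthy = 1, mount_rotation_deg = 0,
                            mount_translation_mm = 0, seed = 1)
  stk <- stack_sections(st)  # identity transforms, true spacings
  v_true <- sum(label_mask(ph$volume, "tumor")) * prod(ph$volume$spacing)
  v_stack <- sum(label_mask(stk, "tumor")) * prod(stk$spacing)
  expect_lt(abs(v_stack / v_true - 1), 0.10)
})

test_that("healthy-tissue shrinkage spares the tumor diameter", {
  vol <- make_ball_volume(R = 14, r = 5, spacing = 0.5)
  st1 <- simulate_sectioning(vol, mean_thickness_mm = 4, spacing_jitter_mm = 0,
                             shrink_healthy = 1, mount_rotation_deg = 0,
                             mount_translation_mm = 0, seed = 1)
  st2 <- simulate_sectioning(vol, mean_thickness_mm = 4, spacing_jitter_mm = 0,
                             shrink_healthy = 0.9, mount_rotation_deg = 0,
                             mount_translation_mm = 0, seed = 1)
  mid <- which.max(vapply(st1$sections,
                          function(s) sum(s$image == 2L), numeric(1)))
  measure <- function(st) {
    img <- st$sections[[mid]]$image
    xs <- st$origin2d[1] + (seq_len(st$dim2d[1]) - 1) * st$spacing2d[1]
    tum <- which(img == 2L, arr.ind = TRUE)
    sup <- which(img != 0L, arr.ind = TRUE)
    c(diam = diff(range(xs[tum[, 1]])), extent = diff(range(xs[sup[, 1]])))
  }
  m1 <- measure(st1); m2 <- measure(st2)
  # tumor diameter preserved within one pixel
  expect_lte(abs(m2[["diam"]] - m1[["diam"]]), st1$spacing2d[1] + 1e-9)
  # healthy rim shrinks by about 10%
  rim1 <- m1[["extent"]] - m1[["diam"]]
  rim2 <- m2[["extent"]] - m2[["diam"]]
  expect_lt(abs(rim2 / rim1 - 0.9), 0.05)
})
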