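# Margin maps, per-region adequacy calls, and the conventional slice-based
# emulation.

test_that("concentric-ball margin map is uniformly near 5 mm", {
  vol <- make_ball_volume(R = 15, r = 10, spacing = 0.5)
  spec <- as_digital_specimen(vol)
  df <- euclidean_distance_field(vol, "tumor")
  mm <- compute_margin_map(spec, df)
  vd <- sqrt(3) * 0.5
  expect_true(all(abs(mm$distance_mm - 5.0) <= vd, na.rm = TRUE))
})

test_that("a tumor touching the outer surface gives a near-zero margin", {
  vol <- make_ball_volume(R = 12, r = 5, spacing = 0.5,
                          tumor_center = c(0, 0, 7))
  spec <- as_digital_specimen(vol)
  mm <- compute_margin_map(spec, euclidean_distance_field(vol, "tumor"))
  expect_lt(min(mm$distance_mm, na.rm = TRUE), sqrt(3) * 0.5)
})

test_that("margin map agrees with brute-force nearest-tumor search", {
  for (seed in c(2, 7, 19)) {
    set.seed(seed)
    cfg <- phantom_config(
      specimen_axes_mm = c(runif(1, 14, 18), runif(1, 16, 20), runif(1, 11, 14)),
      tumor_axes_mm = c(runif(1, 3, 5), runif(1, 3, 5), runif(1, 2.5, 4)),
      tumor_center_mm = c(runif(1, -2, 2), runif(1, -2, 2), runif(1, -3, 3)),
      spacing_mm = 1.4, seed = seed, bumpiness_mm = 0.5)
    ph <- generate_phantom(cfg)
    spec <- as_digital_specimen(ph$volume)
    mm <- compute_margin_map(spec, euclidean_distance_field(ph$volume, "tumor"))
    tpts <- specimargin:::voxel_world_coords(
      which(label_mask(ph$volume, "tumor")), dim(ph$volume$grid),
      ph$volume$spacing, ph$volume$origin)
    keep <- which(!is.na(mm$distance_mm))
    ref <- brute_nn(spec$outer_surface$vertices[keep, , drop = FALSE], tpts)
    expect_lt(max(abs(mm$distance_mm[keep] - ref)),
              sqrt(sum(ph$volume$spacing^2)))
  }
})

test_that("mucosa vertices are excluded unless the exclusion flag is off", {
  ph <- generate_phantom(phantom_config(spacing_mm = 1.2, seed = 2))
  spec <- as_digital_specimen(ph$volume)
  df <- euclidean_distance_field(ph$volume, "tumor")
  mm <- compute_margin_map(spec, df)
  expect_true(all(is.na(mm$distance_mm[spec$mucosa_vertex_flags])))
  mm2 <- compute_margin_map(spec, df, exclude_mucosa = FALSE)
  expect_false(anyNA(mm2$distance_mm))
})

test_that("adequacy calls use the strict 5 mm rule and flag empty regions", {
  m <- mock_margin_inputs(c(4.99, 5.0, 7.5, 0.2, 5.01))
  rep <- classify_regions(m$map, m$partition)
  expect_identical(rep$regions$call,
                   c("inadequate", "adequate", "adequate", "inadequate",
                     "adequate"))
  # a region whose vertices are all excluded is not assessable
  m2 <- mock_margin_inputs(c(6, 6, 6, 6, 6))
  m2$map$distance_mm[m2$partition$region == "anterior"] <- NA
  rep2 <- classify_regions(m2$map, m2$partition)
  expect_identical(rep2$regions$call[rep2$regions$region == "anterior"],
                   "not_assessable")
})

test_that("deep-only inadequacy is localized to the deep central region", {
  # constructed truth: deep margin ~4 mm, all other margins above threshold
  # (with a 45-degree cone the lateral minima sit at the cone boundary and
  # cannot exceed ~sqrt(2) x the deep margin, which bounds the separation)
  cfg <- phantom_config(specimen_axes_mm = c(16, 18, 12),
                        tumor_axes_mm = c(3, 3, 2),
                        tumor_center_mm = c(0, 0, -6),
                        spacing_mm = 0.7, bumpiness_mm = 0, seed = 1)
  ph <- generate_phantom(cfg)
  expect_lt(ph$truth_margins[["deep_central"]], 5)
  expect_true(all(ph$truth_margins[setdiff(margin_regions(), "deep_central")] > 5))
  spec <- as_digital_specimen(ph$volume)
  pl <- fit_mucosa_plane(spec)
  con <- build_deep_cone(spec, pl)
  part <- partition_surface(spec, con, ph$anterior_point, ph$posterior_point,
                            ph$craniomedial_hint)
  mm <- compute_margin_map(spec, euclidean_distance_field(ph$volume, "tumor"))
  rep <- classify_regions(mm, part)
  calls <- stats::setNames(rep$regions$call, rep$regions$region)
  expect_identical(calls[["deep_central"]], "inadequate")
  expect_true(all(calls[setdiff(margin_regions(), "deep_central")] == "adequate"))
})

test_that("dilating the tumor never increases any per-region minimum", {
  ph <- generate_phantom(phantom_config(spacing_mm = 1.0, seed = 6,
                                        bumpiness_mm = 0.4))
  vol <- ph$volume
  spec <- as_digital_specimen(vol)
  pl <- fit_mucosa_plane(spec)
  con <- build_deep_cone(spec, pl)
  part <- partition_surface(spec, con, ph$anterior_point, ph$posterior_point,
                            ph$craniomedial_hint)
  mins <- sapply(c(0, 1, 2), function(b) {
    tm <- if (b == 0) label_mask(vol, "tumor") else
      perturb_tumor_outline(vol, bias_mm = b, roughness_mm = 0)
    mm <- compute_margin_map(spec, euclidean_distance_field(vol, tm))
    classify_regions(mm, part)$regions$min_margin_mm
  })
  expect_true(all(diff(t(mins)) <= 1e-9))
})

test_that("anterior margin follows the tumor-free slice-count rule", {
  # 10 blocks of 4.3 mm; only the most anterior is tumor-free
  st <- make_synthetic_stack(10, tumor_sections = 1:9, thickness = 4.3)
  rep <- conventional_slice_margins(st)
  m <- stats::setNames(rep$regions$margin_mm, rep$regions$region)
  calls <- stats::setNames(rep$regions$call, rep$regions$region)
  expect_equal(m[["anterior"]], 4.3, tolerance = 1e-9)
  expect_identical(calls[["anterior"]], "inadequate")
  # tumor present in the first (most posterior) section
  expect_equal(m[["posterior"]], 0.0)
  # anterior/posterior margins quantized to multiples of the mean thickness
  expect_equal(m[["anterior"]] %% rep$mean_thickness_mm, 0, tolerance = 1e-9)
  st2 <- make_synthetic_stack(10, tumor_sections = 4:7, thickness = 4.3)
  rep2 <- conventional_slice_margins(st2)
  m2 <- stats::setNames(rep2$regions$margin_mm, rep2$regions$region)
  expect_equal(m2[["anterior"]], 3 * 4.3, tolerance = 1e-9)
  expect_equal(m2[["posterior"]], 3 * 4.3, tolerance = 1e-9)
})

test_that("conventional sector margins track the 3D margins on aligned sections", {
  cfg <- phantom_config(specimen_axes_mm = c(16, 18, 12),
                        tumor_axes_mm = c(4, 5, 3),
                        tumor_center_mm = c(0, 1, -4),
                        spacing_mm = 0.7, bumpiness_mm = 0, seed = 2)
  ph <- generate_phantom(cfg)
  rep <- conventional_slice_margins(ph$volume, mean_thickness_mm = 4)
  m <- stats::setNames(rep$regions$margin_mm, rep$regions$region)
  for (r in c("craniomedial", "caudolateral", "deep_central")) {
    expect_lt(abs(m[[r]] - ph$truth_margins[[r]]), 4)  # one section thickness
  }
  # the slice-count rule estimates the anterior/posterior axis gaps between
  # tumor and specimen extent; quantization error is below one block thickness
  sup_y <- which(apply(specimen_support(ph$volume), 2, any))
  tum_y <- which(apply(label_mask(ph$volume, "tumor"), 2, any))
  h <- ph$volume$spacing[2]
  gap_ant <- (max(sup_y) - max(tum_y)) * h
  gap_post <- (min(tum_y) - min(sup_y)) * h
  expect_lt(abs(m[["anterior"]] - gap_ant), 4)
  expect_lt(abs(m[["posterior"]] - gap_post), 4)
  expect_error(conventional_slice_margins(
    make_synthetic_stack(5, tumor_sections = integer(0), thickness = 4)),
    class = "specimargin_error_empty_tumor")
})

test_that("whole-specimen minimum equals the minimum over regions", {
  ph <- generate_phantom(phantom_config(spacing_mm = 1.1, seed = 9))
  spec <- as_digital_specimen(ph$volume)
  pl <- fit_mucosa_plane(spec)
  con <- build_deep_cone(spec, pl)
  part <- partition_surface(spec, con, ph$anterior_point, ph$posterior_point,
                            ph$craniomedial_hint)
  mm <- compute_margin_map(spec, euclidean_distance_field(ph$volume, "tumor"))
  rep <- classify_regions(mm, part)
  expect_equal(min(rep$regions$min_margin_mm, na.rm = TRUE),
               min(mm$distance_mm, na.rm = TRUE))
})
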