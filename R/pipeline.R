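# End-to-end study orchestration: simulate a cohort of phantoms, derive
# MR-like observer outlines and an HE-like reconstructed reference, map
# margins on both, and aggregate region-level diagnostic accuracy against
# the two reference standards (conventional slice-based emulation and the
# reconstructed HE digital specimen).

#' Study run configuration
#'
#' Defaults mirror the emulated study design: 9 specimens, two observers
#' whose outlines overestimate the tumor (positive bias) much more than they
#' underestimate it, sectioning at about 4 mm with 1 mm jitter, differential
#' healthy-tissue shrinkage, the 5 mm adequacy threshold, a 45-degree deep
#' cone and the 95th Hausdorff percentile.
#'
#' @param n_phantoms Number of synthetic specimens.
#' @param base_seed Integer master seed; every case seed derives from it.
#' @param spacing_mm Voxel spacing of the phantoms.
#' @param observer_bias_mm Named numeric: mean outline bias per simulated
#'   observer (positive = overestimation).
#' @param observer_roughness_mm Spatial sd of the outline noise.
#' @param mean_thickness_mm,spacing_jitter_mm,shrink_healthy,rupture
#'   Sectioning settings, see [simulate_sectioning()].
#' @param mount_rotation_deg,mount_translation_mm Section mounting-transform
#'   ranges, see [simulate_sectioning()].
#' @param threshold_mm Margin adequacy threshold.
#' @param half_angle_deg Deep-cone half angle.
#' @param percentile Hausdorff percentile.
#' @param bumpiness_mm Phantom surface bump amplitude.
#' @param output_dir Optional directory for CSV/JSON reports.
#' @return Object of class `run_config`.
#' @export
run_config <- function(n_phantoms = 9L, base_seed = 1L, spacing_mm = 0.3,
                       observer_bias_mm = c(R1 = 1.5, R2 = 0.8),
                       observer_roughness_mm = 0.6,
                       mean_thickness_mm = 4, spacing_jitter_mm = 1,
                       shrink_healthy = 0.95, rupture = FALSE,
                       mount_rotation_deg = 10, mount_translation_mm = 2,
                       threshold_mm = 5, half_angle_deg = 45,
                       percentile = 95, bumpiness_mm = 0.5,
                       output_dir = NULL) {
  if (half_angle_deg <= 0 || half_angle_deg >= 90) {
    sm_error("half angle must be in (0, 90)", "specimargin_error_bad_cone")
  }
  if (threshold_mm <= 0) {
    sm_error("threshold must be positive", "specimargin_error_bad_threshold")
  }
  structure(as.list(environment()), class = "run_config")
}

# random case geometry: tumor size at clinical depth-of-invasion scale, a
# deep gap spanning adequate and inadequate margins, mild lateral offsets
sample_case_config <- function(cfg, case_seed) {
  with_seed(case_seed, {
    sa <- c(runif(1, 16, 21), runif(1, 20, 26), runif(1, 12, 16))
    ta <- c(runif(1, 2.5, 7), runif(1, 2.5, 7.8), runif(1, 2, 6))
    deep_gap <- runif(1, 2, 9)
    tc <- c(runif(1, -0.4, 0.4) * (sa[1] - ta[1] - 2),
            runif(1, -0.4, 0.4) * (sa[2] - ta[2] - 2),
            -sa[3] + ta[3] + deep_gap)
    # shrink the offset until the tumor is strictly inside the ellipsoid
    repeat {
      ok <- sqrt(sum((tc / sa)^2)) + max(ta / sa) < 0.97
      if (ok) break
      tc <- tc * 0.9
    }
    phantom_config(specimen_axes_mm = sa, tumor_center_mm = tc,
                   tumor_axes_mm = ta, spacing_mm = cfg$spacing_mm,
                   seed = case_seed, bumpiness_mm = cfg$bumpiness_mm)
  })
}

# nearest-neighbor resampling of a mask from one grid onto another
resample_mask <- function(mask, src_spacing, src_origin,
                          dst_dim, dst_spacing, dst_origin) {
  idx_all <- arrayInd(seq_len(prod(dst_dim)), dst_dim)
  world <- sweep(sweep(idx_all - 1, 2, dst_spacing, `*`), 2, dst_origin, `+`)
  si <- round(sweep(sweep(world, 2, src_origin, `-`), 2, src_spacing, `/`)) + 1
  d <- dim(mask)
  ok <- si[, 1] >= 1 & si[, 1] <= d[1] & si[, 2] >= 1 & si[, 2] <= d[2] &
    si[, 3] >= 1 & si[, 3] <= d[3]
  out <- logical(prod(dst_dim))
  out[ok] <- mask[si[ok, , drop = FALSE]]
  array(out, dst_dim)
}

# one case: phantom, observer outlines, HE reconstruction, all reports
run_case <- function(cfg, case_id, case_seed) {
  pcfg <- sample_case_config(cfg, case_seed)
  ph <- generate_phantom(pcfg)
  vol <- ph$volume
  truth_calls <- ifelse(ph$truth_margins < cfg$threshold_mm,
                        "inadequate", "adequate")

  # pathologist's sectioning of the physical specimen
  stack <- simulate_sectioning(ph, mean_thickness_mm = cfg$mean_thickness_mm,
                               spacing_jitter_mm = cfg$spacing_jitter_mm,
                               shrink_healthy = cfg$shrink_healthy,
                               rupture = cfg$rupture,
                               mount_rotation_deg = cfg$mount_rotation_deg,
                               mount_translation_mm = cfg$mount_translation_mm,
                               seed = case_seed + 1L)
  conv <- conventional_slice_margins(stack, threshold_mm = cfg$threshold_mm)
  conv_calls <- stats::setNames(conv$regions$call, conv$regions$region)

  # HE digital specimen: register sections on their landmarks, stack with
  # true spacings, take the outer contour from the imaging volume
  transforms <- lapply(stack$sections, function(s) {
    fit_similarity_transform(s$landmarks_image, s$landmarks_ref)
  })
  stacked <- stack_sections(stack, transforms)
  he_tumor <- resample_mask(label_mask(stacked, "tumor"),
                            stacked$spacing, stacked$origin,
                            dim(vol$grid), vol$spacing, vol$origin)
  if (!any(he_tumor)) {
    sm_error("reconstructed HE tumor is empty", "specimargin_error_empty_tumor")
  }
  he_spec <- as_digital_specimen(vol, role = "HE-DS", observer = "pathologist",
                                 tumor_mask = he_tumor)
  mucosa_pl <- fit_mucosa_plane(he_spec)

  classify_specimen <- function(spec, tumor_mask) {
    con <- build_deep_cone(spec, mucosa_pl,
                           half_angle_deg = cfg$half_angle_deg)
    part <- partition_surface(spec, con, ph$anterior_point,
                              ph$posterior_point, ph$craniomedial_hint)
    df <- euclidean_distance_field(vol, tumor_mask)
    mm <- compute_margin_map(spec, df, threshold_mm = cfg$threshold_mm)
    rep <- classify_regions(mm, part)
    stats::setNames(rep$regions$call, rep$regions$region)
  }
  he_calls <- classify_specimen(he_spec, he_tumor)

  observers <- names(cfg$observer_bias_mm) %||%
    paste0("obs", seq_along(cfg$observer_bias_mm))
  obs_out <- list()
  for (k in seq_along(cfg$observer_bias_mm)) {
    om <- perturb_tumor_outline(vol, bias_mm = cfg$observer_bias_mm[[k]],
                                roughness_mm = cfg$observer_roughness_mm,
                                seed = case_seed + 100L + k)
    spec_o <- as_digital_specimen(vol, role = "MR-DS",
                                  observer = observers[k], tumor_mask = om)
    calls_o <- classify_specimen(spec_o, om)
    cmp <- under_over_95hd(reference_tumor = he_tumor, test_tumor = om,
                           spacing = vol$spacing, origin = vol$origin,
                           p = cfg$percentile)
    obs_out[[observers[k]]] <- list(calls = calls_o, comparison = cmp)
  }
  list(case_id = case_id, seed = case_seed,
       truth_margins = ph$truth_margins, truth_calls = truth_calls,
       conventional = conv, conventional_calls = conv_calls,
       he_calls = he_calls, observers = obs_out)
}

#' Run a full simulated margin-assessment study
#'
#' For each phantom: generate the specimen, simulate the observers' MR-like
#' tumor outlines, simulate sectioning, register and stack the sections into
#' an HE-like digital specimen, partition all surfaces into the five margin
#' regions, map margins at the threshold, and compare: per-case under/over
#' percentile-Hausdorff distances of each observer's tumor against the HE
#' reconstruction, and cohort diagnostic accuracy of the observers' calls
#' against both reference standards.
#'
#' @param config A [run_config()].
#' @return Object of class `study_report`: `cases` (per-case results),
#'   `case_table` (data frame of U/O distances per observer),
#'   `accuracy_vs_heds`, `accuracy_vs_conventional` (per-observer
#'   [diagnostic_accuracy()] reports), `slots_per_comparison`, `failed`.
#' @export
run_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  case_seeds <- with_seed(config$base_seed,
                          sample.int(2^30, config$n_phantoms))
  cases <- list(); failed <- list()
  for (i in seq_len(config$n_phantoms)) {
    res <- tryCatch(run_case(config, i, case_seeds[i]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed[[length(failed) + 1]] <- list(case_id = i,
                                           message = conditionMessage(res))
    } else {
      cases[[length(cases) + 1]] <- res
    }
  }
  observers <- names(config$observer_bias_mm) %||%
    paste0("obs", seq_along(config$observer_bias_mm))
  case_table <- do.call(rbind, lapply(cases, function(cs) {
    do.call(rbind, lapply(observers, function(o) {
      cmp <- cs$observers[[o]]$comparison
      data.frame(case = cs$case_id, observer = o,
                 U95HD_mm = cmp$U95HD_mm, O95HD_mm = cmp$O95HD_mm,
                 intersection_mm3 = cmp$intersection_volume_mm3)
    }))
  }))
  collect_calls <- function(o, ref_field) {
    test <- unlist(lapply(cases, function(cs) cs$observers[[o]]$calls))
    ref <- unlist(lapply(cases, function(cs) cs[[ref_field]]))
    keep <- test %in% c("inadequate", "adequate") &
      ref %in% c("inadequate", "adequate")
    list(test = test[keep], ref = ref[keep], n_slots = length(test))
  }
  acc_he <- list(); acc_conv <- list()
  for (o in observers) {
    ch <- collect_calls(o, "he_calls")
    acc_he[[o]] <- diagnostic_accuracy(ch$test, ch$ref)
    cc <- collect_calls(o, "conventional_calls")
    acc_conv[[o]] <- diagnostic_accuracy(cc$test, cc$ref)
  }
  report <- structure(list(config = config, cases = cases,
                           case_table = case_table,
                           accuracy_vs_heds = acc_he,
                           accuracy_vs_conventional = acc_conv,
                           slots_per_comparison =
                             length(cases) * length(margin_regions()),
                           failed = failed),
                      class = "study_report")
  if (!is.null(config$output_dir)) write_study_report(report, config$output_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d cases (%d failed), %d region slots per comparison\n",
              length(x$cases), length(x$failed), x$slots_per_comparison))
  if (!is.null(x$case_table)) {
    cat(sprintf("  U95HD %.1f-%.1f mm, O95HD %.1f-%.1f mm\n",
                min(x$case_table$U95HD_mm, na.rm = TRUE),
                max(x$case_table$U95HD_mm, na.rm = TRUE),
                min(x$case_table$O95HD_mm, na.rm = TRUE),
                max(x$case_table$O95HD_mm, na.rm = TRUE)))
  }
  for (o in names(x$accuracy_vs_heds)) {
    cat(sprintf("-- observer %s vs HE-DS --\n", o))
    print(x$accuracy_vs_heds[[o]])
  }
  invisible(x)
}

# CSV/JSON artifacts under a run directory, with a manifest of seeds/config
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$case_table, file.path(dir, "case_table.csv"),
            row.names = FALSE)
  acc <- lapply(list(vs_heds = report$accuracy_vs_heds,
                     vs_conventional = report$accuracy_vs_conventional),
                function(ref) lapply(ref, function(a) {
                  list(counts = as.list(a$counts), metrics = a$metrics)
                }))
  jsonlite::write_json(acc, file.path(dir, "accuracy.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(package = "specimargin",
                   version = as.character(utils::packageVersion("specimargin")),
                   base_seed = report$config$base_seed,
                   n_phantoms = report$config$n_phantoms,
                   threshold_mm = report$config$threshold_mm,
                   failed_cases = length(report$failed))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
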