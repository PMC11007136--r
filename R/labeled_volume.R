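#' Semantic label codes used in labeled volumes
#'
#' @return Named integer vector mapping semantic names to label codes:
#'   background = 0, specimen = 1, tumor = 2, mucosa = 3.
#' @export
#' @examples
#' specimen_labels()
specimen_labels <- function() {
  c(background = 0L, specimen = 1L, tumor = 2L, mucosa = 3L)
}

#' Labeled volume: a voxel grid with semantic labels
#'
#' The substrate for all geometry. Voxels carry one of four labels
#' (see [specimen_labels()]); the *specimen support* is the union of the
#' specimen, tumor and mucosa labels. Voxel `(i,j,k)` (1-based) has its center
#' at `origin + (c(i,j,k) - 1) * spacing`, all in millimetres.
#'
#' @param grid 3D integer array of label codes in `{0, 1, 2, 3}`.
#' @param spacing Numeric length-3, voxel edge lengths in mm (strictly
#'   positive; may be anisotropic).
#' @param origin Numeric length-3, world position in mm of the center of the
#'   first voxel.
#' @param check_mucosa If `TRUE`, verify that every mucosa voxel lies on the
#'   boundary of the specimen support (has at least one background 6-neighbor).
#' @return An object of class `labeled_volume` with fields `grid`, `spacing`,
#'   `origin`.
#' @export
labeled_volume <- function(grid, spacing, origin = c(0, 0, 0),
                           check_mucosa = TRUE) {
  if (!is.array(grid) || length(dim(grid)) != 3L) {
    sm_error("grid must be a 3D array", "specimargin_error_bad_grid")
  }
  g <- grid
  if (is.double(g)) {
    if (any(g != round(g))) {
      sm_error("grid contains non-integer label values",
               "specimargin_error_non_integer")
    }
    storage.mode(g) <- "integer"
  }
  if (!is.integer(g)) {
    sm_error("grid must be integer-valued", "specimargin_error_non_integer")
  }
  bad <- setdiff(unique(as.vector(g)), unname(specimen_labels()))
  if (length(bad)) {
    sm_error(sprintf("unknown label code(s): %s", paste(bad, collapse = ", ")),
             "specimargin_error_unknown_label")
  }
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    sm_error("spacing must be 3 strictly positive numbers (mm)",
             "specimargin_error_bad_spacing")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    sm_error("origin must be 3 finite numbers (mm)",
             "specimargin_error_bad_origin")
  }
  vol <- structure(list(grid = g, spacing = spacing, origin = origin),
                   class = "labeled_volume")
  if (check_mucosa) {
    muc <- g == specimen_labels()[["mucosa"]]
    if (any(muc)) {
      onb <- boundary_voxels(specimen_support(vol))
      if (any(muc & !onb)) {
        sm_error("mucosa voxels must lie on the specimen-support boundary",
                 "specimargin_error_interior_mucosa")
      }
    }
  }
  vol
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$grid)
  counts <- table(factor(x$grid, levels = unname(specimen_labels()),
                         labels = names(specimen_labels())))
  cat(sprintf("<labeled_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat("  origin (mm):", paste(signif(x$origin, 4), collapse = ", "), "\n")
  cat("  voxels:", paste(sprintf("%s=%d", names(counts), counts),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Specimen support mask
#'
#' Logical mask of the specimen support: the union of the specimen, tumor and
#' mucosa labels.
#'
#' @param vol A [labeled_volume()].
#' @return Logical 3D array.
#' @export
specimen_support <- function(vol) {
  vol$grid != specimen_labels()[["background"]]
}

#' Mask of one label
#'
#' @param vol A [labeled_volume()].
#' @param label Label name (`"tumor"`, ...) or integer code.
#' @return Logical 3D array.
#' @export
label_mask <- function(vol, label) {
  code <- if (is.character(label)) specimen_labels()[[label]] else as.integer(label)
  vol$grid == code
}

#' Write a labeled volume to NIfTI
#'
#' Stores the label grid as a single-channel integer NIfTI file with voxel
#' spacing in `pixdim` and origin in the qform/sform. NIfTI headers hold
#' spacing and origin as 32-bit floats; values not representable in single
#' precision (e.g. 0.3) are rounded to it on disk.
#'
#' @param vol A [labeled_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_labeled_volume <- function(vol, path) {
  arr <- vol$grid
  a2 <- structure(arr, pixdim = vol$spacing, pixunits = c("mm", "s"))
  img <- RNifti::asNifti(a2, datatype = "int16")
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  RNifti::`qform<-`(img, structure(m, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a labeled volume from NIfTI
#'
#' @param path Path to a single-channel integer NIfTI file with labels in
#'   `{0, 1, 2, 3}`.
#' @param check_mucosa Passed to [labeled_volume()].
#' @return A [labeled_volume()] with spacing and origin taken from the header.
#' @export
load_labeled_volume <- function(path, check_mucosa = FALSE) {
  if (!file.exists(path)) {
    sm_error(sprintf("file not found: %s", path), "specimargin_error_missing_file")
  }
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    sm_error("expected a single-channel 3D volume", "specimargin_error_bad_grid")
  }
  vals <- as.vector(img[])
  if (any(vals != round(vals))) {
    sm_error("volume does not hold integer labels", "specimargin_error_non_integer")
  }
  arr <- array(as.integer(vals), dim(img))
  spacing <- as.numeric(RNifti::pixdim(img))[1:3]
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  labeled_volume(arr, spacing = spacing, origin = origin,
                 check_mucosa = check_mucosa)
}
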