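#' Write a mesh to ASCII PLY
#'
#' Optional per-vertex channels: `margin_mm` (float) and `region` (int),
#' matching the margin-map and region-partition exports.
#'
#' @param mesh A [surface_mesh()].
#' @param path Output `.ply` path.
#' @param margin_mm Optional numeric per-vertex margin distances (NA allowed;
#'   written as -1, the conventional "excluded" sentinel).
#' @param region Optional integer or factor per-vertex region labels.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, margin_mm = NULL, region = NULL) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  props <- c("property float x", "property float y", "property float z")
  cols <- format(mesh$vertices, trim = TRUE, digits = 9)
  if (!is.null(margin_mm)) {
    stopifnot(length(margin_mm) == nv)
    mm <- ifelse(is.na(margin_mm), -1, margin_mm)
    props <- c(props, "property float margin_mm")
    cols <- cbind(cols, format(mm, trim = TRUE, digits = 9))
  }
  if (!is.null(region)) {
    stopifnot(length(region) == nv)
    props <- c(props, "property int region")
    cols <- cbind(cols, as.integer(region))
  }
  hdr <- c("ply", "format ascii 1.0",
           "comment produced by specimargin",
           sprintf("element vertex %d", nv), props,
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  vlines <- do.call(paste, c(split(cols, col(cols)), sep = " "))
  flines <- paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                  mesh$faces[, 3] - 1L)
  writeLines(c(hdr, vlines, flines), path)
  invisible(path)
}

#' Read an ASCII PLY mesh written by [write_ply()]
#'
#' @param path Path to the `.ply` file.
#' @return A [surface_mesh()]; any `margin_mm` / `region` channels are
#'   attached as attributes of the same names (margin sentinel -1 mapped back
#'   to NA).
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) {
    sm_error(sprintf("file not found: %s", path), "specimargin_error_missing_file")
  }
  lines <- readLines(path)
  end <- match("end_header", lines)
  hdr <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  vstart <- grep("^element vertex", hdr)
  vend <- grep("^element (face|end)|^end_header", hdr)
  vprops <- sub("^property \\S+ ", "",
                grep("^property (float|int)", hdr, value = TRUE))
  vtab <- read.table(text = lines[(end + 1):(end + nv)], col.names = vprops)
  ftab <- read.table(text = lines[(end + nv + 1):(end + nv + nf)])
  mesh <- surface_mesh(as.matrix(vtab[, c("x", "y", "z")]),
                       as.matrix(ftab[, 2:4]) + 1L)
  if ("margin_mm" %in% vprops) {
    mm <- vtab$margin_mm
    mm[mm < 0] <- NA_real_
    attr(mesh, "margin_mm") <- mm
  }
  if ("region" %in% vprops) attr(mesh, "region") <- as.integer(vtab$region)
  mesh
}

#' Write a mesh to ASCII STL (no per-vertex scalars)
#'
#' @param mesh A [surface_mesh()].
#' @param path Output `.stl` path.
#' @param name Solid name.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, name = "specimen") {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  fmt <- function(p) paste(format(p[, 1], trim = TRUE), format(p[, 2], trim = TRUE),
                           format(p[, 3], trim = TRUE))
  lines <- c(sprintf("solid %s", name),
             as.vector(rbind(
               sprintf("  facet normal %s", fmt(n)),
               "    outer loop",
               sprintf("      vertex %s", fmt(v[f[, 1], , drop = FALSE])),
               sprintf("      vertex %s", fmt(v[f[, 2], , drop = FALSE])),
               sprintf("      vertex %s", fmt(v[f[, 3], , drop = FALSE])),
               "    endloop",
               "  endfacet")),
             sprintf("endsolid %s", name))
  writeLines(lines, path)
  invisible(path)
}
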