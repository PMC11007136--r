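#' Triangulated surface mesh
#'
#' @param vertices n x 3 numeric matrix of world coordinates in mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices, consistently
#'   oriented (counter-clockwise seen from outside).
#' @param scalar Optional per-vertex numeric channel.
#' @return Object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, scalar = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices))) {
    sm_error("face vertex indices out of range", "specimargin_error_bad_faces")
  }
  if (!is.null(scalar) && length(scalar) != nrow(vertices)) {
    sm_error("scalar channel length must equal vertex count",
             "specimargin_error_bad_scalar")
  }
  structure(list(vertices = vertices, faces = faces, scalar = scalar),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Extract the isosurface of a label support
#'
#' Builds a closed, watertight triangulated surface of the indicator function
#' of the requested labels at iso-level 0.5, by dual contouring ("surface
#' nets"): one vertex per boundary cell, placed at the mean of the cell's
#' edge-crossing midpoints, quads across every inside/outside voxel face,
#' split into triangles. Vertices are in world mm.
#'
#' @param vol A [labeled_volume()], or a logical mask array (then `spacing` /
#'   `origin` must be given).
#' @param support Label names or codes whose union forms the solid
#'   (default: the whole specimen support, labels 1, 2, 3).
#' @param smoothing If `TRUE`, apply two rounds of neighborhood averaging to
#'   the vertex positions (shrinks sharp voxel steps; off by default so that
#'   analytic area/volume checks stay tight).
#' @param pad If `TRUE` (default), the mask is padded internally so supports
#'   touching the grid edge still produce a closed surface; with `pad = FALSE`
#'   such supports are an error.
#' @param spacing,origin Grid geometry when `vol` is a bare mask.
#' @return A [surface_mesh()].
#' @export
extract_surface <- function(vol, support = c("specimen", "tumor", "mucosa"),
                            smoothing = FALSE, pad = TRUE,
                            spacing = NULL, origin = NULL) {
  if (inherits(vol, "labeled_volume")) {
    codes <- vapply(support, function(s) {
      if (is.character(s)) specimen_labels()[[s]] else as.integer(s)
    }, integer(1))
    mask <- array(vol$grid %in% codes, dim(vol$grid))
    spacing <- vol$spacing; origin <- vol$origin
  } else {
    mask <- vol
    stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
    mask <- array(as.logical(mask), dim(vol))
    if (is.null(spacing) || is.null(origin)) {
      sm_error("spacing and origin required for a bare mask",
               "specimargin_error_bad_grid")
    }
  }
  if (!any(mask)) {
    sm_error("requested support is empty", "specimargin_error_empty_support")
  }
  d <- dim(mask)
  touches <- any(mask[c(1, d[1]), , ]) || any(mask[, c(1, d[2]), ]) ||
    any(mask[, , c(1, d[3])])
  if (touches && !pad) {
    sm_error("support touches the grid boundary; pad the volume first",
             "specimargin_error_unpadded_support")
  }
  mesh <- surface_nets(mask, spacing, origin)
  if (isTRUE(smoothing)) mesh <- smooth_mesh(mesh, iterations = 2L)
  mesh
}

# dual-contouring core; mask padded by one background voxel on all sides
surface_nets <- function(mask, spacing, origin) {
  d <- dim(mask)
  m <- array(FALSE, d + 2L)
  m[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  d2 <- dim(m)
  nc <- d2 - 1L  # dual cells span padded voxels (i..i+1, j..j+1, k..k+1)
  idx <- function(di, dj, dk) m[(1:nc[1]) + di, (1:nc[2]) + dj, (1:nc[3]) + dk]
  occ8 <- list(idx(0,0,0), idx(1,0,0), idx(0,1,0), idx(1,1,0),
               idx(0,0,1), idx(1,0,1), idx(0,1,1), idx(1,1,1))
  s <- Reduce(`+`, occ8)
  active <- which(s > 0L & s < 8L)
  corners <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(1,1,0),
                   c(0,0,1), c(1,0,1), c(0,1,1), c(1,1,1))
  cube_edges <- rbind(c(1,2), c(3,4), c(5,6), c(7,8),
                      c(1,3), c(2,4), c(5,7), c(6,8),
                      c(1,5), c(2,6), c(3,7), c(4,8))
  occ <- vapply(occ8, function(a) a[active], logical(length(active)))
  pos <- matrix(0, length(active), 3)
  cnt <- numeric(length(active))
  for (e in seq_len(nrow(cube_edges))) {
    a <- cube_edges[e, 1]; b <- cube_edges[e, 2]
    cross <- occ[, a] != occ[, b]
    if (any(cross)) {
      mid <- (corners[a, ] + corners[b, ]) / 2
      pos[cross, ] <- pos[cross, ] + matrix(mid, sum(cross), 3, byrow = TRUE)
      cnt[cross] <- cnt[cross] + 1
    }
  }
  pos <- pos / cnt
  ai <- arrayInd(active, nc)
  # padded voxel i corresponds to original voxel i-1; cell-local coords are in
  # voxel units from the cell's lower-corner voxel center
  verts <- sweep((ai - 2 + pos) %*% diag(spacing), 2, origin, `+`)
  cellid <- array(0L, nc)
  cellid[active] <- seq_along(active)
  others <- list(c(2, 3), c(1, 3), c(1, 2))
  quads <- vector("list", 3)
  for (ax in 1:3) {
    sh <- c(0L, 0L, 0L); sh[ax] <- 1L
    a <- m[1:(d2[1] - sh[1]), 1:(d2[2] - sh[2]), 1:(d2[3] - sh[3])]
    b <- m[(1 + sh[1]):d2[1], (1 + sh[2]):d2[2], (1 + sh[3]):d2[3]]
    ch <- which(a != b)
    if (!length(ch)) next
    ei <- arrayInd(ch, dim(a))
    u <- others[[ax]][1]; v <- others[[ax]][2]
    low_inside <- a[ch]
    q <- matrix(0L, nrow(ei), 4)
    combo <- rbind(c(1, 1), c(0, 1), c(0, 0), c(1, 0))
    for (kk in 1:4) {
      du <- combo[kk, 1]; dv <- combo[kk, 2]
      ii <- ei
      ii[, u] <- ii[, u] - du
      ii[, v] <- ii[, v] - dv
      q[, kk] <- cellid[ii]
    }
    flip <- !low_inside
    q[flip, ] <- q[flip, 4:1, drop = FALSE]
    if (ax == 2) q <- q[, 4:1, drop = FALSE]
    quads[[ax]] <- q
  }
  quads <- do.call(rbind, quads)
  tris <- rbind(quads[, c(1, 2, 3)], quads[, c(1, 3, 4)])
  surface_mesh(verts, tris)
}

# light Laplacian relaxation; keeps topology, pulls vertices toward neighbors
smooth_mesh <- function(mesh, iterations = 2L, lambda = 0.5) {
  f <- mesh$faces
  ed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  ed <- rbind(ed, ed[, 2:1])
  ed <- unique(ed)
  v <- mesh$vertices
  deg <- tabulate(ed[, 1], nbins = nrow(v))
  for (it in seq_len(iterations)) {
    nbsum <- rowsum(v[ed[, 2], , drop = FALSE], ed[, 1])
    mean_nb <- nbsum / deg
    v <- v + lambda * (mean_nb - v)
  }
  surface_mesh(v, f, mesh$scalar)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh A [surface_mesh()].
#' @return Numeric scalar.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Enclosed volume of a closed mesh (mm^3)
#'
#' Signed tetrahedron sum; positive for consistent outward orientation.
#' @param mesh A closed [surface_mesh()].
#' @param signed If `FALSE` (default) return the absolute volume.
#' @return Numeric scalar.
#' @export
mesh_volume <- function(mesh, signed = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  s <- sum(p1[, 1] * (p2[, 2] * p3[, 3] - p3[, 2] * p2[, 3]) -
           p2[, 1] * (p1[, 2] * p3[, 3] - p3[, 2] * p1[, 3]) +
           p3[, 1] * (p1[, 2] * p2[, 3] - p2[, 2] * p1[, 3])) / 6
  if (signed) s else abs(s)
}

#' Check that a mesh is watertight and consistently oriented
#'
#' Watertight: every undirected edge is shared by exactly two faces.
#' Consistently oriented: every directed half-edge appears exactly once.
#'
#' @param mesh A [surface_mesh()].
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  dir_key <- paste(he[, 1], he[, 2])
  und_key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  all(table(und_key) == 2L) && !anyDuplicated(dir_key)
}
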