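# internal helpers: classed errors, small vector algebra, seeded RNG scope

sm_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "specimargin_error"), call = call))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

normalize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) sm_error("cannot normalize a zero vector", "specimargin_error_degenerate")
  v / n
}

# evaluate expr with a locally seeded RNG, restoring global RNG state after
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# one voxel diagonal in mm -- the pipeline's natural discretization tolerance
voxel_diagonal <- function(spacing) sqrt(sum(spacing^2))

# logical 3D array: voxels with at least one 6-neighbor outside `mask`
# (or on the array edge, which counts as outside)
boundary_voxels <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  inner <- mask
  shift_and <- function(m, ax, dir) {
    d <- dim(m)
    res <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (dir > 0) {
      idx_src[[ax]] <- 1:(d[ax] - 1); idx_dst[[ax]] <- 2:d[ax]
    } else {
      idx_src[[ax]] <- 2:d[ax]; idx_dst[[ax]] <- 1:(d[ax] - 1)
    }
    res[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    res
  }
  has_outside_nb <- array(FALSE, d)
  for (ax in 1:3) for (dir in c(-1, 1)) {
    nb_inside <- shift_and(mask, ax, dir)  # TRUE where neighbor in -dir is inside
    has_outside_nb <- has_outside_nb | (!nb_inside)
  }
  mask & has_outside_nb
}

# world coordinates (n x 3) of voxel centers for linear indices into a grid
voxel_world_coords <- function(idx, dim, spacing, origin) {
  ai <- arrayInd(idx, dim)
  sweep(sweep(ai - 1, 2, spacing, `*`), 2, origin, `+`)
}
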