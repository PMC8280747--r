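#' Axis-aligned voxel grid specification
#'
#' @param origin Coordinates of the first voxel centre, angstrom.
#' @param spacing Voxel edge length, angstrom.
#' @param dims Integer vector of three voxel counts.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(origin, spacing, dims) {
  stopifnot(length(origin) == 3, length(dims) == 3)
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0) {
    abort("spacing must be a positive scalar")
  }
  dims <- as.integer(dims)
  if (any(dims < 1)) abort("grid dims must all be >= 1")
  structure(list(origin = as.numeric(origin), spacing = spacing, dims = dims),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, spacing %g A, origin (%.2f, %.2f, %.2f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# Canonical atom-set representation: coords matrix, radii, ids.
as_atom_set <- function(x, frame = 0L, roles = c("core", "ligand"),
                        include_hydrogens = TRUE) {
  if (inherits(x, "frame_series")) {
    keep <- x$atoms$role %in% roles
    if (!include_hydrogens) keep <- keep & x$atoms$element != "H"
    co <- frame_coords(x, frame)[keep, , drop = FALSE]
    list(coords = co, radii = x$atoms$radius[keep], ids = x$atoms$atom_id[keep])
  } else if (is.data.frame(x)) {
    stopifnot(all(c("x", "y", "z", "radius") %in% names(x)))
    if (!include_hydrogens && "element" %in% names(x)) x <- x[x$element != "H", ]
    list(coords = unname(as.matrix(x[, c("x", "y", "z")])), radii = x$radius,
         ids = x$atom_id %||% seq_len(nrow(x)))
  } else if (is.list(x) && !is.null(x$coords)) {
    x
  } else {
    abort("Cannot interpret atom set; give a frame_series or a data frame with x,y,z,radius.")
  }
}

#' Fit a voxel grid around an atom set
#'
#' The grid is the axis-aligned bounding box of the atom spheres, expanded
#' by `padding` on every side and discretised at `spacing`.  `padding` must
#' be at least the largest probe radius that will be used plus one spacing,
#' so that the outer rim of the grid lies in bulk solvent.
#'
#' @param atoms Atom set: a `frame_series`, or a data frame with columns
#'   `x`, `y`, `z`, `radius`.
#' @param spacing Voxel edge, angstrom (default 0.5).
#' @param padding Box expansion, angstrom (default 5 = big probe + 2).
#' @param frame Frame to use when `atoms` is a `frame_series`.
#' @return A [grid_spec()].
#' @export
#' @examples
#' at <- data.frame(x = 0, y = 0, z = 0, radius = 1.5)
#' make_grid(at, spacing = 0.5, padding = 4)
make_grid <- function(atoms, spacing = 0.5, padding = 5, frame = 0L) {
  if (!is.numeric(spacing) || spacing <= 0) abort("spacing must be > 0")
  if (padding < 0) abort("padding must be >= 0")
  a <- as_atom_set(atoms, frame = frame)
  if (nrow(a$coords) == 0) abort("empty atom set")
  lo <- apply(a$coords - a$radii, 2, min) - padding
  hi <- apply(a$coords + a$radii, 2, max) + padding
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  grid_spec(lo, spacing, dims)
}

#' Voxel centre coordinates for linear indices
#' @param grid A [grid_spec()].
#' @param lin 1-based linear voxel indices (column-major); default all.
#' @return Matrix of xyz coordinates, angstrom.
#' @export
voxel_centers <- function(grid, lin = NULL) {
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  if (is.null(lin)) lin <- seq_len(as.double(nx) * ny * nz)
  lin0 <- lin - 1
  i <- lin0 %% nx
  j <- (lin0 %/% nx) %% ny
  k <- lin0 %/% (as.double(nx) * ny)
  cbind(
    grid$origin[1] + i * grid$spacing,
    grid$origin[2] + j * grid$spacing,
    grid$origin[3] + k * grid$spacing
  )
}

#' Clearance field of an atom set on a grid
#'
#' For every voxel centre v, the clearance is `min_i(|v - x_i| - r_i)`:
#' the signed distance to the nearest atom sphere surface (negative inside
#' an atom), capped above at `cap`.  The field drives both the probe
#' rasterisation and the erosion step of the SES computation.
#'
#' @inheritParams make_grid
#' @param grid A [grid_spec()].
#' @param cap Upper cap on the stored clearance, angstrom.
#' @return Numeric array of dimension `grid$dims`.
#' @export
compute_clearance <- function(atoms, grid, cap = 6, frame = 0L) {
  a <- as_atom_set(atoms, frame = frame)
  if (nrow(a$coords) == 0) abort("empty atom set")
  cl <- cpp_clearance_field(a$coords, a$radii, grid$origin, grid$spacing,
                            grid$dims, cap)
  array(cl, dim = grid$dims)
}

#' Region enclosed by the solvent-excluded surface on a voxel grid
#'
#' The solvent-excluded (Connolly) surface is the boundary of the region a
#' spherical probe rolling on the van der Waals surface cannot enter.  On
#' the grid this is computed as: (1) rasterise the analytic clearance field
#' (exact per atom); (2) mark probe centres with clearance above the probe
#' radius as free, and keep only the free region connected to the grid
#' boundary (bulk solvent) -- probe positions sealed inside a closed cavity
#' cannot be reached by rolling and do not excavate it; (3) a voxel is
#' outside the SES iff it lies within the reach `|u - v| < c(u)` of some
#' accessible free voxel `u` (a probe centred anywhere in the clearance
#' ball of `u` stays collision-free, by the 1-Lipschitz property of the
#' clearance field).  Step (3) is an additively-weighted (power) distance
#' transform.  Ties land inside, so the van der Waals voxelisation is
#' always contained in the SES region exactly.  With `probe_radius = 0`
#' the van der Waals voxelisation itself is returned.
#'
#' @inheritParams compute_clearance
#' @param probe_radius Probe radius, angstrom (>= 0).
#' @param clearance Optional precomputed [compute_clearance()] array (must
#'   match `grid` and `cap`); computed when `NULL`.
#' @return An `ses_volume`: list with `grid`, logical array `inside`,
#'   `probe_radius`.
#' @export
compute_ses <- function(atoms, probe_radius, grid, cap = 6, clearance = NULL,
                        frame = 0L) {
  if (!is.numeric(probe_radius) || probe_radius < 0) abort("probe_radius must be >= 0")
  if (cap <= probe_radius) abort("clearance cap must exceed the probe radius")
  a <- as_atom_set(atoms, frame = frame)
  # padding contract: every atom sphere inflated by the probe plus one
  # spacing must fit in the box, so the rim is bulk solvent
  need <- probe_radius + grid$spacing
  lo_ok <- all(apply(a$coords - a$radii, 2, min) - need >= grid$origin)
  hi <- grid$origin + (grid$dims - 1L) * grid$spacing
  hi_ok <- all(apply(a$coords + a$radii, 2, max) + need <= hi)
  if (!lo_ok || !hi_ok) {
    abort("padding violation: grid does not contain the atom spheres inflated by the probe; rebuild with make_grid(padding >= probe + spacing)")
  }
  if (is.null(clearance)) clearance <- compute_clearance(a, grid, cap = cap)
  if (probe_radius == 0) {
    inside <- clearance <= 0
  } else {
    open <- clearance > probe_radius
    acc <- array(cpp_accessible(as.logical(open), grid$dims), dim = grid$dims)
    w_vox <- pmin(clearance, cap) / grid$spacing
    f <- ifelse(acc, -(w_vox^2), Inf)
    pw <- cpp_dt_sampled(as.numeric(f), grid$dims)
    # ties (a probe exactly tangent to the voxel centre) are inside; the
    # tolerance absorbs floating-point rounding of exact tangencies
    inside <- array(pw >= -1e-9, dim = grid$dims)
  }
  structure(list(grid = grid, inside = inside, probe_radius = probe_radius),
            class = "ses_volume")
}

#' @export
print.ses_volume <- function(x, ...) {
  cat(sprintf("<ses_volume> probe %g A, %d inside voxels, volume %.1f A^3\n",
              x$probe_radius, sum(x$inside), enclosed_volume(x)))
  invisible(x)
}

#' Volume enclosed by a solvent-excluded surface
#'
#' @param ses An `ses_volume` from [compute_ses()].
#' @return Volume in cubic angstrom: inside-voxel count times spacing cubed.
#' @export
enclosed_volume <- function(ses) {
  sum(ses$inside) * ses$grid$spacing^3
}

# Voxels adjacent (26-connectivity) to the inside/outside boundary of a mask.
surface_shell <- function(mask) {
  d <- dim(mask)
  shell <- array(FALSE, dim = d)
  for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    xs <- max(1, 1 + di):min(d[1], d[1] + di)
    ys <- max(1, 1 + dj):min(d[2], d[2] + dj)
    zs <- max(1, 1 + dk):min(d[3], d[3] + dk)
    xd <- max(1, 1 - di):min(d[1], d[1] - di)
    yd <- max(1, 1 - dj):min(d[2], d[2] - dj)
    zd <- max(1, 1 - dk):min(d[3], d[3] - dk)
    shell[xd, yd, zd] <- shell[xd, yd, zd] |
      (mask[xd, yd, zd] != mask[xs, ys, zs])
  }
  shell
}
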