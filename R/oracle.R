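# Brute-force SES oracle.  Deliberately shares no code with the grid
# engine: probe positions are enumerated on a dense candidate lattice,
# collision-freedom is evaluated analytically against every atom, bulk
# accessibility is established with an igraph component search, and a
# point is outside the SES iff some accessible collision-free probe
# centre lies within the probe radius of it.

#' Build a brute-force SES oracle on a dense candidate lattice
#'
#' @param atoms Atom set (see [make_grid()]).
#' @param probe Probe radius, angstrom.
#' @param resolution Candidate-lattice spacing, angstrom; when `grid` is
#'   given it is snapped to an integer refinement of the grid spacing so
#'   that grid voxel centres coincide with lattice points.
#' @param grid Optional engine [grid_spec()] to align with; otherwise a
#'   box with `padding` around the atoms is used.
#' @param padding Box padding when no grid is given, angstrom.
#' @return An `ses_oracle` object.
#' @export
oracle_ses <- function(atoms, probe, resolution = 0.2, grid = NULL,
                       padding = probe + 2) {
  a <- as_atom_set(atoms)
  if (!is.null(grid)) {
    refine <- max(1L, as.integer(round(grid$spacing / resolution)))
    res <- grid$spacing / refine
    origin <- grid$origin
    dims <- (grid$dims - 1L) * refine + 1L
  } else {
    refine <- NA_integer_
    res <- resolution
    lo <- apply(a$coords - a$radii, 2, min) - padding
    hi <- apply(a$coords + a$radii, 2, max) + padding
    origin <- lo
    dims <- as.integer(ceiling((hi - lo) / res)) + 1L
  }
  xs <- origin[1] + (seq_len(dims[1]) - 1) * res
  ys <- origin[2] + (seq_len(dims[2]) - 1) * res
  zs <- origin[3] + (seq_len(dims[3]) - 1) * res
  cl <- array(Inf, dim = dims)
  for (i in seq_len(nrow(a$coords))) {
    d2 <- outer(outer((xs - a$coords[i, 1])^2, (ys - a$coords[i, 2])^2, `+`),
                (zs - a$coords[i, 3])^2, `+`)
    cl <- pmin(cl, sqrt(d2) - a$radii[i])
  }
  free <- cl >= probe # a probe centred here overlaps no atom (ties free)
  acc <- free & oracle_bulk_component(free)
  structure(list(origin = origin, res = res, dims = dims, probe = probe,
                 refine = refine, acc = acc, clearance = cl),
            class = "ses_oracle")
}

# Free-lattice component(s) connected to the box boundary, via an
# explicit 6-neighbour graph.
oracle_bulk_component <- function(free) {
  d <- dim(free)
  n <- prod(d)
  id <- array(seq_len(n), dim = d)
  edge_pairs <- function(axis) {
    idx_a <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx_b <- idx_a
    idx_a[[axis]] <- seq_len(d[axis] - 1L)
    idx_b[[axis]] <- 2:d[axis]
    fa <- free[idx_a[[1]], idx_a[[2]], idx_a[[3]], drop = FALSE]
    fb <- free[idx_b[[1]], idx_b[[2]], idx_b[[3]], drop = FALSE]
    m <- fa & fb
    cbind(id[idx_a[[1]], idx_a[[2]], idx_a[[3]], drop = FALSE][m],
          id[idx_b[[1]], idx_b[[2]], idx_b[[3]], drop = FALSE][m])
  }
  e <- rbind(edge_pairs(1), edge_pairs(2), edge_pairs(3))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(e) > 0) g <- igraph::add_edges(g, as.vector(t(e)))
  memb <- igraph::components(g)$membership
  boundary <- array(FALSE, dim = d)
  boundary[c(1, d[1]), , ] <- TRUE
  boundary[, c(1, d[2]), ] <- TRUE
  boundary[, , c(1, d[3])] <- TRUE
  bulk_comps <- unique(memb[boundary & free])
  array(memb %in% bulk_comps, dim = d)
}

#' Is a point inside the solvent-excluded surface? (brute force)
#'
#' The point is outside iff an accessible collision-free probe centre on
#' the dense candidate lattice lies within the probe radius of it
#' (exhaustive search over the probe-ball of candidates around the
#' point).
#'
#' @param atoms Atom set; ignored when `oracle` is supplied.
#' @param probe Probe radius, angstrom; ignored when `oracle` is supplied.
#' @param point xyz position, angstrom.
#' @param resolution Candidate-lattice spacing, angstrom.
#' @param oracle Optional prebuilt [oracle_ses()] (reuse across points).
#' @return `TRUE` when the point is inside the SES region.
#' @export
oracle_point_in_ses <- function(atoms, probe, point, resolution = 0.2,
                                oracle = NULL) {
  orc <- oracle %||% oracle_ses(atoms, probe, resolution)
  d <- orc$dims
  ijk <- (point - orc$origin) / orc$res
  probe_eff <- orc$probe + orc$res / 2
  r_vox <- probe_eff / orc$res
  rng <- lapply(1:3, function(ax) {
    lo <- max(1L, as.integer(floor(ijk[ax] - r_vox)) + 1L)
    hi <- min(d[ax], as.integer(ceiling(ijk[ax] + r_vox)) + 1L)
    if (lo > hi) integer() else lo:hi
  })
  if (any(lengths(rng) == 0)) return(TRUE)
  sub <- orc$acc[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  if (!any(sub)) return(TRUE)
  xs <- orc$origin[1] + (rng[[1]] - 1) * orc$res - point[1]
  ys <- orc$origin[2] + (rng[[2]] - 1) * orc$res - point[2]
  zs <- orc$origin[3] + (rng[[3]] - 1) * orc$res - point[3]
  d2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
  !any(sub & d2 <= probe_eff^2)
}

# Bulk coverage query at lattice points given by 1-based linear indices
# into the oracle lattice.  Offsets are visited nearest-first and already
# covered points are dropped as they resolve.
oracle_covered_lin <- function(orc, lin) {
  d <- orc$dims
  # midpoint allowance: a continuum probe centre can sit up to half a
  # lattice step from the nearest candidate, so the coverage radius
  # carries half-lattice slack (keeps the estimate unbiased under
  # refinement)
  probe_eff <- orc$probe + orc$res / 2
  rmax <- as.integer(floor(probe_eff / orc$res))
  pad <- rmax + 1L
  pd <- d + 2L * pad
  accp <- array(FALSE, dim = pd)
  accp[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- orc$acc
  # map lattice lin -> padded lin
  lin0 <- lin - 1
  i <- lin0 %% d[1]
  j <- (lin0 %/% d[1]) %% d[2]
  k <- lin0 %/% (as.double(d[1]) * d[2])
  plin <- 1 + (i + pad) + pd[1] * ((j + pad) + pd[2] * (k + pad))
  offs <- expand.grid(i = -rmax:rmax, j = -rmax:rmax, k = -rmax:rmax)
  o2 <- offs$i^2 + offs$j^2 + offs$k^2
  keep <- o2 * orc$res^2 <= probe_eff^2
  offs <- offs[keep, ]
  offs <- offs[order(o2[keep]), ]
  olin <- offs$i + pd[1] * (offs$j + pd[2] * offs$k)
  accv <- as.vector(accp)
  covered <- logical(length(lin))
  rem <- seq_along(lin)
  for (t in seq_along(olin)) {
    hit <- accv[plin[rem] + olin[t]]
    if (any(hit)) {
      covered[rem[hit]] <- TRUE
      rem <- rem[!hit]
      if (length(rem) == 0) break
    }
  }
  covered
}

#' Oracle SES membership at the voxel centres of an engine grid
#'
#' @param orc An [oracle_ses()] built with `grid` alignment.
#' @param grid The engine [grid_spec()].
#' @return Logical array over the engine grid: inside the SES.
#' @export
oracle_inside_grid <- function(orc, grid) {
  if (is.na(orc$refine)) abort("oracle was not built aligned to a grid")
  k <- orc$refine
  d <- grid$dims
  io <- (seq_len(d[1]) - 1L) * k
  jo <- (seq_len(d[2]) - 1L) * k
  ko <- (seq_len(d[3]) - 1L) * k
  lin <- 1 + outer(outer(io, jo * orc$dims[1], `+`),
                   ko * as.double(orc$dims[1]) * orc$dims[2], `+`)
  covered <- oracle_covered_lin(orc, as.vector(lin))
  array(!covered, dim = d)
}

#' Agreement between the grid engine and the brute-force oracle
#'
#' Voxel-wise agreement between [compute_ses()] and the oracle over all
#' voxels not in the one-voxel surface shell of the engine mask (the
#' shell carries sub-voxel discretisation ambiguity on both sides).
#'
#' @param ses An `ses_volume`.
#' @param atoms The atom set it was computed from.
#' @param resolution Oracle lattice spacing; default half the grid
#'   spacing.
#' @return List: `agreement` (fraction), `n_compared`, `oracle_inside`
#'   (logical array).
#' @export
oracle_agreement <- function(ses, atoms, resolution = ses$grid$spacing / 2) {
  orc <- oracle_ses(atoms, ses$probe_radius, resolution, grid = ses$grid)
  o_in <- oracle_inside_grid(orc, ses$grid)
  shell <- surface_shell(ses$inside)
  cmp <- !shell
  agree <- sum((ses$inside == o_in) & cmp) / sum(cmp)
  list(agreement = agree, n_compared = sum(cmp), oracle_inside = o_in)
}

#' Brute-force pocket volumes
#'
#' Fine-lattice integration of the dual-probe pocket region using only
#' the oracle machinery: a lattice point belongs to the pocket region
#' when it is inside the large-probe SES and outside the small-probe
#' SES; 6-connected components are measured and those below `min_volume`
#' dropped.
#'
#' @param atoms Atom set.
#' @param params [pocket_params()]; the two probe radii and `min_volume`
#'   are used.
#' @param resolution Lattice spacing, angstrom (0.25 or finer for
#'   reference volumes).
#' @return Numeric vector of pocket volumes, cubic angstrom, sorted
#'   decreasing (empty when none); all component volumes before the
#'   volume filter are attached as attribute `all_volumes`.
#' @export
oracle_pocket_volume <- function(atoms, params = pocket_params(),
                                 resolution = 0.25) {
  a <- as_atom_set(atoms)
  orc_b <- oracle_ses(a, params$probe_big, resolution,
                      padding = params$probe_big + 2)
  orc_s <- oracle_ses(a, params$probe_small, resolution, grid = NULL,
                      padding = params$probe_big + 2)
  stopifnot(all(orc_b$dims == orc_s$dims))
  # the pocket region lies within max(radius) + probe_big of some atom;
  # integrate over the atom bounding box inflated accordingly
  margin <- max(a$radii) + params$probe_big
  lo <- apply(a$coords, 2, min) - margin
  hi <- apply(a$coords, 2, max) + margin
  rng <- lapply(1:3, function(ax) {
    lo_i <- max(1L, as.integer(floor((lo[ax] - orc_b$origin[ax]) / orc_b$res)) + 1L)
    hi_i <- min(orc_b$dims[ax], as.integer(ceiling((hi[ax] - orc_b$origin[ax]) / orc_b$res)) + 1L)
    lo_i:hi_i
  })
  sub_dims <- lengths(rng)
  id <- array(seq_len(prod(orc_b$dims)), dim = orc_b$dims)
  lin <- as.vector(id[rng[[1]], rng[[2]], rng[[3]]])
  in_big <- !oracle_covered_lin(orc_b, lin)
  pocket <- array(FALSE, dim = sub_dims)
  if (any(in_big)) {
    out_small <- oracle_covered_lin(orc_s, lin[in_big])
    pocket[which(in_big)[out_small]] <- TRUE
  }
  if (!any(pocket)) {
    return(structure(numeric(), all_volumes = numeric()))
  }
  comp <- oracle_label6(pocket)
  vols <- sort(tabulate(comp[comp > 0]) * orc_b$res^3, decreasing = TRUE)
  structure(vols[vols >= params$min_volume], all_volumes = vols)
}

# 6-connected labelling of a small boolean array via igraph components.
oracle_label6 <- function(mask) {
  d <- dim(mask)
  n <- prod(d)
  id <- array(seq_len(n), dim = d)
  edge_pairs <- function(axis) {
    idx_a <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx_b <- idx_a
    idx_a[[axis]] <- seq_len(d[axis] - 1L)
    idx_b[[axis]] <- 2:d[axis]
    ma <- mask[idx_a[[1]], idx_a[[2]], idx_a[[3]], drop = FALSE]
    mb <- mask[idx_b[[1]], idx_b[[2]], idx_b[[3]], drop = FALSE]
    m <- ma & mb
    cbind(id[idx_a[[1]], idx_a[[2]], idx_a[[3]], drop = FALSE][m],
          id[idx_b[[1]], idx_b[[2]], idx_b[[3]], drop = FALSE][m])
  }
  e <- rbind(edge_pairs(1), edge_pairs(2), edge_pairs(3))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(e) > 0) g <- igraph::add_edges(g, as.vector(t(e)))
  memb <- igraph::components(g)$membership
  lab <- array(0L, dim = d)
  lab[mask] <- as.integer(factor(memb[as.vector(mask)]))
  lab
}
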