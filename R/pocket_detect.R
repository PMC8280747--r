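#' Pocket-detection parameters
#'
#' Defaults follow the dual-probe convention for monolayer pockets: a
#' water-sized 1.4 A small probe, a 3 A large probe, and a 100 cubic
#' angstrom minimum pocket volume (about the molecular volume of
#' salicylate, or three bulk waters).  The depth threshold splitting deep
#' from shallow pockets is 1.3 nm from the metal-core centre of mass.
#'
#' @param probe_small Small probe radius, angstrom.
#' @param probe_big Large probe radius, angstrom.
#' @param min_volume Minimum pocket volume kept, cubic angstrom.
#' @param spacing Voxel edge, angstrom.
#' @param connectivity Voxel connectivity for component labelling (6, 18
#'   or 26).
#' @param wall_contact_margin Atom-to-pocket contact margin for wall-atom
#'   assignment, angstrom; defaults to the small probe radius.
#' @param depth_threshold_nm Deep/shallow boundary, nm.
#' @param padding Grid padding, angstrom; defaults to `probe_big + 2`.
#' @param clearance_cap Cap on the stored clearance field, angstrom; must
#'   exceed `probe_big`.
#' @param include_hydrogens Include hydrogens in the surface rasterisation.
#' @param occupancy_threshold Fraction of an analyte's heavy atoms that
#'   must sit in the (probe-dilated) pocket region for the analyte to be
#'   counted inside.
#' @return A `pocket_params` list.
#' @export
pocket_params <- function(probe_small = 1.4, probe_big = 3.0, min_volume = 100,
                          spacing = 0.5, connectivity = 26,
                          wall_contact_margin = probe_small,
                          depth_threshold_nm = 1.3,
                          padding = probe_big + 2,
                          clearance_cap = max(6, probe_big + 2),
                          include_hydrogens = TRUE,
                          occupancy_threshold = 0.5) {
  if (probe_small >= probe_big) abort("probe_small must be < probe_big")
  if (probe_small < 0) abort("probe radii must be >= 0")
  if (min_volume <= 0) abort("min_volume must be > 0")
  if (spacing <= 0) abort("spacing must be > 0")
  if (!connectivity %in% c(6L, 18L, 26L)) abort("connectivity must be 6, 18 or 26")
  if (padding < probe_big + spacing) abort("padding must be >= probe_big + spacing")
  if (clearance_cap <= probe_big) abort("clearance_cap must exceed probe_big")
  structure(list(
    probe_small = probe_small, probe_big = probe_big, min_volume = min_volume,
    spacing = spacing, connectivity = as.integer(connectivity),
    wall_contact_margin = wall_contact_margin,
    depth_threshold_nm = depth_threshold_nm, padding = padding,
    clearance_cap = clearance_cap, include_hydrogens = include_hydrogens,
    occupancy_threshold = occupancy_threshold
  ), class = "pocket_params")
}

#' Core centre of mass of a frame
#'
#' Mass-weighted centre of the `role = "core"` atoms, masses from the
#' element table.
#'
#' @param frames A [frame_series()].
#' @param frame 0-based frame index.
#' @return Numeric xyz, angstrom, or `NULL` if there are no core atoms.
#' @export
core_center_of_mass <- function(frames, frame = 0L) {
  core <- frames$atoms$role == "core"
  if (!any(core)) return(NULL)
  co <- frame_coords(frames, frame)[core, , drop = FALSE]
  m <- frames$atoms$mass[core]
  if (anyNA(m)) m[is.na(m)] <- mean(m, na.rm = TRUE)
  as.numeric(colSums(co * m) / sum(m))
}

#' Classify pocket depth
#'
#' A pocket is deep when its centre lies closer to the metal-core centre
#' of mass than the threshold; a depth exactly at the threshold is
#' shallow.
#'
#' @param depth_nm Depth value(s), nm (>= 0).
#' @param threshold_nm Deep/shallow boundary, nm (default 1.3).
#' @return Character vector `"deep"`/`"shallow"`.
#' @export
#' @examples
#' classify_depth(c(1.1, 1.5, 1.3))
classify_depth <- function(depth_nm, threshold_nm = 1.3) {
  if (any(depth_nm < 0, na.rm = TRUE)) abort("depth must be >= 0")
  ifelse(is.na(depth_nm), NA_character_,
         ifelse(depth_nm < threshold_nm, "deep", "shallow"))
}

#' Detect pockets in one or more frames
#'
#' A candidate pocket region is the set of voxels inside the SES of the
#' large probe but outside the SES of the small probe.  Its 26-connected
#' components are labelled, components below `min_volume` are discarded,
#' and survivors are sorted by volume (descending; ties broken by
#' lexicographic centre) with `pocket_id` assigned from 0 in that order.
#' For each pocket the centre (unweighted mean of voxel centres), the
#' depth (distance from the core centre of mass, nm), the wall atoms, and
#' -- when a fragment map is supplied -- the fragment fingerprint are
#' recorded.
#'
#' @param frames A [frame_series()] (solvent and ion atoms are excluded
#'   from the surface; analyte atoms do not contribute to the receptor
#'   surface either).
#' @param params A [pocket_params()] list.
#' @param fmap Optional [parse_fragment_map()] result for fingerprints.
#' @param frame Integer vector of 0-based frame indices; default all.
#' @param core_com Optional explicit core centre of mass (xyz, angstrom);
#'   by default computed from `role = "core"` atoms, and depth left `NA`
#'   when there are none.
#' @return A tibble of class `pocket_table`, one row per (frame, pocket),
#'   with a `voxels` list-column holding each pocket's voxel centres.
#' @export
detect_pockets <- function(frames, params = pocket_params(), fmap = NULL,
                           frame = NULL, core_com = NULL) {
  stopifnot(inherits(frames, "frame_series"))
  if (is.null(frame)) frame <- seq_len(n_frames(frames)) - 1L
  rows <- purrr::map(frame, function(f) {
    detect_pockets_frame(frames, params, fmap, f, core_com)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- empty_pocket_table()
    out$voxels <- list()
  }
  structure(out, class = c("pocket_table", class(out)),
            n_frames_analyzed = length(frame), params = params)
}

detect_pockets_frame <- function(frames, params, fmap, frame, core_com) {
  a <- as_atom_set(frames, frame = frame, roles = c("core", "ligand"),
                   include_hydrogens = params$include_hydrogens)
  if (nrow(a$coords) == 0) abort("empty atom set (no core or ligand atoms)")
  grid <- make_grid(a, spacing = params$spacing, padding = params$padding)
  cl <- compute_clearance(a, grid, cap = params$clearance_cap)
  ses_small <- compute_ses(a, params$probe_small, grid,
                           cap = params$clearance_cap, clearance = cl)
  ses_big <- compute_ses(a, params$probe_big, grid,
                         cap = params$clearance_cap, clearance = cl)
  pocket_mask <- ses_big$inside & !ses_small$inside
  lab <- cpp_label_components(as.logical(pocket_mask), grid$dims,
                              params$connectivity)
  if (all(lab == 0L)) return(NULL)
  vox_per_vol <- grid$spacing^3
  counts <- tabulate(lab)
  keep <- which(counts * vox_per_vol >= params$min_volume)
  if (length(keep) == 0) return(NULL)
  if (is.null(core_com)) {
    ccom <- core_center_of_mass(frames, frame)
  } else {
    ccom <- core_com
  }
  pockets <- purrr::map(keep, function(lb) {
    lin <- which(lab == lb)
    vc <- voxel_centers(grid, lin)
    center <- colMeans(vc)
    list(volume = length(lin) * vox_per_vol, center = center, voxels = vc)
  })
  vols <- vapply(pockets, `[[`, 0, "volume")
  cx <- vapply(pockets, function(p) p$center[1], 0)
  cy <- vapply(pockets, function(p) p$center[2], 0)
  cz <- vapply(pockets, function(p) p$center[3], 0)
  ord <- order(-vols, cx, cy, cz)
  pockets <- pockets[ord]
  rows <- purrr::imap(pockets, function(p, i) {
    depth <- if (is.null(ccom)) NA_real_ else sqrt(sum((p$center - ccom)^2)) / 10
    wall <- wall_atoms(p$voxels, a, params)
    fp <- c(NA_integer_, NA_integer_, NA_integer_)
    nlig <- NA_integer_
    if (!is.null(fmap)) {
      res <- fingerprint_counts(wall, fmap)
      fp <- res$key
      nlig <- res$n_ligands
    }
    tibble(
      frame = as.integer(frame), pocket_id = i - 1L, volume = p$volume,
      x = p$center[1], y = p$center[2], z = p$center[3],
      depth_nm = depth,
      depth_class = classify_depth(depth, params$depth_threshold_nm),
      n_wall_atoms = length(wall), wall_atom_ids = list(wall),
      n_inner = fp[1], n_central = fp[2], n_outer = fp[3],
      fingerprint = if (!is.null(fmap)) paste(fp, collapse = ":") else NA_character_,
      n_ligands = nlig, occupied = NA, analyte_ids = list(integer()),
      voxels = list(p$voxels)
    )
  })
  dplyr::bind_rows(rows)
}

#' Atoms forming a pocket's walls
#'
#' Atom i is a wall atom iff its surface comes within
#' `wall_contact_margin + spacing` of some pocket voxel centre, i.e.
#' `min_v |v - x_i| <= r_i + margin + spacing`.
#'
#' @param pocket_voxels Matrix of pocket voxel centres (n x 3, angstrom).
#' @param atoms Atom set (see [make_grid()]).
#' @param params A [pocket_params()] list.
#' @return Integer vector of wall atom ids.
#' @export
wall_atoms <- function(pocket_voxels, atoms, params = pocket_params()) {
  if (is.null(dim(pocket_voxels)) || nrow(pocket_voxels) == 0) {
    abort("pocket_voxels must be a non-empty n x 3 matrix")
  }
  a <- as_atom_set(atoms)
  cutoff <- a$radii + params$wall_contact_margin + params$spacing
  # bounding-box prefilter, then exact min distance per candidate atom
  lo <- apply(pocket_voxels, 2, min)
  hi <- apply(pocket_voxels, 2, max)
  cand <- which(
    a$coords[, 1] > lo[1] - cutoff & a$coords[, 1] < hi[1] + cutoff &
    a$coords[, 2] > lo[2] - cutoff & a$coords[, 2] < hi[2] + cutoff &
    a$coords[, 3] > lo[3] - cutoff & a$coords[, 3] < hi[3] + cutoff
  )
  if (length(cand) == 0) return(integer())
  hit <- vapply(cand, function(i) {
    d2 <- (pocket_voxels[, 1] - a$coords[i, 1])^2 +
          (pocket_voxels[, 2] - a$coords[i, 2])^2 +
          (pocket_voxels[, 3] - a$coords[i, 3])^2
    min(d2) <= cutoff[i]^2
  }, logical(1))
  sort(as.integer(a$ids[cand[hit]]))
}

#' Maximum pairwise distance between pocket centres
#'
#' @param records A pocket table (typically one frame's rows).
#' @return Maximum pairwise Euclidean centre distance, nm; 0 with fewer
#'   than two pockets.
#' @export
max_pairwise_center_distance <- function(records) {
  if (nrow(records) < 2) return(0)
  co <- as.matrix(records[, c("x", "y", "z")])
  max(stats::dist(co)) / 10
}

#' Median over frames of the per-frame maximum centre distance
#'
#' @param records A pocket table covering multiple frames.
#' @param pooled If `TRUE`, return instead the maximum over all pooled
#'   pairs per frame set -- i.e. compute a single maximum per frame and the
#'   median of those (default), or pool all centres of all frames.
#' @return nm.
#' @export
median_max_distance <- function(records, pooled = FALSE) {
  if (nrow(records) == 0) return(0)
  if (pooled) return(max_pairwise_center_distance(records))
  per_frame <- records |>
    dplyr::group_by(.data$frame) |>
    dplyr::group_map(~ max_pairwise_center_distance(.x))
  median(unlist(per_frame))
}
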