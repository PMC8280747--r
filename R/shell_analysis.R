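#' Pockets-per-frame summary
#'
#' Counts pockets in every analysed frame (frames with zero pockets
#' contribute 0, not missing) and reports the mean and population
#' standard deviation across frames.
#'
#' @param records A pocket table.
#' @param n_frames Total number of frames analysed; defaults to the
#'   `n_frames_analyzed` attribute that [detect_pockets()] sets, falling
#'   back to the number of distinct frames in the table.
#' @return One-row tibble: `n_frames`, `total_pockets`, `mean_pockets`,
#'   `sd_pockets` (population), `min_pockets`, `max_pockets`.
#' @export
frame_summary <- function(records, n_frames = NULL) {
  n_frames <- n_frames %||% attr(records, "n_frames_analyzed") %||%
    length(unique(records$frame))
  if (n_frames < 1) abort("n_frames must be >= 1")
  counts <- rep(0L, n_frames)
  if (nrow(records) > 0) {
    tab <- table(records$frame)
    # frames are 0-based ids; map onto the 1..n_frames count vector
    counts[as.integer(names(tab)) + 1L] <- as.integer(tab)
  }
  m <- mean(counts)
  tibble(
    n_frames = as.integer(n_frames),
    total_pockets = sum(counts),
    mean_pockets = m,
    sd_pockets = sqrt(mean((counts - m)^2)),
    min_pockets = min(counts),
    max_pockets = max(counts)
  )
}

#' Per-frame pocket counts
#' @inheritParams frame_summary
#' @return Tibble with `frame` (0-based) and `n_pockets`.
#' @export
pockets_per_frame <- function(records, n_frames = NULL) {
  n_frames <- n_frames %||% attr(records, "n_frames_analyzed") %||%
    length(unique(records$frame))
  counts <- rep(0L, n_frames)
  if (nrow(records) > 0) {
    tab <- table(records$frame)
    counts[as.integer(names(tab)) + 1L] <- as.integer(tab)
  }
  tibble(frame = seq_len(n_frames) - 1L, n_pockets = counts)
}

#' Volume and depth class fractions
#'
#' Splits pockets into volume classes at the given edges (default below
#' 150, 150-300, above 300 cubic angstrom; the detection floor already
#' removes everything below `min_volume`) and into deep/shallow depth
#' classes at the given threshold.
#'
#' @param records A pocket table.
#' @param volume_edges Strictly increasing class edges, cubic angstrom.
#' @param depth_threshold_nm Deep/shallow boundary, nm.
#' @return Tibble with `measure` (`"volume"` or `"depth"`), `class`, `n`,
#'   `fraction`.
#' @export
volume_depth_classes <- function(records, volume_edges = c(150, 300),
                                 depth_threshold_nm = 1.3) {
  if (is.unsorted(volume_edges, strictly = TRUE)) {
    abort("volume_edges must be strictly increasing")
  }
  edges <- c(-Inf, volume_edges, Inf)
  labels <- c(
    paste0("<", volume_edges[1]),
    paste0("[", head(volume_edges, -1), ",", volume_edges[-1], ")"),
    paste0(">=", volume_edges[length(volume_edges)])
  )
  vcl <- cut(records$volume, breaks = edges, labels = labels, right = FALSE)
  vtab <- table(factor(vcl, levels = labels))
  vrows <- tibble(measure = "volume", class = labels,
                  n = as.integer(vtab),
                  fraction = if (nrow(records) > 0) as.integer(vtab) / nrow(records) else 0)
  dep <- classify_depth(records$depth_nm, depth_threshold_nm)
  dtab <- table(factor(dep, levels = c("deep", "shallow")))
  ndep <- sum(dtab)
  drows <- tibble(measure = "depth", class = c("deep", "shallow"),
                  n = as.integer(dtab),
                  fraction = if (ndep > 0) as.integer(dtab) / ndep else 0)
  dplyr::bind_rows(vrows, drows)
}

#' Dihedral angle of four points
#'
#' Standard signed torsion in (-180, 180], degrees, via the atan2
#' formulation.
#'
#' @param p1,p2,p3,p4 n-by-3 matrices (or length-3 vectors) of positions.
#' @return Numeric vector of angles, degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  as_m <- function(p) if (is.null(dim(p))) matrix(p, ncol = 3) else p
  p1 <- as_m(p1); p2 <- as_m(p2); p3 <- as_m(p3); p4 <- as_m(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(rowSums(b2^2)))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  ang <- -atan2(y, x) * 180 / pi
  # convention: (-180, 180]
  ifelse(ang <= -180, ang + 360, ang)
}

#' Backbone dihedral series of the coating ligands
#'
#' Computes, for every ligand and frame, the dihedral angle of each
#' sliding 4-tuple along the declared heavy-atom chain, and classifies
#' each as trans (|angle| >= 120 degrees) or gauche.
#'
#' @param frames A [frame_series()].
#' @param chain_spec Ordered chain atoms per ligand: either a character
#'   vector of atom names, or an integer vector of 1-based positions
#'   within each ligand's atom order.  At least 4 atoms.
#' @param fmap Optional [parse_fragment_map()]; when given, ligand
#'   membership is taken from it, otherwise from the atom table's
#'   `ligand_index`.
#' @param frame 0-based frame indices; default all.
#' @return Tibble with `frame`, `ligand_index`, `dihedral` (1-based index
#'   along the chain), `angle_deg`, `conformer` (`"trans"`/`"gauche"`).
#' @export
dihedral_series <- function(frames, chain_spec, fmap = NULL, frame = NULL) {
  if (length(chain_spec) < 4) abort("chain_spec must name at least 4 consecutive atoms")
  atoms <- frames$atoms
  if (!is.null(fmap)) {
    atoms$ligand_index[match(fmap$atom_id, atoms$atom_id)] <- fmap$ligand_index
  }
  lig_ids <- sort(unique(atoms$ligand_index[atoms$role == "ligand"]))
  if (length(lig_ids) == 0) abort("no ligand atoms")
  if (is.null(frame)) frame <- seq_len(n_frames(frames)) - 1L
  # resolve chain atom ids per ligand once
  chain_ids <- lapply(lig_ids, function(li) {
    res <- atoms[atoms$role == "ligand" & atoms$ligand_index %in% li, ]
    res <- res[order(res$atom_id), ]
    if (is.numeric(chain_spec)) {
      if (any(chain_spec > nrow(res))) {
        abort(sprintf("Ligand %d has no chain position %d.", li,
                      max(chain_spec)))
      }
      res$atom_id[chain_spec]
    } else {
      idx <- match(chain_spec, res$name)
      if (anyNA(idx)) {
        abort(sprintf("Ligand %d is missing chain atom(s): %s", li,
                      paste(chain_spec[is.na(idx)], collapse = ", ")))
      }
      res$atom_id[idx]
    }
  })
  nd <- length(chain_spec) - 3L
  out <- purrr::map(frame, function(f) {
    co <- frame_coords(frames, f)
    purrr::map(seq_along(lig_ids), function(k) {
      ids <- chain_ids[[k]]
      pos <- co[match(ids, atoms$atom_id), , drop = FALSE]
      ang <- dihedral_angle(pos[1:nd, , drop = FALSE],
                            pos[2:(nd + 1), , drop = FALSE],
                            pos[3:(nd + 2), , drop = FALSE],
                            pos[4:(nd + 3), , drop = FALSE])
      tibble(frame = as.integer(f), ligand_index = lig_ids[k],
             dihedral = seq_len(nd), angle_deg = ang,
             # boundary convention: exactly +/-120 counts as trans; the
             # tiny tolerance absorbs floating-point fuzz at the boundary
             conformer = ifelse(abs(ang) >= 120 - 1e-7, "trans", "gauche"))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  out
}

#' Gauche fraction per dihedral
#' @param dihedrals Output of [dihedral_series()].
#' @return Tibble with `dihedral`, `n`, `gauche_fraction`.
#' @export
gauche_fractions <- function(dihedrals) {
  dihedrals |>
    dplyr::group_by(.data$dihedral) |>
    dplyr::summarise(n = dplyr::n(),
                     gauche_fraction = mean(.data$conformer == "gauche"),
                     .groups = "drop")
}

#' Hydrogen-bond count and fraction of the maximum possible
#'
#' Geometric criterion: a donor-H...acceptor contact is a hydrogen bond
#' when the donor-acceptor heavy-atom distance is at most `d_max` and the
#' donor-H...acceptor angle (at the hydrogen) is at least `angle_min`.
#' The maximum possible count is the number of donor hydrogens; a
#' hydrogen engaged with several acceptors simultaneously counts once in
#' the percentage, so it never exceeds 100.
#'
#' @param frames A [frame_series()].
#' @param donors Integer vector of donor heavy-atom ids.  Attached
#'   hydrogens are resolved per frame as `role`-matching H atoms within
#'   `h_bond_length` of the donor.
#' @param acceptors Integer vector of acceptor heavy-atom ids.
#' @param d_max Donor-acceptor distance cutoff, angstrom (default 3.5).
#' @param angle_min D-H...A angle cutoff, degrees (default 135).
#' @param h_bond_length Covalent D-H search radius, angstrom.
#' @param lenient Skip donors without a resolvable hydrogen instead of
#'   erroring.
#' @param frame 0-based frame indices; default all.
#' @return Tibble per frame: `frame`, `n_donor_h`, `n_pairs`,
#'   `n_h_engaged`, `percent_of_max`.
#' @export
hbond_fractions <- function(frames, donors, acceptors, d_max = 3.5,
                            angle_min = 135, h_bond_length = 1.25,
                            lenient = FALSE, frame = NULL) {
  if (length(donors) == 0 || length(acceptors) == 0) {
    abort("donor and acceptor selections must be non-empty")
  }
  atoms <- frames$atoms
  h_idx <- which(atoms$element == "H")
  if (is.null(frame)) frame <- seq_len(n_frames(frames)) - 1L
  purrr::map(frame, function(f) {
    co <- frame_coords(frames, f)
    # resolve covalent hydrogens of each donor in this frame
    dh <- purrr::map(donors, function(d) {
      di <- match(d, atoms$atom_id)
      if (length(h_idx) == 0) return(integer())
      d2 <- rowSums((co[h_idx, , drop = FALSE] -
                     matrix(co[di, ], length(h_idx), 3, byrow = TRUE))^2)
      atoms$atom_id[h_idx[d2 <= h_bond_length^2]]
    })
    no_h <- lengths(dh) == 0
    if (any(no_h) && !lenient) {
      abort(paste0("Donor(s) without attached hydrogen: ",
                   paste(donors[no_h], collapse = ", ")))
    }
    pairs <- 0L
    engaged <- 0L
    n_donor_h <- sum(lengths(dh))
    for (k in seq_along(donors)) {
      if (length(dh[[k]]) == 0) next
      di <- match(donors[k], atoms$atom_id)
      dpos <- co[di, ]
      acc <- setdiff(acceptors, donors[k])
      ai <- match(acc, atoms$atom_id)
      da2 <- rowSums((co[ai, , drop = FALSE] -
                      matrix(dpos, length(ai), 3, byrow = TRUE))^2)
      close_a <- ai[da2 <= d_max^2]
      for (h in dh[[k]]) {
        hi <- match(h, atoms$atom_id)
        hpos <- co[hi, ]
        hit <- 0L
        for (a in close_a) {
          v1 <- dpos - hpos
          v2 <- co[a, ] - hpos
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
          if (ang >= angle_min) hit <- hit + 1L
        }
        pairs <- pairs + hit
        if (hit > 0) engaged <- engaged + 1L
      }
    }
    tibble(frame = as.integer(f), n_donor_h = as.integer(n_donor_h),
           n_pairs = pairs, n_h_engaged = engaged,
           percent_of_max = if (n_donor_h > 0) 100 * engaged / n_donor_h else 0)
  }) |> dplyr::bind_rows()
}
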