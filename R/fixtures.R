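# Fibonacci lattice over a band of the unit sphere: n points with
# z/R in [z_lo, z_hi], near-uniform area density, deterministic.
fibonacci_band <- function(n, z_lo = -1, z_hi = 1) {
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n) - 0.5
  z <- z_hi - (i / n) * (z_hi - z_lo)
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- golden * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Cup fixture: a bead shell with a known concave cavity
#'
#' Beads are placed on a spherical shell minus a polar cap, enclosing a
#' concave cavity of radius `inner_radius` whose mouth (the cap opening)
#' admits the water-sized probe but is bridged by the 3 A probe.  This is
#' the reference geometry for pocket-volume validation: the cavity is the
#' single expected pocket under default detection parameters.
#'
#' @param inner_radius Cavity radius (shell radius minus bead radius),
#'   angstrom.
#' @param bead_radius Bead van der Waals radius, angstrom.
#' @param shell_radius Radius of the bead-centre shell; defaults to
#'   `inner_radius + bead_radius`.
#' @param aperture_deg Half-angle of the polar cap left open, degrees.
#' @param n_beads Number of beads; by default chosen for a sealed shell
#'   (centre spacing about 0.9 bead radii).
#' @param seed Seed for the (small) placement jitter.
#' @param jitter Positional jitter amplitude, angstrom.
#' @param center Cavity centre, xyz angstrom.
#' @return A [frame_series()] with one frame; beads carry role `core`.
#' @export
make_cup_fixture <- function(inner_radius = 4.5, bead_radius = 1.5,
                             shell_radius = inner_radius + bead_radius,
                             aperture_deg = 45, n_beads = NULL, seed = 1,
                             jitter = 0, center = c(0, 0, 0)) {
  if (aperture_deg < 0 || aperture_deg >= 180) abort("aperture_deg must be in [0, 180)")
  z_hi <- cos(aperture_deg * pi / 180)
  if (is.null(n_beads)) {
    area <- 2 * pi * shell_radius^2 * (z_hi + 1)
    n_beads <- max(12L, as.integer(ceiling(area / (0.9 * bead_radius)^2)))
  }
  dirs <- fibonacci_band(n_beads, z_lo = -1, z_hi = z_hi)
  co <- dirs * shell_radius
  if (jitter > 0) {
    co <- co + withr::with_seed(seed, matrix(stats::runif(3 * n_beads, -jitter, jitter),
                                             ncol = 3))
  }
  co <- sweep(co, 2, center, `+`)
  # sealedness: every bead must touch a neighbour, else the shell leaks
  nn <- apply(as.matrix(stats::dist(co)) + diag(Inf, n_beads), 1, min)
  if (max(nn) > 2 * bead_radius) {
    abort(sprintf(
      "leaky shell: largest bead centre spacing %.2f A exceeds the bead diameter; increase n_beads",
      max(nn)))
  }
  atoms <- tibble(
    atom_id = seq_len(n_beads), element = "C",
    x = co[, 1], y = co[, 2], z = co[, 3],
    radius = bead_radius, role = "core"
  )
  frame_series(atoms)
}

# Rotate unit vector v away from unit axis c by `extra` radians, within
# the plane spanned by (c, v).
tilt_away <- function(v, c_axis, extra) {
  cosang <- sum(v * c_axis)
  if (abs(cosang) > 0.9999) {
    # v parallel to the axis: pick any perpendicular direction
    perp <- if (abs(c_axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    t <- perp - sum(perp * c_axis) * c_axis
  } else {
    t <- v - cosang * c_axis
  }
  t <- t / sqrt(sum(t^2))
  ang <- acos(pmin(pmax(cosang, -1), 1)) + extra
  out <- cos(ang) * c_axis + sin(ang) * t
  out / sqrt(sum(out^2))
}

#' Coated-nanoparticle fixture with splayed-open wedge cavities
#'
#' A spherical core plus radial bead chains, each partitioned into
#' inner / central / outer fragment blocks, emulating a thiolate
#' monolayer at bead (united-atom) resolution.  `splay_groups` clusters
#' of neighbouring chains are bent apart around a common axis -- the
#' "flower opening" motif -- leaving a wedge cavity whose wall ligands
#' contain, by construction, the splayed group (plus, at the rim, part
#' of the ring of background chains immediately surrounding it).
#'
#' @param core_radius Core sphere radius, angstrom (a single smooth
#'   sphere of this radius, gold).
#' @param n_ligands Number of bead chains (>= 4).
#' @param beads_per_fragment Integer triple: beads in the inner, central
#'   and outer block of each chain.
#' @param splay_groups Number of wedge cavities to open (0 for a tight,
#'   unperturbed brush).
#' @param splay_size Chains per splayed group.
#' @param splay_angle_deg Extra polar tilt given to the group ring,
#'   degrees (divergence of the "flower opening").
#' @param splay_base_deg Polar angle of the unopened group ring, degrees.
#' @param guard_deg Angular clearance kept between the splayed ring and
#'   the surrounding background chains, degrees.
#' @param bead_radius Chain bead radius, angstrom; either a scalar or a
#'   length-3 vector of per-fragment radii (inner, central, outer) -- a
#'   bulkier outer block emulates the crowded glycol termini that seal
#'   the outer surface of a real monolayer.  The first outer bead caps
#'   the chain tip; further outer beads form a perpendicular ring (an
#'   "umbrella") that closes the canopy between neighbouring chains.
#' @param bond_length Distance between consecutive chain beads, angstrom.
#' @param umbrella_offset Lateral offset of the outer ring beads from the
#'   chain tip, angstrom.
#' @param n_frames Number of frames (frames beyond the first are jittered
#'   copies, emulating a short trajectory).
#' @param jitter Per-frame coordinate jitter, angstrom.
#' @param seed RNG seed for the jitter.
#' @return A list: `frames` (a [frame_series()]), `fmap` (the matching
#'   fragment map), `groups` (list of ligand-index vectors per splayed
#'   group), `group_axes` (unit vectors of the wedge axes).
#' @export
make_coated_np_fixture <- function(core_radius = 8, n_ligands = 80,
                                   beads_per_fragment = c(2, 1, 4),
                                   splay_groups = 2, splay_size = 6,
                                   splay_angle_deg = 12, splay_base_deg = 14, guard_deg = 8,
                                   bead_radius = c(1.8, 1.8, 2.2),
                                   bond_length = 2.0, umbrella_offset = 2.0,
                                   n_frames = 1, jitter = 0.1, seed = 1) {
  if (n_ligands < 4) abort("n_ligands must be >= 4")
  if (any(beads_per_fragment < 1)) abort("beads_per_fragment must all be >= 1")
  nb <- sum(beads_per_fragment)
  if (length(bead_radius) == 1) bead_radius <- rep(bead_radius, 3)
  bead_r <- rep(bead_radius, times = beads_per_fragment)
  dirs <- fibonacci_band(n_ligands)
  # wedge axes: opposite poles first, then equatorial spread
  axes_pool <- rbind(c(0, 0, 1), c(0, 0, -1), c(1, 0, 0), c(-1, 0, 0),
                     c(0, 1, 0), c(0, -1, 0))
  if (splay_groups > nrow(axes_pool)) abort("too many splay groups")
  groups <- list()
  group_axes <- list()
  taken <- integer()
  if (splay_groups > 0) {
    for (g in seq_len(splay_groups)) {
      ax <- axes_pool[g, ]
      d <- drop(dirs %*% ax)
      cand <- order(-d)
      cand <- setdiff(cand, taken)[seq_len(splay_size)]
      groups[[g]] <- cand
      group_axes[[g]] <- ax
      taken <- c(taken, cand)
      # the group becomes a regular splayed ring (palisade) around the
      # axis: a closed wall of diverged chains enclosing a conical void
      theta <- (splay_base_deg + splay_angle_deg) * pi / 180
      p1 <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- p1 - sum(p1 * ax) * ax
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(ax[2] * e1[3] - ax[3] * e1[2], ax[3] * e1[1] - ax[1] * e1[3],
              ax[1] * e1[2] - ax[2] * e1[1])
      phis <- 2 * pi * (seq_len(splay_size) - 1) / splay_size + 0.3 * g
      for (k in seq_len(splay_size)) {
        dirs[cand[k], ] <- cos(theta) * ax +
          sin(theta) * (cos(phis[k]) * e1 + sin(phis[k]) * e2)
      }
      # guard: non-group chains left inside or hugging the palisade are
      # pushed just outside it so the void is bounded by the group alone
      guard <- theta + guard_deg * pi / 180
      for (li in setdiff(seq_len(n_ligands), taken)) {
        cosang <- sum(dirs[li, ] * ax)
        if (cosang > cos(guard)) {
          extra <- guard - acos(pmin(pmax(cosang, -1), 1))
          dirs[li, ] <- tilt_away(dirs[li, ], ax, extra)
        }
      }
    }
  }
  r0 <- core_radius + 0.8 * bead_r[1]
  n_stem <- beads_per_fragment[1] + beads_per_fragment[2] + 1L
  chain_r <- r0 + (seq_len(n_stem) - 1) * bond_length
  cls <- rep(c("Inner", "Central", "Outer"), times = beads_per_fragment)
  el <- rep(c("C", "N", "O"), times = beads_per_fragment)
  lig_atoms <- purrr::map(seq_len(n_ligands), function(li) {
    u <- dirs[li, ]
    # stem: radial inner + central beads and the outer tip bead
    co <- outer(chain_r, u)
    # remaining outer beads form a perpendicular ring around the tip --
    # the umbrella canopy that seals the outer surface, emulating the
    # crowding of terminal glycol chains
    n_ring <- beads_per_fragment[3] - 1L
    if (n_ring > 0) {
      p1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- p1 - sum(p1 * u) * u
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
              u[1] * e1[2] - u[2] * e1[1])
      tip <- co[n_stem, ]
      ring_phi <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
      ring <- t(vapply(ring_phi, function(ph) {
        tip + umbrella_offset * (cos(ph) * e1 + sin(ph) * e2)
      }, numeric(3)))
      co <- rbind(co, ring)
    }
    tibble(
      element = el, name = paste0("B", seq_len(nb)),
      resid = li, resname = "LIG",
      x = co[, 1], y = co[, 2], z = co[, 3],
      radius = bead_r, role = "ligand",
      ligand_index = li, fragment_class = cls
    )
  })
  core <- tibble(
    element = "Au", name = "AU", resid = 0L, resname = "COR",
    x = 0, y = 0, z = 0, radius = core_radius, role = "core",
    ligand_index = NA_integer_, fragment_class = NA_character_
  )
  atoms <- dplyr::bind_rows(core, lig_atoms)
  atoms$atom_id <- seq_len(nrow(atoms))
  # ligand anchors must not bury into the core beyond tolerance
  anchor_d <- sqrt(atoms$x^2 + atoms$y^2 + atoms$z^2)[atoms$role == "ligand"]
  if (any(anchor_d < core_radius - bead_r[1])) {
    abort("ligand beads overlap the core beyond tolerance")
  }
  base <- unname(as.matrix(atoms[, c("x", "y", "z")]))
  coords <- withr::with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      if (f == 1 || jitter == 0) base
      else base + matrix(stats::rnorm(length(base), 0, jitter), ncol = 3)
    })
  })
  frames <- frame_series(atoms, coords)
  fmap <- atoms[atoms$role == "ligand", c("atom_id", "ligand_index", "fragment_class")]
  fmap <- structure(as_tibble(fmap), n_ligands = n_ligands,
                    class = c("fragment_map", class(as_tibble(fmap))))
  list(frames = frames, fmap = fmap,
       groups = lapply(groups, as.integer), group_axes = group_axes)
}
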