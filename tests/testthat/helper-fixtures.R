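# Seeded random atom cluster used across SES/pocket tests.
random_cluster <- function(n = 30, seed = 1, spread = 3.5) {
  withr::with_seed(seed, {
    co <- matrix(stats::rnorm(3 * n, 0, spread), ncol = 3)
    el <- sample(c("C", "N", "O", "S"), n, replace = TRUE)
    tibble::tibble(
      atom_id = seq_len(n), element = el,
      x = co[, 1], y = co[, 2], z = co[, 3],
      radius = vdw_radii(el), role = "core"
    )
  })
}

# Random rigid motion of an atom table.
rigid_motion <- function(atoms, seed = 1) {
  withr::with_seed(seed, {
    th <- stats::runif(3, 0, 2 * pi)
    tr <- stats::runif(3, -5, 5)
    rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1])), 3, 3)
    ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0, -sin(th[2]), 0, cos(th[2])), 3, 3)
    rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3, 3)
    rot <- rx %*% ry %*% rz
    co <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
    atoms$x <- co[, 1] + tr[1]
    atoms$y <- co[, 2] + tr[2]
    atoms$z <- co[, 3] + tr[3]
    atoms
  })
}

# Minimal three-ligand frame series for fragment-map tests: 3 residues
# of 10 named atoms each.
three_ligand_frames <- function() {
  atoms <- tibble::tibble(
    atom_id = 1:30,
    element = rep(c(rep("C", 4), "N", "N", rep("O", 4)), 3),
    name = rep(paste0("A", 1:10), 3),
    resid = rep(1:3, each = 10),
    resname = "LIG",
    x = rep(1:10, 3), y = rep(1:3, each = 10) * 10, z = 0,
    radius = 1.6, role = "ligand",
    ligand_index = rep(1:3, each = 10)
  )
  frame_series(atoms)
}
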