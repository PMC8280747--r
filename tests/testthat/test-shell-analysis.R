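test_that("frame summaries use population statistics and count empty frames", {
  rec <- tibble::tibble(frame = c(rep(0L, 2), rep(1L, 4), rep(2L, 6)))
  fs <- frame_summary(rec, n_frames = 3)
  expect_equal(fs$mean_pockets, 4)
  expect_equal(fs$sd_pockets, sqrt(8 / 3), tolerance = 1e-9)
  # a frame with zero pockets contributes 0
  fs2 <- frame_summary(rec, n_frames = 4)
  expect_equal(fs2$mean_pockets, 3)
  expect_equal(pockets_per_frame(rec, 4)$n_pockets, c(2L, 4L, 6L, 0L))
  # single frame -> sd 0; mean equals total/frames exactly
  fs1 <- frame_summary(rec[rec$frame == 0L, ], n_frames = 1)
  expect_equal(fs1$sd_pockets, 0)
  expect_equal(fs$mean_pockets, fs$total_pockets / fs$n_frames)
})

test_that("volume and depth classes partition the pockets", {
  rec <- tibble::tibble(volume = c(120, 160, 320), depth_nm = c(1.0, 1.2, 1.6))
  cls <- volume_depth_classes(rec)
  vc <- cls[cls$measure == "volume", ]
  expect_equal(vc$fraction, rep(1 / 3, 3))
  dc <- cls[cls$measure == "depth", ]
  expect_equal(sum(dc$fraction), 1)
  expect_equal(dc$n[dc$class == "deep"], 2L)
  expect_error(volume_depth_classes(rec, volume_edges = c(300, 150)), "increasing")
})

test_that("dihedral angles reproduce textbook geometries and the 120-degree boundary", {
  p1 <- c(-0.5, 1, 0); p2 <- c(0, 0, 0); p3 <- c(1, 0, 0)
  mk4 <- function(phi_deg) {
    phi <- phi_deg * pi / 180
    c(1.5, cos(phi), sin(phi))
  }
  # anti-periplanar: 180 degrees, trans
  expect_equal(abs(dihedral_angle(p1, p2, p3, mk4(180))), 180)
  # synclinal: +/-60, gauche
  expect_equal(abs(dihedral_angle(p1, p2, p3, mk4(60))), 60, tolerance = 1e-9)
  # boundary at exactly 120 counts as trans
  atoms <- tibble::tibble(
    atom_id = 1:4, element = "C", name = paste0("B", 1:4),
    resid = 1L, resname = "LIG",
    x = c(p1[1], p2[1], p3[1], 1.5), y = c(p1[2], p2[2], p3[2], cos(2 * pi / 3)),
    z = c(p1[3], p2[3], p3[3], sin(2 * pi / 3)),
    radius = 1.7, role = "ligand", ligand_index = 1L
  )
  fs <- frame_series(atoms)
  d <- dihedral_series(fs, chain_spec = paste0("B", 1:4))
  expect_equal(abs(d$angle_deg), 120, tolerance = 1e-6)
  expect_equal(d$conformer, "trans")
})

test_that("dihedral series agree with the bio3d torsion oracle", {
  withr::with_seed(21, {
    co <- matrix(stats::rnorm(18, sd = 2), ncol = 3)
  })
  atoms <- tibble::tibble(
    atom_id = 1:6, element = "C", name = paste0("B", 1:6),
    resid = 1L, resname = "LIG",
    x = co[, 1], y = co[, 2], z = co[, 3],
    radius = 1.7, role = "ligand", ligand_index = 1L
  )
  fs <- frame_series(atoms)
  d <- dihedral_series(fs, chain_spec = paste0("B", 1:6))
  expect_equal(nrow(d), 3L)
  for (i in 1:3) {
    ref <- bio3d::torsion.xyz(as.vector(t(co[i:(i + 3), ])))
    expect_equal(d$angle_deg[i], unname(ref), tolerance = 1e-6)
  }
})

test_that("dihedrals are invariant under rigid motion and error on missing atoms", {
  withr::with_seed(31, {
    co <- matrix(stats::rnorm(36, sd = 3), ncol = 3)
  })
  atoms <- tibble::tibble(
    atom_id = 1:12, element = "C", name = rep(paste0("B", 1:6), 2),
    resid = rep(1:2, each = 6), resname = "LIG",
    x = co[, 1], y = co[, 2], z = co[, 3],
    radius = 1.7, role = "ligand", ligand_index = rep(1:2, each = 6)
  )
  fs <- frame_series(atoms)
  d0 <- dihedral_series(fs, chain_spec = paste0("B", 1:6))
  d1 <- dihedral_series(frame_series(rigid_motion(atoms, seed = 3)),
                        chain_spec = paste0("B", 1:6))
  expect_equal(d0$angle_deg, d1$angle_deg, tolerance = 1e-6)
  expect_error(dihedral_series(fs, chain_spec = paste0("B", 6:9)),
               "missing|position")
  expect_error(dihedral_series(fs, chain_spec = paste0("B", 1:3)), "at least 4")
  gf <- gauche_fractions(d0)
  expect_true(all(gf$gauche_fraction >= 0 & gf$gauche_fraction <= 1))
})

test_that("hydrogen bonds follow the geometric distance and angle criteria", {
  mk_fs <- function(da_dist, angle_ok = TRUE) {
    # donor N at origin, H along +x; acceptor placed linearly or bent
    apos <- if (angle_ok) c(da_dist, 0, 0) else c(0.5, 1.2, 0)
    atoms <- tibble::tibble(
      atom_id = 1:3, element = c("N", "H", "O"),
      name = c("N1", "HN", "O1"), resid = 1L, resname = "LIG",
      x = c(0, 1.0, apos[1]), y = c(0, 0, apos[2]), z = c(0, 0, apos[3]),
      radius = c(1.55, 1.2, 1.52), role = "ligand", ligand_index = 1L
    )
    frame_series(atoms)
  }
  hb <- hbond_fractions(mk_fs(2.9), donors = 1L, acceptors = 3L)
  expect_equal(hb$n_pairs, 1L)
  expect_equal(hb$percent_of_max, 100)
  hb2 <- hbond_fractions(mk_fs(4.0), donors = 1L, acceptors = 3L)
  expect_equal(hb2$n_pairs, 0L)
  hb3 <- hbond_fractions(mk_fs(2.9, angle_ok = FALSE), donors = 1L, acceptors = 3L)
  expect_equal(hb3$n_pairs, 0L)
  # donor without hydrogen errors unless lenient
  no_h <- mk_fs(2.9)
  no_h$atoms <- no_h$atoms[-2, ]
  no_h <- frame_series(no_h$atoms)
  expect_error(hbond_fractions(no_h, donors = 1L, acceptors = 3L), "hydrogen")
  hb4 <- hbond_fractions(no_h, donors = 1L, acceptors = 3L, lenient = TRUE)
  expect_equal(hb4$n_donor_h, 0L)
  expect_error(hbond_fractions(no_h, donors = integer(), acceptors = 3L),
               "non-empty")
})

test_that("the hydrogen-bond percentage is engaged hydrogens over donor hydrogens", {
  # 2 donors with one H each; one H-bonds, the other points away
  atoms <- tibble::tibble(
    atom_id = 1:6,
    element = c("N", "H", "O", "N", "H", "O"),
    name = c("N1", "H1", "O1", "N2", "H2", "O2"),
    resid = 1L, resname = "LIG",
    x = c(0, 1, 2.9, 20, 21, 20.5), y = c(0, 0, 0, 0, 0, 1.4),
    z = 0, radius = 1.5, role = "ligand", ligand_index = 1L
  )
  fs <- frame_series(atoms)
  hb <- hbond_fractions(fs, donors = c(1L, 4L), acceptors = c(3L, 6L))
  expect_equal(hb$n_donor_h, 2L)
  expect_equal(hb$n_h_engaged, 1L)
  expect_equal(hb$percent_of_max, 50)
})
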