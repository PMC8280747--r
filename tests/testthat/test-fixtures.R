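test_that("fixture generators are seed-deterministic", {
  a <- make_cup_fixture(seed = 3, jitter = 0.05)
  b <- make_cup_fixture(seed = 3, jitter = 0.05)
  expect_identical(a$coords, b$coords)
  c1 <- make_coated_np_fixture(seed = 5, n_frames = 2, jitter = 0.2)
  c2 <- make_coated_np_fixture(seed = 5, n_frames = 2, jitter = 0.2)
  expect_identical(c1$frames$coords, c2$frames$coords)
  expect_false(identical(c1$frames$coords,
                         make_coated_np_fixture(seed = 6, n_frames = 2,
                                                jitter = 0.2)$frames$coords))
})

test_that("a sealed hollow shell has no pockets at any tested spacing", {
  sealed <- make_cup_fixture(aperture_deg = 0)
  for (h in c(0.5, 0.4)) {
    expect_equal(nrow(detect_pockets(sealed, pocket_params(spacing = h))), 0L)
  }
})

test_that("leaky shells and invalid fixture parameters error", {
  expect_error(make_cup_fixture(n_beads = 20), "leaky")
  expect_error(make_cup_fixture(aperture_deg = -5), "aperture")
  expect_error(make_coated_np_fixture(n_ligands = 3), "n_ligands")
  expect_error(make_coated_np_fixture(beads_per_fragment = c(0, 1, 1)),
               "beads_per_fragment")
})

test_that("the fixture fragment map covers every ligand bead exactly once", {
  fx <- make_coated_np_fixture(n_ligands = 20, beads_per_fragment = c(2, 1, 3),
                               splay_groups = 0)
  expect_equal(nrow(fx$fmap), 20 * 6)
  expect_equal(n_ligands(fx$fmap), 20L)
  expect_equal(anyDuplicated(fx$fmap$atom_id), 0L)
  lig_atoms <- fx$frames$atoms$atom_id[fx$frames$atoms$role == "ligand"]
  expect_setequal(fx$fmap$atom_id, lig_atoms)
  counts <- table(fx$fmap$fragment_class)
  expect_equal(unname(c(counts[c("Inner", "Central", "Outer")])),
               c(40L, 20L, 60L))
})

test_that("splayed wedges open pockets that the tight brush lacks", {
  splayed <- make_coated_np_fixture(splay_groups = 2, seed = 9)
  tight <- make_coated_np_fixture(splay_groups = 0, seed = 9)
  n_splayed <- nrow(detect_pockets(splayed$frames))
  n_tight <- nrow(detect_pockets(tight$frames))
  expect_gte(n_splayed, 2L)
  expect_lt(n_tight, n_splayed)
})

test_that("each splayed group is recovered in the wall set of its wedge pocket", {
  fx <- make_coated_np_fixture(splay_groups = 2, seed = 9)
  pk <- detect_pockets(fx$frames, fmap = fx$fmap)
  at <- fx$frames$atoms
  matched <- integer()
  for (g in seq_along(fx$groups)) {
    ax <- fx$group_axes[[g]]
    centers <- as.matrix(pk[, c("x", "y", "z")])
    proj <- centers %*% ax / sqrt(rowSums(centers^2))
    hit <- which(proj > cos(25 * pi / 180))
    expect_length(hit, 1L)
    wall_ligs <- unique(stats::na.omit(
      at$ligand_index[match(pk$wall_atom_ids[[hit]], at$atom_id)]))
    expect_true(all(fx$groups[[g]] %in% wall_ligs))
    matched <- c(matched, hit)
  }
  expect_equal(anyDuplicated(matched), 0L)
})

test_that("the oracle classifies trivial points correctly", {
  at <- random_cluster(10, seed = 2, spread = 2)
  orc <- oracle_ses(at, probe = 1.4, resolution = 0.25)
  # a point inside an atom sphere is inside the SES for any probe
  expect_true(oracle_point_in_ses(at, 1.4, as.numeric(at[1, c("x", "y", "z")]),
                                  oracle = orc))
  # a far-field point is outside (use a point still within the lattice)
  far <- apply(at[, c("x", "y", "z")], 2, max) + 3.5
  expect_false(oracle_point_in_ses(at, 1.4, as.numeric(far), oracle = orc))
})

test_that("oracle pocket volumes are null for a single atom and stable under refinement", {
  one <- data.frame(atom_id = 1L, x = 0, y = 0, z = 0, radius = 1.7)
  expect_length(oracle_pocket_volume(one, pocket_params(), resolution = 0.4), 0L)
  cup <- make_cup_fixture()
  v1 <- oracle_pocket_volume(cup$atoms, pocket_params(), resolution = 0.5)
  v2 <- oracle_pocket_volume(cup$atoms, pocket_params(), resolution = 0.25)
  expect_length(v1, 1L)
  expect_length(v2, 1L)
  expect_lt(abs(v1[1] - v2[1]) / v2[1], 0.05)
})
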