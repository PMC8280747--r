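test_that("parameter validation enforces the probe and volume contracts", {
  expect_error(pocket_params(probe_small = 3, probe_big = 1.4), "probe_small")
  expect_error(pocket_params(min_volume = 0), "min_volume")
  expect_error(pocket_params(connectivity = 10), "connectivity")
})

test_that("an isolated atom produces no pockets at any tested spacing", {
  one <- frame_series(tibble::tibble(atom_id = 1L, element = "C", x = 0, y = 0,
                                     z = 0, radius = 1.7, role = "core"))
  for (h in c(0.5, 0.4, 0.3)) {
    expect_equal(nrow(detect_pockets(one, pocket_params(spacing = h))), 0L)
  }
})

test_that("the cup cavity is found as exactly one pocket with the oracle volume", {
  cup <- make_cup_fixture()
  pk <- detect_pockets(cup, pocket_params(spacing = 0.25))
  expect_equal(nrow(pk), 1L)
  ov <- oracle_pocket_volume(cup$atoms, pocket_params(), resolution = 0.25)
  expect_length(ov, 1L)
  expect_lt(abs(pk$volume[1] - ov[1]) / ov[1], 0.15)
  # the centre sits at the cavity centre
  expect_lt(sqrt(pk$x[1]^2 + pk$y[1]^2 + pk$z[1]^2), 1)
})

test_that("the minimum-volume filter removes a scaled-down second cup", {
  big <- make_cup_fixture(center = c(0, 0, 0))
  # scaled cup: cavity radius 2.6 -> cavity volume well below the cutoff
  small <- make_cup_fixture(inner_radius = 2.6, bead_radius = 1.3,
                            aperture_deg = 50, center = c(40, 0, 0))
  small$atoms$atom_id <- small$atoms$atom_id + nrow(big$atoms)
  both <- frame_series(dplyr::bind_rows(big$atoms, small$atoms))
  pk <- detect_pockets(both)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$x[1]), 5) # the surviving pocket is the big cup's
  # oracle confirms the scaled cup is sub-threshold
  ov <- oracle_pocket_volume(small$atoms, pocket_params(), resolution = 0.25)
  expect_length(ov, 0L)
  expect_true(all(attr(ov, "all_volumes") < 100))
})

test_that("raising min_volume never increases the pocket count", {
  fx <- make_coated_np_fixture(seed = 4)
  counts <- vapply(c(50, 100, 150, 250, 400), function(mv) {
    nrow(detect_pockets(fx$frames, pocket_params(min_volume = mv)))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("wall atoms are the contact atoms and exclude distant clusters", {
  cup <- make_cup_fixture()
  far <- tibble::tibble(atom_id = 9000L + 1:3, element = "C",
                        x = c(60, 62, 64), y = 0, z = 0, radius = 1.7,
                        role = "core")
  fs <- frame_series(dplyr::bind_rows(cup$atoms, far))
  pk <- detect_pockets(fs)
  expect_equal(nrow(pk), 1L)
  expect_true(all(pk$wall_atom_ids[[1]] %in% cup$atoms$atom_id))
  expect_gt(length(pk$wall_atom_ids[[1]]), 0)
  # direct criterion checks
  p <- pocket_params()
  vox <- matrix(c(0, 0, 0), 1, 3)
  near <- data.frame(atom_id = 1L, x = 1.7 + p$wall_contact_margin - 0.3,
                     y = 0, z = 0, radius = 1.7)
  expect_equal(wall_atoms(vox, near, p), 1L)
  far1 <- data.frame(atom_id = 2L, x = 10, y = 0, z = 0, radius = 1.7)
  expect_equal(length(wall_atoms(vox, far1, p)), 0L)
})

test_that("depth classification uses the strict 1.3 nm convention", {
  expect_equal(classify_depth(1.1), "deep")
  expect_equal(classify_depth(1.5), "shallow")
  expect_equal(classify_depth(1.3), "shallow") # boundary -> shallow
  expect_error(classify_depth(-0.1), "depth")
  pk <- tibble::tibble(depth_nm = c(1.0, 1.25, 1.4, 2.0))
  cls <- classify_depth(pk$depth_nm)
  expect_equal(mean(cls == "deep") + mean(cls == "shallow"), 1)
})

test_that("maximum pairwise centre distance follows its conventions", {
  empty <- tibble::tibble(x = numeric(), y = numeric(), z = numeric())
  expect_equal(max_pairwise_center_distance(empty), 0)
  one <- tibble::tibble(x = 0, y = 0, z = 0)
  expect_equal(max_pairwise_center_distance(one), 0)
  two <- tibble::tibble(x = c(0, 0), y = c(0, 0), z = c(0, 29))
  expect_equal(max_pairwise_center_distance(two), 2.9)
  three <- tibble::tibble(x = c(0, 10, 25), y = 0, z = 0,
                          frame = 0L)
  expect_equal(max_pairwise_center_distance(three), 2.5)
  expect_equal(median_max_distance(three), 2.5)
})

test_that("detection is deterministic including id assignment", {
  fx <- make_coated_np_fixture(n_frames = 2, jitter = 0.15, seed = 6)
  a <- detect_pockets(fx$frames, fmap = fx$fmap)
  b <- detect_pockets(fx$frames, fmap = fx$fmap)
  expect_identical(tidy(a), tidy(b))
  # ids are volume-ordered from 0 within each frame
  for (f in unique(a$frame)) {
    sub <- a[a$frame == f, ]
    expect_equal(sub$pocket_id, seq_len(nrow(sub)) - 1L)
    expect_true(all(diff(sub$volume) <= 1e-9))
  }
})

test_that("pocket voxels never intersect the vdW interior", {
  cup <- make_cup_fixture()
  pk <- detect_pockets(cup)
  vox <- pk$voxels[[1]]
  co <- as.matrix(cup$atoms[, c("x", "y", "z")])
  mind <- apply(vox, 1, function(v) {
    min(sqrt(colSums((t(co) - v)^2)) - cup$atoms$radius)
  })
  expect_true(all(mind > 0))
})
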