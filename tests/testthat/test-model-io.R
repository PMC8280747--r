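test_that("XYZ topologies load as single-frame series with Bondi radii", {
  xyz <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("5", "comment",
               "C 0.0 0.0 0.0", "N 1.5 0.0 0.0", "O 0.0 1.5 0.0",
               "S 0.0 0.0 1.5", "H 1.0 1.0 1.0"), xyz)
  fs <- load_structure(xyz)
  expect_s3_class(fs, "frame_series")
  expect_equal(n_frames(fs), 1L)
  expect_equal(nrow(fs$atoms), 5L)
  expect_equal(fs$atoms$radius, c(1.70, 1.55, 1.52, 1.80, 1.20))
  # idempotence
  fs2 <- load_structure(xyz)
  expect_identical(fs$atoms, fs2$atoms)
  expect_identical(fs$coords, fs2$coords)
})

test_that("GRO coordinates are converted from nm to angstrom and roles assigned", {
  gro <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("t", "3",
    "    1LIG     C1    1   0.100   0.200   0.300",
    "    1LIG     N2    2   0.200   0.300   0.400",
    "    1SOL     OW    3   1.000   1.000   1.000",
    "   2.0 2.0 2.0"), gro)
  fs <- load_structure(gro)
  expect_equal(fs$atoms$x, c(1, 2, 10))
  expect_equal(fs$atoms$role, c("ligand", "ligand", "solvent"))
  expect_equal(fs$atoms$ligand_index, c(1L, 1L, NA))
})

test_that("atom-count mismatch between topology and trajectory errors", {
  top <- withr::local_tempfile(fileext = ".xyz")
  trj <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "c", "C 0 0 0", "C 2 0 0", "C 0 2 0"), top)
  writeLines(c("2", "c", "C 0 0 0", "C 2 0 0"), trj)
  expect_error(load_structure(top, trj), "mismatch")
})

test_that("unknown elements without a radius override error, overrides work", {
  xyz <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "c", "C 0 0 0", "Xx 2 0 0"), xyz)
  expect_error(load_structure(xyz), "Xx")
  fs <- load_structure(xyz, radius_overrides = c(Xx = 2.1))
  expect_equal(fs$atoms$radius[2], 2.1)
})

test_that("explicit role configs must cover every atom", {
  xyz <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "c", "Au 0 0 0", "C 3 0 0"), xyz)
  expect_error(load_structure(xyz, role_config = list(core = list(elements = "Au"))),
               "unassigned")
  fs <- load_structure(xyz, role_config = list(core = list(elements = "Au"),
                                               ligand = "rest"))
  expect_equal(fs$atoms$role, c("core", "ligand"))
})

test_that("multi-frame XYZ trajectories load with one coordinate set per frame", {
  top <- withr::local_tempfile(fileext = ".xyz")
  trj <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "c", "C 0 0 0", "C 2 0 0"), top)
  writeLines(c("2", "f0", "C 0 0 0", "C 2 0 0",
               "2", "f1", "C 0 0 1", "C 2 0 1"), trj)
  fs <- load_structure(top, trj)
  expect_equal(n_frames(fs), 2L)
  expect_equal(frame_coords(fs, 1)[, 3], c(1, 1))
})

test_that("fragment maps count ligands and entries, by names or positions", {
  fs <- three_ligand_frames()
  cfg <- list(species = list(list(
    resname = "LIG",
    inner = paste0("A", 1:4), central = paste0("A", 5:6), outer = paste0("A", 7:10)
  )))
  fmap <- parse_fragment_map(cfg, fs)
  expect_equal(nrow(fmap), 30L)
  expect_equal(n_ligands(fmap), 3L)
  expect_equal(sum(fmap$fragment_class == "Inner"), 12L)
  cfg_pos <- list(species = list(list(
    resname = "*", inner_pos = 1:4, central_pos = 5:6, outer_pos = 7:10
  )))
  expect_equal(as.data.frame(parse_fragment_map(cfg_pos, fs)), as.data.frame(fmap))
})

test_that("fragment-map contract violations error", {
  fs <- three_ligand_frames()
  omit <- list(species = list(list(
    resname = "LIG", inner = paste0("A", 1:4), central = paste0("A", 5:6),
    outer = paste0("A", 7:9) # A10 uncovered
  )))
  expect_error(parse_fragment_map(omit, fs), "not covered")
  dbl <- list(species = list(list(
    resname = "LIG", inner = paste0("A", 1:5), central = paste0("A", 5:6),
    outer = paste0("A", 7:10)
  )))
  expect_error(parse_fragment_map(dbl, fs), "two fragments")
  noncontig <- list(species = list(list(
    resname = "LIG", inner = paste0("A", c(1:4, 7)), central = paste0("A", 5:6),
    outer = paste0("A", 8:10)
  )))
  expect_error(parse_fragment_map(noncontig, fs), "contiguous")
})

test_that("YAML fragment maps parse the thiol-style inner/central/outer split", {
  fs <- three_ligand_frames()
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "species:",
    "  - resname: LIG",
    "    inner: [A1, A2, A3, A4]",
    "    central: [A5, A6]",
    "    outer: [A7, A8, A9, A10]"), yml)
  fmap <- parse_fragment_map(yml, fs)
  expect_equal(n_ligands(fmap), 3L)
  expect_equal(fmap$fragment_class[fmap$atom_id == 5], "Central")
  expect_equal(fmap$fragment_class[fmap$atom_id == 27], "Outer")
})

test_that("pocket tables round-trip through CSV and JSON identically", {
  fx <- make_coated_np_fixture(seed = 2)
  pk <- detect_pockets(fx$frames, fmap = fx$fmap)
  expect_gt(nrow(pk), 0)
  csv <- withr::local_tempfile(fileext = ".csv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_pocket_table(pk, csv)
  write_pocket_table(pk, jsn)
  a <- read_pocket_table(csv)
  b <- read_pocket_table(jsn)
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-9)
  expect_equal(as.data.frame(b), as.data.frame(tidy(pk)),
               ignore_attr = TRUE, tolerance = 1e-9)
  # fingerprint serialization convention
  expect_match(a$fingerprint[1], "^\\d+:\\d+:\\d+$")
})

test_that("an empty pocket table writes a header-only CSV and reads back empty", {
  csv <- withr::local_tempfile(fileext = ".csv")
  empty <- detect_pockets(
    frame_series(tibble::tibble(atom_id = 1L, element = "C", x = 0, y = 0,
                                z = 0, radius = 1.7, role = "core"))
  )
  expect_equal(nrow(empty), 0L)
  write_pocket_table(empty, csv)
  expect_equal(length(readLines(csv)), 1L)
  back <- read_pocket_table(csv)
  expect_equal(nrow(back), 0L)
})
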