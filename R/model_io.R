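#' Build a frame series from an atom table and coordinates
#'
#' A `frame_series` is the central container of the package: an atom table
#' (constant across frames) plus one coordinate matrix per trajectory frame.
#' Coordinates are always angstrom; trajectories are assumed pre-imaged (no
#' periodic-boundary unwrapping is performed).
#'
#' @param atoms A data frame with at least `atom_id`, `element`, `x`, `y`,
#'   `z`, `radius`, `role`.  Optional: `name`, `resid`, `resname`, `mass`,
#'   `ligand_index`, `fragment_class`.
#' @param coords List of numeric n-by-3 matrices, one per frame, angstrom.
#'   Defaults to a single frame taken from the `x`, `y`, `z` columns.
#' @param frame_stride_ps Sampling interval between frames in picoseconds
#'   (metadata only).
#' @return An object of class `frame_series`.
#' @export
frame_series <- function(atoms, coords = NULL, frame_stride_ps = NA_real_) {
  atoms <- as_tibble(atoms)
  required <- c("atom_id", "element", "x", "y", "z", "radius", "role")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atoms is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  for (col in c("name", "resname")) {
    if (!col %in% names(atoms)) atoms[[col]] <- NA_character_
  }
  if (!"resid" %in% names(atoms)) atoms$resid <- NA_integer_
  if (!"mass" %in% names(atoms)) atoms$mass <- atomic_masses(atoms$element, strict = FALSE)
  if (!"ligand_index" %in% names(atoms)) atoms$ligand_index <- NA_integer_
  if (!"fragment_class" %in% names(atoms)) atoms$fragment_class <- NA_character_
  bad_role <- setdiff(unique(atoms$role), c("core", "ligand", "analyte", "solvent", "ion"))
  if (length(bad_role) > 0) {
    abort(paste0("Unknown role(s): ", paste(bad_role, collapse = ", ")))
  }
  solid <- atoms$role %in% c("core", "ligand", "analyte")
  if (any(solid & (!is.finite(atoms$radius) | atoms$radius <= 0))) {
    bad <- atoms$atom_id[solid & (!is.finite(atoms$radius) | atoms$radius <= 0)]
    abort(paste0("Non-positive radius for atom(s): ", paste(head(bad, 10), collapse = ", ")))
  }
  if (is.null(coords)) {
    coords <- list(unname(as.matrix(atoms[, c("x", "y", "z")])))
  }
  if (!is.list(coords)) coords <- list(coords)
  n <- nrow(atoms)
  for (f in seq_along(coords)) {
    coords[[f]] <- unname(as.matrix(coords[[f]]))
    if (!is.numeric(coords[[f]]) || ncol(coords[[f]]) != 3 || nrow(coords[[f]]) != n) {
      abort(sprintf(
        "Frame %d has %d coordinate rows for %d atoms (atom-count mismatch).",
        f - 1L, nrow(coords[[f]]), n
      ))
    }
  }
  structure(
    list(atoms = atoms, coords = coords, frame_stride_ps = frame_stride_ps),
    class = "frame_series"
  )
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf(
    "<frame_series> %d atoms, %d frame(s)%s\n",
    nrow(x$atoms), length(x$coords),
    if (is.finite(x$frame_stride_ps)) sprintf(", stride %g ps", x$frame_stride_ps) else ""
  ))
  print(dplyr::count(x$atoms, .data$role))
  invisible(x)
}

#' Number of frames in a frame series
#' @param frames A `frame_series`.
#' @return Integer frame count.
#' @export
n_frames <- function(frames) length(frames$coords)

#' Coordinates of one frame
#' @param frames A `frame_series`.
#' @param frame 0-based frame index.
#' @return n-by-3 matrix, angstrom.
#' @export
frame_coords <- function(frames, frame = 0L) {
  stopifnot(frame >= 0, frame < n_frames(frames))
  frames$coords[[frame + 1L]]
}

# ---------------------------------------------------------------------------
# readers

read_xyz_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  frames <- list()
  elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) abort(sprintf("XYZ parse error at line %d of %s", i, path))
    block <- lines[(i + 2L):(i + 1L + nat)]
    tok <- strsplit(trimws(block), "\\s+")
    el <- vapply(tok, `[[`, "", 1L)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + nat
  }
  list(elements = elements, coords = frames, name = NA_character_)
}

read_gro_file <- function(path) {
  lines <- readLines(path)
  nat <- as.integer(trimws(lines[2]))
  block <- lines[3:(2 + nat)]
  resid <- as.integer(substr(block, 1, 5))
  resname <- trimws(substr(block, 6, 10))
  name <- trimws(substr(block, 11, 15))
  x <- as.numeric(substr(block, 21, 28))
  y <- as.numeric(substr(block, 29, 36))
  z <- as.numeric(substr(block, 37, 44))
  # element guessed from the atom name: leading letters, digits stripped
  el <- sub("^([A-Za-z]{1,2}).*$", "\\1", name)
  el <- ifelse(nchar(el) == 2 & !(normalize_element(el) %in% names(.bondi_radii)),
               substr(el, 1, 1), el)
  list(
    elements = normalize_element(el), name = name, resid = resid, resname = resname,
    coords = list(cbind(x, y, z) * 10) # nm -> angstrom
  )
}

read_pdb_file <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(el == "")) {
    el <- sub("^([A-Za-z]{1,2}).*$", "\\1", trimws(at$elety))
  }
  nf <- nrow(pdb$xyz)
  coords <- lapply(seq_len(nf), function(f) matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE))
  list(
    elements = normalize_element(el), name = trimws(at$elety),
    resid = at$resno, resname = trimws(at$resid), coords = coords
  )
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xyz", "gro", "pdb", "dcd")) return(ext)
  abort(paste0("Unrecognised structure/trajectory format: .", ext,
               " (supported: pdb, gro, xyz topologies; dcd, multi-model pdb/xyz trajectories)"))
}

# ---------------------------------------------------------------------------

default_solvent_resnames <- c("SOL", "WAT", "HOH", "TIP3", "TIP4", "SPC", "SPCE")
default_ion_resnames <- c("NA", "NA+", "CL", "CL-", "K", "K+", "SOD", "CLA", "ION")

#' Assign roles to atoms by selection patterns
#'
#' `role_config` is a named list whose names are roles (`core`, `ligand`,
#' `analyte`, `solvent`, `ion`); each entry is a selection: a list with any
#' of `elements`, `resname`, `name`, `atom_id`.  Atoms are assigned the
#' first role (in the given order) whose selection matches; a role given the
#' scalar `"rest"` acts as the fallback.  With `role_config = NULL` a
#' heuristic is used: Au/Ag atoms are `core`, water residues `solvent`,
#' monoatomic-ion residues `ion`, everything else `ligand`.
#'
#' @param atoms Atom tibble (element, name, resid, resname columns).
#' @param role_config Named list of selections, or `NULL`.
#' @return Character vector of roles.
#' @keywords internal
assign_roles <- function(atoms, role_config = NULL) {
  n <- nrow(atoms)
  if (is.null(role_config)) {
    role <- rep("ligand", n)
    role[normalize_element(atoms$element) %in% c("Au", "Ag")] <- "core"
    role[toupper(atoms$resname) %in% default_solvent_resnames] <- "solvent"
    role[toupper(atoms$resname) %in% default_ion_resnames] <- "ion"
    return(role)
  }
  role <- rep(NA_character_, n)
  fallback <- NULL
  for (r in names(role_config)) {
    sel <- role_config[[r]]
    if (identical(sel, "rest")) { fallback <- r; next }
    hit <- rep(TRUE, n)
    if (!is.null(sel$elements)) hit <- hit & normalize_element(atoms$element) %in% normalize_element(sel$elements)
    if (!is.null(sel$resname)) hit <- hit & toupper(atoms$resname) %in% toupper(sel$resname)
    if (!is.null(sel$name)) hit <- hit & atoms$name %in% sel$name
    if (!is.null(sel$atom_id)) hit <- hit & atoms$atom_id %in% sel$atom_id
    role[is.na(role) & hit] <- r
  }
  if (!is.null(fallback)) role[is.na(role)] <- fallback
  if (anyNA(role)) {
    abort(paste0(
      "role_config leaves atom(s) unassigned: ",
      paste(head(atoms$atom_id[is.na(role)], 20), collapse = ", ")
    ))
  }
  role
}

#' Load a structure and optional trajectory
#'
#' Reads a topology (PDB, GRO or XYZ) and, optionally, a trajectory (DCD,
#' multi-model PDB, or multi-frame XYZ), assigns van der Waals radii from
#' the built-in Bondi table, and assigns a role to every atom.  GRO
#' coordinates (nm) are converted to angstrom; all other formats are taken
#' as angstrom.
#'
#' @param topology_path Path to the topology file.
#' @param trajectory_path Optional path to a trajectory file.
#' @param role_config Role selection config (see [assign_roles()]); a path
#'   to a YAML/JSON file or a named list, or `NULL` for the heuristic.
#' @param radius_overrides Named numeric vector of per-element radii,
#'   angstrom.
#' @param atom_radius_overrides Named numeric vector of per-atom radii, the
#'   names being atom ids.
#' @param frame_stride_ps Sampling interval metadata, picoseconds.
#' @return A [frame_series()].
#' @export
load_structure <- function(topology_path, trajectory_path = NULL,
                           role_config = NULL, radius_overrides = NULL,
                           atom_radius_overrides = NULL,
                           frame_stride_ps = NA_real_) {
  if (!file.exists(topology_path)) abort(paste0("Topology file not found: ", topology_path))
  fmt <- guess_format(topology_path)
  top <- switch(fmt,
    xyz = read_xyz_file(topology_path),
    gro = read_gro_file(topology_path),
    pdb = read_pdb_file(topology_path),
    abort(paste0("Format not usable as topology: ", fmt))
  )
  n <- length(top$elements)
  coords <- top$coords
  if (!is.null(trajectory_path)) {
    if (!file.exists(trajectory_path)) abort(paste0("Trajectory file not found: ", trajectory_path))
    tfmt <- guess_format(trajectory_path)
    if (tfmt == "dcd") {
      xyz <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
      coords <- lapply(seq_len(nrow(xyz)), function(f) matrix(xyz[f, ], ncol = 3, byrow = TRUE))
    } else {
      tr <- switch(tfmt,
        xyz = read_xyz_file(trajectory_path),
        pdb = read_pdb_file(trajectory_path),
        abort(paste0("Format not usable as trajectory: ", tfmt))
      )
      coords <- tr$coords
    }
    for (f in seq_along(coords)) {
      if (nrow(coords[[f]]) != n) {
        abort(sprintf(
          "Atom-count mismatch: topology has %d atoms, trajectory frame %d has %d.",
          n, f - 1L, nrow(coords[[f]])
        ))
      }
    }
  }
  if (is.character(role_config) && length(role_config) == 1L) {
    role_config <- read_config_file(role_config)
  }
  atoms <- tibble(
    atom_id = seq_len(n),
    element = normalize_element(top$elements),
    name = top$name %||% NA_character_,
    resid = top$resid %||% NA_integer_,
    resname = top$resname %||% NA_character_,
    x = coords[[1]][, 1], y = coords[[1]][, 2], z = coords[[1]][, 3]
  )
  atoms$role <- assign_roles(atoms, role_config)
  atoms$radius <- vdw_radii(atoms$element, overrides = radius_overrides,
                            strict = FALSE)
  if (!is.null(atom_radius_overrides)) {
    idx <- match(as.integer(names(atom_radius_overrides)), atoms$atom_id)
    atoms$radius[idx] <- unname(atom_radius_overrides)
  }
  needs_r <- atoms$role %in% c("core", "ligand", "analyte")
  if (any(needs_r & is.na(atoms$radius))) {
    bad <- atoms[needs_r & is.na(atoms$radius), ]
    abort(paste0(
      "Unknown element with no radius override for atom(s): ",
      paste(head(sprintf("%d (%s)", bad$atom_id, bad$element), 10), collapse = ", ")
    ))
  }
  atoms$mass <- atomic_masses(atoms$element, strict = FALSE)
  # ligand instances: one per (resname, resid) residue among ligand atoms
  atoms$ligand_index <- NA_integer_
  lig <- atoms$role == "ligand"
  if (any(lig)) {
    key <- paste(atoms$resname[lig], atoms$resid[lig], sep = "\r")
    atoms$ligand_index[lig] <- as.integer(factor(key, levels = unique(key)))
  }
  frame_series(atoms, coords, frame_stride_ps)
}

read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) return(yaml::read_yaml(path))
  if (ext == "json") return(jsonlite::fromJSON(path, simplifyVector = TRUE))
  abort(paste0("Config must be YAML or JSON: ", path))
}

# ---------------------------------------------------------------------------
# pocket table serialization

pocket_table_cols <- c(
  "frame", "pocket_id", "volume", "x", "y", "z", "depth_nm", "depth_class",
  "n_wall_atoms", "wall_atom_ids", "n_inner", "n_central", "n_outer",
  "fingerprint", "n_ligands", "occupied", "analyte_ids"
)

empty_pocket_table <- function() {
  tibble(
    frame = integer(), pocket_id = integer(), volume = numeric(),
    x = numeric(), y = numeric(), z = numeric(),
    depth_nm = numeric(), depth_class = character(),
    n_wall_atoms = integer(), wall_atom_ids = list(),
    n_inner = integer(), n_central = integer(), n_outer = integer(),
    fingerprint = character(), n_ligands = integer(),
    occupied = logical(), analyte_ids = list()
  )
}

#' Write and read per-pocket record tables
#'
#' One row per (frame, pocket): frame index, pocket id, volume (cubic
#' angstrom), centre xyz (angstrom), depth (nm), wall-atom ids, fragment
#' fingerprint (serialized `"nI:nC:nO"`), ligand count, occupancy flag and
#' analyte ids.  The JSON dialect round-trips losslessly; CSV stores the id
#' sets as space-separated strings and parses back to the same content.
#'
#' @param records A pocket table, as produced by [detect_pockets()].
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; defaults from the file extension.
#' @return `path`, invisibly (writer); a pocket tibble (reader).
#' @export
write_pocket_table <- function(records, path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("csv", "json")) abort("format must be 'csv' or 'json'")
  records <- as_tibble(records)
  for (col in setdiff(pocket_table_cols, names(records))) {
    records[[col]] <- switch(col,
      wall_atom_ids = , analyte_ids = replicate(nrow(records), integer(), simplify = FALSE),
      occupied = NA, depth_class = , fingerprint = NA_character_, NA
    )
  }
  records <- records[pocket_table_cols]
  flat <- records
  flat$wall_atom_ids <- vapply(records$wall_atom_ids, function(v) paste(v, collapse = " "), "")
  flat$analyte_ids <- vapply(records$analyte_ids, function(v) paste(v, collapse = " "), "")
  if (format == "csv") {
    write.csv(flat, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(flat, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_pocket_table
#' @export
read_pocket_table <- function(path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  if (format == "csv") {
    flat <- read.csv(path, stringsAsFactors = FALSE,
                     colClasses = c(wall_atom_ids = "character",
                                    analyte_ids = "character",
                                    fingerprint = "character",
                                    depth_class = "character"))
    flat <- as_tibble(flat)
  } else if (format == "json") {
    flat <- as_tibble(jsonlite::fromJSON(path, simplifyVector = TRUE))
    if (nrow(flat) == 0) return(empty_pocket_table())
  } else {
    abort("format must be 'csv' or 'json'")
  }
  if (nrow(flat) == 0) return(empty_pocket_table())
  parse_ids <- function(s) {
    lapply(s, function(v) {
      if (is.na(v) || !nzchar(v)) integer() else as.integer(strsplit(v, " ")[[1]])
    })
  }
  flat$wall_atom_ids <- parse_ids(as.character(flat$wall_atom_ids))
  flat$analyte_ids <- parse_ids(as.character(flat$analyte_ids))
  for (col in c("frame", "pocket_id", "n_wall_atoms", "n_inner", "n_central",
                "n_outer", "n_ligands")) {
    flat[[col]] <- as.integer(flat[[col]])
  }
  for (col in c("volume", "x", "y", "z", "depth_nm")) flat[[col]] <- as.numeric(flat[[col]])
  flat$occupied <- as.logical(flat$occupied)
  flat$depth_class <- as.character(flat$depth_class)
  flat$depth_class[!is.na(flat$depth_class) & !nzchar(flat$depth_class)] <- NA_character_
  flat$fingerprint <- as.character(flat$fingerprint)
  flat[pocket_table_cols]
}
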