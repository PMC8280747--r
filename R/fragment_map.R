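#' Parse a fragment-map configuration
#'
#' Every coating ligand is divided into three chemical blocks: an inner
#' (core-proximal, typically alkyl) fragment, a central moiety (amide or
#' urea) and an outer terminus (oligo-ethylene-glycol).  The fragment map
#' assigns every ligand atom to its ligand instance and fragment class;
#' pocket fingerprints are counted over these (ligand, class) pairs.
#'
#' The configuration (YAML, JSON, or an equivalent R list) holds one entry
#' per ligand species under `species:`.  Each entry selects the residues it
#' covers via `resname:` (`"*"` matches any) and declares the membership of
#' the three fragments either by atom name (`inner:`, `central:`, `outer:`)
#' or by 1-based position within the ligand's atom order (`inner_pos:`,
#' `central_pos:`, `outer_pos:`).
#'
#' @param config Path to a YAML/JSON file, or a named list.
#' @param frames A [frame_series()] whose ligand atoms the map must cover.
#' @return A `fragment_map`: a tibble with columns `atom_id`,
#'   `ligand_index`, `fragment_class`, carrying `n_ligands` as an attribute.
#' @export
parse_fragment_map <- function(config, frames) {
  if (is.character(config) && length(config) == 1L) config <- read_config_file(config)
  species <- config$species %||% config
  if (is.data.frame(species)) species <- split(species, seq_len(nrow(species)))
  atoms <- frames$atoms
  lig <- atoms[atoms$role == "ligand", ]
  if (nrow(lig) == 0) abort("No ligand atoms in the structure.")
  if (anyNA(lig$ligand_index)) {
    abort("Ligand atoms without a ligand_index; load_structure assigns these from residues.")
  }
  entries <- vector("list", length(unique(lig$ligand_index)))
  classes <- c("inner", "central", "outer")
  class_labels <- c(inner = "Inner", central = "Central", outer = "Outer")
  for (li in unique(lig$ligand_index)) {
    res <- lig[lig$ligand_index == li, ]
    res <- res[order(res$atom_id), ]
    sp <- NULL
    for (s in species) {
      rn <- s$resname %||% "*"
      if (identical(rn, "*") || (!is.na(res$resname[1]) && toupper(res$resname[1]) %in% toupper(rn))) {
        sp <- s
        break
      }
    }
    if (is.null(sp)) {
      abort(sprintf("Ligand %d (resname %s) matches no species in the fragment map.",
                    li, res$resname[1]))
    }
    cls <- rep(NA_character_, nrow(res))
    for (cl in classes) {
      members <- logical(nrow(res))
      if (!is.null(sp[[cl]])) members <- members | res$name %in% unlist(sp[[cl]])
      pos_key <- paste0(cl, "_pos")
      if (!is.null(sp[[pos_key]])) {
        pos <- as.integer(unlist(sp[[pos_key]]))
        if (any(pos < 1 | pos > nrow(res))) {
          abort(sprintf("Fragment positions out of range for ligand %d.", li))
        }
        members[pos] <- TRUE
      }
      clash <- members & !is.na(cls)
      if (any(clash)) {
        abort(sprintf("Atom(s) %s of ligand %d claimed by two fragments.",
                      paste(res$atom_id[clash], collapse = ", "), li))
      }
      cls[members] <- class_labels[[cl]]
    }
    if (anyNA(cls)) {
      abort(sprintf("Ligand %d atom(s) not covered by any fragment declaration: %s",
                    li, paste(res$atom_id[is.na(cls)], collapse = ", ")))
    }
    # fragment blocks must be contiguous along the ligand's atom order
    runs <- rle(cls)
    if (any(duplicated(runs$values))) {
      abort(sprintf("Fragment classes of ligand %d are not contiguous blocks.", li))
    }
    entries[[match(li, unique(lig$ligand_index))]] <- tibble(
      atom_id = res$atom_id, ligand_index = li, fragment_class = cls
    )
  }
  fmap <- dplyr::bind_rows(entries)
  if (anyDuplicated(fmap$atom_id)) abort("Fragment map covers an atom twice.")
  structure(fmap, n_ligands = length(unique(fmap$ligand_index)),
            class = c("fragment_map", class(fmap)))
}

#' Number of ligands covered by a fragment map
#' @param fmap A `fragment_map`.
#' @return Integer.
#' @export
n_ligands <- function(fmap) attr(fmap, "n_ligands")

#' Stamp fragment assignments onto a frame series
#'
#' @param frames A [frame_series()].
#' @param fmap A [parse_fragment_map()] result.
#' @return The frame series with `fragment_class` filled on the atom table.
#' @export
set_fragments <- function(frames, fmap) {
  idx <- match(frames$atoms$atom_id, fmap$atom_id)
  hit <- !is.na(idx)
  frames$atoms$fragment_class[hit] <- fmap$fragment_class[idx[hit]]
  frames$atoms$ligand_index[hit] <- fmap$ligand_index[idx[hit]]
  frames
}
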