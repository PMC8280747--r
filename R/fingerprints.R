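# Shared counting core: a fragment instance (ligand_index, fragment_class)
# is counted once if at least one of its atoms is a wall atom.
fingerprint_counts <- function(wall_atom_ids, fmap) {
  hit <- fmap[fmap$atom_id %in% wall_atom_ids, , drop = FALSE]
  inst <- dplyr::distinct(hit[, c("ligand_index", "fragment_class")])
  key <- c(
    sum(inst$fragment_class == "Inner"),
    sum(inst$fragment_class == "Central"),
    sum(inst$fragment_class == "Outer")
  )
  list(key = as.integer(key), n_ligands = length(unique(inst$ligand_index)))
}

#' Fragment fingerprint of one pocket
#'
#' The fingerprint is the count triple (inner, central, outer) of ligand
#' fragment instances contributing at least one wall atom; it univocally
#' labels a class of degenerate pockets with the same fragment
#' composition.  Non-ligand wall atoms (e.g. core metal) are ignored.
#'
#' @param wall_atom_ids Integer vector of wall atom ids.
#' @param fmap A [parse_fragment_map()] result.
#' @return A list with `key` (integer triple, inner/central/outer) and
#'   `n_ligands` (distinct ligands contributing).
#' @export
pocket_fingerprint <- function(wall_atom_ids, fmap) {
  res <- fingerprint_counts(wall_atom_ids, fmap)
  if (sum(res$key) == 0) {
    abort("No ligand fragments among the wall atoms (core-only pocket).")
  }
  res
}

#' Ranked fingerprint table
#'
#' Counts pockets per fingerprint and ranks them by count (descending;
#' ties broken by lexicographic key).  A small number of fingerprints
#' typically covers a disproportionate share of all pockets.
#'
#' @param records A pocket table with fingerprint columns filled.
#' @param top_k Number of top fingerprints to keep (default 14).
#' @return Tibble with `fingerprint`, `n_inner`, `n_central`, `n_outer`,
#'   `count`, `percent`, `cumulative_percent`.
#' @export
aggregate_fingerprints <- function(records, top_k = 14) {
  if (top_k < 1) abort("top_k must be >= 1")
  if (nrow(records) == 0) {
    return(tibble(fingerprint = character(), n_inner = integer(),
                  n_central = integer(), n_outer = integer(),
                  count = integer(), percent = numeric(),
                  cumulative_percent = numeric()))
  }
  total <- nrow(records)
  records |>
    dplyr::count(.data$fingerprint, .data$n_inner, .data$n_central,
                 .data$n_outer, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$n_inner, .data$n_central,
                   .data$n_outer) |>
    dplyr::mutate(percent = 100 * .data$count / total,
                  cumulative_percent = cumsum(.data$percent)) |>
    head(top_k)
}

#' Fragment-class occurrence percentages
#'
#' For each fragment class, 100 times the summed per-pocket count of that
#' class divided by the sum of all fragment counts; the three values sum
#' to 100.
#'
#' @param records A pocket table with fingerprint columns filled.
#' @return Tibble with `fragment_class` and `percent`; on an empty table
#'   all-zero with a warning.
#' @export
fragment_occurrence <- function(records) {
  classes <- c("Inner", "Central", "Outer")
  if (nrow(records) == 0 || all(is.na(records$n_inner))) {
    warn("No fingerprinted pockets; fragment occurrence is zero.")
    return(tibble(fragment_class = classes, percent = c(0, 0, 0)))
  }
  tot <- c(sum(records$n_inner), sum(records$n_central), sum(records$n_outer))
  tibble(fragment_class = classes, percent = 100 * tot / sum(tot))
}

#' Mean number of fragments forming a pocket
#' @param records A pocket table with fingerprint columns filled.
#' @return Scalar mean of (inner + central + outer) over pockets.
#' @export
mean_fragments_per_pocket <- function(records) {
  if (nrow(records) == 0) return(NA_real_)
  mean(records$n_inner + records$n_central + records$n_outer)
}
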