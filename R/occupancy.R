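#' Classify pockets as occupied by analyte molecules
#'
#' An analyte molecule (a residue among `role = "analyte"` atoms) is
#' counted inside a pocket when at least `occupancy_threshold` (default
#' 50%) of its heavy atoms lie within the pocket voxel region dilated by
#' the small probe radius -- the dilation admits analytes seated against
#' the wall where voxels are excluded by van der Waals overlap.  Each
#' analyte is assigned to at most one pocket: the one containing most of
#' its heavy atoms, ties going to the lower `pocket_id`.
#'
#' @param records A pocket table from [detect_pockets()] (must retain the
#'   `voxels` list-column).
#' @param frames The [frame_series()] the pockets came from.
#' @param params The [pocket_params()] used for detection.
#' @return The pocket table with `occupied` and `analyte_ids` filled.
#'   Analyte ids are the molecule indices (1-based, in order of appearance
#'   among analyte residues).
#' @export
assign_analytes <- function(records, frames, params = pocket_params()) {
  if (!"voxels" %in% names(records)) {
    abort("records lacks the `voxels` column; run assign_analytes on the in-memory detect_pockets() output")
  }
  an <- frames$atoms$role == "analyte"
  if (!any(an)) abort("No analyte atoms (role = 'analyte') in the structure.")
  heavy <- an & frames$atoms$element != "H"
  key <- paste(frames$atoms$resname[heavy], frames$atoms$resid[heavy], sep = "\r")
  mol <- as.integer(factor(key, levels = unique(key)))
  heavy_idx <- which(heavy)
  records$occupied <- FALSE
  records$analyte_ids <- replicate(nrow(records), integer(), simplify = FALSE)
  cutoff <- params$probe_small
  for (f in unique(records$frame)) {
    co <- frame_coords(frames, f)[heavy_idx, , drop = FALSE]
    rows <- which(records$frame == f)
    # per molecule, count heavy atoms inside each pocket's dilated region
    n_in <- matrix(0L, nrow = max(mol), ncol = length(rows))
    for (ri in seq_along(rows)) {
      vox <- records$voxels[[rows[ri]]]
      lo <- apply(vox, 2, min) - cutoff
      hi <- apply(vox, 2, max) + cutoff
      cand <- which(co[, 1] >= lo[1] & co[, 1] <= hi[1] &
                    co[, 2] >= lo[2] & co[, 2] <= hi[2] &
                    co[, 3] >= lo[3] & co[, 3] <= hi[3])
      for (ai in cand) {
        d2 <- (vox[, 1] - co[ai, 1])^2 + (vox[, 2] - co[ai, 2])^2 +
              (vox[, 3] - co[ai, 3])^2
        if (min(d2) <= cutoff^2) {
          n_in[mol[ai], ri] <- n_in[mol[ai], ri] + 1L
        }
      }
    }
    n_heavy <- tabulate(mol)
    for (m in seq_len(max(mol))) {
      frac <- n_in[m, ] / n_heavy[m]
      ok <- which(frac >= params$occupancy_threshold)
      if (length(ok) == 0) next
      # most heavy atoms inside; tie -> lower pocket_id (rows are id-ordered)
      best <- ok[which.max(n_in[m, ok])]
      r <- rows[best]
      records$occupied[r] <- TRUE
      records$analyte_ids[[r]] <- c(records$analyte_ids[[r]], m)
    }
  }
  records
}

#' Occupancy summary statistics
#'
#' Overall occupied fraction plus depth/volume distributions and fragment
#' occurrence split by occupied vs empty pockets.
#'
#' @param records A pocket table with `occupied` flags.
#' @return A list: `percent_occupied`, `by_status` (per-subset volume and
#'   depth summaries), `fragment_occurrence` (per subset, when
#'   fingerprints are present).
#' @export
occupancy_summary <- function(records) {
  if (nrow(records) == 0) {
    return(list(percent_occupied = 0,
                by_status = tibble(status = character(), n = integer(),
                                   mean_volume = numeric(), mean_depth_nm = numeric()),
                fragment_occurrence = NULL))
  }
  occ <- records$occupied %in% TRUE
  by_status <- tibble(status = ifelse(occ, "occupied", "empty"),
                      volume = records$volume, depth_nm = records$depth_nm) |>
    dplyr::group_by(.data$status) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_volume = mean(.data$volume),
      mean_depth_nm = mean(.data$depth_nm),
      .groups = "drop"
    )
  frag <- NULL
  if (!all(is.na(records$n_inner))) {
    frag <- list(
      occupied = if (any(occ)) fragment_occurrence(records[occ, ]) else NULL,
      empty = if (any(!occ)) fragment_occurrence(records[!occ, ]) else NULL
    )
  }
  list(
    percent_occupied = 100 * mean(occ),
    by_status = by_status,
    fragment_occurrence = frag
  )
}
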