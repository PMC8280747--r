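#' Tidy a pocket table
#'
#' Returns the per-pocket records as a plain tibble without the voxel
#' payload, one row per (frame, pocket).
#'
#' @param x A `pocket_table`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pocket_table
#' @export
tidy.pocket_table <- function(x, ...) {
  out <- as_tibble(x)
  out$voxels <- NULL
  out
}

#' One-row summary of a pocket analysis
#'
#' @param x A `pocket_table`.
#' @param ... Unused.
#' @return One-row tibble: frame and pocket counts, mean/sd pockets per
#'   frame, mean volume, deep fraction, occupancy percentage (NA when
#'   occupancy was not assigned).
#' @method glance pocket_table
#' @export
glance.pocket_table <- function(x, ...) {
  fs <- frame_summary(x)
  deep <- mean(x$depth_class == "deep")
  tibble(
    n_frames = fs$n_frames,
    n_pockets = fs$total_pockets,
    mean_pockets = fs$mean_pockets,
    sd_pockets = fs$sd_pockets,
    mean_volume = if (nrow(x) > 0) mean(x$volume) else NA_real_,
    deep_fraction = deep,
    percent_occupied = if (all(is.na(x$occupied))) NA_real_ else 100 * mean(x$occupied %in% TRUE)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
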