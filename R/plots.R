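#' Plot a pocket table
#'
#' Histogram panels of the quantities used to characterise a monolayer:
#' pockets per frame, pocket volume, and pocket depth (distance of the
#' pocket centre from the metal-core centre of mass), with occupied
#' pockets overlaid when occupancy flags are present.
#'
#' @param object A `pocket_table`.
#' @param which One of `"volume"`, `"depth"`, `"counts"`.
#' @param binwidth Histogram bin width (cubic angstrom, nm, or count).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pocket_table
#' @export
autoplot.pocket_table <- function(object, which = c("volume", "depth", "counts"),
                                  binwidth = NULL, ...) {
  which <- match.arg(which)
  df <- tidy(object)
  if (which == "counts") {
    counts <- pockets_per_frame(object)
    return(
      ggplot2::ggplot(counts, ggplot2::aes(x = .data$n_pockets)) +
        ggplot2::geom_histogram(binwidth = binwidth %||% 1, fill = "grey60",
                                colour = "grey20") +
        ggplot2::labs(x = "pockets per frame", y = "frames") +
        ggplot2::theme_minimal()
    )
  }
  has_occ <- !all(is.na(df$occupied))
  if (which == "volume") {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$volume)) +
      ggplot2::geom_histogram(binwidth = binwidth %||% 25, fill = "grey60",
                              colour = "grey20") +
      ggplot2::labs(x = expression(volume ~ (ring(A)^3)), y = "pockets")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$depth_nm)) +
      ggplot2::geom_histogram(binwidth = binwidth %||% 0.05, fill = "grey60",
                              colour = "grey20") +
      ggplot2::labs(x = "distance from core centre of mass (nm)", y = "pockets")
  }
  if (has_occ) {
    occ <- df[df$occupied %in% TRUE, ]
    xvar <- if (which == "volume") "volume" else "depth_nm"
    p <- p + ggplot2::geom_histogram(
      data = occ, ggplot2::aes(x = .data[[xvar]]),
      binwidth = binwidth %||% (if (which == "volume") 25 else 0.05),
      fill = "cyan3", alpha = 0.6, colour = "grey20"
    )
  }
  p + ggplot2::theme_minimal()
}

#' Fingerprint ranking plot
#'
#' @param records A pocket table with fingerprints.
#' @param top_k Fingerprints to show.
#' @return A ggplot object.
#' @export
plot_fingerprints <- function(records, top_k = 14) {
  agg <- aggregate_fingerprints(records, top_k)
  agg$fingerprint <- factor(agg$fingerprint, levels = rev(agg$fingerprint))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$percent, y = .data$fingerprint)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "% of all pockets", y = "fingerprint (inner:central:outer)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
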