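# ggplot2 views of the main result objects.

#' Plot differential-expression counts by stage, tier and direction
#'
#' Bar chart of DE gene counts per developmental stage, filled by direction
#' of temperature bias, faceted by species and tier.
#'
#' @param object A `thermode_de` object.
#' @param tier Tiers to show (default both).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot thermode_de
#' @export
autoplot.thermode_de <- function(object, tier = c("stringent", "suggestive"),
                                 ...) {
  dat <- object$results |>
    dplyr::filter(.data$tier %in% !!tier) |>
    dplyr::count(.data$species, .data$stage, .data$tier, .data$direction)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$stage), y = .data$n,
                                    fill = .data$direction)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_grid(tier ~ species, scales = "free_y") +
    ggplot2::scale_fill_manual(
      values = c(low = "#2166ac", high = "#b2182b", none = "grey70"),
      labels = c(low = "26°C-biased", high = "31°C-biased",
                 none = "tied")
    ) +
    ggplot2::labs(x = "developmental stage", y = "differentially expressed genes",
                  fill = "direction") +
    ggplot2::theme_minimal()
}

#' Plot normalization factors per library
#'
#' Dot plot of housekeeping, upper-quartile and combined scale factors,
#' with the geometric-mean-1 centering line.
#'
#' @param object A `thermode_norm` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot thermode_norm
#' @export
autoplot.thermode_norm <- function(object, ...) {
  dat <- object$factors |>
    tidyr::pivot_longer(cols = c("hk_factor", "uq_factor", "combined_factor"),
                        names_to = "factor_type", values_to = "factor")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$library_id, y = .data$factor,
                                    colour = .data$factor_type)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(title = paste("normalization factors,", object$scheme$name),
                  x = NULL, y = "scale factor (log)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of per-stage direction profiles
#'
#' Tile plot of direction of temperature bias (26 vs 31 degrees C) per gene
#' and stage, the standard view of how temperature responsiveness unfolds
#' over development.
#'
#' @param profiles Tibble `gene_id`, `stage`, `direction` (e.g. the
#'   `direction_profiles.tsv` pipeline artifact or [direction_profile()]
#'   rows).
#' @return A ggplot.
#' @export
plot_direction_profiles <- function(profiles) {
  check_cols(profiles, c("gene_id", "stage", "direction"))
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = factor(.data$stage), y = .data$gene_id,
                               fill = .data$direction)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(
      values = c(low = "#2166ac", high = "#b2182b", ns = "grey90",
                 none = "grey90"),
      labels = c(low = "26°C-biased", high = "31°C-biased",
                 ns = "not significant", none = "not significant")
    ) +
    ggplot2::labs(x = "developmental stage", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of Venn-region sizes for an overlap report
#'
#' @param object An `overlap_report` from [overlap_sets()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot overlap_report
#' @export
autoplot.overlap_report <- function(object, ...) {
  ggplot2::ggplot(object$regions,
                  ggplot2::aes(x = stats::reorder(.data$region, -.data$size),
                               y = .data$size)) +
    ggplot2::geom_col(fill = "#4393c3") +
    ggplot2::labs(x = "overlap region", y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
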