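#' @importFrom ggplot2 autoplot ggplot aes
#' @export
ggplot2::autoplot

#' Discriminant-space plot of a PCA-LDA fit
#'
#' Samples in the space of the first two linear discriminants (or LD1 by
#' group when only one discriminant exists), coloured by class, with class
#' centroids marked.
#'
#' @param object `md_pca_lda` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot md_pca_lda
#' @export
autoplot.md_pca_lda <- function(object, ...) {
  d <- object$discriminants
  if ("LD2" %in% names(d)) {
    ggplot(d, aes(x = .data$LD1, y = .data$LD2, colour = .data$group)) +
      ggplot2::geom_point(size = 2.5) +
      ggplot2::geom_point(data = object$centroids, shape = 4, size = 4,
                          stroke = 1.5) +
      ggplot2::labs(title = "PCA-LDA discrimination",
                    colour = "state")
  } else {
    ggplot(d, aes(x = .data$LD1, y = .data$group, colour = .data$group)) +
      ggplot2::geom_point(size = 2.5, show.legend = FALSE) +
      ggplot2::labs(title = "PCA-LDA discrimination", y = "state")
  }
}

#' Null-divergence histogram with the fitted cutoff
#'
#' @param object `md_cutoff` model.
#' @param null_hd The null divergences the model was fitted on.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot md_cutoff
#' @export
autoplot.md_cutoff <- function(object, null_hd, ...) {
  ggplot(tibble::tibble(hd = null_hd), aes(x = .data$hd)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$cutoff, colour = "firebrick",
                        linetype = 2) +
    ggplot2::labs(x = "Hellinger divergence (control vs centroid)",
                  y = "sites",
                  title = sprintf("Null divergence and %s cutoff = %.3g",
                                  object$method, object$cutoff))
}

#' Volcano-style plot of DMG test results
#'
#' log2 fold change of treatment vs control DMP counts against the
#' BH-adjusted p-value; called DMGs highlighted.
#'
#' @param dmg DMG result tibble from [test_dmgs()].
#' @return A ggplot.
#' @export
plot_dmg_volcano <- function(dmg) {
  ggplot(dmg, aes(x = .data$log2fc, y = -log10(.data$p_adj),
                  colour = .data$is_dmg)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (DMP counts)",
                  y = "-log10 adjusted p", colour = "DMG")
}

#' Heat-map view of a position frequency matrix
#'
#' A text-free stand-in for a sequence logo: per-position base frequencies
#' as tiles, with the modal base annotated.
#'
#' @param pfm N x 4 frequency matrix from [frequency_matrix()].
#' @return A ggplot.
#' @export
plot_frequency_matrix <- function(pfm) {
  df <- tibble::as_tibble(pfm) |>
    dplyr::mutate(position = dplyr::row_number()) |>
    tidyr::pivot_longer(-"position", names_to = "base",
                        values_to = "frequency")
  modal <- df |>
    dplyr::group_by(.data$position) |>
    dplyr::slice_max(.data$frequency, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  ggplot(df, aes(x = .data$position, y = .data$base,
                 fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(data = modal, ggplot2::aes(label = .data$base),
                       colour = "white", fontface = "bold") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_x_continuous(breaks = seq_len(nrow(pfm))) +
    ggplot2::labs(x = "motif position", y = NULL, fill = "freq")
}
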