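# ggplot2 graphics for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot Ks density curves by pair category
#'
#' @param object A [ks_distribution()] object.
#' @param peaks Optional output of [find_peaks()] to mark peak locations.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ks_distribution <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(object$kde,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Ks (synonymous substitutions per site)",
                  y = "density", colour = "pair category") +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    p <- p + ggplot2::geom_vline(
      data = dplyr::filter(peaks, .data$rank == 1),
      ggplot2::aes(xintercept = .data$peak_ks, colour = .data$category),
      linetype = "dashed", show.legend = FALSE
    )
  }
  p
}

#' Histogram of per-locus subgenome expression bias
#'
#' @param object A [dominance_summary()] tibble.
#' @param binwidth Histogram bin width on the log2 scale.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dominance_summary <- function(object, binwidth = 0.25, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$log2_b_over_a,
                                       fill = .data$bias)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "log2(subgenome B / subgenome A mean TPM)",
                  y = "loci", fill = "bias") +
    ggplot2::theme_minimal()
}

#' Heatmap-style view of a contact map
#'
#' @param contacts Contacts tibble.
#' @param grouping Optional grouping tibble used to order unitigs by group.
#' @return A ggplot.
#' @export
plot_contacts <- function(contacts, grouping = NULL) {
  cc <- canonical_contacts(contacts)
  full <- dplyr::bind_rows(
    cc,
    dplyr::rename(cc, unitig_a = "unitig_b", unitig_b = "unitig_a")
  )
  if (!is.null(grouping)) {
    ord <- grouping |>
      dplyr::arrange(.data$group, .data$unitig) |>
      dplyr::pull(.data$unitig)
    full$unitig_a <- factor(full$unitig_a, levels = ord)
    full$unitig_b <- factor(full$unitig_b, levels = ord)
  }
  ggplot2::ggplot(full, ggplot2::aes(x = .data$unitig_a, y = .data$unitig_b,
                                     fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Hi-C links") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
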