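# ggplot2 displays for the QC and result objects.

#' Footprint length histogram plot
#'
#' @param reads Read tibble (or a precomputed [length_histogram()] tibble).
#' @return A ggplot.
#' @export
plot_length_histogram <- function(reads) {
  h <- if (all(c("length", "n") %in% names(reads))) reads else
    length_histogram(reads)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$length, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "footprint length (nt)", y = "reads",
                  title = "Footprint length distribution") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.metagene_profile <- function(object, ...) {
  anchor <- attr(object, "anchor")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$position, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_wrap(~length, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = sprintf("5' end position relative to %s codon (nt)", anchor),
      y = "reads",
      title = sprintf("Metagene profile (%s-anchored)", anchor)) +
    ggplot2::theme_minimal()
}

#' Reading-frame composition bars
#'
#' @param report Output of [frame_report()] or [frame_in_window()].
#' @return A ggplot.
#' @export
plot_frame_report <- function(report) {
  p <- ggplot2::ggplot(report,
                       ggplot2::aes(x = factor(.data$frame),
                                    y = .data$fraction)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "reading frame of A-site", y = "fraction",
                  title = "Triplet periodicity") +
    ggplot2::theme_minimal()
  if ("length" %in% names(report)) {
    p <- p + ggplot2::facet_wrap(~length, labeller = ggplot2::label_both)
  }
  p
}

#' @export
autoplot.ribo_te_fit <- function(object, ...) {
  res <- dplyr::filter(object$results, .data$class != "low_count")
  ggplot2::ggplot(res, ggplot2::aes(x = .data$rna_log2fc,
                                    y = .data$ribo_log2fc,
                                    colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(
      up = "firebrick", down = "royalblue", unchanged = "grey60")) +
    ggplot2::labs(
      x = "RNA log2 fold change", y = "footprint log2 fold change",
      title = sprintf("%s vs %s: footprint vs transcript fold changes",
                      object$treatment, object$reference)) +
    ggplot2::theme_minimal()
}

#' Volcano plot of translational-efficiency changes
#'
#' @param fit A `ribo_te_fit`.
#' @return A ggplot of TE log2FC against -log10 FDR.
#' @export
plot_te_volcano <- function(fit) {
  res <- dplyr::filter(fit$results, !is.na(.data$fdr))
  ggplot2::ggplot(res, ggplot2::aes(x = .data$te_log2fc,
                                    y = -log10(.data$fdr),
                                    colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-fit$lfc_threshold,
                                       fit$lfc_threshold),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(
      up = "firebrick", down = "royalblue", unchanged = "grey60")) +
    ggplot2::labs(x = "translational-efficiency log2 fold change",
                  y = "-log10 FDR") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
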