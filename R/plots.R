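# ggplot2 views of the main result types.

#' Heat map of a bin index
#'
#' Bins on the y axis, samples on the x axis, tag index as fill -- the
#' visual that makes CDH presence/absence apparent in scaled data.
#'
#' @param object a [bin_index()]
#' @param ... unused
#' @return a ggplot
#' @method autoplot bin_index
#' @export
autoplot.bin_index <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$label,
                                   fill = .data$tag_index)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = if (object$scaled)
      "scaled tag index" else "tag index") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Pseudo-copy-number strip plot
#'
#' @param estimates tibble from [pseudo_copy_number()]
#' @return a ggplot
#' @export
plot_copy_number <- function(estimates) {
  ggplot2::ggplot(estimates,
                  ggplot2::aes(x = .data$cdh, y = .data$pseudo_copy_number)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "pseudo copy number") +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of an association scan
#'
#' @param scan tibble from [gwas()]
#' @param threshold significance line (default 5e-8)
#' @return a ggplot
#' @export
plot_gwas <- function(scan, threshold = 5e-8) {
  df <- scan[!is.na(scan$p), ]
  df$order <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$order, y = -log10(.data$p),
                                   colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = 2) +
    ggplot2::labs(x = "SNP", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}
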