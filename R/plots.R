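#' Plot a composite signal profile
#'
#' Line plot of the probe-trend matrix from [composite_profile()], one
#' line per sample, with the scaled region body shaded.
#'
#' @param object An `oomics_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot oomics_profile
#' @export
autoplot.oomics_profile <- function(object, ...) {
  n_flank <- attr(object, "n_flank")
  interior <- attr(object, "interior_bins")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$signal,
                                       colour = .data$sample)) +
    ggplot2::annotate("rect", xmin = n_flank + 0.5,
                      xmax = n_flank + interior + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "bin (flank | scaled region | flank)",
                  y = "mean log2 RPKM", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential results
#'
#' Works for both expression (`oomics_de`) and protein (`oomics_modt`)
#' results; points are coloured by the `call` column when present.
#'
#' @param object Differential result tibble with log2fc and p columns.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot oomics_modt
#' @export
autoplot.oomics_modt <- function(object, ...) {
  plot_volcano(object)
}

#' @rdname autoplot.oomics_modt
#' @method autoplot oomics_de
#' @export
autoplot.oomics_de <- function(object, ...) {
  plot_volcano(object)
}

#' @rdname autoplot.oomics_modt
#' @export
plot_volcano <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$._col <- if ("call" %in% names(df)) df$call else "none"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p),
                                   colour = .data$._col)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(up = "#b2182b", down = "#2166ac", none = "grey60"),
      name = NULL) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' MA plot of differential-expression results
#'
#' @param object An `oomics_de` tibble.
#' @return A ggplot object.
#' @export
plot_ma <- function(object) {
  df <- tibble::as_tibble(object)
  df$._col <- if ("call" %in% names(df)) df$call else "none"
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$base_mean + 1),
                                   y = .data$log2fc, colour = .data$._col)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(up = "#b2182b", down = "#2166ac", none = "grey60"),
      name = NULL) +
    ggplot2::labs(x = "log2 mean expression", y = "log2 fold change") +
    ggplot2::theme_minimal()
}

#' Plot a barcode enrichment worm
#'
#' Relative set density along the ranking; 1 marks a uniformly spread
#' set.
#'
#' @param object An `oomics_barcode` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot oomics_barcode
#' @export
autoplot.oomics_barcode <- function(object, ...) {
  ggplot2::ggplot(object$worm,
                  ggplot2::aes(x = .data$position, y = .data$enrichment,
                               colour = .data$set)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "rank (most up-regulated first)",
                  y = "relative enrichment", colour = NULL) +
    ggplot2::theme_minimal()
}
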