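## ggplot2 visualisations of the result objects.

#' Plot a library size distribution
#'
#' @param reads Read tibble (or a [size_distribution()] tibble).
#' @param length_range Optional length range passed through.
#' @return A ggplot.
#' @export
plot_size_distribution <- function(reads, length_range = NULL) {
  dist <- if (all(c("length", "fraction") %in% names(reads))) reads
          else size_distribution(reads, length_range)
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$length, y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "read length (nt)", y = "fraction of reads") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a registry spectrum
#'
#' @param object A [registry_spectrum()].
#' @param ... Unused.
#' @return A ggplot of pair fraction against registry.
#' @method autoplot registry_spectrum
#' @export
autoplot.registry_spectrum <- function(object, ...) {
  sizes <- attr(object, "sizes")
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$registry, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "pairing registry (nt): 5' of + read minus 3' of - read",
      y = "fraction of pairs",
      title = sprintf("%d/%d-nt pairing registry spectrum", sizes[1], sizes[2])) +
    ggplot2::theme_minimal()
}

#' Plot a positional frequency matrix
#'
#' @param object A [positional_matrix()].
#' @param ... Unused.
#' @return A ggplot with one line per base.
#' @method autoplot positional_matrix
#' @export
autoplot.positional_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$position, y = .data$freq,
                               colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("position (%s anchor)", attr(object, "anchor")),
                  y = "frequency", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a position-10 U signature report
#'
#' @param object A [u10_signature()] report.
#' @param ... Unused.
#' @return A ggplot of U frequency by position with the peak marked.
#' @method autoplot u10_report
#' @export
autoplot.u10_report <- function(object, ...) {
  dat <- filter(tidy(object), .data$base == "U")
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$position, y = .data$freq)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::labs(x = "position from 5' end", y = "U frequency") +
    ggplot2::theme_minimal()
  if (!is.na(object$peak_position)) {
    p <- p + ggplot2::geom_vline(xintercept = object$peak_position,
                                 linetype = "dashed", colour = "grey50")
  }
  p
}

#' Scatter plot of DMR methylation against siRNA abundance
#'
#' @param assoc A [dmr_sirna_association()] result.
#' @return A ggplot of per-DMR wild-type CHH rate against 24-nt siRNA RPM.
#' @export
plot_dmr_association <- function(assoc) {
  stopifnot(inherits(assoc, "dmr_association"))
  ggplot2::ggplot(assoc$table,
                  ggplot2::aes(x = .data$rpm, y = .data$wt_rate)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "24-nt siRNA abundance (RPM)",
                  y = "wild-type CHH methylation rate") +
    ggplot2::theme_minimal()
}
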