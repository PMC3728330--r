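#' Plot a G' genome scan
#'
#' G' along the genome, faceted by chromosome, with the per-SNP G values
#' underlaid and an optional horizontal significance threshold.
#'
#' @param track `"bsa_gprime"` tibble from [gprime_scan()].
#' @param threshold Optional G' threshold (number or `"bsa_null"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_gprime <- function(track, threshold = NULL, ...) {
  if (inherits(threshold, "bsa_null")) threshold <- threshold$gprime_threshold
  p <- ggplot2::ggplot(track, ggplot2::aes(x = .data$pos / 1e6)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$G), colour = "grey75",
                        size = 0.3, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$Gprime), colour = "#2166ac") +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "G (points), G' (line)")
  if (!is.null(threshold) && is.finite(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "#b2182b")
  }
  p
}

#' @rdname plot_gprime
#' @param object,x `"bsa_gprime"` track.
#' @export
autoplot.bsa_gprime <- function(object, threshold = NULL, ...) {
  plot_gprime(object, threshold = threshold, ...)
}

#' Plot the windowed allele-frequency-difference profile
#'
#' @param nafd `"bsa_nafd"` tibble from [nafd_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_nafd <- function(nafd, ...) {
  ggplot2::ggplot(nafd,
                  ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                               y = .data$nafd)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(colour = "#4d9221") +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "window centre (Mb)",
                  y = "parent-1 frequency difference (ET - ES)")
}

#' @rdname plot_nafd
#' @param object `"bsa_nafd"` profile.
#' @export
autoplot.bsa_nafd <- function(object, ...) plot_nafd(object, ...)

#' Plot the differential-SNP scan
#'
#' Per-SNP `-log10` p-values of the Jensen-Shannon divergence test with
#' the Bonferroni cutoff.
#'
#' @param scan `"bsa_jsd"` tibble from [differential_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_differential <- function(scan, ...) {
  cutoff <- attr(scan, "cutoff")
  p <- ggplot2::ggplot(scan,
                       ggplot2::aes(x = .data$pos / 1e6,
                                    y = -log10(pmax(.data$pvalue, 1e-300)),
                                    colour = .data$significant)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70",
                                            `TRUE` = "#b2182b"),
                                 guide = "none") +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "-log10 p (JSD test)")
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(cutoff),
                                 linetype = "dashed", colour = "#b2182b")
  }
  p
}

#' @rdname plot_differential
#' @param object `"bsa_jsd"` scan.
#' @export
autoplot.bsa_jsd <- function(object, ...) plot_differential(object, ...)
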