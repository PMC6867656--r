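#' Plot flank-GC enrichment with bootstrap confidence band
#'
#' Mean observed-minus-null GC difference against flank distance, with the
#' bootstrap confidence ribbon and a zero reference line.
#'
#' @param object A `flank_enrichment` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flank_enrichment
#' @export
autoplot.flank_enrichment <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$distance, y = .data$mean_diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Distance from recognition site (bp)",
                  y = "GC difference (observed - permuted null)")
}

#' Plot recombining vs non-recombining gene GC per cluster
#'
#' @param object A `gc_contrast` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gc_contrast
#' @export
autoplot.gc_contrast <- function(object, ...) {
  long <- object$clusters |>
    tidyr::pivot_longer(c("gc_recombining", "gc_nonrecombining"),
                        names_to = "class", values_to = "gc") |>
    dplyr::mutate(class = ifelse(.data$class == "gc_recombining",
                                 "recombining", "non-recombining"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$gc)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$cluster_id),
                       colour = "grey70") +
    ggplot2::geom_boxplot(width = 0.3, outlier.shape = NA,
                          fill = "steelblue", alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "Mean gene GC content")
}

#' Plot expected (mutational) versus observed GC content
#'
#' Scatter of per-focal-genome equilibrium GC expected from polarized
#' polymorphisms against observed core-gene GC, with the identity line;
#' points above the line indicate GC-favouring fixation biases (selection or
#' biased gene conversion).
#'
#' @param tbl Output of [run_polymorphism()].
#' @return A ggplot object.
#' @export
plot_expected_observed_gc <- function(tbl) {
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$expected_gc,
                                         y = .data$observed_gc))
  if ("ku" %in% names(tbl)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data$ku)),
                                 alpha = 0.7) +
      ggplot2::labs(colour = "Ku")
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7)
  }
  p +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Expected GC (from polymorphism)",
                  y = "Observed GC (core genes)")
}
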