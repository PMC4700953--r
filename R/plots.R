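#' Plot the parallel-fixation window tracks
#'
#' One line per population showing the window-mean alternate-allele
#' frequency along the chromosome, the fixation threshold as a dashed line,
#' and merged candidate regions shaded.
#'
#' @param object A `fixation_scan`.
#' @param ... Unused.
#' @return A ggplot object (facetted by chromosome).
#' @export
autoplot.fixation_scan <- function(object, ...) {
  af_cols <- grep("^af_", names(object$windows), value = TRUE)
  long <- object$windows |>
    tidyr::pivot_longer(dplyr::all_of(af_cols), names_to = "pop",
                        values_to = "af", names_prefix = "af_") |>
    mutate(mid = (.data$start + .data$end) / 2)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$mid / 1e6, y = .data$af,
                                          colour = .data$pop))
  if (nrow(object$regions)) {
    p <- p + ggplot2::geom_rect(
      data = object$regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, fill = "grey85", colour = NA,
      inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = object$config$fixation_tau,
                        linetype = "dashed") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "window mean allele frequency",
                  colour = "population") +
    ggplot2::theme_minimal()
}

#' Plot the divergence-scan Fst track
#'
#' Window-mean Fst along the chromosome with the empirical top-quantile
#' threshold and merged divergence regions shaded.
#'
#' @param object An `fst_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fst_scan <- function(object, ...) {
  w <- mutate(object$windows, mid = (.data$start + .data$end) / 2)
  p <- ggplot2::ggplot(w, ggplot2::aes(x = .data$mid / 1e6, y = .data$value))
  if (nrow(object$regions)) {
    p <- p + ggplot2::geom_rect(
      data = object$regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, fill = "grey85", colour = NA,
      inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "window mean Fst") +
    ggplot2::theme_minimal()
}

#' Plot an EHH decay curve
#'
#' @param curve Output of [ehh()].
#' @return A ggplot of EHH against physical offset from the core.
#' @export
plot_ehh <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$offset / 1e3, y = .data$ehh,
                                      colour = .data$direction)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "offset from core (kb)", y = "EHH") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
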