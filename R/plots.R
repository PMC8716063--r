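#' Plot the empirical p-value distribution of a calibration run
#'
#' Empirical CDF of the simulated null p-values against the uniform diagonal;
#' a calibrated test tracks or stays below the diagonal at small p.
#'
#' @param object A `clonex_calibration` from [run_calibration()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clonex_calibration <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(x = .data$p)) +
    ggplot2::stat_ecdf(pad = FALSE) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "p-value", y = "empirical CDF",
      title = sprintf("Null calibration, %s placement test (n = %d)",
                      attr(object, "test"), attr(object, "n"))
    ) +
    ggplot2::theme_minimal()
}

#' Signed-significance plot of a cohort results table
#'
#' Displays `-sign(delta) * log10(p)` per gene pair: positive bars indicate
#' clonal exclusivity enrichment (negative shift), negative bars clonal
#' co-occurrence.
#'
#' @param object A `clonex_results` tibble from [run_cohort()].
#' @param alpha Significance threshold drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clonex_results <- function(object, alpha = 0.05, ...) {
  d <- tibble::as_tibble(object)
  d$signed <- -sign(d$delta) * log10(pmax(d$p, .Machine$double.xmin))
  d$signed[d$delta == 0] <- 0
  d$direction <- ifelse(d$delta < 0, "exclusive", "co-occurring")
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$gene_pair, .data$signed),
    y = .data$signed, fill = .data$direction
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-1, 1) * -log10(alpha),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = expression(-sign(Delta) %*% log[10](p)),
      fill = NULL,
      title = sprintf("%s test", attr(object, "method"))
    ) +
    ggplot2::scale_fill_manual(values = c(exclusive = "#2166ac",
                                          "co-occurring" = "#b2182b")) +
    ggplot2::theme_minimal()
}

#' Power surface of the exact placement test
#'
#' @param power_table Output of [run_power()].
#' @return A ggplot of power against effect size, one line per sample size.
#' @export
plot_power <- function(power_table) {
  ggplot2::ggplot(power_table, ggplot2::aes(
    x = .data$delta, y = .data$power,
    colour = factor(.data$n), group = factor(.data$n)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(Delta), y = "power", colour = "n") +
    ggplot2::theme_minimal()
}
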