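#' Plot class abundance against concentration
#'
#' Line plot of the log-odds abundance f per composition class over a
#' concentration series; the f = 0 line is the random-mixing reference.
#'
#' @param series A `solvtess_series` (or its long-format `table`).
#' @return A ggplot object.
#' @export
plot_abundance <- function(series) {
  tab <- if (inherits(series, "solvtess_series")) series$table else series
  tab <- tab[!is.na(tab$f), ]
  tab$class <- factor(tab$class, levels = tet_class_names())
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$chi_s, y = .data$f,
                                    colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(chi[S]), y = "log-odds abundance f",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Plot tetrahedrality distributions
#'
#' Density histograms of the tetrahedrality order parameter, either
#' pooled over all classes or one curve per class.
#'
#' @param dist A `t_distribution`.
#' @param by_class Overlay the five class distributions instead of the
#'   pooled one (default `FALSE`).
#' @return A ggplot object.
#' @export
plot_t_distribution <- function(dist, by_class = FALSE) {
  df <- as.data.frame(dist)
  mid <- (df$bin_left + df$bin_right) / 2
  if (by_class) {
    long <- do.call(rbind, lapply(tet_class_names(), function(cl)
      data.frame(t = mid, density = df[[cl]], class = cl)))
    long$class <- factor(long$class, levels = tet_class_names())
    ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$density,
                                       colour = .data$class)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "tetrahedrality T", y = "density",
                    colour = "class") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(data.frame(t = mid, density = df$pooled),
                    ggplot2::aes(x = .data$t, y = .data$density)) +
      ggplot2::geom_col(width = dist$bin_width, fill = "steelblue") +
      ggplot2::labs(x = "tetrahedrality T", y = "density") +
      ggplot2::theme_minimal()
  }
}
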