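#' Plot an evaluation report
#'
#' GEBV correlation (with its 95% CI) against sequencing coverage, one panel
#' facet per reference-panel filter, coloured by imputation method — the
#' standard way to read a coverage x panel x method sweep.
#'
#' @param object a `skim_eval` from [run_grid()].
#' @param metric column to plot (`"r"`, `"accuracy"`, `"bias"` or
#'   `"concordance"`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.skim_eval <- function(object, metric = c("r", "accuracy", "bias",
                                                  "concordance"), ...) {
  metric <- match.arg(metric)
  df <- tibble::as_tibble(object)
  df <- dplyr::summarise(
    dplyr::group_by(df, .data$coverage, .data$panel, .data$method),
    value = mean(.data[[metric]], na.rm = TRUE),
    lo = if (metric == "r") mean(.data$r_lo) else NA_real_,
    hi = if (metric == "r") mean(.data$r_hi) else NA_real_,
    .groups = "drop"
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$coverage),
                                        y = .data$value,
                                        colour = .data$method,
                                        group = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "sequencing coverage (x)", y = metric,
                  colour = "engine") +
    ggplot2::theme_bw()
  if (metric == "r") {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi), width = 0.15)
  }
  p
}

#' Plot a quartile-transition matrix
#'
#' @param m a 4 x 4 count matrix from [quartile_transitions()].
#' @return a ggplot tile plot (reference quartile vs test quartile).
#' @export
plot_quartile_transitions <- function(m) {
  df <- tibble::as_tibble(as.table(m), .name_repair = "minimal")
  names(df) <- c("reference", "test", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$test, y = .data$reference,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "test GEBV quartile", y = "reference GEBV quartile") +
    ggplot2::theme_minimal()
}
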