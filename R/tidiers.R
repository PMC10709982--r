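#' Tidy an evaluation report
#'
#' Drops the quartile-matrix list column, returning one plain row per grid
#' cell.
#'
#' @param x a `skim_eval` from [run_grid()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.skim_eval <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$quartile_matrix <- NULL
  out
}

#' Summarise an evaluation report
#'
#' One row per imputation method: mean correlation, mean absolute bias,
#' mean accuracy and (when computed) mean concordance over all grid cells.
#'
#' @param x a `skim_eval`.
#' @param ... unused.
#' @return a tibble with one row per method.
#' @export
glance.skim_eval <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$method),
    n_cells = dplyr::n(),
    mean_r = mean(.data$r),
    mean_abs_bias = mean(abs(.data$bias)),
    mean_accuracy = mean(.data$accuracy),
    mean_concordance = mean(.data$concordance),
    .groups = "drop"
  )
}

#' Tidy genotype posteriors
#'
#' @param x a `posterior_genotypes`.
#' @param ... unused.
#' @return the underlying tibble with an `engine` column.
#' @export
tidy.posterior_genotypes <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$engine <- attr(x, "engine")
  out
}
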