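#' Plot a PMF profile
#'
#' Free energy against the reaction coordinate, with an optional error
#' ribbon from [bootstrap_error()].
#'
#' @param object A [wham_solve()] result.
#' @param errors Optional tibble from [bootstrap_error()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pmf_profile
#' @export
autoplot.pmf_profile <- function(object, errors = NULL, ...) {
  df <- object$profile
  if (!is.null(errors)) {
    df <- dplyr::left_join(df, errors, by = "bin_center")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center,
                                        y = .data$free_energy))
  if (!is.null(errors)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$free_energy - .data$error,
                   ymax = .data$free_energy + .data$error),
      alpha = 0.25)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "reaction coordinate (nm)",
                  y = "PMF (kJ/mol)")
}

#' Plot the nearest-obstruction distance distribution
#'
#' Histogram of the per-configuration CDR nearest-obstruction distances,
#' coloured by Fab, with the accessibility threshold marked — the standard
#' view of the simultaneous-binding analysis.
#'
#' @param object A [binding_accessibility()] result.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot accessibility_result
#' @export
autoplot.accessibility_result <- function(object, bins = 60, ...) {
  df <- dplyr::filter(object$distances, is.finite(.data$distance))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance,
                                   fill = .data$fab)) +
    ggplot2::geom_histogram(bins = bins, position = "identity",
                            alpha = 0.4) +
    ggplot2::geom_vline(xintercept = object$threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "CDR nearest-obstruction distance (nm)",
                  y = "configurations", fill = "Fab")
}

#' Scree plot of a PCA result
#'
#' @param object A [pca()] result.
#' @param n_modes Number of leading modes to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pca_result
#' @export
autoplot.pca_result <- function(object, n_modes = 10, ...) {
  df <- tidy(object)[seq_len(min(n_modes, length(object$eigenvalues))), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode,
                                   y = .data$variance_fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "principal mode",
                  y = "fraction of total variance")
}

#' Plot a per-frame series (RMSD, ASA, COM distance)
#'
#' Convenience line plot for the tibbles returned by [rmsd_series()],
#' [asa_timeseries()] and [com_distance_series()].
#'
#' @param data A tibble with a `time_ns` column and one value column.
#' @param y Name of the value column (default: the last column).
#' @return A ggplot.
#' @export
plot_series <- function(data, y = NULL) {
  if (is.null(y)) y <- names(data)[ncol(data)]
  ggplot2::ggplot(data, ggplot2::aes(x = .data$time_ns,
                                     y = .data[[y]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)", y = y)
}
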