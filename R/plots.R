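#' Plot a mismatch profile
#'
#' Unique and overall mapping rate against the allowed mismatch count, with
#' the optimum `N*` marked.
#'
#' @param object A `mismatch_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mismatch_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object), c("unique_rate", "mapped_rate"),
    names_to = "metric", values_to = "rate"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$N, .data$rate, colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = attr(object, "N_star"), linetype = "dashed") +
    ggplot2::labs(
      x = "allowed mismatches per read (N)", y = "rate",
      title = sprintf(
        "optimal N* = %d (%.2f%% of read length)",
        attr(object, "N_star"), attr(object, "optimal_mismatch_rate")
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fitted mismatch-rate model
#'
#' Training points and the OLS line.
#'
#' @param object A `pra_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pra_model <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$slope, colour = "steelblue"
    ) +
    ggplot2::labs(
      x = object$x_name, y = paste0(object$y_name, " (%)"),
      title = sprintf("r² = %.4f, training RMSE = %.2f", object$r2, object$rmse)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pra_model
#' @export
autoplot.virtual_experiment <- function(object, ...) {
  autoplot(object$model) +
    ggplot2::labs(x = "mutation rate", y = "optimal mismatch rate (%)")
}

#' Plot a reconstruction-rate curve
#'
#' Cumulative fraction of genes with coverage at least `t`.
#'
#' @param object A `reconstruction_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reconstruction_report <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$t, .data$fraction)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "coverage threshold t", y = "fraction of genes with coverage ≥ t",
      title = sprintf(
        "reconstruction rate %.3f, AUC %.3f",
        object$reconstruction_rate, object$auc
      )
    ) +
    ggplot2::theme_minimal()
}
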