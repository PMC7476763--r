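# ggplot2 autoplot methods for the package's result types.

#' Plot a belief trajectory
#'
#' Shows the trial-wise outcome-probability prediction with the binary
#' inputs, and the volatility belief, stacked in facets.
#'
#' @param object An `hgf_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hgf_trajectory
#' @export
autoplot.hgf_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("trial", "muhat1", "mu2", "mu3")],
    -"trial", names_to = "state", values_to = "value")
  df$state <- factor(df$state, levels = c("muhat1", "mu2", "mu3"),
                     labels = c("predicted probability", "tendency",
                                "volatility"))
  pts <- tibble::tibble(trial = object$trial, value = object$input,
                        state = factor("predicted probability",
                                       levels = levels(df$state)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$value)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_point(data = pts, alpha = 0.3, size = 0.6) +
    ggplot2::facet_wrap(~state, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "trial", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot model-selection results
#'
#' Expected posterior model frequencies with protected exceedance
#' probabilities overlaid.
#'
#' @param object A `bms_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bms_result
#' @export
autoplot.bms_result <- function(object, ...) {
  df <- tidy(object)
  df$model <- factor(df$model, levels = df$model)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$p_m_y), fill = "#2166ac",
                      alpha = 0.8) +
    ggplot2::geom_point(ggplot2::aes(y = .data$protected_exceedance_prob),
                        colour = "#b2182b", size = 2) +
    ggplot2::labs(y = "p(m|y) (bars), protected EP (points)", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot parameter-recovery scatter
#'
#' Simulated against recovered values per free parameter (estimation
#' space), annotated with Cohen's f.
#'
#' @param object A `recovery_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recovery_report
#' @export
autoplot.recovery_report <- function(object, ...) {
  lab <- dplyr::mutate(object$summary,
                       label = sprintf("%s (f = %.2f)", .data$param,
                                       .data$cohens_f))
  df <- dplyr::left_join(object$values, lab[, c("param", "label")],
                         by = "param")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$simulated_est,
                                   y = .data$recovered_est)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, colour = "#2166ac") +
    ggplot2::facet_wrap(~label, scales = "free") +
    ggplot2::labs(x = "simulated (estimation space)",
                  y = "recovered (estimation space)") +
    ggplot2::theme_minimal()
}
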