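#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a synthetic or recorded trial
#'
#' Facets the excitation channels, the activations, and the joint angle of a
#' trial tibble against time.
#'
#' @param object An `msk_trial` tibble (from [generate_trial()] or
#'   [read_dataset()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot msk_trial
#' @export
autoplot.msk_trial <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, dplyr::any_of(c("t", "e_bi", "e_tri",
                                          "a_bi", "a_tri", "q"))),
    -"t", names_to = "series", values_to = "value")
  long$series <- factor(long$series,
                        levels = c("e_bi", "e_tri", "a_bi", "a_tri", "q"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot training diagnostics of a fitted surrogate
#'
#' `type = "params"` shows the trajectory of the identified physical
#' parameters over epochs (with dashed truth lines when the generating model
#' is known); `type = "loss"` shows the loss components on a log scale.
#'
#' @param object A `pinn_fit`.
#' @param type `"params"` or `"loss"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pinn_fit
#' @export
autoplot.pinn_fit <- function(object, type = c("params", "loss"), ...) {
  type <- match.arg(type)
  if (type == "params") plot_parameter_paths(object) else plot_loss(object)
}

#' @rdname autoplot.pinn_fit
#' @export
plot_parameter_paths <- function(object) {
  path <- object$gamma_path
  for (j in seq_along(.gamma_names))
    path[[.gamma_names[j]]] <- path[[.gamma_names[j]]] * object$gamma0[j]
  long <- tidyr::pivot_longer(path, -"epoch", names_to = "parameter",
                              values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = "parameter value") +
    ggplot2::theme_minimal()
  if (!is.null(object$gamma_true)) {
    truth <- tibble::tibble(parameter = .gamma_names,
                            value = object$gamma_true)
    p <- p + ggplot2::geom_hline(data = truth,
                                 ggplot2::aes(yintercept = .data$value),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' @rdname autoplot.pinn_fit
#' @export
plot_loss <- function(object) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss (log scale)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Overlay measured and predicted motion for one trial
#'
#' @param fit A `pinn_fit`.
#' @param trial A trial tibble with `t`, `e_bi`, `e_tri`, `q`.
#' @return A ggplot object.
#' @export
plot_prediction <- function(fit, trial) {
  pr <- predict(fit, trial)
  df <- tibble::tibble(t = rep(trial$t, 2),
                       q = c(trial$q, pr$q_hat),
                       series = rep(c("data", "prediction"),
                                    each = length(trial$t)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$q,
                                   colour = .data$series,
                                   linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "elbow flexion (rad)",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}
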