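#' Mean squared error between two series
#'
#' \eqn{MSE = \frac{1}{n}\lVert q - \hat q\rVert^2}.
#'
#' @param q Measured series.
#' @param qhat Predicted series of the same length.
#' @return Nonnegative scalar.
#' @export
mse <- function(q, qhat) {
  if (length(q) != length(qhat))
    stop("q and qhat must have the same length", call. = FALSE)
  mean((q - qhat)^2)
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum_i (q_i - \hat q_i)^2 / \sum_i (q_i - \bar q)^2}.
#' Equals 1 for a perfect prediction, 0 for predicting the mean, and can be
#' negative for predictions worse than the mean.
#'
#' @inheritParams mse
#' @return Scalar `<= 1`.
#' @export
r_squared <- function(q, qhat) {
  if (length(q) != length(qhat))
    stop("q and qhat must have the same length", call. = FALSE)
  ss_tot <- sum((q - mean(q))^2)
  if (ss_tot == 0)
    stop("R^2 undefined: the measured series is constant", call. = FALSE)
  1 - sum((q - qhat)^2) / ss_tot
}

#' Per-parameter relative recovery error
#'
#' \eqn{100\,|\Gamma_{id} - \Gamma_{true}| / \Gamma_{true}} per parameter.
#'
#' @param gamma_true True parameter values (positive).
#' @param gamma_hat Identified values.
#' @return A tibble with `parameter`, `truth`, `estimate`, `rel_error_pct`.
#' @export
param_recovery <- function(gamma_true, gamma_hat) {
  if (any(gamma_true <= 0))
    stop("gamma_true must be positive", call. = FALSE)
  nm <- names(gamma_true)
  if (is.null(nm)) nm <- .gamma_names[seq_along(gamma_true)]
  tibble::tibble(parameter = nm,
                 truth = as.numeric(gamma_true),
                 estimate = as.numeric(gamma_hat),
                 rel_error_pct = as.numeric(
                   100 * abs(gamma_hat - gamma_true) / gamma_true))
}

#' Per-trial prediction metrics for a fitted surrogate
#'
#' Predicts every trial of the dataset with the fitted surrogate and reports
#' angle MSE and R-squared per trial, labelled by split.
#'
#' @param fit A `pinn_fit`.
#' @param dataset An `msk_dataset`.
#' @return A tibble with one row per trial: `trial`, `split`, `mse`, `r2`.
#' @export
evaluate_fit <- function(fit, dataset) {
  purrr::map_dfr(seq_along(dataset$trials), function(k) {
    tr <- dataset$trials[[k]]
    pr <- predict(fit, tr)
    tibble::tibble(trial = k,
                   split = if (k %in% dataset$test) "test" else "train",
                   mse = mse(tr$q, pr$q_hat),
                   r2 = r_squared(tr$q, pr$q_hat))
  })
}
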