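#' Fourier + quadratic polynomial design matrix
#'
#' Basis values (or their analytic time derivatives) on a time grid. The
#' column order is the package-wide coefficient layout contract:
#' `cos(2*pi*l*t/T)` for `l = 1..L`, then `sin(2*pi*l*t/T)` for `l = 1..L`,
#' then the polynomial columns `1, t, t^2`. This layout defines the
#' input/output vector layout of the feature-encoded network.
#'
#' @param t Numeric time grid (s).
#' @param n_harmonics Number of Fourier pairs `L`.
#' @param period Signal duration `T` (s) setting the fundamental frequency.
#' @param deriv Derivative order 0, 1, or 2; derivatives are exact term-wise
#'   analytic derivatives of the basis functions.
#' @return A `length(t) x (2 * n_harmonics + 3)` matrix.
#' @export
fe_design_matrix <- function(t, n_harmonics, period, deriv = 0) {
  stopifnot(period > 0, n_harmonics >= 0, deriv %in% 0:2)
  n <- length(t)
  L <- n_harmonics
  out <- matrix(0, n, 2 * L + 3)
  if (L > 0) {
    om <- 2 * pi * seq_len(L) / period
    ph <- outer(t, om)                      # n x L matrix of omega_l * t
    if (deriv == 0) {
      out[, seq_len(L)] <- cos(ph)
      out[, L + seq_len(L)] <- sin(ph)
    } else if (deriv == 1) {
      out[, seq_len(L)] <- -sweep(sin(ph), 2, om, `*`)
      out[, L + seq_len(L)] <- sweep(cos(ph), 2, om, `*`)
    } else {
      out[, seq_len(L)] <- -sweep(cos(ph), 2, om^2, `*`)
      out[, L + seq_len(L)] <- -sweep(sin(ph), 2, om^2, `*`)
    }
  }
  pcol <- 2 * L + 1
  if (deriv == 0) {
    out[, pcol] <- 1; out[, pcol + 1] <- t; out[, pcol + 2] <- t^2
  } else if (deriv == 1) {
    out[, pcol + 1] <- 1; out[, pcol + 2] <- 2 * t
  } else {
    out[, pcol + 2] <- 2
  }
  out
}

#' Fit Fourier + polynomial coefficients by least squares
#'
#' Projects a sampled signal onto the Fourier + quadratic basis of
#' [fe_design_matrix()]. Well-posed systems are solved exactly in the
#' least-squares sense; rank-deficient or underdetermined systems (more
#' coefficients than samples) return the minimum-norm solution via the SVD
#' pseudoinverse. An optional ridge penalty is available for noisy signals.
#'
#' @param x Numeric signal sampled at `t`.
#' @param t Time grid (s).
#' @param n_harmonics Number of Fourier pairs.
#' @param period Signal duration; defaults to `max(t) - min(t)`.
#' @param ridge Ridge regularization weight (0 = pure least squares).
#' @return An `fe_coeffs` object: list with `coef` (layout of
#'   [fe_design_matrix()]), `n_harmonics`, and `period`.
#' @export
fe_fit <- function(x, t, n_harmonics, period = NULL, ridge = 0) {
  stopifnot(length(x) == length(t), length(x) >= 1)
  if (is.null(period)) period <- max(t) - min(t)
  Phi <- fe_design_matrix(t, n_harmonics, period)
  p <- ncol(Phi)
  coef <- if (ridge > 0) {
    solve(crossprod(Phi) + diag(ridge, p), crossprod(Phi, x))[, 1]
  } else {
    # minimum-norm least squares via SVD pseudoinverse
    sv <- svd(Phi)
    tol <- max(dim(Phi)) * .Machine$double.eps * sv$d[1]
    pos <- sv$d > tol
    as.numeric(sv$v[, pos, drop = FALSE] %*%
                 ((crossprod(sv$u[, pos, drop = FALSE], x)) / sv$d[pos]))
  }
  structure(list(coef = as.numeric(coef), n_harmonics = n_harmonics,
                 period = period),
            class = "fe_coeffs")
}

#' Reconstruct a signal (or derivative) from basis coefficients
#'
#' Evaluates the Fourier + quadratic expansion, or its exact first or second
#' time derivative, on an arbitrary time grid. Derivatives are analytic:
#' Fourier terms are scaled by powers of `2*pi*l/T` with cosine/sine rotation;
#' polynomial terms differentiate termwise.
#'
#' @param coeffs An `fe_coeffs` object from [fe_fit()], or a bare numeric
#'   coefficient vector (then `n_harmonics` and `period` must be supplied).
#' @param t Time grid (s).
#' @param deriv Derivative order 0, 1, or 2.
#' @param n_harmonics,period Required when `coeffs` is a bare vector.
#' @return Numeric vector of reconstructed values.
#' @export
fe_reconstruct <- function(coeffs, t, deriv = 0,
                           n_harmonics = NULL, period = NULL) {
  if (inherits(coeffs, "fe_coeffs")) {
    n_harmonics <- coeffs$n_harmonics
    period <- coeffs$period
    coeffs <- coeffs$coef
  }
  stopifnot(!is.null(n_harmonics), !is.null(period),
            length(coeffs) == 2 * n_harmonics + 3)
  as.numeric(fe_design_matrix(t, n_harmonics, period, deriv) %*% coeffs)
}

#' @export
print.fe_coeffs <- function(x, ...) {
  cat(sprintf("<fe_coeffs> %d Fourier pairs + quadratic, T = %g s\n",
              x$n_harmonics, x$period))
  invisible(x)
}
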