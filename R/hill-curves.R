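#' Dimensionless Hill muscle curves
#'
#' Constructs the set of dimensionless force-generation curves used by the
#' Hill-type muscle-tendon model: the active force-length curve `fal`, the
#' force-velocity curve `fv`, and the passive force-length curve `fp`, together
#' with their first derivatives (`dfal`, `dfv`, `dfp`) which the
#' physics-informed training needs for analytic gradients of the
#' equation-of-motion residual.
#'
#' The default `"gaussian_generic"` family is a standard generic
#' parameterization:
#' \itemize{
#'   \item active force-length: Gaussian bump
#'     \eqn{f_{AL}(\tilde l) = \exp(-(\tilde l - 1)^2/\gamma)}, peaking at the
#'     optimal fiber length (\eqn{f_{AL}(1) = 1});
#'   \item force-velocity: classic hyperbolic Hill relation
#'     \eqn{f_V(\tilde v) = (1+\tilde v)/(1-\tilde v/k)} for shortening
#'     (\eqn{-1 \le \tilde v \le 0}, so \eqn{f_V(-1)=0} and \eqn{f_V(0)=1}),
#'     joined with continuous slope at \eqn{\tilde v = 0} to a saturating
#'     lengthening branch with plateau `fv_plateau`; clamped to 0 for
#'     \eqn{\tilde v < -1};
#'   \item passive force-length: exponential toe
#'     \eqn{f_P(\tilde l) = \max(0, (e^{k_P(\tilde l - 1)} - 1)/(e^{k_P/2}-1))},
#'     zero at and below the optimal length and scaled so that
#'     \eqn{f_P(1.5) = 1}.
#' }
#'
#' The sign convention for normalized velocity is \eqn{\tilde v < 0} for
#' shortening (concentric contraction).
#'
#' @param family Curve family name. Only `"gaussian_generic"` is built in;
#'   a custom family can be supplied by constructing the list manually and
#'   calling [new_hill_curves()].
#' @param gamma_al Width of the Gaussian active force-length curve.
#' @param fv_k Curvature constant of the shortening (Hill hyperbola) branch.
#' @param fv_plateau Asymptotic force plateau for lengthening (eccentric)
#'   contraction, in units of maximum isometric force.
#' @param kp Exponential rate of the passive curve.
#'
#' @return An object of class `hill_curves`: a list with vectorized functions
#'   `fal`, `fv`, `fp`, `dfal`, `dfv`, `dfp` and a `family` string.
#' @examples
#' cv <- hill_curves()
#' cv$fal(1)   # 1 at optimal length
#' cv$fv(0)    # 1 isometric
#' cv$fv(-1)   # 0 at maximum shortening velocity
#' @export
hill_curves <- function(family = "gaussian_generic",
                        gamma_al = 0.45, fv_k = 0.25,
                        fv_plateau = 1.4, kp = 4) {
  family <- match.arg(family)
  # lengthening branch: fv = plateau - (plateau-1)*c/(c+v), slope-matched at 0
  # to the shortening branch slope (1 + 1/k)
  slope0 <- 1 + 1 / fv_k
  cc <- (fv_plateau - 1) / slope0
  fp_scale <- exp(kp * 0.5) - 1

  fal <- function(l) exp(-(l - 1)^2 / gamma_al)
  dfal <- function(l) -2 * (l - 1) / gamma_al * exp(-(l - 1)^2 / gamma_al)
  fv <- function(v) {
    out <- numeric(length(v))
    sh <- v <= 0 & v >= -1
    ln <- v > 0
    out[sh] <- (1 + v[sh]) / (1 - v[sh] / fv_k)
    out[ln] <- fv_plateau - (fv_plateau - 1) * cc / (cc + v[ln])
    out  # v < -1 stays 0
  }
  dfv <- function(v) {
    out <- numeric(length(v))
    sh <- v <= 0 & v >= -1
    ln <- v > 0
    out[sh] <- (1 + 1 / fv_k) / (1 - v[sh] / fv_k)^2
    out[ln] <- (fv_plateau - 1) * cc / (cc + v[ln])^2
    out
  }
  fp <- function(l) pmax(0, (exp(kp * (l - 1)) - 1) / fp_scale)
  dfp <- function(l) ifelse(l > 1, kp * exp(kp * (l - 1)) / fp_scale, 0)

  new_hill_curves(fal, fv, fp, dfal, dfv, dfp, family = family)
}

#' Low-level constructor for Hill curve sets
#'
#' Wraps user-supplied curve functions into a `hill_curves` object. All
#' functions must be vectorized; derivative functions are required because the
#' physics-informed training differentiates the equation-of-motion residual
#' analytically.
#'
#' @param fal,fv,fp Active force-length, force-velocity, and passive
#'   force-length functions (dimensionless in, dimensionless out).
#' @param dfal,dfv,dfp Their first derivatives.
#' @param family Label for the curve family.
#' @return A `hill_curves` object.
#' @export
new_hill_curves <- function(fal, fv, fp, dfal, dfv, dfp,
                            family = "custom") {
  stopifnot(is.function(fal), is.function(fv), is.function(fp),
            is.function(dfal), is.function(dfv), is.function(dfp))
  structure(list(fal = fal, fv = fv, fp = fp,
                 dfal = dfal, dfv = dfv, dfp = dfp,
                 family = family),
            class = "hill_curves")
}

#' @export
print.hill_curves <- function(x, ...) {
  cat("<hill_curves> family:", x$family, "\n")
  cat("  fal(1) =", format(x$fal(1)), " fv(0) =", format(x$fv(0)),
      " fv(-1) =", format(x$fv(-1)), " fp(1) =", format(x$fp(1)), "\n")
  invisible(x)
}
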