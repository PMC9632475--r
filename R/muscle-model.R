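#' Hill-type muscle-tendon parameters for one muscle group
#'
#' Bundles the parameter vector of a Hill-type muscle-tendon actuator with the
#' two EMG-to-activation constants. Units follow the biomechanics convention:
#' lengths in metres, velocities in m/s, forces in newtons, angles in radians,
#' delays in seconds.
#'
#' @param l0M Optimal muscle fiber length (m), the length at which active
#'   force peaks.
#' @param vmaxM Maximum contraction velocity (m/s); normalizes fiber velocity.
#' @param f0M Maximum isometric force (N). Zero is allowed so a muscle can be
#'   "detached" in pendulum-limit checks.
#' @param lsT Tendon slack length (m); the tendon is rigid, so the tendon
#'   length is fixed at `lsT`.
#' @param phi Pennation angle (rad), in `[0, pi/2)`.
#' @param d Electromechanical delay (s) between neural excitation and the
#'   muscle's mechanical response.
#' @param A Activation nonlinearity shape factor (dimensionless, nonzero).
#'
#' @return A `muscle_params` object (named list).
#' @examples
#' biceps <- muscle_params(l0M = 0.6, vmaxM = 6, f0M = 300, lsT = 0.55)
#' @export
muscle_params <- function(l0M, vmaxM, f0M, lsT, phi = 0, d = 0.08, A = 0.2) {
  stopifnot(is.numeric(l0M), is.numeric(vmaxM), is.numeric(f0M),
            is.numeric(lsT), is.numeric(phi), is.numeric(d), is.numeric(A))
  if (l0M <= 0) stop("l0M must be > 0", call. = FALSE)
  if (vmaxM <= 0) stop("vmaxM must be > 0", call. = FALSE)
  if (f0M < 0) stop("f0M must be >= 0", call. = FALSE)
  if (lsT < 0) stop("lsT must be >= 0", call. = FALSE)
  if (phi < 0 || phi >= pi / 2) stop("phi must be in [0, pi/2)", call. = FALSE)
  if (d < 0) stop("d must be >= 0", call. = FALSE)
  if (A == 0) stop("shape factor A must be nonzero", call. = FALSE)
  structure(list(l0M = l0M, vmaxM = vmaxM, f0M = f0M, lsT = lsT,
                 phi = phi, d = d, A = A),
            class = "muscle_params")
}

#' @export
print.muscle_params <- function(x, ...) {
  cat(sprintf(
    "<muscle_params> l0M=%g m  vmaxM=%g m/s  f0M=%g N  lsT=%g m  phi=%g rad  d=%g s  A=%g\n",
    x$l0M, x$vmaxM, x$f0M, x$lsT, x$phi, x$d, x$A))
  invisible(x)
}

#' Neural excitation from a sampled sEMG envelope
#'
#' Applies the electromechanical delay `u(t) = e(t - d)` on a uniform time
#' grid. The delay is realized as a shift by `round(d / dt)` samples. Before
#' the first sample the signal is taken as zero (`pad = "zero"`, the default)
#' or held at its first value (`pad = "hold"`), the latter modelling a trial
#' excised from ongoing activity: the subject was already tonically active
#' before recording started, so the pre-trial excitation equals the level at
#' the trial onset rather than silence.
#'
#' @param e Numeric vector: excitation sampled on a uniform grid.
#' @param d Electromechanical delay (s), `>= 0`.
#' @param dt Sample spacing (s), `> 0`.
#' @param pad `"zero"` or `"hold"`: the assumed excitation before the first
#'   sample.
#' @return Numeric vector of the same length: the delayed signal.
#' @examples
#' neural_excitation(c(0, 1, 1, 1), d = 0.02, dt = 0.01)
#' @export
neural_excitation <- function(e, d, dt, pad = c("zero", "hold")) {
  pad <- match.arg(pad)
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be a positive scalar", call. = FALSE)
  if (!is.numeric(d) || length(d) != 1 || d < 0)
    stop("delay d must be a nonnegative scalar", call. = FALSE)
  k <- as.integer(round(d / dt))
  n <- length(e)
  fill <- if (pad == "zero") 0 else e[1]
  if (k == 0) return(e)
  if (k >= n) return(rep(fill, n))
  c(rep(fill, k), e[seq_len(n - k)])
}

#' Muscle activation from neural excitation
#'
#' The algebraic EMG-to-activation nonlinearity
#' \eqn{a(u) = (e^{Au} - 1)/(e^{A} - 1)}, mapping excitation in `[0, 1]` to
#' activation in `[0, 1]` with `a(0) = 0` and `a(1) = 1`. Inputs outside
#' `[0, 1]` are clipped first (processed sEMG is MVC-normalized, but raw
#' artifacts may exceed the range).
#'
#' @param u Numeric vector of neural excitation values.
#' @param A Shape factor (nonzero). The limiting linear form at `A = 0` is not
#'   implemented.
#' @return Numeric vector of activations in `[0, 1]`.
#' @examples
#' activation_from_excitation(c(0, 0.5, 1), A = 0.2)
#' @export
activation_from_excitation <- function(u, A) {
  if (!is.numeric(A) || length(A) != 1 || A == 0)
    stop("shape factor A must be a nonzero scalar", call. = FALSE)
  u <- pmin(pmax(u, 0), 1)
  (exp(A * u) - 1) / (exp(A) - 1)
}

#' Active dimensionless muscle force
#'
#' \eqn{f_A = a \cdot f_{AL}(\tilde l) \cdot f_V(\tilde v)}: activation scales
#' the product of the active force-length and force-velocity curves.
#'
#' @param a Activation in `[0, 1]`.
#' @param l_tilde Normalized muscle length \eqn{l^M / l_0^M}.
#' @param v_tilde Normalized muscle velocity \eqn{v^M / v_{max}^M} (negative =
#'   shortening).
#' @param curves A [hill_curves()] object.
#' @return Dimensionless active force (vectorized).
#' @export
active_force <- function(a, l_tilde, v_tilde, curves = hill_curves()) {
  a * curves$fal(l_tilde) * curves$fv(v_tilde)
}

#' Total muscle fiber force
#'
#' \eqn{F^M = f_0^M (f_A + f_P)}: maximum isometric force scales the sum of
#' active and passive dimensionless components. The result is floored at zero.
#'
#' @inheritParams active_force
#' @param params A [muscle_params()] object (supplies `f0M`).
#' @return Muscle force in newtons (vectorized).
#' @export
total_muscle_force <- function(a, l_tilde, v_tilde, params,
                               curves = hill_curves()) {
  params$f0M * pmax(0, active_force(a, l_tilde, v_tilde, curves) +
                       curves$fp(l_tilde))
}

#' Muscle-tendon complex force
#'
#' Force transmitted along the tendon line of action,
#' \eqn{F^{MT} = F^M \cos\phi}, from fiber-tendon force equilibrium with a
#' rigid tendon.
#'
#' @inheritParams total_muscle_force
#' @return Muscle-tendon force in newtons (vectorized).
#' @export
mt_force <- function(a, l_tilde, v_tilde, params, curves = hill_curves()) {
  total_muscle_force(a, l_tilde, v_tilde, params, curves) * cos(params$phi)
}
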