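#' Two-muscle elbow flexion-extension model
#'
#' A single degree-of-freedom rigid-body elbow driven by two antagonist
#' Hill-type muscle-tendon actuators (biceps flexor, triceps extensor). The
#' upper arm is fixed; the forearm is a massless link of length `l_fa` with a
#' point mass `m_fa` at the wrist, so the moment of inertia about the elbow is
#' \eqn{I = m_{fa} l_{fa}^2}. The flexion angle `q = 0` corresponds to full
#' extension with the forearm hanging vertically, giving the gravity torque
#' \eqn{E(q) = -m_{fa}\, g\, l_{fa} \sin q}.
#'
#' Muscles follow straight-line paths between attachment points at distances
#' `l1` (on the upper arm) and `l2` (on the forearm) from the joint; the
#' included angle is \eqn{\pi - q} for the biceps and \eqn{q} for the triceps,
#' which yields the law-of-cosines muscle-tendon lengths of [mt_length()] and
#' the moment-arm factor \eqn{l_1 l_2 \sin(q)/l^{MT}(q)}.
#'
#' Defaults are the verification configuration used throughout the package
#' (biceps: l0M 0.6 m, vmax 6 m/s, f0M 300 N, lsT 0.55 m; triceps: 0.4 m,
#' 4 m/s, 300 N, 0.33 m; geometry l1/l2 = 0.3/0.8 m and 0.2/0.7 m;
#' forearm 1 kg x 1 m; delay 0.08 s; activation shape 0.2).
#'
#' @param m_fa Forearm point mass (kg).
#' @param l_ua,l_fa Upper-arm and forearm link lengths (m).
#' @param l1_bi,l2_bi Biceps attachment distances from the elbow (m).
#' @param l1_tri,l2_tri Triceps attachment distances from the elbow (m).
#' @param g Gravitational acceleration (m/s^2).
#' @param biceps,triceps [muscle_params()] for each muscle group.
#' @param curves Shared [hill_curves()] object.
#' @return An `elbow_model` object.
#' @examples
#' model <- elbow_model()
#' mt_length(model, "biceps", q = 0)
#' @export
elbow_model <- function(m_fa = 1, l_ua = 1, l_fa = 1,
                        l1_bi = 0.3, l2_bi = 0.8,
                        l1_tri = 0.2, l2_tri = 0.7,
                        g = 9.81,
                        biceps = muscle_params(l0M = 0.6, vmaxM = 6,
                                               f0M = 300, lsT = 0.55),
                        triceps = muscle_params(l0M = 0.4, vmaxM = 4,
                                                f0M = 300, lsT = 0.33),
                        curves = hill_curves()) {
  stopifnot(m_fa > 0, l_ua > 0, l_fa > 0,
            l1_bi > 0, l2_bi > 0, l1_tri > 0, l2_tri > 0, g > 0)
  stopifnot(inherits(biceps, "muscle_params"),
            inherits(triceps, "muscle_params"),
            inherits(curves, "hill_curves"))
  structure(list(m_fa = m_fa, l_ua = l_ua, l_fa = l_fa,
                 l1_bi = l1_bi, l2_bi = l2_bi,
                 l1_tri = l1_tri, l2_tri = l2_tri,
                 g = g, biceps = biceps, triceps = triceps,
                 curves = curves,
                 inertia = m_fa * l_fa^2),
            class = "elbow_model")
}

#' @export
print.elbow_model <- function(x, ...) {
  cat("<elbow_model>\n")
  cat(sprintf("  forearm: m=%g kg, l=%g m (I=%g kg m^2), g=%g m/s^2\n",
              x$m_fa, x$l_fa, x$inertia, x$g))
  cat(sprintf("  biceps:  l1=%g, l2=%g m | f0M=%g N, vmax=%g m/s\n",
              x$l1_bi, x$l2_bi, x$biceps$f0M, x$biceps$vmaxM))
  cat(sprintf("  triceps: l1=%g, l2=%g m | f0M=%g N, vmax=%g m/s\n",
              x$l1_tri, x$l2_tri, x$triceps$f0M, x$triceps$vmaxM))
  invisible(x)
}

muscle_arg <- function(muscle) match.arg(muscle, c("biceps", "triceps"))

# attachment distances and the sign of the included-angle cosine term:
# biceps spans the joint on the flexor side (included angle pi - q),
# triceps on the extensor side (included angle q)
.muscle_geom <- function(model, muscle) {
  if (muscle == "biceps") {
    list(l1 = model$l1_bi, l2 = model$l2_bi, sgn = +1,
         params = model$biceps)
  } else {
    list(l1 = model$l1_tri, l2 = model$l2_tri, sgn = -1,
         params = model$triceps)
  }
}

#' Muscle-tendon complex length
#'
#' Straight-line origin-to-insertion length by the law of cosines:
#' \eqn{l^{MT}_{bi}(q) = \sqrt{l_1^2 + l_2^2 + 2 l_1 l_2 \cos q}} (shortens
#' with flexion) and
#' \eqn{l^{MT}_{tri}(q) = \sqrt{l_1^2 + l_2^2 - 2 l_1 l_2 \cos q}} (lengthens
#' with flexion).
#'
#' @param model An [elbow_model()].
#' @param muscle `"biceps"` or `"triceps"`.
#' @param q Elbow flexion angle (rad); vectorized.
#' @return Muscle-tendon length in metres.
#' @export
mt_length <- function(model, muscle, q) {
  gm <- .muscle_geom(model, muscle_arg(muscle))
  sqrt(gm$l1^2 + gm$l2^2 + 2 * gm$sgn * gm$l1 * gm$l2 * cos(q))
}

#' Muscle moment arm about the elbow
#'
#' \eqn{r(q) = l_1 l_2 \sin(q) / l^{MT}(q)}, the magnitude of the derivative
#' of the muscle-tendon length with respect to the joint angle. Vanishes at
#' full extension (`q = 0`).
#'
#' @inheritParams mt_length
#' @return Moment arm in metres (nonnegative on `[0, pi]`).
#' @export
moment_arm <- function(model, muscle, q) {
  gm <- .muscle_geom(model, muscle_arg(muscle))
  gm$l1 * gm$l2 * sin(q) / mt_length(model, muscle, q)
}

# d lMT / dq: negative for biceps (shortens with flexion), positive for triceps
.dmt_length <- function(model, muscle, q) {
  gm <- .muscle_geom(model, muscle)
  -gm$sgn * gm$l1 * gm$l2 * sin(q) / mt_length(model, muscle, q)
}

# d^2 lMT / dq^2
.d2mt_length <- function(model, muscle, q) {
  gm <- .muscle_geom(model, muscle)
  lmt <- mt_length(model, muscle, q)
  dl <- .dmt_length(model, muscle, q)
  (-gm$sgn * gm$l1 * gm$l2 * cos(q) - dl^2) / lmt
}

#' Normalized muscle fiber kinematics
#'
#' Rigid-tendon fiber state from the joint state: fiber length
#' \eqn{l^M = (l^{MT}(q) - l_s^T)/\cos\phi}, fiber velocity
#' \eqn{v^M = (dl^{MT}/dq)\,\dot q / \cos\phi}, both normalized by the
#' optimal length and maximum contraction velocity.
#'
#' @inheritParams mt_length
#' @param qdot Angular velocity (rad/s); vectorized with `q`.
#' @return A [tibble::tibble()] with columns `l_tilde` and `v_tilde`.
#' @export
muscle_kinematics <- function(model, muscle, q, qdot = 0) {
  muscle <- muscle_arg(muscle)
  gm <- .muscle_geom(model, muscle)
  p <- gm$params
  lmt <- mt_length(model, muscle, q)
  if (any(lmt <= p$lsT)) {
    qbad <- q[which(lmt <= p$lsT)[1]]
    stop(sprintf(
      "degenerate geometry: %s muscle-tendon length <= tendon slack length at q = %.4f rad",
      muscle, qbad), call. = FALSE)
  }
  lm <- (lmt - p$lsT) / cos(p$phi)
  vm <- .dmt_length(model, muscle, q) * qdot / cos(p$phi)
  tibble::tibble(l_tilde = lm / p$l0M, v_tilde = vm / p$vmaxM)
}

#' Gravity torque on the forearm
#'
#' \eqn{E(q) = -m_{fa}\, g\, l_{fa} \sin(q)}: nonpositive on `[0, pi]`, pulling
#' the forearm back toward full extension.
#'
#' @inheritParams mt_length
#' @return Torque in newton-metres (vectorized).
#' @export
gravity_torque <- function(model, q) {
  -model$m_fa * model$g * model$l_fa * sin(q)
}

#' Net muscle-tendon torque at the elbow
#'
#' \eqn{T^{MT} = F^{MT}_{bi} r_{bi}(q) - F^{MT}_{tri} r_{tri}(q)}: the flexor
#' contributes positive torque, the extensor negative torque.
#'
#' @inheritParams mt_length
#' @param a_bi,a_tri Activations in `[0, 1]` (vectorized with `q`).
#' @param qdot Angular velocity (rad/s).
#' @param gamma Optional named override of the identified parameters
#'   `c(f0M_bi, vmaxM_bi, f0M_tri, vmaxM_tri)`; `NULL` uses the model's own.
#' @return Net torque in newton-metres.
#' @export
net_mt_torque <- function(model, a_bi, a_tri, q, qdot = 0, gamma = NULL) {
  gamma <- .resolve_gamma(model, gamma)
  t_bi <- .muscle_torque(model, "biceps", a_bi, q, qdot,
                         gamma[1], gamma[2])
  t_tri <- .muscle_torque(model, "triceps", a_tri, q, qdot,
                          gamma[3], gamma[4])
  t_bi - t_tri
}

.resolve_gamma <- function(model, gamma) {
  if (is.null(gamma)) {
    c(model$biceps$f0M, model$biceps$vmaxM,
      model$triceps$f0M, model$triceps$vmaxM)
  } else {
    stopifnot(length(gamma) == 4)
    as.numeric(gamma)
  }
}

# torque magnitude of one muscle about the elbow (always >= 0)
.muscle_torque <- function(model, muscle, a, q, qdot, f0M, vmaxM) {
  gm <- .muscle_geom(model, muscle)
  p <- gm$params
  cv <- model$curves
  lmt <- mt_length(model, muscle, q)
  if (any(lmt <= p$lsT)) {
    qbad <- q[which(lmt <= p$lsT)[1]]
    stop(sprintf(
      "degenerate geometry: %s muscle-tendon length <= tendon slack length at q = %.4f rad",
      muscle, qbad), call. = FALSE)
  }
  l_t <- (lmt - p$lsT) / (cos(p$phi) * p$l0M)
  v_t <- .dmt_length(model, muscle, q) * qdot / (cos(p$phi) * vmaxM)
  fmt <- f0M * pmax(0, a * cv$fal(l_t) * cv$fv(v_t) + cv$fp(l_t)) * cos(p$phi)
  fmt * gm$l1 * gm$l2 * sin(q) / lmt
}

#' Equation-of-motion right-hand side
#'
#' Angular acceleration from the torque balance
#' \eqn{I \ddot q = E(q) + T^{MT}(a_{bi}, a_{tri}, q, \dot q)}.
#'
#' @inheritParams net_mt_torque
#' @return A list with `qdot` and `qddot` (the state derivative).
#' @export
ode_rhs <- function(model, q, qdot, a_bi, a_tri, gamma = NULL) {
  tq <- gravity_torque(model, q) +
    net_mt_torque(model, a_bi, a_tri, q, qdot, gamma)
  list(qdot = qdot, qddot = tq / model$inertia)
}

#' Forward-solve the elbow equation of motion
#'
#' Integrates \eqn{I\ddot q = E(q) + T^{MT}} with activation signals given on
#' a uniform time grid (linearly interpolated between samples), using an
#' adaptive solver (deSolve lsoda) at tight tolerance so that the resulting
#' trajectory is effectively noise-free. The solution is returned sampled on
#' the input grid.
#'
#' @param model An [elbow_model()].
#' @param activations A data frame with columns `t`, `a_bi`, `a_tri` on a
#'   uniform time grid.
#' @param q0,qdot0 Initial flexion angle (rad) and velocity (rad/s). The
#'   verification protocol uses `q0 = pi/6`, `qdot0 = 0`.
#' @param rtol,atol Solver relative/absolute tolerances.
#' @param gamma Optional parameter override as in [net_mt_torque()].
#' @return A [tibble::tibble()] with columns `t`, `a_bi`, `a_tri`, `q`,
#'   `qdot`.
#' @examples
#' model <- elbow_model()
#' acts <- tibble::tibble(t = seq(0, 1, length.out = 101), a_bi = 0.2, a_tri = 0.05)
#' trial <- forward_solve(model, acts, q0 = pi / 6)
#' @export
forward_solve <- function(model, activations, q0 = pi / 6, qdot0 = 0,
                          rtol = 1e-8, atol = 1e-10, gamma = NULL) {
  stopifnot(all(c("t", "a_bi", "a_tri") %in% names(activations)))
  tt <- activations$t
  f_bi <- stats::approxfun(tt, activations$a_bi, rule = 2)
  f_tri <- stats::approxfun(tt, activations$a_tri, rule = 2)
  deriv <- function(t, y, parms) {
    rhs <- ode_rhs(model, y[1], y[2], f_bi(t), f_tri(t), gamma)
    list(c(rhs$qdot, rhs$qddot))
  }
  sol <- deSolve::ode(y = c(q = q0, qdot = qdot0), times = tt,
                      func = deriv, parms = NULL,
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed near t = ", max(sol[, 1]), call. = FALSE)
  tibble::tibble(t = tt, a_bi = activations$a_bi, a_tri = activations$a_tri,
                 q = sol[, "q"], qdot = sol[, "qdot"])
}

#' Equation-of-motion residual
#'
#' The torque-balance residual
#' \eqn{r = I\ddot q - E(q) - T^{MT}(a_{bi}, a_{tri}, q, \dot q; \Gamma)}
#' evaluated pointwise on a trajectory. On an exact solution of the forward
#' dynamics with matching parameters the residual vanishes (to solver
#' tolerance); it is the physics penalty minimized by the PINN trainers.
#'
#' @inheritParams net_mt_torque
#' @param qddot Angular acceleration (rad/s^2).
#' @return Residual torque in newton-metres (vectorized).
#' @export
eom_residual <- function(model, q, qdot, qddot, a_bi, a_tri, gamma = NULL) {
  model$inertia * qddot - gravity_torque(model, q) -
    net_mt_torque(model, a_bi, a_tri, q, qdot, gamma)
}

# Residual plus analytic partial derivatives, vectorized over samples.
# Returns list(r, dq, dqdot, dqddot, dgamma [n x 4]) where gamma =
# (f0M_bi, vmaxM_bi, f0M_tri, vmaxM_tri). Used by the PINN trainers; validated
# against finite differences in the tests.
eom_residual_grad <- function(model, q, qdot, qddot, a_bi, a_tri, gamma) {
  gamma <- .resolve_gamma(model, gamma)
  n <- length(q)
  cv <- model$curves
  dq <- numeric(n); dqdot <- numeric(n)
  dgamma <- matrix(0, n, 4)
  tmt <- numeric(n)
  for (im in 1:2) {
    muscle <- c("biceps", "triceps")[im]
    gm <- .muscle_geom(model, muscle)
    p <- gm$params
    a <- if (im == 1) a_bi else a_tri
    f0 <- gamma[2 * im - 1]; vmax <- gamma[2 * im]
    tsgn <- if (im == 1) 1 else -1   # flexor +, extensor -
    cphi <- cos(p$phi)
    lmt <- mt_length(model, muscle, q)
    dl <- .dmt_length(model, muscle, q)
    d2l <- .d2mt_length(model, muscle, q)
    l_t <- (lmt - p$lsT) / (cphi * p$l0M)
    v_t <- dl * qdot / (cphi * vmax)
    dlt_dq <- dl / (cphi * p$l0M)
    dvt_dq <- d2l * qdot / (cphi * vmax)
    dvt_dqdot <- dl / (cphi * vmax)
    fal <- cv$fal(l_t); fv <- cv$fv(v_t); fp <- cv$fp(l_t)
    dfal <- cv$dfal(l_t); dfv <- cv$dfv(v_t); dfp <- cv$dfp(l_t)
    ftot <- a * fal * fv + fp                 # dimensionless, >= 0 by curve contract
    fmt <- f0 * cphi * ftot
    rho <- gm$l1 * gm$l2 * sin(q) / lmt
    drho <- gm$l1 * gm$l2 * cos(q) / lmt - rho * dl / lmt
    dfmt_dq <- f0 * cphi * (a * (dfal * fv * dlt_dq + fal * dfv * dvt_dq) +
                              dfp * dlt_dq)
    dfmt_dqdot <- f0 * cphi * a * fal * dfv * dvt_dqdot
    tmt <- tmt + tsgn * fmt * rho
    dq <- dq + tsgn * (dfmt_dq * rho + fmt * drho)
    dqdot <- dqdot + tsgn * dfmt_dqdot * rho
    dgamma[, 2 * im - 1] <- tsgn * cphi * ftot * rho
    dgamma[, 2 * im] <- tsgn * f0 * cphi * a * fal * dfv *
      (-v_t / vmax) * rho
  }
  grav <- gravity_torque(model, q)
  dgrav <- -model$m_fa * model$g * model$l_fa * cos(q)
  list(r = model$inertia * qddot - grav - tmt,
       dq = -dgrav - dq,
       dqdot = -dqdot,
       dqddot = rep(model$inertia, n),
       dgamma = -dgamma)
}
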