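test_that("muscle-tendon lengths follow the law of cosines", {
  model <- verification_model()
  expect_equal(mt_length(model, "biceps", 0), 1.1, tolerance = 1e-12)
  expect_equal(mt_length(model, "biceps", pi), 0.5, tolerance = 1e-12)
  expect_equal(mt_length(model, "triceps", 0), 0.5, tolerance = 1e-12)
  expect_equal(mt_length(model, "triceps", pi),
               sqrt(0.04 + 0.49 + 0.28), tolerance = 1e-12)
  # flexor shortens, extensor lengthens with flexion
  qq <- seq(0.01, pi - 0.01, length.out = 200)
  expect_true(all(diff(mt_length(model, "biceps", qq)) < 0))
  expect_true(all(diff(mt_length(model, "triceps", qq)) > 0))
})

test_that("moment arms vanish at extension and match d(lMT)/dq", {
  model <- verification_model()
  expect_equal(moment_arm(model, "biceps", 0), 0)
  expect_equal(moment_arm(model, "triceps", 0), 0)
  expect_equal(moment_arm(model, "biceps", pi / 2),
               0.3 * 0.8 / sqrt(0.73), tolerance = 1e-12)
  # |d lMT / dq| finite-difference oracle
  h <- 1e-6
  qq <- seq(0.05, pi - 0.05, length.out = 60)
  for (mus in c("biceps", "triceps")) {
    fd <- abs(mt_length(model, mus, qq + h) -
                mt_length(model, mus, qq - h)) / (2 * h)
    expect_equal(moment_arm(model, mus, qq), fd, tolerance = 1e-6)
  }
})

test_that("fiber kinematics follow the rigid-tendon chain", {
  model <- verification_model()
  km <- muscle_kinematics(model, "biceps", q = 0, qdot = 0)
  expect_equal(km$l_tilde, (1.1 - 0.55) / 0.6, tolerance = 1e-12)
  expect_equal(km$v_tilde, 0)
  # zero angular velocity always gives zero fiber velocity
  km2 <- muscle_kinematics(model, "triceps", q = seq(0.2, 2, 0.3), qdot = 0)
  expect_true(all(km2$v_tilde == 0))
  # flexion shortens the biceps fiber (negative normalized velocity)
  km3 <- muscle_kinematics(model, "biceps", q = 1, qdot = 2)
  expect_lt(km3$v_tilde, 0)
  km4 <- muscle_kinematics(model, "triceps", q = 1, qdot = 2)
  expect_gt(km4$v_tilde, 0)
  # degenerate geometry errors name the muscle
  expect_error(muscle_kinematics(model, "biceps", q = 3), "biceps")
})

test_that("gravity torque is zero at extension and matches closed form", {
  model <- verification_model()
  expect_equal(gravity_torque(model, 0), 0)
  expect_equal(gravity_torque(model, pi / 2), -9.81, tolerance = 1e-12)
  expect_equal(gravity_torque(model, pi / 6), -9.81 * 0.5, tolerance = 1e-12)
  qq <- seq(0, pi, 0.1)
  expect_true(all(gravity_torque(model, qq) <= 0))
})

test_that("net torque is antagonistic and vanishes at extension", {
  model <- verification_model()
  expect_equal(net_mt_torque(model, 0.7, 0.3, q = 0, qdot = 0), 0)
  # slack muscles, no activation: no torque anywhere both fibers are short
  expect_equal(net_mt_torque(model, 0, 0, q = 0.3, qdot = 0), 0)
  # flexor activation raises torque, extensor activation lowers it
  qq <- seq(0.2, 2.2, by = 0.4)
  for (q in qq) {
    t_lo <- net_mt_torque(model, 0.2, 0.1, q, 0)
    t_hi <- net_mt_torque(model, 0.5, 0.1, q, 0)
    expect_gt(t_hi, t_lo)
    t_ext <- net_mt_torque(model, 0.2, 0.4, q, 0)
    expect_lt(t_ext, t_lo)
  }
  # composition oracle: single active flexor at right angle
  fmt <- mt_force(1, muscle_kinematics(model, "biceps", pi / 2)$l_tilde, 0,
                  model$biceps, model$curves)
  expect_equal(net_mt_torque(model, 1, 0, pi / 2, 0),
               fmt * moment_arm(model, "biceps", pi / 2), tolerance = 1e-12)
})

test_that("equation-of-motion right-hand side reduces to known limits", {
  model <- verification_model()
  rhs <- ode_rhs(model, q = 0, qdot = 0, a_bi = 0, a_tri = 0)
  expect_equal(rhs$qdot, 0)
  expect_equal(rhs$qddot, 0)
  # detached muscles: pure pendulum acceleration -g/l * sin(q)
  pend <- elbow_model(
    biceps = muscle_params(0.6, 6, 0, 0.55),
    triceps = muscle_params(0.4, 4, 0, 0.33))
  rhs2 <- ode_rhs(pend, q = pi / 2, qdot = 0, a_bi = 0, a_tri = 0)
  expect_equal(rhs2$qddot, -9.81, tolerance = 1e-12)
})

test_that("forward solve matches an independent pendulum integration", {
  # muscles detached -> q'' = -(g/l) sin q; oracle is a fixed-step RK4
  pend <- elbow_model(
    biceps = muscle_params(0.6, 6, 0, 0.55),
    triceps = muscle_params(0.4, 4, 0, 0.33))
  tt <- seq(0, 10, length.out = 1001)
  acts <- tibble::tibble(t = tt, a_bi = 0, a_tri = 0)
  sol <- forward_solve(pend, acts, q0 = pi / 6, qdot0 = 0,
                       rtol = 1e-10, atol = 1e-12)
  fine <- seq(0, 10, length.out = 40001)
  oracle <- rk4_integrate(function(t, y) c(y[2], -9.81 * sin(y[1])),
                          c(pi / 6, 0), fine)
  idx <- seq(1, 40001, by = 40)
  expect_lt(max(abs(sol$q - oracle[idx, 1])), 1e-6)
})

test_that("stable equilibrium stays put and solver self-converges", {
  model <- verification_model()
  tt <- seq(0, 2, length.out = 201)
  acts <- tibble::tibble(t = tt, a_bi = 0, a_tri = 0)
  sol <- forward_solve(model, acts, q0 = 0, qdot0 = 0)
  expect_lt(max(abs(sol$q)), 1e-10)

  # active case: tightening the tolerance changes the trajectory less than
  # the coarser tolerance
  acts2 <- tibble::tibble(t = tt,
                          a_bi = 0.3 + 0.1 * sin(2 * pi * tt),
                          a_tri = 0.05)
  coarse <- forward_solve(model, acts2, rtol = 1e-7, atol = 1e-9)
  tight <- forward_solve(model, acts2, rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(coarse$q - tight$q)), 1e-5)
})

test_that("the residual vanishes on the solver's own trajectory", {
  model <- verification_model()
  tr <- clean_dataset()$trials[[2]]
  # acceleration from the equation of motion itself evaluated on the states
  rhs <- ode_rhs(model, tr$q, tr$qdot, tr$a_bi, tr$a_tri)
  r <- eom_residual(model, tr$q, tr$qdot, rhs$qddot, tr$a_bi, tr$a_tri)
  expect_lt(max(abs(r)), 1e-10)
  # perturbing the acceleration moves the residual by exactly I * delta
  r2 <- eom_residual(model, tr$q, tr$qdot, rhs$qddot + 0.5, tr$a_bi, tr$a_tri)
  expect_equal(r2 - r, rep(model$inertia * 0.5, length(r)), tolerance = 1e-12)
  # zero state, slack muscles: identically zero
  expect_equal(eom_residual(model, 0, 0, 0, 0, 0), 0)
})

test_that("residual-zero property holds with finite-difference acceleration", {
  # independent check that the stored trajectory solves the ODE: accelerations
  # from central differences of qdot rather than from the model
  model <- verification_model()
  tr <- clean_dataset()$trials[[1]]
  n <- nrow(tr)
  dt <- tr$t[2] - tr$t[1]
  qdd <- (tr$qdot[3:n] - tr$qdot[1:(n - 2)]) / (2 * dt)
  idx <- 2:(n - 1)
  r <- eom_residual(model, tr$q[idx], tr$qdot[idx], qdd,
                    tr$a_bi[idx], tr$a_tri[idx])
  expect_lt(max(abs(r)), 0.2)  # O(dt^2) differentiation error dominates
  expect_lt(stats::median(abs(r)), 0.02)
})

test_that("residual partial derivatives match finite differences", {
  model <- verification_model()
  withr::with_seed(11, {
    q <- runif(8, 0.4, 1.8); qd <- runif(8, -2, 2); qdd <- runif(8, -5, 5)
    ab <- runif(8, 0, 0.5); at <- runif(8, 0, 0.3)
  })
  gam <- c(320, 5.2, 270, 4.6)
  rg <- mskpinn:::eom_residual_grad(model, q, qd, qdd, ab, at, gam)
  h <- 1e-6
  expect_equal(rg$r, eom_residual(model, q, qd, qdd, ab, at, gam),
               tolerance = 1e-12)
  fd_q <- (eom_residual(model, q + h, qd, qdd, ab, at, gam) -
             eom_residual(model, q - h, qd, qdd, ab, at, gam)) / (2 * h)
  fd_qd <- (eom_residual(model, q, qd + h, qdd, ab, at, gam) -
              eom_residual(model, q, qd - h, qdd, ab, at, gam)) / (2 * h)
  expect_equal(rg$dq, fd_q, tolerance = 1e-6)
  expect_equal(rg$dqdot, fd_qd, tolerance = 1e-6)
  expect_equal(rg$dqddot, rep(model$inertia, 8))
  for (l in 1:4) {
    gp <- gam; gm <- gam
    gp[l] <- gam[l] + h * gam[l]
    gm[l] <- gam[l] - h * gam[l]
    fd <- (eom_residual(model, q, qd, qdd, ab, at, gp) -
             eom_residual(model, q, qd, qdd, ab, at, gm)) / (2 * h * gam[l])
    expect_equal(rg$dgamma[, l], fd, tolerance = 1e-5)
  }
})

test_that("model configuration round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "m_fa: 1.5",
    "biceps:",
    "  f0M: 350",
    "  vmaxM: 5",
    "  l1: 0.31",
    "  l2: 0.79",
    "triceps:",
    "  lsT: 0.35"), path)
  model <- read_model_yaml(path)
  expect_equal(model$m_fa, 1.5)
  expect_equal(model$biceps$f0M, 350)
  expect_equal(model$biceps$vmaxM, 5)
  expect_equal(model$l1_bi, 0.31)
  expect_equal(model$triceps$lsT, 0.35)
  expect_equal(model$triceps$f0M, 300)  # default preserved
})
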