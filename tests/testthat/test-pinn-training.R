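# Training-facing unit tests: loss definitions, gradient correctness of the
# composite objective, determinism, and the parameter normalization contract.
# Full-protocol parameter recovery lives in test-acceptance.R.

td_setup <- function() {
  ds <- small_dataset()
  ff <- ff_spec(m = 12, sigma = c(2, 1, 1), seed = 4)
  net0 <- mskpinn:::mlp_init(c(12, 8, 1), seed = 5)
  list(ds = ds, ff = ff,
       net = list(W = net0$W, b = net0$b),
       gamma0 = c(360, 4.8, 240, 4.8))
}

test_that("composite time-domain loss obeys its algebra", {
  s <- td_setup()
  model <- verification_model()
  gb <- c(1.05, 0.9, 1.1, 0.95)
  l0 <- loss_td(s$net, gb, s$ds, beta = 0, ff = s$ff, gamma0 = s$gamma0)
  expect_equal(l0$J, l0$Jdata)
  l1 <- loss_td(s$net, gb, s$ds, beta = 1e-4, ff = s$ff, gamma0 = s$gamma0)
  l2 <- loss_td(s$net, gb, s$ds, beta = 2e-4, ff = s$ff, gamma0 = s$gamma0)
  expect_equal(l1$Jdata, l0$Jdata)
  expect_equal(l2$J - l2$Jdata, 2 * (l1$J - l1$Jdata), tolerance = 1e-12)
  expect_gte(l1$Jres, 0)
})

test_that("time-domain loss gradients match central finite differences", {
  s <- td_setup()
  model <- verification_model()
  data <- mskpinn:::.td_data(s$ds$trials[s$ds$train], s$ff)
  params <- list(W = s$net$W, b = s$net$b,
                 gamma_bar = c(1.1, 0.9, 1.05, 0.95))
  beta <- 1e-4
  res <- mskpinn:::.td_objective(params, data, model, beta, s$gamma0)
  obj <- function(p) mskpinn:::.td_objective(p, data, model, beta, s$gamma0,
                                             want_grad = FALSE)$J
  # normalized parameters
  fd_g <- fd_gradient(function(g) {
    p <- params; p$gamma_bar <- g; obj(p)
  }, params$gamma_bar)
  expect_lt(max(abs(res$grads$gamma_bar - fd_g) / (abs(fd_g) + 1e-10)), 1e-4)
  # random weights and biases across layers
  withr::with_seed(61, {
    for (rep in 1:10) {
      k <- sample(2, 1)
      i <- sample(length(params$W[[k]]), 1)
      fd <- fd_gradient(function(v) {
        p <- params; p$W[[k]][i] <- v; obj(p)
      }, params$W[[k]][i])
      expect_lt(abs(res$grads$W[[k]][i] - fd) / (abs(fd) + 1e-10), 1e-4)
    }
    k <- 1
    i <- sample(length(params$b[[k]]), 1)
    fd <- fd_gradient(function(v) {
      p <- params; p$b[[k]][i] <- v; obj(p)
    }, params$b[[k]][i])
    expect_lt(abs(res$grads$b[[k]][i] - fd) / (abs(fd) + 1e-10), 1e-4)
  })
})

test_that("feature-encoded loss vanishes for true coefficients and parameters", {
  ds <- small_dataset()
  model <- verification_model()
  # a network is irrelevant here: evaluate the residual part directly by
  # feeding the true encoded coefficients through an identity-like check
  data <- mskpinn:::.fe_data(ds$trials[ds$train], n_emg = 8, n_q = 20)
  gamma_true <- c(300, 6, 300, 4)
  Jres <- 0
  for (k in seq_along(data$per)) {
    pk <- data$per[[k]]
    o <- data$O[k, ]
    qh <- as.numeric(pk$Phi0 %*% o)
    qh1 <- as.numeric(pk$Phi1 %*% o)
    qh2 <- as.numeric(pk$Phi2 %*% o)
    r <- eom_residual(model, qh, qh1, qh2, pk$a_bi, pk$a_tri, gamma_true)
    Jres <- Jres + mean(r^2)
  }
  # encoding truncation leaves a small but non-dominant residual
  expect_lt(Jres / length(data$per), 0.05)
})

test_that("feature-encoded loss gradients match finite differences", {
  ds <- small_dataset()
  model <- verification_model()
  data <- mskpinn:::.fe_data(ds$trials[ds$train], n_emg = 5, n_q = 8)
  net0 <- mskpinn:::mlp_init(c(ncol(data$X), 6, ncol(data$O)), seed = 13)
  params <- list(W = net0$W, b = net0$b,
                 gamma_bar = c(0.95, 1.1, 1.05, 0.9))
  gamma0 <- c(330, 5, 330, 5)
  beta <- 1e-4
  res <- mskpinn:::.fe_objective(params, data, model, beta, gamma0)
  obj <- function(p) mskpinn:::.fe_objective(p, data, model, beta, gamma0,
                                             want_grad = FALSE)$J
  fd_g <- fd_gradient(function(g) {
    p <- params; p$gamma_bar <- g; obj(p)
  }, params$gamma_bar)
  expect_lt(max(abs(res$grads$gamma_bar - fd_g) / (abs(fd_g) + 1e-10)), 1e-4)
  withr::with_seed(62, {
    for (rep in 1:6) {
      k <- sample(2, 1)
      i <- sample(length(params$W[[k]]), 1)
      fd <- fd_gradient(function(v) {
        p <- params; p$W[[k]][i] <- v; obj(p)
      }, params$W[[k]][i])
      expect_lt(abs(res$grads$W[[k]][i] - fd) / (abs(fd) + 1e-10), 1e-4)
    }
  })
})

test_that("parameter normalization round-trips exactly", {
  gamma0 <- c(300, 6, 300, 4)
  expect_equal(normalize_params(gamma0, gamma0), rep(1, 4))
  gb <- c(1.01, 0.98, 1.2, 0.85)
  expect_equal(denormalize_params(gb, gamma0), gb * gamma0)
  expect_equal(normalize_params(denormalize_params(gb, gamma0), gamma0), gb)
  expect_equal(denormalize_params(c(1.01, 1, 1, 1), c(300, 6, 300, 4))[1], 303)
  expect_error(normalize_params(gamma0, c(0, 6, 300, 4)), "positive")
})

test_that("short training runs are seeded-deterministic and improve the loss", {
  ds <- small_dataset()
  ident <- ident_spec(epochs = 60, patience = 60, log_every = 0)
  net <- net_spec(hidden = c(8, 8), seed = 3)
  ff <- ff_spec(m = 12, sigma = c(2, 1, 1), seed = 4)
  f1 <- train_pinn_td(ds, net = net, ff = ff, ident = ident)
  f2 <- train_pinn_td(ds, net = net, ff = ff, ident = ident)
  expect_identical(f1$history$J, f2$history$J)
  expect_identical(f1$gamma, f2$gamma)
  expect_lt(dplyr::last(f1$history$J), f1$history$J[1])
  # gamma path is recorded every epoch
  expect_equal(nrow(f1$gamma_path), f1$epochs_run)
  # predictions have the tidy shape
  pr <- predict(f1, ds$trials[[1]])
  expect_named(pr, c("t", "q_hat", "qdot_hat", "qddot_hat"))
  expect_equal(nrow(pr), nrow(ds$trials[[1]]))
})

test_that("feature-encoded training runs deterministically end to end", {
  ds <- small_dataset()
  ident <- ident_spec(epochs = 120, patience = 120)
  f1 <- train_pinn_fe(ds, net = net_spec(hidden = c(8, 8), seed = 3),
                      ident = ident, n_emg = 5, n_q = 8)
  f2 <- train_pinn_fe(ds, net = net_spec(hidden = c(8, 8), seed = 3),
                      ident = ident, n_emg = 5, n_q = 8)
  expect_identical(f1$history$J, f2$history$J)
  expect_lt(dplyr::last(f1$history$J), f1$history$J[1])
  pr <- predict(f1, ds$trials[[1]])
  expect_equal(nrow(pr), nrow(ds$trials[[1]]))
  # capping warning when the encoding would be underdetermined
  expect_warning(
    train_pinn_fe(ds, net = net_spec(hidden = c(4,4), seed = 1),
                  ident = ident_spec(epochs = 2, patience = 2),
                  n_emg = 200, n_q = 4),
    "underdetermined")
})

test_that("broom-style accessors summarize a fit", {
  ds <- small_dataset()
  fit <- train_pinn_td(ds, net = net_spec(hidden = c(8, 8), seed = 3),
                       ff = ff_spec(m = 12, sigma = c(2, 1, 1), seed = 4),
                       ident = ident_spec(epochs = 30, patience = 30))
  td <- tidy(fit)
  expect_equal(td$parameter,
               c("f0M_bi", "vmaxM_bi", "f0M_tri", "vmaxM_tri"))
  expect_equal(td$estimate, td$normalized * td$initial)
  expect_equal(td$truth, c(300, 6, 300, 4))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("J", "Jdata", "Jres", "best_epoch") %in% names(gl)))
  # plots build without error
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(fit, type = "loss"), "ggplot")
  expect_s3_class(autoplot(ds$trials[[1]]), "ggplot")
  expect_s3_class(plot_prediction(fit, ds$trials[[1]]), "ggplot")
})

test_that("metrics follow their closed forms", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(0, 0), c(1, 1)), 1)
  expect_equal(mse(c(1, 2, 3), c(1, 1, 1)), 5 / 3)
  expect_error(mse(1:3, 1:4), "length")
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 1, 1)), -1.5)
  expect_error(r_squared(rep(1, 5), rnorm(5)), "constant")
  # algebraic identity r2 = 1 - n * mse / ss_tot, and shift invariance
  withr::with_seed(71, {
    q <- rnorm(50); qh <- q + rnorm(50, sd = 0.3)
  })
  expect_equal(r_squared(q, qh),
               1 - 50 * mse(q, qh) / sum((q - mean(q))^2))
  expect_equal(mse(q + 5, qh + 5), mse(q, qh))
  rec <- param_recovery(c(f0 = 300), c(303))
  expect_equal(rec$rel_error_pct, 1)
  expect_equal(param_recovery(c(300, 6), c(300, 6))$rel_error_pct, c(0, 0))
})
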