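#' Random Fourier feature embedding
#'
#' Fixed sinusoidal embedding \eqn{x_F = \sin(W_F x + b_F)} with `W_F` and
#' `b_F` sampled once from \eqn{N(0, \sigma^2)} and never trained. The
#' embedding counteracts the low-frequency (spectral) bias of fully connected
#' networks.
#'
#' @param m Number of features.
#' @param sigma Standard deviation of the sampled weights: a scalar applied
#'   to every input, or a length-`d` vector giving each input its own
#'   bandwidth. The surrogate's time input is normalized to `[0, 1]`, so its
#'   sigma sets how many feature oscillations span the trial; the default
#'   gives the time channel a bandwidth of `4 * pi` (about two oscillations
#'   per feature across the trial, enough to seed the motion's burst
#'   frequencies) and the sEMG channels a bandwidth of 12 — large enough to
#'   separate trials whose excitation levels differ by a few hundredths,
#'   small enough that the features stay band-limited along the input path
#'   (the surrogate's time derivatives are only trustworthy below the
#'   sampling bandwidth).
#'   With a vector sigma the phases `b_F` are sampled with standard
#'   deviation `pi` (covering the circle); with a scalar they use `sigma`.
#' @param d Input dimension (time plus one sEMG channel per muscle = 3 for
#'   the elbow model).
#' @param seed Integer seed; the same seed reproduces the same embedding.
#' @return An `ff_spec` object with fixed `W` (`m x d`) and `b` (length `m`).
#' @export
ff_spec <- function(m = 64, sigma = c(4 * pi, 12, 12), d = 3, seed = 1L) {
  stopifnot(m >= 1, all(sigma > 0), d >= 1,
            length(sigma) == 1 || length(sigma) == d)
  sigma_b <- if (length(sigma) == 1) sigma else pi
  sd_col <- rep(sigma, length.out = d)
  withr::with_seed(as.integer(seed), {
    W <- sapply(sd_col, function(s) stats::rnorm(m, sd = s))
    b <- stats::rnorm(m, sd = sigma_b)
  })
  structure(list(m = m, sigma = sigma, d = d, seed = as.integer(seed),
                 W = matrix(W, m, d), b = b),
            class = "ff_spec")
}

#' Evaluate Fourier features
#'
#' @param x Input vector (length `d`) or matrix (`n x d`).
#' @param spec An [ff_spec()].
#' @return Feature vector of length `m`, or an `n x m` matrix.
#' @export
fourier_features <- function(x, spec) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  stopifnot(ncol(x) == spec$d)
  out <- sin(sweep(x %*% t(spec$W), 2, spec$b, `+`))
  if (nrow(out) == 1) as.numeric(out) else out
}

#' Network architecture specification
#'
#' @param hidden Integer vector of hidden-layer widths (tanh activations;
#'   the output layer is linear).
#' @param seed Seed for the Glorot-style weight initialization.
#' @return A `net_spec` object.
#' @export
net_spec <- function(hidden = c(32, 32, 32), seed = 1L) {
  stopifnot(length(hidden) >= 1, all(hidden >= 1))
  structure(list(hidden = as.integer(hidden), seed = as.integer(seed)),
            class = "net_spec")
}

#' Identification / optimization specification
#'
#' Controls the co-training of the network weights and the normalized muscle
#' parameters \eqn{\bar\Gamma = \Gamma / \Gamma^{(0)}} (trainable, initialized
#' at 1, so the physical parameters start at \eqn{\Gamma^{(0)}}).
#'
#' @param gamma0 Initial parameter values
#'   `c(f0M_bi, vmaxM_bi, f0M_tri, vmaxM_tri)`. `NULL` (default) derives them
#'   from the model's true values scaled by `gamma0_offset` — the standard
#'   off-truth initialization of recovery studies.
#' @param gamma0_offset Multiplicative offsets applied to the true parameters
#'   when `gamma0` is `NULL`.
#' @param beta Residual (physics) weight in the composite loss
#'   `J = Jdata + beta * Jres`. `NULL` computes `dt^2 * I` from the training
#'   data time-step and the model inertia, the scaling that gives both loss
#'   terms the same units (1e-4 for the default 0.01 s grid and 1 kg m^2
#'   inertia).
#' @param lr,lr_end Initial Adam learning rate and the final rate of the
#'   geometric decay schedule (`lr_end = lr` gives a constant rate).
#' @param epochs Maximum number of full-batch epochs.
#' @param patience Early-stopping patience: training stops after this many
#'   epochs without improvement of the best composite loss.
#' @param gamma_warmup Number of initial epochs during which the normalized
#'   parameters stay frozen at 1 while only the network trains. Co-training
#'   from epoch 1 lets the parameters chase the residual structure of a
#'   still-poor surrogate; a short warmup lets the surrogate reach a faithful
#'   kinematic fit first.
#' @param beta_warmup Number of initial epochs over which the residual weight
#'   ramps quadratically from 0 to `beta` (a physics curriculum). An untrained
#'   network's second time derivative is essentially noise, so at full weight
#'   the physics term initially dwarfs the data term and can trap the
#'   surrogate in a flat, physics-trivial solution; fitting the kinematics
#'   first avoids that failure mode.
#' @param log_every Print loss components every `log_every` epochs (0 = quiet).
#' @return An `ident_spec` object.
#' @export
ident_spec <- function(gamma0 = NULL,
                       gamma0_offset = c(1.2, 0.8, 0.8, 1.2),
                       beta = NULL, lr = 5e-3, lr_end = 2e-4,
                       epochs = 20000L, patience = 2000L,
                       gamma_warmup = 2000L, beta_warmup = 2000L,
                       log_every = 0L) {
  if (!is.null(gamma0) && any(gamma0 <= 0))
    stop("gamma0 must be positive", call. = FALSE)
  stopifnot(is.null(beta) || beta >= 0, lr > 0, lr_end > 0, epochs >= 1)
  structure(list(gamma0 = gamma0, gamma0_offset = gamma0_offset,
                 beta = beta, lr = lr, lr_end = lr_end,
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 gamma_warmup = as.integer(gamma_warmup),
                 beta_warmup = as.integer(beta_warmup),
                 log_every = as.integer(log_every)),
            class = "ident_spec")
}

#' Normalize / denormalize identified parameters
#'
#' \eqn{\bar\Gamma_l = \Gamma_l / \Gamma_l^{(0)}} and its inverse. The
#' normalization puts parameters of very different magnitudes (hundreds of
#' newtons vs a few m/s) on a common O(1) scale for optimization.
#'
#' @param gamma,gamma_bar Parameter vectors (physical / normalized).
#' @param gamma0 Positive reference (initial) values.
#' @return The normalized (or physical) parameter vector.
#' @export
normalize_params <- function(gamma, gamma0) {
  if (any(gamma0 <= 0)) stop("gamma0 must be positive", call. = FALSE)
  gamma / gamma0
}

#' @rdname normalize_params
#' @export
denormalize_params <- function(gamma_bar, gamma0) {
  if (any(gamma0 <= 0)) stop("gamma0 must be positive", call. = FALSE)
  gamma_bar * gamma0
}

.gamma_names <- c("f0M_bi", "vmaxM_bi", "f0M_tri", "vmaxM_tri")

.gamma_true <- function(model) {
  c(model$biceps$f0M, model$biceps$vmaxM,
    model$triceps$f0M, model$triceps$vmaxM)
}

.resolve_ident <- function(ident, model, dt) {
  if (is.null(ident$gamma0)) {
    if (is.null(model))
      stop("gamma0 must be given when the dataset carries no model",
           call. = FALSE)
    ident$gamma0 <- .gamma_true(model) * ident$gamma0_offset
  }
  if (is.null(ident$beta)) ident$beta <- dt^2 * model$inertia
  ident
}

# central differences on a uniform grid (one-sided at the ends)
.fdiff <- function(x, dt) {
  n <- length(x)
  c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) / dt
}

# ---- time-domain training data: precomputed feature triples ----
# The Fourier embedding is fixed, so the features and their first/second time
# derivatives are computed once before the training loop. With
# derivatives = "path" (default) the time derivatives are total derivatives
# along the measured input path (t, e_bi(t), e_tri(t)) — the derivative of
# the predicted motion — with the signal derivatives from central
# differences; "time" differentiates with respect to the time input only.
.td_data <- function(trials, ff, derivatives = "path") {
  rows <- purrr::map(trials, function(tr) {
    T_k <- max(tr$t) - min(tr$t)
    dt <- tr$t[2] - tr$t[1]
    X <- cbind(tr$t / T_k, tr$e_bi, tr$e_tri)
    U <- sweep(X %*% t(ff$W), 2, ff$b, `+`)
    if (derivatives == "path") {
      X1 <- cbind(1 / T_k, .fdiff(tr$e_bi, dt), .fdiff(tr$e_tri, dt))
      X2 <- cbind(0, .fdiff(.fdiff(tr$e_bi, dt), dt),
                  .fdiff(.fdiff(tr$e_tri, dt), dt))
      D1 <- X1 %*% t(ff$W)
      D2 <- X2 %*% t(ff$W)
      Z1 <- cos(U) * D1
      Z2 <- -sin(U) * D1^2 + cos(U) * D2
    } else {
      D <- matrix(ff$W[, 1] / T_k, nrow(X), ff$m, byrow = TRUE)
      Z1 <- cos(U) * D
      Z2 <- -sin(U) * D^2
    }
    list(Z0 = sin(U), Z1 = Z1, Z2 = Z2,
         q = tr$q, a_bi = tr$a_bi, a_tri = tr$a_tri)
  })
  list(Z0 = do.call(rbind, purrr::map(rows, "Z0")),
       Z1 = do.call(rbind, purrr::map(rows, "Z1")),
       Z2 = do.call(rbind, purrr::map(rows, "Z2")),
       q = unlist(purrr::map(rows, "q")),
       a_bi = unlist(purrr::map(rows, "a_bi")),
       a_tri = unlist(purrr::map(rows, "a_tri")))
}

# composite loss and gradients for the time-domain surrogate
.td_objective <- function(params, data, model, beta, gamma0,
                          want_grad = TRUE) {
  fw <- .mlp_out3_cpp(params$W, params$b, data$Z0, data$Z1, data$Z2)
  qh <- fw$out[, 1]; qh1 <- fw$out1[, 1]; qh2 <- fw$out2[, 1]
  n <- length(qh)
  gamma <- params$gamma_bar * gamma0
  rg <- eom_residual_grad(model, qh, qh1, qh2, data$a_bi, data$a_tri, gamma)
  Jdata <- mean((qh - data$q)^2)
  Jres <- mean(rg$r^2)
  out <- list(J = Jdata + beta * Jres, Jdata = Jdata, Jres = Jres)
  if (want_grad) {
    w <- 2 * beta * rg$r / n
    G0 <- 2 * (qh - data$q) / n + w * rg$dq
    G1 <- w * rg$dqdot
    G2 <- w * rg$dqddot
    g <- .mlp_grad3_cpp(params$W, params$b, data$Z0, data$Z1, data$Z2,
                        cbind(G0), cbind(G1), cbind(G2))
    out$grads <- list(W = g$W, b = lapply(g$b, as.numeric),
                      gamma_bar = (2 * beta / n) *
                        as.numeric(crossprod(rg$dgamma, rg$r)) * gamma0)
  }
  out
}

#' Composite time-domain PINN loss
#'
#' Evaluates `J = Jdata + beta * Jres` for a time-domain surrogate:
#' `Jdata` is the mean squared error between predicted and measured joint
#' angles over all training samples, and `Jres` is the mean squared
#' equation-of-motion residual evaluated with the network's predicted angle
#' and its first/second time derivatives and the physical parameters
#' `gamma_bar * gamma0`.
#'
#' @param net A network (`list(W, b)`) as stored in a fitted object.
#' @param gamma_bar Normalized parameter vector (length 4).
#' @param dataset An `msk_dataset` (training trials are used).
#' @param beta Residual weight.
#' @param ff The [ff_spec()] used by the network.
#' @param gamma0 Reference parameter values.
#' @param model Elbow model providing geometry and curves; defaults to the
#'   dataset's model.
#' @param derivatives `"path"` (total derivatives along the measured input
#'   path; default) or `"time"` (partial derivatives with respect to the
#'   time input only).
#' @return A list with `J`, `Jdata`, `Jres`.
#' @export
loss_td <- function(net, gamma_bar, dataset, beta, ff, gamma0,
                    model = dataset$model, derivatives = c("path", "time")) {
  derivatives <- match.arg(derivatives)
  data <- .td_data(dataset$trials[dataset$train], ff, derivatives)
  res <- .td_objective(list(W = net$W, b = net$b, gamma_bar = gamma_bar),
                       data, model, beta, gamma0, want_grad = FALSE)
  res[c("J", "Jdata", "Jres")]
}

# ---- feature-encoded training data ----
.fe_data <- function(trials, n_emg, n_q, allow_underdetermined = FALSE,
                     ridge = 0) {
  n_min <- min(purrr::map_int(trials, nrow))
  cap <- (n_min - 3L) %/% 2L
  if (!allow_underdetermined && n_emg > cap) {
    warning(sprintf(
      "n_emg = %d would make the encoding underdetermined; capped at %d",
      n_emg, cap))
    n_emg <- cap
  }
  if (!allow_underdetermined && n_q > cap) {
    warning(sprintf(
      "n_q = %d would make the encoding underdetermined; capped at %d",
      n_q, cap))
    n_q <- cap
  }
  per <- purrr::map(trials, function(tr) {
    T_k <- max(tr$t) - min(tr$t)
    i_bi <- fe_fit(tr$e_bi, tr$t, n_emg, T_k, ridge = ridge)$coef
    i_tri <- fe_fit(tr$e_tri, tr$t, n_emg, T_k, ridge = ridge)$coef
    o <- fe_fit(tr$q, tr$t, n_q, T_k)$coef
    list(x = c(i_bi, i_tri), o = o, T_k = T_k,
         Phi0 = fe_design_matrix(tr$t, n_q, T_k, 0),
         Phi1 = fe_design_matrix(tr$t, n_q, T_k, 1),
         Phi2 = fe_design_matrix(tr$t, n_q, T_k, 2),
         a_bi = tr$a_bi, a_tri = tr$a_tri)
  })
  list(X = do.call(rbind, purrr::map(per, "x")),
       O = do.call(rbind, purrr::map(per, "o")),
       per = per, n_emg = n_emg, n_q = n_q)
}

# composite loss and gradients for the feature-encoded surrogate; data and
# residual terms are unnormalized sums over trials
.fe_objective <- function(params, data, model, beta, gamma0,
                          want_grad = TRUE) {
  net <- list(W = params$W, b = params$b)
  fw <- mlp_forward(net, data$X, keep_cache = want_grad)
  Ohat <- fw$out
  Jdata <- sum((Ohat - data$O)^2)
  gamma <- params$gamma_bar * gamma0
  Jres <- 0
  Gres <- if (want_grad) matrix(0, nrow(Ohat), ncol(Ohat)) else NULL
  ggamma <- numeric(4)
  for (k in seq_along(data$per)) {
    pk <- data$per[[k]]
    o <- Ohat[k, ]
    qh <- as.numeric(pk$Phi0 %*% o)
    qh1 <- as.numeric(pk$Phi1 %*% o)
    qh2 <- as.numeric(pk$Phi2 %*% o)
    rg <- eom_residual_grad(model, qh, qh1, qh2, pk$a_bi, pk$a_tri, gamma)
    Jres <- Jres + sum(rg$r^2)
    if (want_grad) {
      Gres[k, ] <- 2 * as.numeric(
        crossprod(pk$Phi0, rg$r * rg$dq) +
          crossprod(pk$Phi1, rg$r * rg$dqdot) +
          crossprod(pk$Phi2, rg$r * rg$dqddot))
      ggamma <- ggamma + 2 * as.numeric(crossprod(rg$dgamma, rg$r))
    }
  }
  out <- list(J = Jdata + beta * Jres, Jdata = Jdata, Jres = Jres)
  if (want_grad) {
    G <- 2 * (Ohat - data$O) + beta * Gres
    g <- mlp_backward(net, fw$cache, G)
    out$grads <- list(W = g$W, b = g$b, gamma_bar = beta * ggamma * gamma0)
  }
  out
}

#' Composite feature-encoded PINN loss
#'
#' Evaluates the feature-encoded loss: the data term is the (unnormalized)
#' sum of squared differences between predicted and target motion
#' coefficients, and the residual term evaluates the equation-of-motion
#' residual on the motion reconstructed from the predicted coefficients (with
#' exact analytic derivatives) at each trial's time samples.
#'
#' @inheritParams loss_td
#' @param n_emg,n_q Number of Fourier pairs for the sEMG and motion
#'   encodings.
#' @param allow_underdetermined Allow more coefficients than samples
#'   (minimum-norm fit) without capping.
#' @return A list with `J`, `Jdata`, `Jres`.
#' @export
loss_fe <- function(net, gamma_bar, dataset, beta, n_emg, n_q, gamma0,
                    model = dataset$model, allow_underdetermined = FALSE) {
  data <- .fe_data(dataset$trials[dataset$train], n_emg, n_q,
                   allow_underdetermined)
  res <- .fe_objective(list(W = net$W, b = net$b, gamma_bar = gamma_bar),
                       data, model, beta, gamma0, want_grad = FALSE)
  res[c("J", "Jdata", "Jres")]
}

# ---- shared Adam training loop with best-state tracking ----
.train_loop <- function(params, objective, ident) {
  state <- adam_init(params)
  epochs <- ident$epochs
  hist <- matrix(NA_real_, epochs, 3,
                 dimnames = list(NULL, c("J", "Jdata", "Jres")))
  gpath <- matrix(NA_real_, epochs, 4, dimnames = list(NULL, .gamma_names))
  decay <- (ident$lr_end / ident$lr)^(1 / max(1, epochs - 1))
  best <- list(J = Inf, params = params, epoch = 0L)
  last <- 0L
  bw <- ident$beta_warmup
  for (ep in seq_len(epochs)) {
    beta_ep <- ident$beta * (if (bw > 0) min(1, ep / bw)^2 else 1)
    obj <- objective(params, beta_ep, want_grad = TRUE)
    if (!is.finite(obj$J))
      stop("training diverged (non-finite loss) at epoch ", ep, call. = FALSE)
    # track the loss at the full residual weight so warmup epochs (with their
    # discounted physics term) cannot claim the best state
    J_full <- obj$Jdata + ident$beta * obj$Jres
    hist[ep, ] <- c(J_full, obj$Jdata, obj$Jres)
    gpath[ep, ] <- params$gamma_bar
    if (J_full < best$J && ep >= bw && ep >= ident$gamma_warmup) {
      best <- list(J = J_full, params = params, epoch = ep)
    }
    if (ident$log_every > 0 && ep %% ident$log_every == 0) {
      message(sprintf("epoch %6d  J=%.3e  Jdata=%.3e  Jres=%.3e  gamma_bar=%s",
                      ep, obj$J, obj$Jdata, obj$Jres,
                      paste(sprintf("%.4f", params$gamma_bar),
                            collapse = " ")))
    }
    if (best$epoch > 0 && ep - best$epoch >= ident$patience) {
      last <- ep
      break
    }
    if (ep <= ident$gamma_warmup) obj$grads$gamma_bar[] <- 0
    st <- adam_step(params, obj$grads, state, lr = ident$lr * decay^(ep - 1))
    params <- st$params
    state <- st$state
    last <- ep
  }
  if (best$epoch == 0L) {
    # run shorter than the warmups: report the final state
    best <- list(J = hist[last, 1], params = params, epoch = last)
  }
  list(params = best$params, best_epoch = best$epoch, epochs_run = last,
       history = tibble::as_tibble(hist[seq_len(last), , drop = FALSE]) |>
         dplyr::mutate(epoch = dplyr::row_number(), .before = 1),
       gamma_path = tibble::as_tibble(gpath[seq_len(last), , drop = FALSE]) |>
         dplyr::mutate(epoch = dplyr::row_number(), .before = 1))
}

#' Train the time-domain physics-informed surrogate
#'
#' Fits a tanh network with a fixed random Fourier-feature embedding that maps
#' `(t, e_bi, e_tri)` to the elbow angle, while co-training the normalized
#' muscle parameters, by full-batch Adam on the composite loss
#' `Jdata + beta * Jres`. The first and second time derivatives of the
#' predicted angle needed by the residual are propagated analytically through
#' the network.
#'
#' @param dataset An `msk_dataset`; its training split is used.
#' @param net A [net_spec()] (default: three hidden layers of 32).
#' @param ff An [ff_spec()] for the Fourier embedding.
#' @param ident An [ident_spec()].
#' @param model Elbow model (geometry, curves, and — for recovery studies —
#'   the true parameters); defaults to the dataset's generating model.
#' @param derivatives How the predicted angle is differentiated for the
#'   residual: `"path"` (default) takes total time derivatives along the
#'   measured input path `(t, e_bi(t), e_tri(t))` — the derivative of the
#'   predicted motion, with signal derivatives from central differences —
#'   so a converged kinematic fit pins the predicted velocity and
#'   acceleration; `"time"` differentiates with respect to the time input
#'   only (the sEMG inputs held fixed), which leaves the derivative field
#'   unconstrained by the data term.
#' @return A `pinn_fit` object. Key fields: `gamma` (identified physical
#'   parameters), `gamma_bar`, `gamma0`, `history` (loss components per
#'   epoch), `gamma_path` (normalized parameter trajectory), `net`, `ff`.
#'   Use [generics::tidy()], [generics::glance()], [predict.pinn_fit()],
#'   [ggplot2::autoplot()].
#' @export
train_pinn_td <- function(dataset, net = net_spec(), ff = ff_spec(),
                          ident = ident_spec(), model = dataset$model,
                          derivatives = c("path", "time")) {
  derivatives <- match.arg(derivatives)
  trials <- dataset$trials[dataset$train]
  stopifnot(length(trials) >= 1)
  dt <- diff(trials[[1]]$t[1:2])
  ident <- .resolve_ident(ident, model, dt)
  data <- .td_data(trials, ff, derivatives)
  net0 <- mlp_init(c(ff$m, net$hidden, 1L), seed = net$seed)
  params <- list(W = net0$W, b = net0$b, gamma_bar = rep(1, 4))
  objective <- function(p, beta, want_grad = TRUE)
    .td_objective(p, data, model, beta, ident$gamma0, want_grad)
  run <- .train_loop(params, objective, ident)
  .new_pinn_fit(type = "td", run = run, ident = ident, model = model,
                dataset = dataset, ff = ff,
                extra = list(hidden = net$hidden, derivatives = derivatives))
}

#' Train the feature-encoded physics-informed surrogate
#'
#' Encodes each trial's sEMG and motion signals on a Fourier + quadratic
#' polynomial basis by least squares, then trains a tanh network that maps the
#' input (sEMG) coefficients of a trial to its motion coefficients, while
#' co-training the normalized muscle parameters. The physics residual is
#' evaluated on the motion reconstructed from the predicted coefficients,
#' whose time derivatives are exact.
#'
#' @inheritParams train_pinn_td
#' @param net A [net_spec()] (default: two hidden layers of 32).
#' @param n_emg,n_q Number of Fourier pairs used to encode the sEMG and the
#'   motion signals.
#' @param allow_underdetermined Allow encodings with more coefficients than
#'   samples (solved by minimum-norm least squares) instead of capping.
#' @param ridge Ridge weight used when encoding the sEMG signals (passed to
#'   [fe_fit()]); nonzero values damp the noise-dominated harmonics of noisy
#'   excitations.
#' @return A `pinn_fit` object (see [train_pinn_td()]).
#' @export
train_pinn_fe <- function(dataset, net = net_spec(hidden = c(32, 32)),
                          ident = ident_spec(), n_emg = 10, n_q = 16,
                          model = dataset$model,
                          allow_underdetermined = FALSE, ridge = 0) {
  trials <- dataset$trials[dataset$train]
  stopifnot(length(trials) >= 1)
  dt <- diff(trials[[1]]$t[1:2])
  ident <- .resolve_ident(ident, model, dt)
  data <- .fe_data(trials, n_emg, n_q, allow_underdetermined, ridge)
  d_in <- ncol(data$X)
  d_out <- ncol(data$O)
  net0 <- mlp_init(c(d_in, net$hidden, d_out), seed = net$seed)
  params <- list(W = net0$W, b = net0$b, gamma_bar = rep(1, 4))
  objective <- function(p, beta, want_grad = TRUE)
    .fe_objective(p, data, model, beta, ident$gamma0, want_grad)
  run <- .train_loop(params, objective, ident)
  .new_pinn_fit(type = "fe", run = run, ident = ident, model = model,
                dataset = dataset, ff = NULL,
                extra = list(hidden = net$hidden, n_emg = data$n_emg,
                             n_q = data$n_q, ridge = ridge))
}

.new_pinn_fit <- function(type, run, ident, model, dataset, ff, extra) {
  gamma_bar <- run$params$gamma_bar
  fit <- c(list(type = type,
                net = list(W = run$params$W, b = run$params$b),
                ff = ff,
                gamma_bar = gamma_bar,
                gamma0 = ident$gamma0,
                gamma = denormalize_params(gamma_bar, ident$gamma0),
                gamma_true = if (!is.null(model)) .gamma_true(model),
                beta = ident$beta,
                history = run$history,
                gamma_path = run$gamma_path,
                best_epoch = run$best_epoch,
                epochs_run = run$epochs_run,
                model = model,
                train = dataset$train, test = dataset$test),
           extra)
  class(fit) <- "pinn_fit"
  fit
}

#' @export
print.pinn_fit <- function(x, ...) {
  cat(sprintf("<pinn_fit> %s surrogate, %d epochs (best %d)\n",
              if (x$type == "td") "time-domain" else "feature-encoded",
              x$epochs_run, x$best_epoch))
  cat(sprintf("  final J=%.3e (Jdata=%.3e, Jres=%.3e), beta=%.1e\n",
              x$history$J[x$best_epoch], x$history$Jdata[x$best_epoch],
              x$history$Jres[x$best_epoch], x$beta))
  g <- rbind(identified = x$gamma, initial = x$gamma0)
  colnames(g) <- .gamma_names
  print(round(g, 4))
  invisible(x)
}

#' Predict joint kinematics from a fitted surrogate
#'
#' @param object A `pinn_fit`.
#' @param newdata A trial tibble with columns `t`, `e_bi`, `e_tri` (a row
#'   subset is fine for the time-domain surrogate; the feature-encoded
#'   surrogate encodes the whole signal).
#' @param ... Unused.
#' @return A tibble with `t`, `q_hat`, `qdot_hat`, `qddot_hat`.
#' @export
predict.pinn_fit <- function(object, newdata, ...) {
  tt <- newdata$t
  T_k <- max(tt) - min(tt)
  if (object$type == "td") {
    ff <- object$ff
    dt <- tt[2] - tt[1]
    X <- cbind(tt / T_k, newdata$e_bi, newdata$e_tri)
    U <- sweep(X %*% t(ff$W), 2, ff$b, `+`)
    if (identical(object$derivatives, "time")) {
      D1 <- matrix(ff$W[, 1] / T_k, nrow(X), ff$m, byrow = TRUE)
      Z1 <- cos(U) * D1
      Z2 <- -sin(U) * D1^2
    } else {
      X1 <- cbind(1 / T_k, .fdiff(newdata$e_bi, dt), .fdiff(newdata$e_tri, dt))
      X2 <- cbind(0, .fdiff(.fdiff(newdata$e_bi, dt), dt),
                  .fdiff(.fdiff(newdata$e_tri, dt), dt))
      D1 <- X1 %*% t(ff$W)
      Z1 <- cos(U) * D1
      Z2 <- -sin(U) * D1^2 + cos(U) * (X2 %*% t(ff$W))
    }
    fw <- mlp_forward3(object$net, sin(U), Z1, Z2)
    tibble::tibble(t = tt, q_hat = fw$out[, 1], qdot_hat = fw$out1[, 1],
                   qddot_hat = fw$out2[, 1])
  } else {
    rg <- if (is.null(object$ridge)) 0 else object$ridge
    i_bi <- fe_fit(newdata$e_bi, tt, object$n_emg, T_k, ridge = rg)$coef
    i_tri <- fe_fit(newdata$e_tri, tt, object$n_emg, T_k, ridge = rg)$coef
    o <- mlp_forward(object$net, matrix(c(i_bi, i_tri), 1))$out[1, ]
    tibble::tibble(
      t = tt,
      q_hat = fe_reconstruct(o, tt, 0, object$n_q, T_k),
      qdot_hat = fe_reconstruct(o, tt, 1, object$n_q, T_k),
      qddot_hat = fe_reconstruct(o, tt, 2, object$n_q, T_k))
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the identified parameters of a fit
#'
#' @param x A `pinn_fit`.
#' @param ... Unused.
#' @return One row per identified parameter: `parameter`, `estimate`,
#'   `initial`, `normalized`, and — when the generating model is known —
#'   `truth` and `rel_error_pct`.
#' @method tidy pinn_fit
#' @export
tidy.pinn_fit <- function(x, ...) {
  out <- tibble::tibble(parameter = .gamma_names,
                        estimate = x$gamma,
                        initial = x$gamma0,
                        normalized = x$gamma_bar)
  if (!is.null(x$gamma_true)) {
    out$truth <- x$gamma_true
    out$rel_error_pct <- 100 * abs(out$estimate - out$truth) / out$truth
  }
  out
}

#' One-row summary of a fit
#'
#' @param x A `pinn_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the loss components at the best epoch, the
#'   epochs run, and the maximum parameter recovery error (when truth is
#'   known).
#' @method glance pinn_fit
#' @export
glance.pinn_fit <- function(x, ...) {
  b <- x$best_epoch
  out <- tibble::tibble(type = x$type,
                        J = x$history$J[b],
                        Jdata = x$history$Jdata[b],
                        Jres = x$history$Jres[b],
                        beta = x$beta,
                        epochs_run = x$epochs_run,
                        best_epoch = b)
  if (!is.null(x$gamma_true))
    out$max_rel_error_pct <-
      max(100 * abs(x$gamma - x$gamma_true) / x$gamma_true)
  out
}
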