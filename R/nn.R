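# Internal multilayer-perceptron machinery.
#
# The package trains small tanh networks whose loss involves first and second
# derivatives of the scalar output with respect to the time input. No
# autodiff framework is used: derivatives are propagated forward analytically
# (value / first / second directional derivative along the time direction)
# and parameter gradients are obtained by reverse-mode accumulation through
# that extended computation. Correctness is pinned against central finite
# differences in the tests.
#
# Conventions: samples are rows; weight matrices are stored input x output so
# a layer computes P = A %*% W + b.

mlp_init <- function(sizes, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    L <- length(sizes) - 1
    W <- vector("list", L)
    b <- vector("list", L)
    for (k in seq_len(L)) {
      sd <- sqrt(2 / (sizes[k] + sizes[k + 1]))   # Glorot-style for tanh
      W[[k]] <- matrix(stats::rnorm(sizes[k] * sizes[k + 1], sd = sd),
                       sizes[k], sizes[k + 1])
      b[[k]] <- rep(0, sizes[k + 1])
    }
    list(W = W, b = b, sizes = sizes)
  })
}

.addb <- function(P, b) sweep(P, 2, b, `+`)

# plain forward pass; linear output layer
mlp_forward <- function(net, X, keep_cache = FALSE) {
  L <- length(net$W)
  A <- X
  cache <- if (keep_cache) vector("list", L) else NULL
  for (k in seq_len(L - 1)) {
    P <- .addb(A %*% net$W[[k]], net$b[[k]])
    H <- tanh(P)
    if (keep_cache) cache[[k]] <- list(A = A, H = H)
    A <- H
  }
  out <- .addb(A %*% net$W[[L]], net$b[[L]])
  if (keep_cache) cache[[L]] <- list(A = A)
  list(out = out, cache = cache)
}

# reverse pass for the plain forward; G = dJ/dout (same shape as out)
mlp_backward <- function(net, cache, G) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  Pb <- G
  for (k in rev(seq_len(L))) {
    A <- cache[[k]]$A
    gW[[k]] <- crossprod(A, Pb)
    gb[[k]] <- colSums(Pb)
    if (k > 1) {
      Hb <- Pb %*% t(net$W[[k]])
      H <- cache[[k - 1]]$H
      Pb <- Hb * (1 - H^2)
    }
  }
  list(W = gW, b = gb)
}

# forward pass carrying (value, d/dt, d2/dt2) triples. X1, X2 are the first
# and second time derivatives of the input rows (for Fourier-feature inputs
# these are precomputed once since the embedding is fixed). This is the
# reference implementation; the training loop uses the compiled kernels
# (.mlp_out3_cpp / .mlp_grad3_cpp), which the tests cross-check against it.
mlp_forward3 <- function(net, X, X1, X2) {
  L <- length(net$W)
  A <- X; A1 <- X1; A2 <- X2
  cache <- vector("list", L)
  for (k in seq_len(L - 1)) {
    W <- net$W[[k]]
    P <- .addb(A %*% W, net$b[[k]])
    P1 <- A1 %*% W
    P2 <- A2 %*% W
    H <- tanh(P)
    S <- 1 - H^2
    H1 <- S * P1
    H2 <- S * P2 - 2 * H * H1 * P1
    cache[[k]] <- list(A = A, A1 = A1, A2 = A2,
                       P1 = P1, P2 = P2, H = H, S = S)
    A <- H; A1 <- H1; A2 <- H2
  }
  W <- net$W[[L]]
  cache[[L]] <- list(A = A, A1 = A1, A2 = A2)
  list(out = .addb(A %*% W, net$b[[L]]),
       out1 = A1 %*% W,
       out2 = A2 %*% W,
       cache = cache)
}

# reverse pass through the triple-propagation graph; G0, G1, G2 are the loss
# adjoints of (out, out1, out2)
mlp_backward3 <- function(net, cache, G0, G1, G2) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  Pb <- G0; P1b <- G1; P2b <- G2
  for (k in rev(seq_len(L))) {
    cc <- cache[[k]]
    gW[[k]] <- crossprod(cc$A, Pb) + crossprod(cc$A1, P1b) +
      crossprod(cc$A2, P2b)
    gb[[k]] <- colSums(Pb)
    if (k > 1) {
      Wt <- t(net$W[[k]])
      Hb <- Pb %*% Wt
      H1b <- P1b %*% Wt
      H2b <- P2b %*% Wt
      pc <- cache[[k - 1]]
      H <- pc$H; S <- pc$S; P1 <- pc$P1; P2 <- pc$P2
      # adjoints of h = tanh(p), h1 = s*p1, h2 = s*p2 - 2*h*s*p1^2, s = 1-h^2
      Pb <- Hb * S +
        H1b * (-2 * H * S * P1) +
        H2b * (-2 * H * S * P2 - 2 * S * (S - 2 * H^2) * P1^2)
      P1b <- H1b * S + H2b * (-4 * H * S * P1)
      P2b <- H2b * S
    }
  }
  list(W = gW, b = gb)
}

# ---- Adam optimizer over a list-of-arrays parameter structure ----

adam_init <- function(params) {
  zero <- function(p) {
    if (is.list(p)) lapply(p, zero) else p * 0
  }
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- purrr::pmap(list(p, g, m, v), walk)
      list(p = purrr::map(out, "p"), m = purrr::map(out, "m"),
           v = purrr::map(out, "v"))
    } else {
      upd(p, g, m, v)
    }
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}
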