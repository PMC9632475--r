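# Shared fixtures, generated once per test run and memoized.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, make(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# the standard verification model (all defaults)
verification_model <- function() fixture("model", elbow_model)

# five-trial clean verification dataset (500 samples/trial); slow-ish (ODE
# solves), so shared across test files
clean_dataset <- function() {
  fixture("clean_ds", function() generate_dataset(verification_model()))
}

# problem sizes for the acceptance-level training runs
td_epochs <- function() 12000L
fe_epochs <- function() 12000L

# repeatability dataset with noisy excitations for the robustness comparison
noisy_dataset <- function() {
  fixture("noisy_ds", function() {
    generate_dataset(verification_model(), robustness_trial_configs())
  })
}

# small, fast dataset for unit tests: two short trials, both in training
small_dataset <- function() {
  fixture("small_ds", function() {
    cfgs <- default_trial_configs(freqs = c(0.4, 0.6), n = 80, duration = 2,
                                  settle = 0.5)
    suppressWarnings(generate_dataset(verification_model(), cfgs,
                                      test = integer(0)))
  })
}

# classic fixed-step RK4, independent of deSolve, used as the integration
# oracle
rk4_integrate <- function(rhs, y0, times) {
  n <- length(times)
  out <- matrix(NA_real_, n, length(y0))
  out[1, ] <- y0
  y <- y0
  for (i in seq_len(n - 1)) {
    h <- times[i + 1] - times[i]
    t <- times[i]
    k1 <- rhs(t, y)
    k2 <- rhs(t + h / 2, y + h / 2 * k1)
    k3 <- rhs(t + h / 2, y + h / 2 * k2)
    k4 <- rhs(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1, ] <- y
  }
  out
}

# central finite-difference gradient of f at x
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h
    xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}
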