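# mskpinn

Physics-informed neural networks for EMG-driven musculoskeletal modelling:
simultaneous motion prediction and muscle-parameter identification for
single-joint (elbow flexion-extension) systems, in R.

## The problem

Given surface EMG (sEMG) signals from an antagonist muscle pair (biceps,
triceps) and the measured elbow angle, we want two things at once:

1. a **forward-dynamics surrogate** — a network that predicts the joint
   angle `q(t)` from the sEMG signals, and
2. **subject-specific muscle parameters** — the maximum isometric forces
   `f0M` and maximum contraction velocities `vmaxM` of both muscles, which
   cannot be measured in vivo.

The package trains a neural network on trials of (sEMG, angle) data while
penalizing the residual of the musculoskeletal equation of motion

```
I q̈ = E(q) + T_MT(a_bi, a_tri, q, q̇; Γ),    E(q) = -m g l sin q
```

where the muscle torques come from rigid-tendon Hill-type models and
`Γ = (f0M_bi, vmaxM_bi, f0M_tri, vmaxM_tri)` is co-trained with the network
weights through the composite loss `J = J_data + β J_res`. Two trainers are
provided:

* `train_pinn_td()` — **time-domain**: a tanh network with a random
  Fourier-feature embedding maps `(t, e_bi, e_tri) → q̂`; the residual uses
  the network's first and second time derivatives, propagated analytically.
* `train_pinn_fe()` — **feature-encoded**: signals are first projected onto
  a Fourier + quadratic polynomial basis by least squares; a small network
  maps sEMG coefficients to motion coefficients, whose time derivatives are
  exact. This variant is the robust choice for noisy signals.

Everything needed to verify the machinery without recorded data is
included: the forward-dynamics simulator (`elbow_model()`,
`forward_solve()`), a seeded synthetic-trial generator
(`generate_dataset()`), the raw-sEMG processing chain (`process_semg()`:
median centering, Hampel filter, rectification, 3 Hz Butterworth envelope,
MVC normalization), and evaluation utilities (`mse()`, `r_squared()`,
`param_recovery()`, `evaluate_fit()`).

## Worked example

Generate the five-trial synthetic verification study (elbow model with
`f0M = 300` N for both muscles, `vmax = 6` and `4` m/s, trials of 500
samples starting at `q(0) = π/6`), train the time-domain surrogate on
trials 1, 2, 4, 5, and inspect the identified parameters:

```r
library(mskpinn)

model   <- elbow_model()                      # verification parameters
dataset <- generate_dataset(model)            # 5 trials, test = trial 3

fit <- train_pinn_td(
  dataset,
  net   = net_spec(hidden = c(32, 32, 32), seed = 1),
  ff    = ff_spec(m = 64, seed = 11),
  ident = ident_spec(epochs = 20000, patience = 20000, lr_end = 2e-5,
                     gamma_warmup = 3000, beta_warmup = 3000))

tidy(fit)
#> # A tibble: 4 × 6
#>   parameter estimate initial normalized truth rel_error_pct
#>   <chr>        <dbl>   <dbl>      <dbl> <dbl>         <dbl>
#> 1 f0M_bi      300.     360        0.832   300         0.113
#> 2 vmaxM_bi      5.99     4.8      1.25      6         0.204
#> 3 f0M_tri     299.     240        1.25    300         0.177
#> 4 vmaxM_tri     4.01     4.8      0.835     4         0.217
```

All four muscle parameters are recovered from the motion data to within
0.25% of their true values, starting from a 20% off-truth initialization.
`glance(fit)` gives the one-row training summary — here the angle fit
reaches `Jdata = 6.3e-9` (sub-milliradian RMS) with a mean squared
equation-of-motion residual of `6.5e-3` (N m)^2 at the identified
parameters. Further accessors:

```r
evaluate_fit(fit, dataset)      # per-trial MSE / R² of the motion predictions
autoplot(fit)                   # parameter trajectories over epochs
autoplot(fit, type = "loss")    # loss components
plot_prediction(fit, dataset$trials[[3]])   # held-out trial overlay
```

The feature-encoded variant runs the same way (use `ridge` for noisy
signals):

```r
fe <- train_pinn_fe(dataset, n_emg = 16, n_q = 40,
                    ident = ident_spec(epochs = 12000, patience = 12000,
                                       lr_end = 5e-5, gamma_warmup = 3000,
                                       beta_warmup = 3000))
```

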