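---
title: "Physics-informed identification of muscle parameters from sEMG and motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-informed identification of muscle parameters from sEMG and motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(mskpinn)
```

## The problem

Surface electromyography (sEMG) measures the electrical drive to a muscle;
joint motion is the mechanical outcome. Connecting the two runs through a
cascade of models — EMG-to-activation dynamics, Hill-type muscle-tendon
contraction dynamics, and rigid-body joint dynamics — whose key parameters
(above all the maximum isometric force $f_0^M$ and the maximum contraction
velocity $v_{max}^M$ of each muscle) are subject-specific and essentially
unmeasurable in vivo.

`mskpinn` trains a neural-network surrogate that maps sEMG signals and time
to the elbow flexion angle while *simultaneously* identifying those muscle
parameters, by adding the residual of the equation of motion to the training
loss. The package covers the full verification loop on synthetic data: a
forward-dynamics simulator, a seeded trial generator, an sEMG processing
chain for raw signals, two physics-informed trainers, and evaluation
utilities.

## Forward model

The elbow is a single hinge. A fixed upper arm and a forearm of length
$l_{fa}$ with a point mass $m_{fa}$ at the wrist give the moment of inertia
$I = m_{fa} l_{fa}^2$. With flexion angle $q$ ($q = 0$: forearm hanging
vertically), the equation of motion is

$$ I\ddot q = E(q) + T^{MT}(a_{bi}, a_{tri}, q, \dot q), \qquad
   E(q) = -m_{fa}\,g\,l_{fa}\sin q, $$

where the net muscle torque is the difference of the flexor (biceps) and
extensor (triceps) contributions, each a Hill-type muscle-tendon force times
its moment arm:

$$ T^{MT} = F^{MT}_{bi}\,r_{bi}(q) - F^{MT}_{tri}\,r_{tri}(q), \qquad
   r(q) = \frac{l_1 l_2 \sin q}{l^{MT}(q)}. $$

Muscles follow straight-line paths between attachments at distances $l_1$
(upper arm) and $l_2$ (forearm) from the joint, so the law of cosines gives
$l^{MT}_{bi} = \sqrt{l_1^2 + l_2^2 + 2 l_1 l_2 \cos q}$ (shortening with
flexion) and the triceps form with $-\cos q$ (lengthening). The moment arm
above is exactly $|d l^{MT}/dq|$, which the tests verify by finite
differences.

Each muscle produces force through a rigid-tendon Hill model,
$F^{MT} = F^M \cos\phi$ and

$$ F^M = f_0^M\left(a\, f_{AL}(\tilde l)\, f_V(\tilde v) +
  f_P(\tilde l)\right), $$

with normalized fiber length $\tilde l = l^M / l_0^M$, normalized velocity
$\tilde v = v^M / v_{max}^M$ (negative = shortening), and rigid-tendon
kinematics $l^M = (l^{MT}(q) - l_s^T)/\cos\phi$. The dimensionless curves are
a standard generic family: a Gaussian active force-length curve
($\gamma = 0.45$), the classic hyperbolic force-velocity relation for
shortening ($k = 0.25$, so $f_V(-1) = 0$, $f_V(0) = 1$) joined with matched
slope to a saturating lengthening branch (plateau 1.4), and an exponential
passive curve scaled so $f_P(1.5) = 1$, zero at and below optimal length.
Different curve families can be injected through `hill_curves()`; the
framework only relies on the contract $f_{AL}(1) = 1$, $f_V(0) = 1$,
$f_V(-1) = 0$, $f_P$ non-decreasing and zero below the optimal length. The
curves carry analytic derivatives because the trainers differentiate the
residual.

Activation comes from the excitation (processed sEMG) through a pure
electromechanical delay $u(t) = e(t - d)$ and the algebraic nonlinearity
$a = (e^{Au} - 1)/(e^{A} - 1)$, with $d = 0.08$ s and shape factor $A = 0.2$
by default.

`forward_solve()` integrates the ODE with `deSolve` (lsoda, rtol $10^{-8}$,
atol $10^{-10}$, activations linearly interpolated between samples), so
synthetic trajectories are effectively noise-free; the tests check the
solver against an independent fixed-step RK4 pendulum integration and a
self-convergence criterion.

## The verification study and the synthetic generator

The default configuration reproduces the standard verification setup: both
muscles at $f_0^M = 300$ N, $v_{max}$ of 6 and 4 m/s, optimal lengths
0.6/0.4 m, slack lengths 0.55/0.33 m, zero pennation, attachments
0.3/0.8 m (biceps) and 0.2/0.7 m (triceps), a 1 kg × 1 m forearm, and
initial conditions $q(0) = \pi/6$, $\dot q(0) = 0$. Five trials of $n = 500$
samples are generated; trials 1, 2, 4, 5 train the surrogate and trial 3 is
held out.

The generator produces a constant tonic co-contraction baseline per muscle
plus windowed raised-sine bursts,
$e(t) = b + A_e\, w(t) \max(0, \sin(2\pi f t + \varphi))^2$, with burst
frequencies 0.5–1.1 Hz across the five trials
(`verification_trial_configs()`). Several generator choices deserve
explanation, because they are where this package had genuine design freedom:

* **Trial duration 5 s.** With $n = 500$ this gives $\Delta t = 0.01$ s, so
  the unit-matching residual weight $\beta = \Delta t^2 I$ equals exactly
  $10^{-4}$, the canonical value for this verification problem.
* **Tonic pairs on the equilibrium ridge through $q(0)$.** Each trial holds
  a biceps/triceps baseline pair (biceps 0.40–0.60 with the matching
  triceps level solved from the model) whose static torque balance sits
  exactly at the initial angle $\pi/6$, so every trial starts at rest *at
  equilibrium*. Strong co-contraction also damps the pendulum resonance
  (the force–velocity slope acts as a physical damper proportional to
  activation) and keeps both muscles' Hill curves engaged throughout the
  motion, which the identifiability of all four parameters depends on.
* **Flexor bursts drive the motion; the extensor stays tonic.** Gravity is
  the dominant extensor torque in the flexion range; vigorous antagonist
  burst trains pump the lightly damped pendulum through $q = 0$ into
  hyperextension, where the moment arms ($\propto \sin q$) change sign and
  the model leaves its physical domain. Flexor bursts (amplitude ~0.3)
  with a token extensor burst keep all trials inside $q \in [0.45, 1.35]$
  rad; the triceps parameters are informed by its substantial tonic
  activity moving through the force–length/velocity curves.
* **Rest-to-rest records.** The burst window opens at 0.3 s and closes
  1.5 s before the end, so the joint has settled back near equilibrium by
  the last sample, and the excitation before the trial equals the tonic
  level (`generate_trial()` hold-pads the electromechanical delay
  accordingly — a trial excised from ongoing activity, not from silence).
  Without these two choices the record's ends carry a large
  velocity/acceleration mismatch (or an outright activation step at
  $t = d$), which dominates the second-derivative error of any smooth
  representation of the motion and caps identification accuracy far above
  the 1% level; with them the Fourier-basis encoding reproduces the
  acceleration to a residual of order $10^{-4}$ (N m)$^2$.
* **Baseline separation across trials.** The surrogate maps
  $(t, e_{bi}, e_{tri})$ to $q$; if two trials passed through identical
  input triples with different angles the regression target would be
  ill-defined there. Bursts only add to the baselines, so spacing both
  baselines $\ge 0.05$ apart guarantees the trials never collide in input
  space, and the data term can be driven to the level identification
  requires.
* **Noise model.** Optional Gaussian noise on the excitation (clipped back
  to $[0,1]$) corrupts the *measured* signal while the trajectory is driven
  by the clean activation — the same asymmetry as in recorded data, where
  motion follows the true neural drive but the electrode signal is noisy.

What the generator does *not* emulate: biophysical sEMG texture
(motor-unit interference patterns, electrode artifacts), soft-tissue
artifacts in motion capture, model mismatch between the simulated plant and
the assumed dynamics. Passing the verification study therefore shows that
the identification machinery works when the model class contains the truth;
it does not by itself validate the Hill model against a human subject.

## The sEMG processing chain

For recorded (or synthetically noisy) signals, `process_semg()` implements
the standard envelope pipeline: median centering, Hampel outlier removal
(window 11 samples, 3 scaled MADs; constant windows pass through), full-wave
rectification, a second-order Butterworth low-pass at 3 Hz (zero-phase
forward-backward application by default, doubling the effective order), MVC
normalization by the per-muscle maximum across all trials, then the delay
and activation nonlinearity. Window length, threshold, order, cutoff and
phase mode are configuration (`processing_config()`), since conventions for
these steps vary between labs.

## Physics-informed training

Both trainers minimize $J = J_{data} + \beta J_{res}$ over the network
weights $\theta$ *and* the normalized parameters
$\bar\Gamma = \Gamma / \Gamma^{(0)}$, where
$\Gamma = (f_{0,bi}^M, v_{max,bi}^M, f_{0,tri}^M, v_{max,tri}^M)$ and
$\Gamma^{(0)}$ is the (off-truth) initialization. Normalization puts
hundreds of newtons and a few metres per second on a common O(1) scale.
$J_{res}$ penalizes the pointwise equation-of-motion residual

$$ r_i = I\hat{\ddot q}_i - E(\hat q_i)
   - T^{MT}\!\left(a_{bi}(t_i), a_{tri}(t_i), \hat q_i, \hat{\dot q}_i;
   \bar\Gamma \Gamma^{(0)}\right), $$

evaluated with the *predicted* kinematics and the measured activations.

**Time-domain trainer** (`train_pinn_td()`). A tanh network with a fixed
random Fourier-feature embedding $\sin(W_F x + b_F)$ maps
$x = (t/T, e_{bi}, e_{tri})$ to $\hat q$. The first and second time
derivatives needed by the residual are propagated analytically through the
network (forward-mode differentiation), and gradients with respect to all
weights and $\bar\Gamma$ are computed by reverse-mode accumulation through
that extended graph — the package implements this differentiation by hand
and pins it against central finite differences in the tests. The embedding
is fixed, so features and their time derivatives are precomputed once; the
per-epoch work is a handful of matrix products, executed by compiled
RcppArmadillo kernels that are cross-checked against a pure-R reference
implementation.

Two derivative conventions are implemented (`derivatives` argument). The
default `"path"` convention reads $\hat{\dot q}$ as the derivative of the
*predicted motion*: the total time derivative of
$N(t, e_{bi}(t), e_{tri}(t))$ along the measured input path, with the
signal derivatives obtained by central differences on the sample grid. Its
virtue is that once the network matches the measured angle on a dense grid,
its first and second path derivatives are pinned to the true velocity and
acceleration (a band-limited function interpolating dense samples has no
room to wiggle), so the residual converges to pure parameter mismatch. The
`"time"` convention differentiates with respect to the time input only, as
in standard collocation-style training; it leaves the derivative field
unconstrained by the data term — the network can fit the angle perfectly
while its time-partials carry a persistent structured error, which biases
the identified parameters. Both are available; the verification protocol
uses `"path"`.

Per-channel feature bandwidths matter here. The time input (normalized to
$[0,1]$) uses $\sigma_t = 4\pi$; the sEMG channels use $\sigma_e = 12$,
balancing two constraints: large enough that features separate trials
whose excitation levels differ by a few hundredths (their numerical range
is a few tenths, so unit bandwidth leaves the features nearly blind to the
sEMG inputs and training stalls — the spectral-bias failure mode expressed
per channel), yet small enough that the features stay band-limited along
the input path, without which the path-derivative pinning argument fails
between samples.

**Feature-encoded trainer** (`train_pinn_fe()`). Each trial's sEMG and
motion signals are first projected by least squares onto a Fourier +
quadratic-polynomial basis, $2n + 3$ coefficients per signal with the
layout fixed by `fe_design_matrix()` (cosines, sines, $1, t, t^2$). A small
tanh network then maps input coefficients (biceps block then triceps block)
to motion coefficients; the residual is evaluated on the motion
reconstructed from the predicted coefficients, whose time derivatives are
exact. The data term is the unnormalized sum of squared coefficient errors
over trials; the residual term sums the squared residual over each trial's
samples. Encodings with more coefficients than samples are solved by
minimum-norm least squares (SVD pseudoinverse) and are available behind
`allow_underdetermined`; by default the harmonic count is capped at
$(n-3)/2$ with a warning so fits stay unique.

For noisy excitations the `ridge` argument regularizes the sEMG encodings.
This is not cosmetic: the trainer sees one coefficient vector per trial, so
its input-output map is wildly underdetermined off the training points, and
noise pushes a test trial's coefficients exactly into those uncontrolled
directions — prediction error can explode. Ridge shrinks the
noise-dominated harmonics (the normal-equation diagonal is about $n/2$, so
the meaningful ridge scale is of that order, e.g. 500 for $n = 500$),
collapsing the noise-induced spread of the inputs; the robustness study
below runs with `ridge = 500`.

**The noise-robustness comparison.** The verification family is
deliberately diverse across trials (tonic level, frequency), which is the
hard regime for trial-level generalization: with four training trials,
*neither* surrogate predicts the held-out trial's motion well even on
clean signals. Comparisons of noise robustness are therefore run on a
repeatability protocol (`robustness_trial_configs()`): five repetitions of
one nominal motion with slight frequency variation and independent
measurement noise per repetition — the same structure as recorded-data
studies where a subject repeats a movement. In that setting the
feature-encoded surrogate with ridge-filtered encodings reconstructs the
held-out repetition essentially perfectly while the time-domain surrogate,
whose features are scrambled pointwise by the noise, degrades toward
predicting the mean motion; the acceptance tests assert this ordering on
both MSE and $R^2$.

**Optimization.** Full-batch Adam with initial learning rate
$5 \times 10^{-3}$ and a geometric decay schedule; the best-loss state
(at the full residual weight) is kept, $\bar\Gamma$ starts at 1, and a
patience rule stops stalled runs. Two curricula stabilize the joint
problem: the residual weight ramps quadratically from 0 to $\beta$ over
`beta_warmup` epochs (an untrained network's second derivative is noise —
at full weight the physics term initially dwarfs the data term and traps
training in flat, physics-trivial solutions), and $\bar\Gamma$ stays
frozen for `gamma_warmup` epochs so the parameters do not chase the
residual structure of a still-poor surrogate. $\beta$ defaults to
$\Delta t^2 I = 10^{-4}$ (unit matching between the two loss terms); the
residual uses processed activations as fixed inputs, never predicted ones.
Training is deterministic given the three seeds involved (trial
generation, feature sampling, weight initialization); divergence
(non-finite loss) raises an error naming the epoch.

## Numerical choices and degenerate inputs

* Degenerate geometry ($l^{MT} \le l_s^T$) raises an error naming the
  muscle and angle rather than clamping — silent clamps hide configuration
  mistakes.
* Excitations outside $[0,1]$ are clipped before the activation
  nonlinearity; $A = 0$ (which would need the algebraic limit form) is
  rejected.
* The force-velocity curve is clamped to zero below $\tilde v = -1$
  (super-maximal shortening produces no force), and the total dimensionless
  force is floored at zero; with the default curve family the floor never
  binds.
* Ties and edges in the Hampel filter follow the conventions stated in its
  documentation: truncated windows at the edges, strict exceedance required
  for replacement (so MAD = 0 on constant windows replaces nothing).
* The identified $\Gamma$ is reported from the best-loss epoch, not the
  last one.

## Problem sizes

The shipped verification protocol uses the five-trial, 500-sample dataset
throughout. Unit tests run the trainers for tens to hundreds of epochs on
reduced trials (enough to pin determinism, loss algebra, and gradient
correctness); the acceptance-level recovery studies run the full protocol —
about 12,000 epochs per time-domain run and about the same for the
feature-encoded trainer — which completes in a few minutes per run on a
single CPU and recovers all four parameters well within 1%.

## Known limitations

* The Hill curve family and muscle-path geometry are generic standard
  forms; applications to a specific subject should inject measured or
  literature curves via `hill_curves()` and scaled geometry.
* The time-domain surrogate's parameter accuracy is limited by how well the
  network's *second* time derivative matches the true acceleration; this is
  the hard part of the problem and the reason the feature-encoded variant
  (exact derivatives of a smooth basis) is more robust on noisy signals.
* One degree of freedom, point-mass forearm, rigid tendons, algebraic
  activation dynamics: extensions (compliant tendons, multi-joint models,
  activation ODEs) are out of scope.
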