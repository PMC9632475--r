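#' Configuration for one synthetic trial
#'
#' Describes the smooth burst-like excitation pattern of one elbow
#' flexion-extension trial: a constant tonic co-contraction baseline for each
#' muscle plus a windowed raised-sine burst train
#' \eqn{e(t) = b + A_e\, w(t)\, \max(0, \sin(2\pi f t + \varphi))^2},
#' with the antagonists half a cycle out of phase by default so that flexor
#' and extensor bursts alternate. The window `w(t)` rises smoothly from zero
#' at `burst_on` and falls back to zero `settle` seconds before the end of
#' the trial, so every trial begins and ends in the tonic hold state: the
#' joint starts at rest and has settled back to (near) rest by the last
#' sample. Optional Gaussian noise (clipped back to `[0, 1]`) emulates noisy
#' raw sEMG envelopes.
#'
#' Bounded edge states are not cosmetic: both surrogate trainers
#' differentiate their motion representation twice, and a trial that ends
#' mid-swing leaves a large velocity/acceleration mismatch between the two
#' ends of the record, which dominates the error of any finite smooth
#' representation (most visibly the Fourier-basis encoding). Trials excised
#' from a tonic hold avoid that entirely.
#'
#' @param duration Trial duration (s). Default 5 s: with `n = 500` samples
#'   this gives a 0.01 s time-step.
#' @param n Number of samples per trial.
#' @param burst_freq Burst frequency (Hz).
#' @param burst_amp Peak excitation amplitude(s) in `[0, 1 - baseline]`;
#'   length 1 (both muscles) or 2 (`biceps`, `triceps`).
#' @param baseline Tonic excitation level(s); length 1 or 2 like `burst_amp`.
#' @param phase_bi,phase_tri Burst phase offsets (rad).
#' @param burst_on Time (s) at which the burst window starts to open.
#' @param ramp Rise/fall time (s) of the smoothstep burst window.
#' @param settle Quiet interval (s) at the end of the trial (bursts fully
#'   off), letting the damped joint settle back toward its tonic
#'   equilibrium.
#' @param seed Integer seed used for the optional noise.
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   excitation (0 = clean).
#' @return A `trial_config` object.
#' @export
trial_config <- function(duration = 5, n = 500, burst_freq = 0.5,
                         burst_amp = c(0.15, 0.08), baseline = c(0.25, 0.05),
                         phase_bi = 0, phase_tri = pi,
                         burst_on = 0.3, ramp = 0.3, settle = 1.5,
                         seed = 1L, noise_sd = 0) {
  burst_amp <- rep(burst_amp, length.out = 2)
  baseline <- rep(baseline, length.out = 2)
  stopifnot(duration > 0, n >= 2, burst_freq >= 0,
            all(burst_amp >= 0), all(burst_amp + baseline <= 1),
            all(baseline >= 0), burst_on >= 0, ramp >= 0, settle >= 0,
            burst_on + settle < duration, noise_sd >= 0)
  structure(list(duration = duration, n = as.integer(n),
                 burst_freq = burst_freq, burst_amp = burst_amp,
                 baseline = baseline, phase_bi = phase_bi,
                 phase_tri = phase_tri, burst_on = burst_on, ramp = ramp,
                 settle = settle, seed = as.integer(seed),
                 noise_sd = noise_sd),
            class = "trial_config")
}

#' Default verification trial configurations
#'
#' Five trials with burst frequencies varied from 0.3 to 0.7 Hz (one per
#' trial), mirroring a verification set of distinct flexion-extension motions
#' of varying speed.
#'
#' @param freqs Burst frequencies (Hz), one per trial.
#' @param ... Further arguments passed to [trial_config()] (for example `n`,
#'   `duration`, `burst_amp`).
#' @param seed Base seed; trial k uses `seed + k`.
#' @param noise_sd Excitation noise SD applied to every trial.
#' @return A list of [trial_config()] objects.
#' @export
default_trial_configs <- function(freqs = c(0.3, 0.4, 0.5, 0.6, 0.7), ...,
                                  seed = 100L, noise_sd = 0) {
  purrr::imap(freqs, function(f, k)
    trial_config(burst_freq = f, seed = seed + k, noise_sd = noise_sd, ...))
}

#' The standard five-trial verification configuration
#'
#' Five distinct flexion-extension trials: burst frequencies 0.5-1.1 Hz, and
#' per-trial tonic co-contraction pairs chosen so that each pair's static
#' torque balance sits exactly at the protocol's initial angle
#' `q(0) = pi/6` (biceps baselines 0.40-0.60 with the matching triceps
#' level solved from the default model), with staggered burst phases. The
#' flexor bursts drive the motion (upward swings, returned by gravity and
#' the tonic extensor); the triceps carries only a token burst, since its
#' identification signal comes from the substantial tonic activity moving
#' through the force-length/velocity curves during the motion.
#'
#' Three properties of this design carry the verification study:
#' \itemize{
#'   \item \strong{Separability.} The surrogate regresses `q` on
#'     `(t, e_bi, e_tri)`; if two trials passed through identical input
#'     triples with different angles the target would be ill-defined there.
#'     Because bursts only add to the baselines, spacing both baselines
#'     >= 0.05 apart guarantees that whenever one channel of two trials
#'     coincides the other differs — the trials never collide in input
#'     space.
#'   \item \strong{Identifiability.} Substantial co-contraction keeps both
#'     muscles' force-length and force-velocity terms active throughout the
#'     motion (and damps the pendulum resonance), sharpening the residual's
#'     sensitivity to all four identified parameters; sweeping the tonic
#'     level across trials varies the static/dynamic torque mix.
#'   \item \strong{Rest-to-rest records.} Each tonic pair holds the joint
#'     in equilibrium exactly at the initial angle, and the burst window
#'     closes `settle` seconds before the end, so every trial starts at rest
#'     and ends settled near rest — see [trial_config()] for why bounded
#'     edge states matter to the surrogates.
#' }
#'
#' @param freqs Burst frequencies (Hz), one per trial.
#' @param seed Base seed; trial k uses `seed + k` (relevant only when
#'   `noise_sd > 0`).
#' @param noise_sd Excitation noise SD applied to every trial.
#' @param n,duration Samples per trial and trial duration (s).
#' @return A list of [trial_config()] objects.
#' @export
verification_trial_configs <- function(freqs = c(0.5, 0.65, 0.8, 0.95, 1.1),
                                       seed = 100L, noise_sd = 0,
                                       n = 500, duration = 5) {
  # tonic pairs on the torque-balance ridge through q = pi/6 (biceps level,
  # triceps level solved from the default model)
  base_bi <- c(0.40, 0.45, 0.50, 0.55, 0.60)
  base_tri <- c(0.33435, 0.40470, 0.47476, 0.54455, 0.61405)
  purrr::imap(freqs, function(f, k)
    trial_config(duration = duration, n = n, burst_freq = f,
                 burst_amp = c(0.30 + 0.01 * k, 0.04),
                 baseline = c(base_bi[k], base_tri[k]),
                 phase_bi = 0.5 * (k - 1), phase_tri = pi + 0.5 * (k - 1),
                 seed = seed + k, noise_sd = noise_sd))
}

#' The repeatability configuration for noise-robustness studies
#'
#' Five repetitions of the same nominal flexion-extension motion (mid-level
#' tonic co-contraction, flexor bursts near 0.8 Hz with slight natural
#' frequency variation across repetitions) with independent Gaussian
#' measurement noise on each repetition's excitation signals. This mirrors
#' the protocol of recorded-data studies — a subject repeating one motion
#' while the electrode signal varies — and is the setting in which the
#' feature-encoded surrogate's noise filtering pays off against time-domain
#' training.
#'
#' @param freqs Burst frequencies (Hz), one per repetition.
#' @param seed Base seed; repetition k draws its noise from `seed + k`.
#' @param noise_sd Excitation noise standard deviation.
#' @param n,duration Samples per trial and trial duration (s).
#' @return A list of [trial_config()] objects.
#' @export
robustness_trial_configs <- function(freqs = c(0.78, 0.79, 0.8, 0.81, 0.82),
                                     seed = 200L, noise_sd = 0.15,
                                     n = 500, duration = 5) {
  purrr::imap(freqs, function(f, k)
    trial_config(duration = duration, n = n, burst_freq = f,
                 burst_amp = c(0.33, 0.04),
                 baseline = c(0.50, 0.47476),
                 phase_bi = 0, phase_tri = pi,
                 seed = seed + k, noise_sd = noise_sd))
}

#' Generate a synthetic excitation signal
#'
#' @param cfg A [trial_config()].
#' @param muscle `"biceps"` or `"triceps"` (selects the phase offset).
#' @return Numeric vector of length `cfg$n`, in `[0, 1]`.
#' @export
generate_excitation <- function(cfg, muscle = c("biceps", "triceps")) {
  muscle <- match.arg(muscle)
  tt <- seq(0, cfg$duration, length.out = cfg$n)
  im <- if (muscle == "biceps") 1L else 2L
  phase <- if (muscle == "biceps") cfg$phase_bi else cfg$phase_tri
  smoothstep <- function(x) { x <- pmin(pmax(x, 0), 1); x^2 * (3 - 2 * x) }
  up <- if (cfg$ramp > 0) smoothstep((tt - cfg$burst_on) / cfg$ramp)
        else as.numeric(tt >= cfg$burst_on)
  t_off <- cfg$duration - cfg$settle
  down <- if (cfg$ramp > 0) 1 - smoothstep((tt - (t_off - cfg$ramp)) / cfg$ramp)
          else as.numeric(tt < t_off)
  e <- cfg$baseline[im] + cfg$burst_amp[im] * up * down *
    pmax(0, sin(2 * pi * cfg$burst_freq * tt + phase))^2
  if (cfg$noise_sd > 0) {
    # muscle-specific substream so the two channels get independent noise
    seed_off <- if (muscle == "biceps") 0L else 1L
    e <- withr::with_seed(cfg$seed + seed_off,
                          e + stats::rnorm(cfg$n, sd = cfg$noise_sd))
    e <- pmin(pmax(e, 0), 1)
  }
  e
}

#' Generate one synthetic trial
#'
#' Builds the excitation signals for both muscles, applies the
#' electromechanical delay and the EMG-to-activation nonlinearity, and
#' forward-solves the elbow equation of motion from `q(0) = pi/6`,
#' `qdot(0) = 0` (the verification initial conditions).
#'
#' When the excitations are noisy, the trajectory is driven by the activations
#' derived from the *clean* excitation (noise corrupts the measured signal,
#' not the underlying drive), mirroring how recorded sEMG relates to motion.
#'
#' @param model An [elbow_model()].
#' @param cfg A [trial_config()].
#' @param q0,qdot0 Initial conditions (rad, rad/s).
#' @return A tibble with columns `t`, `e_bi`, `e_tri`, `u_bi`, `u_tri`,
#'   `a_bi`, `a_tri`, `q`, `qdot`; the generating config is attached as
#'   attribute `"config"`.
#' @export
generate_trial <- function(model, cfg, q0 = pi / 6, qdot0 = 0) {
  tt <- seq(0, cfg$duration, length.out = cfg$n)
  dt <- tt[2] - tt[1]
  cfg_clean <- cfg; cfg_clean$noise_sd <- 0
  e_bi <- generate_excitation(cfg, "biceps")
  e_tri <- generate_excitation(cfg, "triceps")
  ec_bi <- generate_excitation(cfg_clean, "biceps")
  ec_tri <- generate_excitation(cfg_clean, "triceps")
  # hold-padding: the trial is excised from ongoing tonic activity, so the
  # pre-trial excitation equals the tonic level rather than silence (a zero
  # pad would put a step into the activation at t = d)
  u_bi <- neural_excitation(ec_bi, model$biceps$d, dt, pad = "hold")
  u_tri <- neural_excitation(ec_tri, model$triceps$d, dt, pad = "hold")
  a_bi <- activation_from_excitation(u_bi, model$biceps$A)
  a_tri <- activation_from_excitation(u_tri, model$triceps$A)
  sol <- forward_solve(model,
                       tibble::tibble(t = tt, a_bi = a_bi, a_tri = a_tri),
                       q0 = q0, qdot0 = qdot0)
  out <- tibble::tibble(t = tt, e_bi = e_bi, e_tri = e_tri,
                        u_bi = u_bi, u_tri = u_tri,
                        a_bi = a_bi, a_tri = a_tri,
                        q = sol$q, qdot = sol$qdot)
  attr(out, "config") <- cfg
  class(out) <- c("msk_trial", class(out))
  out
}

#' Generate a verification dataset
#'
#' Generates one trial per configuration and splits them into training and
#' test sets. The default layout matches the verification protocol: five
#' trials of 500 samples, trials 1, 2, 4, 5 for training and trial 3 for
#' testing.
#'
#' @param model An [elbow_model()].
#' @param configs List of [trial_config()] objects (default
#'   [default_trial_configs()]).
#' @param test Integer indices of the test trials.
#' @param q0,qdot0 Initial conditions shared by all trials.
#' @return An `msk_dataset` object: list with `trials` (list of trial
#'   tibbles), `train`, `test` (index vectors), and `model`.
#' @export
generate_dataset <- function(model, configs = verification_trial_configs(),
                             test = 3L, q0 = pi / 6, qdot0 = 0) {
  n_tr <- length(configs)
  test <- as.integer(test)
  if (any(test < 0) || any(test > n_tr))
    stop("test indices out of range", call. = FALSE)
  test <- test[test > 0]
  train <- setdiff(seq_len(n_tr), test)
  if (length(train) == 0)
    stop("training split is empty", call. = FALSE)
  if (length(test) == 0)
    warning("empty test set: all trials assigned to training")
  trials <- purrr::map(configs, ~generate_trial(model, .x, q0, qdot0))
  structure(list(trials = trials, train = train, test = test, model = model),
            class = "msk_dataset")
}

#' @export
print.msk_dataset <- function(x, ...) {
  cat(sprintf("<msk_dataset> %d trials (%s train / %s test), %d samples each\n",
              length(x$trials), paste(x$train, collapse = ","),
              paste(x$test, collapse = ","), nrow(x$trials[[1]])))
  invisible(x)
}

#' Write / read a dataset bundle as delimited text
#'
#' One CSV per trial (columns `t, e_bi, e_tri, u_bi, u_tri, a_bi, a_tri, q,
#' qdot`) plus a `bundle.json` holding the split and per-trial generating
#' configs.
#'
#' @param dataset An `msk_dataset`.
#' @param dir Directory to write into (created if missing).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` returns an
#'   `msk_dataset` (without the model object, which is not serialized).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(dataset$trials)) {
    utils::write.csv(as.data.frame(dataset$trials[[k]]),
                     file.path(dir, sprintf("trial_%02d.csv", k)),
                     row.names = FALSE)
  }
  meta <- list(
    n_trials = length(dataset$trials),
    train = dataset$train, test = dataset$test,
    configs = purrr::map(dataset$trials, function(tr) {
      cfg <- attr(tr, "config")
      if (is.null(cfg)) NULL else unclass(cfg)
    }))
  writeLines(.to_json(meta), file.path(dir, "bundle.json"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  meta <- .from_json(readLines(file.path(dir, "bundle.json")))
  trials <- purrr::map(seq_len(meta$n_trials), function(k) {
    tr <- tibble::as_tibble(utils::read.csv(
      file.path(dir, sprintf("trial_%02d.csv", k))))
    cfg <- meta$configs[[k]]
    if (!is.null(cfg)) attr(tr, "config") <- do.call(trial_config, cfg)
    class(tr) <- c("msk_trial", class(tr))
    tr
  })
  structure(list(trials = trials, train = as.integer(meta$train),
                 test = as.integer(meta$test), model = NULL),
            class = "msk_dataset")
}

# minimal JSON helpers (jsonlite is only Suggested)
.to_json <- function(x) {
  enc <- function(v) {
    if (is.null(v)) return("null")
    if (is.list(v)) {
      if (!is.null(names(v)) && any(names(v) != "")) {
        paste0("{", paste0("\"", names(v), "\":",
                           vapply(v, enc, ""), collapse = ","), "}")
      } else {
        paste0("[", paste0(vapply(v, enc, ""), collapse = ","), "]")
      }
    } else if (is.character(v)) {
      paste0("[", paste0("\"", v, "\"", collapse = ","), "]")
    } else if (length(v) == 1) {
      format(v, digits = 17)
    } else {
      paste0("[", paste0(format(v, digits = 17), collapse = ","), "]")
    }
  }
  enc(x)
}

.from_json <- function(txt) {
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::fromJSON(paste(txt, collapse = ""), simplifyDataFrame = FALSE)
  } else {
    stop("reading dataset bundles requires the jsonlite package",
         call. = FALSE)
  }
}
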