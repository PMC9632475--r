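#' sEMG processing configuration
#'
#' Parameters of the raw-sEMG-to-activation chain: median centering, Hampel
#' outlier removal, full-wave rectification, Butterworth low-pass envelope
#' extraction, and maximum-voluntary-contraction (MVC) normalization.
#'
#' @param sample_rate Sampling rate of the raw signal (Hz).
#' @param hampel_window Odd rolling-window length (samples) for the Hampel
#'   filter.
#' @param hampel_nsigma Outlier threshold in scaled-MAD units.
#' @param butter_order Butterworth filter order.
#' @param butter_cutoff Low-pass cutoff frequency (Hz); must be below the
#'   Nyquist frequency.
#' @param zero_phase If `TRUE` (default) the filter is applied
#'   forward-backward ([signal::filtfilt()]), doubling the effective order but
#'   removing phase lag; otherwise a single causal pass is used.
#' @return A `processing_config` object.
#' @export
processing_config <- function(sample_rate, hampel_window = 11,
                              hampel_nsigma = 3, butter_order = 2,
                              butter_cutoff = 3, zero_phase = TRUE) {
  stopifnot(sample_rate > 0, butter_order >= 1, butter_cutoff > 0)
  if (hampel_window < 3 || hampel_window %% 2 == 0)
    stop("hampel_window must be odd and >= 3", call. = FALSE)
  if (butter_cutoff >= sample_rate / 2)
    stop("butter_cutoff must be below the Nyquist frequency", call. = FALSE)
  structure(list(sample_rate = sample_rate, hampel_window = hampel_window,
                 hampel_nsigma = hampel_nsigma, butter_order = butter_order,
                 butter_cutoff = butter_cutoff, zero_phase = zero_phase),
            class = "processing_config")
}

#' Center a signal on its median
#'
#' @param x Numeric vector.
#' @return `x - median(x)`.
#' @export
center_median <- function(x) {
  if (length(x) == 0) stop("empty signal", call. = FALSE)
  x - stats::median(x)
}

#' Hampel outlier filter
#'
#' Replaces samples that deviate from the rolling median by more than
#' `n_sigma` scaled median absolute deviations (scale factor 1.4826) with the
#' rolling median. Windows are truncated at the signal edges. With a constant
#' window the MAD is zero and the deviation is also zero, so constant segments
#' pass through unchanged (replacement requires strict exceedance).
#'
#' @param x Numeric vector.
#' @param window Odd window length in samples.
#' @param n_sigma Threshold in scaled-MAD units.
#' @return Filtered vector of the same length.
#' @export
hampel_filter <- function(x, window = 11, n_sigma = 3) {
  if (window %% 2 == 0 || window < 3)
    stop("window must be odd and >= 3", call. = FALSE)
  n <- length(x)
  half <- (window - 1) %/% 2
  out <- x
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    w <- x[lo:hi]
    med <- stats::median(w)
    sigma <- 1.4826 * stats::median(abs(w - med))
    if (abs(x[i] - med) > n_sigma * sigma && abs(x[i] - med) > 0)
      out[i] <- med
  }
  out
}

#' Full-wave rectification
#'
#' @param x Numeric vector.
#' @return `abs(x)`.
#' @export
rectify <- function(x) abs(x)

#' Butterworth low-pass envelope filter
#'
#' Applies a low-pass Butterworth filter (DC gain 1). With
#' `zero_phase = TRUE` the filter runs forward and backward
#' ([signal::filtfilt()]), squaring the magnitude response and cancelling
#' phase distortion; the signal is extended at both ends by odd reflection
#' (preserving level and slope) before filtering and trimmed afterwards, so
#' start-up transients do not leak into the output.
#'
#' @param x Numeric vector.
#' @param cfg A [processing_config()] (supplies order, cutoff, sample rate,
#'   phase mode).
#' @return Filtered vector of the same length.
#' @export
butter_lowpass <- function(x, cfg) {
  if (cfg$butter_cutoff >= cfg$sample_rate / 2)
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  bf <- signal::butter(cfg$butter_order,
                       cfg$butter_cutoff / (cfg$sample_rate / 2),
                       type = "low")
  if (cfg$zero_phase) {
    n <- length(x)
    np <- min(n - 1, ceiling(3 * cfg$sample_rate / cfg$butter_cutoff))
    xp <- c(2 * x[1] - rev(x[2:(np + 1)]), x,
            2 * x[n] - rev(x[(n - np):(n - 1)]))
    as.numeric(signal::filtfilt(bf, xp)[(np + 1):(np + n)])
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

#' Maximum-voluntary-contraction normalization
#'
#' Divides every trial's processed signal for one muscle by the maximum value
#' observed across all trials of that muscle (the MVC estimate), so the global
#' maximum of the normalized signals is exactly 1.
#'
#' @param signals A list of numeric vectors (one per trial) or a single
#'   numeric vector.
#' @return A list with `signals` (same shape, normalized) and `mvc` (the
#'   normalizing value).
#' @export
mvc_normalize <- function(signals) {
  single <- is.numeric(signals)
  if (single) signals <- list(signals)
  mvc <- max(unlist(signals))
  if (!is.finite(mvc) || mvc <= 0)
    stop("MVC undefined: signals must have a positive maximum", call. = FALSE)
  out <- purrr::map(signals, ~.x / mvc)
  list(signals = if (single) out[[1]] else out, mvc = mvc)
}

#' Raw sEMG to activation processing chain
#'
#' The full chain for one muscle across trials: median centering, Hampel
#' outlier removal, full-wave rectification, Butterworth low-pass,
#' MVC normalization (over all trials jointly), electromechanical delay, and
#' the activation nonlinearity.
#'
#' @param raw A list of numeric vectors (raw sEMG per trial) or a single
#'   vector.
#' @param cfg A [processing_config()].
#' @param params A [muscle_params()] supplying the delay `d` and shape factor
#'   `A`.
#' @return A list with `activation` (same shape as `raw`), `excitation`
#'   (normalized envelopes before the delay), and `mvc`.
#' @export
process_semg <- function(raw, cfg, params) {
  single <- is.numeric(raw)
  if (single) raw <- list(raw)
  env <- purrr::map(raw, function(x) {
    x |>
      center_median() |>
      hampel_filter(cfg$hampel_window, cfg$hampel_nsigma) |>
      rectify() |>
      butter_lowpass(cfg = cfg)
  })
  norm <- mvc_normalize(env)
  dt <- 1 / cfg$sample_rate
  act <- purrr::map(norm$signals, function(e) {
    u <- neural_excitation(pmin(pmax(e, 0), 1), params$d, dt)
    activation_from_excitation(u, params$A)
  })
  list(activation = if (single) act[[1]] else act,
       excitation = if (single) norm$signals[[1]] else norm$signals,
       mvc = norm$mvc)
}

#' Elbow flexion angle from three markers
#'
#' Computes the flexion angle from shoulder, elbow, and wrist marker
#' positions: the angle at the elbow between the elbow-to-shoulder and
#' elbow-to-wrist vectors is the anatomical elbow angle; flexion is reported
#' as `q = pi -` that angle, so full extension (straight arm) gives `q = 0`.
#'
#' @param shoulder,elbow,wrist Numeric matrices (frames x 3) or length-3
#'   vectors of marker coordinates.
#' @return Numeric vector of flexion angles (rad).
#' @export
elbow_angle_from_markers <- function(shoulder, elbow, wrist) {
  as_mat <- function(m) if (is.matrix(m)) m else matrix(m, nrow = 1)
  shoulder <- as_mat(shoulder); elbow <- as_mat(elbow); wrist <- as_mat(wrist)
  v1 <- shoulder - elbow
  v2 <- wrist - elbow
  dot <- rowSums(v1 * v2)
  nn <- sqrt(rowSums(v1^2) * rowSums(v2^2))
  pi - acos(pmin(pmax(dot / nn, -1), 1))
}
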