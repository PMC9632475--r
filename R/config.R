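#' Read an elbow model from a YAML configuration
#'
#' The configuration mirrors the forward-dynamics parameter table: per-muscle
#' blocks `biceps:` and `triceps:` with fields `l0M`, `vmaxM`, `f0M`, `lsT`,
#' `phi`, `d`, `A` (units m, m/s, N, m, rad, s), top-level `m_fa`, `l_ua`,
#' `l_fa`, `g`, per-muscle attachment distances `l1`, `l2`, and an optional
#' `curves:` name (currently `gaussian_generic`). Missing fields fall back to
#' the defaults of [elbow_model()] and [muscle_params()].
#'
#' @param path Path to a YAML file.
#' @return An [elbow_model()].
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c("biceps:", "  f0M: 350", "  l1: 0.3", "  l2: 0.8"), cfg)
#' model <- read_model_yaml(cfg)
#' @export
read_model_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  muscle_from <- function(block, defaults) {
    if (is.null(block)) block <- list()
    args <- utils::modifyList(defaults,
                              block[names(block) %in%
                                      c("l0M", "vmaxM", "f0M", "lsT",
                                        "phi", "d", "A")])
    do.call(muscle_params, args)
  }
  bi_def <- list(l0M = 0.6, vmaxM = 6, f0M = 300, lsT = 0.55,
                 phi = 0, d = 0.08, A = 0.2)
  tri_def <- list(l0M = 0.4, vmaxM = 4, f0M = 300, lsT = 0.33,
                  phi = 0, d = 0.08, A = 0.2)
  curves <- hill_curves(if (is.null(cfg$curves)) "gaussian_generic"
                        else cfg$curves)
  pick <- function(x, default) if (is.null(x)) default else x
  elbow_model(
    m_fa = pick(cfg$m_fa, 1), l_ua = pick(cfg$l_ua, 1),
    l_fa = pick(cfg$l_fa, 1), g = pick(cfg$g, 9.81),
    l1_bi = pick(cfg$biceps$l1, 0.3), l2_bi = pick(cfg$biceps$l2, 0.8),
    l1_tri = pick(cfg$triceps$l1, 0.2), l2_tri = pick(cfg$triceps$l2, 0.7),
    biceps = muscle_from(cfg$biceps, bi_def),
    triceps = muscle_from(cfg$triceps, tri_def),
    curves = curves)
}
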