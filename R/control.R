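# Context ("surroundings") modulation of TiR parameters, and the noise model.

#' Attention-modulated integration rate
#'
#' Self-attention -- attention to feedback from one's own speech -- diminishes
#' the rate at which feedback TiRs accumulate force: `alpha = alpha_prime /
#' (1 + beta * lambda)`. External (sensory) and internal (predictive) TiRs
#' carry different sensitivities `beta`, which is what lets a single control
#' variable hand control from one feedback route to the other.
#'
#' @param alpha_prime Base integration rate (activation per unit input per
#'   second), `> 0`.
#' @param beta Attention sensitivity, `>= 0`. Must satisfy
#'   `beta_internal < beta_external` when the two routes compete (checked at
#'   model validation, not here).
#' @param lambda Self-attention in `[0, 1]`.
#' @return The effective rate, strictly decreasing in `lambda`.
#' @examples
#' attention_to_alpha(1, 1, 0)   # lambda = 0 leaves the rate untouched
#' attention_to_alpha(1, 1, 1)   # halved
#' @export
attention_to_alpha <- function(alpha_prime, beta, lambda) {
  if (any(!is.finite(lambda)) || any(lambda < 0) || any(lambda > 1)) {
    stop("`lambda` must lie in [0, 1].", call. = FALSE)
  }
  if (any(alpha_prime <= 0)) stop("`alpha_prime` must be > 0.", call. = FALSE)
  if (any(beta < 0)) stop("`beta` must be >= 0.", call. = FALSE)
  alpha_prime / (1 + beta * lambda)
}

#' Pace-modulated oscillator frequency
#'
#' Planning-oscillator frequencies are taken to be band-limited (roughly the
#' theta band, 3-8 Hz), so pace cannot drive frequency linearly. The map is a
#' logistic in `lambda` centred at 0.5: smooth, strictly increasing, and
#' saturating toward `f_min` and `f_max` at the extremes, so that
#' oscillator-governed intervals plateau at extreme rates.
#'
#' @param lambda Pace in `[0, 1]` (0 slowest, 1 fastest).
#' @param f_min,f_max Soft frequency bounds in Hz (`f_min < f_max`).
#' @param slope Logistic scale; smaller values saturate harder.
#' @return Frequency in Hz, strictly inside `(f_min, f_max)`;
#'   `lambda = 0.5` maps to the midpoint exactly.
#' @examples
#' pace_to_frequency(0.5)              # 5.5 Hz with the default 3-8 Hz band
#' pace_to_frequency(c(0, 1))          # close to, but inside, the bounds
#' @export
pace_to_frequency <- function(lambda, f_min = 3, f_max = 8, slope = 0.15) {
  if (any(!is.finite(lambda)) || any(lambda < 0) || any(lambda > 1)) {
    stop("`lambda` must lie in [0, 1].", call. = FALSE)
  }
  if (!(f_min < f_max)) stop("`f_min` must be < `f_max`.", call. = FALSE)
  f_min + (f_max - f_min) * stats::plogis((lambda - 0.5) / slope)
}

#' Per-run multiplicative rate-noise multipliers
#'
#' Stochastic variation is interpreted as utterance-to-utterance variation in
#' the influence of the surroundings on TiRs, so multipliers are drawn once
#' per run and frozen: `m_i = (1 + sigma_global * eta) * (1 + sigma_local *
#' eta_i)` with `eta` shared across all TiRs in a run (global noise) and
#' `eta_i` independent standard normals (local noise). Multipliers are clipped
#' to stay positive.
#'
#' @param n_tirs Number of TiRs.
#' @param sigma_global,sigma_local Multiplicative noise scales, `>= 0`.
#' @return Numeric vector of length `n_tirs`; all exactly 1 when both scales
#'   are zero.
#' @export
draw_noise_multipliers <- function(n_tirs, sigma_global = 0, sigma_local = 0) {
  if (sigma_global < 0 || sigma_local < 0) {
    stop("noise scales must be >= 0.", call. = FALSE)
  }
  eta_g <- stats::rnorm(1L)
  eta_l <- stats::rnorm(n_tirs)
  pmax((1 + sigma_global * eta_g) * (1 + sigma_local * eta_l), 1e-6)
}

#' Boost attention sensitivity at final positions
#'
#' Selectional anticipation: self-attention effects are strongest on the final
#' unit selected in each competitive domain, producing boundary-related
#' lengthening without any phrase-structural machinery. The attention
#' sensitivities (beta) of the feedback TiRs belonging to word-final
#' mu-systems are multiplied by `gamma_word_final`; those of the
#' utterance-final word additionally by `gamma_utterance_final`.
#'
#' @param model A `tir_model` whose mu-systems carry word membership and
#'   within-word position.
#' @param gamma_word_final,gamma_utterance_final Multiplicative boosts,
#'   `>= 1`. Defaults come from the model's shipped calibration.
#' @return The model with updated per-TiR boost factors; TiRs of non-final
#'   units are untouched.
#' @export
apply_final_position_boost <- function(model,
                                       gamma_word_final = NULL,
                                       gamma_utterance_final = NULL) {
  stopifnot(inherits(model, "tir_model"))
  gw <- gamma_word_final %||% model$params$gamma_word_final %||% 1
  gu <- gamma_utterance_final %||% model$params$gamma_utterance_final %||% 1
  if (gw < 1 || gu < 1) stop("boost factors must be >= 1.", call. = FALSE)
  if (is.null(model$mus) || nrow(model$mus) == 0L) return(model)

  mus <- model$mus
  final_word <- max(mus$word, na.rm = TRUE)
  word_final_mu <- mus |>
    dplyr::group_by(word) |>
    dplyr::filter(pos == max(pos)) |>
    dplyr::ungroup()

  boost_of_mu <- function(mu_id) {
    b <- 1
    row <- mus[mus$id == mu_id, ]
    if (mu_id %in% word_final_mu$id) b <- b * gw
    if (row$word == final_word) b <- b * gu
    b
  }

  tirs <- model$tirs
  integ <- tirs$class %in% c("T_int", "T_ext", "T_intra") & !is.na(tirs$mu)
  for (i in which(integ)) {
    tirs$beta_boost[i] <- tirs$beta_boost[i] * boost_of_mu(tirs$mu[i])
  }
  model$tirs <- tirs
  model
}

# Shipped default calibration -------------------------------------------------

.calib_env <- new.env(parent = emptyenv())

#' Default calibration constants
#'
#' The shipped calibration (oscillator phase offsets and coupling strengths,
#' feedback base intervals, attention sensitivities, pace map, boosts, noise
#' grid) read from the package's `extdata/default_calibration.json`.
#'
#' @return A nested list of calibration constants.
#' @export
default_calibration <- function() {
  if (is.null(.calib_env$calib)) {
    path <- system.file("extdata", "default_calibration.json", package = "tirsim")
    if (!nzchar(path)) {
      # running from a source tree (e.g. pkgload)
      path <- file.path("inst", "extdata", "default_calibration.json")
    }
    .calib_env$calib <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  .calib_env$calib
}
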