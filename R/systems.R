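# Gestural systems, gating systems, and the optional one-dimensional
# tract-variable plant.

#' Gestural activation follows the gate
#'
#' Gestural systems transition between their normalized activation extremes in
#' a single time step: activation is 1 while the gesture's gating system is
#' open and 0 while it is closed. (An activation ramp would be a refinement of
#' the output stage only; nothing in the timing logic depends on it, so the
#' single-step transition is kept.)
#'
#' @param gate_open Logical (vectorized): gate state after this step's TiR
#'   actions.
#' @return Activation in `{0, 1}`.
#' @export
step_gesture <- function(gate_open) {
  as.numeric(gate_open)
}

#' Create a one-dimensional tract-variable plant
#'
#' An optional point-attractor plant for producing movement traces from
#' gestural activation: a critically damped second-order system whose
#' equilibrium is the (weight-blended) target of the currently active driving
#' gestures. The plant holds its position when no gesture drives it, and it
#' never feeds back into timing except, optionally, as the source of the
#' external sensory trace.
#'
#' @param position Initial position.
#' @param omega_n Natural frequency in rad/s (time constant `1/omega_n`).
#' @param max_drive Maximum number of simultaneously driving gestures.
#' @return A list with class `tract_variable`.
#' @export
tract_variable <- function(position = 0, omega_n = 30, max_drive = 2L) {
  stopifnot(omega_n > 0, max_drive >= 1L)
  structure(
    list(position = position, velocity = 0, omega_n = omega_n,
         max_drive = as.integer(max_drive)),
    class = "tract_variable"
  )
}

#' Step a tract variable under a set of active gestures
#'
#' While driven, the position relaxes toward the blended target with
#' critically damped dynamics (no overshoot); undriven, velocity is shed and
#' the position holds.
#'
#' @param tv A [tract_variable()].
#' @param targets Numeric vector of targets of the *active* gestures (may be
#'   empty).
#' @param weights Optional blending weights (default equal).
#' @param dt Time step in seconds.
#' @return The updated `tract_variable`.
#' @export
step_tract_variable <- function(tv, targets, weights = NULL, dt = 0.001) {
  stopifnot(inherits(tv, "tract_variable"))
  n_active <- length(targets)
  if (n_active > tv$max_drive) {
    stop(sprintf("tract variable driven by %d gestures; max_drive is %d.",
                 n_active, tv$max_drive), call. = FALSE)
  }
  if (n_active == 0L) {
    tv$velocity <- 0
    return(tv)
  }
  w <- weights %||% rep(1, n_active)
  x_star <- sum(w * targets) / sum(w)
  acc <- tv$omega_n^2 * (x_star - tv$position) - 2 * tv$omega_n * tv$velocity
  tv$velocity <- tv$velocity + acc * dt
  tv$position <- tv$position + tv$velocity * dt
  tv
}
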