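# Single-step update rules for the five TiR classes and their trigger logic.
# These are the primitive change rules the engine iterates; they are exported
# both as the public contract of the dynamics and for direct experimentation.

#' Threshold-crossing detection
#'
#' A TiR acts when its activation first reaches a threshold: the detector
#' fires iff `x_prev < tau <= x_curr`. Each (TiR, threshold) pair is armed
#' once per gating episode, so repeated calls after a crossing do not re-fire
#' (the engine tracks arming; this primitive is stateless and vectorized).
#'
#' @param x_prev,x_curr Activation at the previous and current step (finite).
#' @param tau Action threshold(s), `>= 0`.
#' @return Logical: did the state cross the threshold this step?
#' @examples
#' detect_crossing(0.24, 0.26, 0.25)  # TRUE
#' detect_crossing(0.26, 0.27, 0.25)  # FALSE: already past
#' @export
detect_crossing <- function(x_prev, x_curr, tau) {
  if (any(!is.finite(x_prev)) || any(!is.finite(x_curr))) {
    stop("activations must be finite.", call. = FALSE)
  }
  x_prev < tau & tau <= x_curr
}

#' Step an autonomous aperiodic TiR
#'
#' An aperiodic clock grows at a context-set rate while its gate is open and
#' is frozen while closed. With the elapsed-time parameterization
#' `omega = 1` activation/s, its activation numerically equals the time its
#' gate has been open.
#'
#' @param x Current activation(s).
#' @param omega Growth rate in activation/s, `>= 0`.
#' @param gate_open Logical; is the TiR de-gated?
#' @param dt Time step in seconds.
#' @return Updated activation.
#' @export
step_aperiodic <- function(x, omega, gate_open, dt) {
  if (any(omega < 0)) stop("growth rate `omega` must be >= 0.", call. = FALSE)
  x + omega * as.numeric(gate_open) * dt
}

#' Step a non-autonomous (integrator) TiR
#'
#' Internal, external and intra-gestural TiRs integrate the force they
#' experience from their source system: `x <- x + alpha * input * dt`. For an
#' external TiR the input is the delayed sensory trace of the source (see
#' [sensory_trace()]); for internal/intra-gestural TiRs it is the source
#' activation itself. With constant unit input an integrator is identical to
#' an aperiodic TiR with `omega = alpha`.
#'
#' @param x Current activation(s).
#' @param alpha Integration rate (activation per unit input-force per second).
#' @param input Input force, `>= 0`.
#' @param dt Time step in seconds.
#' @return Updated activation.
#' @export
step_integrator <- function(x, alpha, input, dt) {
  if (any(input < 0)) stop("integrator input must be >= 0.", call. = FALSE)
  x + alpha * input * dt
}

#' Delayed sensory trace of an activation history
#'
#' External feedback loops through the periphery: information generated in the
#' CNS produces effects outside it, which are transduced back with a delay.
#' The trace is the source signal shifted by `d` seconds, zero before the
#' first delayed sample arrives.
#'
#' @param g Numeric vector: activation sampled on a regular grid.
#' @param delay Delay in seconds, `>= 0`.
#' @param dt Grid spacing in seconds.
#' @return Vector of the same length: `out[t] = g[t - delay]`.
#' @examples
#' sensory_trace(c(0, 0, 1, 1), delay = 0, dt = 0.05)     # identity
#' sensory_trace(c(0, 0, 1, 1), delay = 0.05, dt = 0.05)  # shifted one step
#' @export
sensory_trace <- function(g, delay, dt) {
  if (delay < 0) stop("`delay` must be >= 0.", call. = FALSE)
  k <- as.integer(round(delay / dt))
  if (k == 0L) return(g)
  n <- length(g)
  if (k >= n) return(rep(0, n))
  c(rep(0, k), g[seq_len(n - k)])
}

#' Step a bank of phase-coupled planning oscillators
#'
#' Each oscillator carries a phase, a radial amplitude and the amplitude
#' derivative. Phases advance at their (noise- and pace-modulated) angular
#' frequencies, accelerated or decelerated by sine coupling:
#' `dtheta_i = omega_i + sum_j Phi[i,j] * sin(theta_j - theta_i)`, with
#' positive entries attractive (in-phase) and negative entries repulsive
#' (anti-phase). Amplitude relaxes, critically damped, toward 1 while the
#' oscillator's gate is open and toward 0 while closed; triggering is only
#' possible above an amplitude threshold, which is what prevents premature or
#' repeated triggering.
#'
#' @param phase Phase vector in `[0, 2*pi)`.
#' @param rho,rho_dot Radial amplitude in `[0, 1]` and its derivative.
#' @param omega Angular frequencies in rad/s.
#' @param coupling Square coupling matrix `Phi` (rad/s), zero diagonal.
#' @param gate_open Logical vector: amplitude targets.
#' @param dt Time step in seconds.
#' @param omega_n Natural frequency of the amplitude dynamics in rad/s
#'   (default corresponds to a ~50 ms rise).
#' @return A list with updated `phase` (wrapped mod 2*pi), `rho`, `rho_dot`,
#'   and `wrapped`, a logical vector marking oscillators whose phase passed
#'   the trigger phase (0 mod 2*pi) this step.
#' @export
step_oscillators <- function(phase, rho, rho_dot, omega, coupling, gate_open,
                             dt, omega_n = 95) {
  n <- length(phase)
  if (!is.matrix(coupling) || nrow(coupling) != n || ncol(coupling) != n) {
    stop("`coupling` must be a square matrix matching the bank.", call. = FALSE)
  }
  if (any(diag(coupling) != 0)) {
    stop("oscillators must not be coupled to themselves.", call. = FALSE)
  }
  force <- if (n > 1L) {
    rowSums(coupling * -sin(outer(phase, phase, "-")))
  } else {
    0
  }
  raw <- phase + (omega + force) * dt
  wrapped <- raw >= 2 * pi
  target <- as.numeric(gate_open)
  rho_dd <- omega_n^2 * (target - rho) - 2 * omega_n * rho_dot
  rho_dot <- rho_dot + rho_dd * dt
  rho <- pmin(pmax(rho + rho_dot * dt, 0), 1)
  # wrap only at the trigger phase: a negative phase (a lag imposed by the
  # initial conditions) rises through 0 without registering a crossing
  list(
    phase = raw - ifelse(wrapped, 2 * pi, 0), phase_raw = raw,
    wrapped = wrapped, rho = rho, rho_dot = rho_dot
  )
}

#' Phase-trigger detection for planning oscillators
#'
#' An oscillator triggers the gestural system it is responsible for when its
#' phase crosses the trigger phase (fixed at 0 mod 2*pi, the conventional peak
#' of the cosine) while its amplitude is at or above threshold; an armed
#' trigger fires at most once per gate-open episode.
#'
#' @param wrapped Logical: did the phase pass the trigger phase this step?
#' @param rho Current amplitude.
#' @param threshold Amplitude threshold (default 0.5).
#' @param armed Logical: is the trigger still armed this episode?
#' @return Logical: fire now?
#' @export
detect_phase_trigger <- function(wrapped, rho, threshold = 0.5, armed = TRUE) {
  wrapped & rho >= threshold & armed
}

#' Threshold equivalent of a virtual-cycle phase
#'
#' An intra-gestural TiR with the elapsed-time parameterization can emulate a
#' "virtual cycle": converting its activation to a phase in `[0, 2*pi)` at the
#' natural frequency `f` of the cycle, an action at virtual phase `phi`
#' corresponds to the activation threshold `phi / (2*pi*f)`. The conventional
#' deactivation phase is `3*pi/2`.
#'
#' @param phi Virtual-cycle phase in radians.
#' @param f Virtual-cycle frequency in Hz.
#' @return Activation threshold in elapsed-time units (seconds of input).
#' @export
tau_from_phase <- function(phi, f) {
  if (f <= 0) stop("`f` must be > 0.", call. = FALSE)
  phi / (2 * pi * f)
}
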