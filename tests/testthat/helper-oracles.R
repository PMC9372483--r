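# Independent oracles and small helpers shared across tests.

# hand-coded Pearson correlation (independent of stats::cor)
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# first activation time of each gestural system in run 1
onsets_of <- function(sim) {
  ev <- sim$events[sim$events$event_kind == "activation_on" &
                     sim$events$run_id == 1L, ]
  vapply(split(ev$time_exact_s, ev$system_id), min, numeric(1))
}

# closed-form critically damped step response (unit target)
crit_damped_response <- function(t, omega_n) {
  1 - (1 + omega_n * t) * exp(-omega_n * t)
}

# a minimal one-gesture model: an aperiodic clock opens the gate at tau_on
# and a second clock closes it at tau_off (elapsed-time parameterization)
one_gesture_model <- function(tau_on = 0.1, tau_off = NULL, omega = 1,
                              duration = 1) {
  tirs <- tibble::tibble(id = "eps_on", class = "eps", rate = omega)
  acts <- tibble::tibble(tir = "eps_on", target = "g1", effect = "open",
                         tau = tau_on)
  if (!is.null(tau_off)) {
    tirs <- dplyr::bind_rows(tirs, tibble::tibble(id = "eps_off",
                                                  class = "eps", rate = omega))
    acts <- dplyr::bind_rows(acts, tibble::tibble(tir = "eps_off",
                                                  target = "g1",
                                                  effect = "close",
                                                  tau = tau_off))
  }
  new_tir_model("one_gesture", tibble::tibble(id = "g1"), tirs, acts,
                duration = duration)
}
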