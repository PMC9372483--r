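test_that("aperiodic clocks under elapsed-time parameterization track time", {
  # omega = 1 activation/s: activation numerically equals open time
  m <- one_gesture_model(tau_on = 0.5)
  sim <- run_simulation(m, sim_config(seed = 1))
  ts <- sim$timeseries
  x <- ts[ts$system_id == "eps_on" & ts$variable == "tir_activation", ]
  expect_equal(x$value[abs(x$time_s - 0.1) < 1e-9], 0.1, tolerance = 1e-9)
  # closed clock stays at zero
  m2 <- one_gesture_model(tau_on = 0.5)
  m2$tirs$gate0 <- FALSE
  sim2 <- run_simulation(m2, sim_config(seed = 1))
  x2 <- sim2$timeseries[sim2$timeseries$variable == "tir_activation", ]
  expect_true(all(x2$value == 0))
  expect_error(step_aperiodic(0, -1, TRUE, 0.001), ">= 0")
})

test_that("action time depends only on the tau/omega ratio", {
  t_on <- function(omega, tau) {
    sim <- run_simulation(one_gesture_model(tau_on = tau, omega = omega),
                          sim_config(seed = 1, record_timeseries = FALSE))
    sim$events$time_exact_s[sim$events$event_kind == "activation_on"]
  }
  expect_equal(t_on(2, 0.5), 0.25, tolerance = 1e-9)
  expect_equal(t_on(1, 0.25), 0.25, tolerance = 1e-9)
  expect_equal(t_on(2, 0.5), t_on(1, 0.25), tolerance = 1e-12)
})

test_that("integrators accumulate source activation at rate alpha", {
  # alpha = 1, source active, tau = 0.25 -> deactivation 0.25 s after onset;
  # alpha = 2 halves the interval
  m <- one_gesture_model(tau_on = 0.1)
  for (alpha in c(1, 2)) {
    mi <- m
    mi$tirs <- dplyr::bind_rows(
      mi$tirs,
      tibble::tibble(id = "T_off", class = "T_int", rate = alpha,
                     source = "g1")
    )
    mi$actions <- dplyr::bind_rows(
      mi$actions,
      tibble::tibble(tir = "T_off", target = "g1", effect = "close",
                     tau = 0.25)
    )
    sim <- run_simulation(mi, sim_config(seed = 1, record_timeseries = FALSE))
    ev <- sim$events
    dur <- ev$time_exact_s[ev$event_kind == "activation_off"] -
      ev$time_exact_s[ev$event_kind == "activation_on"]
    expect_equal(dur, 0.25 / alpha, tolerance = 1e-9)
  }
  # zero input: never fires
  m0 <- one_gesture_model(tau_on = 2)  # gesture never activates
  m0$tirs <- dplyr::bind_rows(
    m0$tirs,
    tibble::tibble(id = "T_idle", class = "T_int", rate = 1, source = "g1")
  )
  m0$actions <- dplyr::bind_rows(
    m0$actions,
    tibble::tibble(tir = "T_idle", target = "g1", effect = "close", tau = 0.1)
  )
  sim0 <- run_simulation(m0, sim_config(seed = 1, record_timeseries = FALSE))
  expect_equal(nrow(sim0$events), 0L)
})

test_that("an integrator with constant unit input equals an aperiodic clock", {
  expect_equal(step_integrator(0.2, 0.7, 1, 0.001),
               step_aperiodic(0.2, 0.7, TRUE, 0.001))
  x_int <- Reduce(function(x, .) step_integrator(x, 0.8, 1, 0.001),
                  1:500, accumulate = FALSE, init = 0)
  x_ap <- Reduce(function(x, .) step_aperiodic(x, 0.8, TRUE, 0.001),
                 1:500, accumulate = FALSE, init = 0)
  expect_identical(x_int, x_ap)
})

test_that("sensory traces delay the source signal", {
  g <- c(rep(0, 10), rep(1, 10))
  expect_identical(sensory_trace(g, 0, 0.01), g)
  shifted <- sensory_trace(g, 0.05, 0.01)
  expect_equal(which(shifted == 1)[1], 16L)  # step at index 11 -> 16
  expect_error(sensory_trace(g, -1, 0.01), ">= 0")
})

test_that("external and internal chains differ only by the delay per link", {
  d <- default_calibration()$feedback$delay_s
  se <- run_simulation(build_model("fig8_chain_external"),
                       sim_config(seed = 1, record_timeseries = FALSE))
  si <- run_simulation(build_model("fig8_chain_internal"),
                       sim_config(seed = 1, record_timeseries = FALSE))
  ie <- extract_intervals(se)
  ii <- extract_intervals(si)
  for (nm in c("d12", "d23")) {
    expect_equal(ie$value_ms[ie$name == nm] - ii$value_ms[ii$name == nm],
                 1000 * d, tolerance = 1e-6)
  }
})

test_that("attractive coupling pulls phases together, repulsive pushes to anti-phase", {
  run_pair <- function(K, dphi0, t_end = 3) {
    dt <- 0.001
    phase <- c(0, -dphi0)
    rho <- c(1, 1); rd <- c(0, 0)
    Phi <- matrix(c(0, K, K, 0), 2, 2)
    dphi <- numeric(round(t_end / dt))
    for (i in seq_along(dphi)) {
      st <- step_oscillators(phase, rho, rd, omega = c(31.4, 31.4),
                             coupling = Phi, gate_open = c(TRUE, TRUE),
                             dt = dt)
      phase <- st$phase_raw  # unwrapped: keep the raw difference
      rho <- st$rho; rd <- st$rho_dot
      dphi[i] <- abs(phase[1] - phase[2])
    }
    dphi
  }
  conv <- run_pair(K = 2, dphi0 = pi / 2)
  expect_true(all(diff(conv) <= 1e-12))      # monotone decrease
  expect_lt(conv[length(conv)], 0.01)        # toward in-phase
  rep_ <- run_pair(K = -2, dphi0 = 0.1)
  expect_true(all(diff(rep_) >= -1e-12))
  expect_equal(rep_[length(rep_)], pi, tolerance = 0.01)
})

test_that("strong attractive coupling locks heterogeneous frequencies", {
  dt <- 0.001
  phase <- c(0, 0); rho <- c(1, 1); rd <- c(0, 0)
  omega <- c(30, 34); K <- 10
  Phi <- matrix(c(0, K, K, 0), 2, 2)
  inst <- matrix(0, 2000, 2)
  prev <- phase
  for (i in 1:2000) {
    st <- step_oscillators(phase, rho, rd, omega, Phi, c(TRUE, TRUE), dt)
    inst[i, ] <- (st$phase_raw - prev) / dt
    phase <- st$phase_raw; prev <- phase
    rho <- st$rho; rd <- st$rho_dot
  }
  late <- inst[1500:2000, ]
  expect_lt(max(abs(late[, 1] - late[, 2])), 0.05)  # common frequency
  expect_equal(mean(late), 32, tolerance = 0.1)     # at the mean detuning
})

test_that("oscillators only trigger above the amplitude threshold, once per episode", {
  expect_false(detect_phase_trigger(TRUE, 0.1, 0.5, TRUE))
  expect_true(detect_phase_trigger(TRUE, 0.9, 0.5, TRUE))
  expect_false(detect_phase_trigger(TRUE, 0.9, 0.5, FALSE))
  # an oscillator left open across two cycles triggers its gesture once
  omega <- 2 * pi * 5
  m <- new_tir_model(
    "osc_once", tibble::tibble(id = "g1"),
    tibble::tibble(id = "th1", class = "osc", rate = omega, phase0 = pi / 2),
    tibble::tibble(tir = "th1", target = "g1", effect = "open",
                   tau = NA_real_),
    coupling = matrix(0, 1, 1, dimnames = list("th1", "th1")),
    duration = 0.6  # covers ~3 cycles
  )
  sim <- run_simulation(m, sim_config(seed = 1, record_timeseries = FALSE))
  expect_equal(sum(sim$events$event_kind == "trigger"), 1L)
  expect_equal(sum(sim$events$event_kind == "activation_on"), 1L)
})

test_that("an intra-gestural virtual cycle deactivates at phase 3*pi/2", {
  # activation-to-phase conversion: at virtual frequency f, phase 3*pi/2
  # corresponds to an activation threshold of 0.75 / f seconds of input
  f_v <- 2.5
  tau <- tau_from_phase(3 * pi / 2, f_v)
  expect_equal(tau, 0.75 / f_v)
  m <- one_gesture_model(tau_on = 0.1)
  m$tirs <- dplyr::bind_rows(
    m$tirs,
    tibble::tibble(id = "T_vc", class = "T_intra", rate = 1, source = "g1")
  )
  m$actions <- dplyr::bind_rows(
    m$actions,
    tibble::tibble(tir = "T_vc", target = "g1", effect = "close", tau = tau)
  )
  sim <- run_simulation(m, sim_config(seed = 1, record_timeseries = FALSE))
  ev <- sim$events
  dur <- ev$time_exact_s[ev$event_kind == "activation_off"] -
    ev$time_exact_s[ev$event_kind == "activation_on"]
  expect_equal(dur, 0.3, tolerance = 1e-9)
})

test_that("intra-gestural TiRs may not act outside their own gesture", {
  m <- new_tir_model(
    "bad_intra", tibble::tibble(id = c("g1", "g2")),
    tibble::tibble(id = c("eps_on", "T_x"), class = c("eps", "T_intra"),
                   rate = 1, source = c(NA, "g1")),
    tibble::tibble(tir = c("eps_on", "T_x"), target = c("g1", "g2"),
                   effect = c("open", "close"), tau = c(0.1, 0.2)),
    duration = 1
  )
  expect_error(validate_model(m), "intra-gestural")
})
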