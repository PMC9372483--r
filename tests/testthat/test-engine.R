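test_that("threshold-crossing detection fires exactly at first crossing", {
  expect_true(detect_crossing(0.24, 0.26, 0.25))
  expect_false(detect_crossing(0.26, 0.27, 0.25))
  expect_false(detect_crossing(0.25, 0.26, 0.25))  # already at threshold
  expect_true(detect_crossing(0.2, 0.25, 0.25))    # tau <= x_curr inclusive
  expect_error(detect_crossing(NaN, 1, 0.5), "finite")

  # ramp oracle: x(t) = t sampled at dt must fire within one dt of tau
  dt <- 0.001
  x <- seq(0, 1, by = dt)
  fired <- which(detect_crossing(head(x, -1), tail(x, -1), 0.25))
  t_fire <- fired * dt
  expect_lte(abs(t_fire - 0.25), dt)
})

test_that("a minimal gated model produces one on and one off event", {
  sim <- run_simulation(one_gesture_model(0.1, 0.35), sim_config(seed = 1))
  ev <- sim$events
  expect_equal(sum(ev$event_kind == "activation_on"), 1L)
  expect_equal(sum(ev$event_kind == "activation_off"), 1L)
  expect_equal(ev$time_s[ev$event_kind == "activation_on"], 0.1,
               tolerance = 1e-12)
  expect_equal(ev$time_s[ev$event_kind == "activation_off"], 0.35,
               tolerance = 1e-12)
})

test_that("an empty model leaves all activations at zero", {
  m <- new_tir_model("empty", tibble::tibble(id = c("g1", "g2")),
                     tibble::tibble(id = character(), class = character(),
                                    rate = numeric()),
                     tibble::tibble(tir = character(), target = character(),
                                    effect = character(), tau = numeric()),
                     duration = 0.5)
  sim <- run_simulation(m, sim_config(seed = 1))
  expect_equal(nrow(sim$events), 0L)
  act <- sim$timeseries[sim$timeseries$variable == "activation", ]
  expect_true(all(act$value == 0))
})

test_that("the worked clock/integrator example runs in panel order", {
  sim <- run_simulation(build_model("fig5"), sim_config(seed = 1))
  ev <- sim$events[sim$events$event_kind %in%
                     c("activation_on", "activation_off"), ]
  ev <- ev[order(ev$time_s, ev$system_id), ]
  # g1 and g2 switch on together (shared initiator), g1 off via its clock,
  # g2 off via its feedback integrator at 0.25 of accumulated activation
  expect_equal(ev$system_id[ev$event_kind == "activation_on"], c("g1", "g2"))
  on_t <- ev$time_s[ev$event_kind == "activation_on"]
  expect_equal(on_t[1], on_t[2])
  off <- ev[ev$event_kind == "activation_off", ]
  g2_dur <- off$time_s[off$system_id == "g2"] - on_t[2]
  expect_equal(g2_dur, 0.25, tolerance = 0.001 + 1e-12)
})

test_that("unknown system references are configuration errors", {
  m <- one_gesture_model()
  m$actions$target <- "nonexistent"
  expect_error(validate_model(m), "nonexistent")
  m2 <- one_gesture_model()
  m2$tirs <- dplyr::bind_rows(
    m2$tirs,
    tibble::tibble(id = "T_bad", class = "T_int", rate = 1, source = "ghost")
  )
  expect_error(run_simulation(m2, sim_config()), "ghost")
})

test_that("equal seeds give bit-identical event logs; unequal seeds differ", {
  m <- build_model("fig8_chain_internal", sigma_global = 0.05,
                   sigma_local = 0.05)
  s1 <- run_simulation(m, sim_config(seed = 11, n_runs = 5,
                                     record_timeseries = FALSE))
  s2 <- run_simulation(m, sim_config(seed = 11, n_runs = 5,
                                     record_timeseries = FALSE))
  s3 <- run_simulation(m, sim_config(seed = 12, n_runs = 5,
                                     record_timeseries = FALSE))
  expect_identical(serialize(s1$events, NULL), serialize(s2$events, NULL))
  expect_false(identical(s1$events, s3$events))
})

test_that("gate events coincide with the gate trace switching at that step", {
  sim <- run_simulation(build_model("fig9d_hybrid_cvc"), sim_config(seed = 1))
  gates <- sim$timeseries[sim$timeseries$variable == "gate", ]
  ev <- sim$events[sim$events$event_kind == "gate_open", ]
  for (k in seq_len(nrow(ev))) {
    tr <- gates[gates$system_id == ev$system_id[k], ]
    tr <- tr[order(tr$time_s), ]
    i <- which(abs(tr$time_s - ev$time_s[k]) < 1e-9)
    expect_equal(tr$value[i], 1)
    expect_equal(tr$value[i - 1L], 0)
  }
})

test_that("halving dt moves every event by at most one original dt (zoo, noise off)", {
  dt <- 0.001
  for (nm in list_models()) {
    m <- build_model(nm)
    e1 <- run_simulation(m, sim_config(dt = dt, seed = 1,
                                       record_timeseries = FALSE))$events
    e2 <- run_simulation(m, sim_config(dt = dt / 2, seed = 1,
                                       record_timeseries = FALSE))$events
    expect_equal(nrow(e1), nrow(e2), info = nm)
    expect_lte(max(abs(e1$time_s - e2$time_s)), dt + 1e-12)
  }
})

test_that("numerical instability is reported with the offending system", {
  m <- one_gesture_model()
  m$tirs$rate <- Inf   # blow up the clock
  expect_error(run_simulation(m, sim_config(duration = 1)),
               "non-finite state")
})
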