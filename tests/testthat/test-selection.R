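sel_events <- function(sim, kinds = c("selected", "suppressed")) {
  ev <- sim$events[sim$events$event_kind %in% kinds, ]
  ev[order(ev$time_exact_s), ]
}

test_that("competition is linear growth to threshold from the gradient", {
  # gradient (0.9, 0.6, 0.3), threshold 1, rate 1 -> first selection at 0.1 s
  m <- build_model("fig11_three_cv")
  m$mus$a0 <- c(0.9, 0.6, 0.3)
  sim <- run_simulation(m, sim_config(seed = 1, record_timeseries = FALSE))
  sel <- sel_events(sim, "selected")
  expect_equal(sel$system_id[1], "mu1")
  expect_equal(sel$time_exact_s[1], 0.1, tolerance = 1e-9)
})

test_that("selection order equals descending initial-activation order", {
  set.seed(7)
  for (k in 1:4) {
    m <- build_model("fig11_three_cv")
    perm <- sample(3L)
    m$mus$a0 <- c(0.9, 0.8, 0.7)[perm]
    sim <- run_simulation(m, sim_config(seed = 1, record_timeseries = FALSE))
    sel <- sel_events(sim, "selected")
    expect_equal(sel$system_id, m$mus$id[order(-m$mus$a0)],
                 info = paste(perm, collapse = ","))
  }
})

test_that("selection is mutually exclusive within a domain", {
  sim <- run_simulation(build_model("fig11_three_cv"),
                        sim_config(seed = 1, record_timeseries = FALSE))
  ev <- sel_events(sim)
  # selected and suppressed must strictly alternate: no unit is selected
  # while another is still selected
  expect_equal(ev$event_kind,
               rep(c("selected", "suppressed"), length.out = nrow(ev)))
  sel <- ev[ev$event_kind == "selected", ]
  sup <- ev[ev$event_kind == "suppressed", ]
  expect_equal(sup$system_id, sel$system_id)  # each suppression matches
  expect_true(all(sup$time_exact_s >= sel$time_exact_s))
  expect_true(all(utils::head(sup$time_exact_s, -1) <=
                    utils::tail(sel$time_exact_s, -1)))
})

test_that("each round runs de-gating, selection with gate closure, suppression", {
  sim <- run_simulation(build_model("fig11_three_cv"), sim_config(seed = 1))
  ts <- sim$timeseries
  mu_act <- ts[ts$variable == "mu_activation", ]
  sel <- sel_events(sim)
  # between a selection and its suppression, competitor activations are
  # frozen (gates closed)
  s1 <- sel$time_exact_s[1]; p1 <- sel$time_exact_s[2]
  frozen <- mu_act[mu_act$system_id == "mu2" &
                     mu_act$time_s > s1 + 0.002 & mu_act$time_s < p1, ]
  expect_equal(length(unique(frozen$value)), 1L)
  # after suppression, the remaining competitors grow again
  growing <- mu_act[mu_act$system_id == "mu3" &
                      mu_act$time_s > p1 + 0.002 &
                      mu_act$time_s < p1 + 0.05, ]
  expect_true(all(diff(growing$value[order(growing$time_s)]) > 0))
  # the suppressed unit is reset to zero and retired
  reset <- mu_act[mu_act$system_id == "mu1" & mu_act$time_s > p1, ]
  expect_true(all(reset$value == 0))
  # and the domain reports completion
  expect_equal(sum(sim$events$event_kind == "sequence_complete"), 1L)
})

test_that("tied gradient values warn and resolve to the lowest index", {
  m <- build_model("fig11_three_cv")
  m$mus$a0 <- c(0.8, 0.8, 0.7)
  expect_warning(validate_model(m), "tie")
  sim <- suppressWarnings(
    run_simulation(m, sim_config(seed = 1, record_timeseries = FALSE))
  )
  sel <- sel_events(sim, "selected")
  expect_equal(sel$system_id[1], "mu1")
})

test_that("parallel domains nest mu epochs inside concept epochs", {
  sim <- run_simulation(build_model("fig12_multiword"),
                        sim_config(seed = 1, record_timeseries = FALSE))
  ev <- sim$events
  conc_sel <- ev[ev$event_kind == "selected" & grepl("^w", ev$system_id), ]
  expect_equal(conc_sel$system_id[order(conc_sel$time_exact_s)],
               c("w1", "w2", "w3", "w4"))
  mu_sel <- ev[ev$event_kind == "selected" & grepl("^mu", ev$system_id), ]
  expect_equal(nrow(mu_sel), 9L)  # 2 + 3 + 1 + 3 syllables
  # mu selections of each word fall strictly inside that word's epoch
  conc_sup <- ev[ev$event_kind == "suppressed" & grepl("^w", ev$system_id), ]
  m <- build_model("fig12_multiword")
  counts <- integer(4)
  for (w in 1:4) {
    lo <- conc_sel$time_exact_s[conc_sel$system_id == paste0("w", w)]
    hi <- conc_sup$time_exact_s[conc_sup$system_id == paste0("w", w)]
    members <- m$mus$id[m$mus$word == w]
    inside <- mu_sel$time_exact_s[mu_sel$system_id %in% members]
    counts[w] <- length(inside)
    expect_true(all(inside >= lo & inside <= hi))
  }
  expect_equal(counts, c(2L, 3L, 1L, 3L))
  # gestures are grouped accordingly: each gesture activates within its
  # word's concept epoch
  ons <- ev[ev$event_kind == "activation_on", ]
  gw <- m$gestures
  for (w in 1:4) {
    lo <- conc_sel$time_exact_s[conc_sel$system_id == paste0("w", w)]
    hi <- conc_sup$time_exact_s[conc_sup$system_id == paste0("w", w)]
    t_on <- ons$time_exact_s[ons$system_id %in% gw$id[gw$word == w]]
    expect_true(all(t_on >= lo & t_on <= hi))
  }
})

test_that("concept selection de-gates exactly its member mu-systems", {
  sim <- run_simulation(build_model("fig12_multiword"),
                        sim_config(seed = 1, record_timeseries = FALSE))
  ev <- sim$events
  # while w1 is in progress, no mu of words 2-4 is ever selected
  w1_sup <- min(ev$time_exact_s[ev$event_kind == "suppressed" &
                                  ev$system_id == "w1"])
  m <- build_model("fig12_multiword")
  later_mus <- m$mus$id[m$mus$word > 1]
  early_sel <- ev[ev$event_kind == "selected" &
                    ev$system_id %in% later_mus &
                    ev$time_exact_s < w1_sup, ]
  expect_equal(nrow(early_sel), 0L)
})
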