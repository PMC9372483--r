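# Fixed-step simulation engine: clock, state registry, threshold-crossing
# event detection, per-run RNG streams, and event logging.

#' Simulation configuration
#'
#' @param dt Time step in seconds (`> 0`). Forward-Euler integration on this
#'   grid; event times are reported at the first grid step where a crossing
#'   condition holds (quantization `<= dt`), and additionally carry an exact
#'   sub-step time obtained by linear interpolation of the crossing state,
#'   which interval analysis uses.
#' @param duration Simulated time in seconds (`>= dt`); `NULL` uses the
#'   model's default.
#' @param seed Integer root seed. Per-run child streams are derived by
#'   counter, so Monte-Carlo batches are reproducible run by run.
#' @param n_runs Number of Monte-Carlo repetitions (`>= 1`).
#' @param record_timeseries Record per-step state traces? Defaults to TRUE
#'   for single runs and FALSE for batches.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(dt = 0.001, duration = NULL, seed = 1L, n_runs = 1L,
                       record_timeseries = NULL) {
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be > 0.", call. = FALSE)
  if (!is.null(duration) && duration < dt) {
    stop("`duration` must be >= dt.", call. = FALSE)
  }
  if (n_runs < 1) stop("`n_runs` must be >= 1.", call. = FALSE)
  structure(
    list(dt = dt, duration = duration, seed = as.integer(seed),
         n_runs = as.integer(n_runs),
         record_timeseries = record_timeseries),
    class = "sim_config"
  )
}

# counter-derived child stream seed: runs are independent of batch layout
child_seed <- function(seed, run) {
  as.integer((as.numeric(seed) %% 2147483647 + 48271 * run) %% 2147483647) + 1L
}

# event-kind codes used internally
.EV_KINDS <- c("gate_open", "gate_close", "activation_on", "activation_off",
               "trigger", "selected", "suppressed", "sequence_complete")

# Compile a validated model into flat, integer-indexed structures.
compile_model <- function(model, config) {
  p <- model$params
  dt <- config$dt
  # tolerate partially specified TiR rows (e.g. user-added via bind_rows)
  tr <- model$tirs
  fill <- list(delay = 0, gate0 = TRUE, use_pace = FALSE,
               amp_threshold = 0.5, beta_boost = 1)
  for (col in names(fill)) tr[[col]][is.na(tr[[col]])] <- fill[[col]]
  model$tirs <- tr
  g_ids <- model$gestures$id
  t_ids <- model$tirs$id
  n_g <- length(g_ids)
  n_t <- length(t_ids)
  cls <- match(model$tirs$class, c("eps", "osc", "T_int", "T_ext", "T_intra"))

  beta_class <- numeric(n_t)
  beta_class[cls == 3L | cls == 5L] <- p$beta_internal
  beta_class[cls == 4L] <- p$beta_external
  beta_eff <- beta_class * model$tirs$beta_boost

  rate0 <- model$tirs$rate
  rate_base <- rate0
  integ <- cls %in% 3:5
  if (any(integ)) {
    rate_base[integ] <- attention_to_alpha(rate0[integ], beta_eff[integ],
                                           p$lambda_attention)
  }
  is_osc <- cls == 2L
  if (any(is_osc)) {
    f_pace <- 2 * pi * pace_to_frequency(p$lambda_pace, p$f_min, p$f_max,
                                         p$pace_slope)
    rate_base[is_osc & model$tirs$use_pace] <- f_pace
  }

  source_idx <- match(model$tirs$source, g_ids)
  delay_steps <- as.integer(round(model$tirs$delay / dt))

  osc_idx <- which(is_osc)
  n_o <- length(osc_idx)
  Phi <- matrix(0, n_o, n_o)
  if (n_o > 0L && !is.null(model$coupling)) {
    ord <- t_ids[osc_idx]
    Phi <- model$coupling[ord, ord, drop = FALSE]
  }
  phase0 <- model$tirs$phase0[osc_idx]
  phase0[is.na(phase0)] <- 0
  amp_thr <- model$tirs$amp_threshold[osc_idx]
  omega_n <- 4.744 / p$amp_rise_s  # critically damped: ~95% rise at amp_rise_s

  acts <- model$actions
  a_owner <- match(acts$tir, t_ids)
  a_is_tir <- startsWith(acts$target, "tir:")
  a_tidx <- ifelse(a_is_tir,
                   match(sub("^tir:", "", acts$target), t_ids),
                   match(acts$target, g_ids))
  a_open <- acts$effect == "open"
  a_tau <- acts$tau

  # selection domains
  has_mu <- !is.null(model$mus) && nrow(model$mus) > 0L
  mus <- model$mus
  has_conc <- !is.null(model$concepts) && nrow(model$concepts) > 0L
  mu_children_idx <- NULL
  mu_final_g <- integer(0)
  mu_concept <- integer(0)
  if (has_mu) {
    mu_children_idx <- lapply(mus$id, function(id) {
      match(model$mu_children[[id]] %||% character(0), t_ids)
    })
    mu_final_g <- match(mus$final_gesture, g_ids)
    mu_concept <- if (has_conc) match(mus$concept, model$concepts$id)
                  else rep(1L, nrow(mus))
  }

  list(
    dt = dt, n_g = n_g, n_t = n_t, n_o = n_o,
    g_ids = g_ids, t_ids = t_ids,
    cls = cls, rate_base = rate_base, gate0 = model$tirs$gate0,
    source_idx = source_idx, delay_steps = delay_steps,
    osc_idx = osc_idx, Phi = Phi, phase0 = phase0, amp_thr = amp_thr,
    omega_n = omega_n,
    a_owner = a_owner, a_is_tir = a_is_tir, a_tidx = a_tidx,
    a_open = a_open, a_tau = a_tau, n_a = length(a_owner),
    has_mu = has_mu, mus = mus, mu_children_idx = mu_children_idx,
    mu_final_g = mu_final_g, mu_concept = mu_concept,
    has_conc = has_conc, concepts = model$concepts,
    sigma_global = p$sigma_global, sigma_local = p$sigma_local,
    need_hist = any(cls == 4L),
    all_ids = c(g_ids, t_ids,
                if (has_mu) mus$id else character(0),
                if (has_conc) model$concepts$id else character(0),
                "mu_domain", "concept_domain")
  )
}

# One run of the fixed-step loop. RNG must already be seeded.
simulate_once <- function(cm, n_steps, record_ts) {
  dt <- cm$dt
  n_g <- cm$n_g; n_t <- cm$n_t; n_o <- cm$n_o

  # event accumulator
  cap <- 256L
  ev_t <- numeric(cap); ev_te <- numeric(cap)
  ev_sys <- integer(cap); ev_kind <- integer(cap)
  n_ev <- 0L
  add_event <- function(t, te, sys, kind) {
    if (n_ev == cap) {
      cap <<- cap * 2L
      length(ev_t) <<- cap; length(ev_te) <<- cap
      length(ev_sys) <<- cap; length(ev_kind) <<- cap
    }
    n_ev <<- n_ev + 1L
    ev_t[n_ev] <<- t; ev_te[n_ev] <<- te
    ev_sys[n_ev] <<- sys; ev_kind[n_ev] <<- kind
  }
  sys_mu0 <- n_g + n_t
  sys_conc0 <- sys_mu0 + (if (cm$has_mu) nrow(cm$mus) else 0L)
  sys_mu_dom <- length(cm$all_ids) - 1L
  sys_conc_dom <- length(cm$all_ids)

  # noise multipliers, frozen per run
  mult <- draw_noise_multipliers(n_t, cm$sigma_global, cm$sigma_local)
  rate_eff <- cm$rate_base * mult

  # state
  gate_g <- rep(FALSE, n_g)
  g <- numeric(n_g)
  gate_t <- cm$gate0
  x <- numeric(n_t)
  phase <- cm$phase0
  rho <- numeric(n_o); rho_dot <- numeric(n_o)
  armed <- rep(TRUE, cm$n_a)
  osc_of_tir <- match(seq_len(n_t), cm$osc_idx)  # tir idx -> osc slot or NA
  # sub-step correction: seconds of source activation missed (gate opened
  # mid-window) or over-counted (closed mid-window) in the last window
  carry <- numeric(n_g)

  if (cm$need_hist || record_ts) {
    g_hist <- matrix(0, n_g, n_steps + 1L)
    carry_hist <- matrix(0, n_g, n_steps + 1L)
  } else {
    g_hist <- NULL
  }
  if (record_ts) {
    ts_x <- matrix(0, n_t, n_steps + 1L)
    ts_gate <- matrix(0, n_g, n_steps + 1L)
    ts_rho <- if (n_o) matrix(0, n_o, n_steps + 1L) else NULL
    ts_phase <- if (n_o) matrix(0, n_o, n_steps + 1L) else NULL
    if (n_o) { ts_phase[, 1L] <- phase }
  }

  # selection state
  if (cm$has_mu) {
    n_mu <- nrow(cm$mus)
    mu_a <- cm$mus$a0
    mu_rate <- cm$mus$rate
    mu_thr <- cm$mus$threshold
    mu_state <- rep(0L, n_mu)          # 0 pending, 1 selected, 2 suppressed
    mu_gate <- rep(!cm$has_conc, n_mu) # open at t=0 only without a concept layer
    mu_carry <- numeric(n_mu)          # seconds over-counted at mid-step re-gating
    ts_mu <- if (record_ts) matrix(0, n_mu, n_steps + 1L) else NULL
    if (record_ts) ts_mu[, 1L] <- mu_a
  }
  if (cm$has_conc) {
    n_conc <- nrow(cm$concepts)
    conc_a <- cm$concepts$a0
    conc_rate <- cm$concepts$rate
    conc_thr <- cm$concepts$threshold
    conc_state <- rep(0L, n_conc)
    conc_gate <- rep(TRUE, n_conc)
    conc_carry <- numeric(n_conc)
    ts_conc <- if (record_ts) matrix(0, n_conc, n_steps + 1L) else NULL
    if (record_ts) ts_conc[, 1L] <- conc_a
  }

  # re-gate a TiR at exact time te within the step ending at tn: states are
  # compensated for the partial window so cascade timing is sub-step exact
  open_tir_gate <- function(k, tn, te) {
    gate_t[k] <<- TRUE
    x[k] <<- if (cm$cls[k] == 1L) rate_eff[k] * (tn - te) else 0
    o <- osc_of_tir[k]
    if (!is.na(o)) phase[o] <<- cm$phase0[o] + rate_eff[k] * (tn - te)
    armed[cm$a_owner == k] <<- TRUE
  }

  suppress_mu <- function(k, tn, te) {
    if (mu_state[k] != 1L) {
      stop(sprintf("state error: suppression of non-selected mu-system '%s'.",
                   cm$mus$id[k]), call. = FALSE)
    }
    mu_state[k] <<- 2L
    mu_a[k] <<- 0
    for (ch in cm$mu_children_idx[[k]]) gate_t[ch] <<- FALSE
    add_event(tn, te, sys_mu0 + k, 7L)
    sibs <- which(cm$mu_concept == cm$mu_concept[k] & mu_state == 0L)
    if (length(sibs) > 0L) {
      mu_gate[sibs] <<- TRUE
      mu_carry[sibs] <<- -(te - (tn - dt))
    } else if (cm$has_conc) {
      ci <- cm$mu_concept[k]
      conc_state[ci] <<- 2L
      conc_a[ci] <<- 0
      add_event(tn, te, sys_conc0 + ci, 7L)
      pending <- which(conc_state == 0L)
      if (length(pending) > 0L) {
        conc_gate[pending] <<- TRUE
        conc_carry[pending] <<- -(te - (tn - dt))
      } else {
        add_event(tn, te, sys_conc_dom, 8L)
      }
    } else {
      add_event(tn, te, sys_mu_dom, 8L)
    }
  }

  nonosc <- which(cm$cls != 2L)
  is_int <- cm$cls %in% c(3L, 5L)
  is_ext <- cm$cls == 4L
  int_idx <- which(is_int); ext_idx <- which(is_ext)
  eps_idx <- which(cm$cls == 1L)
  check_every <- 200L

  for (n in seq_len(n_steps)) {
    tn <- n * dt

    ## --- TiR state updates (inputs read from the previous step) -----------
    x_prev <- x
    if (length(eps_idx)) {
      x[eps_idx] <- x[eps_idx] +
        rate_eff[eps_idx] * as.numeric(gate_t[eps_idx]) * dt
    }
    if (length(int_idx)) {
      src <- cm$source_idx[int_idx]
      x[int_idx] <- x[int_idx] +
        rate_eff[int_idx] * (g[src] * dt + carry[src]) *
          as.numeric(gate_t[int_idx])
    }
    if (length(ext_idx)) {
      col <- n - cm$delay_steps[ext_idx]  # g((n-1)dt - d) is history col n - k
      sel <- cbind(cm$source_idx[ext_idx], pmax(col, 1L))
      inp <- ifelse(col >= 1L, g_hist[sel] * dt + carry_hist[sel], 0)
      x[ext_idx] <- x[ext_idx] +
        rate_eff[ext_idx] * inp * as.numeric(gate_t[ext_idx])
    }
    if (n_o) {
      phase_prev <- phase
      st <- step_oscillators(phase, rho, rho_dot, rate_eff[cm$osc_idx],
                             cm$Phi, gate_t[cm$osc_idx], dt, cm$omega_n)
      phase <- st$phase; rho <- st$rho; rho_dot <- st$rho_dot
      wrapped <- st$wrapped
      phase_raw <- st$phase_raw
    }

    ## --- threshold / phase-trigger detection ------------------------------
    fired <- integer(0)
    fired_te <- numeric(0)
    if (cm$n_a) {
      for (j in seq_len(cm$n_a)) {
        if (!armed[j]) next
        o <- cm$a_owner[j]
        oo <- osc_of_tir[o]
        if (is.na(oo)) {
          if (x_prev[o] < cm$a_tau[j] && cm$a_tau[j] <= x[o]) {
            frac <- (cm$a_tau[j] - x_prev[o]) / (x[o] - x_prev[o])
            fired <- c(fired, j)
            fired_te <- c(fired_te, (n - 1 + frac) * dt)
          }
        } else {
          if (wrapped[oo] && rho[oo] >= cm$amp_thr[oo]) {
            frac <- (2 * pi - phase_prev[oo]) / (phase_raw[oo] - phase_prev[oo])
            fired <- c(fired, j)
            fired_te <- c(fired_te, (n - 1 + frac) * dt)
          }
        }
      }
    }

    ## --- apply actions -----------------------------------------------------
    closed_gestures <- integer(0)
    closed_te <- numeric(0)
    gest_te <- rep(tn, n_g)  # exact times of this step's gate flips
    carry <- numeric(n_g)
    if (length(fired)) {
      for (kk in seq_along(fired)) {
        j <- fired[kk]; te <- fired_te[kk]
        armed[j] <- FALSE
        add_event(tn, te, n_g + cm$a_owner[j], 5L)  # trigger
        ti <- cm$a_tidx[j]
        if (cm$a_is_tir[j]) {
          if (cm$a_open[j]) {
            if (!gate_t[ti]) open_tir_gate(ti, tn, te)
          } else {
            gate_t[ti] <- FALSE
          }
        } else {
          if (cm$a_open[j]) {
            if (!gate_g[ti]) {
              gate_g[ti] <- TRUE
              gest_te[ti] <- te
              carry[ti] <- carry[ti] + (tn - te)
              add_event(tn, te, ti, 1L)
            }
          } else if (gate_g[ti]) {
            gate_g[ti] <- FALSE
            gest_te[ti] <- te
            carry[ti] <- carry[ti] - (tn - te)
            add_event(tn, te, ti, 2L)
            closed_gestures <- c(closed_gestures, ti)
            closed_te <- c(closed_te, te)
          }
        }
      }
    }

    ## --- feedback-induced suppression --------------------------------------
    if (cm$has_mu && length(closed_gestures)) {
      for (kk in seq_along(closed_gestures)) {
        hit <- which(cm$mu_final_g == closed_gestures[kk] & mu_state == 1L)
        for (k in hit) suppress_mu(k, tn, closed_te[kk])
      }
    }

    ## --- competitive selection ---------------------------------------------
    if (cm$has_conc) {
      grow <- conc_gate & conc_state == 0L
      if (any(grow)) {
        a_prev <- conc_a
        conc_a[grow] <- conc_a[grow] +
          conc_rate[grow] * (dt + conc_carry[grow])
        conc_carry[grow] <- 0
        cand <- which(grow & a_prev < conc_thr & conc_a >= conc_thr)
        if (length(cand)) {
          win <- cand[order(-conc_a[cand], cand)][1L]
          frac <- (conc_thr[win] - a_prev[win]) / (conc_a[win] - a_prev[win])
          te <- (n - 1 + frac) * dt
          conc_state[win] <- 1L
          conc_gate[] <- FALSE
          # competitors freeze at their activation at the exact selection
          # time, not at the end of the grid step
          others <- grow & seq_len(n_conc) != win
          conc_a[others] <- conc_a[others] - conc_rate[others] * (tn - te)
          add_event(tn, te, sys_conc0 + win, 6L)
          members <- which(cm$mu_concept == win & mu_state == 0L)
          mu_gate[members] <- TRUE
          mu_carry[members] <- -(te - (tn - dt))
        }
      }
    }
    if (cm$has_mu) {
      grow <- mu_gate & mu_state == 0L
      if (any(grow)) {
        a_prev <- mu_a
        mu_a[grow] <- mu_a[grow] + mu_rate[grow] * (dt + mu_carry[grow])
        mu_carry[grow] <- 0
        cand <- which(grow & a_prev < mu_thr & mu_a >= mu_thr)
        if (length(cand)) {
          win <- cand[order(-mu_a[cand], cand)][1L]
          frac <- (mu_thr[win] - a_prev[win]) / (mu_a[win] - a_prev[win])
          te <- (n - 1 + frac) * dt
          mu_state[win] <- 1L
          mu_gate[] <- FALSE
          others <- grow & seq_len(n_mu) != win
          mu_a[others] <- mu_a[others] - mu_rate[others] * (tn - te)
          add_event(tn, te, sys_mu0 + win, 6L)
          for (ch in cm$mu_children_idx[[win]]) {
            if (!gate_t[ch]) open_tir_gate(ch, tn, te)
          }
        }
      }
    }

    ## --- gestural activation follows the gates ------------------------------
    g_new <- step_gesture(gate_g)
    changed <- which(g_new != g)
    for (i in changed) {
      add_event(tn, gest_te[i], i, if (g_new[i] > 0) 3L else 4L)
    }
    g <- g_new
    if (!is.null(g_hist)) {
      g_hist[, n + 1L] <- g
      carry_hist[, n + 1L] <- carry
    }

    if (record_ts) {
      ts_x[, n + 1L] <- x
      ts_gate[, n + 1L] <- as.numeric(gate_g)
      if (n_o) { ts_rho[, n + 1L] <- rho; ts_phase[, n + 1L] <- phase }
      if (cm$has_mu) ts_mu[, n + 1L] <- mu_a
      if (cm$has_conc) ts_conc[, n + 1L] <- conc_a
    }

    if (n %% check_every == 0L || n == n_steps) {
      bad <- which(!is.finite(x))
      if (n_o && any(!is.finite(rho))) {
        bad <- c(bad, cm$osc_idx[!is.finite(rho)])
      }
      if (length(bad)) {
        stop(sprintf("numerical instability: non-finite state in system '%s' at t = %.4f s.",
                     cm$t_ids[bad[1L]], tn), call. = FALSE)
      }
    }
  }

  out <- list(
    n_ev = n_ev,
    ev_t = ev_t[seq_len(n_ev)], ev_te = ev_te[seq_len(n_ev)],
    ev_sys = ev_sys[seq_len(n_ev)], ev_kind = ev_kind[seq_len(n_ev)]
  )
  if (record_ts) {
    out$ts <- list(
      g = g_hist, x = ts_x, gate = ts_gate,
      rho = if (n_o) ts_rho else NULL,
      phase = if (n_o) ts_phase else NULL,
      mu = if (cm$has_mu) ts_mu else NULL,
      conc = if (cm$has_conc) ts_conc else NULL
    )
  }
  out
}

#' Run a simulation
#'
#' Executes the model's change rules on a fixed grid with forward-Euler
#' integration: TiR states are updated from the previous step's gestural
#' activations (external TiRs from the delayed trace), threshold crossings and
#' phase triggers fire pulse-like actions that flip gates, feedback-induced
#' suppression and the two competitive-selection domains are advanced, and
#' gestural activation follows the gates with single-step transitions. Every
#' threshold crossing produces exactly one event; equal seeds produce
#' identical event logs.
#'
#' @param model A validated [new_tir_model()] / [build_model()] object.
#' @param config A [sim_config()].
#' @return An object of class `tir_sim` with elements `events` (tibble:
#'   `run_id`, `time_s` -- grid-quantized --, `time_exact_s` -- sub-step
#'   interpolated --, `system_id`, `event_kind`), `timeseries` (long tibble,
#'   or NULL if not recorded), `model`, `config`.
#' @examples
#' sim <- run_simulation(build_model("fig5"), sim_config(seed = 1))
#' dplyr::count(sim$events, event_kind)
#' @export
run_simulation <- function(model, config = sim_config()) {
  stopifnot(inherits(model, "tir_model"))
  if (!inherits(config, "sim_config")) stop("`config` must be a sim_config.",
                                            call. = FALSE)
  validate_model(model)
  duration <- config$duration %||% model$duration
  n_steps <- floor(duration / config$dt)
  record_ts <- config$record_timeseries %||% (config$n_runs == 1L)
  cm <- compile_model(model, config)

  ev_list <- vector("list", config$n_runs)
  ts_list <- NULL
  for (run in seq_len(config$n_runs)) {
    set.seed(child_seed(config$seed, run))
    res <- simulate_once(cm, n_steps, record_ts)
    ev_list[[run]] <- tibble::tibble(
      run_id = run,
      time_s = res$ev_t,
      time_exact_s = res$ev_te,
      system_id = cm$all_ids[res$ev_sys],
      event_kind = .EV_KINDS[res$ev_kind]
    )
    if (record_ts && run == 1L) {
      ts_list <- timeseries_tibble(res$ts, cm, n_steps, config$dt)
    }
  }

  structure(
    list(
      events = dplyr::bind_rows(ev_list),
      timeseries = ts_list,
      model = model,
      config = config,
      duration = duration
    ),
    class = "tir_sim"
  )
}

timeseries_tibble <- function(ts, cm, n_steps, dt) {
  tgrid <- seq(0, n_steps) * dt
  long <- function(mat, ids, variable) {
    if (is.null(mat)) return(NULL)
    tibble::tibble(
      run_id = 1L,
      time_s = rep(tgrid, each = nrow(mat)),
      system_id = rep(ids, times = length(tgrid)),
      variable = variable,
      value = as.vector(mat)
    )
  }
  osc_ids <- cm$t_ids[cm$osc_idx]
  dplyr::bind_rows(
    long(ts$g, cm$g_ids, "activation"),
    long(ts$gate, cm$g_ids, "gate"),
    long(ts$x, cm$t_ids, "tir_activation"),
    long(ts$rho, osc_ids, "amplitude"),
    long(ts$phase, osc_ids, "phase"),
    long(ts$mu, if (cm$has_mu) cm$mus$id else NULL, "mu_activation"),
    long(ts$conc, if (cm$has_conc) cm$concepts$id else NULL,
         "concept_activation")
  )
}

#' @export
print.tir_sim <- function(x, ...) {
  cat(sprintf("<tir_sim: %s>\n", x$model$name))
  cat(sprintf("  %d run(s), duration %.3g s at dt = %.4g s; %d event(s)\n",
              x$config$n_runs, x$duration, x$config$dt, nrow(x$events)))
  invisible(x)
}
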