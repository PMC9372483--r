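# Analysis of simulated event logs: interval extraction, Delta-correlation
# Monte-Carlo experiments, and rate sweeps.

#' Extract named timing intervals from a simulation
#'
#' Computes the model's named initiation-to-initiation intervals (e.g. `d12`,
#' `d23` for the three-gesture topologies; `CV1`, `CR1`, `VC1`, `Rc1`, `cr1`
#' per syllable for the hybrid models) and, when gestures carry word
#' membership, word durations (`w<k>_dur`: first initiation to last
#' termination within the word). Interval endpoints use the sub-step
#' interpolated event times, so intervals are not quantized to the grid. A
#' missing initiation yields a flagged record (`flag = "missing_onset"`), not
#' a silent drop.
#'
#' @param sim A `tir_sim`, or an events tibble (then `intervals` and
#'   optionally `gestures` must be given).
#' @param intervals Tibble with columns `name`, `from`, `to`; defaults to the
#'   model's interval table.
#' @param gestures The model's gesture table (for word durations).
#' @return Tibble with columns `run_id`, `name`, `value_ms`, `flag`.
#' @export
extract_intervals <- function(sim, intervals = NULL, gestures = NULL) {
  if (inherits(sim, "tir_sim")) {
    events <- sim$events
    intervals <- intervals %||% sim$model$intervals
    gestures <- gestures %||% sim$model$gestures
  } else {
    events <- sim
  }
  if (is.null(intervals) && is.null(gestures)) {
    stop("no interval specification available.", call. = FALSE)
  }

  onsets <- events |>
    dplyr::filter(event_kind == "activation_on") |>
    dplyr::group_by(run_id, system_id) |>
    dplyr::summarise(onset = min(time_exact_s), .groups = "drop")
  offs_ev <- events |> dplyr::filter(event_kind == "activation_off")
  offsets <- if (nrow(offs_ev) > 0L) {
    offs_ev |>
      dplyr::group_by(run_id, system_id) |>
      dplyr::summarise(offset = max(time_exact_s), .groups = "drop")
  } else {
    tibble::tibble(run_id = integer(), system_id = character(),
                   offset = numeric())
  }

  runs <- sort(unique(events$run_id))
  out <- list()

  if (!is.null(intervals) && nrow(intervals) > 0L) {
    grid <- tidyr::expand_grid(run_id = runs, intervals)
    tab <- grid |>
      dplyr::left_join(onsets, by = c("run_id", from = "system_id")) |>
      dplyr::rename(t_from = onset) |>
      dplyr::left_join(onsets, by = c("run_id", to = "system_id")) |>
      dplyr::rename(t_to = onset) |>
      dplyr::mutate(
        value_ms = 1000 * (t_to - t_from),
        flag = ifelse(is.na(t_from) | is.na(t_to), "missing_onset", "ok")
      ) |>
      dplyr::select(run_id, name, value_ms, flag)
    out[[1L]] <- tab
  }

  if (!is.null(gestures) && any(!is.na(gestures$word))) {
    gw <- gestures[!is.na(gestures$word), c("id", "word")]
    wd <- onsets |>
      dplyr::inner_join(gw, by = c(system_id = "id")) |>
      dplyr::left_join(offsets, by = c("run_id", "system_id")) |>
      dplyr::group_by(run_id, word) |>
      dplyr::summarise(
        value_ms = 1000 * (max(offset) - min(onset)),
        flag = ifelse(any(is.na(offset)), "missing_offset", "ok"),
        .groups = "drop"
      ) |>
      dplyr::mutate(name = paste0("w", word, "_dur")) |>
      dplyr::select(run_id, name, value_ms, flag)
    # words whose gestures never activated at all
    expected <- tidyr::expand_grid(run_id = runs,
                                   name = paste0("w", sort(unique(gw$word)), "_dur"))
    wd <- expected |>
      dplyr::left_join(wd, by = c("run_id", "name")) |>
      dplyr::mutate(flag = ifelse(is.na(value_ms), "missing_onset", flag))
    out[[length(out) + 1L]] <- wd
  }

  dplyr::bind_rows(out) |> dplyr::arrange(run_id, name)
}

#' Correlation of successive inter-initiation intervals
#'
#' The Pearson correlation, across Monte-Carlo runs, between two named
#' intervals (by default the successive initiation intervals `d12` and
#' `d23`). Correlations rather than durations are the diagnostic of control
#' topology: under global versus local rate noise, different topologies
#' produce characteristic correlation signatures. Runs with flagged intervals
#' are dropped; a result from fewer than 3 complete runs, or with zero
#' variance in either interval, is flagged rather than propagating NaN.
#'
#' @param interval_table Output of [extract_intervals()].
#' @param x,y Interval names to correlate.
#' @return One-row tibble: `r`, `n`, `ci_lo`, `ci_hi` (Fisher 95% CI),
#'   `flag` (`"ok"`, `"too_few_runs"`, or `"degenerate_variance"`).
#' @examples
#' tab <- tibble::tibble(run_id = 1:3,
#'                       name = rep("d12", 3), value_ms = c(1, 2, 3),
#'                       flag = "ok") |>
#'   dplyr::bind_rows(tibble::tibble(run_id = 1:3, name = "d23",
#'                                   value_ms = c(2, 4, 6), flag = "ok"))
#' delta_correlation(tab)  # r = 1
#' @export
delta_correlation <- function(interval_table, x = "d12", y = "d23") {
  wide <- interval_table |>
    dplyr::filter(name %in% c(x, y), flag == "ok") |>
    dplyr::select(run_id, name, value_ms) |>
    tidyr::pivot_wider(names_from = name, values_from = value_ms) |>
    tidyr::drop_na()
  n <- nrow(wide)
  if (n < 3L || !all(c(x, y) %in% names(wide))) {
    return(tibble::tibble(r = NA_real_, n = n, ci_lo = NA_real_,
                          ci_hi = NA_real_, flag = "too_few_runs"))
  }
  vx <- wide[[x]]; vy <- wide[[y]]
  if (stats::sd(vx) == 0 || stats::sd(vy) == 0) {
    return(tibble::tibble(r = NA_real_, n = n, ci_lo = NA_real_,
                          ci_hi = NA_real_, flag = "degenerate_variance"))
  }
  r <- stats::cor(vx, vy)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(max(n - 3, 1))
  tibble::tibble(r = r, n = n,
                 ci_lo = tanh(z - 1.96 * se), ci_hi = tanh(z + 1.96 * se),
                 flag = "ok")
}

#' Delta-correlation surface over a noise grid
#'
#' Crosses global and local noise levels (excluding the doubly-deterministic
#' zero/zero cell, where the correlation is undefined) and computes the
#' Delta-correlation of a model at each cell by Monte-Carlo simulation.
#'
#' @param model_name Zoo name (see [list_models()]) or a `tir_model`.
#' @param noise_grid List with numeric vectors `sigma_global` and
#'   `sigma_local`; default the shipped 5-level grid (0 to 10% in 2.5% steps).
#' @param n_runs Runs per cell.
#' @param seed Root seed; each cell uses a counter-derived child seed.
#' @param x,y Interval names to correlate.
#' @param dt Time step in seconds.
#' @param lambda Optional control-variable override for zoo models.
#' @return A tibble of class `tir_corr_surface`: `sigma_global`,
#'   `sigma_local`, `r`, `n`, `ci_lo`, `ci_hi`, `flag`.
#' @export
corr_experiment <- function(model_name, noise_grid = NULL, n_runs = 200,
                            seed = 1L, x = "d12", y = "d23", dt = 0.001,
                            lambda = NULL) {
  if (n_runs < 3) stop("`n_runs` must be at least 3.", call. = FALSE)
  grid_levels <- noise_grid %||% {
    lv <- default_calibration()$noise$grid
    list(sigma_global = lv, sigma_local = lv)
  }
  cells <- tidyr::expand_grid(sigma_global = grid_levels$sigma_global,
                              sigma_local = grid_levels$sigma_local) |>
    dplyr::filter(!(sigma_global == 0 & sigma_local == 0))

  base_model <- if (inherits(model_name, "tir_model")) model_name
                else build_model(model_name, lambda = lambda)

  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    m <- base_model
    m$params$sigma_global <- cells$sigma_global[i]
    m$params$sigma_local <- cells$sigma_local[i]
    sim <- run_simulation(m, sim_config(dt = dt,
                                        seed = child_seed(seed, i * 131L),
                                        n_runs = n_runs,
                                        record_timeseries = FALSE))
    res[[i]] <- dplyr::bind_cols(cells[i, ],
                                 delta_correlation(extract_intervals(sim),
                                                   x = x, y = y))
  }
  out <- dplyr::bind_rows(res)
  class(out) <- c("tir_corr_surface", class(out))
  attr(out, "model_name") <- base_model$name
  out
}

#' Speech-rate sweep
#'
#' Runs a model (by default the rate-control utterance) across a grid of the
#' control variable lambda with noise off, returning the named intervals and
#' word durations at each rate. Oscillator-governed (prevocalic) intervals
#' plateau at extreme lambda because the pace map saturates at the frequency
#' bounds; feedback-governed (vocalic/post-vocalic) intervals keep growing
#' with lambda.
#'
#' @param lambda_grid Values of lambda in `[0, 1]`; default 11 evenly spaced.
#' @param seed Seed (the sweep itself is deterministic; the seed fixes the RNG
#'   stream regardless).
#' @param model_name Zoo name or a function(lambda) returning a `tir_model`.
#' @param dt Time step in seconds.
#' @return A tibble of class `tir_sweep`: `lambda`, `name`, `value_ms`,
#'   `flag`.
#' @export
rate_sweep <- function(lambda_grid = seq(0, 1, length.out = 11),
                       seed = 1L, model_name = "fig13_rate_utterance",
                       dt = 0.001) {
  if (any(lambda_grid < 0 | lambda_grid > 1)) {
    stop("`lambda_grid` must lie in [0, 1].", call. = FALSE)
  }
  builder <- if (is.function(model_name)) model_name
             else function(l) build_model(model_name, lambda = l)
  res <- purrr::map(lambda_grid, function(l) {
    sim <- run_simulation(builder(l),
                          sim_config(dt = dt, seed = seed,
                                     record_timeseries = FALSE))
    extract_intervals(sim) |>
      dplyr::mutate(lambda = l) |>
      dplyr::select(lambda, name, value_ms, flag)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("tir_sweep", class(out))
  out
}

#' Endpoint-versus-centre slope ratios of a sweep
#'
#' For each interval in a [rate_sweep()] table, the ratio of the absolute
#' slope over the extreme lambda segments (`[0, 0.1]` and `[0.9, 1]`) to the
#' absolute slope over the central segment (`[0.45, 0.55]`, i.e. the two grid
#' values bracketing 0.5). Ratios below the threshold are labelled plateaus.
#'
#' @param sweep A `tir_sweep`.
#' @param threshold Plateau labelling threshold on the slope ratio.
#' @return Tibble: `name`, `ratio_low`, `ratio_high`, `plateau_low`,
#'   `plateau_high`.
#' @export
plateau_ratios <- function(sweep, threshold = 0.5) {
  lam <- sort(unique(sweep$lambda))
  if (length(lam) < 3L) stop("sweep needs at least 3 lambda values.",
                             call. = FALSE)
  lo <- lam[1:2]
  hi <- lam[(length(lam) - 1):length(lam)]
  mid <- lam[order(abs(lam - 0.5))][1:2]
  slope <- function(df, seg) {
    d <- df[df$lambda %in% seg, ]
    if (nrow(d) < 2L || any(is.na(d$value_ms))) return(NA_real_)
    abs(diff(d$value_ms[order(d$lambda)])) / abs(diff(sort(seg)))
  }
  sweep |>
    dplyr::filter(flag == "ok") |>
    dplyr::group_by(name) |>
    dplyr::group_modify(function(df, key) {
      sl <- slope(df, lo); sh <- slope(df, hi); sm <- slope(df, mid)
      tibble::tibble(
        ratio_low = sl / sm, ratio_high = sh / sm,
        plateau_low = !is.na(sl / sm) && sl / sm < threshold,
        plateau_high = !is.na(sh / sm) && sh / sm < threshold
      )
    }) |>
    dplyr::ungroup()
}
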