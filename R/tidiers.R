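# broom-style tidiers for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation into its event log
#'
#' @param x A `tir_sim`.
#' @param ... Unused.
#' @return The events tibble (`run_id`, `time_s`, `time_exact_s`,
#'   `system_id`, `event_kind`).
#' @method tidy tir_sim
#' @export
tidy.tir_sim <- function(x, ...) x$events

#' One-row summary of a simulation
#'
#' @param x A `tir_sim`.
#' @param ... Unused.
#' @return Tibble with the model name, run count, step, duration, seed and
#'   event count.
#' @method glance tir_sim
#' @export
glance.tir_sim <- function(x, ...) {
  tibble::tibble(
    model = x$model$name,
    n_runs = x$config$n_runs,
    dt = x$config$dt,
    duration_s = x$duration,
    seed = x$config$seed,
    n_events = nrow(x$events)
  )
}

#' @rdname tidy.tir_sim
#' @method tidy tir_corr_surface
#' @export
tidy.tir_corr_surface <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @rdname glance.tir_sim
#' @method glance tir_corr_surface
#' @export
glance.tir_corr_surface <- function(x, ...) {
  ok <- x[x$flag == "ok", ]
  tibble::tibble(
    model = attr(x, "model_name") %||% NA_character_,
    n_cells = nrow(x),
    r_min = min(ok$r), r_max = max(ok$r),
    n_runs_per_cell = max(x$n)
  )
}

#' @rdname tidy.tir_sim
#' @method tidy tir_sweep
#' @export
tidy.tir_sweep <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @rdname glance.tir_sim
#' @method glance tir_sweep
#' @export
glance.tir_sweep <- function(x, ...) {
  tibble::tibble(
    n_lambda = length(unique(x$lambda)),
    n_intervals = length(unique(x$name)),
    lambda_min = min(x$lambda), lambda_max = max(x$lambda)
  )
}
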