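# ggplot2 display methods.

#' Plot a simulation as a gestural score
#'
#' Activation intervals of each gestural system as horizontal segments
#' (first run), the standard "gestural score" display.
#'
#' @param object A `tir_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tir_sim
#' @export
autoplot.tir_sim <- function(object, ...) {
  ev <- object$events |>
    dplyr::filter(run_id == 1L,
                  event_kind %in% c("activation_on", "activation_off"))
  ons <- ev |>
    dplyr::filter(event_kind == "activation_on") |>
    dplyr::group_by(system_id) |>
    dplyr::mutate(k = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select(system_id, k, t_on = time_s)
  offs <- ev |>
    dplyr::filter(event_kind == "activation_off") |>
    dplyr::group_by(system_id) |>
    dplyr::mutate(k = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select(system_id, k, t_off = time_s)
  segs <- dplyr::left_join(ons, offs, by = c("system_id", "k")) |>
    dplyr::mutate(t_off = ifelse(is.na(t_off), object$duration, t_off))
  ggplot2::ggplot(segs,
                  ggplot2::aes(x = t_on, xend = t_off,
                               y = system_id, yend = system_id)) +
    ggplot2::geom_segment(linewidth = 4, colour = "grey35") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = paste0("Gestural activation intervals: ",
                                 object$model$name)) +
    ggplot2::theme_minimal()
}

#' Plot a Delta-correlation surface
#'
#' Correlation against local noise level, one line per global noise level --
#' the standard display for reading off how a control topology responds to
#' the local/global noise balance.
#'
#' @param object A `tir_corr_surface`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tir_corr_surface
#' @export
autoplot.tir_corr_surface <- function(object, ...) {
  df <- tidy.tir_corr_surface(object) |> dplyr::filter(flag == "ok")
  ggplot2::ggplot(df, ggplot2::aes(x = sigma_local, y = r,
                                   colour = factor(sigma_global),
                                   group = factor(sigma_global))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = ci_lo, ymax = ci_hi,
                                      fill = factor(sigma_global)),
                         alpha = 0.15, colour = NA) +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(x = "local noise level", y = "Delta-correlation r",
                  colour = "global noise", fill = "global noise",
                  title = attr(object, "model_name")) +
    ggplot2::theme_minimal()
}

#' Plot a rate sweep
#'
#' Interval durations against the control variable lambda, one facet per
#' interval.
#'
#' @param object A `tir_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tir_sweep
#' @export
autoplot.tir_sweep <- function(object, ...) {
  df <- tidy.tir_sweep(object) |> dplyr::filter(flag == "ok")
  ggplot2::ggplot(df, ggplot2::aes(x = lambda, y = value_ms)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = expression(lambda), y = "interval (ms)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
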