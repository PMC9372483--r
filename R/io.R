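# Configuration parsing/validation, result serialization, run manifests,
# and Praat TextGrid export.

.CFG_SCHEMA <- list(
  model = NULL,
  sim = c("dt", "duration", "seed", "n_runs"),
  attention = c("lambda", "beta_internal", "beta_external"),
  pace = c("lambda", "f_min_hz", "f_max_hz", "slope"),
  boosts = c("word_final", "utterance_final"),
  noise = c("sigma_global", "sigma_local"),
  feedback = c("delay_s")
)

check_keys <- function(x, allowed, path) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("config error at ", path, ".", extra[1L], ": unknown key.",
         call. = FALSE)
  }
}

#' Load and validate a simulation configuration
#'
#' Reads a JSON configuration naming a zoo model plus optional overrides,
#' validates it against the schema (unknown keys are rejected with the key
#' path; out-of-range values and `beta_internal >= beta_external` are
#' validation errors), fills defaults, and returns the assembled model and
#' simulation configuration.
#'
#' @param path Path to a JSON config file.
#' @return List with elements `model` (a `tir_model`), `config`
#'   (a [sim_config()]), and `raw` (the parsed, default-filled config list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_keys(cfg, names(.CFG_SCHEMA), "config")
  for (sec in setdiff(names(.CFG_SCHEMA), "model")) {
    if (!is.null(cfg[[sec]])) check_keys(cfg[[sec]], .CFG_SCHEMA[[sec]], sec)
  }
  if (is.null(cfg$model)) stop("config error at model: required.", call. = FALSE)
  if (!cfg$model %in% list_models()) {
    stop("config error at model: unknown model '", cfg$model, "'.",
         call. = FALSE)
  }
  for (sec in c("attention", "pace")) {
    l <- cfg[[sec]]$lambda
    if (!is.null(l) && (l < 0 || l > 1)) {
      stop("config error at ", sec, ".lambda: must lie in [0, 1].",
           call. = FALSE)
    }
  }

  lambda <- cfg$attention$lambda %||% NULL
  model <- build_model(cfg$model,
                       lambda = if (!is.null(lambda)) as.numeric(lambda),
                       sigma_global = as.numeric(cfg$noise$sigma_global %||% 0),
                       sigma_local = as.numeric(cfg$noise$sigma_local %||% 0),
                       delay = if (!is.null(cfg$feedback$delay_s))
                         as.numeric(cfg$feedback$delay_s))
  if (!is.null(cfg$attention$beta_internal)) {
    model$params$beta_internal <- cfg$attention$beta_internal
  }
  if (!is.null(cfg$attention$beta_external)) {
    model$params$beta_external <- cfg$attention$beta_external
  }
  if (!is.null(cfg$pace$lambda)) model$params$lambda_pace <- cfg$pace$lambda
  if (!is.null(cfg$pace$f_min_hz)) model$params$f_min <- cfg$pace$f_min_hz
  if (!is.null(cfg$pace$f_max_hz)) model$params$f_max <- cfg$pace$f_max_hz
  if (!is.null(cfg$pace$slope)) model$params$pace_slope <- cfg$pace$slope
  if (!is.null(cfg$boosts)) {
    model$params$gamma_word_final <- cfg$boosts$word_final %||% 1
    model$params$gamma_utterance_final <- cfg$boosts$utterance_final %||% 1
    model <- apply_final_position_boost(model)
  }
  validate_model(model)

  config <- sim_config(
    dt = cfg$sim$dt %||% 0.001,
    duration = cfg$sim$duration %||% NULL,
    seed = cfg$sim$seed %||% 1L,
    n_runs = cfg$sim$n_runs %||% 1L
  )
  filled <- utils::modifyList(list(
    sim = list(dt = config$dt, seed = config$seed, n_runs = config$n_runs),
    noise = list(sigma_global = model$params$sigma_global,
                 sigma_local = model$params$sigma_local)
  ), cfg)
  list(model = model, config = config, raw = filled)
}

#' Serialize a configuration to JSON
#'
#' Writes the default-filled configuration list (as returned in `$raw` by
#' [load_config()]) so that load -> write -> load round-trips.
#'
#' @param cfg A config list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write / read an event log as CSV
#'
#' Columns: `run_id`, `time_s` (grid-quantized), `time_exact_s` (sub-step
#' interpolated), `system_id`, `event_kind`.
#'
#' @param sim A `tir_sim` or an events tibble.
#' @param path Output path.
#' @return `path` (write) or the events tibble (read).
#' @export
write_events <- function(sim, path) {
  events <- if (inherits(sim, "tir_sim")) sim$events else sim
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a timeseries as long CSV
#'
#' Columns: `run_id`, `time_s`, `system_id`, `variable`, `value`.
#'
#' @param sim A `tir_sim` with a recorded timeseries.
#' @param path Output path.
#' @export
write_timeseries <- function(sim, path) {
  ts <- if (inherits(sim, "tir_sim")) sim$timeseries else sim
  if (is.null(ts)) stop("no timeseries recorded.", call. = FALSE)
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' A JSON manifest recording the configuration hash, seed, package version,
#' timestamp and output file list, written atomically alongside every output
#' set; re-running with the manifest's seed and config reproduces the outputs
#' exactly.
#'
#' @param path Manifest path (JSON).
#' @param cfg The configuration list that produced the outputs.
#' @param seed The root seed used.
#' @param outputs Character vector of output file paths.
#' @export
write_run_manifest <- function(path, cfg, seed, outputs) {
  manifest <- list(
    config_hash = rlang::hash(cfg),
    seed = as.integer(seed),
    package_version = as.character(utils::packageVersion("tirsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(basename(outputs))
  )
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Export gestural activation intervals as a Praat TextGrid
#'
#' One interval tier per gestural system (label "g" inside activation
#' intervals, empty outside), ordered by role (C, R, V, c, r, then unlabelled
#' systems) and syllable. Only single-run simulations are exported.
#'
#' @param sim A `tir_sim` (single run).
#' @param path Output path (`.TextGrid`).
#' @return `path`, invisibly.
#' @export
export_textgrid <- function(sim, path) {
  stopifnot(inherits(sim, "tir_sim"))
  events <- sim$events |> dplyr::filter(run_id == 1L)
  xmax <- sim$duration
  gestures <- sim$model$gestures
  role_rank <- match(gestures$role, c("C", "R", "V", "c", "r"))
  role_rank[is.na(role_rank)] <- 99L
  ord <- order(role_rank, gestures$syll, gestures$id)
  ids <- gestures$id[ord]

  tier_intervals <- function(id) {
    ev <- events |>
      dplyr::filter(system_id == id,
                    event_kind %in% c("activation_on", "activation_off")) |>
      dplyr::arrange(time_s)
    ons <- ev$time_s[ev$event_kind == "activation_on"]
    offs <- ev$time_s[ev$event_kind == "activation_off"]
    if (length(offs) < length(ons)) offs <- c(offs, xmax)
    segs <- list()
    cur <- 0
    for (k in seq_along(ons)) {
      if (ons[k] > cur) segs[[length(segs) + 1L]] <- c(cur, ons[k], "")
      segs[[length(segs) + 1L]] <- c(ons[k], offs[k], "g")
      cur <- offs[k]
    }
    if (cur < xmax) segs[[length(segs) + 1L]] <- c(cur, xmax, "")
    if (!length(segs)) segs <- list(c(0, xmax, ""))
    segs
  }

  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('File type = "ooTextFile"')
  w('Object class = "TextGrid"')
  w('')
  w('xmin = 0')
  w('xmax = %.6f', xmax)
  w('tiers? <exists>')
  w('size = %d', length(ids))
  w('item []:')
  for (i in seq_along(ids)) {
    segs <- tier_intervals(ids[i])
    w('    item [%d]:', i)
    w('        class = "IntervalTier"')
    w('        name = "%s"', ids[i])
    w('        xmin = 0')
    w('        xmax = %.6f', xmax)
    w('        intervals: size = %d', length(segs))
    for (k in seq_along(segs)) {
      w('        intervals [%d]:', k)
      w('            xmin = %.6f', as.numeric(segs[[k]][1]))
      w('            xmax = %.6f', as.numeric(segs[[k]][2]))
      w('            text = "%s"', segs[[k]][3])
    }
  }
  invisible(path)
}
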