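# The tir_model container: system inventories, topology, and parameters.

#' Construct a model of gestural systems and their temporal control
#'
#' Low-level constructor assembling a complete control topology: gestural
#' systems with their binary gates, TiRs of the five classes with their
#' threshold actions, an oscillator coupling matrix, and (optionally) the two
#' competitive-selection domains (mu-systems and concept systems). Most users
#' should start from [build_model()], which ships calibrated configurations.
#'
#' @param name Model name (a label).
#' @param gestures Tibble with columns `id`, `role` (one of C, R, V, c, r or
#'   NA), `word`, `syll` (integers or NA).
#' @param tirs Tibble with columns `id`, `class` (one of `"eps"`, `"osc"`,
#'   `"T_int"`, `"T_ext"`, `"T_intra"`), `rate` (growth rate omega for `eps`,
#'   angular frequency for `osc` unless `use_pace`, base integration rate
#'   alpha-prime otherwise), `source` (gesture id for integrators), `delay`
#'   (sensory delay in s, external TiRs), `gate0` (open at t = 0?),
#'   `use_pace` (oscillators driven by the pace map?), `phase0` (initial
#'   phase, oscillators), `amp_threshold` (trigger amplitude threshold),
#'   `beta_boost` (selectional-anticipation multiplier on beta), `mu`
#'   (owning mu-system id or NA).
#' @param actions Tibble with columns `tir`, `target` (a gesture id or, with
#'   prefix `tir:`, a TiR id), `effect` (`"open"`/`"close"`), `tau`
#'   (threshold; NA for oscillator phase triggers).
#' @param coupling Square named coupling matrix over the oscillator ids, or
#'   NULL.
#' @param mus,concepts Tibbles describing the competitive-selection domains
#'   (see [compile_utterance()]), or NULL.
#' @param mu_children Named list: mu id -> character vector of TiR ids
#'   de-gated when the mu-system is selected.
#' @param params Named list of modulation parameters (lambda_attention,
#'   lambda_pace, beta_internal, beta_external, f_min, f_max, pace_slope,
#'   sigma_global, sigma_local, amp_rise_s, gamma_word_final,
#'   gamma_utterance_final).
#' @param intervals Tibble with columns `name`, `from`, `to`: the named
#'   initiation-to-initiation intervals this model is analysed with.
#' @param duration Default simulated duration in seconds.
#' @return An object of class `tir_model`.
#' @export
new_tir_model <- function(name, gestures, tirs, actions, coupling = NULL,
                          mus = NULL, concepts = NULL, mu_children = NULL,
                          params = list(), intervals = NULL, duration = 1) {
  defaults <- list(
    lambda_attention = 0, lambda_pace = 0.5,
    beta_internal = 1, beta_external = 4,
    f_min = 3, f_max = 8, pace_slope = 0.15,
    sigma_global = 0, sigma_local = 0,
    amp_rise_s = 0.05,
    gamma_word_final = 1, gamma_utterance_final = 1
  )
  params <- utils::modifyList(defaults, params)

  stopifnot(all(c("id", "class", "rate") %in% names(tirs)))
  fill <- list(source = NA_character_, delay = 0, gate0 = TRUE,
               use_pace = FALSE, phase0 = NA_real_, amp_threshold = 0.5,
               beta_boost = 1, mu = NA_character_)
  for (col in names(fill)) {
    if (!col %in% names(tirs)) tirs[[col]] <- fill[[col]]
  }
  # bind_rows of partial blocks leaves NAs; restore scalar defaults
  for (col in c("delay", "gate0", "use_pace", "amp_threshold", "beta_boost")) {
    tirs[[col]][is.na(tirs[[col]])] <- fill[[col]]
  }
  for (col in c("role", "word", "syll")) {
    if (!col %in% names(gestures)) gestures[[col]] <- NA
  }
  if (!"tau" %in% names(actions)) actions$tau <- NA_real_

  model <- structure(
    list(
      name = name,
      gestures = tibble::as_tibble(gestures),
      tirs = tibble::as_tibble(tirs),
      actions = tibble::as_tibble(actions),
      coupling = coupling,
      mus = if (!is.null(mus)) tibble::as_tibble(mus) else NULL,
      concepts = if (!is.null(concepts)) tibble::as_tibble(concepts) else NULL,
      mu_children = mu_children,
      params = params,
      intervals = if (!is.null(intervals)) tibble::as_tibble(intervals) else NULL,
      duration = duration
    ),
    class = "tir_model"
  )
  model
}

#' Validate a model's topology and parameters
#'
#' Checks that every reference resolves (no TiR acts on a nonexistent gate, no
#' integrator reads a nonexistent gesture), that the oscillator coupling
#' matrix is square with zero diagonal, that thresholds are non-negative, that
#' `beta_internal < beta_external` (required for the internal-to-external
#' control transition to exist), and that selection gradients are well formed.
#' Ties in gradient values are resolved by lowest index and flagged with a
#' warning.
#'
#' @param model A `tir_model`.
#' @return The model, invisibly; stops with a configuration error otherwise.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "tir_model"))
  g_ids <- model$gestures$id
  t_ids <- model$tirs$id
  if (anyDuplicated(c(g_ids, t_ids))) {
    stop("configuration error: duplicated system ids.", call. = FALSE)
  }
  cls_ok <- model$tirs$class %in% c("eps", "osc", "T_int", "T_ext", "T_intra")
  if (!all(cls_ok)) {
    stop("configuration error: unknown TiR class ",
         paste(unique(model$tirs$class[!cls_ok]), collapse = ", "),
         call. = FALSE)
  }
  if (any(model$tirs$rate < 0, na.rm = TRUE)) {
    stop("configuration error: negative TiR rate.", call. = FALSE)
  }
  integ <- model$tirs$class %in% c("T_int", "T_ext", "T_intra")
  bad_src <- integ & !(model$tirs$source %in% g_ids)
  if (any(bad_src)) {
    stop("configuration error: integrator TiR(s) ",
         paste(model$tirs$id[bad_src], collapse = ", "),
         " reference nonexistent source gesture(s): ",
         paste(unique(model$tirs$source[bad_src]), collapse = ", "),
         call. = FALSE)
  }
  # intra-gestural TiRs may only source from and act on their own gesture
  intra <- which(model$tirs$class == "T_intra")
  for (i in intra) {
    acts <- model$actions[model$actions$tir == model$tirs$id[i], ]
    if (any(acts$target != model$tirs$source[i])) {
      stop("configuration error: intra-gestural TiR ", model$tirs$id[i],
           " acts outside its own gesture.", call. = FALSE)
    }
  }
  # action targets resolve
  tgt <- model$actions$target
  is_tir_tgt <- startsWith(tgt, "tir:")
  tgt_plain <- sub("^tir:", "", tgt)
  ok <- ifelse(is_tir_tgt, tgt_plain %in% t_ids, tgt_plain %in% g_ids)
  if (!all(ok)) {
    stop("configuration error: action target(s) ",
         paste(unique(tgt[!ok]), collapse = ", "),
         " do not name an existing system.", call. = FALSE)
  }
  if (!all(model$actions$tir %in% t_ids)) {
    stop("configuration error: action owner TiR not found.", call. = FALSE)
  }
  if (any(model$actions$tau < 0, na.rm = TRUE)) {
    stop("configuration error: negative action threshold.", call. = FALSE)
  }
  osc <- model$tirs$id[model$tirs$class == "osc"]
  if (length(osc) > 0L) {
    Phi <- model$coupling
    if (is.null(Phi)) Phi <- matrix(0, length(osc), length(osc),
                                    dimnames = list(osc, osc))
    if (!is.matrix(Phi) || nrow(Phi) != ncol(Phi) ||
        !setequal(rownames(Phi), osc)) {
      stop("configuration error: coupling matrix must be square over the ",
           "oscillator ids.", call. = FALSE)
    }
    if (any(diag(Phi) != 0)) {
      stop("configuration error: oscillators may not couple to themselves.",
           call. = FALSE)
    }
  }
  p <- model$params
  if (!(p$beta_internal < p$beta_external)) {
    stop("validation error: beta_internal must be < beta_external (the ",
         "internal-to-external control transition requires it).",
         call. = FALSE)
  }
  if (p$lambda_attention < 0 || p$lambda_attention > 1 ||
      p$lambda_pace < 0 || p$lambda_pace > 1) {
    stop("validation error: lambda must lie in [0, 1].", call. = FALSE)
  }
  if (!(p$f_min < p$f_max)) {
    stop("validation error: f_min must be < f_max.", call. = FALSE)
  }
  if (!is.null(model$mus) && nrow(model$mus) > 0L) {
    mus <- model$mus
    if (!all(mus$final_gesture %in% g_ids)) {
      stop("configuration error: mu final_gesture not found.", call. = FALSE)
    }
    for (mu_id in names(model$mu_children %||% list())) {
      kids <- model$mu_children[[mu_id]]
      if (!all(kids %in% t_ids)) {
        stop("configuration error: mu children of ", mu_id,
             " reference unknown TiRs.", call. = FALSE)
      }
    }
    split_by <- if (!is.null(model$concepts)) mus$concept else rep(1L, nrow(mus))
    for (grp in split(mus$a0, split_by)) {
      if (anyDuplicated(grp)) {
        warning("tied gradient values in a competitive-selection set; ",
                "ties resolve to the lowest index.", call. = FALSE)
      }
    }
    if (!is.null(model$concepts) && !all(mus$concept %in% model$concepts$id)) {
      stop("configuration error: mu references unknown concept system.",
           call. = FALSE)
    }
  }
  invisible(model)
}

#' @export
print.tir_model <- function(x, ...) {
  cat(sprintf("<tir_model: %s>\n", x$name))
  cat(sprintf("  %d gestural system(s), %d TiR(s), %d action(s)\n",
              nrow(x$gestures), nrow(x$tirs), nrow(x$actions)))
  if (!is.null(x$mus)) {
    cat(sprintf("  selection: %d mu-system(s)%s\n", nrow(x$mus),
                if (!is.null(x$concepts)) {
                  sprintf(", %d concept system(s)", nrow(x$concepts))
                } else ""))
  }
  cat(sprintf("  lambda_attention = %.3g, lambda_pace = %.3g, noise (g, l) = (%.3g, %.3g)\n",
              x$params$lambda_attention, x$params$lambda_pace,
              x$params$sigma_global, x$params$sigma_local))
  invisible(x)
}
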