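# Model zoo: calibrated control topologies for the simulation experiments,
# and the utterance compiler that turns syllable strings into inventories.

.ZOO <- c(
  "fig5", "fig6", "fig7",
  "fig8_shared_trigger", "fig8_coupled_osc", "fig8_chain_external",
  "fig8_chain_internal", "fig8_independent", "fig8_hybrid",
  "fig9d_hybrid_cvc", "fig11_three_cv", "fig12_multiword",
  "fig13_rate_utterance", "geminate_demo"
)

#' List the built-in models
#'
#' @return Character vector of zoo model names accepted by [build_model()].
#' @export
list_models <- function() .ZOO

#' Build a calibrated model from the zoo
#'
#' Returns a fully parameterized, schema-valid model. The zoo covers the
#' demonstration topologies: minimal clock/integrator control (`fig5`,
#' `fig6`), phase-coupled oscillator triggering with symmetric displacement
#' (`fig7`), the six three-gesture noise-correlation topologies (`fig8_*`),
#' the hybrid CVC syllable in which prevocalic initiation is
#' oscillator-governed and vocalic/post-vocalic timing is feedback-governed
#' (`fig9d_hybrid_cvc`), competitive selection of three CV syllables
#' (`fig11_three_cv`), parallel conceptual and gestural-motoric selection
#' domains (`fig12_multiword`), the rate-control utterance with
#' selectional-anticipation boosts (`fig13_rate_utterance`), and a
#' cross-word geminate demonstration (`geminate_demo`).
#'
#' @param name A zoo name (see [list_models()]).
#' @param lambda Self-attention/pace control variable in `[0, 1]`; a single
#'   lambda drives both maps (the rate-control setup). Defaults to 0.5 for the
#'   hybrid/selection models and 0 for the fig5-fig8 demonstrations.
#' @param sigma_global,sigma_local Multiplicative rate-noise scales (default
#'   0: deterministic).
#' @param delay External (sensory) feedback delay in seconds; default from the
#'   shipped calibration.
#' @param calib Calibration constants; default [default_calibration()].
#' @return A `tir_model`.
#' @examples
#' m <- build_model("fig9d_hybrid_cvc", lambda = 0.5)
#' @export
build_model <- function(name, lambda = NULL, sigma_global = 0,
                        sigma_local = 0, delay = NULL,
                        calib = default_calibration()) {
  if (!is.character(name) || length(name) != 1L || !(name %in% .ZOO)) {
    stop("unknown model '", name, "'. Available models: ",
         paste(.ZOO, collapse = ", "), call. = FALSE)
  }
  d <- delay %||% calib$feedback$delay_s
  model <- switch(
    name,
    fig5 = model_fig5(),
    fig6 = model_fig6(d),
    fig7 = model_fig7(),
    fig8_shared_trigger = model_fig8("shared", d),
    fig8_coupled_osc = model_fig8("osc", d),
    fig8_chain_external = model_fig8("chain_ext", d),
    fig8_chain_internal = model_fig8("chain_int", d),
    fig8_independent = model_fig8("independent", d),
    fig8_hybrid = model_fig8("hybrid", d),
    fig9d_hybrid_cvc = compile_utterance(list("CVC"), selection = FALSE,
                                         lambda = lambda %||% 0.5,
                                         delay = d, calib = calib,
                                         name = "fig9d_hybrid_cvc",
                                         duration = 1.5),
    fig11_three_cv = compile_utterance(list(c("CV", "CV", "CV")),
                                       concepts = FALSE,
                                       lambda = lambda %||% 0.5,
                                       delay = d, calib = calib,
                                       name = "fig11_three_cv",
                                       duration = 3.2),
    fig12_multiword = compile_utterance(
      list(c("CV", "CV"), c("CV", "CV", "CV"), "CV", c("CV", "CV", "CV")),
      lambda = lambda %||% 0.5, delay = d, calib = calib,
      name = "fig12_multiword", duration = 9
    ),
    fig13_rate_utterance = {
      m <- compile_utterance(list("CVC", "CV", "CVC"),
                             lambda = lambda %||% 0.5, delay = d,
                             calib = calib, name = "fig13_rate_utterance",
                             duration = 5.5)
      m$params$gamma_word_final <- calib$boosts$word_final
      m$params$gamma_utterance_final <- calib$boosts$utterance_final
      apply_final_position_boost(m)
    },
    geminate_demo = compile_utterance(
      list(list(c("C", "R", "V", "c")), list(c("R", "V"))),
      lambda = lambda %||% 0.5, delay = d, calib = calib,
      name = "geminate_demo", duration = 4
    )
  )
  model$params$sigma_global <- sigma_global
  model$params$sigma_local <- sigma_local
  if (!is.null(lambda) && !name %in% c("fig9d_hybrid_cvc", "fig11_three_cv",
                                       "fig12_multiword",
                                       "fig13_rate_utterance",
                                       "geminate_demo")) {
    model$params$lambda_attention <- lambda
    model$params$lambda_pace <- lambda
  }
  validate_model(model)
  model
}

gestures_tbl <- function(ids, roles = NA_character_, word = NA_integer_,
                         syll = NA_integer_) {
  tibble::tibble(id = ids, role = roles, word = word, syll = syll)
}

# internal integrator that deactivates its own source after a base interval
off_tir <- function(gesture, base_s, mu = NA_character_) {
  list(
    tir = tibble::tibble(id = paste0("Tint_", gesture, "_off"),
                         class = "T_int", rate = 1, source = gesture,
                         mu = mu),
    act = tibble::tibble(tir = paste0("Tint_", gesture, "_off"),
                         target = gesture, effect = "close", tau = base_s)
  )
}

model_fig5 <- function() {
  tirs <- tibble::tibble(
    id = c("eps_prime", "eps_1", "Tint_2"),
    class = c("eps", "eps", "T_int"),
    rate = 1,
    source = c(NA, NA, "g2")
  )
  actions <- tibble::tibble(
    tir = c("eps_prime", "eps_prime", "eps_1", "Tint_2"),
    target = c("g1", "g2", "g1", "g2"),
    effect = c("open", "open", "close", "close"),
    tau = c(0.1, 0.1, 0.35, 0.25)
  )
  new_tir_model("fig5", gestures_tbl(c("g1", "g2")), tirs, actions,
                duration = 1)
}

model_fig6 <- function(d) {
  tirs <- tibble::tibble(
    id = c("eps_prime", "Tintra_1", "Tint_1", "Text_2"),
    class = c("eps", "T_intra", "T_int", "T_ext"),
    rate = 1,
    source = c(NA, "g1", "g1", "g2"),
    delay = c(0, 0, 0, d)
  )
  actions <- tibble::tibble(
    tir = c("eps_prime", "Tintra_1", "Tint_1", "Text_2"),
    target = c("g1", "g1", "g2", "g2"),
    effect = c("open", "close", "open", "close"),
    tau = c(0.1, 0.3, 0.15, 0.2)
  )
  new_tir_model("fig6", gestures_tbl(c("g1", "g2")), tirs, actions,
                duration = 1.2)
}

# fig7 coupling: th1 and th3 repulsively coupled, both attracted to th2;
# stable symmetric equilibrium at +/- pi/3 around th2, initialized there.
model_fig7 <- function(f_hz = 5, attract = 1, repel = -1) {
  omega <- 2 * pi * f_hz
  phi <- acos(attract / (2 * abs(repel)))  # equilibrium displacement
  base <- pi / 2
  tirs <- dplyr::bind_rows(
    tibble::tibble(
      id = c("th1", "th2", "th3"), class = "osc", rate = omega,
      phase0 = c(base + phi, base, base - phi)
    ),
    off_tir("g1", 0.15)$tir, off_tir("g2", 0.15)$tir, off_tir("g3", 0.15)$tir
  )
  actions <- dplyr::bind_rows(
    tibble::tibble(tir = c("th1", "th2", "th3"),
                   target = c("g1", "g2", "g3"),
                   effect = "open", tau = NA_real_),
    off_tir("g1", 0.15)$act, off_tir("g2", 0.15)$act, off_tir("g3", 0.15)$act
  )
  Phi <- matrix(c(0, attract, repel,
                  attract, 0, attract,
                  repel, attract, 0),
                3, 3, byrow = TRUE,
                dimnames = list(c("th1", "th2", "th3"),
                                c("th1", "th2", "th3")))
  new_tir_model("fig7", gestures_tbl(c("g1", "g2", "g3")), tirs, actions,
                coupling = Phi,
                intervals = tibble::tibble(name = c("d12", "d23"),
                                           from = c("g1", "g2"),
                                           to = c("g2", "g3")),
                duration = 1)
}

model_fig8 <- function(variant, d) {
  g <- gestures_tbl(c("g1", "g2", "g3"))
  # gestures stay active long enough for downstream integrators to act
  offs <- lapply(c("g1", "g2", "g3"), off_tir, base_s = 0.5)
  off_tirs <- dplyr::bind_rows(lapply(offs, `[[`, "tir"))
  off_acts <- dplyr::bind_rows(lapply(offs, `[[`, "act"))
  ivs <- tibble::tibble(name = c("d12", "d23"),
                        from = c("g1", "g2"), to = c("g2", "g3"))
  coupling <- NULL

  if (variant == "shared") {
    tirs <- tibble::tibble(
      id = c("eps_prime", "Tint_1"), class = c("eps", "T_int"),
      rate = 1, source = c(NA, "g1")
    )
    acts <- tibble::tibble(
      tir = c("eps_prime", "Tint_1", "Tint_1"),
      target = c("g1", "g2", "g3"),
      effect = "open", tau = c(0.05, 0.15, 0.30)
    )
  } else if (variant == "osc") {
    # strong coupling: oscillators lock well before triggering, so local
    # frequency noise perturbs the common frequency, not the phase offsets
    m7 <- model_fig7(attract = 60, repel = -60)
    m7$name <- "fig8_coupled_osc"
    return(m7)
  } else if (variant %in% c("chain_ext", "chain_int")) {
    cl <- if (variant == "chain_ext") "T_ext" else "T_int"
    dd <- if (variant == "chain_ext") d else 0
    tirs <- tibble::tibble(
      id = c("eps_prime", "T_1", "T_2"),
      class = c("eps", cl, cl),
      rate = 1, source = c(NA, "g1", "g2"), delay = c(0, dd, dd)
    )
    acts <- tibble::tibble(
      tir = c("eps_prime", "T_1", "T_2"),
      target = c("g1", "g2", "g3"),
      effect = "open", tau = c(0.05, 0.15, 0.15)
    )
  } else if (variant == "independent") {
    tirs <- tibble::tibble(
      id = c("eps_1", "eps_2", "eps_3"), class = "eps", rate = 1
    )
    acts <- tibble::tibble(
      tir = c("eps_1", "eps_2", "eps_3"),
      target = c("g1", "g2", "g3"),
      effect = "open", tau = c(0.2, 0.4, 0.6)
    )
  } else if (variant == "hybrid") {
    tirs <- tibble::tibble(
      id = c("eps_1", "eps_2"), class = "eps", rate = 1
    )
    acts <- tibble::tibble(
      tir = c("eps_1", "eps_2", "eps_1"),
      target = c("g1", "g2", "g3"),
      effect = "open", tau = c(0.2, 0.4, 0.6)
    )
  }
  new_tir_model(paste0("fig8_", variant),
                g, dplyr::bind_rows(tirs, off_tirs),
                dplyr::bind_rows(acts, off_acts),
                coupling = coupling, intervals = ivs, duration = 1.6)
}

expand_syllable <- function(s) {
  if (is.character(s) && length(s) == 1L) {
    switch(s,
      CV = c("C", "R", "V"),
      CVC = c("C", "R", "V", "c", "r"),
      stop("unknown syllable form '", s, "' (use \"CV\" or \"CVC\", or a ",
           "role vector).", call. = FALSE)
    )
  } else {
    bad <- setdiff(s, c("C", "R", "V", "c", "r"))
    if (length(bad)) stop("unknown gesture role(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    s
  }
}

#' Compile an utterance specification into a model
#'
#' The utterance mini-language: a list of words, each a character vector of
#' syllable forms (`"CV"`, `"CVC"`, or an explicit role vector drawn from
#' C, R, V, c, r). Every syllable becomes one competitively selected
#' mu-system; with `concepts = TRUE` every word becomes one concept system
#' that de-gates its member mu-systems when selected. Each syllable follows
#' the hybrid control model: prevocalic constriction (C), release (R) and
#' vocalic (V) initiations are triggered by a bank of phase-coupled
#' oscillators (C and R repulsively coupled, both attracted to V), while
#' vocalic deactivation and post-vocalic constriction (c) and release (r)
#' timing are governed by competing internal and external feedback TiRs whose
#' rates are attention-modulated. The selected mu-system is suppressed by the
#' feedback TiR that deactivates its final gesture.
#'
#' @param words List of words; each word a character vector of syllables.
#' @param concepts Build the conceptual-syntactic selection domain? (Default
#'   TRUE when there is more than one word.)
#' @param selection Build the gestural-motoric selection domain at all? With
#'   FALSE (single-syllable demonstrations) oscillator gates simply open at
#'   t = 0.
#' @param lambda Control variable driving both self-attention and pace.
#' @param delay External feedback delay in seconds.
#' @param calib Calibration constants.
#' @param name Model name.
#' @param duration Default simulated duration in seconds.
#' @return A `tir_model`.
#' @export
compile_utterance <- function(words, concepts = length(words) > 1L,
                              selection = TRUE, lambda = 0.5,
                              delay = NULL, calib = default_calibration(),
                              name = "utterance", duration = NULL) {
  d <- delay %||% calib$feedback$delay_s
  fb <- calib$feedback
  oscp <- calib$oscillators
  selp <- calib$selection

  gest <- list(); tirs <- list(); acts <- list()
  mus <- list(); mu_children <- list(); concs <- list()
  coup_names <- character(0); coup_blocks <- list()
  syll_i <- 0L

  pair_tirs <- function(src, tgt, int_base, ext_base, effect, mu_id) {
    # competing internal/external feedback route acting on the same gate
    idi <- paste0("Tint_", tgt, "_", effect)
    ide <- paste0("Text_", tgt, "_", effect)
    list(
      tir = tibble::tibble(
        id = c(idi, ide), class = c("T_int", "T_ext"), rate = 1,
        source = src, delay = c(0, d), mu = mu_id
      ),
      act = tibble::tibble(
        tir = c(idi, ide), target = tgt, effect = effect,
        tau = c(int_base, ext_base)
      )
    )
  }

  for (w in seq_along(words)) {
    word <- words[[w]]
    conc_id <- paste0("w", w)
    if (concepts) {
      concs[[w]] <- tibble::tibble(
        id = conc_id,
        a0 = selp$gradient_top - (w - 1L) * selp$gradient_step,
        rate = selp$rate, threshold = selp$threshold
      )
    }
    for (s in seq_along(word)) {
      syll_i <- syll_i + 1L
      roles <- expand_syllable(word[[s]])
      mu_id <- if (selection) paste0("mu", syll_i) else NA_character_
      ids <- paste0(roles, syll_i)
      gest[[syll_i]] <- tibble::tibble(id = ids, role = roles,
                                       word = w, syll = syll_i)

      pre <- intersect(c("C", "R", "V"), roles)
      if (!("V" %in% pre)) stop("every syllable needs a vocalic gesture.",
                                call. = FALSE)
      osc_ids <- paste0("osc_", pre, syll_i)
      phase0 <- vapply(pre, function(rl) {
        switch(rl,
               C = oscp$phase_v0_rad + oscp$phase_offset_rad,
               R = oscp$phase_v0_rad - oscp$phase_offset_rad,
               V = oscp$phase_v0_rad)
      }, numeric(1))
      if (!("C" %in% pre) && "R" %in% pre) {
        # a lone prevocalic consonant gesture leads the vowel
        phase0[pre == "R"] <- oscp$phase_v0_rad + oscp$phase_offset_rad
      }
      tirs[[paste0("osc", syll_i)]] <- tibble::tibble(
        id = osc_ids, class = "osc", rate = 2 * pi * 5, use_pace = TRUE,
        phase0 = phase0, amp_threshold = oscp$amp_threshold,
        gate0 = !selection, mu = mu_id
      )
      acts[[paste0("osc", syll_i)]] <- tibble::tibble(
        tir = osc_ids, target = paste0(pre, syll_i),
        effect = "open", tau = NA_real_
      )
      # coupling block: consonantal oscillators repel, each attracts V
      nb <- length(pre)
      blk <- matrix(0, nb, nb, dimnames = list(osc_ids, osc_ids))
      vi <- which(pre == "V")
      for (a in seq_len(nb)) for (b in seq_len(nb)) {
        if (a == b) next
        blk[a, b] <- if (a == vi || b == vi) oscp$coupling_attract
                     else oscp$coupling_repel
      }
      coup_blocks[[syll_i]] <- blk
      coup_names <- c(coup_names, osc_ids)

      add <- function(lst) {
        tirs[[length(tirs) + 1L]] <<- lst$tir
        acts[[length(acts) + 1L]] <<- lst$act
      }
      # prevocalic deactivation (internal feedback)
      if ("C" %in% pre) {
        o <- off_tir(paste0("C", syll_i), fb$on_c_off_internal_base_s, mu_id)
        add(o)
      }
      if ("R" %in% pre) {
        o <- off_tir(paste0("R", syll_i), fb$on_r_off_internal_base_s, mu_id)
        add(o)
      }
      # vocalic deactivation
      add(off_tir(paste0("V", syll_i), fb$v_off_internal_base_s, mu_id))
      # post-vocalic chain: V -> c -> r, each with competing int/ext routes
      if ("c" %in% roles) {
        add(pair_tirs(paste0("V", syll_i), paste0("c", syll_i),
                      fb$vc_internal_base_s, fb$vc_external_base_s,
                      "open", mu_id))
        # c deactivation: internal route only
        add(off_tir(paste0("c", syll_i), fb$c_off_internal_base_s, mu_id))
      }
      if ("r" %in% roles) {
        src_r <- if ("c" %in% roles) paste0("c", syll_i) else paste0("V", syll_i)
        add(pair_tirs(src_r, paste0("r", syll_i),
                      fb$cr_internal_base_s, fb$cr_external_base_s,
                      "open", mu_id))
        add(off_tir(paste0("r", syll_i), fb$r_off_internal_base_s, mu_id))
      }

      if (selection) {
        final_g <- paste0(roles[length(roles)], syll_i)
        mus[[syll_i]] <- tibble::tibble(
          id = mu_id,
          a0 = selp$gradient_top - (s - 1L) * selp$gradient_step,
          rate = selp$rate, threshold = selp$threshold,
          word = w, pos = s,
          concept = if (concepts) conc_id else NA_character_,
          final_gesture = final_g
        )
        mu_children[[mu_id]] <- osc_ids
      }
    }
  }

  n_osc <- length(coup_names)
  coupling <- matrix(0, n_osc, n_osc, dimnames = list(coup_names, coup_names))
  for (blk in coup_blocks) {
    coupling[rownames(blk), colnames(blk)] <- blk
  }

  gestures <- dplyr::bind_rows(gest)
  intervals <- interval_spec_for(gestures)

  new_tir_model(
    name,
    gestures,
    dplyr::bind_rows(tirs),
    dplyr::bind_rows(acts),
    coupling = coupling,
    mus = if (selection) dplyr::bind_rows(mus) else NULL,
    concepts = if (concepts && selection) dplyr::bind_rows(concs) else NULL,
    mu_children = if (selection) mu_children else NULL,
    params = list(lambda_attention = lambda, lambda_pace = lambda),
    intervals = intervals,
    duration = duration %||% (0.9 * syll_i + 0.6)
  )
}

# canonical within-syllable intervals from role tags
interval_spec_for <- function(gestures) {
  out <- list()
  for (s in unique(gestures$syll[!is.na(gestures$syll)])) {
    gs <- gestures[gestures$syll == s & !is.na(gestures$syll), ]
    have <- function(rl) any(gs$role == rl)
    id_of <- function(rl) gs$id[gs$role == rl][1L]
    pairs <- list(c("C", "V", "CV"), c("C", "R", "CR"), c("V", "c", "VC"),
                  c("R", "c", "Rc"), c("c", "r", "cr"))
    for (p in pairs) {
      if (have(p[1]) && have(p[2])) {
        out[[length(out) + 1L]] <- tibble::tibble(
          name = paste0(p[3], s), from = id_of(p[1]), to = id_of(p[2])
        )
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else NULL
}
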