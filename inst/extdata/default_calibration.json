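{
  "engine": { "dt": 0.001 },
  "attention": { "lambda": 0.5, "beta_internal": 1.0, "beta_external": 4.0 },
  "pace": { "lambda": 0.5, "f_min_hz": 3.0, "f_max_hz": 8.0, "slope": 0.15 },
  "oscillators": {
    "phase_offset_rad": 2.1,
    "phase_v0_rad": 1.5708,
    "coupling_attract": 0.5,
    "coupling_repel": -0.5,
    "amp_threshold": 0.5,
    "amp_rise_s": 0.05
  },
  "feedback": {
    "delay_s": 0.12,
    "vc_internal_base_s": 0.142,
    "vc_external_base_s": 0.03,
    "v_off_internal_base_s": 0.30,
    "cr_internal_base_s": 0.10,
    "cr_external_base_s": 0.01,
    "c_off_internal_base_s": 0.10,
    "r_off_internal_base_s": 0.08,
    "on_c_off_internal_base_s": 0.10,
    "on_r_off_internal_base_s": 0.12
  },
  "selection": {
    "rate": 1.0,
    "threshold": 1.0,
    "gradient_top": 0.9,
    "gradient_step": 0.1
  },
  "boosts": { "word_final": 1.2, "utterance_final": 1.6 },
  "noise": {
    "sigma_global": 0.0,
    "sigma_local": 0.0,
    "grid": [0.0, 0.025, 0.05, 0.075, 0.1]
  }
}
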