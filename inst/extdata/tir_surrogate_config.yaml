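# Surrogate coefficients for the built-in RBS window scorer.
# SYNTHETIC: these values encode the qualitative preferences of empirical
# E. coli ribosome-binding-site models (purine-rich upstream context,
# Shine-Dalgarno complementarity at a ~5-7 nt spacer) and are NOT the
# regression coefficients of any published calculator. Only sign-level
# comparisons between windows should be interpreted. Replace this file to
# supply calibrated coefficients.
window: [-11, 1]
sd_consensus: AGGAGG
asd_weight: 0.8
spacing_penalty: 0.35
optimal_spacing: 5
position_weights:
  "-11": {A: 0.12, C: -0.10, G: 0.10, T: -0.05}
  "-10": {A: 0.14, C: -0.12, G: 0.12, T: -0.06}
  "-9":  {A: 0.16, C: -0.14, G: 0.18, T: -0.08}
  "-8":  {A: 0.18, C: -0.16, G: 0.22, T: -0.10}
  "-7":  {A: 0.20, C: -0.18, G: 0.24, T: -0.10}
  "-6":  {A: 0.20, C: -0.18, G: 0.24, T: -0.10}
  "-5":  {A: 0.18, C: -0.16, G: 0.20, T: -0.08}
  "-4":  {A: 0.22, C: -0.14, G: 0.08, T: -0.04}
  "-3":  {A: 0.25, C: -0.12, G: 0.05, T: -0.02}
  "-2":  {A: 0.20, C: -0.10, G: 0.02, T: 0.04}
  "-1":  {A: 0.15, C: -0.08, G: 0.00, T: 0.06}
  "0":   {A: 0.30, C: -0.30, G: -0.10, T: -0.10}
  "1":   {A: -0.10, C: -0.10, G: -0.10, T: 0.30}
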