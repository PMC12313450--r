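# Fully synthetic one-compartment demonstration model. Used by the test suite
# so that transcription-independent properties (analytic-vs-ODE agreement,
# %fT>MIC crossing logic, PTA monotonicity, NPDE/pcVPC calibration, MAP
# recovery) never depend on any real drug's parameter values.
drug: demo
n_compartments: 1
typical_values:
  CL: 0.2    # L/h at 1 kg, full maturation
  V: 1.0     # L at 1 kg
covariate_effects:
  - {parameter: CL, covariate: birth_weight, kind: allometric_power, reference: 1.0, exponent: 0.75}
  - {parameter: V,  covariate: birth_weight, kind: allometric_power, reference: 1.0, exponent: 1.0}
  - {parameter: CL, covariate: PMA, kind: sigmoid_maturation, pma50: 40, gamma: 2}
omega:
  CL: 0.09
  V: 0.04
residual_error:
  proportional_sd: 0.15
  additive_sd: 0.2
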