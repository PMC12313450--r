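# SYNTHETIC neonatal benzylpenicillin parameter set.
#
# Structure follows the published neonatal benzylpenicillin model selected for
# simulation work in this field: two disposition compartments, clearance with
# allometric birth-weight scaling (exponent 0.75) and sigmoidal
# postmenstrual-age maturation, volumes scaling linearly with birth weight.
# The NUMERIC values are NOT transcribed from any published model; they are a
# literature-plausible synthetic set (Vss ~0.6 L/kg; half-life ~3 h at term,
# ~5 h in extremely preterm neonates). Replace with a transcribed parameter
# set for inference about a specific published model.
drug: benzylpenicillin
n_compartments: 2
typical_values:
  CL: 0.76      # L/h at 1.75 kg reference, full maturation
  V: 0.6125     # L central at 1.75 kg (0.35 L/kg)
  Q: 0.4        # L/h at 1.75 kg
  V2: 0.4375    # L peripheral at 1.75 kg (0.25 L/kg)
covariate_effects:
  - {parameter: CL, covariate: birth_weight, kind: allometric_power, reference: 1.75, exponent: 0.75}
  - {parameter: Q,  covariate: birth_weight, kind: allometric_power, reference: 1.75, exponent: 0.75}
  - {parameter: V,  covariate: birth_weight, kind: allometric_power, reference: 1.75, exponent: 1.0}
  - {parameter: V2, covariate: birth_weight, kind: allometric_power, reference: 1.75, exponent: 1.0}
  - {parameter: CL, covariate: PMA, kind: sigmoid_maturation, pma50: 45, gamma: 3}
omega:
  CL: 0.12    # ~36% CV
  V: 0.06
residual_error:
  proportional_sd: 0.25
  additive_sd: 0.3
covariate_ranges:
  PMA: [24, 43]
  birth_weight: [0.4, 5.0]
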