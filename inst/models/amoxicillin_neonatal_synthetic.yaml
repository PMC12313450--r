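# SYNTHETIC neonatal amoxicillin parameter set.
#
# Structure follows the published neonatal amoxicillin models selected for
# simulation work in this field: one disposition compartment, clearance with
# allometric birth-weight scaling (exponent 0.75), sigmoidal postmenstrual-age
# maturation and a linear postnatal-age effect, volume scaling linearly with
# birth weight. The NUMERIC values below are NOT transcribed from any single
# published model; they are a literature-plausible synthetic set chosen to
# give realistic neonatal amoxicillin kinetics (V ~0.6 L/kg; half-life ~4 h at
# term falling from ~10 h in extremely preterm neonates; renal-type PMA
# maturation). Replace with a transcribed parameter set for inference about a
# specific published model.
drug: amoxicillin
n_compartments: 1
typical_values:
  CL: 0.59    # L/h at 1.75 kg reference, full maturation, PNA 0
  V: 1.05     # L at 1.75 kg (0.6 L/kg)
covariate_effects:
  - {parameter: CL, covariate: birth_weight, kind: allometric_power, reference: 1.75, exponent: 0.75}
  - {parameter: V,  covariate: birth_weight, kind: allometric_power, reference: 1.75, exponent: 1.0}
  - {parameter: CL, covariate: PMA, kind: sigmoid_maturation, pma50: 47.7, gamma: 3.4}
  - {parameter: CL, covariate: PNA, kind: linear, slope: 0.2}   # per day
omega:
  CL: 0.09    # ~30% CV
  V: 0.05
residual_error:
  proportional_sd: 0.2
  additive_sd: 0.5
covariate_ranges:
  PMA: [24, 43]
  birth_weight: [0.4, 5.0]
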