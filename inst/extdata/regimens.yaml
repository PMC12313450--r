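# Dosing-regimen catalog for early-onset neonatal sepsis, first 48 h of life.
#
# Each regimen: drug, mode (intermittent | continuous), dose_unit (mg | IU),
# infusion_duration (h; bolus = 5-min infusion), and a list of mutually
# exclusive, exhaustive rules. Rule predicates on birth weight (kg) and GA
# (weeks): *_min is inclusive, *_max exclusive. Intermittent rules carry
# dose_per_kg + interval (h); continuous rules carry daily_dose_per_kg, with a
# top-level loading_fraction of the total daily dose given as a 5-min infusion
# at t = 0 concurrent with the continuous rate.
#
# Entries with "status: stub" are placeholders for formularies whose numeric
# regimens have not been transcribed into this catalog; resolving them errors.

dpf_amoxicillin:
  drug: amoxicillin
  mode: intermittent
  dose_unit: mg
  infusion_duration: 0.0833
  rules:
    - {birth_weight_max: 2, dose_per_kg: 25, interval: 12}
    - {birth_weight_min: 2, dose_per_kg: 25, interval: 8}

dpf_benzylpenicillin:
  drug: benzylpenicillin
  mode: intermittent
  dose_unit: IU
  infusion_duration: 0.0833
  rules:
    - {birth_weight_max: 2, dose_per_kg: 25000, interval: 12}
    - {birth_weight_min: 2, dose_per_kg: 25000, interval: 8}

# GA-based intermittent alternative: 30,000 IU/kg q12h (GA <28 w),
# q8h (28 to <36 w), q6h (>=36 w; GA exactly 36 assigned to the more mature,
# more frequent stratum).
ga_based_benzylpenicillin:
  drug: benzylpenicillin
  mode: intermittent
  dose_unit: IU
  infusion_duration: 0.0833
  rules:
    - {ga_min: 24, ga_max: 28, dose_per_kg: 30000, interval: 12}
    - {ga_min: 28, ga_max: 36, dose_per_kg: 30000, interval: 8}
    - {ga_min: 36, dose_per_kg: 30000, interval: 6}

# Continuous infusion of the weight-stratified total daily dose
# (2 x 25,000 IU/kg/day below 2 kg; 3 x 25,000 IU/kg/day at/above 2 kg)
# plus a 16.7% loading dose.
continuous_benzylpenicillin:
  drug: benzylpenicillin
  mode: continuous
  dose_unit: IU
  infusion_duration: 0.0833
  loading_fraction: 0.167
  rules:
    - {birth_weight_max: 2, daily_dose_per_kg: 50000}
    - {birth_weight_min: 2, daily_dose_per_kg: 75000}

# --- other international formularies: not transcribed ------------------------
anmf_amoxicillin:        {drug: amoxicillin,      status: stub}
anmf_benzylpenicillin:   {drug: benzylpenicillin, status: stub}
bnfc_amoxicillin:        {drug: amoxicillin,      status: stub}
bnfc_benzylpenicillin:   {drug: benzylpenicillin, status: stub}
lexicomp_benzylpenicillin: {drug: benzylpenicillin, status: stub}
neofax_benzylpenicillin: {drug: benzylpenicillin, status: stub}
nf_amoxicillin:          {drug: amoxicillin,      status: stub}
nf_benzylpenicillin:     {drug: benzylpenicillin, status: stub}
ndpgh_benzylpenicillin:  {drug: benzylpenicillin, status: stub}
spd_amoxicillin:         {drug: amoxicillin,      status: stub}
spd_benzylpenicillin:    {drug: benzylpenicillin, status: stub}
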