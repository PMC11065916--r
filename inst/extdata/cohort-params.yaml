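# Default parameters of the synthetic cohort generator.
# Prevalences and log-odds coefficients encode the community population the
# screening protocol targets; factors without a reliable published estimate
# default to prevalence 0.05 and coefficient 0.
"n": 401   # quoted: a bare n is a YAML 1.1 boolean
seed: 1
age_mean: 71.0
age_sd: 6.1
age_min: 60
target_prevalence: 0.798
factor_prevalences:
  male: 0.454
  overweight_obesity: 0.05
  living_alone: 0.075
  widowed_divorced: 0.105
  noise_history: 0.05
  family_deafness: 0.05
  non_light_diet: 0.279
  no_exercise: 0.481
  smoking: 0.177
  drinking: 0.102
  headset_habit: 0.05
  hypertension: 0.643
  diabetes: 0.307
  hyperlipidemia: 0.092
  cardio_cerebrovascular: 0.244
  hyperuricemia: 0.170
  hypothyroidism: 0.05
  ototoxic_drugs: 0.05
coefficients:
  age: 0.104
  male: -0.056
  overweight_obesity: -0.081
  living_alone: 0.0
  widowed_divorced: 0.148
  noise_history: 1.357
  family_deafness: 0.0
  non_light_diet: 0.894
  no_exercise: -0.385
  smoking: 0.0
  drinking: 0.741
  headset_habit: 0.0
  hypertension: 0.609
  diabetes: 1.461
  hyperlipidemia: 0.246
  cardio_cerebrovascular: 0.362
  hyperuricemia: 1.155
  hypothyroidism: 1.645
  ototoxic_drugs: 0.0
grade_mix_given_loss:
  mild: 0.485
  moderate: 0.234
  moderately_severe: 0.078
  severe: 0.013
  profound: 0.007
hhie_mid: 42
hhie_yes_gap: 12
hhie_slope: 5
tone_slope: 3
tilt_step: 4.5
worse_ear_offset_mean: 8
profound_cap: 110
calib_n: 500000
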