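# Body-composition estimation constants, vendored as data so they can be
# audited and swapped without touching code.
#
# Body density: Withers female-athlete skinfold equation,
#   D = intercept - slope * log10(sum of the four listed folds in mm),
# converted to fat %% with the Siri (default) or Brozek transform.
# Skeletal muscle mass: Lee anthropometric model,
#   SM (kg) = stature_m * (c_arm * CAG^2 + c_thigh * CTG^2 + c_calf * CCG^2)
#             + sex_coef * sex + age_coef * age + race_coef + intercept,
# with girths corrected for the overlying fold: CG = girth_cm - pi * fold_mm / 10,
# sex coded 1 = male / 0 = female, race_coef 0 for white/Hispanic subjects.
withers_female:
  intercept: 1.20953
  slope: 0.08294
  skinfolds: [triceps, subscapular, supraspinal, medial_calf]
  density_plausible: [0.9, 1.2]
siri:
  numerator: 495.0
  offset: 450.0
brozek:
  numerator: 457.0
  offset: 414.1
lee_muscle:
  c_arm: 0.00744
  c_thigh: 0.00088
  c_calf: 0.00441
  sex_coef: 2.4
  age_coef: -0.048
  race_coef: 0.0
  intercept: 7.8
  girth_fold_pairs:
    arm_relaxed: triceps
    thigh: front_thigh
    calf: medial_calf
# Frozen worked example: outputs produced once by direct evaluation of the
# equations above on the stated record; used as a self-check that the
# vendored coefficients have not drifted.
worked_example:
  record:
    body_mass: 55.0
    stature: 168.0
    age: 21.0
    sex: female
    sf_subscapular: 8.0
    sf_triceps: 9.0
    sf_supraspinal: 6.0
    sf_abdominal: 11.0
    sf_front_thigh: 16.0
    sf_medial_calf: 9.0
    g_arm_relaxed: 26.0
    g_arm_flexed: 27.5
    g_thigh: 54.0
    g_calf: 34.0
  expected:
    sum6: 59.0
    density: 1.08469286
    fat_pct_siri: 6.35038073
    muscle_mass: 24.24880666
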