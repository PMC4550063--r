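# Guideline configuration for the chest-pain decision support engine.
#
# ptp_table transcribes NICE CG95 Table 1 (percentage of people estimated to
# have coronary artery disease, by sex, age band, pain typicality and
# risk-factor status). investigation_bands transcribe the CG95 investigation
# thresholds; the band above 90 carries the guideline's "no further
# diagnostic investigation" and is overridden by the expert-panel rule
# (panel_threshold: any PTP strictly above it is referred for invasive
# angiography). medication_rules are an editable stand-in for the expert
# panel's unpublished prescribing rules, keyed by (typicality, PTP band).
#
# The engine enforces structural invariants only (bands partition [0,100];
# the PTP table is total and monotone in risk and typicality); every number
# here may be edited without touching code.

age_bands:
  edges: [45, 55, 65]            # cut-points; ages clamp into the outer bands
  labels: [age_35_44, age_45_54, age_55_64, age_65_plus]

ptp_table:
  male:
    age_35_44:
      typical:     {low: 30, high: 88}
      atypical:    {low: 8,  high: 59}
      non_anginal: {low: 3,  high: 35}
    age_45_54:
      typical:     {low: 51, high: 92}
      atypical:    {low: 21, high: 70}
      non_anginal: {low: 9,  high: 47}
    age_55_64:
      typical:     {low: 80, high: 95}
      atypical:    {low: 45, high: 79}
      non_anginal: {low: 23, high: 59}
    age_65_plus:
      typical:     {low: 93, high: 97}
      atypical:    {low: 71, high: 86}
      non_anginal: {low: 49, high: 69}
  female:
    age_35_44:
      typical:     {low: 10, high: 78}
      atypical:    {low: 2,  high: 39}
      non_anginal: {low: 1,  high: 19}
    age_45_54:
      typical:     {low: 20, high: 79}
      atypical:    {low: 5,  high: 43}
      non_anginal: {low: 2,  high: 22}
    age_55_64:
      typical:     {low: 38, high: 82}
      atypical:    {low: 10, high: 47}
      non_anginal: {low: 4,  high: 25}
    age_65_plus:
      typical:     {low: 56, high: 84}
      atypical:    {low: 20, high: 51}
      non_anginal: {low: 9,  high: 29}

# Half-open [lo, hi) bands; the top band is closed at 100.
investigation_bands:
  - {name: ptp_lt_10,  lo: 0,  hi: 10,  investigation: none}
  - {name: ptp_10_29,  lo: 10, hi: 30,  investigation: ct_calcium_scoring}
  - {name: ptp_30_60,  lo: 30, hi: 61,  investigation: functional_imaging}
  - {name: ptp_61_90,  lo: 61, hi: 91,  investigation: invasive_angiography}
  - {name: ptp_gt_90,  lo: 91, hi: 100, investigation: none}

panel_threshold: 90

# Risk flags contributing to high-risk stratification. Whether an abnormal
# resting ECG counted as a high-risk marker in the original tool is not
# documented; it defaults to counting and can be removed here.
risk_flags: [smoker, diabetes, hyperlipidaemia, ecg_abnormal]

# Stand-in panel rules: secondary-prevention classes scale with the
# likelihood of coronary disease and the typicality of symptoms.
medication_rules:
  typical:
    ptp_lt_10:  []
    ptp_10_29:  [antiplatelet, statin]
    ptp_30_60:  [antiplatelet, statin, beta_blocker]
    ptp_61_90:  [antiplatelet, statin, beta_blocker]
    ptp_gt_90:  [antiplatelet, statin, beta_blocker]
  atypical:
    ptp_lt_10:  []
    ptp_10_29:  [statin]
    ptp_30_60:  [antiplatelet, statin]
    ptp_61_90:  [antiplatelet, statin, beta_blocker]
    ptp_gt_90:  [antiplatelet, statin, beta_blocker]
  non_anginal:
    ptp_lt_10:  []
    ptp_10_29:  []
    ptp_30_60:  [statin]
    ptp_61_90:  [antiplatelet, statin]
    ptp_gt_90:  [antiplatelet, statin]
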