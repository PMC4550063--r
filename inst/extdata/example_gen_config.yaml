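# Example cohort-generator configuration for the `simulate` subcommand.
# Values mirror the baseline characteristics of the pre-intervention clinic
# population; seed is supplied on the command line (--seed).
"n": 500     # quoted: a bare n is a YAML 1.1 boolean
age_mean: 59.4
age_sd: 11.0
p_male: 0.49
p_smoker: 0.41
p_diabetes: 0.08
p_hyperlipidaemia: 0.32
p_ecg_abnormal: 0.05        # not reported for the source population; assumption
typicality_probs:
  typical: 0.19
  atypical: 0.16
  non_anginal: 0.65
baseline_med_probs:
  antiplatelet: 0.22
  beta_blocker: 0.05
  statin: 0.25
p_cdss_used: 0.86
group: before
site: site_a
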