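# Example adherence model for the `simulate` subcommand: post-intervention
# behaviour (59% of recommended investigations done; 14% investigated despite
# a "none" recommendation; half of recommended medication classes adopted).
p_follow_investigation_recommended: 0.59
p_investigate_when_not_recommended: 0.14
p_follow_medication: 0.50
p_cdss_used: 0.86
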