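cadre,wage_low,wage_mid,wage_high
NURSING_SISTER,0.24,0.26,0.27
NURSE,0.12,0.16,0.20
NURSE_ASSISTANT,0.11,0.11,0.12
PHLEBOTOMIST,0.055,0.063,0.072
HTS_COUNSELOR,0.047,0.047,0.047
PEER_SUPPORTER,0.014,0.014,0.014
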