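term,estimate,ci_low,ci_high
constant,8.8,6.1,12
PRE_COUNSELING,3.0,-1.3,7.2
RISK_ASSESSMENT,1.8,-2.6,6.1
ELIGIBILITY_SCREENING,3.2,0.0042,6.4
INITIATION,8.9,4.8,13
FOLLOWUP_COUNSELING,4.1,1.2,7.0
BLOOD_TESTING,3.2,1.3,5.0
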