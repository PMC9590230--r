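term,estimate,ci_low,ci_high
constant,8.9,5.8,12
PRE_COUNSELING,4.3,-0.14,8.7
RISK_ASSESSMENT,3.3,-1.4,7.9
ELIGIBILITY_SCREENING,3.8,0.37,7.2
INITIATION,11,6.9,16
FOLLOWUP_COUNSELING,4.7,1.7,7.7
BLOOD_TESTING,4.0,1.8,6.2
n_activities,-1.5,-2.7,-0.30
interrupted,3.4,0.69,6.0
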