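group,n,completion_pct,placebo_completion_pct,printed_adjusted
PALI_6_12,179,64.8,36.8,28.0
RIS_2_4,113,54.0,51.6,2.4
RIS_4_6,129,66.7,51.6,15.1
PLACEBO_PALI,95,36.8,,
PLACEBO_RIS,122,51.6,,
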