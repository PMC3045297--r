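group,response_pct
PALI_6_12,55.1
RIS_2_4,40.7
RIS_4_6,51.6
POOLED_PLACEBO,28.1
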