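comparison,group_a,group_b,printed_difference
PALI_vs_RIS_2_4,PALI_6_12,RIS_2_4,14.4
PALI_vs_RIS_4_6,PALI_6_12,RIS_4_6,3.5
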