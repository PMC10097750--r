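comparison	up	down	ns
T1D_T0_SMT0	149	1208	5255
T1W_T0_SMT0	17	6436	159
T2W_T0_SMT0	21	6360	231
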